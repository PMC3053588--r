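# Accuracy estimation. Site-level matching uses the +/-12 nt criterion: a
# predicted CS within 24 nt (+/- 12) of a mapped site is a true positive.
# Sequence-level negative counting: a negative sequence with at least one
# predicted site is one false positive, otherwise one true negative.

#' Construct a confusion-count object
#'
#' @param tp,fp,tn,fn non-negative counts; `tn`/`fn` may be `NA` when the
#'   context defines no such notion (site-level scans have no TN).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, tn = NA_integer_,
                             fn = NA_integer_) {
  stopifnot(all(c(tp, fp, tn, fn) >= 0L, na.rm = TRUE))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Match predictions to mapped cleavage sites
#'
#' Greedy one-to-one matching, nearest pairs first: every truth site is
#' matched to at most one prediction within `tolerance` nt. Matched pairs
#' are TP, unmatched truth sites FN, unmatched predictions FP.
#'
#' @param truth data.frame with `seq_id` and `cs_index` (0-based) of mapped
#'   sites.
#' @param predictions prediction data.frame (as from [scan_sequence()]/[resolve()]).
#' @param tolerance maximum distance in nt (default 12).
#' @return `confusion_counts` with `tp`, `fp`, `fn` (`tn` = NA).
#' @export
match_predictions <- function(truth, predictions, tolerance = 12L) {
  if (nrow(predictions) > 0L &&
      !all(predictions$seq_id %in% truth$seq_id))
    stop("predictions refer to sequence ids absent from the truth table: ",
         paste(setdiff(predictions$seq_id, truth$seq_id), collapse = ", "))
  pairs <- NULL
  if (nrow(truth) > 0L && nrow(predictions) > 0L) {
    pairs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(ti) {
      sel <- which(predictions$seq_id == truth$seq_id[ti])
      d <- abs(predictions$cs_index[sel] - truth$cs_index[ti])
      ok <- d <= tolerance
      if (!any(ok)) return(NULL)
      data.frame(ti = ti, pi = sel[ok], d = d[ok])
    }))
  }
  tp <- 0L
  used_t <- logical(nrow(truth))
  used_p <- logical(nrow(predictions))
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    pairs <- pairs[order(pairs$d, pairs$ti, pairs$pi), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$ti[k]; pi <- pairs$pi[k]
      if (!used_t[ti] && !used_p[pi]) {
        used_t[ti] <- TRUE
        used_p[pi] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  confusion_counts(tp = tp, fp = sum(!used_p), fn = sum(!used_t))
}

#' Sequence-level counts on a negative set
#'
#' @param negatives list of `genomic_seq` (or character vector of their ids)
#'   that were scanned.
#' @param predictions prediction data.frame from scanning exactly these
#'   sequences.
#' @return `confusion_counts` with `tn` and `fp` (sequence-level; `tp`,
#'   `fn` = 0/NA).
#' @export
negative_set_counts <- function(negatives, predictions) {
  ids <- if (is.character(negatives)) negatives
         else vapply(negatives, `[[`, "", "id")
  hit <- ids %in% predictions$seq_id
  confusion_counts(tp = 0L, fp = sum(hit), tn = sum(!hit))
}

#' Accuracy metrics from confusion counts
#'
#' `Sn^p = TP/(TP+FN)`, `Sn^n = TN/(TN+FP)`, `Sp = TP/(TP+FP)` (as
#' percentages) and the correlation coefficient
#' `CC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`. A metric
#' whose denominator is zero (or whose counts are NA) is `NA`. Values are
#' full precision; round only at reporting surfaces.
#'
#' @param counts a `confusion_counts` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return list with `sn_p`, `sn_n`, `sp` (percent) and `cc`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  rat <- function(num, den) if (anyNA(den) || den == 0) NA_real_ else num / den
  denom <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  cc <- if (anyNA(denom) || denom == 0) NA_real_
        else (tp * tn - fp * fn) / sqrt(denom)
  list(sn_p = 100 * rat(tp, tp + fn),
       sn_n = 100 * rat(tn, tn + fp),
       sp = 100 * rat(tp, tp + fp),
       cc = cc)
}

#' Format metrics at reporting precision
#'
#' Percentages to one decimal, CC to two decimals.
#'
#' @param metrics list from [compute_metrics()].
#' @return named character vector.
#' @export
format_metrics <- function(metrics) {
  fmt <- function(x, d) if (is.na(x)) "NA" else formatC(round(x, d), format = "f",
                                                        digits = d)
  c(sn_p = fmt(metrics$sn_p, 1L), sn_n = fmt(metrics$sn_n, 1L),
    sp = fmt(metrics$sp, 1L), cc = fmt(metrics$cc, 2L))
}

#' Evaluate a trained bundle on labeled test data
#'
#' Per class: scans each positive test record with that class's classifier,
#' resolves, and matches against the true CS with the `+/- tolerance`
#' criterion; scans the class's negative records and counts sequences with
#' at least one call. This mirrors the per-class testing protocol used for
#' the initial accuracy tables.
#'
#' @param bundle trained `classifier_bundle`.
#' @param positives named list per class of `polya_record` test positives.
#' @param negatives named list per class of `polya_record` test negatives.
#' @param tolerance site matching tolerance (default 12).
#' @param min_separation resolution distance (default 100).
#' @return named list per class: `site_counts`, `neg_counts`, `metrics`
#'   (with `sn_p` from site counts, `sn_n` from sequence counts, and `cc`
#'   from the combined quadruple).
#' @export
evaluate_bundle <- function(bundle, positives, negatives, tolerance = 12L,
                            min_separation = 100L) {
  out <- list()
  for (cl in intersect(CLASS_LABELS, names(positives))) {
    preds <- do.call(rbind, lapply(positives[[cl]], function(r)
      resolve(scan_sequence(r$sequence, bundle, classes = cl), min_separation)))
    if (is.null(preds)) preds <- empty_predictions()
    truth <- data.frame(
      seq_id = vapply(positives[[cl]], function(r) r$sequence$id, ""),
      cs_index = vapply(positives[[cl]], `[[`, 0L, "cs_index"))
    site <- match_predictions(truth, preds, tolerance)
    npred <- do.call(rbind, lapply(negatives[[cl]], function(r)
      resolve(scan_sequence(r$sequence, bundle, classes = cl), min_separation)))
    if (is.null(npred)) npred <- empty_predictions()
    neg <- negative_set_counts(lapply(negatives[[cl]], `[[`, "sequence"), npred)
    combined <- confusion_counts(tp = site$tp, fp = site$fp + neg$fp,
                                 tn = neg$tn, fn = site$fn)
    m <- compute_metrics(combined)
    m$sn_p <- compute_metrics(site)$sn_p
    m$sn_n <- compute_metrics(neg)$sn_n
    out[[cl]] <- list(site_counts = site, neg_counts = neg, metrics = m)
  }
  out
}

#' Write an evaluation report TSV
#'
#' One row per class: TP, FN, Sn^p, TN, FP (sequence-level), Sn^n, Sp, CC,
#' mirroring the initial-testing table layout.
#'
#' @param results list from [evaluate_bundle()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  rows <- lapply(names(results), function(cl) {
    r <- results[[cl]]
    f <- format_metrics(r$metrics)
    data.frame(class = cl, TP = r$site_counts$tp, FN = r$site_counts$fn,
               Sn_p = f["sn_p"], TN = r$neg_counts$tn, FP = r$neg_counts$fp,
               Sn_n = f["sn_n"], Sp = f["sp"], CC = f["cc"])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
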