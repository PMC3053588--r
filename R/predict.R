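# Genome scanning. Every position of the input is treated as a candidate CS
# (+1) and evaluated by the cascade of class discriminants: PAS-strong first
# (subject to the PAS gate in [-40:-1]), then PAS-weak, then PAS-less.
# Surviving calls closer than the resolution distance are thinned by class
# precedence and score. For speed the scanner precomputes per-sequence
# placement-score tracks for every PWM and cumulative-sum pentamer tracks, so
# each candidate position costs a few short-range vector operations; the
# per-window reference path (assemble_features + ldf_score) computes
# identical numbers and is cross-checked in the tests.

# Cumulative pentamer-score structure for one table over one sequence:
# region mean = (csum[b+1]-csum[a]) / (cnt[b+1]-cnt[a]) over 1-based
# pentamer start positions a..b; windows containing N are excluded.
penta_cumsum <- function(table, residues) {
  ids <- pentamer_ids(residues)
  v <- table$P[ids]
  ok <- !is.na(v)
  list(csum = c(0, cumsum(ifelse(ok, v, 0))), cnt = c(0, cumsum(ok)))
}

penta_mean <- function(pc, a, b) {
  n <- pc$cnt[b + 1L] - pc$cnt[a]
  if (n < 1L) return(0.5)
  (pc$csum[b + 1L] - pc$csum[a]) / n
}

# Max over track[s1:s2] with ties broken at the largest index (the placement
# closest to the CS for upstream regions); returns c(start, score).
track_best <- function(track, s1, s2) {
  seg <- track[s1:s2]
  j <- which(seg == max(seg))
  j <- j[length(j)]
  c(s1 + j - 1L, seg[j])
}

empty_predictions <- function() {
  data.frame(seq_id = character(0), cs_index = integer(0),
             class_label = character(0), z = numeric(0),
             pas_offset = integer(0), pas_score = numeric(0),
             guu_offset = integer(0), guu_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for candidate cleavage sites (pre-resolution)
#'
#' Evaluates every position where a class window fits, in cascade order
#' strong, weak, less; at most one prediction is emitted per position. For
#' the strong and weak classes a position is a candidate only when its best
#' PAS placement in `[-40:-1]` reaches the class gate.
#'
#' @param seq a `genomic_seq`.
#' @param bundle a trained `classifier_bundle`.
#' @param classes subset of class labels to scan with (default all three).
#' @return data.frame of predictions: `seq_id`, `cs_index` (0-based),
#'   `class_label`, `z`, `pas_offset`/`pas_score` (NA for PAS-less),
#'   `guu_offset`/`guu_score`. Offsets are CS-relative coordinates.
#' @export
scan_sequence <- function(seq, bundle, classes = CLASS_LABELS) {
  if (is.null(bundle$ldf_strong)) stop("bundle is not trained")
  classes <- match.arg(classes, CLASS_LABELS, several.ok = TRUE)
  enc <- encode_dna(seq$residues)
  L <- length(enc)
  g1 <- bundle$config$guu_region[1]; g2 <- bundle$config$guu_region[2]

  tr <- list(
    pas_strong = pwm_track(bundle$pas_pwm_strong, enc),
    pas_weak = pwm_track(bundle$pas_pwm_weak, enc),
    guu = pwm_track(bundle$guu_pwm, enc),
    cs18 = pwm_track(bundle$cs_pwm_strongweak, enc),
    cs12 = pwm_track(bundle$cs_pwm_less, enc))
  pc <- list(
    strong_up = penta_cumsum(bundle$penta$`PAS-strong`$up, seq$residues),
    weak_up = penta_cumsum(bundle$penta$`PAS-weak`$up, seq$residues),
    weak_down = penta_cumsum(bundle$penta$`PAS-weak`$down, seq$residues),
    less_up = penta_cumsum(bundle$penta$`PAS-less`$up, seq$residues),
    less_down = penta_cumsum(bundle$penta$`PAS-less`$down, seq$residues))

  # i is the 0-based candidate CS index; 1-based parent position of
  # coordinate p is i + p for p >= 1 and i + p + 1 for p <= -1.
  guu_at <- function(i) {
    s2 <- min(i + g2 - 9L, length(tr$guu))          # leftmost <= g2 - 9
    track_best(tr$guu, i + g1, s2)
  }
  pas_at <- function(i, track) track_best(track, i - 39L, i - 5L)

  rows <- vector("list", 64L)
  nr <- 0L
  emit <- function(i, cl, z, pas, guu) {
    nr <<- nr + 1L
    rows[[nr]] <<- data.frame(
      seq_id = seq$id, cs_index = i, class_label = cl, z = z,
      pas_offset = if (is.null(pas)) NA_integer_ else (pas[1] - 1L) - i,
      pas_score = if (is.null(pas)) NA_real_ else pas[2],
      guu_offset = if (is.null(guu)) NA_integer_ else guu[1] - i,
      guu_score = if (is.null(guu)) NA_real_ else guu[2],
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(L)) {          # i as 0-based cs index: 1 .. L-1 range below
    ci <- i - 1L
    # PAS-strong: window [-100:+50]
    if ("PAS-strong" %in% classes && ci >= 100L && ci + 50L <= L) {
      pas <- pas_at(ci, tr$pas_strong)
      if (pas[2] >= bundle$pas_gate_strong) {
        Lo <- (pas[1] - 1L) - ci                    # CS-relative offset of leftmost
        guu <- guu_at(ci)
        a0 <- ci + Lo - 60L + 1L                    # pentamer region start
        x <- c(pas[2], tr$cs18[ci - 14L], guu[2],
               penta_mean(pc$strong_up, a0, a0 + 55L),
               distance_score(bundle$dist$`PAS-strong`$pas_cs, -4L - Lo),
               distance_score(bundle$dist$`PAS-strong`$cs_guu, guu[1] - ci - 1L))
        z <- sum(bundle$ldf_strong$a * x)
        if (z > bundle$ldf_strong$operating_threshold) {
          emit(ci, "PAS-strong", z, pas, guu)
          next
        }
      }
    }
    # PAS-weak: window [-60:+60]
    if ("PAS-weak" %in% classes && ci >= 60L && ci + 60L <= L) {
      pas <- pas_at(ci, tr$pas_weak)
      if (pas[2] >= bundle$pas_gate_weak) {
        Lo <- (pas[1] - 1L) - ci
        guu <- guu_at(ci)
        x <- c(pas[2], tr$cs18[ci - 14L], guu[2],
               penta_mean(pc$weak_up, ci - 59L, ci - 4L),
               distance_score(bundle$dist$`PAS-weak`$pas_cs, -4L - Lo),
               distance_score(bundle$dist$`PAS-weak`$cs_guu, guu[1] - ci - 1L),
               penta_mean(pc$weak_down, ci + 2L, ci + 56L))
        z <- sum(bundle$ldf_weak$a * x)
        if (z > bundle$ldf_weak$operating_threshold) {
          emit(ci, "PAS-weak", z, pas, guu)
          next
        }
      }
    }
    # PAS-less: window [-60:+100]
    if ("PAS-less" %in% classes && ci >= 60L && ci + 100L <= L) {
      guu <- guu_at(ci)
      x <- c(tr$cs12[ci - 8L], guu[2],
             penta_mean(pc$less_up, ci - 59L, ci - 4L),
             penta_mean(pc$less_down, ci + 2L, ci + 96L),
             distance_score(bundle$dist$`PAS-less`$cs_guu, guu[1] - ci - 1L))
      z <- sum(bundle$ldf_less$a * x)
      if (z > bundle$ldf_less$operating_threshold)
        emit(ci, "PAS-less", z, NULL, guu)
    }
  }
  if (nr == 0L) return(empty_predictions())
  do.call(rbind, rows[seq_len(nr)])
}

#' Resolve nearby predictions
#'
#' Enforces, for every pair of predictions within `min_separation` bp of each
#' other, the class precedence strong > weak > less; within the same class
#' the higher score wins, ties going to the smaller coordinate. Implemented
#' as a global greedy sweep: predictions are ranked by (class precedence,
#' `z` descending, `cs_index` ascending) and accepted iff no
#' already-accepted prediction lies within `min_separation` bp.
#'
#' @param predictions data.frame from [scan_sequence()] (one sequence).
#' @param min_separation conflict distance in bp (default 100).
#' @return resolved predictions, sorted by `cs_index`.
#' @export
resolve <- function(predictions, min_separation = 100L) {
  if (nrow(predictions) <= 1L) return(predictions)
  prec <- match(predictions$class_label, CLASS_LABELS)
  ord <- order(prec, -predictions$z, predictions$cs_index)
  accepted <- integer(0)
  for (k in ord) {
    if (!any(abs(predictions$cs_index[accepted] - predictions$cs_index[k]) <=
             min_separation))
      accepted <- c(accepted, k)
  }
  out <- predictions[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a FASTA file and write predictions
#'
#' Runs [scan_sequence()] + [resolve()] per record (resolution is never applied across
#' records) and writes a TSV table, optionally BED6.
#'
#' @param fasta_path input FASTA.
#' @param bundle trained `classifier_bundle` or bundle directory path.
#' @param out_path output file.
#' @param format `"tsv"` (default) or `"bed"` (0-based half-open single-base
#'   interval at the CS base; name = class, score = logistic-scaled z in
#'   0..1000).
#' @param min_separation resolution distance (default 100).
#' @param classes class labels to scan with.
#' @param reverse_complement also scan the reverse complement of every
#'   record as an independent sequence (default FALSE).
#' @return the combined prediction data.frame, invisibly.
#' @export
predict_file <- function(fasta_path, bundle, out_path, format = c("tsv", "bed"),
                         min_separation = 100L, classes = CLASS_LABELS,
                         reverse_complement = FALSE) {
  format <- match.arg(format)
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  seqs <- read_fasta(fasta_path)
  if (reverse_complement)
    seqs <- c(seqs, lapply(seqs, polyar::reverse_complement))
  per <- lapply(seqs, function(s)
    resolve(scan_sequence(s, bundle, classes), min_separation))
  res <- if (length(per)) do.call(rbind, per) else empty_predictions()
  rownames(res) <- NULL
  if (format == "tsv") {
    out <- cbind(res[, c("seq_id", "cs_index")],
                 position = res$cs_index + 1L,
                 res[, c("class_label", "z", "pas_offset", "pas_score",
                         "guu_offset", "guu_score")])
    out$z <- sprintf("%.6f", out$z)
    out$pas_score <- ifelse(is.na(res$pas_score), "NA",
                            sprintf("%.6f", res$pas_score))
    out$guu_score <- sprintf("%.6f", out$guu_score)
    utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = res$seq_id, start = res$cs_index,
                      end = res$cs_index + 1L, name = res$class_label,
                      score = as.integer(round(1000 / (1 + exp(-res$z)))),
                      strand = "+")
    utils::write.table(bed, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(res)
}
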