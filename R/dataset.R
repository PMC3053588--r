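# Training machinery: classify poly(A) records into the three PAS classes by
# the hexamer present in [-40:-1], remove near-duplicate regions, build
# negative fragments from coding sequence, and train the full classifier
# bundle (PWMs, pentamer tables, distance distributions, gates, LDFs).

#' Construct a poly(A) record
#'
#' One sequence window with its cleavage-site index and class label; the atom
#' of training and evaluation.
#'
#' @param sequence a `genomic_seq`.
#' @param cs_index 0-based index of the CS base.
#' @param class_label one of the class labels or `"unlabeled"`.
#' @return object of class `polya_record`.
#' @export
polya_record <- function(sequence, cs_index, class_label = "unlabeled") {
  stopifnot(inherits(sequence, "genomic_seq"))
  structure(list(sequence = sequence, cs_index = as.integer(cs_index),
                 class_label = class_label),
            class = "polya_record")
}

# CS-relative region of a record's parent sequence (both ends inclusive).
record_region <- function(record, from, to) {
  i1 <- cs_coord_to_index(record$cs_index, from) + 1L
  i2 <- cs_coord_to_index(record$cs_index, to) + 1L
  n <- nchar(record$sequence$residues)
  if (i1 < 1L || i2 > n)
    stop(sprintf("region [%d:%d] out of range for '%s'", from, to,
                 record$sequence$id), call. = FALSE)
  substr(record$sequence$residues, i1, i2)
}

record_window <- function(record, class_label) {
  geom <- CLASS_GEOMETRY[[class_label]]
  extract_window(record$sequence, record$cs_index, geom["up"], geom["down"])
}

#' Assign the PAS class of a poly(A) record
#'
#' Searches `[-40:-1]` for exact hexamer occurrences: AATAAA/ATTAAA make the
#' record PAS-strong; otherwise any of the 10 minor variants makes it
#' PAS-weak; otherwise it is PAS-less.
#'
#' @param record a `polya_record` whose `[-40:-1]` region is extractable.
#' @return class label string.
#' @export
classify_pas <- function(record) {
  region <- record_region(record, -40L, -1L)
  if (any(vapply(STRONG_HEXAMERS, grepl, TRUE, x = region, fixed = TRUE)))
    return("PAS-strong")
  if (any(vapply(WEAK_HEXAMERS, grepl, TRUE, x = region, fixed = TRUE)))
    return("PAS-weak")
  "PAS-less"
}

#' Remove near-duplicate poly(A) records
#'
#' Greedy filter in input order: a record is kept iff the ungapped identity
#' of its CS-anchored region to every previously kept region is below
#' `max_identity`. Regions share the CS anchor, so they align position by
#' position.
#'
#' @param records list of `polya_record`.
#' @param region CS-relative interval compared (default `c(-50, 50)`).
#' @param max_identity records with identity `>=` this to a kept record are
#'   dropped (default 0.90).
#' @return filtered list, original order.
#' @export
dedupe <- function(records, region = c(-50L, 50L), max_identity = 0.90) {
  if (length(records) == 0L) return(records)
  regs <- lapply(records, function(r)
    utf8ToInt(record_region(r, region[1], region[2])))
  len <- length(regs[[1]])
  kept <- logical(length(records))
  kept_regs <- list()
  for (i in seq_along(records)) {
    dup <- FALSE
    for (kr in kept_regs)
      if (sum(regs[[i]] == kr) / len >= max_identity) { dup <- TRUE; break }
    if (!dup) { kept[i] <- TRUE; kept_regs[[length(kept_regs) + 1L]] <- regs[[i]] }
  }
  records[kept]
}

# Negative fragment geometry: fragment length and pseudo-CS offset chosen so
# the class window exactly covers the fragment (150 = 100+50, 120 = 60+60,
# 160 = 60+100).
NEGATIVE_FRAGMENT <- list(
  "PAS-strong" = c(len = 150L, cs = 100L),
  "PAS-weak"   = c(len = 120L, cs = 60L),
  "PAS-less"   = c(len = 160L, cs = 60L)
)

#' Cut coding sequences into negative fragments
#'
#' Trims 200 bp from each end of every source and tiles the middle with
#' non-overlapping fragments of the class length (150/120/160 bp for
#' strong/weak/less), placing the pseudo-CS so the class window exactly
#' covers the fragment. Sources too short to yield a fragment are skipped
#' (count reported via a message).
#'
#' @param sources list of `genomic_seq` (e.g. CDS regions).
#' @param class_label target class.
#' @return list of `polya_record` with class label `<class>` and ids
#'   `<source id>_f<k>`.
#' @export
make_negative_fragments <- function(sources, class_label) {
  class_label <- match.arg(class_label, CLASS_LABELS)
  fg <- NEGATIVE_FRAGMENT[[class_label]]
  out <- list()
  skipped <- 0L
  for (src in sources) {
    n <- nchar(src$residues)
    mid <- n - 400L
    if (mid < fg["len"]) { skipped <- skipped + 1L; next }
    k <- mid %/% fg["len"]
    for (j in seq_len(k)) {
      start <- 200L + (j - 1L) * fg["len"]      # 0-based fragment start
      frag <- substr(src$residues, start + 1L, start + fg["len"])
      out[[length(out) + 1L]] <- polya_record(
        genomic_seq(sprintf("%s_f%d", src$id, j), frag),
        cs_index = fg["cs"], class_label = class_label)
    }
  }
  if (skipped > 0L)
    message(skipped, " source(s) too short for ", class_label,
            " fragments; skipped")
  out
}

default_train_config <- function() {
  list(pseudocount = 0, guu_region = c(1L, 50L), em_restarts = 10L,
       min_per_class = 50L, penta_mode = "occurrence", target_fpr = NULL)
}

# Best authentic hexamer occurrence (exact match, closest to CS) of a class's
# hexamer set in the [-40:-1] region of a window. Returns NULL when absent.
authentic_pas_occurrence <- function(window, hexamers) {
  region <- window_sub(window, -40L, -1L)
  best <- NULL
  for (h in hexamers) {
    st <- gregexpr(h, region, fixed = TRUE)[[1]]
    if (st[1] == -1L) next
    for (s in st) {
      off <- -40L + (s - 1L)                     # CS-relative offset of leftmost base
      if (is.null(best) || off > best$offset) best <- list(offset = off, hex = h)
    }
  }
  best
}

#' Train the full classifier bundle
#'
#' Builds, from labeled positive records and per-class negative records, all
#' trained artifacts needed to scan new sequence: per-class PAS PWMs and
#' gates, the fixed-window CS PWMs, the EM-discovered GU/U PWM, pentamer
#' Bayes tables, distance distributions, and the three LDF models.
#'
#' @param positives list of `polya_record`; records labeled `"unlabeled"` are
#'   classified first.
#' @param negatives named list (`PAS-strong`, `PAS-weak`, `PAS-less`) of
#'   lists of negative `polya_record` with the class fragment geometry.
#' @param config list of overrides of the default training configuration
#'   (`pseudocount`, `guu_region`, `em_restarts`, `min_per_class`,
#'   `penta_mode`, `target_fpr`).
#' @param seed integer seed (EM initializations; recorded in the bundle).
#' @return object of class `classifier_bundle`.
#' @export
train_bundle <- function(positives, negatives, config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_train_config(), config)
  cfg$seed <- as.integer(seed)

  labels <- vapply(positives, function(r)
    if (identical(r$class_label, "unlabeled")) classify_pas(r) else r$class_label,
    "")
  pos <- split(positives, factor(labels, levels = CLASS_LABELS))
  for (cl in CLASS_LABELS) {
    if (length(pos[[cl]]) < cfg$min_per_class)
      stop(sprintf("class %s has %d positive records; need at least %d",
                   cl, length(pos[[cl]]), cfg$min_per_class))
    if (length(negatives[[cl]]) < cfg$min_per_class)
      stop(sprintf("class %s has %d negative records; need at least %d",
                   cl, length(negatives[[cl]]), cfg$min_per_class))
  }

  win_pos <- lapply(CLASS_LABELS, function(cl)
    lapply(pos[[cl]], record_window, class_label = cl))
  names(win_pos) <- CLASS_LABELS
  win_neg <- lapply(CLASS_LABELS, function(cl)
    lapply(negatives[[cl]], record_window, class_label = cl))
  names(win_neg) <- CLASS_LABELS

  # --- PAS PWMs, gates and PAS-CS distances (strong and weak classes) ---
  pas_occ <- list()
  pas_found <- list()
  pas_pwm <- list()
  gates <- list()
  hexsets <- list("PAS-strong" = STRONG_HEXAMERS, "PAS-weak" = WEAK_HEXAMERS)
  for (cl in c("PAS-strong", "PAS-weak")) {
    occ <- lapply(win_pos[[cl]], authentic_pas_occurrence,
                  hexamers = hexsets[[cl]])
    found <- !vapply(occ, is.null, TRUE)
    if (sum(found) < cfg$min_per_class)
      stop(sprintf("class %s: only %d records carry an authentic hexamer in [-40:-1]",
                   cl, sum(found)))
    occ <- occ[found]
    instances <- vapply(occ, `[[`, "", "hex")
    pas_pwm[[cl]] <- build_pwm(instances, cfg$pseudocount, label = "PAS")
    gates[[cl]] <- pas_gate_threshold(pas_pwm[[cl]], instances)
    pas_occ[[cl]] <- occ
    pas_found[[cl]] <- found
  }

  # --- CS PWMs from fixed windows ---
  cs_inst_sw <- unlist(lapply(c(win_pos$`PAS-strong`, win_pos$`PAS-weak`),
                              window_sub, from = -15L, to = 3L))
  cs_inst_less <- unlist(lapply(win_pos$`PAS-less`, window_sub,
                                from = -9L, to = 3L))
  drop_n <- function(x) x[!grepl("N", x, fixed = TRUE)]
  cs_pwm_strongweak <- build_pwm(drop_n(cs_inst_sw), cfg$pseudocount,
                                 label = "CS")
  cs_pwm_less <- build_pwm(drop_n(cs_inst_less), cfg$pseudocount, label = "CS")

  # --- GU/U PWM by EM on the downstream regions of all positives ---
  down_regions <- unlist(lapply(unlist(win_pos, recursive = FALSE),
                                window_sub,
                                from = cfg$guu_region[1],
                                to = cfg$guu_region[2]))
  guu_pwm <- em_discover(down_regions, width = 10L,
                         restarts = cfg$em_restarts, seed = cfg$seed)

  bundle <- structure(list(
    pas_pwm_strong = pas_pwm$`PAS-strong`, pas_pwm_weak = pas_pwm$`PAS-weak`,
    cs_pwm_strongweak = cs_pwm_strongweak, cs_pwm_less = cs_pwm_less,
    guu_pwm = guu_pwm,
    pas_gate_strong = gates$`PAS-strong`, pas_gate_weak = gates$`PAS-weak`,
    penta = list(), dist = list(), config = cfg),
    class = "classifier_bundle")

  # --- distance distributions ---
  guu_offsets <- function(wins) vapply(wins, function(w)
    best_hit(guu_pwm, w, cfg$guu_region[1], cfg$guu_region[2])$offset, 0L)
  bundle$dist <- list(
    "PAS-strong" = list(
      pas_cs = build_distance_distribution(
        pas_cs_distance(vapply(pas_occ$`PAS-strong`, `[[`, 0L, "offset")),
        "PAS_CS"),
      cs_guu = build_distance_distribution(
        cs_guu_distance(guu_offsets(win_pos$`PAS-strong`)), "CS_GUU")),
    "PAS-weak" = list(
      pas_cs = build_distance_distribution(
        pas_cs_distance(vapply(pas_occ$`PAS-weak`, `[[`, 0L, "offset")),
        "PAS_CS"),
      cs_guu = build_distance_distribution(
        cs_guu_distance(guu_offsets(win_pos$`PAS-weak`)), "CS_GUU")),
    "PAS-less" = list(
      cs_guu = build_distance_distribution(
        cs_guu_distance(guu_offsets(win_pos$`PAS-less`)), "CS_GUU")))

  # --- pentamer tables ---
  # Upstream region of the strong class follows the PAS hexamer (60 nt left
  # of its leftmost base); negatives use the scan-time best hit under the
  # trained PAS PWM so positive and negative frequencies are commensurable.
  strong_up_pos <- mapply(function(w, o) strong_upstream_region(w, o$offset),
                          win_pos$`PAS-strong`[pas_found$`PAS-strong`],
                          pas_occ$`PAS-strong`)
  strong_up_neg <- vapply(win_neg$`PAS-strong`, function(w) {
    hit <- best_hit(bundle$pas_pwm_strong, w, -40L, -1L)
    strong_upstream_region(w, hit$offset)
  }, "")
  up_reg <- function(wins) vapply(wins, window_sub, "", from = -60L, to = -1L)
  dn_reg <- function(wins, to) vapply(wins, window_sub, "", from = 2L, to = to)
  bundle$penta <- list(
    "PAS-strong" = list(up = build_pentamer_table(
      strong_up_pos, strong_up_neg, "upstream", "PAS-strong", cfg$penta_mode)),
    "PAS-weak" = list(
      up = build_pentamer_table(up_reg(win_pos$`PAS-weak`),
                                up_reg(win_neg$`PAS-weak`),
                                "upstream", "PAS-weak", cfg$penta_mode),
      down = build_pentamer_table(dn_reg(win_pos$`PAS-weak`, 60L),
                                  dn_reg(win_neg$`PAS-weak`, 60L),
                                  "downstream", "PAS-weak", cfg$penta_mode)),
    "PAS-less" = list(
      up = build_pentamer_table(up_reg(win_pos$`PAS-less`),
                                up_reg(win_neg$`PAS-less`),
                                "upstream", "PAS-less", cfg$penta_mode),
      down = build_pentamer_table(dn_reg(win_pos$`PAS-less`, 100L),
                                  dn_reg(win_neg$`PAS-less`, 100L),
                                  "downstream", "PAS-less", cfg$penta_mode)))

  # --- feature matrices and LDF models ---
  feat_matrix <- function(wins, cl) {
    rows <- lapply(wins, assemble_features, bundle = bundle, class_label = cl)
    rows <- rows[!vapply(rows, is.null, TRUE)]
    do.call(rbind, lapply(rows, function(v) as.numeric(v)))
  }
  counts <- list()
  for (cl in CLASS_LABELS) {
    X1 <- feat_matrix(win_pos[[cl]], cl)
    X2 <- feat_matrix(win_neg[[cl]], cl)
    colnames(X1) <- colnames(X2) <- FEATURE_SCHEMAS[[cl]]
    model <- train_ldf(X1, X2, class_label = cl,
                       feature_names = FEATURE_SCHEMAS[[cl]])
    if (!is.null(cfg$target_fpr)) {
      zneg <- X2 %*% model$a
      model$operating_threshold <-
        unname(stats::quantile(zneg, 1 - cfg$target_fpr, type = 1L))
    }
    slot <- c("PAS-strong" = "ldf_strong", "PAS-weak" = "ldf_weak",
              "PAS-less" = "ldf_less")[[cl]]
    bundle[[slot]] <- model
    counts[[cl]] <- c(n_pos = nrow(X1), n_neg = nrow(X2))
  }
  bundle$config$counts <- counts
  bundle
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat("<classifier_bundle>\n")
  for (m in list(x$ldf_strong, x$ldf_weak, x$ldf_less)) print(m)
  cat(sprintf("  PAS gates: strong %.4f, weak %.4f; GU/U consensus %s\n",
              x$pas_gate_strong, x$pas_gate_weak, pwm_consensus(x$guu_pwm)))
  invisible(x)
}

#' Write a classifier bundle to a directory
#'
#' Plain-text layout: PWM matrix files, pentamer and distance TSVs, LDF model
#' JSONs, and a config snapshot; reloadable bit-exactly with
#' [read_bundle()].
#'
#' @param bundle a `classifier_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  write_pwm(bundle$pas_pwm_strong, p("pas_strong.pwm"))
  write_pwm(bundle$pas_pwm_weak, p("pas_weak.pwm"))
  write_pwm(bundle$cs_pwm_strongweak, p("cs_strongweak.pwm"))
  write_pwm(bundle$cs_pwm_less, p("cs_less.pwm"))
  write_pwm(bundle$guu_pwm, p("guu.pwm"))
  slug <- c("PAS-strong" = "strong", "PAS-weak" = "weak", "PAS-less" = "less")
  for (cl in names(bundle$penta))
    for (rg in names(bundle$penta[[cl]]))
      write_pentamer_table(bundle$penta[[cl]][[rg]],
                           p("penta_", slug[[cl]], "_", rg, ".tsv"))
  for (cl in names(bundle$dist))
    for (kind in names(bundle$dist[[cl]]))
      write_distance_distribution(bundle$dist[[cl]][[kind]],
                                  p("dist_", slug[[cl]], "_", kind, ".tsv"))
  write_ldf_model(bundle$ldf_strong, p("ldf_strong.json"))
  write_ldf_model(bundle$ldf_weak, p("ldf_weak.json"))
  write_ldf_model(bundle$ldf_less, p("ldf_less.json"))
  meta <- bundle$config
  meta$pas_gate_strong <- bundle$pas_gate_strong
  meta$pas_gate_weak <- bundle$pas_gate_weak
  jsonlite::write_json(meta, p("config.json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")
  invisible(dir)
}

#' Read a classifier bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a `classifier_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, paste0(...))
  meta <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  gates <- list(strong = meta$pas_gate_strong, weak = meta$pas_gate_weak)
  meta$pas_gate_strong <- NULL
  meta$pas_gate_weak <- NULL
  slug <- c("PAS-strong" = "strong", "PAS-weak" = "weak", "PAS-less" = "less")
  penta <- list()
  dist <- list()
  for (cl in CLASS_LABELS) {
    penta[[cl]] <- list()
    for (rg in c("up", "down")) {
      f <- p("penta_", slug[[cl]], "_", rg, ".tsv")
      if (file.exists(f)) penta[[cl]][[rg]] <- read_pentamer_table(f)
    }
    dist[[cl]] <- list()
    for (kind in c("pas_cs", "cs_guu")) {
      f <- p("dist_", slug[[cl]], "_", kind, ".tsv")
      if (file.exists(f)) dist[[cl]][[kind]] <- read_distance_distribution(f)
    }
  }
  structure(list(
    pas_pwm_strong = read_pwm(p("pas_strong.pwm")),
    pas_pwm_weak = read_pwm(p("pas_weak.pwm")),
    cs_pwm_strongweak = read_pwm(p("cs_strongweak.pwm")),
    cs_pwm_less = read_pwm(p("cs_less.pwm")),
    guu_pwm = read_pwm(p("guu.pwm")),
    pas_gate_strong = gates$strong, pas_gate_weak = gates$weak,
    penta = penta, dist = dist,
    ldf_strong = read_ldf_model(p("ldf_strong.json")),
    ldf_weak = read_ldf_model(p("ldf_weak.json")),
    ldf_less = read_ldf_model(p("ldf_less.json")),
    config = meta), class = "classifier_bundle")
}
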