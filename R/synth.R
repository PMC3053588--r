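# Synthetic corpus generator. Emulates the signal architecture the
# recognizer assumes: 600-bp positive windows with the class PAS hexamer
# planted upstream of the CS, a CA cleavage dinucleotide, and a GU/U-rich
# downstream element; and codon-structured negative fragments of 150/120/160
# bp depleted of strong hexamers. Everything flows from one integer seed, so
# corpora are reproducible byte for byte.

#' Default synthetic-corpus configuration
#'
#' Defaults: 500/200/100 positives for strong/weak/less with equal-size
#' negative sets, 600-bp windows (CS at index 300), AT-rich background,
#' strong hexamer mix 70/30 AATAAA/ATTAAA (the two canonical forms cover
#' about 70 percent of mapped human sites), uniform mix over the 10 weak
#' variants, PAS-to-CS gap triangular on [12,35] nt with mode 21, CA
#' cleavage dinucleotide planted with probability 0.7, GU/U element
#' TGTGTTTTGT planted with probability 0.85 at offsets [+5,+40], 70/30
#' train/test split.
#'
#' @param ... overrides of the default fields.
#' @return configuration list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_per_class = c("PAS-strong" = 500L, "PAS-weak" = 200L, "PAS-less" = 100L),
    window = c(up = 300L, down = 300L),
    background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    strong_hexamer_mix = c(AATAAA = 0.7, ATTAAA = 0.3),
    weak_hexamer_mix = stats::setNames(rep(0.1, 10L), WEAK_HEXAMERS),
    pas_cs_gap = list(min = 12L, max = 35L, mode = 21L),
    cs_ca_prob = 0.7,
    guu_element = "TGTGTTTTGT",
    guu_prob = 0.85,
    guu_offset_range = c(5L, 40L),
    codon_structure = TRUE,
    exclude_stops = TRUE,
    train_fraction = 0.7,
    max_tries = 10000L)
  utils::modifyList(cfg, list(...))
}

# Discrete triangular pmf on min..max with the given mode.
triangular_pmf <- function(min, max, mode) {
  d <- min:max
  w <- ifelse(d <= mode, d - min + 1L, max - d + 1L)
  w / sum(w)
}

sample_background <- function(n, background) {
  paste(sample(names(background), n, replace = TRUE, prob = background),
        collapse = "")
}

# Overwrite residues at 0-based index `at` with `insert`.
plant <- function(residues, at, insert) {
  paste0(substr(residues, 1L, at), insert,
         substr(residues, at + nchar(insert) + 1L, nchar(residues)))
}

region_0based <- function(residues, cs, from, to) {
  substr(residues, cs_coord_to_index(cs, from) + 1L, cs_coord_to_index(cs, to) + 1L)
}

has_any <- function(region, hexamers)
  any(vapply(hexamers, grepl, TRUE, x = region, fixed = TRUE))

#' Generate synthetic positive poly(A) windows for one class
#'
#' Background sequence with the class architecture planted: for strong/weak,
#' the class hexamer at a sampled gap upstream of the CS; for PAS-less,
#' rejection sampling ensures no PAS hexamer of the 12 forms occurs in
#' `[-40:-1]` (weak windows likewise exclude the two strong forms). The CA
#' cleavage dinucleotide (-1/+1) and the GU/U element downstream are planted
#' with their configured probabilities.
#'
#' @param class_label site class to generate.
#' @param n number of records.
#' @param config list from [synth_config()].
#' @param seed integer seed.
#' @param id_prefix prefix for record ids.
#' @return list with `records` (list of labeled `polya_record`) and `truth`
#'   (data.frame `seq_id`, `cs_index`, `class_label`).
#' @export
generate_positive <- function(class_label, n, config = synth_config(),
                              seed = config$seed, id_prefix = NULL) {
  class_label <- match.arg(class_label, CLASS_LABELS)
  set.seed(seed)
  up <- config$window["up"]; down <- config$window["down"]
  len <- up + down
  gap <- config$pas_cs_gap
  gap_pmf <- triangular_pmf(gap$min, gap$max, gap$mode)
  if (is.null(id_prefix))
    id_prefix <- c("PAS-strong" = "strong_pos", "PAS-weak" = "weak_pos",
                   "PAS-less" = "less_pos")[[class_label]]
  records <- vector("list", n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(config$max_tries)) {
      res <- sample_background(len, config$background)
      if (class_label != "PAS-less") {
        mix <- if (class_label == "PAS-strong") config$strong_hexamer_mix
               else config$weak_hexamer_mix
        hex <- sample(names(mix), 1L, prob = mix)
        d <- sample(gap$min:gap$max, 1L, prob = gap_pmf)
        # distance convention: d = 1 - (offset of rightmost base) => leftmost
        # CS-relative offset -4 - d; with d in [12,35] the hexamer sits inside
        # the [-40:-1] search region.
        res <- plant(res, cs_coord_to_index(up, -4L - d), hex)
      }
      if (stats::runif(1) < config$cs_ca_prob) {
        res <- plant(res, cs_coord_to_index(up, -1L), "C")
        res <- plant(res, cs_coord_to_index(up, 1L), "A")
      }
      if (stats::runif(1) < config$guu_prob) {
        o <- sample(config$guu_offset_range[1]:config$guu_offset_range[2], 1L)
        res <- plant(res, cs_coord_to_index(up, o), config$guu_element)
      }
      reg <- region_0based(res, up, -40L, -1L)
      valid <- switch(class_label,
        "PAS-strong" = has_any(reg, STRONG_HEXAMERS),
        "PAS-weak" = !has_any(reg, STRONG_HEXAMERS) &&
                     has_any(reg, WEAK_HEXAMERS),
        "PAS-less" = !has_any(reg, c(STRONG_HEXAMERS, WEAK_HEXAMERS)))
      if (valid) { ok <- TRUE; break }
    }
    if (!ok)
      stop("rejection sampling failed for ", class_label,
           " after ", config$max_tries, " tries; config too constrained")
    records[[k]] <- polya_record(
      genomic_seq(sprintf("%s_%04d", id_prefix, k), res),
      cs_index = up, class_label = class_label)
  }
  truth <- data.frame(
    seq_id = vapply(records, function(r) r$sequence$id, ""),
    cs_index = rep(as.integer(up), n),
    class_label = rep(class_label, n), stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate synthetic negative fragments for one class
#'
#' Codon-structured background (in-frame stop codons excluded by default,
#' mimicking mid-CDS sequence) cut to the class fragment length with the
#' pseudo-CS placed so the class window exactly covers the fragment;
#' fragments with a strong hexamer in `[-40:-1]` are rejected so the
#' negative set is depleted of the signal the gate keys on.
#'
#' @param n_fragments number of fragments.
#' @param class_label target class (sets length 150/120/160 and pseudo-CS).
#' @param config list from [synth_config()].
#' @param seed integer seed.
#' @param id_prefix prefix for fragment ids.
#' @return list of `polya_record`.
#' @export
generate_negative <- function(n_fragments, class_label,
                              config = synth_config(), seed = config$seed,
                              id_prefix = NULL) {
  class_label <- match.arg(class_label, CLASS_LABELS)
  set.seed(seed)
  fg <- NEGATIVE_FRAGMENT[[class_label]]
  if (is.null(id_prefix))
    id_prefix <- c("PAS-strong" = "strong_neg", "PAS-weak" = "weak_neg",
                   "PAS-less" = "less_neg")[[class_label]]
  make_codon_seq <- function(len) {
    if (!config$codon_structure) return(sample_background(len, config$background))
    ncod <- ceiling(len / 3)
    codons <- character(ncod)
    for (j in seq_len(ncod)) {
      repeat {
        cod <- sample_background(3L, config$background)
        if (!config$exclude_stops || !(cod %in% STOP_CODONS)) break
      }
      codons[j] <- cod
    }
    substr(paste(codons, collapse = ""), 1L, len)
  }
  out <- vector("list", n_fragments)
  for (k in seq_len(n_fragments)) {
    ok <- FALSE
    for (try in seq_len(config$max_tries)) {
      res <- make_codon_seq(fg["len"])
      reg <- region_0based(res, fg["cs"], -40L, -1L)
      if (!has_any(reg, STRONG_HEXAMERS)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("rejection sampling failed for ", class_label, " negatives")
    out[[k]] <- polya_record(
      genomic_seq(sprintf("%s_%04d", id_prefix, k), res),
      cs_index = fg["cs"], class_label = class_label)
  }
  out
}

#' Generate a full train/test corpus
#'
#' Positives and equal-size negative sets for all three classes, split into
#' train and test by the configured fraction. All randomness derives from
#' `config$seed`.
#'
#' @param config list from [synth_config()].
#' @return list with `train` (`positives` flat list, `negatives` per-class
#'   list), `test` (`positives`, `truth`, `negatives` per class), and
#'   `manifest` (config and counts).
#' @export
generate_corpus <- function(config = synth_config()) {
  seed0 <- as.integer(config$seed)
  train_pos <- list(); test_pos <- list(); test_truth <- list()
  train_neg <- list(); test_neg <- list()
  counts <- list()
  for (ci in seq_along(CLASS_LABELS)) {
    cl <- CLASS_LABELS[ci]
    n <- config$n_per_class[[cl]]
    pos <- generate_positive(cl, n, config, seed = seed0 + 101L * ci)
    n_train <- floor(config$train_fraction * n)
    train_pos[[cl]] <- pos$records[seq_len(n_train)]
    test_pos[[cl]] <- pos$records[setdiff(seq_len(n), seq_len(n_train))]
    test_truth[[cl]] <- pos$truth[setdiff(seq_len(n), seq_len(n_train)), ]
    neg <- generate_negative(n, cl, config, seed = seed0 + 101L * ci + 37L)
    train_neg[[cl]] <- neg[seq_len(n_train)]
    test_neg[[cl]] <- neg[setdiff(seq_len(n), seq_len(n_train))]
    counts[[cl]] <- c(n_pos = n, n_train = n_train, n_test = n - n_train)
  }
  list(train = list(positives = unlist(unname(train_pos), recursive = FALSE),
                    negatives = train_neg),
       test = list(positives = test_pos, truth = do.call(rbind, test_truth),
                   negatives = test_neg),
       manifest = list(config = config, counts = counts))
}

#' Write a corpus to a directory
#'
#' FASTA + truth TSV per part, plus a JSON manifest of all parameters,
#' seed and counts.
#'
#' @param corpus list from [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  getseq <- function(recs) lapply(recs, `[[`, "sequence")
  truth_of <- function(recs) data.frame(
    seq_id = vapply(recs, function(r) r$sequence$id, ""),
    cs_index = vapply(recs, `[[`, 0L, "cs_index"),
    class_label = vapply(recs, `[[`, "", "class_label"))
  write_fasta(getseq(corpus$train$positives),
              file.path(dir, "train_positives.fasta"))
  write_truth_tsv(truth_of(corpus$train$positives),
                  file.path(dir, "train_positives.tsv"))
  slug <- c("PAS-strong" = "strong", "PAS-weak" = "weak", "PAS-less" = "less")
  for (cl in CLASS_LABELS) {
    write_fasta(getseq(corpus$train$negatives[[cl]]),
                file.path(dir, paste0("train_negatives_", slug[[cl]], ".fasta")))
    write_fasta(getseq(corpus$test$positives[[cl]]),
                file.path(dir, paste0("test_positives_", slug[[cl]], ".fasta")))
    write_fasta(getseq(corpus$test$negatives[[cl]]),
                file.path(dir, paste0("test_negatives_", slug[[cl]], ".fasta")))
  }
  write_truth_tsv(corpus$test$truth, file.path(dir, "test_truth.tsv"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       na = "null")
  invisible(dir)
}
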