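# Non-motif characteristics of the discriminant: pentamer-composition Bayes
# scores for the regions flanking the CS, and frequency scores for the
# PAS-to-CS and CS-to-GU/U distances. Feature schemas are fixed per class:
#   PAS-strong: PAS, CS, GU/U, upstream pentamers, D(PAS-CS), D(CS-GU/U)
#   PAS-weak:   the above plus downstream pentamers
#   PAS-less:   CS, GU/U, upstream + downstream pentamers, D(CS-GU/U)

CLASS_LABELS <- c("PAS-strong", "PAS-weak", "PAS-less")

# Window geometry [-up:+down] per class.
CLASS_GEOMETRY <- list(
  "PAS-strong" = c(up = 100L, down = 50L),
  "PAS-weak"   = c(up = 60L,  down = 60L),
  "PAS-less"   = c(up = 60L,  down = 100L)
)

# PAS hexamer variants (DNA spelling of the RNA hexamers).
STRONG_HEXAMERS <- c("AATAAA", "ATTAAA")
WEAK_HEXAMERS <- c("AGTAAA", "TATAAA", "CATAAA", "GATAAA", "AATATA",
                   "AATACA", "AATAGA", "ACTAAA", "AAGAAA", "AATGAA")

FEATURE_SCHEMAS <- list(
  "PAS-strong" = c("pas", "cs", "guu", "up_penta", "d_pas_cs", "d_cs_guu"),
  "PAS-weak"   = c("pas", "cs", "guu", "up_penta", "d_pas_cs", "d_cs_guu",
                   "dn_penta"),
  "PAS-less"   = c("cs", "guu", "up_penta", "dn_penta", "d_cs_guu")
)

ALL_PENTAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, stringsAsFactors = FALSE)[, 5:1]
  apply(g, 1L, paste, collapse = "")
})

# Pentamer ids (1..1024) for every start position of a region; NA where the
# 5-mer contains N. Regions shorter than 5 nt give integer(0).
pentamer_ids <- function(region) {
  e <- encode_dna(region)
  n <- length(e) - 4L
  if (n < 1L) return(integer(0))
  id <- integer(n)
  for (i in 0:4) {
    b <- e[(1L + i):(n + i)]
    id <- id + ifelse(b > 4L, NA_integer_, (b - 1L)) * 4L^(4L - i)
  }
  id + 1L
}

#' Build a pentamer-composition Bayes table
#'
#' For each of the 1024 pentamers, `P = F_p / (F_p + F_n)` where `F_p` and
#' `F_n` are its occurrence frequencies (pentamer windows matching it divided
#' by total pentamer windows) in the positive and negative region sets. A
#' pentamer absent from both sets gets the uninformative `P = 0.5`.
#'
#' @param positive_regions,negative_regions character vectors of regions
#'   (each at least 5 nt).
#' @param region_label `"upstream"` or `"downstream"`.
#' @param class_label site class the table belongs to.
#' @param mode `"occurrence"` (default; frequency of pentamer windows) or
#'   `"presence"` (fraction of regions containing the pentamer).
#' @return object of class `pentamer_table`: list with `P` (named numeric,
#'   length 1024), `region_label`, `class_label`, `mode`.
#' @export
build_pentamer_table <- function(positive_regions, negative_regions,
                                 region_label = "upstream",
                                 class_label = NA_character_,
                                 mode = c("occurrence", "presence")) {
  mode <- match.arg(mode)
  if (length(positive_regions) == 0L || length(negative_regions) == 0L)
    stop("positive and negative region sets must both be non-empty")
  freq_of <- function(regions) {
    idl <- lapply(regions, pentamer_ids)
    if (mode == "occurrence") {
      ids <- unlist(idl)
      ids <- ids[!is.na(ids)]
      if (length(ids) == 0L) return(numeric(1024L))
      tabulate(ids, nbins = 1024L) / length(ids)
    } else {
      pres <- vapply(idl, function(id) tabulate(unique(id[!is.na(id)]),
                                                nbins = 1024L) > 0,
                     logical(1024L))
      rowMeans(pres)
    }
  }
  fp <- freq_of(positive_regions)
  fn <- freq_of(negative_regions)
  P <- ifelse(fp + fn == 0, 0.5, fp / (fp + fn))
  names(P) <- ALL_PENTAMERS
  structure(list(P = P, region_label = region_label,
                 class_label = class_label, mode = mode),
            class = "pentamer_table")
}

#' Mean pentamer Bayes score of a region
#'
#' Mean of `P` over all overlapping pentamer start positions (a 60-nt region
#' has exactly 56). Pentamer windows containing N are excluded from the mean.
#'
#' @param table a `pentamer_table`.
#' @param region sequence string, at least 5 nt.
#' @return score in `[0,1]`; 0.5 when no valid pentamer window exists.
#' @export
pentamer_region_score <- function(table, region) {
  if (nchar(region) < 5L) stop("region must be at least 5 nt")
  ids <- pentamer_ids(region)
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) return(0.5)
  mean(table$P[ids])
}

#' Build an empirical distance distribution
#'
#' Relative frequencies of observed integer distances; unobserved distances
#' score 0. Conventions: the PAS-to-CS distance is `(+1)` minus the
#' offset of the PAS hexamer's rightmost base; the CS-to-GU/U distance is the
#' CS-relative offset of the GU/U motif's leftmost base minus 1.
#'
#' @param observations integer vector of distances from the positive
#'   training set.
#' @param kind `"PAS_CS"` or `"CS_GUU"`.
#' @return object of class `distance_dist`: list with `freq` (named numeric
#'   over observed distances) and `kind`.
#' @export
build_distance_distribution <- function(observations,
                                        kind = c("PAS_CS", "CS_GUU")) {
  kind <- match.arg(kind)
  if (length(observations) == 0L) stop("no distance observations given")
  tab <- table(as.integer(observations))
  freq <- as.numeric(tab) / length(observations)
  names(freq) <- names(tab)
  structure(list(freq = freq, kind = kind), class = "distance_dist")
}

#' Frequency score of a distance
#'
#' @param dist a `distance_dist`.
#' @param d integer distance.
#' @return observed relative frequency of `d`, or 0 if unseen.
#' @export
distance_score <- function(dist, d) {
  v <- dist$freq[as.character(as.integer(d))]
  if (is.na(v)) 0 else unname(v)
}

# Distance conventions shared by training and scanning.
pas_cs_distance <- function(pas_leftmost_offset) 1L - (pas_leftmost_offset + 5L)
cs_guu_distance <- function(guu_leftmost_offset) guu_leftmost_offset - 1L

# The upstream pentamer region of a strong-class window: the 60 nt
# immediately left of the PAS hexamer's leftmost base (CS-relative offsets
# [L-60, L-1]); with the PAS search bounded at -40 this never leaves the
# [-100:+50] window.
strong_upstream_region <- function(window, pas_leftmost_offset) {
  window_sub(window, pas_leftmost_offset - 60L, pas_leftmost_offset - 1L)
}

#' Assemble the per-class feature vector of a candidate site
#'
#' Computes the class schema from a trained bundle: PAS best hit in
#' `[-40:-1]` (strong/weak), CS-motif score on the fixed `[-15:+3]` /
#' `[-9:+3]` window, GU/U best hit in `[+1:+50]`, pentamer region scores,
#' and the two distance scores.
#'
#' @param window a `cs_window` with the class geometry
#'   (`[-100:+50]` strong, `[-60:+60]` weak, `[-60:+100]` less).
#' @param bundle a trained `classifier_bundle`.
#' @param class_label one of `"PAS-strong"`, `"PAS-weak"`, `"PAS-less"`.
#' @return named numeric feature vector following the class schema, with
#'   attributes `pas_hit` and `guu_hit`; or `NULL` when no PAS placement
#'   fits the search region (strong/weak only).
#' @export
assemble_features <- function(window, bundle, class_label) {
  class_label <- match.arg(class_label, CLASS_LABELS)
  geom <- CLASS_GEOMETRY[[class_label]]
  if (window$up != geom["up"] || window$down != geom["down"])
    stop(sprintf("window [-%d:+%d] does not match %s geometry [-%d:+%d]",
                 window$up, window$down, class_label, geom["up"], geom["down"]))
  guu_hit <- best_hit(bundle$guu_pwm, window, bundle$config$guu_region[1],
                      bundle$config$guu_region[2])
  if (class_label == "PAS-less") {
    vals <- c(
      cs = score_pwm(bundle$cs_pwm_less, window_sub(window, -9L, 3L)),
      guu = guu_hit$score,
      up_penta = pentamer_region_score(bundle$penta$`PAS-less`$up,
                                       window_sub(window, -60L, -1L)),
      dn_penta = pentamer_region_score(bundle$penta$`PAS-less`$down,
                                       window_sub(window, 2L, 100L)),
      d_cs_guu = distance_score(bundle$dist$`PAS-less`$cs_guu,
                                cs_guu_distance(guu_hit$offset)))
    return(structure(vals, pas_hit = NULL, guu_hit = guu_hit))
  }
  pas_pwm <- if (class_label == "PAS-strong") bundle$pas_pwm_strong
             else bundle$pas_pwm_weak
  pas_hit <- best_hit(pas_pwm, window, -40L, -1L)
  if (is.null(pas_hit)) return(NULL)
  up_region <- if (class_label == "PAS-strong")
    strong_upstream_region(window, pas_hit$offset)
  else window_sub(window, -60L, -1L)
  tabs <- bundle$penta[[class_label]]
  dists <- bundle$dist[[class_label]]
  vals <- c(
    pas = pas_hit$score,
    cs = score_pwm(bundle$cs_pwm_strongweak, window_sub(window, -15L, 3L)),
    guu = guu_hit$score,
    up_penta = pentamer_region_score(tabs$up, up_region),
    d_pas_cs = distance_score(dists$pas_cs,
                              pas_cs_distance(pas_hit$offset)),
    d_cs_guu = distance_score(dists$cs_guu,
                              cs_guu_distance(guu_hit$offset)))
  if (class_label == "PAS-weak")
    vals <- c(vals, dn_penta = pentamer_region_score(
      tabs$down, window_sub(window, 2L, 60L)))
  structure(vals, pas_hit = pas_hit, guu_hit = guu_hit)
}

#' Write a pentamer table as TSV
#'
#' Header comments record region/class/mode; rows are `pentamer<TAB>P` at
#' full precision.
#'
#' @param table a `pentamer_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pentamer_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pentamer_table region=%s class=%s mode=%s",
                     table$region_label, table$class_label, table$mode), con)
  writeLines(sprintf("%s\t%.17g", names(table$P), table$P), con)
  invisible(path)
}

#' Read a pentamer table written by [write_pentamer_table()]
#' @param path TSV path.
#' @return a `pentamer_table`.
#' @export
read_pentamer_table <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1],
                    regexec("region=(\\S+) class=(\\S+) mode=(\\S+)",
                            lines[1]))[[1]]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  P <- as.numeric(vapply(parts, `[[`, "", 2L))
  names(P) <- vapply(parts, `[[`, "", 1L)
  structure(list(P = P[ALL_PENTAMERS], region_label = hdr[2],
                 class_label = hdr[3], mode = hdr[4]),
            class = "pentamer_table")
}

#' Write a distance distribution as TSV
#' @param dist a `distance_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_distribution <- function(dist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# distance_dist kind=%s", dist$kind), con)
  writeLines(sprintf("%s\t%.17g", names(dist$freq), dist$freq), con)
  invisible(path)
}

#' Read a distance distribution written by [write_distance_distribution()]
#' @param path TSV path.
#' @return a `distance_dist`.
#' @export
read_distance_distribution <- function(path) {
  lines <- readLines(path)
  kind <- regmatches(lines[1], regexec("kind=(\\S+)", lines[1]))[[1]][2]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  freq <- as.numeric(vapply(parts, `[[`, "", 2L))
  names(freq) <- vapply(parts, `[[`, "", 1L)
  structure(list(freq = freq, kind = kind), class = "distance_dist")
}
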