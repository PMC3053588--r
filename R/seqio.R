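# Internal alphabet is DNA: motifs from the RNA literature (AAUAAA) are stored
# with T. Coordinates follow the cleavage-site (CS) convention used throughout:
# the CS base itself is CS-relative coordinate +1, the base before it is -1, and no
# coordinate 0 exists. Internally everything is 0-based; CS-relative coordinates
# appear only at I/O surfaces.

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases, converts U to T, and replaces every character outside
#' \{A,C,G,T\} with N.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

#' Construct a genomic sequence record
#'
#' @param id non-empty sequence identifier.
#' @param residues nucleotide string; normalized via [normalize_residues()].
#' @return an object of class `genomic_seq` with fields `id` and `residues`.
#' @export
genomic_seq <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  structure(list(id = id, residues = normalize_residues(residues)),
            class = "genomic_seq")
}

#' @export
print.genomic_seq <- function(x, ...) {
  cat(sprintf("<genomic_seq> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Records are normalized to the internal DNA alphabet (uppercase, U to T,
#' anything else to N). Input order is preserved; duplicate ids are an error;
#' an empty file yields an empty list.
#'
#' @param path path to a FASTA file.
#' @return list of `genomic_seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- as.character(ss)
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) out[[i]] <- genomic_seq(ids[i], res[[i]])
  out
}

#' Write sequences to FASTA
#'
#' @param seqs list of `genomic_seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(ss) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Convert a CS-relative coordinate to a 0-based parent index
#'
#' The CS-relative convention has no 0: the CS base is +1, its upstream neighbour -1.
#'
#' @param cs_index 0-based index of the CS base in the parent sequence.
#' @param p CS-relative coordinate (nonzero integer).
#' @return 0-based index into the parent residues.
#' @export
cs_coord_to_index <- function(cs_index, p) {
  stopifnot(all(p != 0L))
  ifelse(p >= 1L, cs_index + p - 1L, cs_index + p)
}

#' Extract a CS-anchored window
#'
#' Returns the CS-relative region `[-up:+down]` around the cleavage site: `up`
#' bases upstream of the CS followed by `down` bases starting at the CS base
#' itself (coordinate +1).
#'
#' @param seq a `genomic_seq`.
#' @param cs_index 0-based index of the CS base.
#' @param up,down positive integers; window length is `up + down`.
#' @return object of class `cs_window` with `parent_id`, `cs_index`, `up`,
#'   `down`, `residues`.
#' @export
extract_window <- function(seq, cs_index, up, down) {
  stopifnot(inherits(seq, "genomic_seq"), up >= 1L, down >= 1L)
  n <- nchar(seq$residues)
  if (cs_index - up < 0L || cs_index + down > n)
    stop(sprintf("window [-%d:+%d] at cs_index %d out of range for '%s' (%d nt)",
                 up, down, cs_index, seq$id, n), call. = FALSE)
  structure(list(parent_id = seq$id, cs_index = as.integer(cs_index),
                 up = as.integer(up), down = as.integer(down),
                 residues = substr(seq$residues, cs_index - up + 1L,
                                   cs_index + down)),
            class = "cs_window")
}

# CS-relative slice of a window's residues (both ends inclusive,
# coordinates skipping 0). window_sub(w, -40, -1) is the PAS search region.
window_sub <- function(w, from, to) {
  i1 <- cs_coord_to_index(w$up, from) + 1L   # 1-based within window
  i2 <- cs_coord_to_index(w$up, to) + 1L
  substr(w$residues, i1, i2)
}

# Encode residues as integers: A=1 C=2 G=3 T=4, N (or anything else)=5.
encode_dna <- function(residues) {
  v <- utf8ToInt(residues)
  out <- rep.int(5L, length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}

DNA_BASES <- c("A", "C", "G", "T")

#' Read a cleavage-site truth table
#'
#' Tab-separated columns: sequence id, 0-based CS index, optional class label.
#'
#' @param path TSV path (no header).
#' @return data.frame with `seq_id`, `cs_index`, `class_label` (NA when absent).
#' @export
read_truth_tsv <- function(path) {
  if (!file.exists(path)) stop("truth table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          fill = TRUE)
  names(df) <- c("seq_id", "cs_index", "class_label")[seq_len(ncol(df))]
  if (is.null(df$class_label)) df$class_label <- NA_character_
  df$cs_index <- as.integer(df$cs_index)
  df
}

#' Write a cleavage-site truth table
#'
#' @param df data.frame with `seq_id`, `cs_index` and optionally `class_label`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(df, path) {
  cols <- c("seq_id", "cs_index")
  if (!is.null(df$class_label) && !all(is.na(df$class_label)))
    cols <- c(cols, "class_label")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse-complement a genomic sequence
#'
#' Used when scanning the opposite strand as an independent sequence.
#'
#' @param seq a `genomic_seq`.
#' @return a `genomic_seq` with id suffixed `_rc`.
#' @export
reverse_complement <- function(seq) {
  rc <- chartr("ACGT", "TGCA", seq$residues)
  rc <- paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  genomic_seq(paste0(seq$id, "_rc"), rc)
}
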