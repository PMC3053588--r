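# Positional motif models. Three motifs drive recognition: the PAS hexamer
# upstream of the CS, the fixed-window cleavage-site (CS) motif, and the
# GU/U-rich downstream element discovered de novo by EM. All are scored as the
# mean matched-column frequency, so scores live in [0,1] and an N base
# contributes 0 (PWM matrices carry a fifth all-zero row for N).

#' Build a position weight matrix from aligned instances
#'
#' `w(b,i) = (count(b,i) + pseudocount) / (n + 4*pseudocount)`; each column
#' sums to 1.
#'
#' @param instances character vector of equal-length sequences over
#'   \{A,C,G,T\}.
#' @param pseudocount non-negative smoothing constant added per base
#'   (default 0: raw frequencies).
#' @param label motif label, e.g. `"PAS"`, `"CS"`, `"GUU"`.
#' @return object of class `pwm`: list with `width`, `label`, and `freqs`,
#'   a 5 x width matrix (rows A,C,G,T,N; the N row is all zero).
#' @export
build_pwm <- function(instances, pseudocount = 0, label = "motif") {
  if (length(instances) == 0L) stop("no motif instances given")
  wd <- unique(nchar(instances))
  if (length(wd) != 1L) stop("motif instances have unequal lengths")
  stopifnot(pseudocount >= 0)
  counts <- matrix(0, nrow = 5L, ncol = wd)
  for (s in instances) {
    e <- encode_dna(s)
    counts[cbind(e, seq_len(wd))] <- counts[cbind(e, seq_len(wd))] + 1
  }
  if (any(counts[5L, ] > 0)) stop("motif instances must not contain N")
  freqs <- (counts[1:4, , drop = FALSE] + pseudocount) /
    (length(instances) + 4 * pseudocount)
  m <- rbind(freqs, 0)
  rownames(m) <- c("A", "C", "G", "T", "N")
  structure(list(width = as.integer(wd), label = label, freqs = m),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$label, x$width))
  print(round(x$freqs[1:4, , drop = FALSE], 3))
  invisible(x)
}

#' Score a window under a PWM
#'
#' Mean matched-column frequency `(1/width) * sum_i w(window_i, i)`.
#'
#' @param pwm a `pwm`.
#' @param window sequence string of length `pwm$width`.
#' @return score in `[0,1]`.
#' @export
score_pwm <- function(pwm, window) {
  e <- encode_dna(window)
  if (length(e) != pwm$width)
    stop(sprintf("window length %d != pwm width %d", length(e), pwm$width))
  mean(pwm$freqs[cbind(e, seq_len(pwm$width))])
}

# Vector of placement scores for a PWM along an integer-encoded sequence:
# score[s] for placements starting at s = 1 .. length(enc)-width+1.
pwm_track <- function(pwm, enc) {
  L <- length(enc) - pwm$width + 1L
  if (L < 1L) return(numeric(0))
  acc <- numeric(L)
  for (i in seq_len(pwm$width))
    acc <- acc + pwm$freqs[cbind(enc[i:(i + L - 1L)], i)]
  acc / pwm$width
}

#' Best-scoring motif placement within a CS-anchored region
#'
#' Scans all placements whose leftmost base lies in
#' `[region_start, region_end - width + 1]` (CS-relative coordinates) and returns
#' the maximum-scoring one. Ties are broken in favour of the placement
#' closest to the CS (largest offset).
#'
#' @param pwm a `pwm`.
#' @param window a `cs_window`.
#' @param region_start,region_end CS-relative coordinates bounding the search
#'   region (inclusive), fully inside the window.
#' @return list with `offset` (CS-relative coordinate of the motif's leftmost
#'   base) and `score`, or `NULL` when the region is shorter than the motif.
#' @export
best_hit <- function(pwm, window, region_start, region_end) {
  i1 <- cs_coord_to_index(window$up, region_start) + 1L  # 1-based window pos
  i2 <- cs_coord_to_index(window$up, region_end) + 1L
  stopifnot(i1 >= 1L, i2 <= nchar(window$residues))
  if (i2 - i1 + 1L < pwm$width) return(NULL)
  enc <- encode_dna(substr(window$residues, i1, i2))
  tr <- pwm_track(pwm, enc)
  best <- which(tr == max(tr))
  best <- best[length(best)]                 # largest offset = closest to CS
  idx0 <- (i1 - 1L) + (best - 1L)            # 0-based window index of start
  off <- idx0 - window$up                    # 0-based offset from CS base
  list(offset = if (off >= 0L) off + 1L else off, score = tr[best])
}

#' PAS gate threshold
#'
#' The minimum PWM score over the authentic PAS instances; at scan time only
#' placements scoring at least this threshold are treated as candidate
#' polyadenylation signals.
#'
#' @param pwm a `pwm`.
#' @param authentic_hexamers character vector of authentic instances, each of
#'   `pwm$width`.
#' @return minimum score.
#' @export
pas_gate_threshold <- function(pwm, authentic_hexamers) {
  if (length(authentic_hexamers) == 0L) stop("no authentic instances given")
  min(vapply(authentic_hexamers, function(s) score_pwm(pwm, s), 0))
}

#' Discover a motif by one-occurrence-per-sequence expectation maximization
#'
#' Each sequence is assumed to contain exactly one occurrence of an unknown
#' fixed-width motif against a 0-order background. The E-step computes the
#' posterior over start positions per sequence under the current PWM; the
#' M-step re-estimates the PWM from posterior-weighted counts. The best of
#' `restarts` random initializations (by final log-likelihood) is returned.
#'
#' @param sequences character vector, each at least `width` nt.
#' @param width motif width (default 10, the GU/U element).
#' @param restarts number of seeded random restarts.
#' @param seed integer seed controlling the initializations.
#' @param background optional length-4 base-composition vector (A,C,G,T);
#'   default: pooled composition of `sequences`.
#' @param tol stop when log-likelihood improves by less than this.
#' @param max_iter iteration cap per restart.
#' @return a `pwm` (label `"GUU"`), with attribute `loglik`.
#' @export
em_discover <- function(sequences, width = 10L, restarts = 10L, seed = 1L,
                        background = NULL, tol = 1e-6, max_iter = 500L) {
  if (length(sequences) == 0L) stop("no sequences given")
  if (any(nchar(sequences) < width))
    stop("every sequence must be at least `width` nt")
  stopifnot(restarts >= 1L)
  encs <- lapply(sequences, encode_dna)
  if (is.null(background)) {
    tab <- tabulate(unlist(encs), nbins = 5L)[1:4]
    background <- if (sum(tab) > 0) tab / sum(tab) else rep(0.25, 4)
  }
  background <- pmax(background / sum(background), 1e-9)
  bg5 <- c(background, 1)       # N contributes a neutral factor
  logbg <- lapply(encs, function(e) log(bg5[e]))

  run_once <- function(freqs) {
    ll_old <- -Inf
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      lw5 <- rbind(log(pmax(freqs, 1e-12)), 0)   # N neutral in motif too
      counts <- matrix(0, nrow = 4L, ncol = width)
      ll <- 0
      for (k in seq_along(encs)) {
        e <- encs[[k]]
        L <- length(e) - width + 1L
        sc <- numeric(L)
        for (i in seq_len(width))
          sc <- sc + lw5[cbind(e[i:(i + L - 1L)], i)] -
            logbg[[k]][i:(i + L - 1L)]
        m <- max(sc)
        post <- exp(sc - m)
        Z <- sum(post)
        post <- post / Z
        ll <- ll + m + log(Z) - log(L) + sum(logbg[[k]])
        for (i in seq_len(width)) {
          b <- e[i:(i + L - 1L)]
          ok <- b <= 4L
          if (any(ok))
            counts[, i] <- counts[, i] +
              vapply(1:4, function(bb) sum(post[ok][b[ok] == bb]), 0)
        }
      }
      trace <- c(trace, ll)
      counts <- counts + 1e-4                      # keep columns proper
      freqs <- sweep(counts, 2L, colSums(counts), "/")
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(freqs = freqs, loglik = ll, trace = trace)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- matrix(stats::runif(4L * width, 0.2, 1), nrow = 4L)
    init <- sweep(init, 2L, colSums(init), "/")
    fit <- run_once(init)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  m <- rbind(best$freqs, 0)
  rownames(m) <- c("A", "C", "G", "T", "N")
  structure(list(width = as.integer(width), label = "GUU", freqs = m),
            class = "pwm", loglik = best$loglik, loglik_trace = best$trace)
}

#' Consensus (modal base per column) of a PWM
#'
#' @param pwm a `pwm`.
#' @return character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freqs[1:4, , drop = FALSE], 2L, which.max)],
        collapse = "")
}

#' Write a PWM as a plain-text matrix file
#'
#' Header line `# label=<label> width=<w>` followed by four tab-separated
#' rows (A, C, G, T) at full precision; loadable bit-exactly.
#'
#' @param pwm a `pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s width=%d", pwm$label, pwm$width), con)
  for (b in 1:4)
    writeLines(paste(c(DNA_BASES[b],
                       sprintf("%.17g", pwm$freqs[b, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#'
#' @param path path to a PWM matrix file.
#' @return a `pwm`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1], regexec("label=(\\S+) width=(\\d+)", lines[1]))[[1]]
  wd <- as.integer(hdr[3])
  m <- matrix(0, nrow = 5L, ncol = wd,
              dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in 1:4) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    m[f[1], ] <- as.numeric(f[-1])
  }
  structure(list(width = wd, label = hdr[2], freqs = m), class = "pwm")
}
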