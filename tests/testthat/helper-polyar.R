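# Shared fixtures and independent oracles for the suite. Fixtures are built
# in code; the small trained bundle is cached per session because several
# files exercise it.

random_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# A 600-bp record with `hexamer` planted so its rightmost base sits at
# coordinate -(gap), i.e. PAS-CS distance d = gap + 1 under the training convention.
# Filler base C avoids accidental PAS hexamers.
planted_record <- function(id = "p1", hexamer = "AATAAA", leftmost = -21L,
                           filler = "C", len = 600L, cs = 300L) {
  res <- strrep(filler, len)
  at <- cs + leftmost                       # 0-based index (leftmost < 0)
  res <- paste0(substr(res, 1, at), hexamer,
                substr(res, at + nchar(hexamer) + 1L, len))
  polya_record(genomic_seq(id, res), cs_index = cs)
}

# Small synthetic corpus + trained bundle, cached across test files.
tiny_corpus <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- synth_config(
        seed = 42L,
        n_per_class = c("PAS-strong" = 60L, "PAS-weak" = 50L,
                        "PAS-less" = 50L))
      val <<- generate_corpus(cfg)
    }
    val
  }
})

tiny_bundle <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      corpus <- tiny_corpus()
      val <<- train_bundle(corpus$train$positives, corpus$train$negatives,
                           config = list(min_per_class = 30L,
                                         em_restarts = 2L),
                           seed = 42L)
    }
    val
  }
})

# Independent two-class Fisher discriminant oracle: covariances and solve()
# computed from first principles, no shared code with train_ldf().
fisher_oracle <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colSums(X1) / n1
  m2 <- colSums(X2) / n2
  covm <- function(X, m) {
    Xc <- sweep(X, 2, m)
    t(Xc) %*% Xc / (nrow(X) - 1)
  }
  s <- ((n1 - 1) * covm(X1, m1) + (n2 - 1) * covm(X2, m2)) / (n1 + n2 - 2)
  a <- solve(s) %*% (m1 - m2)
  list(a = drop(a), c = drop(t(a) %*% (m1 + m2)) / 2,
       d_squared = drop(t(m1 - m2) %*% a))
}

# Independent Matthews correlation oracle.
mcc_oracle <- function(tp, fp, tn, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tp + fn) * sqrt(tn + fp)
  num / den
}

# Exhaustive best-placement oracle: enumerate every start, score with
# score_pwm, take the max with the closest-to-CS tie-break.
best_hit_oracle <- function(pwm, window, region_start, region_end) {
  offs <- region_start:(region_end - pwm$width + 1L)
  best <- NULL
  for (o in offs) {
    if (o == 0L) next
    i1 <- cs_coord_to_index(window$up, o) + 1L
    s <- score_pwm(pwm, substr(window$residues, i1, i1 + pwm$width - 1L))
    if (is.null(best) || s > best$score ||
        (s == best$score && o > best$offset))
      best <- list(offset = o, score = s)
  }
  best
}
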