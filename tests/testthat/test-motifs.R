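test_that("PWM frequencies are per-position base proportions", {
  p1 <- build_pwm("AATAAA")
  expect_equal(unname(p1$freqs["A", 1]), 1.0)
  expect_equal(unname(p1$freqs["T", 3]), 1.0)
  expect_equal(sum(p1$freqs[, 2]), 1.0)

  p2 <- build_pwm(c("AATAAA", "ATTAAA"))
  expect_equal(unname(p2$freqs["A", 2]), 0.5)
  expect_equal(unname(p2$freqs["T", 2]), 0.5)
  expect_equal(unname(p2$freqs["A", 1]), 1.0)

  p3 <- build_pwm(c(rep("AATAAA", 3), "ATTAAA"))
  expect_equal(unname(p3$freqs["A", 2]), 0.75)
  expect_equal(unname(p3$freqs["T", 2]), 0.25)

  # pseudocount spreads mass but keeps columns normalized
  ps <- build_pwm("AATAAA", pseudocount = 1)
  expect_equal(unname(ps$freqs["A", 1]), 2 / 5)
  expect_equal(colSums(ps$freqs), rep(1, 6), ignore_attr = TRUE)

  expect_error(build_pwm(c("AAT", "AATA")), "unequal")
  expect_error(build_pwm(character(0)), "no motif instances")
})

test_that("PWM scoring is the mean matched-column frequency", {
  p <- build_pwm("AATAAA")
  expect_equal(score_pwm(p, "AATAAA"), 1.0)

  uni <- build_pwm(c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"))
  expect_equal(score_pwm(uni, "ACGTAC"), 0.25)

  p3 <- build_pwm(c(rep("AATAAA", 3), "ATTAAA"))
  expect_equal(score_pwm(p3, "AATAAA"), (1 + 0.75 + 1 + 1 + 1 + 1) / 6)
  expect_equal(score_pwm(p3, "ATTAAA"), (1 + 0.25 + 1 + 1 + 1 + 1) / 6)

  # N contributes zero frequency
  expect_equal(score_pwm(p, "AANAAA"), 5 / 6)
  expect_error(score_pwm(p, "AATAAAA"), "width")
})

test_that("best placement search matches exhaustive enumeration", {
  pas <- build_pwm("AATAAA")
  rec <- planted_record(leftmost = -21L)
  w <- extract_window(rec$sequence, 300L, 100L, 50L)
  hit <- best_hit(pas, w, -40L, -1L)
  expect_equal(hit$offset, -21L)
  expect_equal(hit$score, 1.0)

  # two exact occurrences: the one closest to the CS wins
  res <- strrep("C", 600)
  for (at in c(300 - 30, 300 - 18))
    res <- paste0(substr(res, 1, at), "AATAAA", substr(res, at + 7, 600))
  w2 <- extract_window(genomic_seq("two", res), 300L, 100L, 50L)
  expect_equal(best_hit(pas, w2, -40L, -1L)$offset, -18L)

  # a window with no A/T in the region still returns a (zero-score) placement
  w3 <- extract_window(genomic_seq("gc", strrep("G", 600)), 300L, 100L, 50L)
  expect_equal(best_hit(pas, w3, -40L, -1L)$score, 0.0)

  # region shorter than the motif
  expect_null(best_hit(pas, w, -4L, -1L))

  # brute-force oracle agreement on random windows, both strands of the CS
  set.seed(13)
  mixed <- build_pwm(c(rep("AATAAA", 3), "ATTAAA", "AGTAAA"))
  for (k in 1:25) {
    wr <- extract_window(genomic_seq("r", random_dna(600)), 300L, 100L, 50L)
    expect_equal(best_hit(mixed, wr, -40L, -1L),
                 best_hit_oracle(mixed, wr, -40L, -1L))
    expect_equal(best_hit(mixed, wr, 1L, 50L),
                 best_hit_oracle(mixed, wr, 1L, 50L))
  }
})

test_that("the PAS gate is the minimum authentic-instance score", {
  p3 <- build_pwm(c(rep("AATAAA", 3), "ATTAAA"))
  expect_equal(pas_gate_threshold(p3, c(rep("AATAAA", 3), "ATTAAA")),
               (1 + 0.25 + 1 + 1 + 1 + 1) / 6)
  p1 <- build_pwm("AATAAA")
  expect_equal(pas_gate_threshold(p1, "AATAAA"), 1.0)
  # an authentic instance absent from training scores low but defines the gate
  expect_equal(pas_gate_threshold(p1, c("AATAAA", "TTTTTT")), 1 / 6)
  expect_error(pas_gate_threshold(p1, character(0)), "no authentic")
})

test_that("EM motif discovery is deterministic and improves monotonically", {
  set.seed(5)
  seqs <- vapply(1:20, function(i) {
    bg <- random_dna(50)
    at <- sample(0:40, 1)
    paste0(substr(bg, 1, at), "TGTGTTTTGT", substr(bg, at + 11, 50))
  }, "")
  m1 <- em_discover(seqs, width = 10L, restarts = 3L, seed = 9L)
  m2 <- em_discover(seqs, width = 10L, restarts = 3L, seed = 9L)
  expect_identical(m1$freqs, m2$freqs)

  trace <- attr(m1, "loglik_trace")
  expect_true(all(diff(trace) > -1e-8))

  # degenerate case: identical sequences exactly motif-wide
  md <- em_discover(rep("ACGTACGTAC", 8), width = 10L, restarts = 2L,
                    seed = 1L)
  expect_equal(md$freqs, build_pwm("ACGTACGTAC")$freqs, tolerance = 1e-3)

  expect_error(em_discover(c("ACGT", "ACGTACGTAC"), width = 10L), "at least")
})

test_that("PWM text serialization round-trips bit-exactly", {
  set.seed(3)
  pwm <- build_pwm(vapply(1:7, function(i) random_dna(10), ""),
                   pseudocount = 0.5, label = "GUU")
  f <- withr::local_tempfile(fileext = ".pwm")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_identical(back$freqs, pwm$freqs)
  expect_identical(back$width, pwm$width)
  expect_identical(back$label, pwm$label)
})
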