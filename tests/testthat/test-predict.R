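test_that("scanning a planted site recovers it within the matching tolerance", {
  b <- tiny_bundle()
  corpus <- tiny_corpus()
  recs <- corpus$test$positives$`PAS-strong`
  recovered <- vapply(recs, function(r) {
    p <- resolve(scan_sequence(r$sequence, b, classes = "PAS-strong"))
    nrow(p) > 0L && any(abs(p$cs_index - r$cs_index) <= 12L)
  }, TRUE)
  # a small training set localizes most, not all, planted sites
  expect_gte(mean(recovered), 0.75)
  rec <- recs[[which(recovered)[1]]]
  preds <- resolve(scan_sequence(rec$sequence, b, classes = "PAS-strong"))
  near <- preds[which.min(abs(preds$cs_index - rec$cs_index)), ]
  expect_equal(near$class_label, "PAS-strong")

  # every gated strong/weak call reaches its class gate
  raw <- scan_sequence(rec$sequence, b)
  sw <- raw[raw$class_label != "PAS-less", ]
  gates <- c("PAS-strong" = b$pas_gate_strong, "PAS-weak" = b$pas_gate_weak)
  expect_true(all(sw$pas_score >= gates[sw$class_label] - 1e-12))
})

test_that("sequences shorter than every class window give an empty result", {
  b <- tiny_bundle()
  out <- scan_sequence(genomic_seq("short", random_dna(50)), b)
  expect_equal(nrow(out), 0L)
})

test_that("the scanner agrees with the per-window reference path", {
  b <- tiny_bundle()
  set.seed(47)
  for (cl in c("PAS-strong", "PAS-weak", "PAS-less")) {
    rec <- tiny_corpus()$test$positives[[cl]][[1]]
    preds <- scan_sequence(rec$sequence, b, classes = cl)
    expect_gt(nrow(preds), 0L)
    geom <- list("PAS-strong" = c(100L, 50L), "PAS-weak" = c(60L, 60L),
                 "PAS-less" = c(60L, 100L))[[cl]]
    take <- preds[sample(nrow(preds), min(5L, nrow(preds))), ]
    models <- list("PAS-strong" = b$ldf_strong, "PAS-weak" = b$ldf_weak,
                   "PAS-less" = b$ldf_less)
    for (k in seq_len(nrow(take))) {
      w <- extract_window(rec$sequence, take$cs_index[k], geom[1], geom[2])
      x <- assemble_features(w, b, cl)
      expect_equal(ldf_score(models[[cl]], as.numeric(x))$z, take$z[k],
                   tolerance = 1e-12)
    }
  }
})

test_that("resolution enforces class precedence and score order within 100 bp", {
  mk <- function(cs, cl, z) data.frame(
    seq_id = "s", cs_index = cs, class_label = cl, z = z,
    pas_offset = NA_integer_, pas_score = NA_real_,
    guu_offset = 10L, guu_score = 0.5, stringsAsFactors = FALSE)

  # strong beats a higher-scoring weak nearby
  p <- rbind(mk(100L, "PAS-strong", 2), mk(150L, "PAS-weak", 5))
  expect_equal(resolve(p)$class_label, "PAS-strong")
  # weak beats less nearby
  p <- rbind(mk(100L, "PAS-weak", 1), mk(150L, "PAS-less", 9))
  expect_equal(resolve(p)$class_label, "PAS-weak")
  # far-apart same-class calls both survive
  p <- rbind(mk(100L, "PAS-strong", 2), mk(250L, "PAS-strong", 3))
  expect_equal(nrow(resolve(p)), 2L)
  # nearby same-class: highest score wins
  p <- rbind(mk(100L, "PAS-strong", 3.0), mk(180L, "PAS-strong", 2.5))
  expect_equal(resolve(p)$z, 3.0)
  # score tie: smaller coordinate wins
  p <- rbind(mk(180L, "PAS-strong", 2.5), mk(100L, "PAS-strong", 2.5))
  expect_equal(resolve(p)$cs_index, 100L)
})

test_that("resolution is idempotent and leaves no winnable conflicts", {
  set.seed(53)
  classes <- c("PAS-strong", "PAS-weak", "PAS-less")
  for (trial in 1:20) {
    n <- sample(2:15, 1)
    p <- data.frame(seq_id = "s", cs_index = sort(sample(0:600, n)),
                    class_label = sample(classes, n, replace = TRUE),
                    z = round(stats::rnorm(n), 2),
                    pas_offset = NA_integer_, pas_score = NA_real_,
                    guu_offset = 10L, guu_score = 0.5,
                    stringsAsFactors = FALSE)
    r <- resolve(p)
    expect_equal(resolve(r), r)
    # brute-force audit: no surviving pair within 100 bp where one dominates
    if (nrow(r) > 1L) {
      for (i in seq_len(nrow(r) - 1L))
        for (j in (i + 1L):nrow(r))
          expect_gt(abs(r$cs_index[i] - r$cs_index[j]), 100L)
    }
  }
})

test_that("file prediction is deterministic and scoped per record", {
  b <- tiny_bundle()
  corpus <- tiny_corpus()
  recs <- corpus$test$positives$`PAS-strong`[1:2]
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(lapply(recs, `[[`, "sequence"), fa)
  out1 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  r1 <- predict_file(fa, b, out1)
  predict_file(fa, b, out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_true(all(r1$seq_id %in% vapply(recs, function(r) r$sequence$id, "")))

  # per-record resolution: each record keeps its own near-CS call even if
  # coordinates coincide across records
  for (id in unique(r1$seq_id)) {
    sub <- r1[r1$seq_id == id, ]
    expect_equal(nrow(resolve(sub)), nrow(sub))
  }

  # empty input gives a header-only table
  fa0 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa0)
  out0 <- withr::local_tempfile(fileext = ".tsv")
  predict_file(fa0, b, out0)
  expect_length(readLines(out0), 1L)

  # BED output has six columns and one row per prediction
  bed <- withr::local_tempfile(fileext = ".bed")
  predict_file(fa, b, bed, format = "bed")
  bl <- utils::read.table(bed, sep = "\t")
  expect_equal(ncol(bl), 6L)
  expect_equal(nrow(bl), nrow(r1))
})
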