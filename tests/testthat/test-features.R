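test_that("pentamer Bayes probabilities follow the positive/negative ratio", {
  # equal positive and negative frequencies give the uninformative 0.5
  tab <- build_pentamer_table(c("AAAAA", "CCCCC"), c("AAAAA", "CCCCC"))
  expect_equal(unname(tab$P["AAAAA"]), 0.5)
  # every pentamer absent from both sets is also 0.5
  expect_true(all(tab$P[setdiff(names(tab$P), c("AAAAA", "CCCCC"))] == 0.5))

  # positive-only pentamer saturates at 1
  tab2 <- build_pentamer_table("AAAAA", "CCCCC")
  expect_equal(unname(tab2$P["AAAAA"]), 1.0)
  expect_equal(unname(tab2$P["CCCCC"]), 0.0)

  # F_p twice F_n gives 2/3
  tab3 <- build_pentamer_table(c("AAAAA", "CCCCC"),
                               c("AAAAA", "CCCCC", "GGGGG", "TTTTT"))
  expect_equal(unname(tab3$P["AAAAA"]), (1/2) / (1/2 + 1/4))

  expect_error(build_pentamer_table(character(0), "AAAAA"), "non-empty")
})

test_that("region score averages pentamer probabilities over all windows", {
  tab <- build_pentamer_table(c("AAAAA", "CCCCC"), c("AAAAA", "CCCCC"))
  set.seed(2)
  expect_equal(pentamer_region_score(tab, random_dna(60)), 0.5)

  # hand-checked mean over the two windows of a 6-nt region
  tab$P[] <- 0
  tab$P["AAAAA"] <- 0.8
  expect_equal(pentamer_region_score(tab, "AAAAAA"), 0.8)

  # a 60-nt region has exactly 56 pentamer windows: oracle by substring loop
  set.seed(8)
  tab$P[] <- stats::runif(1024)
  region <- random_dna(60)
  manual <- mean(vapply(1:56, function(i)
    tab$P[[substr(region, i, i + 4)]], 0))
  expect_equal(pentamer_region_score(tab, region), manual)

  # pentamer windows containing N are excluded from the mean
  tab$P[] <- 0
  tab$P["AAAAA"] <- 1
  # only AAAAA (P=1) and CCCCC (P=0) avoid the N; the five N windows drop
  expect_equal(pentamer_region_score(tab, "AAAAANCCCCC"), 0.5)
  expect_error(pentamer_region_score(tab, "ACGT"), "at least 5")
})

test_that("distance distributions are empirical frequencies with 0 for unseen", {
  d <- build_distance_distribution(c(15L, 15L, 20L, 30L), "PAS_CS")
  expect_equal(distance_score(d, 15L), 0.5)
  expect_equal(distance_score(d, 20L), 0.25)
  expect_equal(distance_score(d, 30L), 0.25)
  expect_equal(distance_score(d, 7L), 0.0)
  expect_equal(distance_score(d, 999L), 0.0)
  expect_equal(sum(d$freq), 1.0)

  single <- build_distance_distribution(16L, "CS_GUU")
  expect_equal(distance_score(single, 16L), 1.0)
  expect_error(build_distance_distribution(integer(0)), "no distance")
})

test_that("feature vectors follow the class schemas and stay in [0,1]", {
  b <- tiny_bundle()
  corpus <- tiny_corpus()
  recs <- list("PAS-strong" = corpus$test$positives$`PAS-strong`[[1]],
               "PAS-weak" = corpus$test$positives$`PAS-weak`[[1]],
               "PAS-less" = corpus$test$positives$`PAS-less`[[1]])
  lens <- c("PAS-strong" = 6L, "PAS-weak" = 7L, "PAS-less" = 5L)
  for (cl in names(recs)) {
    geom <- list("PAS-strong" = c(100L, 50L), "PAS-weak" = c(60L, 60L),
                 "PAS-less" = c(60L, 100L))[[cl]]
    w <- extract_window(recs[[cl]]$sequence, recs[[cl]]$cs_index,
                        geom[1], geom[2])
    x <- assemble_features(w, b, cl)
    expect_length(x, lens[[cl]])
    expect_true(all(x >= 0 & x <= 1))
    # deterministic
    expect_equal(as.numeric(assemble_features(w, b, cl)), as.numeric(x))
  }
  # weak schema carries the downstream pentamer term, less has no PAS terms
  wweak <- extract_window(recs$`PAS-weak`$sequence, 300L, 60L, 60L)
  expect_true("dn_penta" %in% names(assemble_features(wweak, b, "PAS-weak")))
  wless <- extract_window(recs$`PAS-less`$sequence, 300L, 60L, 100L)
  expect_false(any(c("pas", "d_pas_cs") %in%
                     names(assemble_features(wless, b, "PAS-less"))))
  # wrong geometry is rejected
  expect_error(assemble_features(wless, b, "PAS-strong"), "geometry")
})

test_that("pentamer and distance tables round-trip through TSV bit-exactly", {
  set.seed(21)
  pos <- vapply(1:10, function(i) random_dna(60), "")
  neg <- vapply(1:10, function(i) random_dna(60), "")
  tab <- build_pentamer_table(pos, neg, "upstream", "PAS-weak")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pentamer_table(tab, f)
  expect_identical(read_pentamer_table(f)$P, tab$P)

  d <- build_distance_distribution(sample(10:40, 50, replace = TRUE), "CS_GUU")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_distribution(d, f2)
  expect_identical(read_distance_distribution(f2)$freq, d$freq)
})
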