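test_that("discriminant training matches closed forms in low dimension", {
  # 1-D: m1=1, m2=0, pooled variance 2 -> a = 1/2, c = 1/4, D^2 = 1/2
  X1 <- matrix(c(0, 2), ncol = 1)
  X2 <- matrix(c(-1, 1), ncol = 1)
  m <- train_ldf(X1, X2)
  expect_equal(m$a, 0.5)
  expect_equal(m$c, 0.25)
  expect_equal(m$d_squared, 0.5)

  # 2-D identity pooled covariance: D^2 = ||m1 - m2||^2 = 25
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(3 / 2)
  X1 <- sweep(base, 2, c(3, 4), "+")
  X2 <- base
  m2 <- train_ldf(X1, X2)
  expect_equal(m2$d_squared, 25)
  expect_equal(m2$a, c(3, 4))

  expect_error(train_ldf(matrix(1), matrix(0)), "at least 2")
})

test_that("training agrees with an independent Fisher oracle on Gaussians", {
  set.seed(17)
  for (k in 1:5) {
    X1 <- matrix(stats::rnorm(50 * 5, mean = 0.3), ncol = 5)
    X2 <- matrix(stats::rnorm(60 * 5), ncol = 5)
    m <- train_ldf(X1, X2)
    o <- fisher_oracle(X1, X2)
    expect_equal(m$a, o$a, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(m$c, o$c, tolerance = 1e-8)
    expect_equal(m$d_squared, o$d_squared, tolerance = 1e-8)
  }
})

test_that("scoring applies the z > c rule with the boundary in Class 2", {
  m <- structure(list(class_label = "test", feature_names = c("f1", "f2"),
                      a = c(1, 1), c = 0.9, operating_threshold = 0.9,
                      d_squared = 1, n1 = 10L, n2 = 10L),
                 class = "ldf_model")
  r <- ldf_score(m, c(f1 = 0.5, f2 = 0.5))
  expect_equal(r$z, 1.0)
  expect_true(r$is_class1)
  # boundary z == threshold is Class 2
  m$operating_threshold <- 1.0
  expect_false(ldf_score(m, c(f1 = 0.5, f2 = 0.5))$is_class1)
  # degenerate zero coefficients
  m$a <- c(0, 0); m$operating_threshold <- 0
  expect_equal(ldf_score(m, c(f1 = 0.9, f2 = 0.9))$z, 0)
  expect_error(ldf_score(m, c(1, 2, 3)), "length")
})

test_that("Mahalanobis distance is consistent, zero at equal means, monotone", {
  set.seed(23)
  X1 <- matrix(stats::rnorm(80 * 4, 0.4), ncol = 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  X2 <- matrix(stats::rnorm(80 * 4), ncol = 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(mahalanobis_d2(X1, X2), train_ldf(X1, X2)$d_squared)

  # single feature with equal class means
  Xa <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(mahalanobis_d2(Xa, Xa, "f"), 0)

  # nested subsets never decrease D^2
  for (k in 1:10) {
    sub <- sample(colnames(X1), 2)
    sup <- union(sub, sample(colnames(X1), 3))
    expect_gte(mahalanobis_d2(X1, X2, sup),
               mahalanobis_d2(X1, X2, sub) - 1e-9)
  }
})

test_that("classification is invariant to rescaling a feature column", {
  set.seed(29)
  X1 <- matrix(stats::rnorm(60 * 3, 0.5), ncol = 3)
  X2 <- matrix(stats::rnorm(60 * 3), ncol = 3)
  m <- train_ldf(X1, X2)
  k <- -3.7
  Y1 <- X1; Y1[, 2] <- Y1[, 2] * k
  Y2 <- X2; Y2[, 2] <- Y2[, 2] * k
  ms <- train_ldf(Y1, Y2)
  expect_equal(ms$d_squared, m$d_squared, tolerance = 1e-9)
  x <- stats::rnorm(3)
  xs <- x; xs[2] <- xs[2] * k
  expect_equal(ldf_score(ms, xs)$z - ms$c, ldf_score(m, x)$z - m$c,
               tolerance = 1e-9)
})

test_that("empirical D^2 approaches the population value on large samples", {
  set.seed(31)
  n <- 10000L
  delta <- c(1, 0.5)
  X1 <- cbind(stats::rnorm(n, delta[1]), stats::rnorm(n, delta[2]))
  X2 <- cbind(stats::rnorm(n), stats::rnorm(n))
  expect_equal(train_ldf(X1, X2)$d_squared, sum(delta^2), tolerance = 0.1)
})

test_that("stepwise selection ranks informative features and honors the gain rule", {
  set.seed(37)
  n <- 2000L
  signal <- stats::rnorm(n, 1)
  noise1 <- stats::rnorm(n)
  X1 <- cbind(inf = signal, dup = signal, noise = noise1)
  X2 <- cbind(inf = stats::rnorm(n), dup = stats::rnorm(n),
              noise = stats::rnorm(n))
  # duplicated informative column in class 1 only: keep data simple by
  # testing redundancy with a literal copy in both classes instead
  X1[, "dup"] <- X1[, "inf"]
  X2[, "dup"] <- X2[, "inf"]
  sel <- suppressWarnings(stepwise_select(X1, X2))
  expect_equal(sel$feature[1], "inf")
  expect_false("dup" %in% sel$feature)   # collinear twin adds no distance

  # informative before pure noise
  expect_true(which(sel$feature == "inf") <
                ifelse("noise" %in% sel$feature,
                       which(sel$feature == "noise"), Inf))

  # disabled stopping rule selects everything
  sel0 <- suppressWarnings(stepwise_select(X1, X2, min_relative_gain = 0))
  expect_setequal(sel0$feature, c("inf", "dup", "noise"))
  expect_true(all(diff(sel0$d_squared) > -1e-6))
})

test_that("model JSON serialization round-trips", {
  set.seed(41)
  m <- train_ldf(matrix(stats::rnorm(40, 1), ncol = 2),
                 matrix(stats::rnorm(40), ncol = 2),
                 class_label = "PAS-strong", feature_names = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".json")
  write_ldf_model(m, f)
  back <- read_ldf_model(f)
  expect_equal(back$a, m$a)
  expect_equal(back$c, m$c)
  expect_equal(back$d_squared, m$d_squared)
  expect_equal(back$feature_names, m$feature_names)
})
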