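test_that("residualization removes exactly the instrument-explained part", {
  set.seed(21)
  g <- random_genotypes(200, 5)
  # fully explained: output collapses to the input mean
  v <- 3 * g$dosage[, 1]
  out <- residualize(v, g, "rs1")
  expect_equal(out, rep(mean(v), 200), tolerance = 1e-10)

  # nothing to remove: output ~ input, orthogonal to instruments
  v2 <- rnorm(200)
  out2 <- residualize(v2, g)
  expect_lt(max(abs(out2 - v2)), 0.5 * sd(v2))
  expect_equal(mean(out2), mean(v2), tolerance = 1e-10)
  for (j in 1:5) {
    expect_lt(abs(cor(out2, g$dosage[, j])), 1e-8)
  }

  # 10-row fixture vs an independent centered-projection oracle
  g10 <- random_genotypes(10, 3)
  v10 <- rnorm(10, 20, 3)
  D <- g10$dosage
  pred <- fitted(lm(v10 ~ D))
  oracle <- v10 - (pred - mean(pred))
  expect_equal(residualize(v10, g10), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)

  # idempotent
  expect_equal(residualize(out2, g), out2, tolerance = 1e-10)

  # collinear instruments are an error naming a column
  gc <- toy_genotypes(cbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1)))
  expect_error(residualize(rnorm(4), gc), "collinear.*b|b.*collinear")
})

test_that("residualization mean-imputes missing dosages for its fit", {
  set.seed(3)
  d <- matrix(rbinom(300, 2, 0.3), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  d[sample(100, 10), 2] <- NA
  g <- genotype_matrix(d)
  v <- rnorm(100, 25, 4)
  out <- residualize(v, g)
  expect_false(anyNA(out))
  expect_equal(mean(out), mean(v), tolerance = 1e-10)
})

test_that("decile matching keeps exposed and subsamples unexposed at the ratio", {
  # single bin: 10 exposed, 100 unexposed -> keep 10 + 45
  exposed <- c(rep(TRUE, 10), rep(FALSE, 100))
  m <- match_by_prediction(exposed, rep(0.5, 110), ratio = 4.5,
                           n_bins = 1, seed = 9)
  expect_equal(m$report$n_exposed_kept, 10)
  expect_equal(m$report$n_unexposed_kept, 45)
  expect_true(all(which(exposed) %in% m$kept))

  # rounding convention: 7 exposed -> round-half-away(31.5) = 32
  exposed7 <- c(rep(TRUE, 7), rep(FALSE, 80))
  m7 <- match_by_prediction(exposed7, seq_len(87), ratio = 4.5,
                            n_bins = 1, seed = 9)
  expect_equal(m7$report$n_unexposed_kept, 32)

  # shortfall: fewer unexposed than the target keeps all, records deficit
  short <- c(rep(TRUE, 10), rep(FALSE, 20))
  ms <- match_by_prediction(short, rep(1, 30), ratio = 4.5, n_bins = 1,
                            seed = 1)
  expect_equal(ms$report$n_unexposed_kept, 20)
  expect_equal(ms$report$per_bin$shortfall, 25)

  # infinite ratio keeps everyone
  minf <- match_by_prediction(exposed, rnorm(110), ratio = Inf,
                              n_bins = 10, seed = 2)
  expect_equal(length(minf$kept), 110)

  # the subsampling stream leaves the caller's RNG state untouched
  preds <- rnorm(110)
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(match_by_prediction(exposed, preds, ratio = 2,
                                n_bins = 2, seed = 77))
  expect_identical(rnorm(1), before)
})

test_that("cohort-scale matching reproduces the study's 4.5:1 bookkeeping", {
  # 287,394 individuals: 48,238 with family history, 239,156 without,
  # with even per-decile exposed counts so the per-bin round(4.5 x n)
  # totals are exact: kept 217,071 and excluded 22,085
  n <- 287394
  pred <- seq_len(n) / n
  bins <- ceiling(10 * seq_len(n) / n)
  exposed <- logical(n)
  target_exposed <- c(rep(4824L, 9), 4822L)
  for (b in 1:10) {
    idx <- which(bins == b)
    exposed[idx[seq_len(target_exposed[b])]] <- TRUE
  }
  expect_equal(sum(exposed), 48238L)
  m <- match_by_prediction(exposed, pred, ratio = 4.5, n_bins = 10,
                           seed = 4)
  expect_equal(m$report$n_exposed_kept, 48238L)
  expect_equal(m$report$n_unexposed_kept, 217071L)
  expect_equal(m$report$n_excluded, 22085L)
  expect_true(all(m$report$per_bin$shortfall == 0))
})

test_that("matching weakens the exposure-instrument association it targets", {
  set.seed(31)
  n <- 12000
  g <- random_genotypes(n, 12)
  D <- g$dosage
  # induced dependence of the binary variable on the instruments
  eta <- -1.8 + D %*% rnorm(12, 0, 0.15)
  exposed <- runif(n) < plogis(eta)
  m <- match_binary(exposed, g, ratio = 4.5, n_bins = 10, seed = 5)
  zs <- function(rows) {
    res <- logistic_assoc(genotype_matrix(D[rows, , drop = FALSE]),
                          exposed[rows])
    abs(res$beta / res$se)
  }
  z_before <- zs(seq_len(n))
  z_after <- zs(m$kept)
  expect_lt(median(z_after), median(z_before))
})
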