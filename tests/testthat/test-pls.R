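test_that("autoscaling centers, scales, errors on constant columns and inverts", {
  set.seed(3)
  X <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- autoscale(X)
  expect_equal(colMeans(s$scaled), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  expect_equal(apply(s$scaled, 2, sd), c(a = 1, b = 1, c = 1),
               tolerance = 1e-12)
  expect_equal(sqrt(colSums(s$scaled^2)), rep(sqrt(19), 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  back <- sweep(sweep(s$scaled, 2, s$scale, "*"), 2, s$center, "+")
  expect_equal(back, X, tolerance = 1e-12)
  X2 <- cbind(X, d = 1)
  expect_error(autoscale(X2), "d")
})

test_that("one-component weights are proportional to X'y and full rank matches least squares", {
  set.seed(8)
  X <- matrix(rnorm(80), 20, 4)
  y <- X %*% c(1, -2, 0.5, 0) + rnorm(20, 0, 0.3)
  dat <- tibble::as_tibble(as.data.frame(X))
  dat$y <- as.numeric(y)
  m1 <- fit_ribbon_pls(dat, responses = "y", ncomp = 1, cv_folds = 5)
  w <- m1$W[, 1]
  xy <- crossprod(scale(X), scale(y))[, 1]
  expect_equal(abs(sum(w * xy) / sqrt(sum(xy^2))), 1, tolerance = 1e-10)

  m4 <- fit_ribbon_pls(dat, responses = "y", ncomp = 4, cv_folds = 5)
  pls_pred <- predict(m4, dat)$y
  ols_pred <- unname(fitted(lm(y ~ X)))
  expect_equal(pls_pred, ols_pred, tolerance = 1e-8)
})

test_that("NIPALS predictions match an SVD-based oracle across 50 random blocks", {
  worst <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    X <- matrix(rnorm(120), 20, 6)
    Y <- matrix(rnorm(40), 20, 2)
    colnames(X) <- paste0("x", 1:6); colnames(Y) <- c("TS", "SF")
    dat <- tibble::as_tibble(cbind(X, Y))
    A <- sample(1:4, 1)
    m <- fit_ribbon_pls(dat, responses = c("TS", "SF"), ncomp = A,
                        cv_folds = 5)
    got <- as.matrix(predict(m, dat))
    want <- svd_pls_predict(X, Y, A, X)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("scores are orthogonal and the squared VIPs average to one on every fit", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(200), 25, 8)
    Y <- cbind(TS = as.numeric(X %*% rnorm(8) + rnorm(25)),
               SF = as.numeric(X %*% rnorm(8) + rnorm(25)))
    colnames(X) <- paste0("x", 1:8)
    dat <- tibble::as_tibble(cbind(X, Y))
    m <- fit_ribbon_pls(dat, ncomp = 4, cv_folds = 5)
    G <- crossprod(m$scores)
    off <- G - diag(diag(G))
    norms <- sqrt(diag(G))
    expect_lt(max(abs(off) / outer(norms, norms)), 1e-8)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
    expect_equal(sum(m$vip^2), length(m$x_names), tolerance = 1e-8)
  }
})

test_that("VIP is one for symmetric independent predictors of equal relevance", {
  set.seed(4)
  n <- 4000 # large n so empirical correlations are negligible
  X <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rowSums(X)
  dat <- tibble::as_tibble(as.data.frame(X)); dat$y <- y
  m <- fit_ribbon_pls(dat, responses = "y", ncomp = 1, cv_folds = 5)
  expect_equal(unname(m$vip), rep(1, 4), tolerance = 0.05)
})

test_that("cross-validation gives Q2 <= R2Y, punishes noise and rewards structure", {
  set.seed(99)
  X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("x", 1:6)))
  noise <- tibble::as_tibble(as.data.frame(X))
  noise$y <- rnorm(50)
  cvn <- cross_validate_pls(X, as.matrix(noise[, "y"]), ncomp_max = 5)
  expect_true(all(cvn$Q2cum <= 0.1))

  lin <- tibble::as_tibble(as.data.frame(X))
  lin$y <- as.numeric(X %*% c(2, -1, 1, 0.5, 0, 0))
  cvl <- cross_validate_pls(X, as.matrix(lin[, "y"]), ncomp_max = 5)
  expect_gt(max(cvl$Q2cum), 0.99)

  m <- fit_ribbon_pls(lin, responses = "y", cv_folds = 7)
  expect_lte(m$Q2cum, m$r2y_cum[m$ncomp] + 1e-8)
  # fold assignment is deterministic under a fixed seed
  cv2 <- cross_validate_pls(X, as.matrix(lin[, "y"]), ncomp_max = 5)
  expect_identical(cvl$Q2cum, cv2$Q2cum)
})

test_that("coefficient predictions equal score-times-loading predictions", {
  set.seed(14)
  X <- matrix(rnorm(200), 25, 8, dimnames = list(NULL, paste0("x", 1:8)))
  Y <- cbind(TS = as.numeric(X %*% rnorm(8) + rnorm(25, 0, 0.2)),
             SF = as.numeric(X %*% rnorm(8) + rnorm(25, 0, 0.2)))
  dat <- tibble::as_tibble(cbind(X, Y))
  m <- fit_ribbon_pls(dat, ncomp = 3, cv_folds = 5)
  via_b <- as.matrix(predict(m, dat))
  pred_s <- m$scores %*% t(m$C)
  via_tc <- sweep(sweep(pred_s, 2, m$scale_y, "*"), 2, m$center_y, "+")
  expect_equal(unname(via_b), unname(via_tc), tolerance = 1e-10)

  # single predictor, single response reduces to simple regression
  d1 <- tibble::tibble(x = rnorm(30))
  d1$y <- 2 * d1$x + rnorm(30, 0, 0.1)
  d1$x2 <- rnorm(30) * 1e-8 + d1$x # near-duplicate to allow 1 comp
  m1 <- fit_ribbon_pls(d1, responses = "y", predictors = "x", ncomp = 1,
                       cv_folds = 5)
  cf <- pls_coefficients(m1)
  slope <- coef(lm(y ~ x, data = d1))[["x"]]
  expect_equal(cf$y_raw, slope, tolerance = 1e-10)
})

test_that("score-plane confidence limits match closed forms and flag outliers", {
  set.seed(123)
  n <- 4000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("x1", "x2")))
  dat <- tibble::as_tibble(as.data.frame(X))
  dat$y <- X[, 1] + X[, 2] + rnorm(n, 0, 0.05)
  m <- fit_ribbon_pls(dat, responses = "y", ncomp = 2, cv_folds = 5)
  lim <- score_limits(m)
  # standard-normal-ish 2-D scores: Hotelling ellipse ~ circle of radius
  # sqrt(chi2_{0.95}(2)) ~ 2.448 times the per-axis sd
  sds <- apply(m$scores, 2, sd)
  expect_equal(lim$hotelling$a / sds[1], sqrt(qchisq(0.95, 2)),
               tolerance = 0.02)
  expect_equal(lim$hotelling$b / sds[2], sqrt(qchisq(0.95, 2)),
               tolerance = 0.02)
  expect_lt(abs(mean(lim$outside) - 0.05), 0.01)
  d <- sqrt(rowSums(m$scores[, 1:2]^2))
  expect_equal(unname(lim$euclidean_radius), unname(quantile(d, 0.95)))
  expect_error(score_limits(m, comps = c(1, 2, 3)))
})

test_that("a serialized model restores with identical predictions", {
  fix <- make_lvm_fixture(n_materials = 12, seed = 5)
  m <- fit_ribbon_pls(fix$data, ncomp = 3, cv_folds = 5)
  path <- tempfile(fileext = ".json")
  write_pls_json(m, path)
  m2 <- read_pls_json(path)
  newdata <- fix$data[sample(nrow(fix$data), 10), ]
  expect_equal(predict(m2, newdata), predict(m, newdata), tolerance = 1e-12)
  expect_equal(m2$vip, m$vip, tolerance = 1e-12)
  expect_equal(glance(m2), glance(m), tolerance = 1e-12)
  unlink(path)
})

test_that("diagnostic plots build without error", {
  fix <- make_lvm_fixture(n_materials = 12, seed = 6)
  m <- fit_ribbon_pls(fix$data, ncomp = 2, cv_folds = 5)
  expect_s3_class(autoplot(m, "scores"), "ggplot")
  expect_s3_class(autoplot(m, "vip"), "ggplot")
  expect_s3_class(autoplot(m, "q2"), "ggplot")
  expect_s3_class(tidy(m), "tbl_df")
})
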