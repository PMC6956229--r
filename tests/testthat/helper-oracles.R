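# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the PLS oracle extracts weights by SVD of the
# cross-covariance, the strength-porosity oracle is a refining grid search
# on the log-space SSE, and the classification oracle is a scalar
# point-by-point rule walk.

# SVD-based PLS2 with the same deflation convention (X and Y deflated on
# the X-scores); returns raw-unit predictions for Xnew.
svd_pls_predict <- function(X, Y, A, Xnew) {
  sx <- scale(X)
  sy <- scale(Y)
  Xd <- sx[, , drop = FALSE]
  Yd <- sy[, , drop = FALSE]
  W <- NULL; P <- NULL; C <- NULL
  for (a in seq_len(A)) {
    sv <- svd(crossprod(Xd, Yd))
    w <- sv$u[, 1]
    tt <- Xd %*% w
    cc <- crossprod(Yd, tt) / sum(tt^2)
    pp <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(cc)
    W <- cbind(W, w); P <- cbind(P, pp); C <- cbind(C, cc)
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(C)
  Xn <- scale(Xnew, center = attr(sx, "scaled:center"),
              scale = attr(sx, "scaled:scale"))
  pred <- Xn %*% B
  sweep(sweep(pred, 2, attr(sy, "scaled:scale"), "*"),
        2, attr(sy, "scaled:center"), "+")
}

# Grid-search minimizer of the log-space SSE of ln(TS) = ln(TS0) - kb*eps,
# three refinement rounds of a 201 x 201 grid.
grid_search_rd <- function(eps, TS) {
  y <- log(TS)
  sse <- function(a, b) sum((y - (a - b * eps))^2)
  a0 <- mean(y); b0 <- 0
  half_a <- max(abs(y - mean(y))) + 5
  half_b <- 50
  for (round in 1:3) {
    as <- seq(a0 - half_a, a0 + half_a, length.out = 201)
    bs <- seq(b0 - half_b, b0 + half_b, length.out = 201)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(sse, grid$a, grid$b)
    best <- grid[which.min(vals), ]
    a0 <- best$a; b0 <- best$b
    half_a <- half_a / 40; half_b <- half_b / 40
  }
  list(TS0 = exp(a0), kb = b0, sse = sse(a0, b0))
}

# Scalar rule-walk RCBCS evaluator: classify each point, then combine by
# precedence (any target point -> I; else any above-band point -> II;
# else III), sub A when a qualifying pressure is at most 70 bar.
brute_classify <- function(pressure, SF, TS) {
  point_class <- character(0)
  qual_target <- numeric(0)
  qual_above <- numeric(0)
  for (i in seq_along(pressure)) {
    if (is.na(SF[i]) || is.na(TS[i])) next
    if (TS[i] < 1) next
    if (SF[i] >= 0.6 && SF[i] <= 0.8) {
      qual_target <- c(qual_target, pressure[i])
    } else if (SF[i] > 0.8) {
      qual_above <- c(qual_above, pressure[i])
    }
  }
  if (length(qual_target)) {
    main <- "I"; qual <- qual_target
  } else if (length(qual_above)) {
    main <- "II"; qual <- qual_above
  } else {
    return("III")
  }
  sub <- if (any(qual <= 70)) "A" else "B"
  paste0(main, sub)
}

random_profile <- function() {
  grid <- c(30, 50, 70, 90, 110)
  k <- sample(1:5, 1)
  p <- sort(sample(grid, k))
  SF <- runif(k, 0.3, 1)
  TS <- runif(k, 0, 3)
  SF[runif(k) < 0.1] <- NA
  TS[runif(k) < 0.1] <- NA
  list(pressure = p, SF = SF, TS = TS)
}

small_library <- function(seed = 11, ...) {
  generate_library(library_config(
    n_materials = 20, mix = c(IA = 7, IB = 2, IIA = 5, IIB = 3, III = 3),
    n_noncompactable = 1, seed = seed, ...))
}
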