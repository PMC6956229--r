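# Multi-response PLS (NIPALS PLS2) with venetian-blind cross-validation,
# VIP variable importance, regression coefficients and score-space
# confidence limits. Preprocessing is mean-centering + unit-variance
# scaling of every column of both blocks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Autoscale a numeric matrix
#'
#' Mean-centering and unit-variance scaling per column, the standard
#' chemometric preprocessing. The transform is invertible; a zero-variance
#' column is an error naming the column.
#'
#' @param x Numeric matrix (or data frame of numeric columns).
#' @return A list with `scaled` (matrix), `center`, `scale` (named
#'   vectors).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  list(scaled = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# Core NIPALS PLS2 on pre-scaled matrices. Returns weights W, X-loadings P,
# Y-loadings C (q x A), scores Tm (n x A), per-component explained sums of
# squares. Weight sign convention: first nonzero element of each weight
# vector is positive.
nipals_pls <- function(Xs, Ys, ncomp, tol = 1e-10, maxit = 500) {
  X <- Xs; Y <- Ys
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  ssx0 <- sum(Xs^2); ssy0 <- sum(Ys^2)
  r2x <- r2y <- ssy_comp <- numeric(ncomp)
  converged <- logical(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_new <- X %*% w
      cc <- crossprod(Y, t_new)[, 1] / sum(t_new^2)
      u <- (Y %*% cc) / sum(cc^2)
      if (sqrt(sum((t_new - t_old)^2)) < tol * max(sqrt(sum(t_new^2)), 1)) {
        converged[a] <- TRUE
        t_old <- t_new
        break
      }
      t_old <- t_new
    }
    if (!all(is.finite(t_old))) {
      stop("NIPALS iteration diverged for component ", a, call. = FALSE)
    }
    # near-degenerate minor components stall in direction while the
    # extracted subspace (hence predictions) is already stable; proceed
    # with the current vectors and record the status
    tvec <- as.numeric(t_old)
    # sign tie-break: first nonzero weight element positive
    nz <- which(abs(w) > 1e-12)[1]
    if (length(nz) && !is.na(nz) && w[nz] < 0) {
      w <- -w; tvec <- -tvec; cc <- -cc
    }
    pvec <- crossprod(X, tvec)[, 1] / sum(tvec^2)
    X <- X - tcrossprod(tvec, pvec)
    Y <- Y - tcrossprod(tvec, cc)
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cc; Tm[, a] <- tvec
    r2x[a] <- sum(tvec^2) * sum(pvec^2) / ssx0
    ssy_comp[a] <- sum(tvec^2) * sum(cc^2)
    r2y[a] <- ssy_comp[a] / ssy0
  }
  rot <- W %*% solve(crossprod(P, W)) # X-rotation: scores = Xs %*% rot
  B <- rot %*% t(C)
  list(W = W, P = P, C = C, scores = Tm, rotation = rot, B = B,
       r2x = r2x, r2y = r2y, ssy_comp = ssy_comp, converged = converged)
}

pls_vip <- function(W, ssy_comp) {
  p <- nrow(W)
  wt <- sweep(W^2, 2, colSums(W^2), "/") # guard against numeric drift
  as.numeric(sqrt(p * (wt %*% ssy_comp) / sum(ssy_comp)))
}

venetian_folds <- function(n, folds, seed) {
  ord <- with_seed(seed, sample.int(n))
  f <- integer(n)
  f[ord] <- ((seq_len(n) - 1L) %% folds) + 1L
  f
}

#' Cross-validate a PLS model over a range of component counts
#'
#' Venetian-blind fold assignment over a seed-shuffled row order (folds
#' deterministic given the seed). For each number of components `A`, each
#' fold is predicted from a model fitted (with its own autoscaling) on the
#' remaining folds; `Q2cum(A) = 1 - PRESS_A / SS` with `SS` the total sum
#' of squares of the mean-centered response block, and RMSECV per response.
#'
#' @param x Predictor matrix or data frame.
#' @param y Response matrix or data frame.
#' @param ncomp_max Largest component count to evaluate.
#' @param folds Number of folds (default 7).
#' @param seed Seed for the fold shuffle (default 1).
#' @return A tibble with columns `ncomp`, `Q2cum`, `press`, and one
#'   `rmsecv_<response>` column per response.
#' @export
cross_validate_pls <- function(x, y, ncomp_max, folds = 7, seed = 1) {
  X <- as.matrix(x); Y <- as.matrix(y)
  n <- nrow(X)
  if (n < 2 * folds) stop("need at least 2 rows per fold", call. = FALSE)
  ncomp_max <- min(ncomp_max, ncol(X), n - ceiling(n / folds) - 1)
  fold <- venetian_folds(n, folds, seed)
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  press <- matrix(0, ncomp_max, ncol(Y))
  n_pred <- 0L
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- !tr
    if (any(apply(Y[tr, , drop = FALSE], 2, stats::sd) == 0)) {
      warning("fold ", k, " lacks response variation; fold skipped",
              call. = FALSE)
      next
    }
    n_pred <- n_pred + sum(te)
    sx <- autoscale(X[tr, , drop = FALSE])
    sy <- autoscale(Y[tr, , drop = FALSE])
    fit <- nipals_pls(sx$scaled, sy$scaled, ncomp_max)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, sx$center), 2, sx$scale, "/")
    for (a in seq_len(ncomp_max)) {
      Ba <- fit$W[, 1:a, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:a, drop = FALSE],
                        fit$W[, 1:a, drop = FALSE])) %*%
        t(fit$C[, 1:a, drop = FALSE])
      pred_s <- Xte %*% Ba
      pred <- sweep(sweep(pred_s, 2, sy$scale, "*"), 2, sy$center, "+")
      press[a, ] <- press[a, ] + colSums((Y[te, , drop = FALSE] - pred)^2)
    }
  }
  press_tot <- rowSums(press)
  out <- tibble::tibble(
    ncomp = seq_len(ncomp_max),
    press = press_tot,
    Q2cum = 1 - press_tot / ss
  )
  rmse <- sqrt(press / max(n_pred, 1L))
  colnames(rmse) <- paste0("rmsecv_", colnames(Y))
  dplyr::bind_cols(out, tibble::as_tibble(rmse))
}

#' Fit a multi-response PLS model for ribbon quality
#'
#' NIPALS PLS2 with X-block deflation on autoscaled blocks. When `ncomp`
#' is `NULL` the component count is chosen by cross-validation as the
#' smallest `A` whose cumulative `Q2` gain over `A - 1` is below
#' `q2_gain` (capped at `ncomp_max`).
#'
#' @param data A data frame holding predictors and responses
#'   (observations = material x pressure rows).
#' @param responses Character vector of response column names
#'   (default `c("TS", "SF")`).
#' @param predictors Character vector of predictor columns; default all
#'   numeric columns except the responses and any of
#'   `material_id`, `category`, `type`.
#' @param ncomp Number of latent variables, or `NULL` to choose by CV.
#' @param ncomp_min Lower bound on the selected component count (default 1;
#'   set to 2 when the model feeds a two-component score-plane map).
#' @param ncomp_max Cap on the component count (default 10).
#' @param cv_folds,seed Cross-validation settings (venetian blinds).
#' @param q2_gain Q2 improvement threshold for component selection.
#' @return An object of class `ribbon_pls`: preprocessing statistics,
#'   weights / loadings / scores, rotation, coefficients, `r2x`/`r2y`
#'   (per component and cumulative), `Q2cum`, RMSEC / RMSECV per response,
#'   VIP per predictor, and the CV table.
#' @export
fit_ribbon_pls <- function(data, responses = c("TS", "SF"),
                           predictors = NULL, ncomp = NULL, ncomp_min = 1,
                           ncomp_max = 10, cv_folds = 7, seed = 1,
                           q2_gain = 0.01) {
  drop_cols <- c("material_id", "category", "type", "label")
  if (is.null(predictors)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(num, c(responses, drop_cols))
  }
  missing <- setdiff(c(predictors, responses), names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[predictors]); Y <- as.matrix(data[responses])
  if (anyNA(X) || anyNA(Y)) {
    stop("modeling matrices must not contain missing cells", call. = FALSE)
  }
  n <- nrow(X)
  cv_max <- if (is.null(ncomp)) ncomp_max else min(ncomp, ncomp_max)
  cv <- cross_validate_pls(X, Y, cv_max, folds = cv_folds, seed = seed)
  if (is.null(ncomp)) {
    gains <- diff(c(0, cv$Q2cum))
    pick <- which(gains < q2_gain)
    ncomp <- if (length(pick)) max(1L, pick[1] - 1L) else nrow(cv)
    ncomp <- max(ncomp, ncomp_min)
  }
  ncomp <- min(ncomp, ncomp_max, qr(scale(X))$rank)
  sx <- autoscale(X); sy <- autoscale(Y)
  core <- nipals_pls(sx$scaled, sy$scaled, ncomp)
  pred_s <- sx$scaled %*% core$B
  pred <- sweep(sweep(pred_s, 2, sy$scale, "*"), 2, sy$center, "+")
  rmsec <- sqrt(colMeans((Y - pred)^2))
  resid_y <- sy$scaled - pred_s
  r2ycum_final <- 1 - sum(resid_y^2) / sum(sy$scaled^2)
  obj <- structure(
    list(
      x_names = predictors, y_names = responses,
      center_x = sx$center, scale_x = sx$scale,
      center_y = sy$center, scale_y = sy$scale,
      W = core$W, P = core$P, C = core$C,
      scores = core$scores, rotation = core$rotation, B = core$B,
      ncomp = ncomp, n = n, nipals_converged = core$converged,
      r2x = core$r2x, r2x_cum = cumsum(core$r2x),
      r2y = core$r2y, r2y_cum = cumsum(core$r2y),
      r2y_cum_final = r2ycum_final,
      ssy_comp = core$ssy_comp,
      Q2cum = cv$Q2cum[ncomp], cv = cv,
      rmsec = rmsec,
      rmsecv = unlist(cv[ncomp, grep("^rmsecv_", names(cv))]),
      vip = stats::setNames(pls_vip(core$W, core$ssy_comp), predictors)
    ),
    class = "ribbon_pls"
  )
  obj
}

#' Predict from a fitted ribbon PLS model
#'
#' @param object A `ribbon_pls` model.
#' @param newdata Data frame containing all predictor columns (extra
#'   columns are ignored).
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A tibble of predicted responses in raw units.
#' @export
predict.ribbon_pls <- function(object, newdata, ncomp = object$ncomp, ...) {
  missing <- setdiff(object$x_names, names(newdata))
  if (length(missing)) {
    stop("newdata lacks predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Xs <- scale_new(object, newdata)
  a <- seq_len(ncomp)
  B <- object$W[, a, drop = FALSE] %*%
    solve(crossprod(object$P[, a, drop = FALSE],
                    object$W[, a, drop = FALSE])) %*%
    t(object$C[, a, drop = FALSE])
  pred_s <- Xs %*% B
  pred <- sweep(sweep(pred_s, 2, object$scale_y, "*"), 2, object$center_y, "+")
  colnames(pred) <- object$y_names
  tibble::as_tibble(pred)
}

scale_new <- function(object, newdata) {
  missing <- setdiff(object$x_names, names(newdata))
  if (length(missing)) {
    stop("newdata lacks predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(newdata)[object$x_names])
  sweep(sweep(X, 2, object$center_x), 2, object$scale_x, "/")
}

#' Project observations into the model's score space
#'
#' @param object A `ribbon_pls` model.
#' @param newdata Data frame with the model's predictor columns; default
#'   returns the training scores.
#' @return A tibble of scores `t1 ... tA`.
#' @export
pls_scores <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "ribbon_pls"))
  s <- if (is.null(newdata)) object$scores
       else scale_new(object, newdata) %*% object$rotation
  colnames(s) <- paste0("t", seq_len(ncol(s)))
  tibble::as_tibble(s)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` over the fitted
#' components, with normalized weight vectors; the mean of squared VIPs is
#' 1, so VIP > 1 flags above-average importance.
#'
#' @param object A `ribbon_pls` model.
#' @return A tibble `variable`, `vip`, sorted descending.
#' @export
pls_vip_table <- function(object) {
  stopifnot(inherits(object, "ribbon_pls"))
  tibble::tibble(variable = object$x_names, vip = unname(object$vip)) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' PLS regression coefficients
#'
#' Coefficients of the linear predictor in scaled space and back-scaled to
#' raw response units per unit of raw predictor.
#'
#' @param object A `ribbon_pls` model.
#' @return A tibble: `variable`, then `<response>_scaled` and
#'   `<response>_raw` columns.
#' @export
pls_coefficients <- function(object) {
  stopifnot(inherits(object, "ribbon_pls"))
  Bs <- object$B
  Braw <- sweep(sweep(Bs, 2, object$scale_y, "*"), 1, object$scale_x, "/")
  out <- tibble::tibble(variable = object$x_names)
  for (j in seq_along(object$y_names)) {
    out[[paste0(object$y_names[j], "_scaled")]] <- Bs[, j]
    out[[paste0(object$y_names[j], "_raw")]] <- Braw[, j]
  }
  out
}

#' Confidence limits in a two-component score plot
#'
#' Hotelling T2 ellipse from the F distribution for the chosen pair of
#' components, and the empirical Euclidean-distance radius (the
#' `level` quantile of the observations' score distances from the
#' origin).
#'
#' @param object A `ribbon_pls` model with at least the two requested
#'   components.
#' @param level Confidence level (default 0.95).
#' @param comps Which two components (default `c(1, 2)`).
#' @return A list: `hotelling` (semi-axes `a`, `b` and the T2 limit),
#'   `euclidean_radius`, `level`, `comps`, and `outside` (logical per
#'   training observation, by Hotelling T2).
#' @export
score_limits <- function(object, level = 0.95, comps = c(1, 2)) {
  stopifnot(inherits(object, "ribbon_pls"), length(comps) == 2)
  Tm <- object$scores[, comps, drop = FALSE]
  n <- nrow(Tm)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  v <- apply(Tm, 2, function(t) sum(t^2) / (n - 1))
  t2lim <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  t2 <- rowSums(sweep(Tm^2, 2, v, "/"))
  d <- sqrt(rowSums(Tm^2))
  list(
    hotelling = list(a = sqrt(v[1] * t2lim), b = sqrt(v[2] * t2lim),
                     t2_limit = t2lim, variances = v),
    euclidean_radius = unname(stats::quantile(d, level)),
    level = level, comps = comps,
    outside = t2 > t2lim
  )
}

#' @export
print.ribbon_pls <- function(x, ...) {
  cat("Ribbon PLS model:", length(x$x_names), "predictors,",
      length(x$y_names), "responses,", x$ncomp, "latent variables\n")
  cat(sprintf("  R2Xcum %.3f  R2Ycum %.3f  Q2cum %.3f\n",
              x$r2x_cum[x$ncomp], x$r2y_cum[x$ncomp], x$Q2cum))
  invisible(x)
}

#' @export
glance.ribbon_pls <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp, nobs = x$n,
    r2x_cum = x$r2x_cum[x$ncomp], r2y_cum = x$r2y_cum[x$ncomp],
    q2_cum = x$Q2cum
  )
}

#' @export
tidy.ribbon_pls <- function(x, ...) {
  coefs <- pls_coefficients(x)
  dplyr::left_join(pls_vip_table(x), coefs, by = "variable")
}

#' Plot PLS diagnostics
#'
#' `autoplot()` for a fitted ribbon PLS model: `"scores"` (first two LVs
#' with the Hotelling ellipse and Euclidean radius), `"vip"` (VIP bars
#' with the importance threshold) or `"q2"` (component selection curve).
#'
#' @param object A `ribbon_pls` model.
#' @param type One of `"scores"`, `"vip"`, `"q2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ribbon_pls <- function(object, type = c("scores", "vip", "q2"), ...) {
  type <- match.arg(type)
  if (type == "vip") {
    dat <- pls_vip_table(object)
    return(
      ggplot2::ggplot(dat, ggplot2::aes(
        x = stats::reorder(.data$variable, -.data$vip), y = .data$vip)) +
        ggplot2::geom_col() +
        ggplot2::geom_hline(yintercept = 1, linetype = 2) +
        ggplot2::labs(x = NULL, y = "VIP") +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           vjust = 0.5))
    )
  }
  if (type == "q2") {
    return(
      ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$ncomp,
                                              y = .data$Q2cum)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::geom_vline(xintercept = object$ncomp, linetype = 2) +
        ggplot2::labs(x = "latent variables", y = "cumulative Q2")
    )
  }
  lim <- score_limits(object)
  theta <- seq(0, 2 * pi, length.out = 256)
  ell <- tibble::tibble(t1 = lim$hotelling$a * cos(theta),
                        t2 = lim$hotelling$b * sin(theta))
  circ <- tibble::tibble(t1 = lim$euclidean_radius * cos(theta),
                         t2 = lim$euclidean_radius * sin(theta))
  sc <- pls_scores(object)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$t1, y = .data$t2)) +
    ggplot2::geom_path(data = ell, colour = "grey40") +
    ggplot2::geom_path(data = circ, colour = "steelblue", linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "t[1]", y = "t[2]")
}

#' Serialize / restore a ribbon PLS model as JSON
#'
#' Plain-text round-trip of the full model state; predictions from the
#' restored model are identical to the original.
#'
#' @param object A `ribbon_pls` model.
#' @param path Output (input) file path.
#' @return `write_pls_json()` returns `path` invisibly;
#'   `read_pls_json()` returns the restored `ribbon_pls`.
#' @export
write_pls_json <- function(object, path) {
  stopifnot(inherits(object, "ribbon_pls"))
  payload <- unclass(object)
  payload$cv <- as.data.frame(object$cv)
  for (f in c("W", "P", "C", "scores", "rotation", "B")) {
    payload[[f]] <- as.data.frame(object[[f]])
  }
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_pls_json
#' @export
read_pls_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("W", "P", "C", "scores", "rotation", "B")) {
    raw[[f]] <- as.matrix(as.data.frame(raw[[f]]))
    dimnames(raw[[f]]) <- NULL
  }
  for (f in c("center_x", "scale_x", "vip")) {
    raw[[f]] <- stats::setNames(as.numeric(raw[[f]]), raw$x_names)
  }
  for (f in c("center_y", "scale_y")) {
    raw[[f]] <- stats::setNames(as.numeric(raw[[f]]), raw$y_names)
  }
  raw$rmsec <- stats::setNames(as.numeric(raw$rmsec), raw$y_names)
  raw$rmsecv <- stats::setNames(as.numeric(raw$rmsecv),
                                paste0("rmsecv_", raw$y_names))
  raw$cv <- tibble::as_tibble(raw$cv)
  structure(raw, class = "ribbon_pls")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
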