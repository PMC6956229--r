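# Compaction models: the Ryshkewitch-Duckworth strength-porosity law
# TS = TS0 * exp(-kb * eps), fitted linearly on ln(TS) vs eps, and the
# power strength-pressure law TS = d * P^g, fitted by Levenberg-Marquardt
# in raw space. Both carry the applicability screen used to reject poor or
# physically unreasonable fits (r2 < 0.7, runaway TS0).

new_rd_fit <- function(TS0, kb, r2, n_points, applicable, reject_reason,
                       monotone = TRUE, data = NULL) {
  structure(
    list(TS0 = TS0, kb = kb, r2 = r2, n_points = n_points,
         applicable = applicable, reject_reason = reject_reason,
         monotone = monotone, data = data),
    class = "rd_fit"
  )
}

new_power_fit <- function(d, g, r2, n_points, applicable, reject_reason,
                          converged = TRUE, monotone = TRUE, data = NULL) {
  structure(
    list(d = d, g = g, r2 = r2, n_points = n_points,
         applicable = applicable, reject_reason = reject_reason,
         converged = converged, monotone = monotone, data = data),
    class = "power_fit"
  )
}

r2_of <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(0)
  1 - sum((obs - pred)^2) / sst
}

#' Fit the Ryshkewitch-Duckworth strength-porosity model
#'
#' Ordinary least squares of `ln(TS)` on porosity `eps`; the slope gives
#' the bonding-capacity coefficient `kb = -slope` and the intercept the
#' zero-porosity strength `TS0 = exp(intercept)`. `r2` is reported in log
#' space, matching the linearized presentation of the model. Points with
#' missing or non-positive TS are excluded, not imputed.
#'
#' @param eps Ribbon porosities (fractions).
#' @param TS Ribbon tensile strengths, MPa.
#' @param r2_threshold Applicability threshold on `r2` (default 0.7).
#' @param ts0_cap Reject fits whose extrapolated `TS0` exceeds this cap
#'   (default 1000 MPa), guarding against runaway intercepts from nearly
#'   porosity-invariant data.
#' @return An object of class `rd_fit` with elements `TS0`, `kb`, `r2`,
#'   `n_points`, `applicable`, `reject_reason`, `monotone`.
#' @seealso [predict.rd_fit()], [fit_power()]
#' @export
fit_rd <- function(eps, TS, r2_threshold = 0.7, ts0_cap = 1000) {
  keep <- is.finite(eps) & is.finite(TS) & TS > 0
  eps <- eps[keep]; TS <- TS[keep]
  n <- length(eps)
  if (n < 3) {
    return(new_rd_fit(NA_real_, NA_real_, NA_real_, n, FALSE, "too_few_points"))
  }
  y <- log(TS)
  ord <- order(eps, decreasing = TRUE)
  monotone <- !is.unsorted(TS[ord]) || !is.unsorted(rev(TS[ord]))
  if (stats::var(eps) == 0) {
    return(new_rd_fit(NA_real_, NA_real_, 0, n, FALSE, "low_r2",
                      monotone = monotone, data = tibble::tibble(eps = eps, TS = TS)))
  }
  fit <- stats::lm(y ~ eps)
  slope <- unname(stats::coef(fit)[2])
  TS0 <- exp(unname(stats::coef(fit)[1]))
  kb <- -slope
  r2 <- r2_of(y, stats::fitted(fit))
  reason <- if (r2 < r2_threshold) "low_r2"
            else if (TS0 > ts0_cap) "unreasonable_coeff"
            else "none"
  new_rd_fit(TS0, kb, r2, n, reason == "none", reason,
             monotone = monotone, data = tibble::tibble(eps = eps, TS = TS))
}

#' Predict tensile strength from a Ryshkewitch-Duckworth fit
#'
#' `TS = TS0 * exp(-kb * eps)`; strictly decreasing in porosity for
#' `kb > 0`, equal to `TS0` at zero porosity.
#'
#' @param object An `rd_fit` (or any list with `TS0` and `kb`).
#' @param eps Porosity (fraction) at which to predict.
#' @param ... Unused.
#' @return Predicted TS in MPa.
#' @export
predict.rd_fit <- function(object, eps, ...) {
  object$TS0 * exp(-object$kb * eps)
}

#' Evaluate the Ryshkewitch-Duckworth model at given coefficients
#'
#' Direct evaluation of `TS = TS0 * exp(-kb * eps)` without fitting, e.g.
#' to compare materials at a common porosity using published coefficients.
#'
#' @param TS0 Zero-porosity tensile strength, MPa.
#' @param kb Bonding-capacity coefficient (dimensionless).
#' @param eps Porosity, fraction in `[0, 1)`.
#' @return TS in MPa.
#' @examples
#' rd_strength(TS0 = 8.353, kb = 13.85, eps = 0.164)
#' @export
rd_strength <- function(TS0, kb, eps) {
  TS0 * exp(-kb * eps)
}

#' Fit the power strength-pressure model
#'
#' Nonlinear least squares of `TS = d * P^g` in raw space via
#' Levenberg-Marquardt, initialized from a log-log OLS line. `r2` is
#' reported in raw space. On non-convergence the log-log coefficients are
#' reported with the fit rejected (`low_r2`).
#'
#' @param P Hydraulic pressures, bar (`> 0`).
#' @param TS Ribbon tensile strengths, MPa.
#' @param r2_threshold Applicability threshold on raw-space `r2`.
#' @return An object of class `power_fit` with elements `d`, `g`, `r2`,
#'   `n_points`, `applicable`, `reject_reason`, `converged`, `monotone`.
#' @export
fit_power <- function(P, TS, r2_threshold = 0.7) {
  keep <- is.finite(P) & is.finite(TS) & TS > 0 & P > 0
  P <- P[keep]; TS <- TS[keep]
  n <- length(P)
  if (n < 3) {
    return(new_power_fit(NA_real_, NA_real_, NA_real_, n, FALSE,
                         "too_few_points"))
  }
  ord <- order(P)
  monotone <- !is.unsorted(TS[ord]) || !is.unsorted(rev(TS[ord]))
  dat <- tibble::tibble(P = P, TS = TS)
  ll <- stats::lm(log(TS) ~ log(P))
  start <- list(d = exp(unname(stats::coef(ll)[1])),
                g = unname(stats::coef(ll)[2]))
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(TS ~ d * P^g, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(nls_fit)) {
    r2 <- r2_of(TS, start$d * P^start$g)
    return(new_power_fit(start$d, start$g, r2, n, FALSE, "low_r2",
                         converged = FALSE, monotone = monotone, data = dat))
  }
  cf <- stats::coef(nls_fit)
  r2 <- r2_of(TS, unname(cf["d"]) * P^unname(cf["g"]))
  reason <- if (r2 < r2_threshold) "low_r2"
            else if (cf[["d"]] <= 0) "unreasonable_coeff"
            else "none"
  new_power_fit(unname(cf["d"]), unname(cf["g"]), r2, n, reason == "none",
                reason, monotone = monotone, data = dat)
}

#' Predict tensile strength from a power fit
#'
#' `TS = d * P^g`; strictly increasing in pressure for positive
#' coefficients, convex for `g > 1`, concave for `g < 1`, linear through
#' the origin at `g = 1`.
#'
#' @param object A `power_fit` (or any list with `d` and `g`).
#' @param P Hydraulic pressure, bar.
#' @param ... Unused.
#' @return Predicted TS in MPa.
#' @export
predict.power_fit <- function(object, P, ...) {
  object$d * P^object$g
}

#' Re-screen a fitted compaction model
#'
#' Applies the applicability screen (minimum point count, `r2` threshold,
#' coefficient cap for the zero-porosity strength) to an existing fit,
#' e.g. with a tightened threshold. Non-monotone TS sequences are flagged
#' as metadata, not rejected on their own.
#'
#' @param fit An `rd_fit` or `power_fit`.
#' @param r2_threshold Minimum `r2` for applicability.
#' @param ts0_cap Maximum admissible `TS0` (MPa) for `rd_fit` objects.
#' @return The fit with `applicable` and `reject_reason` updated.
#' @export
screen_fit <- function(fit, r2_threshold = 0.7, ts0_cap = 1000) {
  stopifnot(inherits(fit, "rd_fit") || inherits(fit, "power_fit"))
  reason <-
    if (fit$n_points < 3) "too_few_points"
    else if (!is.finite(fit$r2) || fit$r2 < r2_threshold) "low_r2"
    else if (inherits(fit, "rd_fit") && is.finite(fit$TS0) && fit$TS0 > ts0_cap)
      "unreasonable_coeff"
    else if (inherits(fit, "power_fit") && is.finite(fit$d) && fit$d <= 0)
      "unreasonable_coeff"
    else "none"
  fit$applicable <- reason == "none"
  fit$reject_reason <- reason
  fit
}

#' @export
print.rd_fit <- function(x, ...) {
  cat("Ryshkewitch-Duckworth fit: TS0 =", signif(x$TS0, 4), "MPa, kb =",
      signif(x$kb, 4), "\n  r2(log) =", signif(x$r2, 4), "on", x$n_points,
      "points;", if (x$applicable) "applicable" else
        paste0("rejected (", x$reject_reason, ")"), "\n")
  invisible(x)
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Power fit: TS = d * P^g with d =", signif(x$d, 4), ", g =",
      signif(x$g, 4), "\n  r2(raw) =", signif(x$r2, 4), "on", x$n_points,
      "points;", if (x$applicable) "applicable" else
        paste0("rejected (", x$reject_reason, ")"), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rd_fit <- function(x, ...) {
  tibble::tibble(term = c("TS0", "kb"), estimate = c(x$TS0, x$kb))
}

#' @export
glance.rd_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n_points,
                 applicable = x$applicable, reject_reason = x$reject_reason,
                 monotone = x$monotone)
}

#' @export
tidy.power_fit <- function(x, ...) {
  tibble::tibble(term = c("d", "g"), estimate = c(x$d, x$g))
}

#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n_points,
                 applicable = x$applicable, reject_reason = x$reject_reason,
                 converged = x$converged, monotone = x$monotone)
}

#' Fit both compaction models for every material in a profile table
#'
#' Runs [fit_rd()] (TS vs porosity) and [fit_power()] (TS vs pressure) per
#' material and returns one row per material with coefficients,
#' fit quality and applicability screening results.
#'
#' @param profiles Profile table from [build_profiles()] (columns
#'   `material_id`, `pressure_bar`, `eps`, `TS`).
#' @param r2_threshold Applicability threshold passed to both fits.
#' @param ts0_cap Zero-porosity strength cap passed to [fit_rd()].
#' @return A tibble with columns `material_id`, `TS0`, `kb`, `r2_rd`,
#'   `rd_applicable`, `rd_reject_reason`, `d`, `g`, `r2_pow`,
#'   `pow_applicable`, `pow_reject_reason`, `n_points`, `monotone`.
#' @export
fit_compaction_models <- function(profiles, r2_threshold = 0.7, ts0_cap = 1000) {
  profiles |>
    dplyr::group_by(.data$material_id) |>
    dplyr::group_map(function(df, key) {
      rd <- fit_rd(df$eps, df$TS, r2_threshold, ts0_cap)
      pw <- fit_power(df$pressure_bar, df$TS, r2_threshold)
      tibble::tibble(
        material_id = key$material_id,
        TS0 = rd$TS0, kb = rd$kb, r2_rd = rd$r2,
        rd_applicable = rd$applicable, rd_reject_reason = rd$reject_reason,
        d = pw$d, g = pw$g, r2_pow = pw$r2,
        pow_applicable = pw$applicable, pow_reject_reason = pw$reject_reason,
        n_points = rd$n_points, monotone = rd$monotone
      )
    }) |>
    dplyr::bind_rows()
}

#' Write a compaction fit table
#'
#' Comma-separated and JSON renderings of the per-material fit table.
#'
#' @param fits Output of [fit_compaction_models()].
#' @param path_csv,path_json Output paths; either may be `NULL` to skip.
#' @return `fits`, invisibly.
#' @export
write_fits <- function(fits, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) readr::write_csv(fits, path_csv)
  if (!is.null(path_json)) {
    jsonlite::write_json(fits, path_json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(fits)
}
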