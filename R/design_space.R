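# Multi-objective design space in latent-variable score space: refit the
# PLS model on the VIP > 1 predictors, then map the ribbon quality targets
# (TS >= 1 MPa, 0.6 <= SF <= 0.8) into the first-two-LV score plane.
# Because the two-component prediction is linear in (t1, t2), each target
# is a half-plane (TS) or a band (SF); the design space is their
# intersection with the 95% score-distance circle.

#' Refit a PLS model on its important variables
#'
#' Refits the model using only predictors whose VIP exceeds `vip_cutoff`
#' (default 1, the usual importance rule), with component count re-chosen
#' by cross-validation.
#'
#' @param object A fitted `ribbon_pls` model.
#' @param data The data frame the full model was fitted on.
#' @param vip_cutoff VIP threshold for retaining a predictor.
#' @param ... Passed to [fit_ribbon_pls()] (e.g. `ncomp`, `seed`).
#' @return A `ribbon_pls` fitted on the retained columns, with an
#'   attribute `"dropped"` listing the discarded predictors.
#' @export
refine_model <- function(object, data, vip_cutoff = 1, ...) {
  stopifnot(inherits(object, "ribbon_pls"))
  keep <- object$x_names[object$vip > vip_cutoff]
  if (length(keep) < 2) {
    stop("fewer than 2 predictors exceed the VIP cutoff; cannot refine",
         call. = FALSE)
  }
  refined <- fit_ribbon_pls(data, responses = object$y_names,
                            predictors = keep, ...)
  attr(refined, "dropped") <- setdiff(object$x_names, keep)
  refined
}

# Predicted raw-unit responses at score-plane points (t1, t2), using only
# the first two Y-loading columns: yhat = center + scale * (t1 c1 + t2 c2).
predict_at_scores <- function(object, t1, t2) {
  C2 <- object$C[, 1:2, drop = FALSE]
  if (any(colSums(abs(C2)) == 0)) {
    stop("degenerate Y-loadings: a component carries no response loading",
         call. = FALSE)
  }
  pred_s <- cbind(t1, t2) %*% t(C2)
  pred <- sweep(sweep(pred_s, 2, object$scale_y, "*"), 2, object$center_y, "+")
  colnames(pred) <- object$y_names
  pred
}

# Sutherland-Hodgman clip of a convex polygon (matrix with columns t1, t2)
# by the half-plane a . x <= b.
clip_halfplane <- function(poly, a, b) {
  if (!nrow(poly)) return(poly)
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  val <- poly %*% a - b
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- val[i] <= 0; pj_in <- val[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      s <- val[i] / (val[i] - val[j])
      out <- rbind(out, poly[i, ] + s * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Map ribbon quality targets into the score plane
#'
#' Builds the multi-objective design space of a (refined) PLS model: a
#' grid over the first two latent-variable scores is evaluated with the
#' two-component prediction, masked by the tensile strength target, the
#' solid fraction band and the score-distance confidence circle; their
#' conjunction is the design-space region. The region boundary is also
#' emitted analytically by clipping the confidence circle with the target
#' half-planes.
#'
#' @param object A `ribbon_pls` model with at least 2 components.
#' @param ts_min Tensile strength target, MPa (default 1).
#' @param sf_band Solid fraction band (default `c(0.6, 0.8)`).
#' @param level Confidence level for the score-distance limit.
#' @param limit `"euclidean"` (the empirical score-distance quantile, the
#'   default) or `"hotelling"` (ellipse approximated by its bounding
#'   circle is NOT used; the ellipse itself clips the region).
#' @param grid_n Grid resolution per axis (default 201), spanning 1.2x
#'   the limit radius.
#' @return An object of class `design_space`: `grid` (tibble `t1`, `t2`,
#'   `ts_ok`, `sf_ok`, `inside_limit`, `in_region`), `polygon` (region
#'   vertices), `area_fraction` (region area / limit-circle area),
#'   `radius`, `ts_min`, `sf_band`, `level` and the generating `model`.
#' @export
map_targets <- function(object, ts_min = 1, sf_band = c(0.6, 0.8),
                        level = 0.95, limit = c("euclidean", "hotelling"),
                        grid_n = 201) {
  stopifnot(inherits(object, "ribbon_pls"))
  if (object$ncomp < 2) stop("need a model with >= 2 components", call. = FALSE)
  limit <- match.arg(limit)
  lims <- score_limits(object, level = level)
  r <- if (limit == "euclidean") lims$euclidean_radius
       else max(lims$hotelling$a, lims$hotelling$b)
  ax <- seq(-1.2 * r, 1.2 * r, length.out = grid_n)
  grid <- tidyr::expand_grid(t1 = ax, t2 = ax)
  pred <- predict_at_scores(object, grid$t1, grid$t2)
  inside <-
    if (limit == "euclidean") sqrt(grid$t1^2 + grid$t2^2) <= r
    else (grid$t1^2 / lims$hotelling$a^2 + grid$t2^2 / lims$hotelling$b^2) <= 1
  iy_ts <- match("TS", object$y_names)
  iy_sf <- match("SF", object$y_names)
  grid <- grid |>
    dplyr::mutate(
      pred_TS = pred[, iy_ts], pred_SF = pred[, iy_sf],
      ts_ok = .data$pred_TS >= ts_min,
      sf_ok = .data$pred_SF >= sf_band[1] & .data$pred_SF <= sf_band[2],
      inside_limit = inside,
      in_region = .data$ts_ok & .data$sf_ok & .data$inside_limit
    )
  area_fraction <- {
    n_in <- sum(grid$inside_limit)
    if (n_in > 0) sum(grid$in_region) / n_in else 0
  }
  # analytic boundary: clip the limit circle/ellipse polygon by the three
  # linear constraints in scaled-prediction space
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- if (limit == "euclidean") {
    cbind(r * cos(theta), r * sin(theta))
  } else {
    cbind(lims$hotelling$a * cos(theta), lims$hotelling$b * sin(theta))
  }
  cts <- object$C[iy_ts, 1:2] * object$scale_y[iy_ts]
  csf <- object$C[iy_sf, 1:2] * object$scale_y[iy_sf]
  poly <- circle
  # TS: center + c . t >= ts_min  <=>  (-c) . t <= center - ts_min
  poly <- clip_halfplane(poly, -cts, object$center_y[iy_ts] - ts_min)
  poly <- clip_halfplane(poly, csf, sf_band[2] - object$center_y[iy_sf])
  poly <- clip_halfplane(poly, -csf, object$center_y[iy_sf] - sf_band[1])
  colnames(poly) <- c("t1", "t2")
  structure(
    list(grid = grid, polygon = tibble::as_tibble(poly),
         area_fraction = area_fraction, radius = r, ts_min = ts_min,
         sf_band = sf_band, level = level, limit = limit, model = object),
    class = "design_space"
  )
}

#' Project new materials onto a design space
#'
#' Scales the supplied rows with the refined model's preprocessing,
#' projects them onto the model weights and flags whether each row's
#' first-two-LV score point lies inside the design-space region.
#' Predictions with the full component count are reported alongside the
#' two-component score-plane predictions. Columns the refined model
#' discarded may be present and are ignored.
#'
#' @param ds A `design_space` from [map_targets()].
#' @param newdata Data frame with the refined model's predictor columns
#'   (e.g. one row per pressure level of a candidate material).
#' @return A tibble: scores `t1`, `t2`, two-LV predictions `pred_TS_2lv`,
#'   `pred_SF_2lv`, full-model predictions `pred_TS`, `pred_SF`, and
#'   logical `in_region`.
#' @export
project_material <- function(ds, newdata) {
  stopifnot(inherits(ds, "design_space"))
  model <- ds$model
  sc <- pls_scores(model, newdata)
  pred2 <- predict_at_scores(model, sc$t1, sc$t2)
  predA <- predict(model, newdata)
  iy_ts <- match("TS", model$y_names); iy_sf <- match("SF", model$y_names)
  inside <-
    if (ds$limit == "euclidean") sqrt(sc$t1^2 + sc$t2^2) <= ds$radius
    else {
      lims <- score_limits(model, level = ds$level)
      (sc$t1^2 / lims$hotelling$a^2 + sc$t2^2 / lims$hotelling$b^2) <= 1
    }
  tibble::tibble(
    t1 = sc$t1, t2 = sc$t2,
    pred_TS_2lv = pred2[, iy_ts], pred_SF_2lv = pred2[, iy_sf],
    pred_TS = predA[[model$y_names[iy_ts]]],
    pred_SF = predA[[model$y_names[iy_sf]]],
    in_region = pred2[, iy_ts] >= ds$ts_min &
      pred2[, iy_sf] >= ds$sf_band[1] & pred2[, iy_sf] <= ds$sf_band[2] &
      inside
  )
}

#' @export
print.design_space <- function(x, ...) {
  cat("Design space over the first two latent variables\n")
  cat(sprintf("  limit: %s radius %.3f (level %.2f); targets TS >= %g MPa, %g <= SF <= %g\n",
              x$limit, x$radius, x$level, x$ts_min, x$sf_band[1], x$sf_band[2]))
  cat(sprintf("  region area fraction within limit: %.3f\n", x$area_fraction))
  invisible(x)
}

#' Plot a design space
#'
#' Shaded target masks, the design-space region, the confidence circle
#' and (optionally) projected material score points.
#'
#' @param object A `design_space`.
#' @param points Optional tibble from [project_material()] (or any data
#'   frame with `t1`, `t2`) overlaid on the map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_space <- function(object, points = NULL, ...) {
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$t1, y = .data$t2)) +
    ggplot2::geom_tile(data = dplyr::filter(g, .data$ts_ok & .data$inside_limit),
                       fill = "gold", alpha = 0.4) +
    ggplot2::geom_tile(data = dplyr::filter(g, .data$sf_ok & .data$inside_limit),
                       fill = "skyblue", alpha = 0.4) +
    ggplot2::geom_tile(data = dplyr::filter(g, .data$in_region),
                       fill = "red", alpha = 0.6) +
    ggplot2::geom_path(data = object$polygon, colour = "black",
                       linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "t[1]", y = "t[2]")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, shape = 21, fill = "white")
  }
  p
}

#' Export a design space to plain-text files
#'
#' Writes the region polygon (JSON vertex list), the grid mask (CSV) and
#' optionally a membership table.
#'
#' @param ds A `design_space`.
#' @param dir Output directory (created if absent).
#' @param membership Optional tibble from [project_material()].
#' @return `dir`, invisibly.
#' @export
write_design_space <- function(ds, dir, membership = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(ds$polygon, file.path(dir, "region_polygon.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  readr::write_csv(ds$grid, file.path(dir, "grid_mask.csv"))
  if (!is.null(membership)) {
    readr::write_csv(membership, file.path(dir, "membership.csv"))
  }
  invisible(dir)
}
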