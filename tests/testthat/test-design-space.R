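fit_refined_pair <- function(seed = 31) {
  fix <- make_lvm_fixture(seed = seed)
  full <- fit_ribbon_pls(fix$data, ncomp = 4, cv_folds = 7, seed = seed)
  refined <- refine_model(full, fix$data, ncomp = 2, cv_folds = 7,
                          seed = seed)
  list(fix = fix, full = full, refined = refined)
}

test_that("model refinement keeps VIP > 1 columns and nearly preserves Q2", {
  pr <- fit_refined_pair()
  kept <- pr$refined$x_names
  expect_true(all(pr$full$vip[kept] > 1))
  expect_true("pressure" %in% kept)
  expect_false(any(grepl("^z", kept))) # true-zero columns discarded
  expect_setequal(attr(pr$refined, "dropped"),
                  setdiff(pr$full$x_names, kept))
  expect_lt(abs(pr$refined$Q2cum - pr$full$Q2cum), 0.05)

  # no informative variables -> nothing exceeds the cutoff
  expect_error(refine_model(pr$full, pr$fix$data, vip_cutoff = 100),
               "fewer than 2")
})

test_that("the design-space region is the exact conjunction of its masks", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, grid_n = 81)
  g <- ds$grid
  expect_identical(g$in_region, g$ts_ok & g$sf_ok & g$inside_limit)
  expect_true(all(g$in_region | !g$in_region)) # no NA
  expect_gte(ds$area_fraction, 0)
  expect_lte(ds$area_fraction, 1)
})

test_that("every grid point inside the region satisfies the direct 2-LV predictions", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, grid_n = 101)
  inside <- dplyr::filter(ds$grid, in_region)
  expect_gt(nrow(inside), 0)
  C2 <- pr$refined$C[, 1:2]
  pred_s <- cbind(inside$t1, inside$t2) %*% t(C2)
  raw <- sweep(sweep(pred_s, 2, pr$refined$scale_y, "*"), 2,
               pr$refined$center_y, "+")
  iy_ts <- match("TS", pr$refined$y_names)
  iy_sf <- match("SF", pr$refined$y_names)
  expect_true(all(raw[, iy_ts] >= ds$ts_min))
  expect_true(all(raw[, iy_sf] >= ds$sf_band[1] &
                    raw[, iy_sf] <= ds$sf_band[2]))
  expect_true(all(sqrt(inside$t1^2 + inside$t2^2) <= ds$radius))
})

test_that("the analytic boundary polygon agrees with the grid mask", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, grid_n = 101)
  poly <- as.matrix(ds$polygon)
  expect_gt(nrow(poly), 2)
  # all polygon vertices satisfy the constraints (up to numeric slack)
  pred <- sweep(sweep(poly %*% t(pr$refined$C[, 1:2]), 2,
                      pr$refined$scale_y, "*"), 2, pr$refined$center_y, "+")
  iy_ts <- match("TS", pr$refined$y_names)
  iy_sf <- match("SF", pr$refined$y_names)
  eps <- 1e-8
  expect_true(all(pred[, iy_ts] >= ds$ts_min - eps))
  expect_true(all(pred[, iy_sf] >= ds$sf_band[1] - eps &
                    pred[, iy_sf] <= ds$sf_band[2] + eps))
  expect_true(all(sqrt(rowSums(poly^2)) <= ds$radius * (1 + 1e-9)))
  # point-in-polygon oracle: grid points farther than 2 cells from the
  # polygon boundary must carry the same membership as the grid mask
  cell <- diff(sort(unique(ds$grid$t1)))[1]
  px <- ds$grid$t1; py <- ds$grid$t2
  n_v <- nrow(poly)
  inside_poly <- rep(FALSE, length(px))
  dist2 <- rep(Inf, length(px))
  for (i in seq_len(n_v)) {
    j <- if (i == n_v) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside_poly <- xor(inside_poly, crosses)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    tt <- pmin(1, pmax(0, ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) /
                         max(len2, 1e-300)))
    dist2 <- pmin(dist2, (px - (x1 + tt * (x2 - x1)))^2 +
                    (py - (y1 + tt * (y2 - y1)))^2)
  }
  far <- sqrt(dist2) > 2 * cell
  expect_identical(ds$grid$in_region[far], inside_poly[far])
})

test_that("an unattainable strength target empties the region", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, ts_min = 1e9, grid_n = 61)
  expect_equal(sum(ds$grid$in_region), 0)
  expect_equal(ds$area_fraction, 0)
  expect_equal(nrow(ds$polygon), 0)
})

test_that("training rows project onto their training scores and ignore dropped columns", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, grid_n = 61)
  proj <- project_material(ds, pr$fix$data)
  expect_equal(proj$t1, pr$refined$scores[, 1], tolerance = 1e-10)
  expect_equal(proj$t2, pr$refined$scores[, 2], tolerance = 1e-10)
  # adding discarded columns (or junk) does not change membership
  extra <- pr$fix$data
  extra$junk <- rnorm(nrow(extra))
  proj2 <- project_material(ds, extra)
  expect_identical(proj$in_region, proj2$in_region)
  # missing predictor column errors with its name
  bad <- pr$fix$data[setdiff(names(pr$fix$data), "pressure")]
  expect_error(project_material(ds, bad), "pressure")
})

test_that("a weak Category-III-like material projects outside the region at every pressure", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, grid_n = 61)
  # a material far on the weak side of every informative descriptor:
  # its predicted strength stays below the target at all pressures
  weak <- tibble::tibble(pressure = c(30, 50, 70, 90, 110))
  for (v in setdiff(pr$refined$x_names, "pressure")) {
    weak[[v]] <- min(pr$fix$data[[v]]) - 2 * sd(pr$fix$data[[v]])
  }
  proj <- project_material(ds, weak)
  expect_false(any(proj$in_region))
})

test_that("design-space exports and plot build", {
  pr <- fit_refined_pair()
  ds <- map_targets(pr$refined, grid_n = 41)
  dir <- tempfile()
  write_design_space(ds, dir, membership = project_material(ds, pr$fix$data))
  expect_true(file.exists(file.path(dir, "region_polygon.json")))
  expect_true(file.exists(file.path(dir, "grid_mask.csv")))
  expect_true(file.exists(file.path(dir, "membership.csv")))
  expect_s3_class(autoplot(ds), "ggplot")
  unlink(dir, recursive = TRUE)
})
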