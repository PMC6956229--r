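test_that("oil-intrusion porosity reproduces hand-computed values", {
  # V_oil = 0.15/0.85 = 0.17647, V_ribbon = 1.0 -> eps = 0.15
  expect_equal(ribbon_porosity(1.5, 1.65, 0.85, 1.5), 0.15, tolerance = 1e-10)
  expect_equal(ribbon_porosity(1.0, 1.0, 0.85, 1.4), 0) # no uptake -> SF = 1
  expect_error(ribbon_porosity(1.5, 1.4, 0.85, 1.5), "below dry mass")
  expect_error(ribbon_porosity(1.5, 1.6, 0, 1.5), "positive")
})

test_that("porosity is invariant to ribbon sample size", {
  set.seed(1)
  for (i in 1:20) {
    m <- runif(1, 0.5, 3)
    uptake <- runif(1, 0.05, 0.5)
    c0 <- runif(1, 0.5, 4)
    e1 <- ribbon_porosity(m, m + uptake, 0.85, 1.5)
    e2 <- ribbon_porosity(c0 * m, c0 * (m + uptake), 0.85, 1.5)
    expect_equal(e1, e2, tolerance = 1e-12)
    expect_true(e1 >= 0 && e1 < 1)
  }
})

test_that("three-point bending tensile strength follows TS = 3FL/(2WT^2)", {
  expect_equal(tensile_strength(10, 15, 25, 3), 1.000)
  expect_equal(tensile_strength(5, 15, 30, 2), 0.9375)
  # homogeneous in force; T^2 scaling
  expect_equal(tensile_strength(20, 15, 25, 3), 2 * tensile_strength(10, 15, 25, 3))
  expect_equal(tensile_strength(10, 15, 25, 6),
               tensile_strength(10, 15, 25, 3) / 4)
  expect_error(tensile_strength(-1, 15, 25, 3), "positive")
})

test_that("splitting tallies count T and L families independently", {
  s <- tibble::tibble(
    material_id = c("a", "b", "c"),
    pressure_bar = c(30, 50, 50),
    splitting_modes = c("T", "L2", "LJ")
  )
  tab <- splitting_frequency_table(s)
  get <- function(p, m) tab$n[tab$pressure_bar == p & tab$mode == m]
  expect_equal(get(30, "T"), 1L)
  expect_equal(get(50, "L_total"), 2L)
  expect_equal(get(50, "T"), 0L)
  expect_equal(get(30, "L_total"), 0L)

  empty <- splitting_frequency_table(s[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(splitting_frequency_table(
    tibble::tibble(material_id = "a", pressure_bar = 30,
                   splitting_modes = "X9")), "unknown splitting mode")

  # a ribbon with both T and an L mode counts once in each family
  both <- tibble::tibble(material_id = "a", pressure_bar = 70,
                         splitting_modes = "T;L2")
  tb <- splitting_frequency_table(both)
  expect_equal(tb$n[tb$mode == "T"], 1L)
  expect_equal(tb$n[tb$mode == "L_total"], 1L)

  r <- transversal_rate(tibble::tibble(
    material_id = letters[1:4], pressure_bar = 30,
    splitting_modes = c("T", "", "NO_RIBBON", "T;LJ")))
  expect_equal(r$n_transversal, 2L)
  expect_equal(r$n_tangible, 3L)
  expect_equal(r$rate_pct, 100 * 2 / 3)
})

test_that("tally marginals never exceed the tangible sample count", {
  lib <- small_library(seed = 9)
  samples <- dplyr::distinct(lib$ribbons, material_id, pressure_bar,
                             splitting_modes)
  tab <- splitting_frequency_table(samples)
  tangible <- samples |>
    dplyr::filter(splitting_modes != "NO_RIBBON") |>
    dplyr::count(pressure_bar)
  for (p in tangible$pressure_bar) {
    n_tan <- tangible$n[tangible$pressure_bar == p]
    expect_lte(tab$n[tab$pressure_bar == p & tab$mode == "T"], n_tan)
    expect_lte(tab$n[tab$pressure_bar == p & tab$mode == "L_total"], n_tan)
  }
})

test_that("profiles aggregate replicates by mean with SF = 1 - eps", {
  dt <- tibble::tibble(material_id = "m1", Dt = 1.5)
  mk <- function(eps, rep_i) {
    v_oil <- eps / (1 - eps) * (1.5 / 1.5)
    tibble::tibble(material_id = "m1", pressure_bar = 50, replicate = rep_i,
                   m_ribbon_g = 1.5, m_oilsat_g = 1.5 + v_oil * 0.85,
                   rho_oil = 0.85, width_mm = 25, thickness_mm = 3,
                   force_N = 10, span_mm = 15, splitting_modes = "")
  }
  one <- build_profile(mk(0.30, 1L), dt)
  expect_equal(one$eps, 0.30, tolerance = 1e-12)
  expect_equal(one$SF, 0.70, tolerance = 1e-12)
  expect_equal(one$TS, 1.0)

  three <- build_profile(dplyr::bind_rows(mk(0.30, 1L), mk(0.32, 2L),
                                          mk(0.34, 3L)), dt)
  expect_equal(three$eps, 0.32, tolerance = 1e-12)
  expect_equal(three$SF, 0.68, tolerance = 1e-12)
  expect_equal(three$n_reps, 3L)
  expect_equal(three$eps_sd, sd(c(0.30, 0.32, 0.34)))

  none <- tibble::tibble(material_id = "m1",
                         pressure_bar = c(30, 50), replicate = 1L,
                         m_ribbon_g = NA_real_, m_oilsat_g = NA_real_,
                         rho_oil = 0.85, width_mm = NA_real_,
                         thickness_mm = NA_real_, force_N = NA_real_,
                         span_mm = 15, splitting_modes = "NO_RIBBON")
  flagged <- build_profile(none, dt)
  expect_true(all(flagged$non_compactable))
  expect_true(all(is.na(flagged$TS)))

  mixed <- dplyr::bind_rows(mk(0.3, 1L),
                            dplyr::mutate(mk(0.3, 1L), material_id = "m2"))
  expect_error(build_profile(mixed, dt), "single material")
})

test_that("profile SF + eps is identically one across a generated library", {
  lib <- small_library(seed = 2)
  desc <- compute_descriptors(lib$raw, lib$psd)
  prof <- build_profiles(lib$ribbons, desc)
  ok <- !is.na(prof$eps)
  expect_identical(prof$SF[ok] + prof$eps[ok], rep(1, sum(ok)))
  expect_true(all(diff(prof$pressure_bar[prof$material_id == prof$material_id[1]]) > 0))
})
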