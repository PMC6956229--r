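test_that("density and packing descriptors reproduce hand-computed values", {
  d <- bulk_and_tapped_density(100, 200, 160)
  expect_equal(d$Da, 0.500)
  expect_equal(d$Dc, 0.625)
  expect_true(d$Dc >= d$Da)

  same <- bulk_and_tapped_density(100, 150, 150)
  expect_equal(same$Da, same$Dc)
  expect_error(bulk_and_tapped_density(0, 200, 160), "positive")
  expect_error(bulk_and_tapped_density(100, 150, 160), "exceeds")

  p <- packing_indices(0.500, 0.625)
  expect_equal(p$Ie, 0.400)
  expect_equal(p$IC, 20.0)
  expect_equal(p$IH, 1.25)
  expect_equal(packing_indices(0.7, 0.7), tibble::tibble(Ie = 0, IC = 0, IH = 1))
  expect_error(packing_indices(0, 0.5), "positive")
  expect_error(packing_indices(0.7, 0.6), "inconsistent")
})

test_that("packing indices are scale-invariant and obey IC = 100(1 - 1/IH)", {
  set.seed(42)
  for (i in 1:25) {
    Da <- runif(1, 0.2, 1)
    Dc <- Da * runif(1, 1, 1.8)
    cc <- runif(1, 0.5, 3)
    p1 <- packing_indices(Da, Dc)
    p2 <- packing_indices(cc * Da, cc * Dc)
    expect_equal(p2$IC, p1$IC, tolerance = 1e-12)
    expect_equal(p2$IH, p1$IH, tolerance = 1e-12)
    expect_true(p1$IH >= 1 && p1$IC >= 0)
    expect_equal(p1$IC, 100 * (1 - 1 / p1$IH), tolerance = 1e-12)
  }
})

test_that("angle of repose, hygroscopicity and true density follow their formulas", {
  expect_equal(angle_of_repose(25, 50), 45)
  expect_equal(angle_of_repose(0, 50), 0)
  expect_equal(angle_of_repose(25, 100), atan(0.5) * 180 / pi)
  expect_lt(angle_of_repose(1e6, 1), 90)
  expect_error(angle_of_repose(10, 0), "positive")

  expect_equal(hygroscopicity(10.0, 11.0, 11.2), 20.0)
  expect_equal(hygroscopicity(9, 12, 12), 0)
  expect_lt(hygroscopicity(10, 11, 10.9), 0) # mass loss allowed
  expect_error(hygroscopicity(10, 10, 11), "empty sample")

  expect_equal(true_density(3.0, 10.0, 8.0), 1.5)
  expect_error(true_density(3.0, 8.0, 10.0), "V1")
})

test_that("powder solid fraction and porosity always sum to one", {
  sf <- powder_solid_fraction(0.5, 1.5)
  expect_equal(sf$SFp, 1 / 3, tolerance = 1e-12)
  expect_equal(sf$epsP, 2 / 3, tolerance = 1e-12)
  expect_equal(powder_solid_fraction(1.2, 1.2),
               tibble::tibble(SFp = 1, epsP = 0))
  # library-extreme consistency: highly porous cellulose-like powder
  expect_equal(powder_solid_fraction(0.26, 1.68)$epsP, 0.845, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:20) {
    Da <- runif(1, 0.1, 1.6)
    Dt <- runif(1, Da, 3)
    s <- powder_solid_fraction(Da, Dt)
    expect_identical(s$SFp + s$epsP, 1)
  }
  expect_warning(powder_solid_fraction(2, 1.5), "exceeds")
})

test_that("PSD span, fines percentage and homogeneity index behave as defined", {
  h <- psd_histogram(c(0, 25, 75, 200), c(30, 40, 30),
                     d10 = 10, d50 = 50, d90 = 150)
  s <- psd_summary(h)
  expect_equal(s$span, 2.8)
  # cumulative at 50 um: 30 + 40 * (50-25)/50 = 50
  expect_equal(s$PfPct, 50)

  mono <- psd_histogram(c(40, 60), 100, d10 = 50, d50 = 50, d90 = 50)
  expect_equal(psd_summary(mono)$span, 0)
  expect_equal(homogeneity_index(mono), 1) # single bin: Fm / 100

  fine <- psd_histogram(c(1, 10, 40), c(50, 50))
  expect_equal(psd_summary(fine)$PfPct, 100)

  expect_error(psd_histogram(c(0, 10), c(50)), "sum to 100")
  expect_error(psd_histogram(c(10, 5), c(100)), "ascending")
})

test_that("homogeneity index shrinks as mass moves to farther bins", {
  edges <- seq(0, 600, by = 100)
  base <- c(0, 0, 100, 0, 0, 0)
  i_prev <- Inf
  for (shift in c(0, 10, 20, 30)) {
    f <- base
    f[3] <- 100 - 2 * shift
    f[1] <- shift  # two bins below majority
    f[5] <- shift  # two bins above majority
    i_now <- homogeneity_index(psd_histogram(edges, f))
    expect_lt(i_now, i_prev + 1e-12)
    i_prev <- i_now
  }
  # tie on the majority bin resolves to the smaller-diameter bin
  tie <- psd_histogram(edges, c(40, 40, 20, 0, 0, 0))
  d <- (edges[-7] + edges[-1]) / 2
  denom <- 100 + (d[2] - d[1]) * 40 + (d[3] - d[1]) * 20
  expect_equal(homogeneity_index(tie), 40 / denom)
})

test_that("descriptor table computation matches the scalar operations and round-trips CSV", {
  lib <- small_library(seed = 4)
  desc <- compute_descriptors(lib$raw, lib$psd)
  expect_equal(nrow(desc), 20)
  expect_named(desc, c("material_id", descriptor_columns()))
  expect_false(anyNA(desc))
  i <- 5
  expect_equal(desc$Da[i],
               lib$raw$sample_mass_g[i] / lib$raw$bulk_volume_ml[i])
  expect_equal(desc$Dt[i], true_density(lib$raw$td_mass_g[i],
                                        lib$raw$td_v1_ml[i],
                                        lib$raw$td_v2_ml[i]))
  expect_equal(desc$SFp + desc$epsP, rep(1, nrow(desc)))
  expect_equal(desc$IC, 100 * (1 - 1 / desc$IH), tolerance = 1e-12)
  expect_true(all(desc$D10 <= desc$D50 & desc$D50 <= desc$D90))

  prov <- descriptor_provenance()
  expect_setequal(prov$descriptor, descriptor_columns())
  expect_true(all(c("Da", "span", "Itheta") %in%
                    prov$descriptor[prov$source == "computed"]))
  expect_true(all(c("Icd", "tflow", "Co") %in%
                    prov$descriptor[prov$source == "measured"]))

  path <- tempfile(fileext = ".csv")
  rounded <- dplyr::mutate(desc, dplyr::across(-material_id, ~ signif(.x, 6)))
  write_descriptors(rounded, path)
  back <- read_descriptors(path)
  expect_equal(as.data.frame(back), as.data.frame(rounded))
  unlink(path)
})
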