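#' Bulk and tapped density
#'
#' Bulk density `Da = m / Va` and tapped density `Dc = m / Vc` from the
#' cylinder mass and the loose / tapped powder volumes.
#'
#' @param m Sample mass in g.
#' @param Va Bulk (loose) volume in mL.
#' @param Vc Tapped volume in mL. Must satisfy `Vc <= Va`.
#' @return A tibble with columns `Da` and `Dc` (g/mL).
#' @examples
#' bulk_and_tapped_density(100, 200, 160)
#' @export
bulk_and_tapped_density <- function(m, Va, Vc) {
  if (any(m <= 0) || any(Va <= 0) || any(Vc <= 0)) {
    stop("invalid measurement: mass and volumes must be positive", call. = FALSE)
  }
  if (any(Vc > Va)) {
    stop("invalid measurement: tapped volume Vc exceeds bulk volume Va", call. = FALSE)
  }
  tibble::tibble(Da = m / Va, Dc = m / Vc)
}

#' Packing (flowability) indices from bulk and tapped density
#'
#' Inter-particle porosity `Ie = (Dc - Da) / (Dc * Da)`, Carr index
#' `IC = (Dc - Da) / Dc * 100` and Hausner ratio `IH = Dc / Da`.
#'
#' The Carr index and Hausner ratio are scale-free: multiplying both
#' densities by a constant leaves them unchanged. `Ie` carries the printed
#' mL/g dimension of its defining formula and is stored as computed.
#'
#' @param Da,Dc Bulk and tapped density in g/mL, `Dc >= Da > 0`.
#' @return A tibble with columns `Ie`, `IC` (percent), `IH`.
#' @examples
#' packing_indices(0.5, 0.625)
#' @export
packing_indices <- function(Da, Dc) {
  if (any(Da <= 0) || any(Dc <= 0)) {
    stop("invalid measurement: densities must be positive", call. = FALSE)
  }
  if (any(Dc < Da)) {
    stop("inconsistent densities: tapped density Dc below bulk density Da", call. = FALSE)
  }
  tibble::tibble(
    Ie = (Dc - Da) / (Dc * Da),
    IC = (Dc - Da) / Dc * 100,
    IH = Dc / Da
  )
}

#' Angle of repose from cone dimensions
#'
#' `tan(AOR) = 2 h / r` with cone height `h` and base diameter `r`,
#' returned in degrees.
#'
#' @param h Cone height, mm (`>= 0`).
#' @param r Cone base diameter, mm (`> 0`).
#' @return Angle of repose in degrees, in `[0, 90)`.
#' @examples
#' angle_of_repose(25, 100) # atan(0.5) in degrees
#' @export
angle_of_repose <- function(h, r) {
  if (any(r <= 0)) stop("invalid measurement: cone diameter must be positive", call. = FALSE)
  if (any(h < 0)) stop("invalid measurement: cone height must be non-negative", call. = FALSE)
  atan(2 * h / r) * 180 / pi
}

#' Hygroscopicity from bottle weighings
#'
#' `%H = (m3 - m2) / (m2 - m1) * 100`, where `m1` is the dry bottle, `m2`
#' the bottle plus sample before exposure and `m3` after 24 h at 80% RH.
#' Negative values (mass loss) are legitimate and preserved.
#'
#' @param m1,m2,m3 Weights in g, `m2 > m1`.
#' @return Hygroscopicity in percent.
#' @export
hygroscopicity <- function(m1, m2, m3) {
  if (any(m2 <= m1)) stop("invalid measurement: empty sample (m2 <= m1)", call. = FALSE)
  (m3 - m2) / (m2 - m1) * 100
}

#' True density by gas displacement
#'
#' `Dt = m / (V1 - V2)` with the empty-cell volume `V1` and the volume
#' after loading the sample `V2`. Replicate-convergence stopping is
#' instrument behaviour upstream of this computation.
#'
#' @param m Sample mass, g.
#' @param V1,V2 Cell volumes in mL, `V1 > V2`.
#' @return True density in g/mL.
#' @export
true_density <- function(m, V1, V2) {
  if (any(m <= 0)) stop("invalid measurement: mass must be positive", call. = FALSE)
  if (any(V1 <= V2)) stop("invalid measurement: displaced volume non-positive (V1 <= V2)", call. = FALSE)
  m / (V1 - V2)
}

#' Powder solid fraction and porosity
#'
#' `SFp = Da / Dt` and `eps_p = 1 - SFp`. The two always sum to one. If a
#' bulk density exceeds the true density the pair is still reported (with a
#' warning) so that inconsistent measurements remain auditable.
#'
#' @param Da Bulk density, g/mL.
#' @param Dt True density, g/mL.
#' @return A tibble with columns `SFp` and `epsP` (fractions).
#' @export
powder_solid_fraction <- function(Da, Dt) {
  if (any(Da <= 0) || any(Dt <= 0)) {
    stop("invalid measurement: densities must be positive", call. = FALSE)
  }
  if (any(Da > Dt)) {
    warning("bulk density exceeds true density for some rows; reporting as measured",
            call. = FALSE)
  }
  SFp <- Da / Dt
  tibble::tibble(SFp = SFp, epsP = 1 - SFp)
}

#' Particle size distribution summary: span and fines fraction
#'
#' `span = (D90 - D10) / D50`; `%Pf` is the cumulative percentage of
#' particles below 50 um obtained by linear interpolation of the cumulative
#' undersize curve on the histogram bin edges.
#'
#' @param psd A PSD histogram as returned by [psd_histogram()].
#' @param fines_cutoff_um Cut-off for the fines percentage (default 50 um).
#' @return A tibble with columns `span` and `PfPct`.
#' @export
psd_summary <- function(psd, fines_cutoff_um = 50) {
  stopifnot(inherits(psd, "psd_histogram"))
  if (psd$d50 <= 0) stop("invalid PSD: D50 must be positive", call. = FALSE)
  span <- (psd$d90 - psd$d10) / psd$d50
  edges <- psd$bin_edges
  cum <- c(0, cumsum(psd$freq_pct))
  PfPct <-
    if (fines_cutoff_um <= edges[1]) 0
    else if (fines_cutoff_um >= edges[length(edges)]) 100
    else stats::approx(edges, cum, xout = fines_cutoff_um)$y
  tibble::tibble(span = span, PfPct = PfPct)
}

#' Construct a particle size distribution histogram
#'
#' Bundles bin edges, per-bin frequency (percent) and the instrument's
#' reported quantiles into a validated object used by [psd_summary()] and
#' [homogeneity_index()]. When quantiles are omitted they are interpolated
#' from the cumulative undersize curve.
#'
#' @param bin_edges Ascending bin edges, um (length `nbins + 1`).
#' @param freq_pct Per-bin frequency in percent, summing to 100 (+-0.01).
#' @param d10,d50,d90 Optional instrument-reported quantiles, um.
#' @return An object of class `psd_histogram`.
#' @export
psd_histogram <- function(bin_edges, freq_pct, d10 = NULL, d50 = NULL, d90 = NULL) {
  if (length(bin_edges) != length(freq_pct) + 1L) {
    stop("bin_edges must be one longer than freq_pct", call. = FALSE)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly ascending", call. = FALSE)
  }
  if (any(freq_pct < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(freq_pct) - 100) > 0.01) {
    stop("frequencies must sum to 100 (+-0.01)", call. = FALSE)
  }
  qfun <- function(p) {
    cum <- c(0, cumsum(freq_pct))
    stats::approx(cum, bin_edges, xout = p, ties = "ordered")$y
  }
  d10 <- if (is.null(d10)) qfun(10) else d10
  d50 <- if (is.null(d50)) qfun(50) else d50
  d90 <- if (is.null(d90)) qfun(90) else d90
  if (!(d10 <= d50 && d50 <= d90)) {
    stop("quantiles must satisfy D10 <= D50 <= D90", call. = FALSE)
  }
  structure(
    list(bin_edges = bin_edges, freq_pct = freq_pct,
         d10 = d10, d50 = d50, d90 = d90),
    class = "psd_histogram"
  )
}

#' Homogeneity index of a particle size distribution
#'
#' SeDeM homogeneity index: with majority bin `m` (largest frequency; ties
#' resolved to the smaller-diameter bin), mean bin diameters `d` in um and
#' frequencies `F` in percent,
#' `Itheta = Fm / (100 + sum_n (d_{m+n} - d_m) F_{m+n} + (d_m - d_{m-n}) F_{m-n})`.
#' A single occupied bin gives `Fm / 100 = 1`; spreading mass into farther
#' bins grows the denominator and shrinks the index.
#'
#' @param psd A [psd_histogram()] object.
#' @return The homogeneity index, in `(0, 1]`.
#' @export
homogeneity_index <- function(psd) {
  stopifnot(inherits(psd, "psd_histogram"))
  f <- psd$freq_pct
  if (all(f <= 0)) stop("invalid PSD: empty histogram", call. = FALSE)
  d <- (psd$bin_edges[-length(psd$bin_edges)] + psd$bin_edges[-1]) / 2
  m <- which.max(f) # which.max takes the first (smaller-diameter) tie
  denom <- 100 + sum(abs(d - d[m]) * f)
  f[m] / denom
}

# Canonical descriptor column order (Table-3 symbol schema of the CSV interface)
descriptor_columns <- function() {
  c("D10", "D50", "D90", "span", "PfPct", "Itheta", "Da", "Dc", "Dt",
    "SFp", "epsP", "IH", "IC", "Ie", "tflow", "AOR", "HRpct", "Hpct",
    "Icd", "Co", "Sp", "Spco")
}

#' Provenance of the 22 powder descriptors
#'
#' Which descriptors are computed from raw measurements and which are
#' validated pass-throughs of directly measured quantities.
#'
#' @return A tibble with columns `descriptor` and `source`
#'   (`"computed"` or `"measured"`).
#' @export
descriptor_provenance <- function() {
  measured <- c("D10", "D50", "D90", "tflow", "HRpct", "Icd", "Co", "Sp", "Spco")
  tibble::tibble(
    descriptor = descriptor_columns(),
    source = ifelse(descriptor_columns() %in% measured, "measured", "computed")
  )
}

#' Compute the 22-descriptor vector for each material
#'
#' Takes a raw powder measurement table (one row per material) and a long
#' PSD histogram table and returns the per-material descriptor table in the
#' Table-3 symbol schema. Directly measured descriptors (flow time,
#' moisture, tablet hardness, texture metrics) are range-validated and
#' passed through; all others are computed from the raw readings.
#'
#' @param raw A data frame with one row per material and columns
#'   `material_id`, `sample_mass_g`, `bulk_volume_ml`, `tapped_volume_ml`,
#'   `cone_height_mm`, `cone_diameter_mm`, `flow_time_s`, `moisture_pct`,
#'   `m1_g`, `m2_g`, `m3_g`, `td_mass_g`, `td_v1_ml`, `td_v2_ml`,
#'   `tablet_hardness_n`, `co`, `sp`, `spco`, and optionally
#'   `d10_um`, `d50_um`, `d90_um` (instrument-reported quantiles).
#' @param psd A data frame with columns `material_id`, `bin_lower_um`,
#'   `bin_upper_um`, `freq_pct` describing each material's PSD histogram.
#' @return A tibble, one row per material, with `material_id` followed by
#'   the 22 descriptor columns (see [descriptor_provenance()]).
#' @export
compute_descriptors <- function(raw, psd) {
  req <- c("material_id", "sample_mass_g", "bulk_volume_ml", "tapped_volume_ml",
           "cone_height_mm", "cone_diameter_mm", "flow_time_s", "moisture_pct",
           "m1_g", "m2_g", "m3_g", "td_mass_g", "td_v1_ml", "td_v2_ml",
           "tablet_hardness_n", "co", "sp", "spco")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("raw measurement table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(raw$flow_time_s < 0, na.rm = TRUE) || any(raw$tablet_hardness_n < 0)) {
    stop("invalid measurement: flow time and tablet hardness must be non-negative",
         call. = FALSE)
  }

  dens <- bulk_and_tapped_density(raw$sample_mass_g, raw$bulk_volume_ml,
                                  raw$tapped_volume_ml)
  pack <- packing_indices(dens$Da, dens$Dc)
  Dt <- true_density(raw$td_mass_g, raw$td_v1_ml, raw$td_v2_ml)
  sf <- powder_solid_fraction(dens$Da, Dt)

  per_psd <- psd |>
    dplyr::group_by(.data$material_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$bin_lower_um)
      id <- key$material_id
      i <- match(id, raw$material_id)
      h <- psd_histogram(
        c(df$bin_lower_um, df$bin_upper_um[nrow(df)]), df$freq_pct,
        d10 = if ("d10_um" %in% names(raw)) raw$d10_um[i] else NULL,
        d50 = if ("d50_um" %in% names(raw)) raw$d50_um[i] else NULL,
        d90 = if ("d90_um" %in% names(raw)) raw$d90_um[i] else NULL
      )
      s <- psd_summary(h)
      tibble::tibble(material_id = id, D10 = h$d10, D50 = h$d50, D90 = h$d90,
                     span = s$span, PfPct = s$PfPct,
                     Itheta = homogeneity_index(h))
    }) |>
    dplyr::bind_rows()

  tibble::tibble(
    material_id = raw$material_id,
    Da = dens$Da, Dc = dens$Dc, Dt = Dt,
    SFp = sf$SFp, epsP = sf$epsP,
    IH = pack$IH, IC = pack$IC, Ie = pack$Ie,
    tflow = raw$flow_time_s,
    AOR = angle_of_repose(raw$cone_height_mm, raw$cone_diameter_mm),
    HRpct = raw$moisture_pct,
    Hpct = hygroscopicity(raw$m1_g, raw$m2_g, raw$m3_g),
    Icd = raw$tablet_hardness_n,
    Co = raw$co, Sp = raw$sp, Spco = raw$spco
  ) |>
    dplyr::left_join(per_psd, by = "material_id") |>
    dplyr::select("material_id", dplyr::all_of(descriptor_columns()))
}

#' Read / write descriptor tables
#'
#' Comma-separated, UTF-8, decimal point, one row per material, columns
#' named by the Table-3 symbols.
#'
#' @param path File path.
#' @return `read_descriptors()` returns a tibble; `write_descriptors()`
#'   returns `path` invisibly.
#' @export
read_descriptors <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_descriptors
#' @param x Descriptor tibble.
#' @export
write_descriptors <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
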