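# Ribbon quality metrology: oil-intrusion porosity, three-point bending
# tensile strength, splitting-mode tallies and per-material compaction
# profiles.

#' Ribbon porosity by oil intrusion
#'
#' From the dry ribbon mass, the oil-saturated mass, the oil density and
#' the material's true density:
#' `V_oil = (m_oilsat - m_ribbon) / rho_oil`, `V_ribbon = m_ribbon / rho_true`,
#' `eps = V_oil / (V_oil + V_ribbon)`. Stored as a fraction; the percent
#' form is applied only when rendering reports.
#'
#' @param m_ribbon Dry ribbon mass, g.
#' @param m_oilsat Oil-saturated ribbon mass, g (`>= m_ribbon`).
#' @param rho_oil Paraffin oil density, g/mL.
#' @param rho_true Material true density (powder `Dt`), g/mL.
#' @return Porosity as a fraction in `[0, 1)`.
#' @examples
#' ribbon_porosity(1.5, 1.65, 0.85, 1.5) # 0.15
#' @export
ribbon_porosity <- function(m_ribbon, m_oilsat, rho_oil, rho_true) {
  if (any(rho_oil <= 0, na.rm = TRUE) || any(rho_true <= 0, na.rm = TRUE)) {
    stop("invalid measurement: densities must be positive", call. = FALSE)
  }
  if (any(m_ribbon <= 0, na.rm = TRUE)) {
    stop("invalid measurement: ribbon mass must be positive", call. = FALSE)
  }
  if (any(m_oilsat < m_ribbon, na.rm = TRUE)) {
    stop("invalid measurement: oil-saturated mass below dry mass", call. = FALSE)
  }
  v_oil <- (m_oilsat - m_ribbon) / rho_oil
  v_ribbon <- m_ribbon / rho_true
  tot <- v_oil + v_ribbon
  if (any(tot <= 0, na.rm = TRUE)) {
    stop("invalid measurement: zero total volume", call. = FALSE)
  }
  v_oil / tot
}

#' Ribbon tensile strength by three-point bending
#'
#' `TS = 3 F L / (2 W T^2)`; with force in N and dimensions in mm the
#' result is in MPa. Homogeneous of degree one in the break force.
#'
#' @param force_n Break force, N.
#' @param span_mm Distance between the lower supports, mm (instrument
#'   default 15 mm).
#' @param width_mm Ribbon width, mm.
#' @param thickness_mm Ribbon thickness, mm.
#' @return Tensile strength in MPa.
#' @examples
#' tensile_strength(10, 15, 25, 3) # 1 MPa
#' @export
tensile_strength <- function(force_n, span_mm = 15, width_mm, thickness_mm) {
  if (any(force_n <= 0, na.rm = TRUE) || any(span_mm <= 0, na.rm = TRUE) ||
      any(width_mm <= 0, na.rm = TRUE) || any(thickness_mm <= 0, na.rm = TRUE)) {
    stop("invalid measurement: bending inputs must be positive", call. = FALSE)
  }
  3 * force_n * span_mm / (2 * width_mm * thickness_mm^2)
}

splitting_mode_levels <- function() c("T", "L2", "L3", "LJ", "LN")

parse_splitting_modes <- function(x) {
  if (!length(x)) return(list())
  modes <- strsplit(ifelse(is.na(x) | x == "" | x == "NONE", "", x), ";", fixed = TRUE)
  ok <- c(splitting_mode_levels(), "NO_RIBBON")
  bad <- setdiff(unique(unlist(modes)), ok)
  if (length(bad)) {
    stop("unknown splitting mode label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  modes
}

#' Splitting-mode frequency table
#'
#' Tallies transversal (`T`) and longitudinal (`L2`, `L3`, `LJ`, `LN`)
#' splitting occurrences per hydraulic pressure, with the `L` total. A
#' ribbon can display both a `T` and an `L` mode; the two families are
#' counted independently. `NO_RIBBON` rows are excluded from tallies but
#' counted as intangible.
#'
#' @param samples A data frame with columns `material_id`, `pressure_bar`
#'   and `splitting_modes` (semicolon-joined codes; empty or `"NONE"` for
#'   an intact ribbon, `"NO_RIBBON"` when no ribbon formed).
#' @return A tibble with columns `pressure_bar`, `mode`
#'   (`T`, `L2`, `L3`, `LJ`, `LN`, `L_total`) and `n`.
#' @export
splitting_frequency_table <- function(samples) {
  prs <- sort(unique(samples$pressure_bar))
  modes <- parse_splitting_modes(samples$splitting_modes)
  grid <- tidyr::expand_grid(
    pressure_bar = prs,
    mode = c(splitting_mode_levels(), "L_total")
  )
  long <- tibble::tibble(
    pressure_bar = rep(samples$pressure_bar, lengths(modes)),
    mode = as.character(unlist(modes))
  ) |>
    dplyr::filter(.data$mode != "NO_RIBBON")
  counts <- long |>
    dplyr::count(.data$pressure_bar, .data$mode)
  l_tot <- long |>
    dplyr::filter(.data$mode != "T") |>
    dplyr::count(.data$pressure_bar) |>
    dplyr::mutate(mode = "L_total")
  grid |>
    dplyr::left_join(dplyr::bind_rows(counts, l_tot),
                     by = c("pressure_bar", "mode")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Transversal splitting occurrence rate
#'
#' Share of tangible ribbon samples (those that formed a ribbon) that
#' display transversal splitting. Reported as a percentage.
#'
#' @inheritParams splitting_frequency_table
#' @return A one-row tibble with `n_transversal`, `n_tangible`, `rate_pct`.
#' @export
transversal_rate <- function(samples) {
  modes <- parse_splitting_modes(samples$splitting_modes)
  tangible <- !vapply(modes, function(m) "NO_RIBBON" %in% m, logical(1))
  has_t <- vapply(modes, function(m) "T" %in% m, logical(1))
  n_t <- sum(has_t & tangible)
  n_tan <- sum(tangible)
  tibble::tibble(
    n_transversal = n_t, n_tangible = n_tan,
    rate_pct = if (n_tan > 0) 100 * n_t / n_tan else NA_real_
  )
}

#' Build per-material compaction profiles from ribbon measurements
#'
#' Aggregates replicate ribbon measurements into per-pressure means of
#' porosity (from oil intrusion) and tensile strength (from three-point
#' bending), with `SF = 1 - eps`. Pressures at which no ribbon formed are
#' retained with `NA` quality values and flagged; a material whose every
#' pressure produced no ribbon is flagged non-compactable.
#'
#' @param ribbons Long-format ribbon measurement table with columns
#'   `material_id`, `pressure_bar`, `replicate`, `m_ribbon_g`, `m_oilsat_g`,
#'   `rho_oil`, `width_mm`, `thickness_mm`, `force_N`, `span_mm`,
#'   `splitting_modes`. Oil-intrusion or bending columns may be `NA`
#'   (untestable ribbons).
#' @param true_density A data frame with `material_id` and `Dt` (g/mL), or
#'   a descriptor table containing those columns.
#' @return A tibble with one row per material and pressure: `eps`, `SF`,
#'   `TS`, replicate counts and standard deviations, and flags
#'   `ribbon_formed` and (per material) `non_compactable`.
#' @export
build_profiles <- function(ribbons, true_density) {
  req <- c("material_id", "pressure_bar", "replicate", "m_ribbon_g",
           "m_oilsat_g", "rho_oil", "width_mm", "thickness_mm", "force_N",
           "span_mm", "splitting_modes")
  missing <- setdiff(req, names(ribbons))
  if (length(missing)) {
    stop("ribbon table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  parse_splitting_modes(ribbons$splitting_modes) # validates labels
  dt <- dplyr::select(true_density, "material_id", "Dt")
  x <- ribbons |>
    dplyr::left_join(dt, by = "material_id") |>
    dplyr::mutate(
      tangible = !grepl("NO_RIBBON", .data$splitting_modes, fixed = TRUE),
      eps_i = ifelse(.data$tangible,
                     ribbon_porosity(.data$m_ribbon_g, .data$m_oilsat_g,
                                     .data$rho_oil, .data$Dt),
                     NA_real_),
      ts_i = ifelse(.data$tangible,
                    tensile_strength(.data$force_N, .data$span_mm,
                                     .data$width_mm, .data$thickness_mm),
                    NA_real_)
    )
  prof <- x |>
    dplyr::group_by(.data$material_id, .data$pressure_bar) |>
    dplyr::summarise(
      n_reps = sum(.data$tangible),
      eps = mean(.data$eps_i[.data$tangible]),
      eps_sd = stats::sd(.data$eps_i[.data$tangible]),
      TS = mean(.data$ts_i[.data$tangible]),
      TS_sd = stats::sd(.data$ts_i[.data$tangible]),
      ribbon_formed = any(.data$tangible),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      eps = ifelse(is.nan(.data$eps), NA_real_, .data$eps),
      TS = ifelse(is.nan(.data$TS), NA_real_, .data$TS),
      SF = 1 - .data$eps
    ) |>
    dplyr::group_by(.data$material_id) |>
    dplyr::mutate(non_compactable = !any(.data$ribbon_formed)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$material_id, .data$pressure_bar) |>
    dplyr::select("material_id", "pressure_bar", "eps", "SF", "TS",
                  "n_reps", "eps_sd", "TS_sd", "ribbon_formed",
                  "non_compactable")
  prof
}

#' Build a single-material compaction profile
#'
#' Convenience wrapper around [build_profiles()] that insists on a single
#' material (mixed inputs are an error).
#'
#' @inheritParams build_profiles
#' @return As [build_profiles()], one material only.
#' @export
build_profile <- function(ribbons, true_density) {
  if (length(unique(ribbons$material_id)) > 1) {
    stop("build_profile expects a single material; got several", call. = FALSE)
  }
  build_profiles(ribbons, true_density)
}
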