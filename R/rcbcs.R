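# Roll compaction behavior classification system (RCBCS).
#
# Category I:  at least one pressure point with 0.6 <= SF <= 0.8 and
#              TS >= 1 MPa (the ribbon quality target region).
# Category II: no point in the target region, but at least one point with
#              SF > 0.8 and TS >= 1 MPa.
# Category III: TS < 1 MPa everywhere (including non-compactable or
#              untestable materials).
# Subcategory A: the main criterion is met at some pressure in 30-70 bar;
# B: only at 90-110 bar. Boundaries are inclusive as stated.

rcbcs_pressure_grid <- function() c(30, 50, 70, 90, 110)

#' Classify a single compaction profile into RCBCS categories
#'
#' @param pressure_bar Pressures of the profile points (bar), on the
#'   standard grid `{30, 50, 70, 90, 110}` unless `strict = FALSE`.
#' @param SF Ribbon solid fractions at those pressures (`NA` allowed for
#'   absent points).
#' @param TS Ribbon tensile strengths, MPa (`NA` = untestable, treated as
#'   failing `TS >= 1`).
#' @param sf_min,sf_max,ts_min Target-region bounds (defaults 0.6, 0.8,
#'   1 MPa; all inclusive).
#' @param low_pressures,high_pressures Pressure sets defining the A and B
#'   subcategories.
#' @param strict Error on pressures off the standard grid (default TRUE).
#' @return A one-row tibble: `main` (`"I"`, `"II"`, `"III"`), `sub`
#'   (`"A"`, `"B"` or `NA`), `label` (e.g. `"IA"`), `qualifying_pressures`
#'   (comma-joined bar values) and `rationale`.
#' @export
classify_profile <- function(pressure_bar, SF, TS,
                             sf_min = 0.6, sf_max = 0.8, ts_min = 1,
                             low_pressures = c(30, 50, 70),
                             high_pressures = c(90, 110),
                             strict = TRUE) {
  if (strict && length(pressure_bar) &&
      !all(pressure_bar %in% rcbcs_pressure_grid())) {
    stop("profile contains pressures off the standard grid ",
         "{30, 50, 70, 90, 110} bar (use strict = FALSE to allow)",
         call. = FALSE)
  }
  ok <- !is.na(SF) & !is.na(TS)
  ts_ok <- ok & TS >= ts_min
  in_target <- ts_ok & SF >= sf_min & SF <= sf_max
  above_band <- ts_ok & SF > sf_max

  if (any(in_target)) {
    main <- "I"
    qual <- pressure_bar[in_target]
  } else if (any(above_band)) {
    main <- "II"
    qual <- pressure_bar[above_band]
  } else {
    main <- "III"
    qual <- numeric(0)
  }
  sub <- if (main == "III") NA_character_
         else if (any(qual %in% low_pressures)) "A"
         else "B"
  rationale <- switch(
    main,
    I = sprintf("target region (%.2g <= SF <= %.2g, TS >= %.2g MPa) reached at %s bar",
                sf_min, sf_max, ts_min, paste(qual, collapse = ", ")),
    II = sprintf("SF > %.2g with TS >= %.2g MPa at %s bar; target region never reached",
                 sf_max, ts_min, paste(qual, collapse = ", ")),
    III = sprintf("TS < %.2g MPa (or untestable) at every pressure", ts_min)
  )
  tibble::tibble(
    main = main, sub = sub,
    label = paste0(main, ifelse(is.na(sub), "", sub)),
    qualifying_pressures = paste(qual, collapse = ","),
    rationale = rationale
  )
}

#' Classify every material in a profile table
#'
#' Applies [classify_profile()] per material. Non-compactable materials
#' (no ribbon at any pressure) and materials with untestable TS fall into
#' Category III.
#'
#' @param profiles Profile table from [build_profiles()] (columns
#'   `material_id`, `pressure_bar`, `SF`, `TS`).
#' @inheritParams classify_profile
#' @return A tibble with one row per material: `material_id`, `main`,
#'   `sub`, `label`, `qualifying_pressures`, `rationale`.
#' @export
classify_materials <- function(profiles, sf_min = 0.6, sf_max = 0.8,
                               ts_min = 1, strict = TRUE) {
  profiles |>
    dplyr::group_by(.data$material_id) |>
    dplyr::group_map(function(df, key) {
      dplyr::bind_cols(
        tibble::tibble(material_id = key$material_id),
        classify_profile(df$pressure_bar, df$SF, df$TS,
                         sf_min = sf_min, sf_max = sf_max, ts_min = ts_min,
                         strict = strict)
      )
    }) |>
    dplyr::bind_rows()
}

#' Category contingency summary
#'
#' Counts of materials per (sub)category split by material type, plus the
#' per-main-category transversal splitting occurrence rate when ribbon
#' samples are supplied.
#'
#' @param labels Output of [classify_materials()].
#' @param material_types A data frame with `material_id` and `type`
#'   (e.g. `"excipient"` / `"npp"`).
#' @param samples Optional ribbon sample table (see
#'   [splitting_frequency_table()]) used to compute per-category
#'   transversal splitting rates.
#' @return A list with `counts` (tibble label x type) and, if `samples`
#'   given, `transversal` (tibble main-category rates).
#' @export
category_summary <- function(labels, material_types, samples = NULL) {
  counts <- labels |>
    dplyr::left_join(material_types, by = "material_id") |>
    dplyr::count(.data$label, .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n",
                       values_fill = 0L)
  out <- list(counts = counts)
  if (!is.null(samples)) {
    out$transversal <- samples |>
      dplyr::left_join(dplyr::select(labels, "material_id", "main"),
                       by = "material_id") |>
      dplyr::group_by(.data$main) |>
      dplyr::group_map(function(df, key) {
        dplyr::bind_cols(tibble::tibble(main = key$main), transversal_rate(df))
      }) |>
      dplyr::bind_rows()
  }
  out
}

#' TS-SF map with target-region membership
#'
#' Long-format export of every profile point with an `in_target` flag
#' (inclusive bounds), the data behind the classification scatter.
#'
#' @inheritParams classify_materials
#' @return A tibble: `material_id`, `pressure_bar`, `SF`, `TS`,
#'   `in_target`.
#' @export
ts_sf_map <- function(profiles, sf_min = 0.6, sf_max = 0.8, ts_min = 1) {
  profiles |>
    dplyr::transmute(
      .data$material_id, .data$pressure_bar, .data$SF, .data$TS,
      in_target = !is.na(.data$SF) & !is.na(.data$TS) &
        .data$SF >= sf_min & .data$SF <= sf_max & .data$TS >= ts_min
    )
}

#' Plot the TS-SF classification map
#'
#' Scatter of tensile strength against solid fraction for every profile
#' point, with the ribbon quality target region shaded.
#'
#' @inheritParams ts_sf_map
#' @param labels Optional label table from [classify_materials()] to
#'   colour points by category.
#' @return A ggplot object.
#' @export
plot_ts_sf_map <- function(profiles, labels = NULL, sf_min = 0.6,
                           sf_max = 0.8, ts_min = 1) {
  dat <- ts_sf_map(profiles, sf_min, sf_max, ts_min)
  if (!is.null(labels)) {
    dat <- dplyr::left_join(dat, dplyr::select(labels, "material_id", "main"),
                            by = "material_id")
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$SF, y = .data$TS)) +
    ggplot2::annotate("rect", xmin = sf_min, xmax = sf_max, ymin = ts_min,
                      ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_hline(yintercept = ts_min, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ribbon solid fraction", y = "tensile strength (MPa)")
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$main), na.rm = TRUE) +
      ggplot2::labs(colour = "RCBCS")
  } else {
    p + ggplot2::geom_point(na.rm = TRUE)
  }
}
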