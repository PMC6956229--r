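# End-to-end orchestration: descriptors -> profiles -> compaction fits ->
# RCBCS labels -> PLS -> refined model -> design space, with plain-text
# outputs and a run log. Fully deterministic under a fixed seed.

#' Assemble the latent-variable modeling dataset
#'
#' One observation per material x pressure: the 22 powder descriptors,
#' the four compaction descriptors (`TS0`, `kb`, `d`, `g`), the hydraulic
#' pressure as predictor, and the ribbon responses `TS` and `SF`.
#' Materials without both compaction models applicable, or with missing
#' ribbon quality values, are excluded (the modeling matrices must be
#' complete).
#'
#' @param descriptors Descriptor table from [compute_descriptors()].
#' @param profiles Profile table from [build_profiles()].
#' @param fits Fit table from [fit_compaction_models()].
#' @return A tibble with `material_id`, `pressure` and the modeling
#'   columns; attribute `"excluded"` lists dropped materials.
#' @export
assemble_lvm_dataset <- function(descriptors, profiles, fits) {
  ok_fits <- fits |>
    dplyr::filter(.data$rd_applicable, .data$pow_applicable) |>
    dplyr::select("material_id", "TS0", "kb", "d", "g")
  dat <- profiles |>
    dplyr::filter(!is.na(.data$TS), !is.na(.data$SF)) |>
    dplyr::select("material_id", pressure = "pressure_bar", "TS", "SF") |>
    dplyr::inner_join(ok_fits, by = "material_id") |>
    dplyr::inner_join(descriptors, by = "material_id") |>
    dplyr::select("material_id", "pressure",
                  dplyr::all_of(descriptor_columns()),
                  "TS0", "kb", "d", "g", "TS", "SF")
  attr(dat, "excluded") <- setdiff(unique(profiles$material_id),
                                   unique(dat$material_id))
  dat
}

#' Pipeline configuration
#'
#' Thresholds and settings of the full analysis, with the published
#' defaults: ribbon quality targets `0.6 <= SF <= 0.8`, `TS >= 1` MPa,
#' fit applicability at `r2 >= 0.7`, 7-fold cross-validation, VIP cutoff
#' 1, 95% confidence limits.
#'
#' @param sf_min,sf_max,ts_min Ribbon quality target band.
#' @param r2_threshold Compaction-fit applicability threshold.
#' @param ts0_cap Zero-porosity strength cap, MPa.
#' @param cv_folds Cross-validation folds.
#' @param vip_cutoff VIP threshold for the refined model.
#' @param level Confidence level for score limits.
#' @param ncomp_max Cap on PLS components.
#' @param seed Seed for every random element (library generation, CV
#'   shuffles).
#' @param output_dir Where [run_pipeline()] writes its bundle, or `NULL`
#'   for no file output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sf_min = 0.6, sf_max = 0.8, ts_min = 1,
                            r2_threshold = 0.7, ts0_cap = 1000,
                            cv_folds = 7, vip_cutoff = 1, level = 0.95,
                            ncomp_max = 10, seed = 1, output_dir = NULL) {
  if (!(sf_min > 0 && sf_min < sf_max && sf_max <= 1)) {
    stop("require 0 < sf_min < sf_max <= 1", call. = FALSE)
  }
  if (ts_min <= 0) stop("require ts_min > 0", call. = FALSE)
  structure(
    list(sf_min = sf_min, sf_max = sf_max, ts_min = ts_min,
         r2_threshold = r2_threshold, ts0_cap = ts0_cap,
         cv_folds = cv_folds, vip_cutoff = vip_cutoff, level = level,
         ncomp_max = ncomp_max, seed = seed, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full material-library analysis
#'
#' Chains every stage on the supplied inputs (or on a synthetic library
#' generated with the configured seed): descriptor computation, ribbon
#' metrology, compaction model fitting with applicability screening,
#' RCBCS classification, the full and refined PLS models, and the
#' multi-objective design space. If `output_dir` is set, all tables are
#' written as CSV/JSON alongside a plain-text run log.
#'
#' @param config A [pipeline_config()].
#' @param library Optional list with `raw`, `psd`, `ribbons`, `types`
#'   (as from [generate_library()]); default generates the standard
#'   synthetic library with `config$seed`.
#' @return A list: `descriptors`, `profiles`, `splitting`, `fits`,
#'   `labels`, `summary`, `lvm_data`, `pls`, `refined`, `design_space`,
#'   `membership`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), library = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(library)) {
    library <- stage("simulate", generate_library(
      library_config(seed = config$seed)))
  }
  descriptors <- stage("descriptors",
                       compute_descriptors(library$raw, library$psd))
  profiles <- stage("profiles", build_profiles(library$ribbons, descriptors))
  splitting <- stage("splitting", splitting_frequency_table(
    dplyr::distinct(library$ribbons, .data$material_id, .data$pressure_bar,
                    .data$splitting_modes)))
  fits <- stage("fit", fit_compaction_models(
    profiles, r2_threshold = config$r2_threshold, ts0_cap = config$ts0_cap))
  labels <- stage("classify", classify_materials(
    profiles, sf_min = config$sf_min, sf_max = config$sf_max,
    ts_min = config$ts_min))
  summary <- stage("classify", category_summary(
    labels, library$types,
    samples = dplyr::distinct(library$ribbons, .data$material_id,
                              .data$pressure_bar, .data$splitting_modes)))
  lvm_data <- stage("pls", assemble_lvm_dataset(descriptors, profiles, fits))
  pls <- stage("pls", fit_ribbon_pls(
    lvm_data, ncomp_max = config$ncomp_max, cv_folds = config$cv_folds,
    seed = config$seed))
  refined <- stage("designspace", refine_model(
    pls, lvm_data, vip_cutoff = config$vip_cutoff, ncomp_min = 2,
    ncomp_max = config$ncomp_max, cv_folds = config$cv_folds,
    seed = config$seed))
  ds <- stage("designspace", map_targets(
    refined, ts_min = config$ts_min,
    sf_band = c(config$sf_min, config$sf_max), level = config$level))
  membership <- stage("designspace", dplyr::bind_cols(
    dplyr::select(lvm_data, "material_id", "pressure"),
    project_material(ds, lvm_data)))
  out <- list(descriptors = descriptors, profiles = profiles,
              splitting = splitting, fits = fits, labels = labels,
              summary = summary, lvm_data = lvm_data, pls = pls,
              refined = refined, design_space = ds,
              membership = membership, config = config)
  if (!is.null(config$output_dir)) {
    write_pipeline_bundle(out, config$output_dir)
  }
  out
}

write_pipeline_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$descriptors, file.path(dir, "descriptors.csv"))
  readr::write_csv(result$profiles, file.path(dir, "profiles.csv"))
  readr::write_csv(result$splitting, file.path(dir, "splitting.csv"))
  write_fits(result$fits, file.path(dir, "fits.csv"),
             file.path(dir, "fits.json"))
  readr::write_csv(result$labels, file.path(dir, "labels.csv"))
  readr::write_csv(result$summary$counts, file.path(dir, "category_counts.csv"))
  readr::write_csv(pls_vip_table(result$pls), file.path(dir, "vip.csv"))
  readr::write_csv(pls_coefficients(result$pls),
                   file.path(dir, "coefficients.csv"))
  readr::write_csv(result$pls$cv, file.path(dir, "cv_diagnostics.csv"))
  write_pls_json(result$pls, file.path(dir, "pls_model.json"))
  write_pls_json(result$refined, file.path(dir, "pls_refined.json"))
  write_design_space(result$design_space, file.path(dir, "design_space"),
                     membership = result$membership)
  cfg <- result$config
  log_lines <- c(
    paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " run_pipeline"),
    paste0("rollcompactr version: ",
           as.character(utils::packageVersion("rollcompactr"))),
    paste0("seed: ", cfg$seed),
    paste0("targets: sf in [", cfg$sf_min, ", ", cfg$sf_max, "], ts_min ",
           cfg$ts_min, " MPa"),
    paste0("fit screen: r2 >= ", cfg$r2_threshold, ", TS0 cap ", cfg$ts0_cap,
           " MPa"),
    paste0("cv folds: ", cfg$cv_folds, "; vip cutoff: ", cfg$vip_cutoff,
           "; level: ", cfg$level)
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Thin argv-level wrapper over the pipeline, used by the
#' `inst/scripts/rollcompact.R` script. Subcommands: `simulate`,
#' `descriptors`, `profiles`, `fit`, `classify`, `pls`, `designspace`,
#' `run-all`. Returns an exit code (0 success, 2 validation error)
#' instead of quitting, so it is testable in-process.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
rc_cli <- function(argv = character()) {
  usage <- paste(
    "usage: rollcompact <command> [--seed N] [--out DIR] [--r2-threshold X]",
    "commands: simulate | run-all (descriptors, profiles, fit, classify,",
    "          pls and designspace run as part of run-all)", sep = "\n")
  if (!length(argv) || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[1]
  opts <- list(seed = 1L, out = "rollcompact_out", r2_threshold = 0.7)
  rest <- argv[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) {
      message("unknown or incomplete flag: ", key, "\n", usage)
      return(invisible(2L))
    }
    val <- rest[i + 1]
    switch(key,
      "--seed" = { opts$seed <- as.integer(val) },
      "--out" = { opts$out <- val },
      "--r2-threshold" = { opts$r2_threshold <- as.numeric(val) },
      {
        message("unknown flag: ", key, "\n", usage)
        return(invisible(2L))
      }
    )
    i <- i + 2
  }
  if (is.na(opts$seed)) {
    message("invalid --seed")
    return(invisible(2L))
  }
  known <- c("simulate", "descriptors", "profiles", "fit", "classify",
             "pls", "designspace", "run-all")
  if (!cmd %in% known) {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  res <- tryCatch({
    if (cmd == "simulate") {
      lib <- generate_library(library_config(seed = opts$seed))
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(lib$raw, file.path(opts$out, "raw_measurements.csv"))
      readr::write_csv(lib$psd, file.path(opts$out, "psd.csv"))
      readr::write_csv(lib$ribbons, file.path(opts$out, "ribbons.csv"))
      readr::write_csv(lib$truth, file.path(opts$out, "ground_truth.csv"))
      0L
    } else {
      cfg <- pipeline_config(seed = opts$seed, output_dir = opts$out,
                             r2_threshold = opts$r2_threshold)
      run_pipeline(cfg)
      0L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(res)
}
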