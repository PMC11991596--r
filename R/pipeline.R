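#' Default pipeline configuration
#'
#' Full configuration of an end-to-end run on the synthetic scenario, as a
#' plain serializable list: the scenario arguments (see [nep_scenario()]),
#' significance thresholds, stage toggles, optimal-parameter GeoDetector
#' settings and output options. Unknown keys anywhere in the list are
#' rejected by [run_pipeline()] (typo safety). The default desk-scale
#' scenario is 100 x 100 pixels over 2000-2023.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    scenario = list(shape = c(100L, 100L), years = 2000:2023, seed = 42L),
    thresholds = list(alpha = 0.05, alpha_high = 0.01),
    validation = list(n_points = 100L, noise_sd_fraction = 0.15),
    stages = list(validate = TRUE, trend = TRUE, attribution = TRUE,
                  opgd = TRUE),
    opgd = list(methods = c("equal", "quantile", "natural_breaks",
                            "geometric", "std_dev"),
                L_range = 3:10, min_stratum_size = 2L, n_sample = 8000L,
                interactions = TRUE),
    output = list(write_rasters = FALSE))
}

check_config_keys <- function(config, defaults, path = "config") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(path, ": unknown key(s) ", paste(unknown, collapse = ", "))
  for (nm in intersect(names(config), names(defaults))) {
    if (nm %in% c("scenario")) next  # validated by nep_scenario() itself
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(config[[nm]]))
      check_config_keys(config[[nm]], defaults[[nm]],
                        paste(path, nm, sep = "$"))
  }
  invisible(TRUE)
}

merge_config <- function(config, defaults) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && is.list(config[[nm]]) &&
             !is.null(names(defaults[[nm]])) && nm != "scenario")
      config[[nm]] <- merge_config(config[[nm]], defaults[[nm]])
  }
  config
}

stage_log <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(proc.time()[3] - t0)))
}

#' Run the full carbon-sink pipeline
#'
#' Executes generation -> NPP -> NEP -> trend -> climate attribution -> OPGD
#' on the configured synthetic scenario, returns all stage products and a
#' machine-readable report, and (when `output_dir` is given) writes the
#' report, a copy of the configuration, and optionally the headline rasters.
#' The run is deterministic: an identical configuration (including seed)
#' reproduces a byte-identical report file.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file holding one; missing keys take their defaults, unknown keys
#'   are an error.
#' @param output_dir directory for `report.json`, `config.yaml` and rasters;
#'   `NULL` (default) writes nothing.
#' @param quiet suppress per-stage log messages.
#' @return list of class `nep_pipeline_run`: `report` (serializable list),
#'   plus the stage objects (`scenario`, `climate`, `vegetation`, `npp`,
#'   `nep`, `trend`, `attribution`, `opgd`, `budget`).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  check_config_keys(config, defaults)
  config <- merge_config(config, defaults)
  scenario <- do.call(nep_scenario, config$scenario)
  alpha <- config$thresholds$alpha

  t0 <- proc.time()[3]
  terrain <- scenario_terrain(scenario)
  climate <- generate_climate(scenario, terrain)
  veg <- generate_vegetation(scenario, climate, terrain)
  drv <- generate_drivers(scenario, terrain)
  stage_log(quiet, "generate", t0)

  t0 <- proc.time()[3]
  npp <- compute_npp(climate, veg$ndvi, veg$vegtype)
  npp_mean_annual <- apply(npp$npp_annual, 3, mean, na.rm = TRUE)
  npp_multi <- apply(npp$npp_annual, c(1, 2), mean)
  report_npp <- list(
    annual_mean = stats::setNames(as.list(npp_mean_annual),
                                  as.character(npp$years)),
    multiyear_mean = mean(npp_multi, na.rm = TRUE))
  validation <- NULL
  if (isTRUE(config$stages$validate)) {
    # synthetic reference product: the estimate plus independent
    # observation noise, standing in for an external NPP dataset
    vcfg <- config$validation
    ref <- withr::with_seed(sub_seed(scenario, 70L),
      npp_multi + stats::rnorm(length(npp_multi),
        sd = vcfg$noise_sd_fraction * stats::sd(npp_multi)))
    validation <- validate_npp(npp_multi, ref, n_points = vcfg$n_points,
                               seed = sub_seed(scenario, 71L))
    report_npp$validation <- validation[c("r", "r2", "p", "n")]
  }
  stage_log(quiet, "npp", t0)

  t0 <- proc.time()[3]
  rh <- compute_rh(climate$T, climate$R)
  nep <- compute_nep(npp, rh)
  nep_multi <- apply(nep$nep_annual, c(1, 2), mean)
  tr <- nep$transform
  budget <- aggregate_regional(nep_multi, tr)
  annual_budgets <- lapply(seq_along(nep$years), function(j)
    aggregate_regional(nep$nep_annual[, , j], tr))
  sink_series <- vapply(annual_budgets, `[[`, numeric(1), "sink_total")
  mean_series <- vapply(annual_budgets, `[[`, numeric(1), "mean_nep")
  report_nep <- list(
    annual_mean = stats::setNames(as.list(mean_series),
                                  as.character(nep$years)),
    multiyear_mean = budget$mean_nep,
    sink_total_tg = budget$sink_total,
    source_total_tg = budget$source_total,
    net_total_tg = budget$net_total,
    sink_area_fraction = budget$sink_area_fraction,
    sink_total_trend_tg = unname(fit_trend(sink_series)["slope"]),
    masked_nonpositive_precip = attr(rh, "n_nonpositive_precip"))
  stage_log(quiet, "nep", t0)

  report <- list(
    config = config,
    generate = list(shape = scenario$shape,
                    years = range(scenario$years),
                    n_years = length(scenario$years),
                    seed = scenario$seed,
                    n_drivers = length(drv$drivers),
                    vegetation_classes =
                      length(unique(as.vector(veg$vegtype$values)))),
    npp = report_npp, nep = report_nep)
  trend <- attribution <- opgd <- NULL

  if (isTRUE(config$stages$trend)) {
    t0 <- proc.time()[3]
    trend <- trend_map(nep$nep_annual)
    report$trend <- list(
      mean_slope = mean(trend$slope, na.rm = TRUE),
      nep_mean_series_slope = unname(fit_trend(mean_series)["slope"]),
      class_proportions = as.list(trend$class_proportions),
      significant_increase_fraction = sum(trend$class_proportions[
        c("extremely_significant_increase", "significant_increase")]),
      significant_decrease_fraction = sum(trend$class_proportions[
        c("extremely_significant_decrease", "significant_decrease")]))
    stage_log(quiet, "trend", t0)
  }

  if (isTRUE(config$stages$attribution)) {
    t0 <- proc.time()[3]
    attribution <- attribution_map(nep$nep_annual, annual_climate(climate),
                                   alpha = alpha)
    report$attribution <- list(
      type_proportions = as.list(attribution$type_proportions),
      positive_fraction = as.list(attribution$positive_fraction),
      significance_fractions =
        as.list(as.data.frame(attribution$significance_fractions)),
      n_valid = attribution$n_valid, n_dropped = attribution$n_dropped)
    stage_log(quiet, "attribution", t0)
  }

  if (isTRUE(config$stages$opgd)) {
    t0 <- proc.time()[3]
    opgd <- opgd_stage(scenario, nep_multi, climate, veg, terrain, drv,
                       config$opgd)
    report$opgd <- opgd$report
    stage_log(quiet, "opgd", t0)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(output_dir, "config.yaml"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(config$output$write_rasters)) {
      mk <- function(v, sem) raster_grid(v, xmin = tr$xmin, ymax = tr$ymax,
                                         dx = tr$dx, dy = tr$dy,
                                         crs = nep$crs, semantic = sem)
      write_raster(mk(nep_multi, "multiyear mean NEP g C m-2 a-1"),
                   file.path(output_dir, "nep_multiyear_mean.asc"))
      if (!is.null(trend)) {
        write_raster(mk(trend$slope, "NEP trend g C m-2 a-1 per year"),
                     file.path(output_dir, "nep_trend_slope.asc"))
        write_raster(mk(trend$p, "NEP trend p-value"),
                     file.path(output_dir, "nep_trend_p.asc"))
        write_raster(mk(trend$class + 0, "trend class code"),
                     file.path(output_dir, "nep_trend_class.asc"))
      }
      if (!is.null(attribution))
        write_raster(mk(attribution$type + 0, "climate driving type code"),
                     file.path(output_dir, "nep_driver_type.asc"))
    }
  }

  structure(list(report = report, scenario = scenario, climate = climate,
                 vegetation = veg, drivers = drv, npp = npp, nep = nep,
                 budget = budget, validation = validation, trend = trend,
                 attribution = attribution, opgd = opgd),
            class = "nep_pipeline_run")
}

# Factor/interaction/risk detection over the 12-factor design: annual-mean
# climate and NDVI plus the generated terrain and anthropogenic layers.
opgd_stage <- function(scenario, nep_multi, climate, veg, terrain, drv, cfg) {
  ann <- annual_climate(climate)
  cont <- list(
    temperature = apply(ann$T, c(1, 2), mean),
    precipitation = apply(ann$R, c(1, 2), mean),
    solar_radiation = apply(ann$SOL, c(1, 2), mean),
    ndvi = apply(veg$ndvi$values, c(1, 2), mean),
    elevation = terrain$elevation$values,
    slope = terrain$slope$values,
    population_density = drv$drivers$population_density$values,
    nighttime_light = drv$drivers$nighttime_light$values)
  cats <- list(
    impervious_change = drv$drivers$impervious_change$values,
    human_footprint_change = drv$drivers$human_footprint_change$values,
    land_use_change = drv$drivers$land_use_change$values,
    arable_expansion_change = drv$drivers$arable_expansion_change$values)
  y <- as.vector(nep_multi)
  valid <- which(!is.na(y))
  n_sample <- min(cfg$n_sample, length(valid))
  idx <- withr::with_seed(sub_seed(scenario, 80L),
                          sort(sample(valid, n_sample)))
  ys <- y[idx]
  layers <- list(); qtab <- list()
  for (nm in names(cont)) {
    opt <- optimize_discretization(as.vector(cont[[nm]])[idx], ys,
                                   methods = cfg$methods,
                                   L_range = cfg$L_range,
                                   min_stratum_size = cfg$min_stratum_size,
                                   name = nm)
    layers[[nm]] <- opt$factor
    qtab[[nm]] <- data.frame(factor = nm, q = opt$q_result$q,
                             p = opt$q_result$p, L = opt$factor$L,
                             method = opt$factor$method)
  }
  for (nm in names(cats)) {
    fl <- as_factor_layer(as.vector(cats[[nm]])[idx], name = nm)
    qr <- factor_q(ys, fl)
    layers[[nm]] <- fl
    qtab[[nm]] <- data.frame(factor = nm, q = qr$q, p = qr$p, L = qr$L,
                             method = "native")
  }
  qtab <- do.call(rbind, qtab)
  qtab <- qtab[order(-qtab$q), ]
  rownames(qtab) <- NULL
  interactions <- NULL
  if (isTRUE(cfg$interactions)) {
    nms <- names(layers)
    rows <- list()
    for (a in seq_along(nms)[-length(nms)]) for (b in (a + 1):length(nms)) {
      it <- interaction_detect(ys, layers[[nms[a]]], layers[[nms[b]]],
                               min_stratum_size = cfg$min_stratum_size)
      rows[[length(rows) + 1L]] <- data.frame(
        f1 = nms[a], f2 = nms[b], q1 = it$q1, q2 = it$q2, q12 = it$q12,
        type = it$type)
    }
    interactions <- do.call(rbind, rows)
    interactions <- interactions[order(-interactions$q12), ]
    rownames(interactions) <- NULL
  }
  risk <- lapply(layers, function(fl) risk_detect(ys, fl))
  risk_report <- lapply(risk, function(r)
    list(optimal = r$optimal_label, optimal_mean = max(r$stratum_means),
         minimal = r$minimal_label, minimal_mean = min(r$stratum_means)))
  list(layers = layers, q_table = qtab, interactions = interactions,
       risk = risk, sample_index = idx,
       report = list(
         n_sample = n_sample,
         q_table = qtab,
         top_factor = qtab$factor[1],
         interactions = if (!is.null(interactions))
           utils::head(interactions, 20) else NULL,
         enhancement_fraction = if (!is.null(interactions))
           mean(grepl("enhancement", interactions$type)) else NULL,
         risk = risk_report))
}
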