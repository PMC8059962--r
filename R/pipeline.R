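#' Run the full drilling-predation analysis pipeline
#'
#' Orchestrates ingest (or synthesis), filtering, frequency series,
#' phase-model fitting (two- and three-phase, for the systematically
#' surveyed data alone and for the combined compilation), changepoint
#' detection on diversity curves, and taphonomic partial correlations, and
#' writes every result plus a manifest to an output directory. Reruns with
#' the same configuration produce identical outputs.
#'
#' @param out_dir Output directory (created; existing files overwritten).
#' @param populations Either a validated population data.frame, a path to a
#'   populations CSV, or NULL to generate data from \code{synth}.
#' @param synth A \code{synth_config} used when \code{populations} is NULL.
#' @param diversity Optional diversity data.frame or CSV path
#'   (\code{group, stage, richness}).
#' @param k_phases Phase counts to fit (default both 2 and 3).
#' @param n_iter Monte Carlo iterations per model.
#' @param quota Standardization quota (NULL = minimum occupied-bin count).
#' @param seed Master seed for every stochastic step.
#' @param min_n Population-size inclusion threshold.
#' @param chart_version Timescale chart.
#' @param sources List of source filters to analyse (default EAT-only and
#'   EAT+LIT).
#' @return Invisibly, a list of in-memory results (\code{series},
#'   \code{standardized}, \code{surfaces}, \code{reports},
#'   \code{changepoints}, \code{correlations}, \code{manifest}).
#' @export
run_pipeline <- function(out_dir, populations = NULL, synth = synth_config(),
                         diversity = NULL, k_phases = c(2L, 3L),
                         n_iter = 1000L, quota = NULL, seed = 1L,
                         min_n = 10L, chart_version = "ICS2013",
                         sources = list(EAT = "EAT",
                                        EAT_LIT = c("EAT", "LIT"))) {
  if (n_iter < 1L) stop_ctx("pipeline: n_iter must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- load_timescale(chart_version)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop_ctx("pipeline stage '", what, "' failed: ", conditionMessage(e)))
  }

  dataset <- NULL
  if (is.null(populations)) {
    synth$seed <- child_seed(seed, 1L)
    dataset <- stage("synthesize", generate_dataset(synth))
    populations <- dataset$populations
    write_dataset_csv(dataset, file.path(out_dir, "synthetic_input"))
  } else if (is.character(populations)) {
    populations <- stage("ingest", read_populations(populations, ts))
  } else {
    populations <- stage("ingest",
      validate_populations(populations, ts, what = "pipeline populations"))
  }
  pops <- stage("filter", filter_populations(populations, min_n = min_n))
  if (!nrow(pops)) stop_ctx("pipeline stage 'filter': no populations retained")

  results <- list(series = list(), standardized = list(), surfaces = list(),
                  reports = list())
  ctr <- 10L
  for (sn in names(sources)) {
    src <- sources[[sn]]
    if (!any(pops$source %in% src)) next
    ser <- stage(paste0("series/", sn), bin_series(pops, ts, sources = src))
    std <- stage(paste0("standardize/", sn),
      standardized_means(pops, ts, quota = quota, n_reps = n_iter,
                         seed = child_seed(seed, ctr), sources = src))
    write_series_csv(ser, file.path(out_dir, paste0("series_raw_", sn, ".csv")))
    write_series_csv(std, file.path(out_dir,
                                    paste0("series_standardized_", sn, ".csv")))
    results$series[[sn]] <- ser
    results$standardized[[sn]] <- std
    for (k in k_phases) {
      ctr <- ctr + 1L
      surf <- stage(paste0("phases/", sn, "/k", k),
        fit_all_models(pops, ser, k_phases = k, n_iter = n_iter,
                       seed = child_seed(seed, ctr)))
      rep <- best_fit_report(surf, ts)
      tag <- paste0(sn, "_k", k)
      write_surface_csv(surf, file.path(out_dir, paste0("surface_", tag, ".csv")),
                        file.path(out_dir, paste0("bands_", tag, ".csv")))
      write_report_json(rep, file.path(out_dir, paste0("report_", tag, ".json")))
      results$surfaces[[tag]] <- surf
      results$reports[[tag]] <- rep
    }
    ctr <- ctr + 10L
  }

  results$changepoints <- list()
  if (!is.null(diversity)) {
    if (is.character(diversity)) diversity <- read_diversity(diversity, ts)
    for (g in unique(diversity$group)) {
      cp <- stage(paste0("changepoint/", g),
        detect_changepoints(diversity[diversity$group == g, , drop = FALSE],
                            timescale = ts))
      results$changepoints[[g]] <- cp
      jsonlite::write_json(
        list(group = g, cp_indices = cp$cp_indices,
             segment_means = cp$segment_means,
             event_start_stage = cp$event_start_stage,
             event_end_stage = cp$event_end_stage,
             interval_start_ma = cp$interval_start_ma,
             interval_end_ma = cp$interval_end_ma),
        file.path(out_dir, paste0("changepoints_", g, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  eat <- pops[pops$source == "EAT", , drop = FALSE]
  results$correlations <- NULL
  if (nrow(eat) >= 6L && !all(is.na(eat$mean_taph_grade))) {
    eat$age_ma <- vapply(eat$stage, function(s) stage_midpoint(ts, s),
                         numeric(1))
    results$correlations <- stage("correlations",
      partial_correlation(eat, target = "drilling_frequency",
                          covariates = c("mean_taph_grade", "age_ma",
                                         "n_individuals")))
    pc <- results$correlations
    utils::write.csv(data.frame(covariate = pc$covariates,
                                r_partial = pc$r_partial,
                                p_value = pc$p_value, n = pc$n),
                     file.path(out_dir, "partial_correlations.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("echinodrill")),
    r_version = R.version.string,
    chart_version = attr(ts, "chart_version"),
    seed = seed, n_iter = n_iter, min_n = min_n,
    quota = quota %||% "min occupied-bin count",
    k_phases = k_phases,
    sources = sources,
    synthetic = !is.null(dataset),
    n_populations = nrow(pops),
    n_populations_by_source = as.list(table(pops$source))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
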