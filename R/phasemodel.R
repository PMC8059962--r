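#' @title Multi-phase drilling-intensification models
#' @description
#' The central inference of the package: was the rise in drilling frequency
#' gradual or phased, and when did the transition happen? A phase model
#' partitions the occupied stage bins into 2 contiguous phases (pre- and
#' post-intensification) or 3 phases (pre, transitional ramp, post). Each
#' candidate partition is scored by Monte Carlo simulation: per iteration the
#' populations in every bin are resampled with replacement (propagating
#' uneven-sampling uncertainty into the bin means), first differences of the
#' resampled means are pooled by phase, and a simulated trajectory is grown
#' from the oldest bin by drawing each step's increment from its phase's
#' pool. Model fit is the inverse of the mean sum of squared deviations (SSQ)
#' between simulated trajectories and the observed mean series.
#' @name phasemodel
NULL

#' Construct a phase-model specification
#'
#' @param k_phases 2 or 3.
#' @param boundaries Occupied-bin indices (1-based) at which a new phase
#'   begins; strictly increasing, interior (between 2 and \code{n_bins});
#'   length \code{k_phases - 1}.
#' @param n_bins Number of occupied bins the model applies to.
#' @return A \code{phase_spec} list: \code{k_phases}, \code{boundaries},
#'   \code{n_bins}, and \code{phase_of_transition} (phase membership of each
#'   of the \code{n_bins - 1} bin-to-bin transitions; a transition straddling
#'   a phase boundary belongs to the younger phase).
#' @export
phase_model_spec <- function(k_phases, boundaries, n_bins) {
  k_phases <- as.integer(k_phases)
  boundaries <- as.integer(boundaries)
  n_bins <- as.integer(n_bins)
  if (!k_phases %in% c(2L, 3L)) stop_ctx("k_phases must be 2 or 3")
  if (length(boundaries) != k_phases - 1L)
    stop_ctx("need ", k_phases - 1L, " boundary index(es) for a ",
             k_phases, "-phase model")
  if (any(boundaries < 2L) || any(boundaries > n_bins) ||
      any(diff(boundaries) < 1L))
    stop_ctx("boundaries must be strictly increasing and interior (2..",
             n_bins, ")")
  trans_to <- seq_len(n_bins - 1L) + 1L  # younger bin of each transition
  phase_of_transition <- 1L + vapply(trans_to,
    function(b) sum(boundaries <= b), integer(1))
  structure(list(k_phases = k_phases, boundaries = boundaries,
                 n_bins = n_bins, phase_of_transition = phase_of_transition),
            class = "phase_spec")
}

#' Enumerate all phase-model specifications
#'
#' All contiguous partitions of \code{n_bins} ordered bins into
#' \code{k_phases} non-empty phases: \code{n_bins - 1} two-phase models and
#' \code{choose(n_bins - 1, 2)} three-phase models.
#'
#' @param n_bins Number of occupied bins.
#' @param k_phases 2 or 3.
#' @return List of \code{phase_spec}, in lexicographic boundary order.
#' @export
enumerate_phase_models <- function(n_bins, k_phases) {
  n_bins <- as.integer(n_bins)
  k_phases <- as.integer(k_phases)
  if (n_bins < k_phases)
    stop_ctx("cannot fit ", k_phases, " phases into ", n_bins, " bins")
  if (k_phases == 2L) {
    lapply(2:n_bins, function(b) phase_model_spec(2L, b, n_bins))
  } else if (k_phases == 3L) {
    combs <- utils::combn(2:n_bins, 2L)
    lapply(seq_len(ncol(combs)),
           function(j) phase_model_spec(3L, combs[, j], n_bins))
  } else stop_ctx("k_phases must be 2 or 3")
}

# Group population frequencies by occupied bin, in series order.
# Errors if an occupied bin has no backing populations.
.pops_by_occupied_bin <- function(populations, series) {
  occ <- series[series$occupied, , drop = FALSE]
  sources <- attr(series, "sources") %||% c("EAT", "LIT")
  populations <- populations[populations$source %in% sources, , drop = FALSE]
  by_bin <- split(populations$drilling_frequency,
                  factor(populations$stage, levels = occ$stage))
  n_by <- lengths(by_bin)
  if (any(n_by == 0L))
    stop_ctx("occupied bin(s) without backing populations: ",
             paste(occ$stage[n_by == 0L], collapse = ", "))
  list(freqs = by_bin, stages = occ$stage, obs = occ$mean_f,
       spans_gap = diff(occ$index) > 1L)
}

#' Simulate one phase model and score its fit
#'
#' Per iteration: (1) resample each occupied bin's populations with
#' replacement and recompute the bin means; (2) take first differences of
#' the resampled means and pool them by the phase of each transition;
#' (3) grow a simulated trajectory from the oldest bin's resampled mean,
#' drawing each transition's increment (with replacement) from its phase's
#' pool, clamped to [0, 1]; (4) record the SSQ of the simulated trajectory
#' against the observed (unresampled) mean series. Fit is
#' \code{1 / (mean(SSQ) + 1e-12)}; the epsilon caps the degenerate
#' perfect-fit case where every SSQ is zero.
#'
#' @param populations Population data.frame backing \code{series}.
#' @param series A \code{frequency_series} (its source filter is honoured).
#' @param spec A \code{phase_spec} whose \code{n_bins} equals the number of
#'   occupied bins in \code{series}.
#' @param n_iter Monte Carlo iterations (default 1000).
#' @param seed Optional RNG seed; a fixed seed gives an identical fit.
#' @param include_gap_diffs Keep gap-spanning first differences in the phase
#'   pools (default TRUE). Excluding them can empty a pool, which is an
#'   error when that phase still contains transitions.
#' @param summary_only Skip per-bin quantile bands (used internally when
#'   scanning many models).
#' @return A \code{phase_fit} list: \code{spec}, \code{n_iter},
#'   \code{ssq_per_iter}, \code{fit_score}, \code{traj_r} (Pearson r of the
#'   ensemble median trajectory vs the observed series), \code{bands}
#'   (per-bin q25/q50/q75), \code{mean_traj}, \code{n_clamped}, \code{seed}.
#' @export
simulate_phase_model <- function(populations, series, spec, n_iter = 1000L,
                                 seed = NULL, include_gap_diffs = TRUE,
                                 summary_only = FALSE) {
  stopifnot(inherits(spec, "phase_spec"))
  prep <- .pops_by_occupied_bin(populations, series)
  B <- length(prep$stages)
  if (spec$n_bins != B)
    stop_ctx("spec was built for ", spec$n_bins, " bins but the series has ",
             B, " occupied bins")
  if (B < spec$k_phases) stop_ctx("fewer occupied bins than phases")
  pot <- spec$phase_of_transition
  pool_rows <- lapply(seq_len(spec$k_phases), function(p)
    which(pot == p & (include_gap_diffs | !prep$spans_gap)))
  has_trans <- tabulate(pot, spec$k_phases) > 0L
  empty <- which(has_trans & lengths(pool_rows) == 0L)
  if (length(empty))
    stop_ctx("phase ", empty[1], " has transitions but an empty first-",
             "difference pool (all its differences span gaps and were excluded)")

  obs <- prep$obs
  n_iter <- as.integer(n_iter)
  res <- with_seed(seed, {
    # resampled bin means, B x n_iter
    M <- matrix(0, B, n_iter)
    for (b in seq_len(B)) {
      f <- prep$freqs[[b]]
      nb <- length(f)
      M[b, ] <- if (nb == 1L) f else
        colMeans(matrix(f[sample.int(nb, nb * n_iter, replace = TRUE)],
                        nrow = nb))
    }
    D <- M[-1L, , drop = FALSE] - M[-B, , drop = FALSE]
    drawn <- matrix(0, B - 1L, n_iter)
    for (p in seq_len(spec$k_phases)) {
      tr <- which(pot == p)
      if (!length(tr)) next
      pool <- pool_rows[[p]]
      ridx <- pool[sample.int(length(pool), length(tr) * n_iter, replace = TRUE)]
      drawn[tr, ] <- D[cbind(ridx, rep(seq_len(n_iter), each = length(tr)))]
    }
    traj <- matrix(0, B, n_iter)
    cur <- pmin(pmax(M[1L, ], 0), 1)
    traj[1L, ] <- cur
    n_clamped <- 0L
    for (t in seq_len(B - 1L)) {
      nxt <- cur + drawn[t, ]
      cl <- pmin(pmax(nxt, 0), 1)
      n_clamped <- n_clamped + sum(cl != nxt)
      traj[t + 1L, ] <- cl
      cur <- cl
    }
    ssq <- colSums((traj - obs)^2)
    med <- apply(traj, 1L, stats::median)
    list(traj = traj, ssq = ssq, med = med, n_clamped = n_clamped)
  })
  fit_score <- 1 / (mean(res$ssq) + 1e-12)
  traj_r <- if (stats::sd(res$med) > 0 && stats::sd(obs) > 0)
    stats::cor(res$med, obs) else NA_real_
  bands <- NULL
  if (!summary_only) {
    qs <- t(apply(res$traj, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
                  names = FALSE))
    bands <- data.frame(stage = prep$stages, q25 = qs[, 1], q50 = qs[, 2],
                        q75 = qs[, 3], stringsAsFactors = FALSE)
  }
  structure(list(
    spec = spec, n_iter = n_iter,
    ssq_per_iter = if (summary_only) NULL else res$ssq,
    mean_ssq = mean(res$ssq), fit_score = fit_score, traj_r = traj_r,
    bands = bands, mean_traj = rowMeans(res$traj), median_traj = res$med,
    observed = obs, stages = prep$stages, n_clamped = res$n_clamped,
    seed = seed, include_gap_diffs = include_gap_diffs
  ), class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  tr <- .transition_bins(x$spec)
  cat(x$spec$k_phases, "-phase model fit (", x$n_iter, " iterations)\n",
      "  transition bins: ", tr$start, "..", tr$end,
      " (", x$stages[tr$start], " - ", x$stages[tr$end], ")\n",
      "  fit score 1/SSQ: ", signif(x$fit_score, 4),
      "; median-trajectory r: ", round(x$traj_r, 3), "\n", sep = "")
  invisible(x)
}

# First and last occupied-bin index of the "change" phase: phase 2 of a
# three-phase model (the transitional ramp), or the post phase's first bin
# for a two-phase model.
.transition_bins <- function(spec) {
  if (spec$k_phases == 3L)
    list(start = spec$boundaries[1], end = spec$boundaries[2] - 1L)
  else
    list(start = spec$boundaries[1], end = spec$boundaries[1])
}

#' Fit every phase model and rank them
#'
#' Runs [simulate_phase_model()] over the full enumeration for the given
#' number of phases. Each model gets a child seed derived from the master
#' seed by a counter-based scheme (counter = position in the enumeration),
#' so results are reproducible and independent of simulation order. Ranking
#' is by fit score, ties broken by earlier transition start, then shorter
#' transition phase.
#'
#' @param populations Population data.frame backing \code{series}.
#' @param series A \code{frequency_series}.
#' @param k_phases 2 or 3.
#' @param n_iter Iterations per model (default 1000).
#' @param seed Master seed.
#' @param include_gap_diffs Passed to [simulate_phase_model()].
#' @return A \code{fit_surface}: \code{grid} (one row per model:
#'   boundaries, transition start/end bins and stages, \code{fit_score},
#'   \code{mean_ssq}, \code{traj_r}, \code{rank}), \code{best} (the five
#'   best \code{phase_fit} objects, re-simulated with their own child seeds),
#'   plus \code{k_phases}, \code{n_iter}, \code{seed}, \code{series}.
#' @export
fit_all_models <- function(populations, series, k_phases, n_iter = 1000L,
                           seed = NULL, include_gap_diffs = TRUE) {
  occ_stages <- series$stage[series$occupied]
  B <- length(occ_stages)
  specs <- enumerate_phase_models(B, k_phases)
  n_mod <- length(specs)
  fit_score <- mean_ssq <- traj_r <- numeric(n_mod)
  b1 <- b2 <- integer(n_mod)
  for (j in seq_len(n_mod)) {
    fit <- simulate_phase_model(populations, series, specs[[j]],
                                n_iter = n_iter, seed = child_seed(seed, j),
                                include_gap_diffs = include_gap_diffs,
                                summary_only = TRUE)
    fit_score[j] <- fit$fit_score
    mean_ssq[j] <- fit$mean_ssq
    traj_r[j] <- fit$traj_r
    b1[j] <- specs[[j]]$boundaries[1]
    b2[j] <- if (k_phases == 3L) specs[[j]]$boundaries[2] else NA_integer_
  }
  start_bin <- b1
  end_bin <- if (k_phases == 3L) b2 - 1L else b1
  ord <- order(-fit_score, start_bin, end_bin - start_bin)
  rank <- integer(n_mod)
  rank[ord] <- seq_len(n_mod)
  grid <- data.frame(
    model = seq_len(n_mod), boundary1 = b1, boundary2 = b2,
    start_bin = start_bin, end_bin = end_bin,
    start_stage = occ_stages[start_bin], end_stage = occ_stages[end_bin],
    fit_score = fit_score, mean_ssq = mean_ssq, traj_r = traj_r, rank = rank,
    stringsAsFactors = FALSE
  )
  top <- ord[seq_len(min(5L, n_mod))]
  best <- lapply(top, function(j)
    simulate_phase_model(populations, series, specs[[j]], n_iter = n_iter,
                         seed = child_seed(seed, j),
                         include_gap_diffs = include_gap_diffs))
  structure(list(k_phases = as.integer(k_phases), grid = grid, best = best,
                 n_iter = as.integer(n_iter), seed = seed,
                 stages = occ_stages, series = series,
                 include_gap_diffs = include_gap_diffs),
            class = "fit_surface")
}

#' @export
print.fit_surface <- function(x, ...) {
  cat("Phase-model fit surface: ", nrow(x$grid), " ", x$k_phases,
      "-phase models over ", length(x$stages), " occupied bins (",
      x$n_iter, " iterations each)\n", sep = "")
  top <- x$grid[order(x$grid$rank), ][1:min(5, nrow(x$grid)), ]
  cat("Five best-fit models:\n")
  print.data.frame(top[, c("rank", "start_stage", "end_stage", "fit_score",
                           "traj_r")], row.names = FALSE)
  invisible(x)
}

#' Report the best-fit model in stage terms
#'
#' Translates the best model's transition phase into stage names and
#' midpoint ages on the pinned timescale, and collects the five best-fit
#' models (the horizontal-bar data of a fit-surface figure).
#'
#' @param surface A \code{fit_surface} from [fit_all_models()].
#' @param table The \code{stage_table} the series was binned on.
#' @return A \code{phase_report} list with elements \code{k_phases},
#'   \code{chart_version}, \code{best} (transition start/end stage, midpoint
#'   ages in Ma, fit score, trajectory r) and \code{top5} (data.frame).
#' @export
best_fit_report <- function(surface, table = load_timescale()) {
  stopifnot(inherits(surface, "fit_surface"))
  g <- surface$grid[order(surface$grid$rank), ]
  top5 <- g[seq_len(min(5L, nrow(g))), ]
  best <- top5[1L, ]
  rep <- list(
    k_phases = surface$k_phases,
    chart_version = attr(table, "chart_version"),
    n_iter = surface$n_iter,
    seed = surface$seed,
    best = list(
      transition_start_stage = best$start_stage,
      transition_start_midpoint_ma = as.numeric(stage_midpoint(table, best$start_stage)),
      transition_end_stage = best$end_stage,
      transition_end_midpoint_ma = as.numeric(stage_midpoint(table, best$end_stage)),
      fit_score = best$fit_score,
      traj_r = best$traj_r
    ),
    top5 = data.frame(
      rank = top5$rank,
      start_stage = top5$start_stage,
      end_stage = top5$end_stage,
      start_midpoint_ma = as.numeric(stage_midpoint(table, top5$start_stage)),
      end_midpoint_ma = as.numeric(stage_midpoint(table, top5$end_stage)),
      fit_score = top5$fit_score,
      traj_r = top5$traj_r,
      stringsAsFactors = FALSE
    )
  )
  class(rep) <- "phase_report"
  rep
}

#' @export
print.phase_report <- function(x, ...) {
  b <- x$best
  cat(x$k_phases, "-phase best-fit model (chart ", x$chart_version, "):\n",
      "  transition ", b$transition_start_stage, " (",
      b$transition_start_midpoint_ma, " Ma) -> ", b$transition_end_stage,
      " (", b$transition_end_midpoint_ma, " Ma)\n",
      "  fit score ", signif(b$fit_score, 4), ", trajectory r ",
      round(b$traj_r, 3), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a phase report as JSON
#'
#' @param report A \code{phase_report}.
#' @param path JSON file path.
#' @return \code{path} (write) or the restored \code{phase_report} (read).
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$top5 <- as.data.frame(x$top5, stringsAsFactors = FALSE)
  class(x) <- "phase_report"
  x
}

#' Write fit-surface CSVs
#'
#' Writes the model-fit grid (heatmap data) and, optionally, the best
#' model's interquartile band per stage.
#'
#' @param surface A \code{fit_surface}.
#' @param grid_path CSV path for the heatmap grid.
#' @param bands_path Optional CSV path for the best model's bands.
#' @return \code{grid_path}, invisibly.
#' @export
write_surface_csv <- function(surface, grid_path, bands_path = NULL) {
  g <- surface$grid
  utils::write.csv(g[, c("start_stage", "end_stage", "fit_score", "traj_r",
                         "rank")], grid_path, row.names = FALSE)
  if (!is.null(bands_path))
    utils::write.csv(surface$best[[1]]$bands, bands_path, row.names = FALSE)
  invisible(grid_path)
}
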