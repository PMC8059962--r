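#' Mean-shift changepoint detection on a diversity series
#'
#' Exhaustive least-squares segmentation: over all placements of up to
#' \code{max_cp} changepoints, minimizes total within-segment squared error
#' plus \code{penalty} per changepoint. Series at stage resolution are short
#' enough that the exhaustive search is exact. Used to date radiation events
#' in predator (cassid gastropod) and prey (echinoid) richness curves: the
#' radiation event is the earliest segment across which the mean rises.
#'
#' @param series data.frame with ordered (oldest to youngest) columns
#'   \code{stage} and \code{richness}; a \code{group} column is carried
#'   through if present.
#' @param max_cp Maximum number of changepoints (default 2).
#' @param penalty Cost per changepoint. Default \code{2 * sigma2 * log(n)}
#'   (SIC-flavoured), where \code{sigma2} is a mean-shift-robust noise
#'   variance estimate from the median absolute first difference; scaling
#'   the penalty by the noise level makes the detected changepoints
#'   invariant under affine rescaling of richness.
#' @param timescale A \code{stage_table} for translating the event into
#'   midpoint ages.
#' @return A \code{changepoint_result} list: \code{cp_indices} (1-based
#'   indices of the first bin of each new segment), \code{segment_means},
#'   \code{segments} (start/end/mean per segment), \code{event_start_stage},
#'   \code{event_end_stage}, \code{interval_start_ma}, \code{interval_end_ma}
#'   (midpoints bracketing the first rising segment; \code{NA} if the series
#'   never rises), \code{penalty}, \code{sse}.
#' @export
detect_changepoints <- function(series, max_cp = 2L, penalty = NULL,
                                timescale = load_timescale()) {
  check_cols(series, c("stage", "richness"), "diversity series")
  y <- as.numeric(series$richness)
  if (any(is.na(y) | y < 0)) stop_ctx("richness must be non-negative")
  n <- length(y)
  max_cp <- as.integer(max_cp)
  if (n < max_cp + 2L)
    stop_ctx("series too short (", n, " bins) for max_cp = ", max_cp)
  if (is.null(penalty)) {
    # noise variance from first differences: robust to the mean shifts the
    # segmentation is meant to find (MAD is already scaled to the sd)
    sigma2 <- stats::mad(diff(y))^2 / 2
    penalty <- 2 * sigma2 * log(n)
  }
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  sse <- function(i, j) {  # inclusive bounds
    a1 <- s1[j] - if (i > 1) s1[i - 1] else 0
    a2 <- s2[j] - if (i > 1) s2[i - 1] else 0
    max(a2 - a1^2 / (j - i + 1L), 0)
  }
  seg_cost <- function(bounds) {  # bounds: first-bin indices of segments
    starts <- c(1L, bounds)
    ends <- c(bounds - 1L, n)
    sum(mapply(sse, starts, ends))
  }
  best <- list(cost = seg_cost(integer(0)), bounds = integer(0))
  if (max_cp >= 1L) {
    for (k in seq_len(max_cp)) {
      if (n - 1L < k) break
      combs <- utils::combn(2:n, k)
      for (j in seq_len(ncol(combs))) {
        bounds <- combs[, j]
        cost <- seg_cost(bounds) + penalty * k
        # ties: fewer changepoints, then earlier (lexicographic) boundaries
        if (cost < best$cost - 1e-12) best <- list(cost = cost, bounds = bounds)
      }
    }
  }
  bounds <- best$bounds
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, n)
  means <- mapply(function(i, j) mean(y[i:j]), starts, ends)
  segments <- data.frame(start = starts, end = ends, mean = means)
  # first segment whose mean exceeds its predecessor's
  rise <- which(diff(means) > 0)
  ev <- if (length(rise)) rise[1] + 1L else NA_integer_
  event_start_stage <- event_end_stage <- NA_character_
  interval_start_ma <- interval_end_ma <- NA_real_
  if (!is.na(ev)) {
    event_start_stage <- series$stage[starts[ev]]
    event_end_stage <- series$stage[ends[ev]]
    interval_start_ma <- as.numeric(stage_midpoint(timescale, event_start_stage))
    interval_end_ma <- as.numeric(stage_midpoint(timescale, event_end_stage))
  }
  structure(list(
    group = if ("group" %in% names(series)) series$group[1] else NA_character_,
    cp_indices = bounds, segment_means = means, segments = segments,
    event_start_stage = event_start_stage, event_end_stage = event_end_stage,
    interval_start_ma = interval_start_ma, interval_end_ma = interval_end_ma,
    penalty = penalty, sse = best$cost - penalty * length(bounds), n = n
  ), class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat("Changepoint segmentation (", length(x$cp_indices), " changepoint(s), ",
      "penalty ", signif(x$penalty, 4), ")\n", sep = "")
  print.data.frame(x$segments, row.names = FALSE)
  if (!is.na(x$event_start_stage))
    cat("First rising segment: ", x$event_start_stage, " (",
        x$interval_start_ma, " Ma) -> ", x$event_end_stage, " (",
        x$interval_end_ma, " Ma)\n", sep = "")
  invisible(x)
}

#' Partial Pearson correlations with significance tests
#'
#' Partial correlation of a target variable with each covariate, controlling
#' for the remaining covariates, via the inverse-correlation-matrix
#' construction: with \eqn{P = R^{-1}}, the partial correlation of variables
#' i and j given all others is \eqn{-P_{ij} / \sqrt{P_{ii} P_{jj}}}.
#' Two-sided p-values come from the t transform
#' \eqn{t = r \sqrt{df / (1 - r^2)}} with \eqn{df = n - 2 - g} degrees of
#' freedom, where g is the number of controlled variables. Used to ask
#' whether drilling frequency is confounded by preservation quality
#' (taphonomic grade), sample age or sample size. Rows with missing values
#' (e.g. literature populations, which carry no taphonomic grades) are
#' dropped and counted.
#'
#' @param data data.frame containing \code{target} and \code{covariates}.
#' @param target Name of the target column (drilling frequency).
#' @param covariates Character vector of covariate column names.
#' @return A \code{partial_corr_result}: \code{r_partial} and \code{p_value}
#'   (named by covariate), \code{n} complete cases used, \code{n_dropped}.
#' @export
partial_correlation <- function(data, target = "drilling_frequency",
                                covariates = c("mean_taph_grade", "age_ma",
                                               "n_individuals")) {
  vars <- c(target, covariates)
  check_cols(data, vars, "correlation input")
  x <- data[, vars, drop = FALSE]
  cc <- stats::complete.cases(x)
  n_dropped <- sum(!cc)
  x <- as.matrix(x[cc, , drop = FALSE])
  n <- nrow(x)
  if (n < length(vars) + 2L)
    stop_ctx("need at least ", length(vars) + 2L,
             " complete rows for ", length(vars), " variables; got ", n)
  r_partial <- p_value <- stats::setNames(numeric(length(covariates)), covariates)
  for (cv in covariates) {
    sub <- c(target, cv, setdiff(covariates, cv))
    R <- stats::cor(x[, sub, drop = FALSE])
    P <- tryCatch(solve(R), error = function(e)
      stop_ctx("correlation matrix is singular (collinear covariates?): ",
               conditionMessage(e)))
    r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    g <- length(sub) - 2L
    df <- n - 2L - g
    if (df < 1L) stop_ctx("insufficient n for the t test (df = ", df, ")")
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    r_partial[cv] <- r
    p_value[cv] <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(target = target, covariates = covariates,
                 r_partial = r_partial, p_value = p_value,
                 n = n, n_dropped = n_dropped),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat("Partial Pearson correlations with '", x$target, "' (n = ", x$n,
      if (x$n_dropped) paste0("; ", x$n_dropped, " incomplete rows dropped"),
      ")\n", sep = "")
  print.data.frame(data.frame(covariate = x$covariates,
                              r_partial = round(x$r_partial, 3),
                              p_value = signif(x$p_value, 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Read a diversity series CSV
#'
#' @param path CSV with columns \code{group, stage, richness}, ordered
#'   oldest to youngest within each group.
#' @param timescale A \code{stage_table} for stage validation.
#' @return data.frame ordered oldest-first by stage index within group.
#' @export
read_diversity <- function(path, timescale = load_timescale()) {
  df <- read_csv_checked(path)
  check_cols(df, c("group", "stage", "richness"), "diversity file")
  idx <- vapply(df$stage, function(s) resolve_stage(timescale, s), integer(1))
  df$stage <- timescale$name[idx]
  if (any(is.na(df$richness) | df$richness < 0))
    stop_ctx("richness must be non-negative")
  df[order(df$group, idx), , drop = FALSE]
}
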