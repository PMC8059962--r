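#' Configuration for the synthetic drill-hole dataset generator
#'
#' The generator emulates the statistical structure of a museum-survey
#' compilation of drilling predation on echinoids: stage-binned populations
#' with uneven sampling intensity, beta-binomial overdispersion in
#' population drilling frequencies around a three-phase (low / ramp /
#' elevated) true trajectory, taphonomic-grade-dependent loss of drill-hole
#' detection, rare incomplete holes, occasional minute (parasite-type)
#' traces, and a literature subset biased toward highly drilled populations.
#'
#' Defaults are pinned to the study conditions the package is designed
#' around: 41 stage bins Aalenian-Holocene, 201 systematically surveyed
#' (EAT) populations allocated over an uneven per-bin profile, 62
#' literature (LIT) populations, populations of at least 10 individuals
#' with a heavy-tailed size distribution (mean near 130), a true trajectory
#' at 0.02 before the Lutetian ramping to 0.25 by the Rupelian, beta
#' concentration \code{kappa = 75} (about 70\% of pre-phase populations of
#' 20 individuals record zero drilling), and a 3.4\% incomplete-hole rate.
#'
#' @param seed RNG seed; the whole dataset is deterministic given the seed.
#' @param chart_version Timescale chart (see [load_timescale()]).
#' @param stage_from,stage_to First and last stage generated.
#' @param lambda Per-bin expected EAT population count. Either a single
#'   number (flat profile), a numeric vector (one per bin), or NULL for the
#'   default age-dependent profile \code{2 + 6 * exp(-age / 40)} (sampling
#'   improves toward the recent).
#' @param n_eat_target If non-NULL, total EAT population count drawn
#'   multinomially over the \code{lambda} profile (exact total); if NULL,
#'   per-bin counts are independent Poisson(\code{lambda}).
#' @param min_pops_per_bin Floor on per-bin EAT population counts.
#' @param min_n,nb_mu,nb_size Population size model: \code{n = min_n +
#'   NegBin(mu = nb_mu - min_n, size = nb_size)}.
#' @param f_pre,f_post True drilling frequency before and after the ramp.
#' @param ramp_start,ramp_end Stage names bounding the transitional ramp
#'   (inclusive); the true frequency interpolates linearly in age across it.
#' @param kappa Beta concentration of population-level overdispersion:
#'   population true frequency p ~ Beta(kappa f, kappa (1 - f)).
#' @param scale_max Taphonomic sub-score maximum per test region.
#' @param grade_drift Intercept/slope of the per-region abrasion score model
#'   \code{Binom(scale_max, plogis(a + b * age))}; older samples are more
#'   abraded.
#' @param delta_slope,delta_floor Detection-loss model: a true hole on a
#'   specimen of summed grade g goes unobserved with probability
#'   \code{min(delta_floor + delta_slope * g, 1)}.
#' @param p_incomplete Probability a recorded hole is incomplete (failed
#'   attack), independent per hole.
#' @param minute_frac Fraction of taxa that are minute (test under 10 mm).
#' @param p_multi_hole Probability a drilled individual bears two holes.
#' @param p_parasitic Per-specimen probability of an additional minute
#'   eulimid-type (sub-0.5 mm) hole on a non-minute host.
#' @param p_lowvis Expected extra specimens (fraction of n) failing the
#'   visibility filter.
#' @param n_lit_candidates,n_lit_target Literature model: candidate
#'   population count and (if non-NULL) exact retained count.
#' @param lit_intercept,lit_slope Logistic literature-inclusion model:
#'   \code{P(include) = plogis(lit_intercept + lit_slope * frequency)}.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L, chart_version = "ICS2013",
                         stage_from = "Aalenian", stage_to = "Holocene",
                         lambda = NULL, n_eat_target = 201L,
                         min_pops_per_bin = 0L,
                         min_n = 10L, nb_mu = 130, nb_size = 0.6,
                         f_pre = 0.02, f_post = 0.25,
                         ramp_start = "Lutetian", ramp_end = "Rupelian",
                         kappa = 75,
                         scale_max = 3L, grade_drift = c(-1.2, 0.012),
                         delta_slope = 0.04, delta_floor = 0,
                         p_incomplete = 0.034,
                         minute_frac = 0.08, p_multi_hole = 0.1,
                         p_parasitic = 0.03, p_lowvis = 0.05,
                         n_lit_candidates = 200L, n_lit_target = 62L,
                         lit_intercept = -1.5, lit_slope = 8) {
  cfg <- as.list(environment())
  probs <- c(f_pre = f_pre, f_post = f_post, delta_slope = delta_slope,
             delta_floor = delta_floor,
             p_incomplete = p_incomplete, minute_frac = minute_frac,
             p_multi_hole = p_multi_hole, p_parasitic = p_parasitic)
  if (any(probs < 0 | probs > 1))
    stop_ctx("probabilities must lie in [0,1]: ",
             paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (!(f_pre < f_post)) stop_ctx("intensification requires f_pre < f_post")
  if (kappa <= 0) stop_ctx("kappa must be positive")
  if (min_n < 1) stop_ctx("min_n must be >= 1")
  class(cfg) <- "synth_config"
  cfg
}

# True three-phase trajectory over the stage range: f_pre through the bin
# before ramp_start, then linear in stage index so that every between-bin
# step of the rise falls inside the labelled ramp (the transitions into
# ramp_start .. ramp_end), then f_post. The truth is thus itself a member
# of the three-phase model class the fitter searches over.
.truth_trajectory <- function(cfg, ts) {
  i0 <- resolve_stage(ts, cfg$ramp_start)
  i1 <- resolve_stage(ts, cfg$ramp_end)
  if (i0 > i1) stop_ctx("ramp_start must not be younger than ramp_end")
  i <- seq_len(nrow(ts))
  f <- ifelse(i < i0, cfg$f_pre,
         ifelse(i >= i1, cfg$f_post,
           cfg$f_pre + (cfg$f_post - cfg$f_pre) * (i - (i0 - 1L)) /
             (i1 - i0 + 1L)))
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}

.sub_timescale <- function(cfg) {
  ts <- load_timescale(cfg$chart_version)
  i0 <- resolve_stage(ts, cfg$stage_from)
  i1 <- resolve_stage(ts, cfg$stage_to)
  if (i0 >= i1) stop_ctx("stage_from must be older than stage_to")
  sub <- as.data.frame(ts)[i0:i1, ]
  as_stage_table(data.frame(name = sub$name, older_bound_ma = sub$older_bound,
                            younger_bound_ma = sub$younger_bound),
                 chart_version = attr(ts, "chart_version"),
                 aliases = attr(ts, "aliases"))
}

#' Generate a synthetic specimen/population dataset with known truth
#'
#' Draws, per stage bin, a population count from the configured sampling
#' profile; per population, a size from a shifted negative binomial and a
#' true drilling probability from the beta-overdispersed phase trajectory;
#' per individual, drilled status, taphonomic sub-scores drifting with age,
#' and hole records thinned by the grade-dependent detection-loss model.
#' Observed population records are built by the package's own aggregation
#' ([summarize_populations()]) applied to the generated specimen and trace
#' tables, so generated data passes exactly the checks ingested data does.
#' A literature (LIT) population set is generated at population level and
#' thinned by [apply_literature_bias()].
#'
#' @param config A \code{synth_config}.
#' @return List with \code{specimens}, \code{traces}, \code{pop_info}
#'   (EAT specimen backing), \code{eat}, \code{lit}, \code{populations}
#'   (EAT + LIT, validated), \code{timescale} (the generated stage range),
#'   and \code{truth} (per-bin true trajectory, ramp stages, per-population
#'   true p).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  ts <- .sub_timescale(cfg)
  nb <- nrow(ts)
  f_true <- .truth_trajectory(cfg, ts)
  lam <- cfg$lambda
  if (is.null(lam)) lam <- 2 + 6 * exp(-ts$midpoint / 40)
  lam <- rep_len(lam, nb)

  with_seed(cfg$seed, {
    counts <- if (!is.null(cfg$n_eat_target))
      as.integer(stats::rmultinom(1L, cfg$n_eat_target, prob = lam))
    else stats::rpois(nb, lam)
    counts <- pmax(counts, cfg$min_pops_per_bin)
    n_pop <- sum(counts)
    if (n_pop == 0L) stop_ctx("sampling profile generated zero populations")

    bin_of_pop <- rep(seq_len(nb), counts)
    pop_id <- sprintf("EAT_%03d", seq_len(n_pop))
    n_ind <- cfg$min_n + stats::rnbinom(n_pop, size = cfg$nb_size,
                                        mu = max(cfg$nb_mu - cfg$min_n, 1))
    fb <- f_true[bin_of_pop]
    p_true <- stats::rbeta(n_pop, cfg$kappa * fb, cfg$kappa * (1 - fb))
    d_true <- stats::rbinom(n_pop, n_ind, p_true)
    minute <- stats::runif(n_pop) < cfg$minute_frac
    life <- sample(c("epifaunal", "infaunal"), n_pop, TRUE, prob = c(0.3, 0.7))

    # specimen-level tables, vectorized across all populations
    ns <- sum(n_ind)
    spec_pop <- rep(seq_len(n_pop), n_ind)
    spec_id <- sprintf("S%06d", seq_len(ns))
    age <- ts$midpoint[bin_of_pop][spec_pop]
    psub <- stats::plogis(cfg$grade_drift[1] + cfg$grade_drift[2] * age)
    sub <- matrix(stats::rbinom(4L * ns, cfg$scale_max, rep(psub, 4L)),
                  ncol = 4L)
    test_d <- ifelse(minute[spec_pop],
                     stats::runif(ns, 3, 9.5),
                     stats::rlnorm(ns, log(35), 0.4))
    specimens <- data.frame(
      specimen_id = spec_id,
      population_id = pop_id[spec_pop],
      visible_fraction = stats::runif(ns, 0.501, 1),
      subscore_ambitus = sub[, 1], subscore_periproct = sub[, 2],
      subscore_peristome = sub[, 3], subscore_apical = sub[, 4],
      test_diameter = test_d,
      stringsAsFactors = FALSE
    )
    grade <- rowSums(sub)

    # drilled individuals: the first d_true specimens of each population
    first_of_pop <- c(0L, cumsum(n_ind))[seq_len(n_pop)]
    drilled_rows <- unlist(lapply(seq_len(n_pop), function(i)
      if (d_true[i] > 0L) first_of_pop[i] + seq_len(d_true[i]) else integer(0)))
    n_holes <- if (length(drilled_rows))
      1L + stats::rbinom(length(drilled_rows), 1L, cfg$p_multi_hole) else integer(0)
    hole_spec <- rep(drilled_rows, n_holes)
    nh <- length(hole_spec)
    p_lost <- pmin(cfg$delta_floor + cfg$delta_slope * grade[hole_spec], 1)
    observed <- stats::runif(nh) >= p_lost
    hole_spec <- hole_spec[observed]
    nh <- length(hole_spec)
    hole_minute_host <- minute[spec_pop[hole_spec]]
    diam <- ifelse(hole_minute_host,
                   stats::runif(nh, 0.15, 0.45),
                   0.5 + stats::rlnorm(nh, log(0.8), 0.6))
    outl <- sample(c("circular", "subcircular", "irregular", "rectangular",
                     "elongated", "notched"), nh, TRUE,
                   prob = c(0.45, 0.3, 0.1, 0.05, 0.05, 0.05))
    complete <- stats::runif(nh) >= cfg$p_incomplete
    traces <- data.frame(specimen_id = spec_id[hole_spec],
                         diameter_mm = diam, outline = outl,
                         complete = as.integer(complete),
                         stringsAsFactors = FALSE)

    # eulimid-type parasitic traces on non-minute hosts (excluded downstream)
    para_rows <- which(stats::runif(ns) < cfg$p_parasitic &
                       !minute[spec_pop])
    if (length(para_rows)) {
      traces <- rbind(traces, data.frame(
        specimen_id = spec_id[para_rows],
        diameter_mm = stats::runif(length(para_rows), 0.1, 0.45),
        outline = "circular",
        complete = 1L, stringsAsFactors = FALSE))
    }

    # extra low-visibility specimens (dropped by the visibility filter)
    n_extra <- stats::rpois(1L, cfg$p_lowvis * ns)
    if (n_extra > 0L) {
      xpop <- sample.int(n_pop, n_extra, replace = TRUE)
      xsub <- matrix(stats::rbinom(4L * n_extra, cfg$scale_max, 0.6), ncol = 4L)
      specimens <- rbind(specimens, data.frame(
        specimen_id = sprintf("X%06d", seq_len(n_extra)),
        population_id = pop_id[xpop],
        visible_fraction = stats::runif(n_extra, 0, 0.5),
        subscore_ambitus = xsub[, 1], subscore_periproct = xsub[, 2],
        subscore_peristome = xsub[, 3], subscore_apical = xsub[, 4],
        test_diameter = stats::rlnorm(n_extra, log(35), 0.4),
        stringsAsFactors = FALSE))
    }

    pop_info <- data.frame(
      population_id = pop_id,
      taxon = sprintf("Taxon_%02d", 1L + (seq_len(n_pop) %% 40L)),
      life_habit = life,
      stage = ts$name[bin_of_pop],
      source = "EAT",
      stringsAsFactors = FALSE
    )
    eat <- summarize_populations(filter_specimens(specimens), traces, pop_info,
                                 timescale = ts, scale_max = cfg$scale_max)

    # literature candidates: population-level records only
    lit_counts <- if (cfg$n_lit_candidates > 0L)
      as.integer(stats::rmultinom(1L, cfg$n_lit_candidates, prob = lam))
    else integer(nb)
    nl <- sum(lit_counts)
    lit_bin <- rep(seq_len(nb), lit_counts)
    if (nl == 0L) {
      lit <- NULL
    } else {
    lit_n <- cfg$min_n + stats::rnbinom(nl, size = cfg$nb_size,
                                        mu = max(cfg$nb_mu - cfg$min_n, 1))
    lit_p <- stats::rbeta(nl, cfg$kappa * f_true[lit_bin],
                          cfg$kappa * (1 - f_true[lit_bin]))
    lit_d <- stats::rbinom(nl, lit_n, lit_p)
    lit_holes <- lit_d + stats::rbinom(nl, lit_d, cfg$p_multi_hole)
    lit_inc <- stats::rbinom(nl, lit_holes, cfg$p_incomplete)
    lit_cand <- data.frame(
      population_id = sprintf("LIT_%03d", seq_len(nl)),
      taxon = sprintf("Taxon_%02d", 1L + (seq_len(nl) %% 40L)),
      life_habit = sample(c("epifaunal", "infaunal"), nl, TRUE,
                          prob = c(0.3, 0.7)),
      stage = ts$name[lit_bin],
      source = "EAT",  # relabelled LIT by apply_literature_bias
      n_individuals = lit_n, n_drilled = lit_d,
      n_holes_complete = lit_holes - lit_inc, n_holes_incomplete = lit_inc,
      mean_taph_grade = stats::runif(nl, 2, 9),
      stringsAsFactors = FALSE
    )
    lit_cand$drilling_frequency <- lit_cand$n_drilled / lit_cand$n_individuals
    lit <- apply_literature_bias(lit_cand, intercept = cfg$lit_intercept,
                                 slope = cfg$lit_slope,
                                 n_target = cfg$n_lit_target)
    }

    populations <- validate_populations(
      if (is.null(lit)) eat else rbind(eat, lit), ts,
      what = "generated populations")
    truth <- list(
      f_true = stats::setNames(f_true, ts$name),
      ramp_start = ts$name[resolve_stage(ts, cfg$ramp_start)],
      ramp_end = ts$name[resolve_stage(ts, cfg$ramp_end)],
      ramp_start_index = resolve_stage(ts, cfg$ramp_start),
      ramp_end_index = resolve_stage(ts, cfg$ramp_end),
      pop_p_true = stats::setNames(p_true, pop_id)
    )
    list(specimens = specimens, traces = traces, pop_info = pop_info,
         eat = eat, lit = lit, populations = populations,
         timescale = ts, truth = truth, config = cfg)
  })
}

#' Thin populations into a literature-style biased subset
#'
#' Literature compilations tend to over-report heavily drilled populations:
#' a population is retained with probability
#' \code{plogis(intercept + slope * drilling_frequency)}. With
#' \code{n_target} set, exactly that many populations are drawn without
#' replacement with weights proportional to the inclusion probability.
#' Retained rows are relabelled \code{source = "LIT"} and their taphonomic
#' grades blanked (literature reports carry none).
#'
#' @param populations Validated population data.frame.
#' @param intercept,slope Logistic inclusion model; \code{slope = 0} is
#'   unbiased thinning.
#' @param n_target Exact retained count, or NULL for Bernoulli thinning.
#' @param seed Optional seed (omit when calling inside a seeded generator).
#' @return The retained populations, relabelled.
#' @export
apply_literature_bias <- function(populations, intercept = -1.5, slope = 8,
                                  n_target = NULL, seed = NULL) {
  if (!nrow(populations)) return(populations)
  check_cols(populations, "drilling_frequency", "population table")
  w <- stats::plogis(intercept + slope * populations$drilling_frequency)
  with_seed(seed, {
    keep <- if (is.null(n_target)) {
      which(stats::runif(nrow(populations)) < w)
    } else {
      if (n_target > nrow(populations))
        stop_ctx("n_target (", n_target, ") exceeds candidate count (",
                 nrow(populations), ")")
      sample.int(nrow(populations), n_target, replace = FALSE, prob = w)
    }
    out <- populations[sort(keep), , drop = FALSE]
    out$source <- "LIT"
    out$mean_taph_grade <- NA_real_
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic diversity series with planted changepoints
#'
#' Piecewise-constant mean richness with rounded Gaussian noise floored at
#' zero; the planted segmentation is recorded so changepoint recovery can be
#' verified.
#'
#' @param stages Ordered stage names (oldest to youngest).
#' @param changepoints Indices (into \code{stages}) of the first bin of each
#'   new segment; empty for a constant series.
#' @param segment_means Mean richness per segment
#'   (\code{length(changepoints) + 1}).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Optional RNG seed.
#' @param group Label carried on the series.
#' @return data.frame \code{group, stage, richness} with attributes
#'   \code{truth_changepoints} and \code{truth_means}.
#' @export
generate_diversity_series <- function(stages, changepoints, segment_means,
                                      noise_sd = 0, seed = NULL,
                                      group = "synthetic") {
  n <- length(stages)
  changepoints <- as.integer(changepoints)
  if (length(segment_means) != length(changepoints) + 1L)
    stop_ctx("need one segment mean per segment (changepoints + 1)")
  if (length(changepoints) &&
      (any(changepoints < 2L) || any(changepoints > n) ||
       any(diff(changepoints) < 1L)))
    stop_ctx("changepoints must be strictly increasing indices in 2..", n)
  seg <- findInterval(seq_len(n), c(1L, changepoints))
  mu <- segment_means[seg]
  y <- with_seed(seed, pmax(round(mu + stats::rnorm(n, 0, noise_sd)), 0))
  out <- data.frame(group = group, stage = stages, richness = as.integer(y),
                    stringsAsFactors = FALSE)
  attr(out, "truth_changepoints") <- changepoints
  attr(out, "truth_means") <- segment_means
  out
}

#' Write a generated dataset to CSV files
#'
#' Emits the same schemas [read_specimens()], [read_traces()] and
#' [read_populations()] ingest, plus a \code{truth.json}.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$traces, file.path(dir, "traces.csv"),
                   row.names = FALSE)
  pops <- dataset$populations
  utils::write.csv(pops[, setdiff(names(pops), "drilling_frequency")],
                   file.path(dir, "populations.csv"), row.names = FALSE)
  truth <- dataset$truth
  truth$pop_p_true <- as.list(truth$pop_p_true)
  truth$f_true <- as.list(truth$f_true)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
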