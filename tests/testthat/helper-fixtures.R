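# Shared fixture builders. Everything is generated in code; no data files.

the_timescale <- load_timescale()

# Minimal valid population table. `stage` and `freq` are recycled together.
make_pops <- function(stage, freq, n = 20L, source = "EAT", grade = 5,
                      holes_complete = NULL, holes_incomplete = 0L) {
  k <- max(length(stage), length(freq), length(n))
  stage <- rep_len(stage, k)
  freq <- rep_len(freq, k)
  n <- rep_len(n, k)
  drilled <- as.integer(round(freq * n))
  data.frame(
    population_id = sprintf("P%03d", seq_len(k)),
    taxon = "Taxon_A",
    life_habit = "infaunal",
    stage = stage,
    source = rep_len(source, k),
    n_individuals = n,
    n_drilled = drilled,
    n_holes_complete = if (is.null(holes_complete)) drilled else
      rep_len(holes_complete, k),
    n_holes_incomplete = rep_len(holes_incomplete, k),
    mean_taph_grade = rep_len(grade, k),
    drilling_frequency = drilled / n,
    stringsAsFactors = FALSE
  )
}

# Tiny synthetic stage table: k stages named S1 (oldest) .. Sk, 1 Myr each.
make_toy_timescale <- function(k = 6L) {
  as_stage_table(data.frame(name = paste0("S", seq_len(k)),
                            older_bound_ma = seq(k, 1),
                            younger_bound_ma = seq(k - 1, 0)),
                 chart_version = "toy")
}

# Populations with exact per-bin frequencies on the toy timescale: one
# population per bin at exactly the given frequency (zero sampling variance).
make_exact_pops <- function(freqs, ts = make_toy_timescale(length(freqs)),
                            denom = 1000L) {
  make_pops(ts$name, freqs, n = denom)
}

# Brute-force changepoint oracle: enumerate every placement, naive segment
# SSE, same penalty and tie rules (fewer changepoints, lexicographic).
oracle_changepoints <- function(y, max_cp, penalty) {
  n <- length(y)
  sse_seg <- function(i, j) { v <- y[i:j]; sum((v - mean(v))^2) }
  total <- function(bounds) {
    starts <- c(1L, bounds); ends <- c(bounds - 1L, n)
    sum(mapply(sse_seg, starts, ends))
  }
  best <- list(cost = total(integer(0)), bounds = integer(0))
  for (k in seq_len(max_cp)) {
    if (n - 1L < k) break
    cm <- combn(2:n, k)
    for (j in seq_len(ncol(cm))) {
      cost <- total(cm[, j]) + penalty * k
      if (cost < best$cost - 1e-12) best <- list(cost = cost, bounds = cm[, j])
    }
  }
  best
}

# Strong-effect recovery scenario: flat sampling of at least 8 populations
# per bin and a planted Lutetian -> Rupelian ramp whose per-step rise is
# about six plateau-level bin-mean standard errors (kappa = 500 with large,
# weakly dispersed populations).
recovery_config <- function(seed) {
  synth_config(seed = seed, lambda = 8, min_pops_per_bin = 8,
               n_eat_target = NULL, n_lit_candidates = 0, n_lit_target = NULL,
               kappa = 500, min_n = 200, nb_mu = 600, nb_size = 5)
}
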