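test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(seed = 17, n_eat_target = 40, n_lit_candidates = 40,
                      n_lit_target = 10)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$specimens, d2$specimens)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$populations, d2$populations)
  expect_identical(d1$truth, d2$truth)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(f_pre = 0.4, f_post = 0.2), "f_pre < f_post")
  expect_error(synth_config(kappa = 0), "kappa")
  expect_error(synth_config(p_incomplete = 1.2), "\\[0,1\\]")
  expect_error(synth_config(min_n = 0), "min_n")
})

test_that("generated data satisfy every population invariant", {
  for (s in c(3, 8)) {
    d <- generate_dataset(synth_config(seed = s))
    p <- d$populations
    expect_true(all(p$n_drilled >= 0 & p$n_drilled <= p$n_individuals))
    expect_true(all(p$n_individuals >= 10))
    expect_equal(p$drilling_frequency, p$n_drilled / p$n_individuals)
    expect_true(all(p$source %in% c("EAT", "LIT")))
    expect_true(all(is.na(p$mean_taph_grade[p$source == "LIT"])))
    expect_true(all(!is.na(p$mean_taph_grade[p$source == "EAT"])))
    # re-validation (the readers' own checks) passes untouched
    expect_silent(validate_populations(p, d$timescale))
  }
})

test_that("with no detection loss and no overdispersion the pre-phase mean is unbiased", {
  lam <- c(rep(10, 20), rep(0, 21))  # populations only in pre-phase bins
  cfg <- synth_config(seed = 4, lambda = lam, n_eat_target = NULL,
                      n_lit_candidates = 0, n_lit_target = NULL,
                      delta_slope = 0, kappa = 1e6, p_parasitic = 0)
  d <- generate_dataset(cfg)
  f <- d$eat$drilling_frequency
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - cfg$f_pre), 3 * se + 1e-6)
})

test_that("total detection loss erases every observed drill hole", {
  cfg <- synth_config(seed = 9, n_eat_target = 40, n_lit_candidates = 0,
                      n_lit_target = NULL, delta_floor = 1, delta_slope = 0,
                      p_parasitic = 0)
  d <- generate_dataset(cfg)
  expect_true(all(d$eat$n_drilled == 0))
  expect_true(all(d$eat$drilling_frequency == 0))
})

test_that("raising detection loss never raises an observed frequency", {
  for (s in 1:5) {
    lo <- generate_dataset(synth_config(seed = 60 + s, n_eat_target = 60,
                                        n_lit_candidates = 0, n_lit_target = NULL,
                                        delta_slope = 0.01))
    hi <- generate_dataset(synth_config(seed = 60 + s, n_eat_target = 60,
                                        n_lit_candidates = 0, n_lit_target = NULL,
                                        delta_slope = 0.08))
    expect_identical(lo$eat$population_id, hi$eat$population_id)
    expect_true(all(hi$eat$n_drilled <= lo$eat$n_drilled))
  }
})

test_that("grade-dependent loss induces the negative grade-frequency trend", {
  cors <- vapply(1:20, function(s) {
    d <- generate_dataset(synth_config(seed = 200 + s, delta_slope = 0.08))
    cor(d$eat$mean_taph_grade, d$eat$drilling_frequency)
  }, numeric(1))
  expect_lt(mean(cors), 0)
  expect_gte(sum(cors < 0), 16L)  # sign check across seeds
})

test_that("literature bias enriches highly drilled populations", {
  set.seed(5)
  pops <- make_pops(rep("Chattian", 400), round(rbeta(400, 1.5, 6), 3),
                    n = 50L)
  flat <- apply_literature_bias(pops, slope = 0, intercept = 0.5, seed = 8)
  se <- sd(pops$drilling_frequency) / sqrt(nrow(flat))
  expect_lt(abs(mean(flat$drilling_frequency) -
                mean(pops$drilling_frequency)), 3 * se)
  biased <- apply_literature_bias(pops, slope = 12, intercept = -1, seed = 8)
  expect_gt(mean(biased$drilling_frequency),
            mean(pops$drilling_frequency) + 3 * se)
  expect_true(all(biased$source == "LIT"))
  expect_true(all(is.na(biased$mean_taph_grade)))
  empty <- apply_literature_bias(pops[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_error(apply_literature_bias(pops, n_target = 600), "exceeds")
})

test_that("diversity generator plants exact, recoverable segmentations", {
  stages <- the_timescale$name[1:12]
  s0 <- generate_diversity_series(stages, c(5, 9), c(3, 11, 26), noise_sd = 0)
  expect_equal(s0$richness, c(rep(3L, 4), rep(11L, 4), rep(26L, 4)))
  cp <- detect_changepoints(s0, max_cp = 2, timescale = the_timescale)
  expect_equal(cp$cp_indices, c(5L, 9L))
  a <- generate_diversity_series(stages, 6, c(4, 20), noise_sd = 3, seed = 2)
  b <- generate_diversity_series(stages, 6, c(4, 20), noise_sd = 3, seed = 2)
  expect_identical(a, b)
  expect_true(all(a$richness >= 0))
  expect_error(generate_diversity_series(stages, c(5), c(1, 2, 3)),
               "one segment mean per segment")
})
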