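test_that("phase enumeration is exhaustive and duplicate-free", {
  expect_length(enumerate_phase_models(4, 2), 3L)
  expect_length(enumerate_phase_models(4, 3), 3L)   # C(3,2)
  expect_length(enumerate_phase_models(36, 3), 595L) # C(35,2)
  expect_length(enumerate_phase_models(10, 3), 36L)  # C(9,2)
  keys <- vapply(enumerate_phase_models(8, 3),
                 function(s) paste(s$boundaries, collapse = "-"), "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(enumerate_phase_models(2, 3), "cannot fit")
  expect_error(phase_model_spec(3, c(5, 5), 10), "strictly increasing")
  expect_error(phase_model_spec(2, 1, 10), "interior")
})

test_that("transitions straddling a boundary belong to the younger phase", {
  s <- phase_model_spec(3, c(3, 5), 6)
  # transitions into bins 2..6
  expect_equal(s$phase_of_transition, c(1L, 2L, 2L, 3L, 3L))
})

test_that("zero-variance data give capped scores and exact trajectories", {
  ts <- make_toy_timescale(6)
  pops <- make_exact_pops(rep(0.3, 6), ts)
  ser <- bin_series(pops, ts)
  fit <- simulate_phase_model(pops, ser, phase_model_spec(2, 4, 6),
                              n_iter = 50, seed = 1)
  expect_true(all(fit$ssq_per_iter == 0))
  expect_equal(fit$fit_score, 1e12)   # capped inverse at SSQ = 0
  # arithmetic progression: every pool difference is exactly d
  d <- 0.05
  pops2 <- make_exact_pops(0.1 + d * (0:5), ts)
  ser2 <- bin_series(pops2, ts)
  fit2 <- simulate_phase_model(pops2, ser2, phase_model_spec(3, c(3, 5), 6),
                               n_iter = 200, seed = 2)
  expect_equal(fit2$median_traj, 0.1 + d * (0:5), tolerance = 1e-9)
  expect_equal(fit2$bands$q25, fit2$bands$q75, tolerance = 1e-9)
  expect_equal(fit2$traj_r, 1, tolerance = 1e-9)
})

test_that("SSQ is translation-diagnostic at zero variance", {
  ts <- make_toy_timescale(5)
  pops <- make_exact_pops(rep(0.4, 5), ts)
  ser <- bin_series(pops, ts)
  shifted <- ser
  c0 <- 0.12
  shifted$mean_f[shifted$occupied] <- shifted$mean_f[shifted$occupied] + c0
  fit <- simulate_phase_model(pops, shifted, phase_model_spec(2, 3, 5),
                              n_iter = 20, seed = 1)
  expect_equal(unname(fit$mean_ssq), c0^2 * 5, tolerance = 1e-12)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  d <- generate_dataset(synth_config(seed = 21, n_eat_target = 60,
                                     n_lit_candidates = 0, n_lit_target = NULL))
  pops <- filter_populations(d$eat)
  ser <- bin_series(pops, d$timescale, sources = "EAT")
  spec <- phase_model_spec(3, c(10, 20), sum(ser$occupied))
  f1 <- simulate_phase_model(pops, ser, spec, n_iter = 300, seed = 77)
  f2 <- simulate_phase_model(pops, ser, spec, n_iter = 300, seed = 77)
  expect_identical(f1$ssq_per_iter, f2$ssq_per_iter)
  expect_identical(f1$bands, f2$bands)
  expect_true(all(f1$bands$q25 <= f1$bands$q50 + 1e-15) &&
              all(f1$bands$q50 <= f1$bands$q75 + 1e-15))
  expect_true(all(f1$bands$q25 >= 0 & f1$bands$q75 <= 1))
})

test_that("excluding gap-spanning differences can empty a pool, with error", {
  pops <- make_pops(c("Aalenian", "Bathonian", "Callovian", "Oxfordian"),
                    c(0.1, 0.2, 0.1, 0.3), n = 50L)  # Bajocian unoccupied
  ser <- bin_series(pops, the_timescale)
  spec <- phase_model_spec(2, 3, 4)  # phase 1 transitions: only the gap one
  expect_error(simulate_phase_model(pops, ser, spec, n_iter = 10, seed = 1,
                                    include_gap_diffs = FALSE),
               "phase 1.*empty")
  fit <- simulate_phase_model(pops, ser, spec, n_iter = 10, seed = 1)
  expect_s3_class(fit, "phase_fit")
})

test_that("flat noiseless data rank models purely by the tie-break", {
  ts <- make_toy_timescale(6)
  pops <- make_exact_pops(rep(0.5, 6), ts)
  ser <- bin_series(pops, ts)
  surf <- fit_all_models(pops, ser, k_phases = 3, n_iter = 30, seed = 5)
  expect_true(all(surf$grid$fit_score == surf$grid$fit_score[1]))
  top <- surf$grid[surf$grid$rank == 1, ]
  expect_equal(top$start_bin, 2L)  # earliest start, then shortest transition
  expect_equal(top$end_bin, 2L)
  surf2 <- fit_all_models(pops, ser, k_phases = 3, n_iter = 30, seed = 5)
  expect_identical(surf$grid, surf2$grid)
})

test_that("a planted two-phase step is localized by the two-phase scan", {
  ts <- make_toy_timescale(10)
  freqs <- c(rep(0.05, 5), rep(0.45, 5))
  pops <- make_pops(rep(ts$name, each = 4), rep(freqs, each = 4), n = 1000L)
  ser <- bin_series(pops, ts)
  surf <- fit_all_models(pops, ser, k_phases = 2, n_iter = 2000, seed = 9)
  best <- surf$grid[surf$grid$rank == 1, ]
  expect_equal(best$start_bin, 6L)  # the jump enters at bin 6
})

test_that("best-fit report translates bins to stages and survives JSON", {
  d <- generate_dataset(recovery_config(3))
  pops <- filter_populations(d$eat)
  ser <- bin_series(pops, d$timescale, sources = "EAT")
  surf <- fit_all_models(pops, ser, k_phases = 3, n_iter = 100, seed = 13)
  rep <- best_fit_report(surf, d$timescale)
  expect_equal(rep$best$transition_start_midpoint_ma,
               unname(stage_midpoint(d$timescale, rep$best$transition_start_stage)))
  expect_equal(rep$best$transition_end_midpoint_ma,
               unname(stage_midpoint(d$timescale, rep$best$transition_end_stage)))
  expect_equal(nrow(rep$top5), 5L)
  expect_equal(rep$top5$rank, 1:5)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  rep2 <- read_report_json(path)
  expect_equal(rep2$best$transition_start_stage, rep$best$transition_start_stage)
  expect_equal(rep2$best$fit_score, rep$best$fit_score)
  expect_equal(rep2$top5$end_midpoint_ma, rep$top5$end_midpoint_ma)
})
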