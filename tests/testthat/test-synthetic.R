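test_that("phase sampling degenerates to the component means and recovers the circular mean", {
  p <- condition_params("uninjured_control", phase_sd = 1e-12,
                        sync_mixture_weight = 0)
  set.seed(1)
  expect_equal(sample_phase(p, 5), rep(0.5, 5), tolerance = 1e-9)

  p_sync <- condition_params("uninjured_silenced", phase_sd = 1e-12,
                             sync_mixture_weight = 1)
  draws <- sample_phase(p_sync, 5)
  expect_lt(max(pmin(draws, 1 - draws)), 1e-9)  # circular distance to 0

  # Monte-Carlo: wrapped-normal circular mean within 3 SE of the target
  p2 <- condition_params("uninjured_control", phase_mean = 0.5,
                         phase_sd = 0.05, sync_mixture_weight = 0)
  set.seed(7)
  draws <- sample_phase(p2, 10000)
  cd <- circular_descriptives(draws)
  se <- 0.05 / sqrt(10000)
  expect_lt(abs(cd$mean - 0.5), 3 * se)
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(condition_params("uninjured_control", phase_sd = 0))
  expect_error(condition_params("uninjured_control", dorsal_prob = 1.5))
  expect_error(condition_params("uninjured_control",
                                speed_range = c(50, 40)))
  expect_error(condition_params("sci_control",
                                stance_curve = c(-0.5, 0.1, 0.01)))
  expect_error(generate_pass(default_conditions()$uninjured_control,
                             frame_rate = 0))
  expect_error(generate_pass(default_conditions()$uninjured_control,
                             n_strides = 1))
  dup <- list(condition_params("sci_control"), condition_params("sci_control"))
  expect_error(synthetic_config(conditions = dup), "duplicate")
})

test_that("pass generation is deterministic and events are sane", {
  p <- default_conditions()$sci_control
  set.seed(99); a <- generate_pass(p, n_strides = 6)
  set.seed(99); b <- generate_pass(p, n_strides = 6)
  expect_identical(a, b)
  set.seed(100); c <- generate_pass(p, n_strides = 6)
  expect_false(identical(a$footfalls, c$footfalls))

  for (lm in split(a$footfalls, a$footfalls$limb)) {
    expect_true(all(lm$contact_s < lm$liftoff_s))
    n <- nrow(lm)
    if (n > 1) expect_true(all(lm$liftoff_s[-n] < lm$contact_s[-1]))
  }
  # stance + swing = stride exactly, by construction of the cycles
  cyc <- step_cycles_from_events(a$footfalls[a$footfalls$limb == "LH", ])
  expect_equal(cyc$stance_s + cyc$swing_s, cyc$stride_s, tolerance = 1e-12)
})

test_that("dorsal fraction and phase dispersion match their generative laws", {
  p <- condition_params("sci_control", dorsal_prob = 0.25, phase_sd = 0.05)
  set.seed(21)
  steps <- character(0)
  while (length(steps) < 400) {
    pp <- generate_pass(p, n_strides = 8, include_markers = FALSE)
    hind <- pp$footfalls[pp$footfalls$limb %in% c("LH", "RH"), ]
    steps <- c(steps, hind$step_type)
  }
  steps <- steps[1:400]
  ci <- stats::binom.test(sum(steps == "dorsal"), 400, 0.25)$conf.int
  expect_true(ci[1] <= 0.25 && 0.25 <= ci[2])

  # >= 95% of hindlimb phases inside mean +/- 2 realized SD (no mixture)
  p2 <- condition_params("uninjured_control", phase_sd = 0.03,
                         sync_mixture_weight = 0)
  set.seed(22)
  ph <- numeric(0)
  for (i in 1:40) {
    pp <- generate_pass(p2, n_strides = 8, include_markers = FALSE)
    obs <- pass_phases(pp$footfalls, pairs = "hindlimb")
    ph <- c(ph, obs$linear_phase)
  }
  m <- mean(ph); s <- sd(ph)
  expect_gte(mean(ph >= m - 2 * s & ph <= m + 2 * s), 0.95)
})

test_that("cohort bookkeeping, determinism, and manifest are consistent", {
  cfg <- synthetic_config(n_animals = 3, passes_per_animal = 4,
                          strides_per_pass = c(3, 5), seed = 5)
  coh <- generate_cohort(cfg)
  key <- unique(coh$footfalls[c("condition", "animal", "pass")])
  expect_equal(nrow(key), 4 * 3 * 4)  # conditions x animals x passes
  expect_length(coh$manifest$animals, 4 * 3)
  expect_equal(coh$manifest$seed, 5L)

  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)
  cfg3 <- synthetic_config(n_animals = 3, passes_per_animal = 4,
                           strides_per_pass = c(3, 5), seed = 6)
  expect_false(identical(generate_cohort(cfg3)$footfalls, coh$footfalls))
})

test_that("swim pass generation alternates strokes around the sampled phase", {
  p <- condition_params("uninjured_control", phase_sd = 0.02)
  set.seed(31)
  sw <- generate_swim_pass(p, n_strokes = 6)
  expect_length(sw$reference_peaks, 7)
  expect_length(sw$nearside_peaks, 6)
  obs <- swim_phase(sw$nearside_peaks, sw$reference_peaks)
  expect_true(all(abs(obs$linear_phase - 0.5) < 0.1))
})
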