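test_that("two-proportion z reproduces hand arithmetic in both variants", {
  # unpooled convention
  z1 <- two_proportion_z(7, 168, 72, 161, "unpooled")
  expect_equal(abs(z1$z), 9.63, tolerance = 0.005)
  expect_lt(z1$p, 0.001)
  # pooled convention
  z2 <- two_proportion_z(113, 281, 51, 233, "pooled")
  expect_equal(abs(z2$z), 4.44, tolerance = 0.005)
  # equal proportions -> z = 0
  expect_equal(two_proportion_z(10, 100, 20, 200)$z, 0)
  # degenerate proportions -> error
  expect_error(two_proportion_z(0, 50, 0, 60), "zero")
  expect_error(two_proportion_z(50, 50, 60, 60, "pooled"), "zero")
})

test_that("two-proportion z is antisymmetric under group swap", {
  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(20:300, 1); n2 <- sample(20:300, 1)
    k1 <- rbinom(1, n1, 0.3); k2 <- rbinom(1, n2, 0.5)
    if (k1 == 0 && k2 == 0) next
    for (v in c("pooled", "unpooled")) {
      a <- two_proportion_z(k1, n1, k2, n2, v)
      b <- two_proportion_z(k2, n2, k1, n1, v)
      expect_equal(a$z, -b$z, tolerance = 1e-12)
      expect_equal(sign(a$z), sign(a$p2 - a$p1))
    }
  }
})

test_that("Watson U2 statistic matches the brute-force EDF oracle", {
  set.seed(43)
  for (i in 1:20) {
    a <- runif(sample(5:30, 1))
    b <- runif(sample(5:30, 1))
    expect_equal(quadgait:::.watson_u2_stat(a, b),
                 watson_u2_bruteforce(a, b), tolerance = 1e-12)
  }
  # with ties across samples
  a <- c(0.1, 0.2, 0.2, 0.5); b <- c(0.2, 0.3, 0.5, 0.9)
  expect_equal(quadgait:::.watson_u2_stat(a, b),
               watson_u2_bruteforce(a, b), tolerance = 1e-12)
})

test_that("Watson U2 is rotation invariant and exchangeable under the null", {
  set.seed(47)
  a <- (0.5 + rnorm(20, 0, 0.08)) %% 1
  b <- (0.5 + rnorm(25, 0, 0.08)) %% 1
  u <- quadgait:::.watson_u2_stat(a, b)
  for (rot in c(0.13, 0.5, 0.91)) {
    expect_equal(quadgait:::.watson_u2_stat((a + rot) %% 1, (b + rot) %% 1),
                 u, tolerance = 1e-9)
  }
  # same sample shuffled: exchangeable, permutation p large
  w <- watson_u2(a, sample(a), n_permutations = 499, seed = 11)
  expect_gte(w$p, 0.9)
  expect_error(watson_u2(a[1:3], b, n_permutations = 99), "at least 4")
})

test_that("Watson U2 permutation p agrees with the exhaustive label permutation", {
  # two fixed 5-point samples; all C(10,5) = 252 relabelings
  a <- c(0.05, 0.15, 0.32, 0.48, 0.97)
  b <- c(0.41, 0.52, 0.58, 0.67, 0.74)
  u_obs <- quadgait:::.watson_u2_stat(a, b)
  expect_equal(u_obs, watson_u2_bruteforce(a, b), tolerance = 1e-12)
  pool <- c(a, b)
  combs <- utils::combn(10, 5)
  u_all <- apply(combs, 2, function(idx)
    quadgait:::.watson_u2_stat(pool[idx], pool[-idx]))
  p_exact <- mean(u_all >= u_obs - 1e-12)
  w <- watson_u2(a, b, n_permutations = 9999, seed = 3)
  expect_equal(w$p, p_exact, tolerance = 0.02)
})

test_that("Watson U2 separates alternation from synchrony with high power", {
  set.seed(53)
  p_vals <- replicate(50, {
    a <- (0.5 + rnorm(50, 0, 0.05)) %% 1
    b <- rnorm(50, 0, 0.05) %% 1
    watson_u2(a, b, method = "asymptotic")$p
  })
  expect_gte(mean(p_vals < 0.01), 0.99)
})

test_that("circular descriptives match the direct vector sum", {
  d <- circular_descriptives(rep(0.5, 8))
  expect_equal(d$mean, 0.5)
  expect_equal(d$R, 1)
  # four equispaced points: resultant 0, mean undefined
  d0 <- circular_descriptives(c(0, 0.25, 0.5, 0.75))
  expect_equal(d0$R, 0, tolerance = 1e-12)
  expect_true(is.na(d0$mean))
  set.seed(59)
  for (i in 1:10) {
    v <- runif(sample(3:50, 1))
    got <- circular_descriptives(v)
    ang <- 2 * pi * v
    Cs <- sum(cos(ang)) / length(v); Ss <- sum(sin(ang)) / length(v)
    expect_equal(got$R, sqrt(Cs^2 + Ss^2), tolerance = 1e-12)
    expect_equal(got$mean, (atan2(Ss, Cs) / (2 * pi)) %% 1, tolerance = 1e-12)
    expect_equal(got$circ_sd_rad, sqrt(-2 * log(got$R)), tolerance = 1e-12)
  }
})

test_that("speed-curve fits recover noiseless coefficients exactly", {
  x <- seq(10, 100, length.out = 40)
  y <- 0.05 + 0.4 * exp(-0.06 * x)
  f <- fit_speed_curve(x, y, "exponential_decay")
  expect_equal(unname(f$coefficients), c(0.05, 0.4, 0.06), tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  fl <- fit_speed_curve(x, 2 + 0.3 * x, "linear")
  expect_equal(unname(fl$coefficients), c(2, 0.3), tolerance = 1e-9)
  pi_tab <- f$prediction_interval(c(20, 50))
  expect_true(all(pi_tab$lwr <= pi_tab$fit & pi_tab$fit <= pi_tab$upr))
  expect_error(fit_speed_curve(rep(50, 10), runif(10), "exponential_decay"),
               "spread")
  expect_error(fit_speed_curve(x[1:3], y[1:3], "exponential_decay"),
               "too few")
})

test_that("paired t matches the closed form and guards zero variance", {
  a <- c(10.2, 11.5, 9.8, 12.0, 10.9, 11.1, 10.0, 12.3, 11.7, 10.4)
  b <- c(11.0, 12.1, 10.5, 12.2, 11.8, 11.0, 10.9, 13.0, 12.5, 10.8)
  d <- b - a
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  got <- paired_t(a, b)
  expect_equal(got$t, t_closed, tolerance = 1e-12)
  expect_equal(got$df, 9)
  expect_equal(got$p, 2 * pt(-abs(t_closed), 9), tolerance = 1e-12)
  expect_equal(paired_t(a, a + c(1e-8, rep(0, 9)))$df, 9)
  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(a, a + 2), "zero variance")
})
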