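mk_markers <- function(crest, hip, ankle, toe, time_s = 0) {
  data.frame(
    time_s = time_s,
    marker = c("crest", "hip", "ankle", "toe"),
    x_cm = c(crest[1], hip[1], ankle[1], toe[1]),
    y_cm = c(crest[2], hip[2], ankle[2], toe[2])
  )
}

test_that("joint angles match elementary geometry", {
  # collinear crest-hip-ankle: proximal 180
  m <- mk_markers(c(0, 2), c(0, 1), c(0, 0), c(1, 0))
  ang <- compute_joint_angles(m)
  expect_equal(ang$proximal_deg, 180)
  # hip above ankle, toe at right angle: distal 90
  expect_equal(ang$distal_deg, 90)
})

test_that("angles are invariant to rigid motion and uniform scaling", {
  set.seed(4)
  base <- list(crest = c(0.3, 6.1), hip = c(0.5, 4.2),
               ankle = c(2.4, 1.3), toe = c(3.9, 0.2))
  ref <- compute_joint_angles(do.call(mk_markers, unname(base)))
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 5)
    shift <- runif(2, -10, 10)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- lapply(base, function(p) as.vector(sc * R %*% p + shift))
    got <- compute_joint_angles(do.call(mk_markers, unname(tr)))
    expect_equal(got$proximal_deg, ref$proximal_deg, tolerance = 1e-9)
    expect_equal(got$distal_deg, ref$distal_deg, tolerance = 1e-9)
  }
})

test_that("coincident markers are flagged and excluded with a warning", {
  m <- rbind(mk_markers(c(0, 2), c(0, 1), c(0, 0), c(1, 0), time_s = 0),
             mk_markers(c(0, 1), c(0, 1), c(0, 0), c(1, 0), time_s = 0.01))
  expect_warning(ang <- compute_joint_angles(m), "coincident")
  expect_equal(nrow(ang), 1)
})

test_that("excursion follows amplitude and grows with the window", {
  t <- seq(0, 2, by = 1 / 120)
  series <- data.frame(time_s = t,
                       proximal_deg = rep(100, length(t)),
                       distal_deg = 105 + 40 * sin(2 * pi * t))
  exc <- angle_excursion(series)
  expect_equal(unname(exc["proximal_deg"]), 0)
  expect_equal(unname(exc["distal_deg"]), 80, tolerance = 0.1)
  # monotone non-decreasing under window widening
  prev <- 0
  for (w in c(0.3, 0.6, 1.2, 2)) {
    e <- angle_excursion(series, c(0, w))[["distal_deg"]]
    expect_gte(e + 1e-12, prev)
    prev <- e
  }
  expect_error(angle_excursion(series, c(0, 1e-4)), "2 frames")
})

test_that("intralimb lag matches construction and a cross-correlation oracle", {
  t <- seq(0, 3, by = 1 / 120)
  P <- 0.5
  mk <- function(lag_frac) data.frame(
    time_s = t,
    proximal_deg = 120 + 25 * sin(2 * pi * t / P),
    distal_deg = 105 + 40 * sin(2 * pi * (t / P - lag_frac)))
  cyc <- c(1.0, 1.5)
  expect_equal(intralimb_lag(mk(0), cyc), 0, tolerance = 0.02)
  expect_equal(intralimb_lag(mk(0.5), cyc), 0.5, tolerance = 0.02)

  # circular cross-correlation argmax oracle, to one frame
  for (lag_frac in c(0.1, 0.25, 0.4)) {
    s <- mk(lag_frac)
    got <- intralimb_lag(s, cyc)
    shifts <- 0:(round(P * 120) - 1)
    cc <- vapply(shifts, function(k) {
      d <- if (k == 0) s$distal_deg
      else c(s$distal_deg[-seq_len(k)], s$distal_deg[seq_len(k)])
      stats::cor(s$proximal_deg, d)
    }, numeric(1))
    oracle <- shifts[which.max(cc)] / (P * 120)
    expect_equal(got, oracle, tolerance = 1 / (P * 120) + 1e-9)
  }
})

test_that("lag is undefined without an identifiable peak", {
  t <- seq(0, 1, by = 1 / 120)
  flat <- data.frame(time_s = t, proximal_deg = rep(120, length(t)),
                     distal_deg = 105 + 40 * sin(2 * pi * t / 0.5))
  expect_true(is.na(intralimb_lag(flat, c(0.2, 0.7))))
})

test_that("stick figures decimate and invert back to the source angles", {
  p <- default_conditions()$uninjured_control
  set.seed(12)
  pass <- generate_pass(p, n_strides = 3)
  lh <- pass$markers[pass$markers$limb == "LH", ]
  n_frames <- length(unique(lh$time_s))
  sf1 <- stick_figure(lh, decimation = 1)
  expect_equal(nrow(sf1$polylines) / 4, n_frames)
  sf5 <- stick_figure(lh, decimation = 5)
  expect_equal(nrow(sf5$polylines) / 4, ceiling(n_frames / 5))
  expect_equal(nrow(sf1$toe_height), n_frames)

  # round trip: polylines re-fed to compute_joint_angles reproduce angles
  poly <- sf1$polylines
  back <- data.frame(time_s = poly$time_s,
                     marker = poly$point, x_cm = poly$x_cm, y_cm = poly$y_cm)
  expect_equal(compute_joint_angles(back), compute_joint_angles(lh),
               tolerance = 1e-9)
})

test_that("angle-to-marker synthesis is inverted by angle computation", {
  prox <- c(95, 120, 140); dist <- c(70, 105, 150)
  xy <- angles_to_markers(prox, dist, hip_x = c(0, 5, 10))
  m <- data.frame(
    time_s = rep(c(0, 0.01, 0.02), times = 4),
    marker = rep(c("crest", "hip", "ankle", "toe"), each = 3),
    x_cm = c(xy$crest_x, xy$hip_x, xy$ankle_x, xy$toe_x),
    y_cm = c(xy$crest_y, xy$hip_y, xy$ankle_y, xy$toe_y))
  ang <- compute_joint_angles(m)
  expect_equal(ang$proximal_deg, prox, tolerance = 1e-9)
  expect_equal(ang$distal_deg, dist, tolerance = 1e-9)
})
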