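#' Sample interlimb phase values from a condition's mixture model
#'
#' Draws from a two-component wrapped-normal mixture: with probability
#' `1 - sync_mixture_weight` a wrapped-normal around `phase_mean`
#' (alternation), otherwise a wrapped-normal around 0 (synchrony). Results are
#' wrapped to `[0, 1)`.
#'
#' Uses the global RNG; seed with [set.seed()] (or go through
#' [generate_cohort()], which seeds once for the whole cohort).
#'
#' @param params a [condition_params()] object.
#' @param n number of draws.
#' @param mean,sd optional overrides of `params$phase_mean` / `params$phase_sd`
#'   (used internally for the heterolateral pair).
#' @return numeric vector of circular fractions in `[0, 1)`.
#' @export
sample_phase <- function(params, n = 1, mean = params$phase_mean,
                         sd = params$phase_sd) {
  stopifnot(inherits(params, "condition_params"), n >= 1)
  sync <- stats::runif(n) < params$sync_mixture_weight
  centre <- ifelse(sync, 0, mean)
  (centre + stats::rnorm(n, 0, sd)) %% 1
}

# fixed segment lengths for angle -> coordinate synthesis (cm); recorded in
# the cohort manifest and invertible by compute_joint_angles()
.segment_lengths <- c(crest_hip = 2.5, hip_ankle = 4, ankle_toe = 2)
.limb_levels <- c("LH", "RH", "LF", "RF")

# positive truncation helper: resample-free clamp at a small floor
.clamp_pos <- function(x, floor = 0.02) pmax(x, floor)

#' Generate one stepping pass: marker trajectories and footfall events
#'
#' Synthesizes contact/lift-off events for all four limbs and sagittal
#' four-marker trajectories for both hindlimbs, consistent with the
#' condition's generative parameters. The left hindlimb is the timing
#' reference: its stance times follow the condition's exponential
#' stance-vs-speed law plus noise, swing times are Gaussian, and the right
#' hindlimb's contacts are offset by a phase drawn from [sample_phase()].
#' The forelimb girdle shares the stride timing; the right forelimb is
#' phase-locked near synchrony with the left hindlimb (heterolateral pair) and
#' the forelimb pair's internal phase is drawn independently from the same
#' mixture model. Hindlimb steps are flagged dorsal with the condition's
#' per-limb probabilities. Joint angles are sinusoid templates with the
#' configured excursions and intralimb lag, converted to marker coordinates
#' with fixed segment lengths.
#'
#' @param params a [condition_params()] object.
#' @param frame_rate frames per second (> 0).
#' @param n_strides number of complete reference-limb strides (>= 2).
#' @param include_markers if `FALSE`, skip marker-trajectory synthesis (events
#'   only); markers dominate the generation cost.
#' @param stance_noise_sd additive Gaussian noise on stance times, seconds.
#' @return list with elements `markers` (data.frame: frame, time_s, marker,
#'   limb, x_cm, y_cm; `NULL` when `include_markers = FALSE`), `footfalls`
#'   (data.frame: limb, contact_s, liftoff_s, toe_x_cm, step_type), and
#'   `speed_cm_s` (the pass's sampled reference speed).
#' @export
generate_pass <- function(params, frame_rate = 120, n_strides = 6,
                          include_markers = TRUE, stance_noise_sd = 0.008) {
  stopifnot(inherits(params, "condition_params"))
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (n_strides < 2) stop("n_strides must be >= 2")

  speed <- stats::runif(1, params$speed_range[1], params$speed_range[2])
  sc <- params$stance_curve

  stance_of <- function(n) .clamp_pos(
    sc[1] + sc[2] * exp(-sc[3] * speed) + stats::rnorm(n, 0, stance_noise_sd))
  swing_of <- function(n) .clamp_pos(
    stats::rnorm(n, params$swing_mean, params$swing_sd))

  # reference limb (LH): contact onsets from cumulated stride times
  lh_stance <- stance_of(n_strides + 1)
  lh_swing <- swing_of(n_strides + 1)
  lh_stride <- lh_stance + lh_swing
  lh_contact <- 0.2 + cumsum(c(0, lh_stride[seq_len(n_strides)]))
  lh_liftoff <- lh_contact + lh_stance

  # one phase draw per reference stride places the RH contact in that stride
  ph_hind <- sample_phase(params, n_strides)
  rh_contact <- lh_contact[seq_len(n_strides)] + ph_hind * lh_stride[seq_len(n_strides)]
  rh_contact <- sort(rh_contact)
  rh_stance <- stance_of(n_strides)
  # keep events ordered: stance may not run past the next contact
  gap <- c(diff(rh_contact), Inf)
  rh_stance <- pmin(rh_stance, 0.9 * gap)
  rh_liftoff <- rh_contact + rh_stance

  # Each forelimb leads its diagonal hindlimb by a small consistent fraction
  # of the cycle (diagonal-couplet lead, mean 0.1): the heterolateral LH-RF
  # pair is then concentrated at synchrony and, with zero noise, the footfall
  # order is exactly the alternate pattern RF,LH,LF,RH. The forelimb pair's
  # internal phase is an independent draw from the same mixture model, so the
  # girdles share stride timing but not their phase noise.
  lead_rf <- stats::rnorm(n_strides, 0.1, 0.8 * params$phase_sd)
  lead_lf <- stats::rnorm(n_strides, 0.1, 0.8 * params$phase_sd)
  ph_fore <- sample_phase(params, n_strides)
  str_i <- lh_stride[seq_len(n_strides)]
  rf_contact <- lh_contact[seq_len(n_strides)] - lead_rf * str_i
  lf_contact <- lh_contact[seq_len(n_strides)] + (ph_fore - lead_lf) * str_i
  fl_scale <- 0.95  # forelimb stance slightly shorter than hindlimb
  rf_contact <- sort(rf_contact); lf_contact <- sort(lf_contact)
  rf_stance <- pmin(fl_scale * stance_of(n_strides), 0.9 * c(diff(rf_contact), Inf))
  lf_stance <- pmin(fl_scale * stance_of(n_strides), 0.9 * c(diff(lf_contact), Inf))

  # dorsal flags: per-limb probabilities preserve the overall dorsal_prob
  # while splitting expected dorsal counts dorsal_right_share : (1 - share)
  p_right <- min(1, params$dorsal_prob * 2 * params$dorsal_right_share)
  p_left <- min(1, params$dorsal_prob * 2 * (1 - params$dorsal_right_share))
  lh_type <- ifelse(stats::runif(n_strides + 1) < p_left, "dorsal", "plantar")
  rh_type <- ifelse(stats::runif(n_strides) < p_right, "dorsal", "plantar")

  toe_x <- function(t, off) speed * t + off
  footfalls <- rbind(
    data.frame(limb = "LH", contact_s = lh_contact, liftoff_s = lh_liftoff,
               toe_x_cm = toe_x(lh_contact, 0), step_type = lh_type),
    data.frame(limb = "RH", contact_s = rh_contact, liftoff_s = rh_liftoff,
               toe_x_cm = toe_x(rh_contact, 1), step_type = rh_type),
    data.frame(limb = "LF", contact_s = lf_contact,
               liftoff_s = lf_contact + lf_stance,
               toe_x_cm = toe_x(lf_contact, 8), step_type = "plantar"),
    data.frame(limb = "RF", contact_s = rf_contact,
               liftoff_s = rf_contact + rf_stance,
               toe_x_cm = toe_x(rf_contact, 9), step_type = "plantar")
  )
  footfalls <- footfalls[order(footfalls$limb, footfalls$contact_s), ]
  rownames(footfalls) <- NULL

  markers <- NULL
  if (include_markers) {
    t_end <- lh_contact[n_strides + 1]
    frames <- seq(0, floor(t_end * frame_rate))
    time_s <- frames / frame_rate
    markers <- rbind(
      .limb_markers("LH", time_s, frames, lh_contact, params, speed),
      .limb_markers("RH", time_s, frames, c(rh_contact, rh_contact[n_strides] +
                                              mean(lh_stride)), params, speed)
    )
  }
  list(markers = markers, footfalls = footfalls, speed_cm_s = speed)
}

# sinusoid-template joint angles -> 4-marker sagittal coordinates for one limb
.limb_markers <- function(limb, time_s, frames, contacts, params, speed) {
  # within-cycle position u in [0,1) relative to this limb's own contacts
  idx <- findInterval(time_s, contacts)
  idx_c <- pmin(pmax(idx, 1), length(contacts) - 1)
  u <- (time_s - contacts[idx_c]) / (contacts[idx_c + 1] - contacts[idx_c])
  prox <- 120 + (params$excursion_proximal / 2) * sin(2 * pi * u)
  dist <- 105 + (params$excursion_distal / 2) *
    sin(2 * pi * (u - params$intralimb_lag))
  xy <- angles_to_markers(prox, dist, hip_x = speed * time_s, hip_y = 6)
  data.frame(
    frame = rep(frames, times = 4),
    time_s = rep(time_s, times = 4),
    marker = rep(c("crest", "hip", "ankle", "toe"), each = length(frames)),
    limb = limb,
    x_cm = c(xy$crest_x, xy$hip_x, xy$ankle_x, xy$toe_x),
    y_cm = c(xy$crest_y, xy$hip_y, xy$ankle_y, xy$toe_y)
  )
}

#' Convert proximal/distal joint angles to sagittal marker coordinates
#'
#' Inverse of [compute_joint_angles()] up to a rigid placement: the crest sits
#' vertically above the hip, the thigh segment leaves the hip at the interior
#' proximal angle from the hip-to-crest direction, and the foot segment leaves
#' the ankle at the interior distal angle from the ankle-to-hip direction.
#' Segment lengths are fixed (crest-hip 2.5, hip-ankle 4, ankle-toe 2 cm).
#'
#' @param proximal_deg,distal_deg interior angles in degrees, `(0, 180]`.
#' @param hip_x,hip_y hip marker position(s), cm.
#' @return data.frame of the eight coordinates per frame.
#' @export
angles_to_markers <- function(proximal_deg, distal_deg, hip_x = 0, hip_y = 6) {
  L <- .segment_lengths
  tp <- proximal_deg * pi / 180
  td <- distal_deg * pi / 180
  n <- max(length(proximal_deg), length(distal_deg), length(hip_x))
  hip_x <- rep_len(hip_x, n); hip_y <- rep_len(hip_y, n)
  crest_x <- hip_x; crest_y <- hip_y + L[["crest_hip"]]
  # hip -> ankle: rotate the up direction by the proximal angle (toward +x)
  ax <- hip_x + L[["hip_ankle"]] * sin(tp)
  ay <- hip_y + L[["hip_ankle"]] * cos(tp)
  # ankle -> toe: rotate ankle -> hip by -distal (clockwise, toward +x/down)
  wx <- (hip_x - ax) / L[["hip_ankle"]]
  wy <- (hip_y - ay) / L[["hip_ankle"]]
  vx <- cos(-td) * wx - sin(-td) * wy
  vy <- sin(-td) * wx + cos(-td) * wy
  data.frame(crest_x = crest_x, crest_y = crest_y,
             hip_x = hip_x, hip_y = hip_y,
             ankle_x = ax, ankle_y = ay,
             toe_x = ax + L[["ankle_toe"]] * vx,
             toe_y = ay + L[["ankle_toe"]] * vy)
}

#' Generate one swimming pass: peak-extension event times for both hindlimbs
#'
#' The reference (opposite) hindlimb's peak-extension times follow regular
#' stroke cycles with mild cycle-time jitter; each nearside peak is placed in
#' its reference stroke cycle at a phase drawn from the condition's mixture
#' model.
#'
#' @param params a [condition_params()] object.
#' @param n_strokes complete reference stroke cycles (>= 2).
#' @param stroke_time_s mean stroke-cycle duration, seconds.
#' @return list with `reference_peaks` (length `n_strokes + 1`) and
#'   `nearside_peaks` (length `n_strokes`), times in seconds.
#' @export
generate_swim_pass <- function(params, n_strokes = 5, stroke_time_s = 0.35) {
  stopifnot(inherits(params, "condition_params"), n_strokes >= 2)
  cyc <- .clamp_pos(stats::rnorm(n_strokes, stroke_time_s, 0.02 * stroke_time_s))
  ref <- 0.1 + cumsum(c(0, cyc))
  ph <- sample_phase(params, n_strokes)
  near <- ref[seq_len(n_strokes)] + ph * cyc
  list(reference_peaks = ref, nearside_peaks = sort(near))
}

#' Generate a full synthetic cohort across conditions
#'
#' Seeds the global RNG once from `config$seed`; per-animal parameter jitter
#' (phase dispersion, dorsal probability, excursions, within 10%) and all
#' per-pass draws derive from that single stream, so identical configurations
#' give bit-identical output.
#'
#' @param config a [synthetic_config()] object.
#' @param include_markers generate marker trajectories (slower) as well as
#'   footfall events.
#' @return list with `footfalls` and `markers` data.frames keyed by
#'   (`condition`, `animal`, `pass`), and a `manifest` list recording the
#'   seed, frame rate, segment lengths and every realized per-animal
#'   parameter set.
#' @export
generate_cohort <- function(config, include_markers = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  foot_all <- list(); mark_all <- list(); manifest <- list()
  k <- 0L
  for (cond in config$conditions) {
    for (animal in seq_len(config$n_animals)) {
      jp <- .jitter_params(cond)
      manifest[[length(manifest) + 1L]] <- c(
        list(condition = cond$label, animal = animal),
        jp[c("phase_mean", "phase_sd", "sync_mixture_weight", "dorsal_prob",
             "swing_mean", "excursion_proximal", "excursion_distal",
             "intralimb_lag")],
        list(stance_curve = jp$stance_curve))
      for (pass in seq_len(config$passes_per_animal)) {
        n_str <- sample(config$strides_per_pass[1]:config$strides_per_pass[2], 1)
        p <- generate_pass(jp, frame_rate = config$frame_rate,
                           n_strides = n_str,
                           include_markers = include_markers)
        k <- k + 1L
        foot_all[[k]] <- cbind(condition = cond$label, animal = animal,
                               pass = pass, p$footfalls)
        if (include_markers)
          mark_all[[k]] <- cbind(condition = cond$label, animal = animal,
                                 pass = pass, p$markers)
      }
    }
  }
  list(
    footfalls = do.call(rbind, foot_all),
    markers = if (include_markers) do.call(rbind, mark_all) else NULL,
    manifest = list(seed = config$seed, frame_rate = config$frame_rate,
                    segment_lengths_cm = as.list(.segment_lengths),
                    animals = manifest)
  )
}

# mild per-animal heterogeneity; jittered object revalidated by construction
.jitter_params <- function(cond) {
  j <- function(x, f = 0.1) x * stats::runif(1, 1 - f, 1 + f)
  condition_params(
    cond$label,
    phase_mean = cond$phase_mean,
    phase_sd = j(cond$phase_sd),
    sync_mixture_weight = min(1, j(cond$sync_mixture_weight)),
    dorsal_prob = min(1, j(cond$dorsal_prob)),
    stance_curve = cond$stance_curve,
    swing_mean = j(cond$swing_mean, 0.05),
    swing_sd = cond$swing_sd,
    excursion_proximal = j(cond$excursion_proximal, 0.05),
    excursion_distal = j(cond$excursion_distal, 0.05),
    intralimb_lag = cond$intralimb_lag,
    speed_range = cond$speed_range,
    dorsal_right_share = cond$dorsal_right_share
  )
}
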