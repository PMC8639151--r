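#' Generative parameters of one behavioral condition
#'
#' A `condition_params` object holds everything the synthetic gait generator
#' needs to emulate one behavioral condition: the target left-right hindlimb
#' phase and its circular dispersion, the weight of a synchrony-centred
#' mixture component (silencing drifts steps toward synchrony), the per-step
#' probability of a dorsal placement (a spinal-cord-injury deficit), the
#' exponential stance-time-vs-speed law, the swing-time distribution, the
#' proximal/distal joint-angle excursions with their intralimb lag, and the
#' pass speed range.
#'
#' Phase noise is wrapped-normal rather than von Mises so that the linear-scale
#' 2-SD irregularity thresholds used downstream have an exact generative
#' counterpart.
#'
#' @param label one of `"uninjured_control"`, `"uninjured_silenced"`,
#'   `"sci_control"`, `"sci_silenced"`.
#' @param phase_mean target hindlimb-pair phase, circular fraction in `[0,1)`;
#'   0.5 is strict alternation.
#' @param phase_sd circular dispersion of the alternation component, as a
#'   fraction of the cycle; must be positive.
#' @param sync_mixture_weight probability in `[0,1]` that a step's phase is
#'   drawn from the synchrony-centred component (mean 0) instead of the
#'   alternation component.
#' @param dorsal_prob per-hindlimb-step probability of a dorsal placement.
#' @param stance_curve numeric `c(y0, a, b)` of
#'   `stance_time = y0 + a * exp(-b * speed)` (seconds, speed in cm/s).
#' @param swing_mean,swing_sd swing-time distribution, seconds.
#' @param excursion_proximal,excursion_distal joint-angle excursions, degrees.
#' @param intralimb_lag delay of the distal angle behind the proximal angle,
#'   fraction of the step cycle in `[0,1)`.
#' @param speed_range pass speed range `c(min, max)`, cm/s.
#' @param dorsal_right_share fraction of expected dorsal steps assigned to the
#'   right hindlimb (sidedness); per-limb probabilities are scaled so the
#'   overall dorsal fraction stays `dorsal_prob`.
#' @return an object of class `condition_params`.
#' @seealso [default_conditions()], [generate_pass()], [generate_cohort()]
#' @export
condition_params <- function(label,
                             phase_mean = 0.5,
                             phase_sd = 0.03,
                             sync_mixture_weight = 0,
                             dorsal_prob = 0,
                             stance_curve = c(y0 = 0.08, a = 0.36, b = 0.025),
                             swing_mean = 0.10,
                             swing_sd = 0.010,
                             excursion_proximal = 52,
                             excursion_distal = 90,
                             intralimb_lag = 0.08,
                             speed_range = c(40, 90),
                             dorsal_right_share = 0.6) {
  labels <- c("uninjured_control", "uninjured_silenced",
              "sci_control", "sci_silenced")
  label <- match.arg(label, labels)
  stopifnot(
    is.numeric(phase_mean), length(phase_mean) == 1,
    phase_mean >= 0, phase_mean < 1,
    is.numeric(phase_sd), length(phase_sd) == 1, phase_sd > 0,
    sync_mixture_weight >= 0, sync_mixture_weight <= 1,
    dorsal_prob >= 0, dorsal_prob <= 1,
    length(stance_curve) == 3,
    swing_mean > 0, swing_sd >= 0,
    excursion_proximal > 0, excursion_distal > 0,
    intralimb_lag >= 0, intralimb_lag < 1,
    length(speed_range) == 2, speed_range[1] < speed_range[2],
    speed_range[1] > 0,
    dorsal_right_share >= 0, dorsal_right_share <= 1
  )
  stance_curve <- unname(stance_curve)
  # stance law must stay positive over the admissible speeds
  smin <- min(stance_curve[1] + stance_curve[2] * exp(-stance_curve[3] * speed_range))
  if (smin <= 0) stop("stance_curve yields non-positive stance time over speed_range")
  structure(
    list(label = label, phase_mean = phase_mean, phase_sd = phase_sd,
         sync_mixture_weight = sync_mixture_weight, dorsal_prob = dorsal_prob,
         stance_curve = stance_curve, swing_mean = swing_mean,
         swing_sd = swing_sd, excursion_proximal = excursion_proximal,
         excursion_distal = excursion_distal, intralimb_lag = intralimb_lag,
         speed_range = speed_range, dorsal_right_share = dorsal_right_share),
    class = "condition_params"
  )
}

#' Default generative parameters for the four behavioral conditions
#'
#' The defaults encode the qualitative structure the analysis is built to
#' detect. Uninjured controls alternate tightly (phase SD 0.03 cycle, no
#' synchrony component, no dorsal steps). Silencing in the uninjured animal
#' loosens alternation and adds a synchrony-drifting mixture component.
#' Spinal cord injury adds dorsal steps (about a quarter of hindlimb steps,
#' right-biased ~60/40), widens phase dispersion, reduces joint excursions and
#' delays the distal angle; post-injury silencing partially normalizes phase
#' dispersion, dorsal stepping, excursions and swing time while leaving
#' hindlimb-forelimb coupling deficits in place.
#'
#' @return named list of four [condition_params()] objects.
#' @export
default_conditions <- function() {
  list(
    uninjured_control = condition_params(
      "uninjured_control",
      phase_sd = 0.03, sync_mixture_weight = 0, dorsal_prob = 0,
      stance_curve = c(0.08, 0.36, 0.025), swing_mean = 0.100, swing_sd = 0.010,
      excursion_proximal = 52, excursion_distal = 90, intralimb_lag = 0.08,
      speed_range = c(40, 90)),
    uninjured_silenced = condition_params(
      "uninjured_silenced",
      phase_sd = 0.06, sync_mixture_weight = 0.35, dorsal_prob = 0,
      stance_curve = c(0.08, 0.36, 0.025), swing_mean = 0.100, swing_sd = 0.010,
      excursion_proximal = 52, excursion_distal = 93, intralimb_lag = 0.08,
      speed_range = c(40, 90)),
    sci_control = condition_params(
      "sci_control",
      phase_sd = 0.10, sync_mixture_weight = 0.15, dorsal_prob = 0.25,
      stance_curve = c(0.09, 0.42, 0.025), swing_mean = 0.087, swing_sd = 0.016,
      excursion_proximal = 47, excursion_distal = 75, intralimb_lag = 0.15,
      speed_range = c(40, 70)),
    sci_silenced = condition_params(
      "sci_silenced",
      phase_sd = 0.05, sync_mixture_weight = 0.05, dorsal_prob = 0.12,
      stance_curve = c(0.09, 0.42, 0.023), swing_mean = 0.106, swing_sd = 0.012,
      excursion_proximal = 51, excursion_distal = 85, intralimb_lag = 0.10,
      speed_range = c(40, 70))
  )
}

#' Synthetic cohort configuration
#'
#' @param conditions list of [condition_params()] objects (unique labels).
#' @param n_animals animals per condition.
#' @param passes_per_animal stepping passes per animal.
#' @param strides_per_pass integer range `c(min, max)` of reference-limb
#'   strides per pass.
#' @param frame_rate camera frame rate, frames/s.
#' @param seed integer seed; every stochastic draw of the cohort derives from
#'   this one stream.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(conditions = default_conditions(),
                             n_animals = 6,
                             passes_per_animal = 6,
                             strides_per_pass = c(3, 9),
                             frame_rate = 120,
                             seed = 1L) {
  stopifnot(length(conditions) >= 1,
            n_animals >= 1, passes_per_animal >= 1,
            length(strides_per_pass) == 2,
            strides_per_pass[1] >= 2,
            strides_per_pass[1] <= strides_per_pass[2],
            frame_rate > 0)
  labels <- vapply(conditions, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  structure(
    list(conditions = stats::setNames(conditions, labels),
         n_animals = as.integer(n_animals),
         passes_per_animal = as.integer(passes_per_animal),
         strides_per_pass = as.integer(strides_per_pass),
         frame_rate = frame_rate, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}
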