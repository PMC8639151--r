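#' Segment a per-frame contact trace into step cycles
#'
#' A step cycle runs from one contact onset to the next (stride time); stance
#' is onset to lift-off, swing is lift-off to the next onset. Contact-state
#' runs shorter than `debounce_frames` are merged into the surrounding state
#' before segmentation to suppress single-frame digitization dropouts.
#' Incomplete trailing cycles are dropped; a trace with fewer than two onsets
#' yields an empty result.
#'
#' @param trace data.frame with `time_s` (strictly increasing), `contact`
#'   (logical), `toe_x_cm`, and optionally `step_type` (per-frame, read at the
#'   contact onset; defaults to `"plantar"`).
#' @param limb limb label attached to the cycles.
#' @param debounce_frames minimum run length kept as a distinct contact state.
#' @return data.frame of step cycles (see [step_cycles_from_events()] for the
#'   columns).
#' @export
segment_step_cycles <- function(trace, limb = "LH", debounce_frames = 3) {
  stopifnot(all(c("time_s", "contact", "toe_x_cm") %in% names(trace)))
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("trace times must be strictly increasing")
  contact <- .debounce(as.logical(trace$contact), debounce_frames)
  d <- diff(c(FALSE, contact))
  onset_i <- which(d == 1)
  offset_i <- which(d == -1)  # first non-contact frame after a bout
  if (length(onset_i) < 2) return(.empty_cycles())
  st <- if ("step_type" %in% names(trace)) trace$step_type else
    rep("plantar", nrow(trace))
  events <- data.frame(
    limb = limb,
    contact_s = trace$time_s[onset_i],
    liftoff_s = NA_real_,
    toe_x_cm = trace$toe_x_cm[onset_i],
    step_type = st[onset_i]
  )
  for (i in seq_along(onset_i)) {
    off <- offset_i[offset_i > onset_i[i]][1]
    events$liftoff_s[i] <- if (is.na(off)) NA_real_ else trace$time_s[off]
  }
  step_cycles_from_events(events)
}

# merge runs shorter than k frames into the surrounding state
.debounce <- function(x, k) {
  if (k <= 1 || length(x) == 0) return(x)
  r <- rle(x)
  while (any(short <- r$lengths < k) && length(r$lengths) > 1) {
    i <- which(short)[1]
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

.empty_cycles <- function() {
  data.frame(limb = character(0), contact_s = numeric(0),
             liftoff_s = numeric(0), next_contact_s = numeric(0),
             stance_s = numeric(0), swing_s = numeric(0),
             stride_s = numeric(0), stride_distance_cm = numeric(0),
             instantaneous_speed_cm_s = numeric(0),
             stride_frequency_hz = numeric(0), duty_cycle = numeric(0),
             step_type = character(0))
}

#' Build step cycles from a footfall event table
#'
#' One limb's (contact, lift-off, toe position, step type) events become
#' complete step cycles: stride time is initial contact to initial contact,
#' stance is contact to lift-off, swing the remainder, stride distance the
#' toe displacement between successive contacts, and instantaneous speed the
#' stride distance over the stride time. The last (incomplete) event is
#' dropped. The dorsal/plantar label is passed through untouched.
#'
#' @param events data.frame with `limb`, `contact_s`, `liftoff_s`, `toe_x_cm`,
#'   `step_type`, one limb, time-ordered (sorted internally).
#' @return data.frame with one row per complete cycle: `limb`, `contact_s`,
#'   `liftoff_s`, `next_contact_s`, `stance_s`, `swing_s`, `stride_s`,
#'   `stride_distance_cm`, `instantaneous_speed_cm_s`, `stride_frequency_hz`,
#'   `duty_cycle`, `step_type`.
#' @export
step_cycles_from_events <- function(events) {
  if (nrow(events) < 2) return(.empty_cycles())
  events <- events[order(events$contact_s), ]
  n <- nrow(events) - 1
  idx <- seq_len(n)
  contact <- events$contact_s[idx]
  liftoff <- events$liftoff_s[idx]
  nxt <- events$contact_s[idx + 1]
  if (any(!is.na(liftoff) & (liftoff <= contact | liftoff >= nxt)))
    stop("lift-off must fall strictly inside its stride interval")
  stride <- nxt - contact
  if (any(stride <= 0)) stop("zero-length reference stride")
  stance <- liftoff - contact
  dist <- abs(events$toe_x_cm[idx + 1] - events$toe_x_cm[idx])
  data.frame(
    limb = events$limb[idx],
    contact_s = contact, liftoff_s = liftoff, next_contact_s = nxt,
    stance_s = stance, swing_s = stride - stance, stride_s = stride,
    stride_distance_cm = dist,
    instantaneous_speed_cm_s = dist / stride,
    stride_frequency_hz = 1 / stride,
    duty_cycle = stance / stride,
    step_type = events$step_type[idx]
  )
}

#' Per-limb spatiotemporal means over step cycles
#'
#' Arithmetic means of swing, stance and stride times, stride distance and
#' duty cycle; average speed is the mean of the per-step instantaneous speeds
#' (stride distance over stride time), following the convention that pass
#' speed is stride-derived rather than body-marker-derived.
#'
#' @param cycles data.frame of step cycles.
#' @return one-row data.frame of means plus `n_cycles`.
#' @export
spatiotemporal_summary <- function(cycles) {
  if (nrow(cycles) == 0) stop("no step cycles")
  data.frame(
    n_cycles = nrow(cycles),
    swing_s = mean(cycles$swing_s),
    stance_s = mean(cycles$stance_s),
    stride_s = mean(cycles$stride_s),
    stride_distance_cm = mean(cycles$stride_distance_cm),
    speed_cm_s = mean(cycles$instantaneous_speed_cm_s),
    duty_cycle = mean(cycles$duty_cycle)
  )
}

#' Assemble a four-limb footfall sequence from per-limb step cycles
#'
#' Contact onsets of all limbs are merged and time-sorted; placements sharing
#' the exact same time take the deterministic tie order LH < RH < LF < RF.
#' The dorsal/plantar label rides along unchanged.
#'
#' @param cycle_list list of per-limb step-cycle data.frames (or event tables
#'   with `limb`, `contact_s`, `step_type`); empty elements are allowed.
#' @return data.frame (`time_s`, `limb`, `step_type`), the substrate for the
#'   footfall-pattern indices.
#' @export
build_footfall_sequence <- function(cycle_list) {
  recs <- lapply(cycle_list, function(d) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    data.frame(time_s = d$contact_s, limb = as.character(d$limb),
               step_type = d$step_type)
  })
  out <- do.call(rbind, recs)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(time_s = numeric(0), limb = character(0),
                      step_type = character(0)))
  tie <- match(out$limb, .limb_levels)
  out <- out[order(out$time_s, tie), ]
  rownames(out) <- NULL
  out
}
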