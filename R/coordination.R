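.pairs_alternating <- c("hindlimb", "forelimb", "homolateral", "swim")
.pairs_synchronous <- c("heterolateral")
.all_pairs <- c(.pairs_alternating, .pairs_synchronous)

#' Interlimb phase of a test limb within a reference limb's stride cycles
#'
#' For each reference stride `[t_i, t_{i+1})`, every test-limb contact `t*`
#' falling in the interval yields a raw phase `(t* - t_i) / (t_{i+1} - t_i)`:
#' the initial contact time of one limb divided by the stride time of the
#' other. 0 (equivalently 1) is synchrony, 0.5 strict alternation. Cycles
#' with no test contact yield no observation; cycles with two or more
#' ("double steps") yield one observation per contact, flagged `multi_step`.
#'
#' @param reference_cycles step-cycle data.frame of the reference limb (left
#'   hindlimb for the hindlimb pair, left forelimb for the forelimb pair,
#'   hindlimb for hindlimb-forelimb pairs).
#' @param test_contacts numeric vector of test-limb contact-onset times, or an
#'   event/cycle data.frame with a `contact_s` column.
#' @param test_step_type optional per-contact dorsal/plantar labels.
#' @param pair pair label, one of `"hindlimb"`, `"forelimb"`,
#'   `"homolateral"`, `"heterolateral"`, `"swim"`.
#' @return data.frame with `pair`, `stride_index`, `raw_phase`,
#'   `linear_phase`, `step_type`, `multi_step`.
#' @export
interlimb_phase <- function(reference_cycles, test_contacts,
                            test_step_type = NULL, pair = "hindlimb") {
  pair <- match.arg(pair, .all_pairs)
  if (is.data.frame(test_contacts)) {
    if (is.null(test_step_type) && "step_type" %in% names(test_contacts))
      test_step_type <- test_contacts$step_type
    test_contacts <- test_contacts$contact_s
  }
  if (nrow(reference_cycles) < 1) stop("at least one reference cycle required")
  if (any(reference_cycles$stride_s <= 0)) stop("zero-length reference stride")
  if (is.null(test_step_type))
    test_step_type <- rep("plantar", length(test_contacts))
  ord <- order(test_contacts)
  test_contacts <- test_contacts[ord]
  test_step_type <- test_step_type[ord]
  out <- list()
  for (i in seq_len(nrow(reference_cycles))) {
    t0 <- reference_cycles$contact_s[i]
    t1 <- reference_cycles$next_contact_s[i]
    in_cyc <- which(test_contacts >= t0 & test_contacts < t1)
    if (length(in_cyc) == 0) next
    raw <- (test_contacts[in_cyc] - t0) / (t1 - t0)
    out[[length(out) + 1L]] <- data.frame(
      pair = pair, stride_index = i, raw_phase = raw,
      linear_phase = transform_phase(raw, pair),
      step_type = test_step_type[in_cyc],
      multi_step = length(in_cyc) > 1
    )
  }
  if (length(out) == 0)
    return(data.frame(pair = character(0), stride_index = integer(0),
                      raw_phase = numeric(0), linear_phase = numeric(0),
                      step_type = character(0), multi_step = logical(0)))
  do.call(rbind, out)
}

#' Fold circular phase onto a lead-limb-free linear scale
#'
#' Eliminates lead-limb preference by reflecting the circular value: for the
#' nominally alternating pairs (hindlimb, forelimb, homolateral
#' hindlimb-forelimb, swim) phase maps to `[0.5, 1]` (`raw` if `raw >= 0.5`,
#' else `1 - raw`); for the nominally synchronous heterolateral pair it maps
#' to `[0, 0.5]` (`raw` if `raw <= 0.5`, else `1 - raw`). The transform is
#' idempotent on its output range and satisfies `T(raw) == T(1 - raw)`.
#'
#' @param raw circular fractions in `[0, 1)` (values of exactly 1 are also
#'   accepted and treated as 0 wrapped).
#' @param pair pair label (see [interlimb_phase()]).
#' @return linear fractions.
#' @export
transform_phase <- function(raw, pair = "hindlimb") {
  pair <- match.arg(pair, .all_pairs)
  if (any(raw < 0 | raw > 1)) stop("raw phase must lie in [0, 1]")
  if (pair %in% .pairs_alternating) ifelse(raw >= 0.5, raw, 1 - raw)
  else ifelse(raw <= 0.5, raw, 1 - raw)
}

#' Control-derived irregularity threshold for a limb pair
#'
#' Mean and sample SD (n-1 denominator) of the uninjured-control linear-scale
#' phase values; the irregularity bounds are mean +/- 2 SD, clipped to the
#' pair's valid linear range. Downstream, a step is "irregular" when it falls
#' strictly beyond these bounds (beyond control variability).
#'
#' @param control_values linear-scale control phases (>= 3, nonzero spread).
#' @param pair pair label.
#' @return object of class `irregularity_threshold` with `pair`,
#'   `control_mean`, `control_sd`, `lower`, `upper`.
#' @export
control_threshold <- function(control_values, pair = "hindlimb") {
  pair <- match.arg(pair, .all_pairs)
  if (length(control_values) < 3) stop("need at least 3 control values")
  s <- stats::sd(control_values)
  if (s == 0) stop("degenerate threshold: control values have zero spread")
  m <- mean(control_values)
  rng <- if (pair %in% .pairs_alternating) c(0.5, 1) else c(0, 0.5)
  structure(list(pair = pair, control_mean = m, control_sd = s,
                 lower = max(m - 2 * s, rng[1]),
                 upper = min(m + 2 * s, rng[2])),
            class = "irregularity_threshold")
}

#' Classify phase values against a 2-SD control threshold
#'
#' A value is irregular iff it lies strictly outside `[lower, upper]`
#' (boundary values are regular, matching a "> 2 SD" rule). The percentage is
#' `100 * k / n` rounded to two decimals, the form printed alongside each
#' `k/n` pair in the study figures.
#'
#' @param values linear-scale phase values (non-empty).
#' @param threshold an [control_threshold()] object.
#' @return list with `flags` (logical), `k_irregular`, `n_total`,
#'   `percentage`.
#' @export
classify_irregular <- function(values, threshold) {
  stopifnot(inherits(threshold, "irregularity_threshold"))
  if (length(values) == 0) stop("no values to classify")
  flags <- values < threshold$lower | values > threshold$upper
  k <- sum(flags)
  list(flags = flags, k_irregular = k, n_total = length(values),
       percentage = round(100 * k / length(values), 2))
}

#' Hindlimb phase during swimming
#'
#' The time of peak extension of the nearside hindlimb within one complete
#' stroke cycle of the reference (opposite) hindlimb, as a fraction of that
#' stroke cycle — identical arithmetic to [interlimb_phase()] with
#' peak-extension events substituting contacts. Values are transformed and
#' thresholded as for the hindlimb pair.
#'
#' @param nearside_peaks peak-extension times of the nearside hindlimb.
#' @param reference_peaks peak-extension times of the reference hindlimb
#'   (>= 2; consecutive peaks delimit stroke cycles).
#' @return data.frame as returned by [interlimb_phase()] with
#'   `pair = "swim"`.
#' @export
swim_phase <- function(nearside_peaks, reference_peaks) {
  if (length(reference_peaks) < 2) stop("at least one reference stroke cycle required")
  reference_peaks <- sort(reference_peaks)
  n <- length(reference_peaks) - 1
  ref_cycles <- data.frame(
    contact_s = reference_peaks[seq_len(n)],
    next_contact_s = reference_peaks[seq_len(n) + 1],
    stride_s = diff(reference_peaks)
  )
  interlimb_phase(ref_cycles, nearside_peaks, pair = "swim")
}
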