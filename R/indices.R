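#' The six normal step sequence patterns
#'
#' Canonical cruciate (Ca, Cb), alternate (Aa, Ab) and rotary (Ra, Rb)
#' four-limb placement orders seen in normally stepping rats, used by the
#' regularity and central pattern indices.
#'
#' @return named list of length-4 character vectors over LH/RH/LF/RF.
#' @export
normal_step_patterns <- function() {
  list(
    Ca = c("RF", "LF", "RH", "LH"),
    Cb = c("LF", "RF", "LH", "RH"),
    Aa = c("RF", "LH", "LF", "RH"),
    Ab = c("LF", "RH", "RF", "LH"),
    Ra = c("RF", "LF", "LH", "RH"),
    Rb = c("LF", "RF", "RH", "LH")
  )
}

.is_normal_window <- function(w, patterns) {
  any(vapply(patterns, function(p) all(w == p), logical(1)))
}

# cyclic-order match: the window, read as a cycle, equals some rotation of a
# normal pattern (and hence contains each limb exactly once)
.is_normal_window_cyclic <- function(w, patterns) {
  if (anyDuplicated(w)) return(FALSE)
  rot <- lapply(0:3, function(k) c(w[(k + 1):4], w[seq_len(k)])[1:4])
  any(vapply(patterns, function(p)
    any(vapply(rot, function(r) all(r == p), logical(1))), logical(1)))
}

#' Regularity index (RI)
#'
#' `RI = 100 * (number of normal step sequence patterns * 4) / paw placements`.
#' Dorsal placements are excluded before matching, and the denominator counts
#' the post-exclusion placements. The remaining placement string is scanned
#' left to right, greedily and non-overlappingly, for the six normal patterns;
#' windows in which the four paws are not all sequential (a repeated limb) do
#' not match. Fewer than four placements after exclusion yields `NA`.
#'
#' @param seq footfall sequence data.frame (`time_s`, `limb`, `step_type`)
#'   from [build_footfall_sequence()].
#' @param patterns pattern set, default [normal_step_patterns()].
#' @return percentage in `[0, 100]`, or `NA_real_`.
#' @export
regularity_index <- function(seq, patterns = normal_step_patterns()) {
  limbs <- as.character(seq$limb[seq$step_type != "dorsal"])
  n <- length(limbs)
  if (n < 4) return(NA_real_)
  matches <- 0L
  i <- 1L
  while (i + 3L <= n) {
    if (.is_normal_window(limbs[i:(i + 3L)], patterns)) {
      matches <- matches + 1L
      i <- i + 4L
    } else i <- i + 1L
  }
  100 * (matches * 4) / n
}

#' Central pattern index (CPI)
#'
#' `CPI = 100 * correctly patterned step cycles / total step cycles`,
#' evaluated in a rolling fashion: a window of four consecutive placements
#' advances one placement at a time, and a cycle is correctly patterned if its
#' window contains each limb exactly once in one of the six normal orders.
#' Because the window rolls one placement at a time, a window is compared
#' against the normal orders cyclically (the six patterns are lead-limb
#' representatives of the normal cyclic orders; a perfectly patterned pass
#' scores 100 regardless of which limb a window happens to start on).
#' Dorsal steps are included, and double steps (a limb repeated within the
#' window) count as incorrect — this is what lets CPI detect them.
#'
#' @inheritParams regularity_index
#' @return percentage in `[0, 100]`.
#' @export
central_pattern_index <- function(seq, patterns = normal_step_patterns()) {
  limbs <- as.character(seq$limb)
  n <- length(limbs)
  if (n == 0) stop("empty footfall sequence")
  if (n < 4) return(0)
  wins <- n - 3L
  ok <- vapply(seq_len(wins), function(i)
    .is_normal_window_cyclic(limbs[i:(i + 3L)], patterns), logical(1))
  100 * sum(ok) / wins
}

#' Plantar stepping index (PSI)
#'
#' `PSI = 100 * hindlimb plantar steps / forelimb plantar steps`; 100 in the
#' uninjured animal where hindlimb and forelimb steps come 1:1.
#'
#' @param hind_plantar,fore_plantar plantar step counts (forelimb >= 1).
#' @param cap cap reporting at 100 (`TRUE` by default); hindlimbs occasionally
#'   out-count forelimbs through double steps.
#' @return percentage.
#' @export
plantar_stepping_index <- function(hind_plantar, fore_plantar, cap = TRUE) {
  if (fore_plantar < 1) stop("forelimb plantar step count must be >= 1")
  psi <- 100 * hind_plantar / fore_plantar
  if (cap) min(psi, 100) else psi
}

#' Dorsal stepping index (DSI) and dorsal-step sidedness
#'
#' `DSI = 100 * dorsal hindlimb steps / total hindlimb steps` over both
#' hindlimbs; sidedness splits the dorsal steps into right and left fractions
#' (unset when there are no dorsal steps).
#'
#' @param hind_cycles hindlimb step-cycle or event data.frame with `limb`
#'   (LH/RH) and `step_type`.
#' @return list with `dsi`, `right_fraction`, `left_fraction`, `n_dorsal`,
#'   `n_total`.
#' @export
dorsal_stepping_index <- function(hind_cycles) {
  n <- nrow(hind_cycles)
  if (n < 1) stop("at least one hindlimb cycle required")
  dorsal <- hind_cycles$step_type == "dorsal"
  nd <- sum(dorsal)
  right <- if (nd > 0) sum(dorsal & hind_cycles$limb == "RH") / nd else NA_real_
  list(dsi = 100 * nd / n,
       right_fraction = right,
       left_fraction = if (nd > 0) 1 - right else NA_real_,
       n_dorsal = nd, n_total = n)
}

#' All gait indices for one pass
#'
#' Computes RI, CPI, PSI and DSI from one pass's four-limb footfall events.
#'
#' @param events footfall event table for one pass (`limb`, `contact_s`,
#'   `step_type`).
#' @return one-row data.frame: `RI`, `CPI`, `PSI`, `DSI`,
#'   `dorsal_right_fraction`, `dorsal_left_fraction`, `n_placements`.
#' @export
gait_indices <- function(events) {
  seq <- build_footfall_sequence(split(events, events$limb))
  hind <- events[events$limb %in% c("LH", "RH"), ]
  fore <- events[events$limb %in% c("LF", "RF"), ]
  hp <- sum(hind$step_type == "plantar")
  fp <- sum(fore$step_type == "plantar")
  dsi <- dorsal_stepping_index(hind)
  data.frame(
    RI = regularity_index(seq),
    CPI = central_pattern_index(seq),
    PSI = if (fp >= 1) plantar_stepping_index(hp, fp) else NA_real_,
    DSI = dsi$dsi,
    dorsal_right_fraction = dsi$right_fraction,
    dorsal_left_fraction = dsi$left_fraction,
    n_placements = nrow(events)
  )
}
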