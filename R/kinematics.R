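#' Compute hindlimb joint angles from four-marker sagittal trajectories
#'
#' The proximal angle is the interior angle at the hip between the segments
#' hip-to-crest and hip-to-ankle; the distal angle is the interior angle at
#' the ankle between ankle-to-hip and ankle-to-toe. The knee is not marked:
#' the two angles summarize the proximal (hip/knee) and distal (knee/ankle)
#' limb segments from the four digitized markers (iliac crest, hip, ankle,
#' toe). Angles are interior, in degrees, range `(0, 180]`, and invariant to
#' rigid rotation, translation and uniform scaling of the marker set.
#'
#' @param markers data.frame with columns `time_s`, `marker`
#'   (`crest`/`hip`/`ankle`/`toe`), `x_cm`, `y_cm`, one limb's frames (a
#'   `frame` column is carried through if present).
#' @return data.frame with `time_s`, `proximal_deg`, `distal_deg`. Frames with
#'   a zero-length segment (coincident adjacent markers) are dropped with a
#'   warning.
#' @export
compute_joint_angles <- function(markers) {
  need <- c("time_s", "marker", "x_cm", "y_cm")
  if (!all(need %in% names(markers))) stop("marker table missing columns")
  wide <- .markers_wide(markers)
  if (any(!is.finite(as.matrix(wide[-1])))) stop("non-finite marker coordinates")
  prox <- .interior_angle(
    wide$crest_x - wide$hip_x, wide$crest_y - wide$hip_y,
    wide$ankle_x - wide$hip_x, wide$ankle_y - wide$hip_y)
  dist <- .interior_angle(
    wide$hip_x - wide$ankle_x, wide$hip_y - wide$ankle_y,
    wide$toe_x - wide$ankle_x, wide$toe_y - wide$ankle_y)
  bad <- !is.finite(prox) | !is.finite(dist)
  if (any(bad)) {
    warning(sprintf("%d frame(s) with coincident adjacent markers excluded",
                    sum(bad)))
  }
  out <- data.frame(time_s = wide$time_s,
                    proximal_deg = prox, distal_deg = dist)[!bad, ]
  rownames(out) <- NULL
  out
}

# long -> wide (one row per time, eight coordinate columns), time-sorted
.markers_wide <- function(markers) {
  sp <- split(markers, markers$marker)
  need <- c("crest", "hip", "ankle", "toe")
  if (!all(need %in% names(sp))) stop("all four markers required per frame")
  tms <- sort(unique(markers$time_s))
  if (any(vapply(sp, function(d) anyDuplicated(d$time_s) > 0, logical(1))))
    stop("non-monotone frame times (duplicated time for a marker)")
  out <- data.frame(time_s = tms)
  for (m in need) {
    d <- sp[[m]][order(sp[[m]]$time_s), ]
    if (nrow(d) != length(tms) || any(d$time_s != tms))
      stop(sprintf("marker '%s' missing for some frames", m))
    out[[paste0(m, "_x")]] <- d$x_cm
    out[[paste0(m, "_y")]] <- d$y_cm
  }
  out
}

# interior angle (deg) between vectors (ax,ay) and (bx,by); NaN on zero length
.interior_angle <- function(ax, ay, bx, by) {
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  cosang <- (ax * bx + ay * by) / (na * nb)
  cosang[na == 0 | nb == 0] <- NaN
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Joint-angle excursion within a time window
#'
#' Excursion is the max-minus-min of each angle over the window, the standard
#' summary of how far a joint travels during stepping.
#'
#' @param series data.frame from [compute_joint_angles()].
#' @param window numeric `c(start, end)` seconds; default spans the series.
#' @return named numeric: `proximal_deg`, `distal_deg`.
#' @export
angle_excursion <- function(series, window = range(series$time_s)) {
  keep <- series$time_s >= window[1] & series$time_s <= window[2]
  if (sum(keep) < 2) stop("window must contain at least 2 frames")
  c(proximal_deg = diff(range(series$proximal_deg[keep])),
    distal_deg = diff(range(series$distal_deg[keep])))
}

# local maxima after 5-frame centred moving average, minimum prominence (deg);
# returns peak times
.find_peak_times <- function(time_s, angle, smooth_frames = 5, min_prom = 5) {
  if (length(angle) >= smooth_frames) {
    k <- rep(1 / smooth_frames, smooth_frames)
    sm <- stats::filter(angle, k, sides = 2)
    sm[is.na(sm)] <- angle[is.na(sm)]
    angle <- as.numeric(sm)
  }
  pk <- pracma::findpeaks(angle, minpeakheight = min(angle) + min_prom / 2,
                          minpeakdistance = 3)
  if (is.null(pk)) return(numeric(0))
  # prominence filter: peak height above the higher of its flanking minima
  keep <- (pk[, 1] - pmax(angle[pk[, 3]], angle[pk[, 4]])) >= min_prom |
    (pk[, 1] - min(angle)) >= min_prom
  sort(time_s[pk[keep, 2]])
}

#' Intralimb proximal-distal coordination lag
#'
#' The temporal offset between the proximal and distal angle peaks within one
#' step cycle, expressed as a fraction of the lead (earlier-peaking) angle's
#' peak-to-peak period. Identical angle timing gives 0; a distal angle delayed
#' by half a period gives 0.5. When the two first peaks tie exactly, the
#' proximal angle is taken as lead.
#'
#' @param series data.frame from [compute_joint_angles()].
#' @param cycle numeric `c(contact_s, next_contact_s)` of one step cycle lying
#'   inside the series.
#' @param smooth_frames,min_prominence_deg peak-detection controls (centred
#'   moving average width; minimum prominence in degrees).
#' @return lag as a fraction of cycle in `[0, 1)`, or `NA_real_` when either
#'   angle has no identifiable peak in the cycle (excluded from aggregates).
#' @export
intralimb_lag <- function(series, cycle, smooth_frames = 5,
                          min_prominence_deg = 5) {
  stopifnot(length(cycle) == 2, cycle[1] < cycle[2])
  pk_p <- .find_peak_times(series$time_s, series$proximal_deg,
                           smooth_frames, min_prominence_deg)
  pk_d <- .find_peak_times(series$time_s, series$distal_deg,
                           smooth_frames, min_prominence_deg)
  in_cyc <- function(t) t[t >= cycle[1] & t < cycle[2]]
  p1 <- in_cyc(pk_p)[1]; d1 <- in_cyc(pk_d)[1]
  if (is.na(p1) || is.na(d1)) return(NA_real_)
  lead_peaks <- if (d1 < p1) pk_d else pk_p  # tie -> proximal leads
  lead1 <- min(p1, d1)
  nxt <- lead_peaks[lead_peaks > lead1][1]
  if (is.na(nxt)) return(NA_real_)
  P <- nxt - lead1
  ((d1 - p1) %% P) / P
}

#' Two-dimensional stick figures of hindlimb stepping
#'
#' @param markers one limb's marker table (long format, as read/generated).
#' @param stride numeric `c(start, end)` seconds; default full track.
#' @param decimation keep every `decimation`-th frame.
#' @return list with `polylines` (data.frame: frame, time_s, point in
#'   crest/hip/ankle/toe order, x_cm, y_cm) and `toe_height` (data.frame:
#'   time_s, y_cm).
#' @export
stick_figure <- function(markers, stride = range(markers$time_s),
                         decimation = 1) {
  wide <- .markers_wide(markers)
  wide <- wide[wide$time_s >= stride[1] & wide$time_s <= stride[2], ]
  if (nrow(wide) == 0) stop("stride interval outside track")
  keep <- wide[seq(1, nrow(wide), by = decimation), ]
  n <- nrow(keep)
  polylines <- data.frame(
    frame = rep(seq_len(n), each = 4),
    time_s = rep(keep$time_s, each = 4),
    point = rep(c("crest", "hip", "ankle", "toe"), times = n),
    x_cm = as.vector(t(keep[, c("crest_x", "hip_x", "ankle_x", "toe_x")])),
    y_cm = as.vector(t(keep[, c("crest_y", "hip_y", "ankle_y", "toe_y")]))
  )
  list(polylines = polylines,
       toe_height = data.frame(time_s = wide$time_s, y_cm = wide$toe_y))
}
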