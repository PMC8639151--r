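#' Per-pass interlimb phase observations from a footfall event table
#'
#' Computes phase observations for the four overground limb pairs of one
#' pass. Reference conventions: left hindlimb for the hindlimb pair, left
#' forelimb for the forelimb pair, and the hindlimb (left) as reference for
#' the hindlimb-forelimb pairs — homolateral is LH-LF, heterolateral LH-RF.
#'
#' @param events one pass's footfall events (`limb`, `contact_s`,
#'   `liftoff_s`, `toe_x_cm`, `step_type`).
#' @param pairs subset of pairs to compute.
#' @return data.frame of phase observations (possibly empty).
#' @export
pass_phases <- function(events,
                        pairs = c("hindlimb", "forelimb", "homolateral",
                                  "heterolateral")) {
  ev <- split(events, factor(as.character(events$limb), levels = .limb_levels))
  cyc <- lapply(ev, function(d)
    if (is.null(d) || nrow(d) < 2) .empty_cycles() else
      step_cycles_from_events(d))
  spec <- list(
    hindlimb = c(ref = "LH", test = "RH"),
    forelimb = c(ref = "LF", test = "RF"),
    homolateral = c(ref = "LH", test = "LF"),
    heterolateral = c(ref = "LH", test = "RF")
  )
  out <- list()
  for (pr in intersect(pairs, names(spec))) {
    rc <- cyc[[spec[[pr]][["ref"]]]]
    te <- ev[[spec[[pr]][["test"]]]]
    if (nrow(rc) == 0 || is.null(te) || nrow(te) == 0) next
    ph <- interlimb_phase(rc, te, pair = pr)
    # tag each observation with the step types of the contributing steps:
    # the reference stride's own type is carried alongside the test step's
    if (nrow(ph) > 0) {
      ph$ref_step_type <- rc$step_type[ph$stride_index]
      out[[length(out) + 1L]] <- ph
    }
  }
  if (length(out) == 0)
    return(data.frame(pair = character(0), stride_index = integer(0),
                      raw_phase = numeric(0), linear_phase = numeric(0),
                      step_type = character(0), multi_step = logical(0),
                      ref_step_type = character(0)))
  do.call(rbind, out)
}

#' Analyze a cohort of footfall (and optionally marker) data
#'
#' End-to-end analysis of a multi-condition data set: per-pass step-cycle
#' segmentation, interlimb phase for all four pairs, 2-SD irregularity
#' classification against the control condition's pooled thresholds, gait
#' indices (RI/CPI/PSI/DSI) per pass, per-animal and group index averages,
#' hindlimb spatiotemporal measures, and (when marker trajectories are
#' supplied) intralimb proximal-distal lag per pass.
#'
#' @param footfalls footfall event table with `condition`, `animal`, `pass`
#'   keys (as produced by [generate_cohort()] or [read_footfall_table()]).
#' @param markers optional marker table with the same keys.
#' @param control_condition condition label whose pooled linear-phase values
#'   define the irregularity thresholds.
#' @param pairs limb pairs to analyze.
#' @return list with `phase`, `thresholds`, `classification`, `indices`
#'   (per pass), `animal_indices`, `group_indices`, `cycles` (hindlimb step
#'   cycles, all passes), and `intralimb` (per-pass lag table or `NULL`).
#' @export
analyze_cohort <- function(footfalls, markers = NULL,
                           control_condition = "uninjured_control",
                           pairs = c("hindlimb", "forelimb", "homolateral",
                                     "heterolateral")) {
  if (!control_condition %in% footfalls$condition)
    stop("control condition '", control_condition, "' absent from data")
  key <- interaction(footfalls$condition, footfalls$animal, footfalls$pass,
                     drop = TRUE)
  phase_all <- list(); idx_all <- list(); cyc_all <- list()
  for (g in split(footfalls, key)) {
    meta <- g[1, c("condition", "animal", "pass")]
    ph <- pass_phases(g, pairs)
    if (nrow(ph) > 0)
      phase_all[[length(phase_all) + 1L]] <- cbind(meta, ph, row.names = NULL)
    if (nrow(g) >= 4)
      idx_all[[length(idx_all) + 1L]] <- cbind(meta, gait_indices(g),
                                               row.names = NULL)
    hind <- g[g$limb %in% c("LH", "RH"), ]
    for (lm in split(hind, hind$limb)) {
      if (nrow(lm) >= 2) {
        cc <- step_cycles_from_events(lm)
        if (nrow(cc) > 0)
          cyc_all[[length(cyc_all) + 1L]] <- cbind(meta, cc, row.names = NULL)
      }
    }
  }
  phase <- do.call(rbind, phase_all)
  indices <- do.call(rbind, idx_all)
  cycles <- do.call(rbind, cyc_all)

  # thresholds from the control condition, pooled across animals
  phase$irregular <- NA
  thresholds <- list(); classification <- list()
  for (pr in unique(phase$pair)) {
    ctrl <- phase$linear_phase[phase$pair == pr &
                                 phase$condition == control_condition]
    if (length(ctrl) < 3 || stats::sd(ctrl) == 0) next
    th <- control_threshold(ctrl, pr)
    thresholds[[pr]] <- th
    for (cond in unique(phase$condition)) {
      v <- phase$linear_phase[phase$pair == pr & phase$condition == cond]
      if (length(v) == 0) next
      cl <- classify_irregular(v, th)
      phase$irregular[phase$pair == pr & phase$condition == cond] <- cl$flags
      classification[[length(classification) + 1L]] <- data.frame(
        condition = cond, pair = pr, k_irregular = cl$k_irregular,
        n_total = cl$n_total, percentage = cl$percentage)
    }
  }
  classification <- do.call(rbind, classification)

  # indices averaged per animal, then per group (animal-average convention)
  animal_indices <- stats::aggregate(
    indices[c("RI", "CPI", "PSI", "DSI")],
    by = indices[c("condition", "animal")], FUN = mean, na.rm = TRUE)
  group_indices <- stats::aggregate(
    animal_indices[c("RI", "CPI", "PSI", "DSI")],
    by = animal_indices["condition"], FUN = mean, na.rm = TRUE)

  intralimb <- if (!is.null(markers)) .intralimb_table(markers, footfalls)
  else NULL

  list(phase = phase, thresholds = thresholds,
       classification = classification, indices = indices,
       animal_indices = animal_indices, group_indices = group_indices,
       cycles = cycles, intralimb = intralimb)
}

# per (condition, animal, pass, limb): mean intralimb lag and excursions
.intralimb_table <- function(markers, footfalls) {
  key <- interaction(markers$condition, markers$animal, markers$pass,
                     markers$limb, drop = TRUE)
  rows <- list()
  for (g in split(markers, key)) {
    meta <- g[1, c("condition", "animal", "pass", "limb")]
    ang <- compute_joint_angles(g)
    exc <- angle_excursion(ang)
    ev <- footfalls[footfalls$condition == meta$condition &
                      footfalls$animal == meta$animal &
                      footfalls$pass == meta$pass &
                      footfalls$limb == meta$limb, ]
    lags <- NA_real_
    if (nrow(ev) >= 2) {
      cyc <- step_cycles_from_events(ev)
      lags <- vapply(seq_len(nrow(cyc)), function(i)
        intralimb_lag(ang, c(cyc$contact_s[i], cyc$next_contact_s[i])),
        numeric(1))
    }
    rows[[length(rows) + 1L]] <- cbind(
      meta,
      data.frame(proximal_excursion_deg = exc[["proximal_deg"]],
                 distal_excursion_deg = exc[["distal_deg"]],
                 intralimb_lag = mean(lags, na.rm = TRUE),
                 n_cycles_with_lag = sum(!is.na(lags))),
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Fit the speed-dependent curves for a set of hindlimb step cycles
#'
#' Convenience wrapper fitting stance time and stride time against
#' instantaneous speed with the exponential-decay model, and stride distance
#' with the linear model.
#'
#' @param cycles hindlimb step-cycle table (from [analyze_cohort()]).
#' @return named list of [fit_speed_curve()] objects: `stance`, `stride`,
#'   `distance`.
#' @export
fit_spatiotemporal_curves <- function(cycles) {
  x <- cycles$instantaneous_speed_cm_s
  list(
    stance = fit_speed_curve(x, cycles$stance_s, "exponential_decay"),
    stride = fit_speed_curve(x, cycles$stride_s, "exponential_decay"),
    distance = fit_speed_curve(x, cycles$stride_distance_cm, "linear")
  )
}
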