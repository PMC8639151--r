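#' @title Delimited-table schemas
#' @description Tables are plain comma-separated UTF-8 text with a one-line
#'   versioned header comment (`# quadgait <schema> v1 ...`). Times are in
#'   seconds, positions in cm, angles in degrees; frame indices are 0-based;
#'   time intervals are half-open `[contact, next contact)`.
#' @name quadgait-io
NULL

.marker_cols <- c("condition", "animal", "pass", "frame", "time_s",
                  "marker", "limb", "x_cm", "y_cm")
.footfall_cols <- c("condition", "animal", "pass", "limb", "contact_s",
                    "liftoff_s", "toe_x_cm", "step_type")

.write_table <- function(df, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_table <- function(path, schema, cols) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, paste("# quadgait", schema)))
    stop("file does not carry the '", schema, "' schema header: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read a marker-trajectory table
#'
#' @param markers marker table (see [generate_cohort()]).
#' @param path file path.
#' @param frame_rate frames per second, recorded in the header.
#' @return the path (write) / the validated data.frame (read).
#' @export
write_marker_table <- function(markers, path, frame_rate = 120) {
  .write_table(markers[.marker_cols], path,
               sprintf("# quadgait marker v1 frame_rate=%g", frame_rate))
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- .read_table(path, "marker", .marker_cols)
  if (any(!is.finite(df$x_cm)) || any(!is.finite(df$y_cm))) {
    bad <- which(!is.finite(df$x_cm) | !is.finite(df$y_cm))[1]
    stop("non-finite coordinate at row ", bad)
  }
  if (!all(df$marker %in% c("crest", "hip", "ankle", "toe")))
    stop("unknown marker label")
  cnt <- table(interaction(df$condition, df$animal, df$pass, df$limb,
                           df$frame, drop = TRUE))
  if (any(cnt != 4)) {
    bad <- names(cnt)[cnt != 4][1]
    stop("frame without all four markers: ", bad)
  }
  df
}

#' Write / read a footfall event table
#'
#' @param footfalls footfall table (see [generate_cohort()]).
#' @param path file path.
#' @return the path (write) / the validated data.frame (read).
#' @export
write_footfall_table <- function(footfalls, path) {
  .write_table(footfalls[.footfall_cols], path, "# quadgait footfall v1")
}

#' @rdname write_footfall_table
#' @export
read_footfall_table <- function(path) {
  df <- .read_table(path, "footfall", .footfall_cols)
  if (!all(df$step_type %in% c("plantar", "dorsal"))) {
    bad <- which(!df$step_type %in% c("plantar", "dorsal"))[1]
    stop("unknown step_type at row ", bad)
  }
  bad <- which(!is.na(df$liftoff_s) & df$contact_s >= df$liftoff_s)
  if (length(bad) > 0)
    stop("contact_s >= liftoff_s at row ", bad[1])
  df
}

# small non-cryptographic FNV-1a hash for run provenance
.config_hash <- function(obj) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(obj)),
                           collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes segmentation, phase computation, 2-SD classification, the gait
#' indices and the within-bundle statistics on a footfall table (plus
#' optional markers), and writes per-pass tables and a JSON summary carrying
#' the seed, a configuration hash and the package version. Passes without
#' analyzable cycles are skipped, not fatal.
#'
#' @param footfalls footfall event table or a path readable by
#'   [read_footfall_table()].
#' @param markers optional marker table or path.
#' @param out_dir output directory (created if needed).
#' @param control_condition condition defining the irregularity thresholds.
#' @param variant two-proportion variance convention for the
#'   condition-vs-control comparisons.
#' @param seed seed recorded in the summary (and used for any permutation
#'   p-values).
#' @return (invisibly) the [analyze_cohort()] result, with `$summary` added.
#' @export
run_pipeline <- function(footfalls, markers = NULL, out_dir,
                         control_condition = "uninjured_control",
                         variant = c("unpooled", "pooled"), seed = 1L) {
  variant <- match.arg(variant)
  if (is.character(footfalls)) footfalls <- read_footfall_table(footfalls)
  if (is.character(markers)) markers <- read_marker_table(markers)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- analyze_cohort(footfalls, markers, control_condition)

  # condition-vs-control proportion tests on irregular-step counts
  tests <- list()
  cls <- res$classification
  for (pr in unique(cls$pair)) {
    ctrl <- cls[cls$pair == pr & cls$condition == control_condition, ]
    if (nrow(ctrl) != 1) next
    for (cond in setdiff(unique(cls$condition), control_condition)) {
      row <- cls[cls$pair == pr & cls$condition == cond, ]
      if (nrow(row) != 1) next
      zt <- tryCatch(two_proportion_z(ctrl$k_irregular, ctrl$n_total,
                                      row$k_irregular, row$n_total,
                                      variant = variant),
                     error = function(e) NULL)
      if (!is.null(zt))
        tests[[length(tests) + 1L]] <- c(
          list(test = "two_proportion_z", pair = pr, condition = cond,
               control = control_condition), zt)
    }
  }

  cfg <- list(control_condition = control_condition, variant = variant,
              seed = seed)
  summary <- list(
    package = "quadgait",
    version = as.character(utils::packageVersion("quadgait")),
    seed = seed, config_hash = .config_hash(cfg), config = cfg,
    thresholds = lapply(res$thresholds, unclass),
    classification = res$classification,
    group_indices = res$group_indices,
    tests = tests
  )
  utils::write.csv(res$indices, file.path(out_dir, "indices_per_pass.csv"),
                   row.names = FALSE)
  utils::write.csv(res$phase, file.path(out_dir, "phase_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cycles, file.path(out_dir, "step_cycles.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  invisible(res)
}
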