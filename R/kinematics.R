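#' Canonical lower-limb channel labels
#'
#' Channel labels follow the `<joint>_<side>_<plane>` convention with joints
#' ordered hip, knee, ankle, sides L then R, and anatomical planes sagittal,
#' frontal, transverse. The full lower-limb set has 18 channels (3 joints x
#' 2 sides x 3 planes), the usual degree-of-freedom count for bilateral
#' hip/knee/ankle kinematics.
#'
#' @param joints character vector of joints to include.
#' @param sides character vector of sides to include.
#' @param planes character vector of planes to include.
#' @return Character vector of channel labels in canonical order.
#' @export
#' @examples
#' canonical_channels()           # all 18
#' canonical_channels(planes = "sagittal")
canonical_channels <- function(joints = c("hip", "knee", "ankle"),
                               sides = c("L", "R"),
                               planes = c("sagittal", "frontal", "transverse")) {
  joints <- match.arg(joints, c("hip", "knee", "ankle"), several.ok = TRUE)
  sides <- match.arg(sides, c("L", "R"), several.ok = TRUE)
  planes <- match.arg(planes, c("sagittal", "frontal", "transverse"),
                      several.ok = TRUE)
  out <- character(0)
  for (j in joints) for (s in sides) for (p in planes)
    out <- c(out, paste(j, s, p, sep = "_"))
  out
}

#' Construct a kinematics trial
#'
#' A trial is a frames x channels matrix of joint angles in degrees sampled
#' at a fixed rate, with channel labels identifying joint, side and
#' anatomical plane.
#'
#' @param samples numeric matrix, frames x channels, angles in degrees.
#' @param fs sampling rate in Hz (must be positive).
#' @param channels character vector of channel labels (defaults to the
#'   column names of `samples`).
#' @param trial_id,activity_label identifying metadata strings.
#' @return An object of class `kin_trial`.
#' @export
kin_trial <- function(samples, fs, channels = colnames(samples),
                      trial_id = "trial", activity_label = "") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2) stop("a trial needs at least 2 frames")
  if (ncol(samples) < 1) stop("a trial needs at least 1 channel")
  if (anyNA(samples)) {
    bad <- which(is.na(samples), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at frame %d, channel %d", bad[1], bad[2]))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channels) != ncol(samples))
    stop("channel labels must match the number of columns")
  colnames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels,
         trial_id = trial_id, activity_label = activity_label),
    class = "kin_trial")
}

#' @export
print.kin_trial <- function(x, ...) {
  cat(sprintf("<kin_trial> %s%s\n", x$trial_id,
              if (nzchar(x$activity_label))
                paste0(" [", x$activity_label, "]") else ""))
  cat(sprintf("  %d frames x %d channels at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' Construct a foot-contact event series
#'
#' @param events strictly increasing integer frame indices (1-based) of
#'   initial contacts for one foot.
#' @param foot `"L"` or `"R"`.
#' @param n_frames optional trial length used to validate the indices.
#' @return An object of class `foot_contacts`.
#' @export
foot_contacts <- function(events, foot = c("L", "R"), n_frames = NULL) {
  foot <- match.arg(foot)
  events <- as.integer(events)
  if (length(events) == 0) stop("no contact events")
  if (any(events < 1)) stop("contact frame indices must be >= 1")
  if (any(diff(events) <= 0))
    stop("contact events must be strictly increasing")
  if (!is.null(n_frames) && any(events > n_frames))
    stop("contact events fall outside the trial")
  structure(list(events = events, foot = foot), class = "foot_contacts")
}

#' @export
print.foot_contacts <- function(x, ...) {
  cat(sprintf("<foot_contacts> foot %s, %d initial contacts (frames %d..%d)\n",
              x$foot, length(x$events), min(x$events), max(x$events)))
  invisible(x)
}

parse_channel_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  ok <- length(parts) == 3 &&
    parts[1] %in% c("hip", "knee", "ankle") &&
    parts[2] %in% c("L", "R") &&
    parts[3] %in% c("sagittal", "frontal", "transverse")
  if (!ok)
    stop(sprintf(
      "unknown channel label '%s'; valid labels are <joint>_<side>_<plane> with joint in {hip,knee,ankle}, side in {L,R}, plane in {sagittal,frontal,transverse}",
      label))
  parts
}

#' Load a trial from a wide CSV file
#'
#' Reads a wide CSV with one row per frame: a time column (seconds) followed
#' by one column per joint-angle channel named `<joint>_<side>_<plane>`.
#' Channels are reordered into canonical order (hip-knee-ankle x L-R x
#' sagittal-frontal-transverse). The sampling rate is taken from `fs` if
#' given, otherwise inferred from the median time step.
#'
#' @param path path to the CSV file.
#' @param fs sampling rate in Hz; `NULL` to infer from the time column.
#' @param time_col name of the time column (first column by default).
#' @param trial_id,activity_label metadata; `trial_id` defaults to the file
#'   name without extension.
#' @return A [kin_trial()] object.
#' @export
load_trial <- function(path, fs = NULL, time_col = NULL,
                       trial_id = NULL, activity_label = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("trial CSV needs a time column plus >= 1 channel")
  time_col <- time_col %||% names(df)[1]
  if (!time_col %in% names(df))
    stop(sprintf("time column '%s' not found", time_col))
  tvec <- df[[time_col]]
  ang <- df[setdiff(names(df), time_col)]
  # locate any missing cell before touching labels so the error names it
  for (cn in names(ang)) {
    nas <- which(!is.finite(as.numeric(ang[[cn]])))
    if (length(nas) > 0)
      stop(sprintf("missing or non-numeric value in column '%s', row %d",
                   cn, nas[1]))
  }
  for (cn in names(ang)) parse_channel_label(cn)
  present <- intersect(canonical_channels(), names(ang))
  ang <- as.matrix(ang[present])
  if (is.null(fs)) {
    dt <- stats::median(diff(tvec))
    if (!is.finite(dt) || dt <= 0)
      stop("cannot infer sampling rate from the time column")
    fs <- 1 / dt
  }
  trial_id <- trial_id %||% sub("\\.[^.]*$", "", basename(path))
  kin_trial(ang, fs = fs, channels = present, trial_id = trial_id,
            activity_label = activity_label)
}

#' Write a trial to a wide CSV file
#'
#' Inverse of [load_trial()]: writes a time column (frame index / fs)
#' followed by the angle channels.
#'
#' @param trial a [kin_trial()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "kin_trial"))
  df <- data.frame(time = (seq_len(nrow(trial$samples)) - 1) / trial$fs,
                   check.names = FALSE)
  df[trial$channels] <- as.data.frame(trial$samples)
  # %.17g preserves doubles exactly through the text round trip
  out <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  utils::write.table(rbind(names(df), out), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read foot-contact events from a two-column CSV
#'
#' Expects columns `frame_index` (1-based) and `foot` (`L`/`R`).
#'
#' @param path path to the contacts CSV.
#' @param foot which foot's events to return.
#' @param n_frames optional trial length for validation.
#' @return A [foot_contacts()] object.
#' @export
load_contacts <- function(path, foot = c("L", "R"), n_frames = NULL) {
  foot <- match.arg(foot)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path)
  if (!all(c("frame_index", "foot") %in% names(df)))
    stop("contacts CSV needs columns 'frame_index' and 'foot'")
  ev <- df$frame_index[df$foot == foot]
  if (length(ev) == 0) stop(sprintf("no contacts for foot %s", foot))
  foot_contacts(sort(ev), foot = foot, n_frames = n_frames)
}

#' Write foot-contact events to CSV
#'
#' @param contacts a [foot_contacts()] object or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  if (inherits(contacts, "foot_contacts")) contacts <- list(contacts)
  df <- do.call(rbind, lapply(contacts, function(fc)
    data.frame(frame_index = fc$events, foot = fc$foot)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Segment a trial into gait cycles at initial contacts
#'
#' A stride runs from one initial contact to the next of the same foot,
#' half-open: cycle i spans frames `[event_i, event_{i+1})`. Cycles shorter
#' than `min_duration` seconds are dropped with a warning (spurious double
#' contacts).
#'
#' @param trial a [kin_trial()] object.
#' @param contacts a [foot_contacts()] object with >= 2 events.
#' @param min_duration minimum cycle duration in seconds; shorter cycles
#'   are dropped.
#' @return A list of numeric matrices (frames x channels), one per retained
#'   cycle, with attribute `"dropped"` giving indices of dropped cycles.
#' @export
segment_cycles <- function(trial, contacts, min_duration = 0.4) {
  stopifnot(inherits(trial, "kin_trial"), inherits(contacts, "foot_contacts"))
  ev <- contacts$events
  if (length(ev) < 2)
    stop("cannot segment: need at least 2 contact events")
  if (max(ev) > nrow(trial$samples))
    stop("contact events fall outside the trial")
  n_cyc <- length(ev) - 1
  min_frames <- ceiling(min_duration * trial$fs)
  cycles <- vector("list", n_cyc)
  keep <- logical(n_cyc)
  for (i in seq_len(n_cyc)) {
    idx <- ev[i]:(ev[i + 1] - 1)
    keep[i] <- length(idx) >= min_frames
    cycles[[i]] <- trial$samples[idx, , drop = FALSE]
  }
  if (any(!keep))
    warning(sprintf("dropped %d cycle(s) shorter than %.2g s",
                    sum(!keep), min_duration))
  out <- cycles[keep]
  attr(out, "dropped") <- which(!keep)
  attr(out, "trial_id") <- trial$trial_id
  out
}

#' Time-normalize gait cycles to a fixed phase grid
#'
#' Each cycle is linearly interpolated onto `T` equally spaced phase points
#' spanning 0-100% of the cycle, endpoints included, so the first and last
#' normalized samples equal the cycle's first and last frames exactly.
#'
#' @param cycles a list of frames x channels matrices, as returned by
#'   [segment_cycles()], each with >= 2 frames.
#' @param T number of phase points (101 by convention: 0-100% in 1% steps).
#' @param source_trial_ids optional character vector of originating trials.
#' @return A `cycle_set`: array N x T x p with channel dimnames.
#' @export
time_normalize <- function(cycles, T = 101, source_trial_ids = NULL) {
  if (length(cycles) < 1) stop("no cycles to normalize")
  p <- ncol(cycles[[1]])
  chans <- colnames(cycles[[1]])
  out <- array(NA_real_, dim = c(length(cycles), T, p))
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    nf <- nrow(cyc)
    if (nf < 2) stop(sprintf("cycle %d has fewer than 2 frames", i))
    grid <- seq(1, nf, length.out = T)
    for (k in seq_len(p))
      out[i, , k] <- approx(seq_len(nf), cyc[, k], xout = grid)$y
  }
  cycle_set(out, channels = chans,
            source_trial_ids = source_trial_ids %||%
              attr(cycles, "trial_id") %||% character(0))
}

#' Construct a set of time-normalized gait cycles
#'
#' @param cycles numeric array N x T x p (cycles x phase points x channels).
#' @param channels optional channel labels (length p).
#' @param source_trial_ids originating trial identifiers.
#' @return An object of class `cycle_set`.
#' @export
cycle_set <- function(cycles, channels = NULL, source_trial_ids = character(0)) {
  stopifnot(is.array(cycles), length(dim(cycles)) == 3)
  if (dim(cycles)[1] < 1) stop("need at least 1 cycle")
  if (anyNA(cycles)) stop("cycle tensor contains missing values")
  if (!is.null(channels)) {
    stopifnot(length(channels) == dim(cycles)[3])
    dimnames(cycles) <- list(NULL, NULL, channels)
  }
  structure(list(cycles = cycles,
                 source_trial_ids = as.character(source_trial_ids)),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  d <- dim(x$cycles)
  cat(sprintf("<cycle_set> %d cycles x %d phase points x %d channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Serialize a cycle set as a long CSV plus a JSON header
#'
#' Writes `<stem>.csv` in long format (cycle, phase, channel, value) and
#' `<stem>.json` with dimensions, channel labels and source trials, so the
#' tensor round-trips exactly through [read_cycle_set()].
#'
#' @param cs a [cycle_set()].
#' @param stem output path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_cycle_set <- function(cs, stem) {
  stopifnot(inherits(cs, "cycle_set"))
  d <- dim(cs$cycles)
  long <- data.frame(
    cycle = rep(seq_len(d[1]), times = d[2] * d[3]),
    phase = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    channel = rep(dimnames(cs$cycles)[[3]] %||% paste0("ch", seq_len(d[3])),
                  each = d[1] * d[2]),
    value = as.vector(cs$cycles))
  write.csv(long, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_cycles = d[1], n_phase = d[2], n_channels = d[3],
         channels = dimnames(cs$cycles)[[3]],
         source_trial_ids = cs$source_trial_ids),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a cycle set written by [write_cycle_set()]
#'
#' @param stem path stem used when writing.
#' @return A [cycle_set()].
#' @export
read_cycle_set <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  long <- read.csv(paste0(stem, ".csv"))
  arr <- array(long$value,
               dim = c(meta$n_cycles, meta$n_phase, meta$n_channels))
  cycle_set(arr, channels = meta$channels,
            source_trial_ids = meta$source_trial_ids)
}
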