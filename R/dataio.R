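# Session containers, validation, and plain-CSV persistence.
#
# All times are session-relative seconds; intervals are half-open
# [t_start, t_end) so a spike at a trial boundary is counted once.
# Positions are centimeters (an optional pixels_per_cm converts raw pixel
# tracks at read time).

#' Position track
#'
#' Uniformly sampled 2-D trajectory. `dt` is the sampling period in seconds
#' (0.0256 s for the tracking system the analysis was designed around).
#'
#' @param timestamps numeric, strictly increasing, uniform step `dt`.
#' @param x,y coordinates in centimeters.
#' @param dt sampling period in seconds.
#' @return an object of class `position_track`.
#' @export
position_track <- function(timestamps, x, y, dt = 0.0256) {
  n <- length(timestamps)
  if (length(x) != n || length(y) != n)
    stop("timestamps, x and y must have equal length")
  if (n < 6)
    stop("position track needs at least 6 samples")
  if (any(!is.finite(timestamps)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("position track contains non-finite values")
  steps <- diff(timestamps)
  if (max(abs(steps - dt)) > 1e-6)
    stop("timestamps are not uniform at dt within 1e-6 s")
  structure(list(timestamps = timestamps, x = x, y = y, dt = dt),
            class = "position_track")
}

#' Spike train
#'
#' @param unit_id identifier (coerced to character).
#' @param spike_times sorted spike times in seconds.
#' @param cell_type one of `"MSN"`, `"FSI"`, `"UNKNOWN"`.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, cell_type = "UNKNOWN") {
  cell_type <- match.arg(cell_type, c("MSN", "FSI", "UNKNOWN"))
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times))
    stop("spike_times must be sorted ascending")
  if (length(spike_times) && spike_times[1] < 0)
    stop("spike_times must be non-negative")
  structure(list(unit_id = as.character(unit_id),
                 spike_times = spike_times,
                 cell_type = cell_type),
            class = "spike_train")
}

#' Trial table
#'
#' Validates and normalizes a per-trial data.frame with columns `trial_id`,
#' `t_start`, `t_end`, `cue` (visual/spatial), `choice` (left/right),
#' `outcome` (rewarded/non_rewarded) and optionally `block`.
#'
#' @param df data.frame of trials.
#' @return the validated data.frame with class `trial_table`.
#' @export
trial_table <- function(df) {
  req <- c("trial_id", "t_start", "t_end", "cue", "choice", "outcome")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  if (!"block" %in% names(df)) df$block <- NA_integer_
  df <- df[order(df$t_start), , drop = FALSE]
  rownames(df) <- NULL
  bad <- df$t_end <= df$t_start
  if (any(bad))
    stop("trial ", df$trial_id[which(bad)[1]], " has t_end <= t_start")
  if (nrow(df) > 1 && any(df$t_start[-1] < df$t_end[-nrow(df)] - 1e-9))
    stop("trial intervals overlap")
  for (col in c("cue", "choice", "outcome"))
    if (any(is.na(df[[col]])))
      stop("trial table has missing values in column ", col)
  lv <- list(cue = c("visual", "spatial"), choice = c("left", "right"),
             outcome = c("rewarded", "non_rewarded"))
  for (col in names(lv)) {
    if (!all(df[[col]] %in% lv[[col]]))
      stop("invalid level in trial column ", col)
    df[[col]] <- as.character(df[[col]])
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Session bundle
#'
#' @param position a [position_track()].
#' @param units list of [spike_train()] objects.
#' @param trials a [trial_table()].
#' @param session_id identifier.
#' @return an object of class `session_bundle`.
#' @export
session_bundle <- function(position, units, trials, session_id = "session") {
  stopifnot(inherits(position, "position_track"),
            inherits(trials, "trial_table"))
  t0 <- position$timestamps[1]
  t1 <- position$timestamps[length(position$timestamps)]
  if (any(trials$t_start < t0 - 1e-9) || any(trials$t_end > t1 + 1e-9))
    stop("trial bounds fall outside the position timestamp range")
  for (u in units) {
    stopifnot(inherits(u, "spike_train"))
    if (length(u$spike_times) &&
        (u$spike_times[1] < t0 - 1e-9 ||
         u$spike_times[length(u$spike_times)] > t1 + 1e-9))
      stop("unit ", u$unit_id, " has spikes outside the position time range")
  }
  structure(list(position = position, units = units, trials = trials,
                 session_id = as.character(session_id)),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  tr <- range(x$position$timestamps)
  cat("session_bundle '", x$session_id, "': ",
      length(x$units), " units, ", nrow(x$trials), " trials, ",
      sprintf("%.1f", diff(tr)), " s of tracking\n", sep = "")
  invisible(x)
}

#' Read a session from a directory of CSV tables
#'
#' Expects `position.csv` (time,x,y), `spikes.csv` (unit_id,time,cell_type)
#' and `trials.csv` (trial_id,t_start,t_end,cue,choice,outcome\[,block\]).
#'
#' @param path directory containing the three tables.
#' @param dt position sampling period in seconds.
#' @param pixels_per_cm if the raw track is in pixels, the calibration used
#'   to convert it to centimeters at read time; `NULL` means the track is
#'   already in cm.
#' @param session_id identifier; defaults to the directory name.
#' @return a [session_bundle()].
#' @export
read_session <- function(path, dt = 0.0256, pixels_per_cm = NULL,
                         session_id = basename(path)) {
  f <- function(name) file.path(path, name)
  if (!file.exists(f("position.csv")))
    stop("missing position.csv in ", path)
  pos <- read.csv(f("position.csv"))
  for (col in c("time", "x", "y"))
    if (!col %in% names(pos))
      stop("position table missing column \"", col, "\"")
  if (!is.null(pixels_per_cm)) {
    pos$x <- pos$x / pixels_per_cm
    pos$y <- pos$y / pixels_per_cm
  }
  track <- position_track(pos$time, pos$x, pos$y, dt = dt)

  spk <- read.csv(f("spikes.csv"))
  for (col in c("unit_id", "time", "cell_type"))
    if (!col %in% names(spk))
      stop("spike table missing column \"", col, "\"")
  units <- lapply(split(spk, spk$unit_id), function(d) {
    spike_train(d$unit_id[1], sort(d$time), as.character(d$cell_type[1]))
  })
  units <- unname(units)

  trials <- trial_table(read.csv(f("trials.csv")))
  bundle <- session_bundle(track, units, trials, session_id = session_id)
  message("read session '", session_id, "': ", length(units), " units, ",
          nrow(trials), " trials")
  bundle
}

#' Write a session to a directory of CSV tables
#'
#' Inverse of [read_session()]; numeric fields round-trip to full double
#' precision.
#'
#' @param bundle a [session_bundle()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- bundle$position
  write_table(data.frame(time = p$timestamps, x = p$x, y = p$y),
              file.path(path, "position.csv"))
  spk <- do.call(rbind, lapply(bundle$units, function(u) {
    if (!length(u$spike_times)) return(NULL)
    data.frame(unit_id = u$unit_id, time = u$spike_times,
               cell_type = u$cell_type)
  }))
  if (is.null(spk))
    spk <- data.frame(unit_id = character(), time = numeric(),
                      cell_type = character())
  write_table(spk, file.path(path, "spikes.csv"))
  tr <- as.data.frame(bundle$trials)
  write_table(tr, file.path(path, "trials.csv"))
  invisible(path)
}

# Full-precision CSV writer used for every on-disk table.
write_table <- function(df, file) {
  df <- as.data.frame(df)
  for (col in names(df))
    if (is.numeric(df[[col]]))
      df[[col]] <- sprintf("%.17g", df[[col]])
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write result tables
#'
#' Writes each element of a named list of data.frames as `<name>.csv` under
#' `path`. NaN/NA numeric fields are preserved through the round trip.
#'
#' @param results named list of data.frames.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results))
    write_table(results[[nm]], file.path(path, paste0(nm, ".csv")))
  invisible(path)
}

#' Read back result tables written by [write_results()]
#'
#' @param path directory of CSV tables.
#' @return named list of data.frames.
#' @export
read_results <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, read.csv)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `speed.bin_s=1.0`; `#` starts a comment. Values that
#' parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
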