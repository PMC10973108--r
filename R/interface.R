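detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a behavioral gaze table
#'
#' Reads delimited text (tab-separated canonically; comma accepted) with a
#' header. Required columns: `participant`, `condition`, `trial`, a time
#' axis (`step`, or `time_ms` which is normalized into steps using the
#' timeline's event durations by proportional binning), and either an `aoi`
#' column or pixel coordinates `x`, `y` (mapped to zones through the
#' layout; points outside the face AOIs or off screen become `"away"`).
#'
#' @param path Path to the file.
#' @param layout An [aoi_layout()]; required when only `x`/`y` are present.
#' @param timeline A [trial_timeline()]; used to normalize `time_ms`.
#' @return Data frame of validated gaze records with columns `participant`,
#'   `group` (if present), `condition`, `trial`, `step`, `aoi`.
#' @export
read_gaze_table <- function(path, layout = NULL,
                            timeline = trial_timeline()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, sep = detect_sep(path), stringsAsFactors = FALSE,
                   check.names = TRUE)
  need <- c("participant", "condition", "trial")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gaze table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  has_step <- "step" %in% names(df)
  if (!has_step && !("time_ms" %in% names(df)))
    stop("gaze table needs a 'step' or 'time_ms' column", call. = FALSE)
  if (!("aoi" %in% names(df)) && "zone" %in% names(df))
    df$aoi <- df$zone   # simulated-trajectory dialect
  if (!("aoi" %in% names(df)) && !all(c("x", "y") %in% names(df)))
    stop("gaze table needs an 'aoi' column or 'x' and 'y' columns",
         call. = FALSE)
  bad_cond <- setdiff(unique(df$condition), c("ER", "LP"))
  if (length(bad_cond) > 0) {
    lines <- which(df$condition %in% bad_cond)[1] + 1L
    stop("unknown condition label '", bad_cond[1], "' (first at line ",
         lines, ")", call. = FALSE)
  }
  if (!has_step) {
    df$step <- normalize_time(df$time_ms, timeline)
  } else {
    key <- paste(df$participant, df$condition, df$trial, df$step, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) > 0)
      stop("duplicate (participant, condition, trial, step) record at line ",
           dup[1] + 1L, call. = FALSE)
  }
  if (!("aoi" %in% names(df))) {
    if (is.null(layout))
      stop("a layout is required to map x/y coordinates to zones",
           call. = FALSE)
    z <- zone_at(layout, df$x, df$y)
    df$aoi <- ifelse(z == "Other", "away", z)
  } else {
    bad <- setdiff(unique(df$aoi), c(ZONES, "away"))
    if (length(bad) > 0) {
      line <- which(df$aoi %in% bad)[1] + 1L
      stop("unknown aoi label '", bad[1], "' at line ", line, call. = FALSE)
    }
    if (all(c("x", "y") %in% names(df)) && !is.null(layout)) {
      z <- zone_at(layout, df$x, df$y)
      mapped <- ifelse(z == "Other", "away", z)
      clash <- which(df$aoi != mapped & df$aoi != "away")
      if (length(clash) > 0)
        stop("aoi label disagrees with x/y under the layout at line ",
             clash[1] + 1L, call. = FALSE)
    }
  }
  keep <- intersect(c("participant", "group", "condition", "trial", "step",
                      "aoi", "x", "y"), names(df))
  df[, keep, drop = FALSE]
}

#' Normalize millisecond timestamps into percentage steps
#'
#' Proportional binning of within-trial timestamps into the timeline's
#' normalized steps: times inside the speech event map to steps
#' `0..n_speech_steps - 1` in proportion to the speech duration, later
#' times to the non-speech steps in proportion to the non-speech duration
#' (clamped to the last step).
#'
#' @param time_ms Numeric timestamps from trial onset, in ms.
#' @param timeline A [trial_timeline()] carrying the event durations.
#' @return Integer step indices (0-based).
#' @export
normalize_time <- function(time_ms, timeline) {
  stopifnot(is.numeric(time_ms), all(time_ms >= 0, na.rm = TRUE))
  sp <- timeline$speech_duration_ms
  np <- timeline$nonspeech_duration_ms
  in_speech <- time_ms < sp
  step <- integer(length(time_ms))
  step[in_speech] <-
    pmin(floor(time_ms[in_speech] / sp * timeline$n_speech_steps),
         timeline$n_speech_steps - 1L)
  step[!in_speech] <- timeline$t_ER +
    pmin(floor((time_ms[!in_speech] - sp) / np * timeline$n_nonspeech_steps),
         timeline$n_nonspeech_steps - 1L)
  as.integer(step)
}

#' Write a gaze table as tab-separated text
#'
#' @param records Gaze record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write an AOI layout as JSON
#'
#' JSON keys: `image_size`, `eyes`, `mouth`, `face` (rectangles
#' `[x0, y0, x1, y1]`, 0-based, half-open).
#'
#' @param path File path.
#' @return `read_aoi_layout`: an [aoi_layout()].
#' @export
read_aoi_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("image_size", "eyes", "mouth", "face")
  miss <- setdiff(need, names(j))
  if (length(miss) > 0)
    stop("layout JSON is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  aoi_layout(j$image_size, j$eyes, j$mouth, j$face)
}

#' @rdname read_aoi_layout
#' @param layout An [aoi_layout()] to write.
#' @export
write_aoi_layout <- function(layout, path) {
  jsonlite::write_json(list(image_size = layout$image_size,
                            eyes = layout$eyes, mouth = layout$mouth,
                            face = layout$face),
                       path, digits = NA)
  invisible(path)
}

#' Read or write a per-zone saliency stream as tab-separated text
#'
#' Columns: `step`, `static_eyes` .. `static_other`,
#' `dyn_eyes` .. `dyn_other`.
#'
#' @param path File path.
#' @return `read_saliency_stream`: an `aoi_saliency_stream`.
#' @export
read_saliency_stream <- function(path) {
  df <- read.delim(path, sep = detect_sep(path))
  scol <- paste0("static_", tolower(ZONES))
  dcol <- paste0("dyn_", tolower(ZONES))
  miss <- setdiff(c("step", scol, dcol), names(df))
  if (length(miss) > 0)
    stop("stream file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$step), , drop = FALSE]
  aoi_saliency_stream(as.matrix(df[, scol]), as.matrix(df[, dcol]))
}

#' @rdname read_saliency_stream
#' @param stream An `aoi_saliency_stream` to write.
#' @export
write_saliency_stream <- function(stream, path) {
  df <- data.frame(step = 0:(stream$n_steps - 1L), stream$static,
                   stream$dynamic)
  names(df) <- c("step", paste0("static_", tolower(ZONES)),
                 paste0("dyn_", tolower(ZONES)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a parameter grid as JSON
#'
#' JSON keys: `beta`, `gamma`, `theta` (lists of values).
#'
#' @param path File path.
#' @return `read_parameter_grid`: a [parameter_grid()].
#' @export
read_parameter_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(c("beta", "gamma", "theta"), names(j))
  if (length(miss) > 0)
    stop("grid JSON is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  parameter_grid(j$beta, j$gamma, j$theta)
}

#' @rdname read_parameter_grid
#' @param grid A [parameter_grid()] to write.
#' @export
write_parameter_grid <- function(grid, path) {
  jsonlite::write_json(list(beta = grid$beta, gamma = grid$gamma,
                            theta = grid$theta), path, digits = NA)
  invisible(path)
}

#' Write frames as PNG files
#'
#' @param frames List of gray matrices in \[0, 1\].
#' @param dir Output directory (created if needed); files are named
#'   `frame_0001.png`, ...
#' @return Character vector of file paths, invisibly.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    png::writePNG(pmin(pmax(frames[[i]], 0), 1), paths[i])
  }
  invisible(paths)
}

#' Read a directory of PNG/PGM frames as gray matrices
#'
#' @param dir Directory containing `*.png` frames (sorted by name).
#' @return List of gray matrices.
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no PNG frames found in ", dir, call. = FALSE)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
}

#' Write a run manifest
#'
#' Records, next to a run's outputs, the subcommand, the parameters and
#' seeds used, and the package version, so runs can be reproduced.
#'
#' @param path Output JSON path.
#' @param ... Named fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package <- "gazesim"
  fields$version <- as.character(utils::packageVersion("gazesim"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
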