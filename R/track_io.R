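#' Read 3D cell tracks from a delimited text file
#'
#' Reads position exports in the shape produced by common cell-tracking
#' software: one row per (track, time point) with columns `track_id`, `t`,
#' `x`, `y`, `z` (matched case-insensitively by header name). Units are
#' assumed to be minutes and micrometres. Rows are returned sorted by
#' `(track_id, t)` and validated: time must be strictly increasing within a
#' track and the sampling interval constant to within 1%.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A `track_table`: a data frame with columns `track_id` (character),
#'   `t`, `x`, `y`, `z` (numeric).
#' @export
read_tracks <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  required <- c("track_id", "t", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  as_track_table(df[required])
}

#' Construct / validate a track table
#'
#' @param df Data frame with columns `track_id`, `t` (min), `x`, `y`, `z`
#'   (um).
#' @return The validated, `(track_id, t)`-sorted `track_table`.
#' @export
as_track_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("track_id", "t", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  df$track_id <- as.character(df$track_id)
  for (col in c("t", "x", "y", "z")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]) || !all(is.finite(df[[col]])))
      stop("non-finite values in column `", col, "`")
  }
  df <- df[order(df$track_id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$track_id)) {
    tt <- df$t[df$track_id == id]
    if (anyDuplicated(tt))
      stop("duplicated time points in track `", id, "`")
    if (length(tt) > 1L) {
      dts <- diff(tt)
      if (any(dts <= 0))
        stop("non-monotone time within track `", id, "`")
      if (max(dts) - min(dts) > 0.01 * stats::median(dts))
        stop("non-constant sampling interval in track `", id,
             "` (beyond 1% tolerance)")
    }
  }
  class(df) <- c("track_table", "data.frame")
  df
}

#' Write a track table to CSV
#'
#' @param tracks A `track_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(is.data.frame(tracks))
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Drop tracks of insufficient duration
#'
#' Removes tracks whose duration (last minus first time point) is below
#' `min_duration`; tracks lasting exactly `min_duration` are kept. Records
#' of surviving tracks are untouched. The 10-min default is the standard
#' track-quality filter applied before any motility quantification.
#'
#' @param tracks A `track_table`.
#' @param min_duration Minimum track duration to keep (minutes).
#' @return The filtered `track_table`.
#' @export
filter_tracks <- function(tracks, min_duration = 10) {
  stopifnot(is.data.frame(tracks), min_duration >= 0)
  if (nrow(tracks) == 0L) return(tracks)
  dur <- tapply(tracks$t, tracks$track_id, function(tt) max(tt) - min(tt))
  keep <- names(dur)[dur >= min_duration]
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

split_tracks <- function(tracks) {
  split(tracks[c("t", "x", "y", "z")], tracks$track_id)
}

#' Write recorded frames to a delimited file
#'
#' Writes a long-format `(t, x, y)` table. Floats are formatted at 6
#' significant digits so the file is bit-stable for a given input.
#'
#' @param frames A `frame_table` (data frame with columns `t`, `x`, `y`) as
#'   returned by [run_simulation()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_frames <- function(frames, path) {
  stopifnot(is.data.frame(frames),
            all(c("t", "x", "y") %in% names(frames)))
  if (!all(frames$t == sort(frames$t)))
    stop("frames must be time-sorted")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,x,y", con)
  if (nrow(frames) > 0L) {
    fmt <- function(v) formatC(v, format = "g", digits = 6)
    writeLines(paste(fmt(frames$t), fmt(frames$x), fmt(frames$y), sep = ","),
               con)
  }
  invisible(path)
}

#' Read frames written by [write_frames()]
#'
#' @param path Path to a frames CSV.
#' @return A `frame_table` data frame with columns `t`, `x`, `y`.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  missing <- setdiff(c("t", "x", "y"), names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[order(df$t), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("frame_table", "data.frame")
  df
}

#' Extract one frame from a frame table
#'
#' @param frames A `frame_table`.
#' @param t Frame time (minutes); must match a recorded time exactly.
#' @return Data frame with columns `x`, `y` for that time point.
#' @export
frame_at <- function(frames, t) {
  sel <- frames$t == t
  if (!any(sel)) stop("no frame recorded at t = ", t)
  out <- as.data.frame(frames[sel, c("x", "y"), drop = FALSE])
  rownames(out) <- NULL
  out
}
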