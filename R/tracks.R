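TRACK_COLUMNS <- c("cell_id", "channel", "track_id", "frame",
                   "x_um", "y_um", "intensity")

#' Construct a track set
#'
#' A `track_set` holds per-localization rows for one or more cells and
#' channels, together with acquisition metadata. One row is one
#' localization: `cell_id, channel, track_id, frame, x_um, y_um,
#' intensity`. Frames are 0-based; positions are in micrometres.
#'
#' @param tracks data.frame with the columns above.
#' @param dt frame interval (s).
#' @param pixel_size pixel size (um), metadata only.
#' @param n_frames movie length (frames).
#' @return an object of class `track_set`.
#' @export
track_set <- function(tracks, dt, pixel_size = 0.067, n_frames = NULL) {
  tracks <- as.data.frame(tracks)
  missing <- setdiff(TRACK_COLUMNS, names(tracks))
  if (length(missing))
    stop("track table is missing column(s): ", paste(missing, collapse = ", "))
  tracks <- tracks[TRACK_COLUMNS]
  if (dt <= 0) stop("dt must be > 0")
  if (nrow(tracks)) {
    bad <- which(!is.finite(tracks$x_um) | !is.finite(tracks$y_um))
    if (length(bad))
      stop("non-finite coordinate at row ", bad[1])
    if (any(tracks$channel != 1 & tracks$channel != 2))
      stop("channel must be 1 or 2")
    o <- order(tracks$cell_id, tracks$channel, tracks$track_id, tracks$frame)
    tracks <- tracks[o, , drop = FALSE]
    rownames(tracks) <- NULL
    key <- paste(tracks$cell_id, tracks$channel, tracks$track_id)
    dup <- duplicated(cbind(key, tracks$frame))
    if (any(dup))
      stop("duplicate (track, frame) at row ", which(dup)[1])
    if (any(tracks$frame < 0)) stop("frames must be >= 0")
  }
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 0L
  structure(list(tracks = tracks,
                 metadata = list(dt = dt, pixel_size = pixel_size,
                                 n_frames = as.integer(n_frames))),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  tr <- x$tracks
  nt <- if (nrow(tr)) nrow(unique(tr[c("cell_id", "channel", "track_id")])) else 0L
  cat(sprintf("track_set: %d localizations, %d tracks, %d cell(s), dt = %g s\n",
              nrow(tr), nt, length(unique(tr$cell_id)), x$metadata$dt))
  invisible(x)
}

#' Read tracks from the package CSV dialect
#'
#' The dialect has a mandatory header `cell_id, channel, track_id,
#' frame, x_um, y_um, intensity`, 0-based frames and positions in um.
#' Rows are validated (finite coordinates, no duplicate frames, frames
#' strictly increasing per track after sorting) and returned sorted by
#' (cell, channel, track, frame).
#'
#' @param path CSV file path.
#' @param dt frame interval (s).
#' @param pixel_size pixel size (um).
#' @return a `track_set`.
#' @export
read_tracks <- function(path, dt, pixel_size = 0.067) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing))
    stop("track CSV is missing column(s): ", paste(missing, collapse = ", "))
  track_set(df, dt = dt, pixel_size = pixel_size)
}

#' Write tracks in canonical CSV form
#'
#' Output is deterministic: rows sorted by (cell, channel, track,
#' frame), positions printed with 6 decimals (sub-nm), intensities with
#' 4. `write_tracks(read_tracks(f))` reproduces a canonicalized `f`
#' byte for byte.
#'
#' @param ts a `track_set`.
#' @param path output path.
#' @export
write_tracks <- function(ts, path) {
  tr <- ts$tracks
  lines <- c(paste(TRACK_COLUMNS, collapse = ","),
             if (nrow(tr))
               sprintf("%s,%d,%s,%d,%.6f,%.6f,%.4f",
                       tr$cell_id, as.integer(tr$channel),
                       as.character(tr$track_id), as.integer(tr$frame),
                       tr$x_um, tr$y_um, tr$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Split a track set into per-track matrices
#'
#' @param ts a `track_set`.
#' @param channel optional channel filter.
#' @param min_frames drop tracks shorter than this many frames.
#' @return list of data.frames, one per track, named
#'   `cell_id|channel|track_id`; attribute `n_dropped` counts excluded
#'   short tracks.
#' @keywords internal
split_tracks <- function(ts, channel = NULL, min_frames = 1L) {
  tr <- ts$tracks
  if (!is.null(channel)) tr <- tr[tr$channel %in% channel, , drop = FALSE]
  if (!nrow(tr)) {
    out <- list(); attr(out, "n_dropped") <- 0L; return(out)
  }
  key <- paste(tr$cell_id, tr$channel, tr$track_id, sep = "|")
  parts <- split(tr, factor(key, levels = unique(key)))
  lens <- vapply(parts, nrow, integer(1))
  out <- parts[lens >= min_frames]
  attr(out, "n_dropped") <- sum(lens < min_frames)
  out
}
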