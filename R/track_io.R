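#' Construct a comet track
#'
#' A comet track is one EB1 comet's time-ordered 2-D trajectory in
#' micrometres, together with its provenance and a flag for the
#' first-frame exclusion rule (comets already present in the first frame of a
#' movie may be pre-existing microtubules rather than new growth events and
#' are excluded from analysis).
#'
#' @param comet_id Identifier of the comet within its movie.
#' @param movie_id Identifier of the source movie.
#' @param t Numeric vector of time points in seconds, strictly increasing,
#'   with consecutive gaps equal to the movie frame interval.
#' @param x,y Numeric vectors of positions in micrometres.
#' @param present_at_first_frame Logical; was the comet present in the
#'   movie's first frame?
#' @param frame_interval Frame interval in seconds used to validate `t`.
#' @return An object of class `comet_track`.
#' @export
comet_track <- function(comet_id, movie_id, t, x, y,
                        present_at_first_frame = FALSE,
                        frame_interval = NULL) {
  if (length(t) < 2) {
    stop("comet track '", comet_id, "' must have at least 2 points")
  }
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("t, x, y must have equal length")
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("comet track '", comet_id, "' has non-finite coordinates")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("comet track '", comet_id, "' has non-increasing time points")
  }
  if (is.null(frame_interval)) frame_interval <- dt[1]
  if (any(abs(dt - frame_interval) > 1e-6)) {
    bad <- which(abs(dt - frame_interval) > 1e-6)[1]
    stop("comet track '", comet_id, "' has a time gap between points ",
         bad, " and ", bad + 1, " (", dt[bad], " s, expected ",
         frame_interval, " s); gaps are an error, not spanned")
  }
  structure(
    list(comet_id = as.character(comet_id),
         movie_id = as.character(movie_id),
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         present_at_first_frame = isTRUE(present_at_first_frame)),
    class = "comet_track")
}

#' @export
print.comet_track <- function(x, ...) {
  cat("<comet_track> ", x$movie_id, "/", x$comet_id, ": ",
      length(x$t), " points, t = ", x$t[1], "..", x$t[length(x$t)], " s",
      if (x$present_at_first_frame) " [present at first frame]" else "",
      "\n", sep = "")
  invisible(x)
}

.track_points <- function(track) cbind(track$x, track$y)

.dialect_columns <- list(
  native          = c(comet_id = "comet_id", movie_id = "movie_id",
                      frame = "frame", x = "x_px", y = "y_px"),
  manual_tracking = c(comet_id = "Track n°", frame = "Slice n°",
                      x = "X", y = "Y"),
  trackmate       = c(comet_id = "TRACK_ID", frame = "FRAME",
                      x = "POSITION_X", y = "POSITION_Y")
)

.dialect_min_frame <- c(native = 0L, manual_tracking = 1L, trackmate = 0L)

.match_column <- function(df_names, wanted) {
  # read.csv mangles ImageJ's "Track n°" into e.g. "Track.n."
  canon <- function(s) tolower(gsub("[^a-z0-9]", "", tolower(s)))
  hit <- which(canon(df_names) == canon(wanted))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Read comet track tables
#'
#' Reads a delimited track table (comma- or tab-separated, with header) in
#' one of three dialects, converts pixel coordinates to micrometres, and
#' returns validated [comet_track()] objects sorted by movie and comet id.
#'
#' Dialects: `"native"` expects columns `comet_id, movie_id, frame, x_px,
#' y_px`; `"manual_tracking"` maps the ImageJ Manual Tracking columns
#' (`Track n°`, `Slice n°`, `X`, `Y`); `"trackmate"` maps `TRACK_ID`,
#' `FRAME`, `POSITION_X`, `POSITION_Y`. A comet is flagged as present at the
#' first frame when its first row carries the dialect's minimum frame index
#' (0 for native/trackmate, 1 for Manual Tracking slices). Any `z` column is
#' ignored with a warning (tracking is single Z-plane).
#'
#' @param path Path to the track table.
#' @param dialect One of `"native"`, `"manual_tracking"`, `"trackmate"`.
#' @param frame_interval Frame interval in seconds (default 5, the EB1
#'   acquisition interval).
#' @param pixel_size Pixel size in micrometres per pixel; positions are
#'   multiplied by this factor.
#' @return List of `comet_track` objects.
#' @export
read_tracks <- function(path, dialect = c("native", "manual_tracking", "trackmate"),
                        frame_interval = 5, pixel_size = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path)
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = TRUE, stringsAsFactors = FALSE)
  cols <- .dialect_columns[[dialect]]
  idx <- vapply(cols, function(w) .match_column(names(df), w), integer(1))
  missing_cols <- cols[is.na(idx)]
  # movie_id is optional outside the native dialect
  required <- setdiff(names(missing_cols), if (dialect == "native") character() else "movie_id")
  if (length(required) > 0) {
    stop("track file ", path, " is missing required ", dialect,
         " column(s): ", paste(cols[required], collapse = ", "))
  }
  zcol <- .match_column(names(df), "z_px")
  if (is.na(zcol)) zcol <- .match_column(names(df), "POSITION_Z")
  if (is.na(zcol)) zcol <- .match_column(names(df), "Z")
  if (!is.na(zcol)) {
    warning("ignoring z column '", names(df)[zcol],
            "': tracks are treated as single Z-plane")
  }
  out <- data.frame(
    comet_id = as.character(df[[idx[["comet_id"]]]]),
    movie_id = if (!is.na(idx["movie_id"]) && "movie_id" %in% names(idx)) {
      as.character(df[[idx[["movie_id"]]]])
    } else {
      rep(tools::file_path_sans_ext(basename(path)), nrow(df))
    },
    frame = as.integer(df[[idx[["frame"]]]]),
    x = as.numeric(df[[idx[["x"]]]]) * pixel_size,
    y = as.numeric(df[[idx[["y"]]]]) * pixel_size,
    row = seq_len(nrow(df)),
    stringsAsFactors = FALSE)

  key <- paste(out$movie_id, out$comet_id, out$frame, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out$row[duplicated(key)]
    stop("duplicate (track, frame) rows in ", path, " at row(s): ",
         paste(head(dup, 10), collapse = ", "))
  }
  min_frame <- .dialect_min_frame[[dialect]]
  groups <- split(out, paste(out$movie_id, out$comet_id, sep = "\r"))
  # deterministic order: sorted by movie_id then comet_id
  ord <- order(vapply(groups, function(g) g$movie_id[1], character(1)),
               vapply(groups, function(g) g$comet_id[1], character(1)))
  tracks <- lapply(groups[ord], function(g) {
    g <- g[order(g$frame), ]
    df_frames <- diff(g$frame)
    if (any(df_frames == 0)) stop("internal: duplicate frames survived check")
    if (any(df_frames != 1)) {
      gap <- which(df_frames != 1)[1]
      stop("track ", g$comet_id[1], " in movie ", g$movie_id[1],
           " has a frame gap between frames ", g$frame[gap], " and ",
           g$frame[gap + 1], " (rows ", g$row[gap], ", ", g$row[gap + 1], ")")
    }
    comet_track(
      comet_id = g$comet_id[1], movie_id = g$movie_id[1],
      t = (g$frame - min_frame) * frame_interval, x = g$x, y = g$y,
      present_at_first_frame = g$frame[1] == min_frame,
      frame_interval = frame_interval)
  })
  names(tracks) <- NULL
  tracks
}

#' Write comet tracks in the native dialect
#'
#' Inverse of [read_tracks()] for the native dialect: positions are divided
#' by `pixel_size` back into pixel units and times by `frame_interval` back
#' into frame indices.
#'
#' @param tracks List of `comet_track` objects.
#' @param path Output path.
#' @param pixel_size,frame_interval Units used to serialise (defaults 1 and
#'   the tracks' own interval).
#' @export
write_tracks <- function(tracks, path, pixel_size = 1, frame_interval = NULL) {
  stopifnot(pixel_size > 0)
  rows <- lapply(tracks, function(tr) {
    fi <- if (is.null(frame_interval)) {
      if (length(tr$t) > 1) diff(tr$t)[1] else 1
    } else frame_interval
    data.frame(comet_id = tr$comet_id, movie_id = tr$movie_id,
               frame = as.integer(round(tr$t / fi)),
               x_px = tr$x / pixel_size, y_px = tr$y / pixel_size,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude comets present at the first movie frame
#'
#' Comets already visible in a movie's first frame may be pre-existing
#' microtubules rather than newly initiated growth events, so they are
#' excluded from all downstream analysis.
#'
#' @param tracks List of `comet_track` objects.
#' @return The tracks with `present_at_first_frame` comets removed. The
#'   number removed is reported via `message()`; if nothing survives a
#'   warning is raised.
#' @export
filter_first_frame <- function(tracks) {
  keep <- !vapply(tracks, function(tr) tr$present_at_first_frame, logical(1))
  removed <- sum(!keep)
  if (removed > 0) {
    message("filter_first_frame: excluded ", removed,
            " comet(s) present at the first frame")
  }
  out <- tracks[keep]
  if (length(tracks) > 0 && length(out) == 0) {
    warning("all tracks were present at the first frame; nothing remains")
  }
  out
}
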