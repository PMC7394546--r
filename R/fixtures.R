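# Deterministic fixture-track builders: piecewise-linear tracks constructed
# (not sampled) so that classification reproduces a requested event table
# exactly. Used to rebuild published percentages from their k/n counts.

#' Canonical fixture geometry
#'
#' A circular soma of the given radius with the axon entering at the top and
#' one dendrite at the bottom (with a branchpoint marker 3.5 um out), in
#' math convention. No nucleus, so fixture paths are unobstructed.
#'
#' @param radius Soma radius in micrometres (default 6).
#' @param n_vertices Polygon resolution (default 64).
#' @return A `neuron_geometry`.
#' @export
fixture_geometry <- function(radius = 6, n_vertices = 64) {
  angs <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  soma <- cbind(radius * cos(angs), radius * sin(angs))
  neuron_geometry(
    soma = soma,
    axon_entry = c(0, radius),
    dendrite_entries = list(dendrite1 = c(0, -radius)),
    dendrite_branchpoints = list(dendrite1 = c(0, -radius - 3.5)),
    frame_interval = 5, y_axis = "math")
}

# straight fixture path along the inward->outward axis of a neurite entry,
# from `from` to `to` micrometres relative to the entry point (positive =
# outward), sampled every 0.5 um
.gate_line_track <- function(geometry, neurite, from, to, comet_id,
                             frame_interval = 5) {
  entry <- if (identical(neurite, "axon")) geometry$axon_entry else
    geometry$dendrite_entries[[neurite]]
  outward <- .outward_normal(geometry$soma, entry)
  s <- seq(from, to, by = 0.5)
  pts <- t(vapply(s, function(si) entry + outward * si, numeric(2)))
  comet_track(comet_id = comet_id, movie_id = "fixture",
              t = seq_along(s) * frame_interval,
              x = pts[, 1], y = pts[, 2],
              present_at_first_frame = FALSE,
              frame_interval = frame_interval)
}

#' Build fixture tracks with exact approach/entry counts
#'
#' Emits exactly `n_total` soma-origin tracks such that
#' [classify_approach_entry()] yields the requested per-neurite approach and
#' entry counts: entering tracks run straight through the entry zone to
#' 1.25 um beyond it, approach-only tracks stop on the inner gate, and the
#' remainder are short tracks in the soma centre that touch no zone. Track
#' shapes are deterministic (no randomness), so derived percentages are
#' exact.
#'
#' @param counts Data frame with columns `neurite`, `n_approach`,
#'   `n_enter`.
#' @param n_total Total number of soma-origin tracks.
#' @param geometry A `neuron_geometry` (default [fixture_geometry()]).
#' @return List with `geometry` and `tracks`.
#' @export
fixture_counts <- function(counts, n_total, geometry = fixture_geometry()) {
  stopifnot(is.data.frame(counts),
            all(c("neurite", "n_approach", "n_enter") %in% names(counts)))
  if (any(counts$n_enter > counts$n_approach)) {
    stop("n_enter cannot exceed n_approach for any neurite")
  }
  if (sum(counts$n_approach) > n_total) {
    stop("requested approaches exceed n_total")
  }
  tracks <- list()
  idx <- 0L
  for (r in seq_len(nrow(counts))) {
    nm <- counts$neurite[r]
    entry_ok <- identical(nm, "axon") || nm %in% names(geometry$dendrite_entries)
    if (!entry_ok) stop("fixture table names unknown neurite '", nm, "'")
    for (i in seq_len(counts$n_enter[r])) {
      idx <- idx + 1L
      tracks[[idx]] <- .gate_line_track(geometry, nm, -2.75, 1.25,
                                        sprintf("f%04d", idx),
                                        geometry$frame_interval)
    }
    for (i in seq_len(counts$n_approach[r] - counts$n_enter[r])) {
      idx <- idx + 1L
      tracks[[idx]] <- .gate_line_track(geometry, nm, -2.75, -0.25,
                                        sprintf("f%04d", idx),
                                        geometry$frame_interval)
    }
  }
  for (i in seq_len(n_total - sum(counts$n_approach))) {
    idx <- idx + 1L
    s <- seq(-0.5, 0.5, by = 0.5)
    tracks[[idx]] <- comet_track(
      comet_id = sprintf("f%04d", idx), movie_id = "fixture",
      t = seq_along(s) * geometry$frame_interval,
      x = s, y = rep(0, length(s)),
      present_at_first_frame = FALSE,
      frame_interval = geometry$frame_interval)
  }
  list(geometry = geometry, tracks = tracks)
}

#' Build fixture tracks with exact turning counts
#'
#' Emits `n_qualifying` tracks that all qualify for turning analysis (longer
#' than 2 um within the soma, away from the cortex), of which `n_turned`
#' execute a single 90-degree direction change 1.5 um into the path, far
#' from all boundaries, and the rest run straight.
#'
#' @param n_turned Number of turning tracks.
#' @param n_qualifying Total number of qualifying tracks (>= `n_turned`).
#' @param geometry A `neuron_geometry` (default [fixture_geometry()]).
#' @return List with `geometry` and `tracks`.
#' @export
fixture_turning <- function(n_turned, n_qualifying,
                            geometry = fixture_geometry()) {
  if (n_turned > n_qualifying) stop("n_turned cannot exceed n_qualifying")
  fi <- geometry$frame_interval
  mk <- function(pts, id) {
    comet_track(comet_id = id, movie_id = "fixture",
                t = seq_len(nrow(pts)) * fi,
                x = pts[, 1], y = pts[, 2],
                present_at_first_frame = FALSE, frame_interval = fi)
  }
  bent <- rbind(
    cbind(seq(-1.5, 0.5, by = 0.5), -1),           # 4 segments along +x
    cbind(0.5, seq(-0.5, 1.5, by = 0.5)))          # 4 segments along +y
  straight <- cbind(seq(-2, 2, by = 0.5), 1)
  tracks <- vector("list", n_qualifying)
  for (i in seq_len(n_qualifying)) {
    tracks[[i]] <- mk(if (i <= n_turned) bent else straight,
                      sprintf("t%04d", i))
  }
  list(geometry = geometry, tracks = tracks)
}
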