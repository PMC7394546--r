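#' Construct a neuron geometry
#'
#' The spatial frame all classification runs in: the soma outline, an
#' optional nucleus outline, the axon entry point, named dendrite entry
#' points (optionally with a branchpoint marker delimiting the proximal
#' dendrite segment), and named Golgi stack centres with an association
#' radius used to assign comet origins to stacks.
#'
#' @param soma Closed simple polygon, an n x 2 matrix of vertices in
#'   micrometres (first vertex not repeated).
#' @param axon_entry Point `c(x, y)` on (or within 1 um of) the soma
#'   boundary where the axon leaves the soma.
#' @param dendrite_entries Named list of points where dendrites leave the
#'   soma.
#' @param nucleus Optional polygon fully inside the soma.
#' @param golgi_stacks Named list; each element a list with `center`
#'   (point) and `radius` (association radius in micrometres, > 0).
#' @param dendrite_branchpoints Optional named list of points marking the
#'   first branchpoint of each dendrite (end of the proximal segment).
#' @param frame_interval Movie frame interval in seconds.
#' @param y_axis `"math"` (y up) or `"image"` (y down, ImageJ convention).
#'   All analysis runs in math convention; see [as_math_convention()].
#' @return An object of class `neuron_geometry`.
#' @export
neuron_geometry <- function(soma, axon_entry, dendrite_entries = list(),
                            nucleus = NULL, golgi_stacks = list(),
                            dendrite_branchpoints = list(),
                            frame_interval = 5, y_axis = c("math", "image")) {
  y_axis <- match.arg(y_axis)
  soma <- .as_points(soma)
  if (nrow(soma) < 3) stop("soma polygon needs at least 3 vertices")
  # drop a repeated closing vertex if present
  if (all(abs(soma[1, ] - soma[nrow(soma), ]) < 1e-12)) {
    soma <- soma[-nrow(soma), , drop = FALSE]
  }
  if (nrow(soma) < 3) stop("soma polygon needs at least 3 vertices")
  if (!.poly_is_simple(soma)) stop("soma polygon is self-intersecting")
  if (!is.null(nucleus)) {
    nucleus <- .as_points(nucleus)
    if (all(abs(nucleus[1, ] - nucleus[nrow(nucleus), ]) < 1e-12)) {
      nucleus <- nucleus[-nrow(nucleus), , drop = FALSE]
    }
    if (nrow(nucleus) < 3) stop("nucleus polygon needs at least 3 vertices")
    if (!.poly_is_simple(nucleus)) stop("nucleus polygon is self-intersecting")
    if (!all(.point_in_poly(nucleus, soma))) {
      stop("nucleus not contained in soma")
    }
  }
  axon_entry <- as.numeric(axon_entry)
  check_entry <- function(p, what) {
    if (length(p) != 2 || !all(is.finite(p))) {
      stop(what, " must be a finite (x, y) point")
    }
    d <- .dist_to_poly(p, soma)
    if (d > 1) {
      stop(what, " lies ", round(d, 3),
           " um from the soma boundary (must be within 1 um)")
    }
  }
  check_entry(axon_entry, "axon_entry")
  dendrite_entries <- lapply(dendrite_entries, as.numeric)
  if (length(dendrite_entries) > 0 && is.null(names(dendrite_entries))) {
    names(dendrite_entries) <- paste0("dendrite", seq_along(dendrite_entries))
  }
  for (nm in names(dendrite_entries)) {
    check_entry(dendrite_entries[[nm]], paste0("dendrite entry '", nm, "'"))
  }
  golgi_stacks <- lapply(golgi_stacks, function(g) {
    g$center <- as.numeric(g$center)
    g$radius <- as.numeric(g$radius)
    if (length(g$center) != 2 || !all(is.finite(g$center))) {
      stop("golgi stack center must be a finite (x, y) point")
    }
    if (!is.finite(g$radius) || g$radius <= 0) {
      stop("golgi stack association_radius must be > 0")
    }
    g
  })
  if (length(golgi_stacks) > 0 && is.null(names(golgi_stacks))) {
    names(golgi_stacks) <- paste0("golgi", seq_along(golgi_stacks))
  }
  dendrite_branchpoints <- lapply(dendrite_branchpoints, as.numeric)
  unknown <- setdiff(names(dendrite_branchpoints), names(dendrite_entries))
  if (length(unknown) > 0) {
    stop("branchpoint(s) for unknown dendrite(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  structure(
    list(soma = soma, nucleus = nucleus, axon_entry = axon_entry,
         dendrite_entries = dendrite_entries,
         dendrite_branchpoints = dendrite_branchpoints,
         golgi_stacks = golgi_stacks,
         frame_interval = frame_interval, y_axis = y_axis),
    class = "neuron_geometry")
}

#' @export
print.neuron_geometry <- function(x, ...) {
  cat("<neuron_geometry> soma: ", nrow(x$soma), " vertices",
      if (!is.null(x$nucleus)) paste0("; nucleus: ", nrow(x$nucleus), " vertices") else "",
      "\n  axon entry at (", paste(signif(x$axon_entry, 4), collapse = ", "),
      "); ", length(x$dendrite_entries), " dendrite entr",
      if (length(x$dendrite_entries) == 1) "y" else "ies",
      "; ", length(x$golgi_stacks), " Golgi stack(s)",
      "\n  frame interval ", x$frame_interval, " s; y-axis convention: ",
      x$y_axis, "\n", sep = "")
  invisible(x)
}

.pts_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

#' Read or write a neuron geometry file
#'
#' Geometries are stored as YAML with keys `y_axis`, `frame_interval_s`,
#' `soma`, `nucleus` (optional), `axon_entry`, `dendrite_entries`,
#' `dendrite_branchpoints` (optional) and `golgi_stacks` (each stack a map
#' with `center` and `radius`); polygons are lists of `[x, y]` vertices in
#' micrometres. All [neuron_geometry()] invariants are checked on read;
#' violations are errors, not warnings.
#'
#' @param path File path.
#' @return `read_geometry()` returns a `neuron_geometry`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (key in c("soma", "axon_entry", "y_axis")) {
    if (is.null(doc[[key]])) stop("geometry file missing required key '", key, "'")
  }
  as_poly <- function(v) do.call(rbind, lapply(v, as.numeric))
  neuron_geometry(
    soma = as_poly(doc$soma),
    nucleus = if (!is.null(doc$nucleus)) as_poly(doc$nucleus) else NULL,
    axon_entry = as.numeric(doc$axon_entry),
    dendrite_entries = lapply(doc$dendrite_entries, as.numeric),
    dendrite_branchpoints = lapply(doc$dendrite_branchpoints, as.numeric),
    golgi_stacks = doc$golgi_stacks,
    frame_interval = if (!is.null(doc$frame_interval_s)) doc$frame_interval_s else 5,
    y_axis = doc$y_axis)
}

#' @rdname read_geometry
#' @param geometry A `neuron_geometry` object.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "neuron_geometry"))
  doc <- list(
    y_axis = geometry$y_axis,
    frame_interval_s = geometry$frame_interval,
    soma = .pts_to_list(geometry$soma),
    axon_entry = as.numeric(geometry$axon_entry))
  if (!is.null(geometry$nucleus)) doc$nucleus <- .pts_to_list(geometry$nucleus)
  if (length(geometry$dendrite_entries) > 0) {
    doc$dendrite_entries <- lapply(geometry$dendrite_entries, as.numeric)
  }
  if (length(geometry$dendrite_branchpoints) > 0) {
    doc$dendrite_branchpoints <- lapply(geometry$dendrite_branchpoints, as.numeric)
  }
  if (length(geometry$golgi_stacks) > 0) {
    doc$golgi_stacks <- lapply(geometry$golgi_stacks, function(g) {
      list(center = as.numeric(g$center), radius = as.numeric(g$radius))
    })
  }
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Convert geometry and tracks to math-convention coordinates
#'
#' ImageJ exports use the image convention (origin top-left, y increasing
#' downward); all angle arithmetic in this package assumes the math
#' convention (y up, angles positive counterclockwise). When the geometry
#' declares `y_axis: image`, this flips the y coordinate of the geometry and
#' of every track; in math convention it is a no-op. The flip is explicit so
#' that sign conventions are never silently mixed.
#'
#' @param geometry A `neuron_geometry`.
#' @param tracks Optional list of `comet_track` objects recorded in the same
#'   convention as the geometry.
#' @return A list with elements `geometry` and `tracks`.
#' @export
as_math_convention <- function(geometry, tracks = NULL) {
  if (geometry$y_axis == "math") {
    return(list(geometry = geometry, tracks = tracks))
  }
  flip_poly <- function(p) if (is.null(p)) NULL else cbind(p[, 1], -p[, 2])
  flip_pt <- function(p) c(p[1], -p[2])
  geom2 <- neuron_geometry(
    soma = flip_poly(geometry$soma),
    nucleus = flip_poly(geometry$nucleus),
    axon_entry = flip_pt(geometry$axon_entry),
    dendrite_entries = lapply(geometry$dendrite_entries, flip_pt),
    dendrite_branchpoints = lapply(geometry$dendrite_branchpoints, flip_pt),
    golgi_stacks = lapply(geometry$golgi_stacks, function(g) {
      list(center = flip_pt(g$center), radius = g$radius)
    }),
    frame_interval = geometry$frame_interval, y_axis = "math")
  tracks2 <- if (is.null(tracks)) NULL else lapply(tracks, function(tr) {
    tr$y <- -tr$y
    tr
  })
  list(geometry = geom2, tracks = tracks2)
}
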