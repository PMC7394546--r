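#' Fold a signed growth angle onto [0, 180]
#'
#' Comets growing to the left or right of the axon entry site are not
#' distinguished, so signed angles in (-180, 180] are folded to their
#' absolute value.
#'
#' @param theta_signed Numeric vector of angles in degrees, each in
#'   (-180, 180].
#' @return Angles in degrees in `[0, 180]`.
#' @export
fold_angle <- function(theta_signed) {
  if (any(!is.finite(theta_signed)) ||
      any(theta_signed <= -180 | theta_signed > 180)) {
    stop("theta_signed must lie in (-180, 180]")
  }
  abs(theta_signed)
}

#' Measure a comet's initial growth angle relative to the axon entry site
#'
#' The angle at the comet origin between the ray from the origin to the axon
#' entry point and the comet's initial direction of growth. The initial
#' direction is the total-least-squares line through the first
#' `n_direction_points` positions, oriented by the net displacement over
#' those points. An angle of 0 means growth straight at the axon entry site;
#' 180 means growth diametrically away; the sign is positive for
#' counterclockwise rotation from the origin-to-axon ray (math convention).
#'
#' The comet origin is also assigned to the nearest Golgi stack whose
#' association radius contains it (exact distance ties break to the
#' lexicographically first stack name, with a message).
#'
#' @param track A `comet_track` with origin inside the soma.
#' @param geometry A `neuron_geometry` in math convention.
#' @param n_direction_points Number of leading positions used to estimate
#'   the initial direction (default 3: the origin plus the next two frames).
#' @return An object of class `growth_angle`: a list with `comet_id`,
#'   `theta_signed`, `theta_folded` and `origin_stack` (`NA` when the origin
#'   is not within any stack's association radius).
#' @export
initial_growth_angle <- function(track, geometry, n_direction_points = 3) {
  stopifnot(inherits(track, "comet_track"), inherits(geometry, "neuron_geometry"))
  if (n_direction_points < 2) stop("n_direction_points must be >= 2")
  pts <- .track_points(track)
  if (nrow(pts) < n_direction_points) {
    stop("track ", track$comet_id, " has fewer than ", n_direction_points,
         " points")
  }
  origin <- pts[1, ]
  if (!.point_in_poly(origin, geometry$soma)) {
    stop("comet ", track$comet_id, " origin lies outside the soma")
  }
  lead <- pts[seq_len(n_direction_points), , drop = FALSE]
  net <- lead[nrow(lead), ] - lead[1, ]
  if (sqrt(sum(net^2)) < 1e-12) {
    stop("comet ", track$comet_id,
         " has zero net displacement over the first ", n_direction_points,
         " points; initial direction undefined")
  }
  # total-least-squares direction: first principal axis of the lead points
  pc <- prcomp(lead, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (sum(v * net) < 0) v <- -v
  u <- geometry$axon_entry - origin
  if (sqrt(sum(u^2)) < 1e-12) {
    stop("comet ", track$comet_id, " originates at the axon entry point")
  }
  theta <- .signed_angle(u, v)
  structure(
    list(comet_id = track$comet_id,
         theta_signed = theta,
         theta_folded = fold_angle(theta),
         origin_stack = .assign_origin_stack(origin, geometry)),
    class = "growth_angle")
}

.assign_origin_stack <- function(origin, geometry) {
  stacks <- geometry$golgi_stacks
  if (length(stacks) == 0) return(NA_character_)
  d <- vapply(stacks, function(g) sqrt(sum((origin - g$center)^2)), numeric(1))
  r <- vapply(stacks, function(g) g$radius, numeric(1))
  ok <- which(d <= r)
  if (length(ok) == 0) return(NA_character_)
  dok <- d[ok]
  best <- ok[dok == min(dok)]
  if (length(best) > 1) {
    nms <- sort(names(stacks)[best])
    message("origin equidistant from stacks ", paste(nms, collapse = ", "),
            "; assigning lexicographically first ('", nms[1], "')")
    return(nms[1])
  }
  names(stacks)[best]
}

#' Build the entry zone across a neurite mouth
#'
#' An entry zone is a band of the given width laid across the entrance to
#' the axon or a dendrite, used to score comets that approach (touch the
#' band) versus enter (cross the band out of the soma). The band is bounded
#' by two parallel gates perpendicular to the local outward boundary normal
#' at the entry point: the inner gate on the soma side, the outer gate on
#' the neurite side, each centred on the entry point and spanning the
#' neurite caliber.
#'
#' @param geometry A `neuron_geometry`.
#' @param neurite_name `"axon"` or the name of a dendrite entry.
#' @param width Band width in micrometres (default 0.5).
#' @param caliber Gate length in micrometres, clamped to `[1, 5]`
#'   (default 2); the geometry carries no neurite silhouette, so the mouth
#'   caliber is an explicit parameter.
#' @return An object of class `entry_zone` with the gate segments, the band
#'   polygon, and the outward normal.
#' @export
build_entry_zone <- function(geometry, neurite_name, width = 0.5, caliber = 2) {
  stopifnot(inherits(geometry, "neuron_geometry"))
  if (!is.numeric(width) || width <= 0) stop("zone width must be > 0")
  caliber <- min(max(caliber, 1), 5)
  if (identical(neurite_name, "axon")) {
    entry <- geometry$axon_entry
    kind <- "axon"
  } else {
    entry <- geometry$dendrite_entries[[neurite_name]]
    if (is.null(entry)) stop("no dendrite named '", neurite_name, "' in geometry")
    kind <- "dendrite"
  }
  nrm <- .outward_normal(geometry$soma, entry)
  tang <- c(-nrm[2], nrm[1])
  half <- caliber / 2
  inner_c <- entry - nrm * width / 2
  outer_c <- entry + nrm * width / 2
  inner_gate <- rbind(inner_c - tang * half, inner_c + tang * half)
  outer_gate <- rbind(outer_c - tang * half, outer_c + tang * half)
  band <- rbind(inner_gate[1, ], inner_gate[2, ], outer_gate[2, ], outer_gate[1, ])
  structure(
    list(neurite_name = if (kind == "axon") "axon" else neurite_name,
         kind = kind, entry = entry,
         inner_gate = inner_gate, outer_gate = outer_gate, band = band,
         width = width, caliber = caliber, normal = nrm),
    class = "entry_zone")
}

#' Distance from an interior point to the soma cortex
#'
#' Euclidean distance from a point inside the soma to the nearest point of
#' the soma outline; when a nucleus is present, the distance to the nucleus
#' boundary is reported alongside.
#'
#' @param point Point `c(x, y)` inside the soma.
#' @param geometry A `neuron_geometry`.
#' @return Named numeric vector with elements `cortex` and, if a nucleus is
#'   present, `nucleus`.
#' @export
distance_to_cortex <- function(point, geometry) {
  stopifnot(inherits(geometry, "neuron_geometry"))
  point <- as.numeric(point)
  if (!.point_in_poly(point, geometry$soma)) {
    stop("point lies outside the soma")
  }
  out <- c(cortex = .dist_to_poly(point, geometry$soma))
  if (!is.null(geometry$nucleus)) {
    out <- c(out, nucleus = .dist_to_poly(point, geometry$nucleus))
  }
  out
}
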