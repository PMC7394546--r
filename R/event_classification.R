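#' Turning-detection parameters
#'
#' Turning was originally scored by eye; this package uses an explicit
#' operational rule so the classification is reproducible. A comet
#' qualifies for turning analysis if its within-soma path is longer than
#' `min_path_length` and it is not a cortex traveller (at least half of its
#' within-soma points within `cortex_margin` of the soma outline). A
#' qualifying comet turned if two smoothed direction estimates separated
#' along the path differ by at least `turn_angle_threshold`, with the
#' direction-change vertex farther than `cortex_margin` from both the soma
#' outline and the nucleus (direction changes at boundaries are collisions,
#' not turns).
#'
#' @param min_path_length Minimum within-soma path length in micrometres
#'   (default 2).
#' @param turn_angle_threshold Angular change counting as a turn, degrees in
#'   (0, 180) (default 45).
#' @param smoothing_window Frames per direction estimate (default 3).
#' @param cortex_margin Distance from a boundary within which direction
#'   changes are treated as collisions, micrometres (default 1).
#' @return An object of class `turning_params`.
#' @export
turning_params <- function(min_path_length = 2, turn_angle_threshold = 45,
                           smoothing_window = 3, cortex_margin = 1) {
  if (min_path_length <= 0 || smoothing_window <= 0 || cortex_margin <= 0) {
    stop("all turning parameters must be positive")
  }
  if (turn_angle_threshold <= 0 || turn_angle_threshold >= 180) {
    stop("turn_angle_threshold must lie in (0, 180)")
  }
  structure(list(min_path_length = min_path_length,
                 turn_angle_threshold = turn_angle_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 cortex_margin = cortex_margin),
            class = "turning_params")
}

# earliest contact of a track with a zone band: list(seg, t, s) or NULL
.first_band_contact <- function(pts, band) {
  n <- nrow(pts)
  if (n < 2) return(NULL)
  ss <- numeric(0)
  inb <- .point_in_poly(pts[-n, , drop = FALSE], band)
  if (any(inb)) ss <- which(inb)[1]
  for (i in seq_len(nrow(band))) {
    ss <- c(ss, .crossing_s(pts, band[i, ],
                            band[if (i == nrow(band)) 1L else i + 1L, ]))
  }
  if (length(ss) == 0) return(NULL)
  s <- min(ss)
  seg <- min(floor(s + 1e-12), n - 1)
  # last path point strictly before the contact (contact exactly at a
  # sampled point excludes that point)
  prefix <- max(ceiling(s - 1e-9) - 1, 1)
  list(seg = as.integer(seg), t = s - seg, s = s, prefix = as.integer(prefix))
}

# does the path cross the outer gate in the outward direction at or after
# path position s0 (segment index + fraction)?
.crosses_outer_gate <- function(pts, zone, s0) {
  ss <- .crossing_s(pts, zone$outer_gate[1, ], zone$outer_gate[2, ])
  ss <- ss[ss >= s0 - 1e-9]
  if (length(ss) == 0) return(FALSE)
  for (s in ss) {
    i <- min(floor(s + 1e-12), nrow(pts) - 1)
    step <- pts[i + 1, ] - pts[i, ]
    if (sum(step * zone$normal) > 0) return(TRUE)
  }
  FALSE
}

.zones_overlap <- function(zones) {
  if (length(zones) < 2) return(FALSE)
  for (i in seq_len(length(zones) - 1)) {
    for (j in (i + 1):length(zones)) {
      a <- zones[[i]]$band; b <- zones[[j]]$band
      if (any(.point_in_poly(a, b)) || any(.point_in_poly(b, a))) return(TRUE)
    }
  }
  FALSE
}

#' Classify a comet's approach to and entry into neurites
#'
#' A comet approaches a neurite when its path touches that neurite's entry
#' zone band, and enters when the path subsequently crosses the outer gate
#' leaving the soma side. A comet may approach without entering (it
#' terminates inside the band or retreats); once it has entered, later
#' positions are outside the soma classification domain. Comets whose
#' origin already lies inside an entry zone are flagged
#' (`origin_in_zone = TRUE`) and should be excluded from approach/entry
#' denominators.
#'
#' @param track A `comet_track` whose origin is inside the soma.
#' @param zones List of `entry_zone` objects (must not overlap).
#' @param geometry A `neuron_geometry`.
#' @return List with `approached` (character vector of zone names in order
#'   of first contact; empty if none), `entered` (single zone name or `NA`),
#'   and `origin_in_zone`.
#' @export
classify_approach_entry <- function(track, zones, geometry) {
  stopifnot(inherits(track, "comet_track"))
  pts <- .track_points(track)
  if (!.point_in_poly(pts[1, ], geometry$soma)) {
    stop("comet ", track$comet_id, " origin lies outside the soma")
  }
  if (.zones_overlap(zones)) {
    stop("entry zones overlap; two zones would claim the same crossing")
  }
  names(zones) <- vapply(zones, `[[`, character(1), "neurite_name")
  origin_in <- vapply(zones, function(z) {
    .point_in_poly(pts[1, ], z$band)
  }, logical(1))
  if (any(origin_in)) {
    return(list(approached = character(0), entered = NA_character_,
                origin_in_zone = TRUE))
  }
  contacts <- lapply(zones, function(z) .first_band_contact(pts, z$band))
  hit <- !vapply(contacts, is.null, logical(1))
  if (!any(hit)) {
    return(list(approached = character(0), entered = NA_character_,
                origin_in_zone = FALSE))
  }
  ss <- vapply(contacts[hit], `[[`, numeric(1), "s")
  ord <- names(sort(ss))
  entered <- NA_character_
  for (nm in ord) {
    if (.crosses_outer_gate(pts, zones[[nm]], contacts[[nm]]$s)) {
      entered <- nm
      # once entered, the comet leaves the soma domain: drop later contacts
      ord <- ord[seq_len(match(nm, ord))]
      break
    }
  }
  list(approached = ord, entered = entered, origin_in_zone = FALSE)
}

#' Detect turning behaviour of a comet within the soma
#'
#' Applies the qualification and turning rule of [turning_params()].
#' Direction estimates are displacement vectors over `smoothing_window`
#' frames; a turn is an angular change of at least the threshold between
#' two consecutive non-overlapping windows. The direction-change vertex is
#' located at the point of maximal local bend inside the window span and
#' must lie farther than `cortex_margin` from the soma outline and the
#' nucleus (direction changes at boundaries are collisions, not turns).
#' Analysis covers the within-soma portion of the path up to the first
#' entry-zone contact: behaviour at and beyond a neurite gate is not soma
#' turning.
#'
#' @param track A `comet_track` whose origin is inside the soma.
#' @param geometry A `neuron_geometry`.
#' @param params A `turning_params` object.
#' @param zones Optional list of `entry_zone` objects delimiting the soma
#'   classification domain; by default zones for the axon and every
#'   dendrite are built with default width and caliber.
#' @return List with `qualifies`, `turned`, `cortex_traveller` and `reason`
#'   (why a track failed to qualify, or `NA`).
#' @export
detect_turning <- function(track, geometry, params = turning_params(),
                           zones = NULL) {
  stopifnot(inherits(track, "comet_track"), inherits(params, "turning_params"))
  pts <- .track_points(track)
  if (!.point_in_poly(pts[1, ], geometry$soma)) {
    stop("comet ", track$comet_id, " origin lies outside the soma")
  }
  if (is.null(zones)) {
    zones <- c(list(build_entry_zone(geometry, "axon")),
               lapply(names(geometry$dendrite_entries),
                      function(nm) build_entry_zone(geometry, nm)))
  }
  inside <- .point_in_poly(pts, geometry$soma)
  # within-soma prefix of the path (up to the first exit)
  last_in <- if (all(inside)) nrow(pts) else which(!inside)[1] - 1L
  # ... further truncated at the first entry-zone contact
  for (z in zones) {
    hit <- .first_band_contact(pts, z$band)
    if (!is.null(hit)) last_in <- min(last_in, hit$prefix)
  }
  sp <- pts[seq_len(last_in), , drop = FALSE]
  if (nrow(sp) < 2) {
    return(list(qualifies = FALSE, turned = FALSE, cortex_traveller = FALSE,
                reason = "fewer than 2 within-soma points"))
  }
  dc <- .dist_to_poly(sp, geometry$soma)
  cortex_traveller <- mean(dc <= params$cortex_margin) >= 0.5
  path_len <- sum(sqrt(rowSums((sp[-1, , drop = FALSE] -
                                sp[-nrow(sp), , drop = FALSE])^2)))
  if (path_len <= params$min_path_length) {
    return(list(qualifies = FALSE, turned = FALSE,
                cortex_traveller = cortex_traveller,
                reason = sprintf("within-soma path %.2f um <= %.2f um",
                                 path_len, params$min_path_length)))
  }
  if (cortex_traveller) {
    return(list(qualifies = FALSE, turned = FALSE, cortex_traveller = TRUE,
                reason = "travelled along the cell cortex"))
  }
  dn <- if (is.null(geometry$nucleus)) NULL else .dist_to_poly(sp, geometry$nucleus)
  turned <- .turn_signature(sp, dc, dn, params)
  list(qualifies = TRUE, turned = turned, cortex_traveller = FALSE,
       reason = NA_character_)
}

# The angular turn signature of a polyline: TRUE when two smoothed
# direction windows differ by at least the threshold and the bend vertex
# (maximal pointwise direction change in the window span) lies farther
# than cortex_margin from both boundaries. Shared by detect_turning and
# the simulator's ground-truth labelling, so the label is defined once.
.turn_signature <- function(sp, dc, dn, params) {
  w <- params$smoothing_window
  n <- nrow(sp)
  if (n < 2 * w + 1) return(FALSE)
  steps <- sp[-1, , drop = FALSE] - sp[-n, , drop = FALSE]
  bend <- rep(0, n)
  for (j in 2:(n - 1)) {
    if (sum(steps[j - 1, ]^2) < 1e-16 || sum(steps[j, ]^2) < 1e-16) next
    bend[j] <- abs(.signed_angle(steps[j - 1, ], steps[j, ]))
  }
  for (i in seq_len(n - 2 * w)) {
    v1 <- sp[i + w, ] - sp[i, ]
    v2 <- sp[i + 2 * w, ] - sp[i + w, ]
    if (sum(v1^2) < 1e-16 || sum(v2^2) < 1e-16) next
    ang <- abs(.signed_angle(v1, v2))
    if (ang >= params$turn_angle_threshold) {
      span <- seq(i + 1, i + 2 * w - 1)
      vtx <- span[which.max(bend[span])]
      away <- dc[vtx] > params$cortex_margin &&
        (is.null(dn) || dn[vtx] > params$cortex_margin)
      if (away) return(TRUE)
    }
  }
  FALSE
}

#' Classify comet polarity within a proximal dendrite
#'
#' A comet with positions inside the proximal segment of the named dendrite
#' (the corridor from the entry zone's outer gate to the dendrite's
#' branchpoint marker) is anterograde if its net displacement projected on
#' the dendrite axis points away from the soma, retrograde if towards.
#' Anterograde comets report plus-end-out microtubules, retrograde comets
#' minus-end-out. Net displacements below the noise floor are indeterminate
#' and excluded from denominators.
#'
#' @param track A `comet_track`.
#' @param geometry A `neuron_geometry` with a branchpoint marker for the
#'   dendrite.
#' @param dendrite_name Name of the dendrite entry.
#' @param zone_width,caliber Entry-zone parameters (see
#'   [build_entry_zone()]); the corridor halfwidth is `caliber / 2`.
#' @param noise_floor Minimum |net axial displacement| in micrometres for a
#'   determinate call (default 0.2).
#' @return `"anterograde"`, `"retrograde"` or `"indeterminate"`.
#' @export
classify_dendrite_polarity <- function(track, geometry, dendrite_name,
                                       zone_width = 0.5, caliber = 2,
                                       noise_floor = 0.2) {
  stopifnot(inherits(track, "comet_track"))
  entry <- geometry$dendrite_entries[[dendrite_name]]
  if (is.null(entry)) stop("no dendrite named '", dendrite_name, "'")
  branch <- geometry$dendrite_branchpoints[[dendrite_name]]
  if (is.null(branch)) {
    stop("dendrite '", dendrite_name, "' has no branchpoint marker; the ",
         "proximal segment end is a geometry-file marker, not inferred")
  }
  zone <- build_entry_zone(geometry, dendrite_name, width = zone_width,
                           caliber = caliber)
  base <- (zone$outer_gate[1, ] + zone$outer_gate[2, ]) / 2
  axis_vec <- branch - base
  L <- sqrt(sum(axis_vec^2))
  if (L < 1e-9) stop("branchpoint coincides with the entry zone outer gate")
  u <- axis_vec / L
  pts <- .track_points(track)
  rel_x <- pts[, 1] - base[1]
  rel_y <- pts[, 2] - base[2]
  s <- rel_x * u[1] + rel_y * u[2]
  lateral <- abs(rel_x * u[2] - rel_y * u[1])
  in_seg <- s >= 0 & s <= L & lateral <= caliber / 2
  if (sum(in_seg) < 2) {
    stop("comet ", track$comet_id, " has fewer than 2 points within the ",
         "proximal segment of dendrite '", dendrite_name, "'")
  }
  s_in <- s[in_seg]
  net <- s_in[length(s_in)] - s_in[1]
  if (abs(net) < noise_floor) {
    message("comet ", track$comet_id, ": net axial displacement ",
            signif(abs(net), 3), " um below the ", noise_floor,
            " um noise floor; polarity indeterminate")
    return("indeterminate")
  }
  if (net > 0) "anterograde" else "retrograde"
}

#' Tabulate comet event classifications
#'
#' Summarises a set of per-comet event records into the standard event
#' table: per condition, the number of soma-origin comets, the number and
#' percentage approaching the axon or a dendrite, of the approachers the
#' number entering, the percentage of qualifying comets that turned, and
#' the dendrite polarity split -- each as a [proportion()] with its Wilson
#' 95% interval. Entry percentages are reported both as a proportion of
#' approachers and of all soma-origin comets.
#'
#' @param events Data frame with one row per comet and columns
#'   `approached_axon`, `approached_dendrite`, `entered_axon`,
#'   `entered_dendrite` (logicals), `qualifies`, `turned` (logicals),
#'   `dendrite_polarity` (character or `NA`), and `origin_in_zone`
#'   (logical; such comets are excluded from approach/entry denominators).
#' @param condition Condition label attached to every row.
#' @return Data frame with columns `condition`, `metric`, `k`, `n`,
#'   `percent`, `ci_low`, `ci_high`. Metrics with zero denominators are
#'   flagged with `NA` percentages.
#' @export
tabulate_events <- function(events, condition = "all") {
  row_of <- function(metric, k, n) {
    if (n == 0) {
      return(data.frame(condition = condition, metric = metric, k = 0L,
                        n = 0L, percent = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE))
    }
    pr <- proportion(k, n)
    data.frame(condition = condition, metric = metric, k = pr$k, n = pr$n,
               percent = pr$percent, ci_low = pr$ci_low,
               ci_high = pr$ci_high, stringsAsFactors = FALSE)
  }
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(approached_axon = logical(0),
                         approached_dendrite = logical(0),
                         entered_axon = logical(0),
                         entered_dendrite = logical(0),
                         qualifies = logical(0), turned = logical(0),
                         dendrite_polarity = character(0),
                         origin_in_zone = logical(0))
  }
  excl <- sum(events$origin_in_zone, na.rm = TRUE)
  if (excl > 0) {
    message(excl, " comet(s) originating inside an entry zone excluded ",
            "from approach/entry denominators")
  }
  ev <- events[!events$origin_in_zone, , drop = FALSE]
  n_soma <- nrow(ev)
  app_ax <- sum(ev$approached_axon, na.rm = TRUE)
  app_de <- sum(ev$approached_dendrite, na.rm = TRUE)
  ent_ax <- sum(ev$entered_axon, na.rm = TRUE)
  ent_de <- sum(ev$entered_dendrite, na.rm = TRUE)
  pol <- events$dendrite_polarity
  pol <- pol[!is.na(pol) & pol != "indeterminate"]
  out <- rbind(
    row_of("approached_axon", app_ax, n_soma),
    row_of("approached_dendrite", app_de, n_soma),
    row_of("entered_axon_of_approached", ent_ax, app_ax),
    row_of("entered_dendrite_of_approached", ent_de, app_de),
    row_of("entered_axon_of_all", ent_ax, n_soma),
    row_of("entered_dendrite_of_all", ent_de, n_soma),
    row_of("turned_of_qualifying", sum(ev$qualifies & ev$turned, na.rm = TRUE),
           sum(ev$qualifies, na.rm = TRUE)),
    row_of("anterograde_in_dendrite", sum(pol == "anterograde"), length(pol)))
  out
}
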