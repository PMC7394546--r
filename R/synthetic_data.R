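# Synthetic comet-track generator: Golgi-anchored biased nucleation,
# guided turning, Bernoulli entry gates, cortex/nucleus reflection.

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used by the simulator for
#' directionally biased nucleation angles and turn jitter; `kappa = 0`
#' reduces to the uniform circular distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  mu_r <- .deg2rad(mu)
  if (kappa < 1e-10) {
    th <- runif(n, -pi, pi) + mu_r
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    i <- 1L
    while (i <= n) {
      u1 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        th[i] <- mu_r + sign(runif(1) - 0.5) * acos(f)
        i <- i + 1L
      }
    }
  }
  deg <- .rad2deg(th)
  deg <- deg - 360 * floor((deg + 180) / 360)
  deg[deg == -180] <- 180
  deg
}

#' Simulation configuration
#'
#' All tunable parameters of the synthetic comet-track generator. Defaults
#' describe a class I da-neuron-like soma imaged every 5 s: an elliptical
#' soma of 6 x 5 um semi-axes with a concentric nucleus, the axon leaving at
#' the top and two dendrites at the bottom, Golgi stacks scattered in the
#' cytoplasmic annulus, comet growth at 0.1 um/s with a 0.005/s catastrophe
#' hazard, Golgi nucleation biased towards the axon with von Mises
#' concentration `kappa_nucleation`, occasional guided turns that redirect
#' growth towards the axon entry, and Bernoulli entry gates at neurite
#' mouths with axon/dendrite entry probabilities matching the control
#' entry proportions (0.54 and 0.28).
#'
#' @param soma_semi_axes Ellipse semi-axes in micrometres.
#' @param nucleus_fraction Nucleus semi-axes as a fraction of the soma's
#'   (0 disables the nucleus).
#' @param axon_angle_deg Parametric angle of the axon entry on the ellipse.
#' @param dendrite_angles_deg Parametric angles of dendrite entries.
#' @param n_golgi Number of Golgi stacks.
#' @param golgi_radius Stack association radius in micrometres.
#' @param kappa_nucleation von Mises concentration of Golgi-origin initial
#'   angles about the origin-to-axon direction; 0 means uniform.
#' @param frac_golgi_origin Probability a comet originates at a Golgi stack.
#' @param growth_speed Comet speed in um/s.
#' @param frame_interval Sampling interval in seconds.
#' @param catastrophe_rate Per-second termination hazard.
#' @param p_turn_per_frame Probability per frame of a guided turn.
#' @param turn_jitter_kappa von Mises concentration of the post-turn
#'   direction about the towards-axon direction.
#' @param p_enter_axon,p_enter_dendrite Bernoulli entry-gate probabilities.
#' @param position_noise_sd Gaussian localisation jitter in micrometres.
#' @param n_comets Number of comets to simulate.
#' @param zone_width,caliber Entry-zone geometry shared with the analysis.
#' @param max_frames Hard cap on track length in frames.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(soma_semi_axes = c(6, 5),
                              nucleus_fraction = 0.5,
                              axon_angle_deg = 90,
                              dendrite_angles_deg = c(210, 330),
                              n_golgi = 8,
                              golgi_radius = 1,
                              kappa_nucleation = 3,
                              frac_golgi_origin = 0.6,
                              growth_speed = 0.1,
                              frame_interval = 5,
                              catastrophe_rate = 0.005,
                              p_turn_per_frame = 0.04,
                              turn_jitter_kappa = 8,
                              p_enter_axon = 0.54,
                              p_enter_dendrite = 0.28,
                              position_noise_sd = 0.05,
                              n_comets = 100,
                              zone_width = 0.5,
                              caliber = 2,
                              max_frames = 240,
                              seed = 1) {
  probs <- c(frac_golgi_origin, p_turn_per_frame, p_enter_axon,
             p_enter_dendrite)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (growth_speed <= 0 || frame_interval <= 0) {
    stop("growth_speed and frame_interval must be > 0")
  }
  if (catastrophe_rate < 0 || kappa_nucleation < 0 || position_noise_sd < 0) {
    stop("rates, kappa and noise sd must be >= 0")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# point on an ellipse at parametric angle (degrees)
.ellipse_pt <- function(axes, ang) {
  r <- .deg2rad(ang)
  c(axes[1] * cos(r), axes[2] * sin(r))
}

#' Build the parametric neuron geometry of a simulation config
#'
#' @param config A `simulation_config`.
#' @return A `neuron_geometry` in math convention.
#' @export
simulation_geometry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  axes <- config$soma_semi_axes
  angs <- seq(0, 360, length.out = 65)[-65]
  soma <- t(vapply(angs, function(a) .ellipse_pt(axes, a), numeric(2)))
  nucleus <- if (config$nucleus_fraction > 0) {
    t(vapply(angs, function(a) .ellipse_pt(axes * config$nucleus_fraction, a),
             numeric(2)))
  } else NULL
  dendrites <- lapply(config$dendrite_angles_deg,
                      function(a) .ellipse_pt(axes, a))
  names(dendrites) <- paste0("dendrite", seq_along(dendrites))
  branchpoints <- lapply(config$dendrite_angles_deg, function(a) {
    p <- .ellipse_pt(axes, a)
    p + .unit(p) * 3  # proximal segment: 3 um of dendrite before a branch
  })
  names(branchpoints) <- names(dendrites)
  # Golgi stacks on the mid-cytoplasm annulus, offset from the entry sites
  gr <- (1 + config$nucleus_fraction) / 2
  gang <- seq(0, 360, length.out = config$n_golgi + 1)[-(config$n_golgi + 1)] + 17
  golgi <- lapply(gang, function(a) {
    list(center = .ellipse_pt(axes * gr, a), radius = config$golgi_radius)
  })
  names(golgi) <- sprintf("golgi%02d", seq_along(golgi))
  neuron_geometry(
    soma = soma, nucleus = nucleus,
    axon_entry = .ellipse_pt(axes, config$axon_angle_deg),
    dendrite_entries = dendrites, dendrite_branchpoints = branchpoints,
    golgi_stacks = if (config$n_golgi > 0) golgi else list(),
    frame_interval = config$frame_interval, y_axis = "math")
}

#' Simulate a neuron's comet tracks with ground-truth labels
#'
#' Tracks are straight-segment walks at `growth_speed` sampled every
#' `frame_interval`. A comet originates at a Golgi stack with probability
#' `frac_golgi_origin`, in which case its initial angle relative to the
#' origin-to-axon direction is von Mises with concentration
#' `kappa_nucleation`; otherwise it starts uniformly in the cytoplasm with a
#' uniform angle. Each frame the comet may execute a guided turn
#' (probability `p_turn_per_frame`) that redirects growth towards the axon
#' entry with von Mises jitter; turns are suppressed for the first two
#' frames (so the initial direction is well defined) and for
#' `2 * smoothing-window` frames after any direction change (guidance
#' events are not instantaneous re-engagements). Contact with the cortex or
#' nuclear envelope reflects the direction. On first contact with an entry
#' zone a single Bernoulli draw decides entry: an entering comet grows
#' straight on until 1 um past the outer gate and terminates; a rejected
#' comet terminates inside the band. Termination otherwise occurs by
#' catastrophe (`catastrophe_rate`) or the frame cap. Gaussian position
#' noise is added to the emitted coordinates only.
#'
#' The ground-truth table records, per comet, the origin stack, the true
#' initial angle, the gate contacted and its outcome, the termination
#' cause, and the turning labels: `n_turn_events` and `max_turn_angle`
#' summarise the guided-turn event log; `turned` is the angular turn
#' signature of the noise-free pre-gate path (the operational definition
#' [detect_turning()] applies to the emitted track, so on noise-free
#' tracks the classifier recovers it exactly); `clean_turn_event` records
#' an event-log fact -- a guided turn of at least 45 degrees away from
#' boundaries with three undisturbed frames on either side -- that is
#' sufficient for a detectable signature.
#'
#' @param config A `simulation_config`.
#' @return List with `geometry`, `tracks` (list of `comet_track`) and
#'   `truth` (data frame).
#' @export
simulate_neuron <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(config$seed))
  geom <- simulation_geometry(config)
  zones <- c(list(build_entry_zone(geom, "axon", width = config$zone_width,
                                   caliber = config$caliber)),
             lapply(names(geom$dendrite_entries), function(nm) {
               build_entry_zone(geom, nm, width = config$zone_width,
                                caliber = config$caliber)
             }))
  names(zones) <- vapply(zones, `[[`, character(1), "neurite_name")
  step_len <- config$growth_speed * config$frame_interval
  p_cat <- 1 - exp(-config$catastrophe_rate * config$frame_interval)
  w <- 3L  # classifier smoothing window the clean-turn label refers to
  refractory <- 2L * w

  stacks <- geom$golgi_stacks
  stack_names <- names(stacks)
  in_any_band <- function(p) {
    any(vapply(zones, function(z) .point_in_poly(p, z$band), logical(1)))
  }
  # cheap bounding-circle prechecks for the per-frame loop
  cen <- .poly_centroid(geom$soma)
  r_in <- .dist_to_poly(cen, geom$soma)  # inscribed radius about the centroid
  r_nuc <- if (is.null(geom$nucleus)) 0 else
    sqrt(max((geom$nucleus[, 1] - cen[1])^2 + (geom$nucleus[, 2] - cen[2])^2))
  zone_centers <- t(vapply(zones, `[[`, numeric(2), "entry"))
  zone_reach <- vapply(zones, function(z) {
    sqrt(max((z$band[, 1] - z$entry[1])^2 + (z$band[, 2] - z$entry[2])^2))
  }, numeric(1)) + step_len
  in_cytoplasm_fast <- function(p) {
    dc <- sqrt(sum((p - cen)^2))
    dc < r_in && dc > r_nuc
  }
  near_zone <- function(p) {
    which(sqrt((zone_centers[, 1] - p[1])^2 +
               (zone_centers[, 2] - p[2])^2) <= zone_reach)
  }
  find_gate <- function(pos, cand) {
    nz <- near_zone(pos)
    if (length(nz) == 0) return(NULL)
    hits <- rep(Inf, length(zones))
    for (zi in nz) {
      t <- .seg_band_contact(pos, cand, zones[[zi]]$band)
      if (!is.na(t)) hits[zi] <- t
    }
    if (!any(is.finite(hits))) return(NULL)
    zi <- which.min(hits)
    list(zi = zi, t = hits[zi])
  }
  sample_cytoplasm <- function() {
    axes <- config$soma_semi_axes
    repeat {
      p <- c(runif(1, -axes[1], axes[1]), runif(1, -axes[2], axes[2]))
      if (!.point_in_poly(p, geom$soma)) next
      if (!is.null(geom$nucleus) && .point_in_poly(p, geom$nucleus)) next
      if (in_any_band(p)) next
      return(p)
    }
  }

  tracks <- vector("list", config$n_comets)
  truth <- vector("list", config$n_comets)
  for (ci in seq_len(config$n_comets)) {
    golgi_origin <- length(stacks) > 0 && runif(1) < config$frac_golgi_origin
    if (golgi_origin) {
      si <- sample.int(length(stacks), 1)
      g <- stacks[[si]]
      repeat {
        jit <- runif(2, -1, 1) * g$radius * 0.3
        origin <- g$center + jit
        if (sqrt(sum(jit^2)) <= g$radius * 0.3 &&
            .point_in_poly(origin, geom$soma) &&
            (is.null(geom$nucleus) || !.point_in_poly(origin, geom$nucleus)) &&
            !in_any_band(origin)) break
      }
      origin_stack <- stack_names[si]
      theta0 <- rvonmises(1, 0, config$kappa_nucleation)
    } else {
      origin <- sample_cytoplasm()
      origin_stack <- NA_character_
      theta0 <- rvonmises(1, 0, 0)
    }
    toward_axon <- .unit(geom$axon_entry - origin)
    dir <- .rotate(toward_axon, theta0)

    path <- matrix(NA_real_, nrow = config$max_frames + 1, ncol = 2)
    path[1, ] <- origin
    npts <- 1L
    change_frames <- integer(0)   # vertices where direction changed
    turn_events <- list()
    gate_contacted <- NA_character_
    gate_outcome <- NA_character_
    gate_seg <- NA_integer_
    cause <- "max_frames"
    entering <- FALSE
    enter_zone <- NULL
    last_change <- -Inf

    for (fr in seq_len(config$max_frames)) {
      pos <- path[npts, ]
      if (!entering) {
        # guided turn, with refractory period after any direction change
        if (fr > 2 && (fr - last_change) > refractory &&
            runif(1) < config$p_turn_per_frame) {
          target <- .unit(geom$axon_entry - pos)
          new_dir <- .rotate(target, rvonmises(1, 0, config$turn_jitter_kappa))
          realized <- abs(.signed_angle(dir, new_dir))
          dc <- .dist_to_poly(pos, geom$soma)
          dnuc <- if (is.null(geom$nucleus)) Inf else .dist_to_poly(pos, geom$nucleus)
          turn_events[[length(turn_events) + 1]] <-
            list(vertex = npts, angle = realized, dist_cortex = dc,
                 dist_nucleus = dnuc)
          dir <- new_dir
          change_frames <- c(change_frames, npts)
          last_change <- fr
        }
        cand <- pos + dir * step_len
        # entry-zone gating on first contact; reflection changes the step,
        # so gating is re-checked on the reflected segment
        hit <- if (is.na(gate_outcome)) find_gate(pos, cand) else NULL
        if (is.null(hit)) {
          # cortex / nuclear envelope collision: reflect
          tries <- 0L
          while (tries < 8 && !in_cytoplasm_fast(cand) &&
                 (!.point_in_poly(cand, geom$soma) ||
                  (!is.null(geom$nucleus) && .point_in_poly(cand, geom$nucleus)))) {
            if (!.point_in_poly(cand, geom$soma)) {
              nrm <- .outward_normal(geom$soma, cand)
            } else {
              nrm <- -.outward_normal(geom$nucleus, cand)
            }
            dir <- .unit(.reflect(dir, nrm))
            cand <- pos + dir * step_len
            tries <- tries + 1L
          }
          if (tries > 0) {
            change_frames <- c(change_frames, npts)
            last_change <- fr
            hit <- if (is.na(gate_outcome)) find_gate(pos, cand) else NULL
          }
          if (tries == 8) {
            # trapped in a boundary pocket: stall in place for one frame so
            # the track still has two points, then terminate
            cause <- "stuck_at_boundary"
            if (npts == 1) { npts <- 2L; path[2, ] <- pos }
            break
          }
        }
        if (!is.null(hit)) {
          zone <- zones[[hit$zi]]
          gate_contacted <- zone$neurite_name
          gate_seg <- npts
          p_enter <- if (zone$kind == "axon") config$p_enter_axon else
            config$p_enter_dendrite
          if (runif(1) < p_enter) {
            gate_outcome <- "entered"
            entering <- TRUE
            enter_zone <- zone
            contact <- pos + dir * hit$t * step_len
            # pass through the contact point, then aim through the middle
            # of the outer gate so the crossing is unambiguous
            gc_out <- (zone$outer_gate[1, ] + zone$outer_gate[2, ]) / 2
            aim <- gc_out - contact
            dir <- if (sqrt(sum(aim^2)) < 1e-9) zone$normal else .unit(aim)
            change_frames <- c(change_frames, npts)
            last_change <- fr
            cand <- contact
          } else {
            gate_outcome <- "rejected"
            contact <- pos + dir * min(hit$t + 1e-6, 1) * step_len
            # terminate inside the band, short of the outer gate
            t_out <- .seg_intersect_param(contact, contact + dir * 5,
                                          zone$outer_gate[1, ],
                                          zone$outer_gate[2, ])
            inset <- if (is.na(t_out)) 0.2 else min(0.2, 0.5 * t_out * 5)
            final <- contact + dir * inset
            npts <- npts + 1L
            path[npts, ] <- final
            cause <- "gate_rejected"
            break
          }
        }
      } else {
        cand <- path[npts, ] + dir * step_len
      }
      npts <- npts + 1L
      path[npts, ] <- cand
      if (entering) {
        gc_out <- (enter_zone$outer_gate[1, ] + enter_zone$outer_gate[2, ]) / 2
        if (sum((cand - gc_out) * enter_zone$normal) >= 1) {
          cause <- "entered_neurite"
          break
        }
      } else if (npts >= 2 && runif(1) < p_cat) {
        cause <- "catastrophe"
        break
      }
    }
    path <- path[seq_len(npts), , drop = FALSE]
    emitted <- if (config$position_noise_sd > 0) {
      path + matrix(rnorm(2 * npts, 0, config$position_noise_sd), ncol = 2)
    } else path
    # comets appear at frame 1: frame 0 is reserved for the first-frame
    # exclusion rule, which never applies to tracks born during the movie
    tt <- seq_len(npts) * config$frame_interval
    tracks[[ci]] <- comet_track(
      comet_id = sprintf("c%04d", ci), movie_id = "sim",
      t = tt, x = emitted[, 1], y = emitted[, 2],
      present_at_first_frame = FALSE,
      frame_interval = config$frame_interval)

    # ground-truth turning labels on the noise-free internal path:
    # `turned` is the angular turn signature of the pre-gate path
    # (the operational definition the classifier applies to the emitted
    # track); `clean_turn_event` is an event-log fact -- a guided turn of
    # >= 45 degrees away from boundaries with w undisturbed frames on
    # either side -- that guarantees a detectable signature
    prefix_end <- if (!is.na(gate_seg)) gate_seg else npts
    sp <- path[seq_len(prefix_end), , drop = FALSE]
    dc_sp <- .dist_to_poly(sp, geom$soma)
    dn_sp <- if (is.null(geom$nucleus)) NULL else .dist_to_poly(sp, geom$nucleus)
    turned_truth <- .turn_signature(sp, dc_sp, dn_sp, turning_params())
    clean_turn <- FALSE
    for (ev in turn_events) {
      k <- ev$vertex
      if (ev$angle < 45) next
      if (ev$dist_cortex <= 1 || ev$dist_nucleus <= 1) next
      if (k - w < 1 || k + w > prefix_end) next
      others <- setdiff(change_frames, k)
      if (any(abs(others - k) <= w)) next
      clean_turn <- TRUE
      break
    }
    max_event_angle <- if (length(turn_events) > 0) {
      max(vapply(turn_events, `[[`, numeric(1), "angle"))
    } else NA_real_
    truth[[ci]] <- data.frame(
      comet_id = sprintf("c%04d", ci),
      origin_stack = origin_stack,
      true_initial_angle = theta0,
      n_turn_events = length(turn_events),
      max_turn_angle = max_event_angle,
      turned = turned_truth,
      clean_turn_event = clean_turn,
      gate_contacted = gate_contacted,
      gate_outcome = gate_outcome,
      termination_cause = cause,
      n_frames = npts,
      stringsAsFactors = FALSE)
  }
  list(geometry = geom, tracks = tracks, truth = do.call(rbind, truth))
}
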