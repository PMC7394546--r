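#' Run the full comet-direction analysis pipeline
#'
#' Orchestrates every stage on one condition's tracks: conversion to math
#' convention, first-frame exclusion, initial growth angles relative to the
#' axon entry site, per-Golgi-stack normalised resultant vectors with the
#' upper-quadrant binomial test, the Monte-Carlo uniform-angle null and the
#' resultant-length comparison, entry-zone approach/entry classification,
#' turning detection, proximal-dendrite polarity, and the event summary
#' table with Wilson 95% intervals.
#'
#' @param tracks List of `comet_track` objects.
#' @param geometry A `neuron_geometry` (any y-axis convention; converted).
#' @param condition Condition label for the summary table.
#' @param n_direction_points Leading points for the initial direction
#'   (default 3).
#' @param zone_width,caliber Entry-zone geometry (defaults 0.5 and 2 um).
#' @param turning A [turning_params()] object.
#' @param angle_bins Bin edges in degrees for the folded-angle histogram
#'   (default 12 bins of 15 degrees).
#' @param length_bins Bin edges on `[0, 1]` for resultant lengths.
#' @param null_replicates Replicate null data sets (default 3).
#' @param seed Seed for the Monte-Carlo null.
#' @param apply_first_frame_filter Apply the first-frame exclusion
#'   (default TRUE).
#' @return An object of class `comet_analysis`; see Details.
#'
#' @details The returned object contains `angles` (per-comet data frame),
#'   `resultants` (per-stack data frame, stacks with >= 2 comets),
#'   `quadrant` (upper-quadrant [proportion()]), `quadrant_binomial_p`
#'   (exact upper tail at p0 = 0.5), `angle_test` (folded angles vs
#'   uniform), `null` (the `null_distribution`), `length_comparison`
#'   (observed vs null lengths), `events` (per-comet classification),
#'   `summary` (the event table) and `params`.
#' @export
analyze_comets <- function(tracks, geometry, condition = "all",
                           n_direction_points = 3,
                           zone_width = 0.5, caliber = 2,
                           turning = turning_params(),
                           angle_bins = seq(0, 180, by = 15),
                           length_bins = seq(0, 1, by = 0.1),
                           null_replicates = 3,
                           seed = 1,
                           apply_first_frame_filter = TRUE) {
  stopifnot(inherits(geometry, "neuron_geometry"))
  conv <- as_math_convention(geometry, tracks)
  geometry <- conv$geometry
  tracks <- conv$tracks
  if (apply_first_frame_filter) tracks <- filter_first_frame(tracks)

  zones <- c(list(build_entry_zone(geometry, "axon", width = zone_width,
                                   caliber = caliber)),
             lapply(names(geometry$dendrite_entries), function(nm) {
               build_entry_zone(geometry, nm, width = zone_width,
                                caliber = caliber)
             }))
  names(zones) <- vapply(zones, `[[`, character(1), "neurite_name")
  dendrites_with_bp <- names(geometry$dendrite_branchpoints)

  angle_rows <- list()
  event_rows <- list()
  for (tr in tracks) {
    origin_in_soma <- .point_in_poly(.track_points(tr)[1, ], geometry$soma)
    ga <- if (origin_in_soma) {
      tryCatch(initial_growth_angle(tr, geometry, n_direction_points),
               error = function(e) NULL)
    } else NULL
    if (!is.null(ga)) {
      angle_rows[[length(angle_rows) + 1]] <- data.frame(
        comet_id = ga$comet_id, movie_id = tr$movie_id,
        theta_signed = ga$theta_signed, theta_folded = ga$theta_folded,
        origin_stack = ga$origin_stack, stringsAsFactors = FALSE)
    }
    if (origin_in_soma) {
      ae <- classify_approach_entry(tr, zones, geometry)
      tu <- detect_turning(tr, geometry, turning, zones)
      dendr <- intersect(ae$approached[!ae$approached %in% "axon"],
                         names(geometry$dendrite_entries))
      pol <- NA_character_
      for (dn in dendrites_with_bp) {
        pol_try <- tryCatch(
          suppressMessages(classify_dendrite_polarity(
            tr, geometry, dn, zone_width = zone_width, caliber = caliber)),
          error = function(e) NA_character_)
        if (!is.na(pol_try)) { pol <- pol_try; break }
      }
      event_rows[[length(event_rows) + 1]] <- data.frame(
        comet_id = tr$comet_id, movie_id = tr$movie_id,
        approached_first = if (length(ae$approached) > 0) ae$approached[1] else NA_character_,
        approached_axon = "axon" %in% ae$approached,
        approached_dendrite = length(dendr) > 0,
        entered = ae$entered,
        entered_axon = identical(ae$entered, "axon"),
        entered_dendrite = !is.na(ae$entered) && ae$entered != "axon",
        qualifies = tu$qualifies, turned = tu$turned,
        cortex_traveller = tu$cortex_traveller,
        dendrite_polarity = pol,
        origin_in_zone = ae$origin_in_zone,
        stringsAsFactors = FALSE)
    }
  }
  angles <- if (length(angle_rows) > 0) do.call(rbind, angle_rows) else
    data.frame(comet_id = character(0), movie_id = character(0),
               theta_signed = numeric(0), theta_folded = numeric(0),
               origin_stack = character(0))
  events <- if (length(event_rows) > 0) do.call(rbind, event_rows) else NULL

  # per-stack resultants (Golgi-origin comets, stacks with >= 2 comets)
  golgi_angles <- angles[!is.na(angles$origin_stack), , drop = FALSE]
  res_list <- list()
  if (nrow(golgi_angles) > 0) {
    for (sid in sort(unique(golgi_angles$origin_stack))) {
      th <- golgi_angles$theta_signed[golgi_angles$origin_stack == sid]
      if (length(th) >= 2) {
        res_list[[length(res_list) + 1]] <- stack_resultant(sid, th)
      }
    }
  }
  resultants <- resultant_table(res_list)

  quadrant <- NULL
  quadrant_binomial_p <- NA_real_
  null_dist <- NULL
  length_comparison <- NULL
  if (length(res_list) > 0) {
    quadrant <- suppressMessages(upper_quadrant_fraction(res_list))
    quadrant_binomial_p <- binomial_upper_tail(quadrant$k, quadrant$n, 0.5)
    null_dist <- random_null(resultants$n_comets,
                             n_replicates = null_replicates, seed = seed)
    length_comparison <- compare_length_distributions(
      resultants$d, null_dist, bins = length_bins)
  }

  # folded-angle histogram of Golgi-origin comets vs uniform
  angle_test <- NULL
  angle_hist <- NULL
  if (nrow(golgi_angles) > 0) {
    cuts <- findInterval(golgi_angles$theta_folded, angle_bins,
                         rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(cuts, nbins = length(angle_bins) - 1)
    widths <- diff(angle_bins)
    angle_hist <- data.frame(bin_low = angle_bins[-length(angle_bins)],
                             bin_high = angle_bins[-1], count = counts)
    angle_test <- chisq_gof(counts, widths / sum(widths))
  }

  structure(
    list(condition = condition,
         angles = angles, resultants = resultants,
         quadrant = quadrant, quadrant_binomial_p = quadrant_binomial_p,
         angle_hist = angle_hist, angle_test = angle_test,
         null = null_dist, length_comparison = length_comparison,
         events = events,
         summary = tabulate_events(events, condition = condition),
         geometry = geometry,
         params = list(condition = condition,
                       n_direction_points = n_direction_points,
                       zone_width = zone_width, caliber = caliber,
                       turning = unclass(turning),
                       angle_bins = angle_bins, length_bins = length_bins,
                       null_replicates = null_replicates, seed = seed,
                       apply_first_frame_filter = apply_first_frame_filter,
                       n_tracks_analyzed = length(tracks))),
    class = "comet_analysis")
}

#' @export
print.comet_analysis <- function(x, ...) {
  cat("<comet_analysis> condition '", x$condition, "': ",
      x$params$n_tracks_analyzed, " tracks, ",
      nrow(x$angles), " measurable angles, ",
      nrow(x$resultants), " Golgi stacks with >= 2 comets\n", sep = "")
  if (!is.null(x$quadrant)) {
    cat("  upper-quadrant resultants: ")
    print(x$quadrant)
    cat("  binomial upper tail (p0 = 0.5): p = ",
        signif(x$quadrant_binomial_p, 3), "\n", sep = "")
  }
  if (!is.null(x$angle_test)) {
    cat("  folded angles vs uniform: ")
    print(x$angle_test)
  }
  if (!is.null(x$length_comparison)) {
    cat("  resultant lengths vs Monte-Carlo null: ")
    print(x$length_comparison$test)
  }
  invisible(x)
}

#' @export
summary.comet_analysis <- function(object, ...) {
  object$summary
}

#' @export
plot.comet_analysis <- function(x, which = c("angles", "resultants",
                                             "lengths", "events"), ...) {
  which <- match.arg(which)
  if (which == "angles" && !is.null(x$angle_hist)) {
    barplot(x$angle_hist$count,
            names.arg = paste0(x$angle_hist$bin_low, "-", x$angle_hist$bin_high),
            xlab = "initial growth angle from axon entry (deg, folded)",
            ylab = "comets", main = x$condition, las = 2)
  } else if (which == "resultants" && nrow(x$resultants) > 0) {
    plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
         xlab = "resultant x", ylab = "resultant y (towards axon)",
         main = paste0(x$condition, ": per-stack resultants"))
    abline(h = 0, v = 0, col = "grey70")
    symbols(x$resultants$x, x$resultants$y,
            circles = sqrt(x$resultants$n_comets) * 0.04,
            inches = FALSE, add = TRUE, fg = "steelblue")
  } else if (which == "lengths" && !is.null(x$length_comparison)) {
    tab <- x$length_comparison$table
    bp <- rbind(observed = tab$obs_freq, null = tab$null_freq)
    barplot(bp, beside = TRUE, names.arg = paste0(tab$bin_low, "-", tab$bin_high),
            legend.text = TRUE, las = 2,
            xlab = "resultant length d", ylab = "frequency",
            main = paste0(x$condition, ": observed vs uniform null"))
  } else if (which == "events" && nrow(x$summary) > 0) {
    ok <- !is.na(x$summary$percent)
    barplot(x$summary$percent[ok], names.arg = x$summary$metric[ok],
            ylab = "% of comets", las = 2, main = x$condition)
  }
  invisible(x)
}

#' Pairwise comparison of event proportions between two conditions
#'
#' Runs [compare_proportions()] on each shared metric of two
#' `comet_analysis` summary tables.
#'
#' @param a,b `comet_analysis` objects.
#' @return Data frame with per-metric counts and chi-squared p-values.
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "comet_analysis"), inherits(b, "comet_analysis"))
  shared <- intersect(a$summary$metric, b$summary$metric)
  rows <- lapply(shared, function(m) {
    ra <- a$summary[a$summary$metric == m, ]
    rb <- b$summary[b$summary$metric == m, ]
    if (ra$n == 0 || rb$n == 0) return(NULL)
    cp <- suppressMessages(compare_proportions(ra$k, ra$n, rb$k, rb$n))
    data.frame(metric = m,
               condition_1 = a$condition, k1 = ra$k, n1 = ra$n,
               condition_2 = b$condition, k2 = rb$k, n2 = rb$n,
               statistic = cp$statistic, p_value = cp$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report bundle for one or more analyses
#'
#' Serialises every table of the analysis as delimited text (angles,
#' per-stack resultants, null summary, per-comet events, event summary
#' with Wilson intervals, pairwise condition comparisons) plus a
#' machine-readable JSON manifest of all parameters, seeds and the package
#' version, so each reported number traces to a serialised object.
#'
#' @param analyses A `comet_analysis` or list of them.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analyses, dir) {
  if (inherits(analyses, "comet_analysis")) analyses <- list(analyses)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  for (x in analyses) {
    pre <- paste0(gsub("[^A-Za-z0-9_.-]", "_", x$condition), "_")
    wr(x$angles, paste0(pre, "angles.tsv"))
    if (nrow(x$resultants) > 0) wr(x$resultants, paste0(pre, "resultants.tsv"))
    if (!is.null(x$null)) {
      null_sum <- data.frame(
        replicate = seq_along(x$null$replicate_lengths),
        mean_d = vapply(x$null$replicate_lengths, mean, numeric(1)),
        n_stacks = length(x$null$comet_counts))
      wr(null_sum, paste0(pre, "null_summary.tsv"))
    }
    if (!is.null(x$length_comparison)) {
      wr(x$length_comparison$table, paste0(pre, "length_distribution.tsv"))
    }
    if (!is.null(x$angle_hist)) wr(x$angle_hist, paste0(pre, "angle_histogram.tsv"))
    if (!is.null(x$events)) wr(x$events, paste0(pre, "events.tsv"))
    wr(x$summary, paste0(pre, "summary.tsv"))
  }
  if (length(analyses) > 1) {
    cmp <- list()
    for (i in seq_len(length(analyses) - 1)) {
      for (j in (i + 1):length(analyses)) {
        cmp[[length(cmp) + 1]] <- compare_conditions(analyses[[i]], analyses[[j]])
      }
    }
    wr(do.call(rbind, cmp), "comparisons.tsv")
  }
  manifest <- list(
    package = "eb1comet",
    version = as.character(packageVersion("eb1comet")),
    conditions = lapply(analyses, function(x) x$params))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
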