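#' Unit direction vector of a comet angle
#'
#' Maps a signed growth angle to a unit vector in the axon-referenced frame:
#' the Y component is `cos(theta)` (the toward-axon axis, so 0 degrees maps
#' to the positive Y-axis) and the X component is `sin(theta)`.
#'
#' @param theta_signed Numeric vector of angles in degrees in (-180, 180].
#' @return A matrix with columns `x` and `y`; unit rows.
#' @export
comet_unit_vector <- function(theta_signed) {
  if (any(!is.finite(theta_signed)) ||
      any(theta_signed <= -180 | theta_signed > 180)) {
    stop("theta_signed must lie in (-180, 180]")
  }
  r <- .deg2rad(theta_signed)
  cbind(x = sin(r), y = cos(r))
}

#' Normalised resultant vector of one Golgi stack's comet angles
#'
#' Each comet contributes a unit vector ([comet_unit_vector()]); the
#' resultant is their sum normalised by the number of comets, so its length
#' `d` lies in `[0, 1]`: 1 when all comet angles coincide, 0 when they
#' cancel. Only stacks that generated more than one comet are summarised.
#'
#' @param stack_id Stack identifier.
#' @param angles Signed comet angles in degrees (at least 2).
#' @return An object of class `stack_resultant`: list with `stack_id`,
#'   `n_comets`, `resultant_x`, `resultant_y`, `length_d` and `mean_angle`
#'   (degrees from the toward-axon axis, signed).
#' @export
stack_resultant <- function(stack_id, angles) {
  if (length(angles) < 2) {
    stop("stack '", stack_id, "' has fewer than 2 comets; stacks with a ",
         "single comet are excluded from resultant analysis")
  }
  uv <- comet_unit_vector(angles)
  rx <- mean(uv[, "x"])
  ry <- mean(uv[, "y"])
  d <- sqrt(rx^2 + ry^2)
  structure(
    list(stack_id = as.character(stack_id), n_comets = length(angles),
         resultant_x = rx, resultant_y = ry, length_d = d,
         mean_angle = .rad2deg(atan2(rx, ry))),
    class = "stack_resultant")
}

#' @export
print.stack_resultant <- function(x, ...) {
  cat("<stack_resultant> ", x$stack_id, ": n = ", x$n_comets,
      ", d = ", signif(x$length_d, 4),
      ", mean angle = ", signif(x$mean_angle, 4), " deg\n", sep = "")
  invisible(x)
}

#' Summarise resultants into a data frame
#'
#' @param resultants List of `stack_resultant` objects.
#' @return Data frame with one row per stack.
#' @export
resultant_table <- function(resultants) {
  do.call(rbind, lapply(resultants, function(r) {
    data.frame(stack_id = r$stack_id, n_comets = r$n_comets,
               x = r$resultant_x, y = r$resultant_y,
               d = r$length_d, mean_angle = r$mean_angle,
               stringsAsFactors = FALSE)
  }))
}

#' Fraction of stack resultants pointing towards the axon
#'
#' A resultant with positive Y component points, on average, towards the
#' axon (upper quadrants of the resultant scatter). Resultants with Y
#' exactly 0 count as neither and are dropped from the denominator with a
#' message.
#'
#' @param resultants Non-empty list of `stack_resultant` objects.
#' @return A [proportion()] result (k upper-quadrant stacks out of n).
#' @export
upper_quadrant_fraction <- function(resultants) {
  if (length(resultants) == 0) stop("empty resultant list")
  ys <- vapply(resultants, function(r) r$resultant_y, numeric(1))
  on_axis <- sum(ys == 0)
  if (on_axis > 0) {
    message(on_axis, " resultant(s) with y exactly 0 excluded from the ",
            "upper-quadrant denominator")
  }
  proportion(sum(ys > 0), length(ys) - on_axis)
}

#' Monte-Carlo uniform-angle null for resultant lengths
#'
#' For each replicate and each stack size `n` in `comet_counts`, draws `n`
#' angles uniformly on (-180, 180) and computes the normalised resultant
#' length, emulating comet angles that are independent of each other and of
#' the axon position. Per-replicate RNG substreams are derived from the
#' single top-level seed (via `sample.int` under that seed), so results are
#' reproducible and replicates are independent.
#'
#' @param comet_counts Integer vector of per-stack comet counts (all >= 2).
#' @param n_replicates Number of replicate null data sets (default 3).
#' @param seed Integer seed.
#' @return An object of class `null_distribution`: list with
#'   `replicate_lengths` (list of numeric vectors), `replicates` (list of
#'   data frames with per-stack `n`, `x`, `y`, `d`), `comet_counts`,
#'   `n_replicates`, `seed`.
#' @export
random_null <- function(comet_counts, n_replicates = 3, seed = 1) {
  comet_counts <- as.integer(comet_counts)
  if (length(comet_counts) == 0 || any(comet_counts < 2)) {
    stop("all comet counts must be >= 2")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(as.integer(seed))
  substreams <- sample.int(.Machine$integer.max, n_replicates)
  replicates <- lapply(seq_len(n_replicates), function(r) {
    set.seed(substreams[r])
    total <- sum(comet_counts)
    ang <- runif(total, -180, 180)
    idx <- rep(seq_along(comet_counts), comet_counts)
    rxy <- .deg2rad(ang)
    x <- tapply(sin(rxy), idx, mean)
    y <- tapply(cos(rxy), idx, mean)
    data.frame(n = comet_counts, x = as.numeric(x), y = as.numeric(y),
               d = sqrt(as.numeric(x)^2 + as.numeric(y)^2))
  })
  structure(
    list(replicate_lengths = lapply(replicates, `[[`, "d"),
         replicates = replicates,
         comet_counts = comet_counts,
         n_replicates = n_replicates, seed = as.integer(seed)),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_replicates, " replicate(s) of ",
      length(x$comet_counts), " stack(s); mean length_d = ",
      signif(mean(unlist(x$replicate_lengths)), 4),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Compare observed resultant lengths against the uniform null
#'
#' Bins observed and pooled-null resultant lengths on `[0, 1]` and tests the
#' observed bin counts against the null bin proportions with a one-way
#' chi-squared goodness-of-fit test ([chisq_gof()]). Bins in which the
#' pooled null has zero mass are merged into their lower neighbour (or the
#' first positive bin) so that all expected counts are positive.
#'
#' @param observed Numeric vector of observed resultant lengths in `[0, 1]`.
#' @param null A `null_distribution`.
#' @param bins Bin edges covering `[0, 1]` (default 10 equal bins).
#' @return List with `table` (per-bin observed/null frequencies) and `test`
#'   (a `chisq_result`).
#' @export
compare_length_distributions <- function(observed, null,
                                         bins = seq(0, 1, by = 0.1)) {
  if (length(observed) == 0) stop("empty observed length vector")
  stopifnot(inherits(null, "null_distribution"))
  bins <- sort(unique(as.numeric(bins)))
  if (length(bins) < 2 || bins[1] > 0 || bins[length(bins)] < 1) {
    stop("bins must cover [0, 1]")
  }
  if (any(observed < bins[1] | observed > bins[length(bins)])) {
    stop("observed lengths fall outside the bin range")
  }
  bin_of <- function(v) {
    i <- findInterval(v, bins, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(i, nbins = length(bins) - 1)
  }
  obs_counts <- bin_of(observed)
  null_counts <- bin_of(unlist(null$replicate_lengths))
  tab <- data.frame(
    bin_low = bins[-length(bins)], bin_high = bins[-1],
    obs_count = obs_counts,
    obs_freq = obs_counts / sum(obs_counts),
    null_freq = null_counts / sum(null_counts))
  # merge zero-mass null bins so expected counts are all positive
  grp <- seq_along(obs_counts)
  for (i in seq_along(grp)) {
    if (null_counts[i] == 0) {
      grp[i] <- if (i > 1) grp[i - 1] else NA_integer_
    }
  }
  if (anyNA(grp)) {
    first_pos <- which(null_counts > 0)[1]
    if (is.na(first_pos)) stop("null distribution has no mass in any bin")
    grp[is.na(grp)] <- first_pos
  }
  grp <- match(grp, unique(grp))
  obs_m <- as.numeric(tapply(obs_counts, grp, sum))
  null_m <- as.numeric(tapply(null_counts, grp, sum))
  test <- chisq_gof(obs_m, null_m / sum(null_m))
  list(table = tab, test = test)
}
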