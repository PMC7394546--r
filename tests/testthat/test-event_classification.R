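zones_for <- function(geom) {
  zs <- c(list(build_entry_zone(geom, "axon")),
          lapply(names(geom$dendrite_entries),
                 function(nm) build_entry_zone(geom, nm)))
  names(zs) <- vapply(zs, `[[`, character(1), "neurite_name")
  zs
}

test_that("approach and entry are scored by band contact and gate crossing", {
  geom <- square_geometry()
  zs <- zones_for(geom)
  # stops 1 um short of the axon band (band starts at y = 4.75)
  r <- classify_approach_entry(line_track(c(0, 0), c(0, 3.7)), zs, geom)
  expect_length(r$approached, 0)
  expect_true(is.na(r$entered))
  # reaches into the band but terminates inside it
  r <- classify_approach_entry(line_track(c(0, 0), c(0, 4.9), n = 11), zs, geom)
  expect_equal(r$approached, "axon")
  expect_true(is.na(r$entered))
  # crosses both gates out of the soma
  r <- classify_approach_entry(line_track(c(0, 0), c(0, 6), n = 13), zs, geom)
  expect_equal(r$approached, "axon")
  expect_equal(r$entered, "axon")
  # dendrite path
  r <- classify_approach_entry(line_track(c(-2.5, 0), c(-2.5, -6), n = 13),
                               zs, geom)
  expect_equal(r$approached, "d_left")
  expect_equal(r$entered, "d_left")
})

test_that("a comet that retreats from one zone and enters another approaches both", {
  geom <- square_geometry()
  zs <- zones_for(geom)
  pts <- rbind(c(2.5, -3), c(2.5, -4), c(2.5, -4.8),  # touch d_right band
               c(2.5, -4), c(2.5, -2), c(2.5, 0),     # retreat
               c(1.5, 2), c(0.5, 4), c(0, 4.8), c(0, 5.6), c(0, 6.4))
  r <- classify_approach_entry(pts_track(pts), zs, geom)
  expect_equal(r$approached, c("d_right", "axon"))
  expect_equal(r$entered, "axon")
})

test_that("comets originating inside an entry zone are flagged for exclusion", {
  geom <- square_geometry()
  zs <- zones_for(geom)
  r <- classify_approach_entry(line_track(c(0, 4.9), c(0, 3), n = 5), zs, geom)
  expect_true(r$origin_in_zone)
  expect_length(r$approached, 0)
})

test_that("overlapping zones are a geometry error", {
  geom <- neuron_geometry(
    soma = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
    axon_entry = c(0, 5),
    dendrite_entries = list(d1 = c(0.5, 5)),  # 0.5 um from the axon entry
    frame_interval = 5, y_axis = "math")
  zs <- zones_for(geom)
  expect_error(classify_approach_entry(line_track(c(0, 0), c(0, 3)), zs, geom),
               "overlap")
})

test_that("turning qualification follows the path-length and cortex rules", {
  geom <- square_geometry()
  # straight 5 um mid-soma: qualifies, does not turn
  r <- detect_turning(line_track(c(-2.5, 0), c(2.5, 0), n = 11), geom)
  expect_true(r$qualifies)
  expect_false(r$turned)
  expect_false(r$cortex_traveller)
  # 1.5 um track: below the > 2 um qualification threshold
  r <- detect_turning(line_track(c(0, 0), c(0, 1.5), n = 4), geom)
  expect_false(r$qualifies)
  # hugging the boundary: cortex traveller
  r <- detect_turning(line_track(c(-2, 4.5), c(2, 4.5), n = 9), geom)
  expect_false(r$qualifies)
  expect_true(r$cortex_traveller)
  # shorter than the smoothing window: no exception, logged reason
  two <- comet_track("s", "m", t = c(0, 5), x = c(0, 0.1), y = c(0, 0))
  r <- detect_turning(two, geom)
  expect_false(r$qualifies)
  expect_match(r$reason, "within-soma")
})

test_that("a 90-degree mid-soma bend is a turn; a boundary collision is not", {
  geom <- neuron_geometry(
    soma = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
    nucleus = rbind(c(-1, 2.4), c(1, 2.4), c(1, 3.4), c(-1, 3.4)),
    axon_entry = c(0, 5),
    frame_interval = 5, y_axis = "math")
  # single 90-degree bend, 3+ um from every boundary
  bend <- rbind(cbind(seq(-2, 0, 0.5), -1), cbind(0, seq(-0.5, 1.5, 0.5)))
  r <- detect_turning(pts_track(bend), geom)
  expect_true(r$qualifies)
  expect_true(r$turned)
  # same shape but the vertex sits against the nuclear envelope: a collision
  coll <- rbind(cbind(seq(-2, 0, 0.5), 2.2), cbind(0, seq(1.7, -0.3, -0.5)))
  r2 <- detect_turning(pts_track(coll), geom)
  expect_true(r2$qualifies)
  expect_false(r2$turned)
})

test_that("turning analysis ignores direction changes beyond an entry gate", {
  geom <- square_geometry()
  # straight to the axon, enters, then bends outside the soma
  pts <- rbind(cbind(0, seq(0, 5.5, 0.5)), cbind(c(0.5, 1), 5.5))
  r <- detect_turning(pts_track(pts), geom)
  expect_false(r$turned)
})

test_that("turning parameters are validated", {
  expect_error(turning_params(min_path_length = 0), "positive")
  expect_error(turning_params(turn_angle_threshold = 180), "0, 180")
  p <- turning_params(min_path_length = 3, turn_angle_threshold = 60)
  expect_equal(p$min_path_length, 3)
})

test_that("dendrite polarity follows net displacement along the dendrite axis", {
  geom <- square_geometry()  # d_left entry (-2.5,-5), branchpoint (-2.5,-8)
  away <- line_track(c(-2.5, -5.3), c(-2.5, -7.5), n = 6)
  expect_equal(classify_dendrite_polarity(away, geom, "d_left"), "anterograde")
  toward <- line_track(c(-2.5, -7.5), c(-2.5, -5.3), n = 6)
  expect_equal(classify_dendrite_polarity(toward, geom, "d_left"), "retrograde")
  # below the noise floor: indeterminate, with a message
  wiggle <- comet_track("w", "m", t = c(0, 5, 10),
                        x = rep(-2.5, 3), y = c(-6, -6.04, -6.05))
  expect_message(pol <- classify_dendrite_polarity(wiggle, geom, "d_left"),
                 "noise floor")
  expect_equal(pol, "indeterminate")
  # never inside the proximal segment
  expect_error(classify_dendrite_polarity(line_track(c(0, 0), c(1, 1)),
                                          geom, "d_left"),
               "fewer than 2 points")
  expect_error(classify_dendrite_polarity(away, geom, "nope"), "no dendrite")
})

test_that("event tabulation reproduces counts and flags empty denominators", {
  ev <- data.frame(
    approached_axon = rep(c(TRUE, FALSE), c(104, 666 - 104)),
    approached_dendrite = rep(c(FALSE, TRUE, FALSE), c(104, 47, 515)),
    entered_axon = rep(c(TRUE, FALSE), c(56, 610)),
    entered_dendrite = rep(c(FALSE, TRUE, FALSE), c(104, 13, 549)),
    qualifies = FALSE, turned = FALSE,
    dendrite_polarity = NA_character_, origin_in_zone = FALSE)
  tab <- tabulate_events(ev, condition = "control")
  get <- function(m) tab[tab$metric == m, ]
  expect_equal(round(get("approached_axon")$percent, 1), 15.6)
  expect_equal(round(get("approached_dendrite")$percent, 1), 7.1)
  expect_equal(round(get("entered_axon_of_approached")$percent, 1), 53.8)
  expect_equal(round(get("entered_dendrite_of_approached")$percent, 1), 27.7)
  expect_equal(round(get("entered_axon_of_all")$percent, 1), 8.4)
  expect_equal(round(get("entered_dendrite_of_all")$percent, 1), 2.0)
  expect_true(all(!is.na(get("approached_axon")[c("ci_low", "ci_high")])))
  # empty input: zero denominators, flagged not crashed
  tab0 <- tabulate_events(NULL)
  expect_true(all(tab0$n == 0))
  expect_true(all(is.na(tab0$percent)))
})

test_that("approach classification conserves comets and entry implies approach", {
  cfg <- simulation_config(n_comets = 120, seed = 31, position_noise_sd = 0)
  sim <- simulate_neuron(cfg)
  zs <- zones_for(sim$geometry)
  app_counts <- c(axon = 0, dendrite = 0, none = 0)
  for (tr in sim$tracks) {
    r <- classify_approach_entry(tr, zs, sim$geometry)
    if (!is.na(r$entered)) expect_true(r$entered %in% r$approached)
    first <- if (length(r$approached) > 0) r$approached[1] else "none"
    key <- if (first == "axon") "axon" else if (first == "none") "none" else "dendrite"
    app_counts[key] <- app_counts[key] + 1
  }
  expect_equal(sum(app_counts), 120)
})

test_that("classifications are invariant under rotation of the whole scene", {
  geom <- square_geometry()
  pts <- rbind(cbind(seq(-2, 0, 0.5), -1), cbind(0, seq(-0.5, 1.5, 0.5)))
  r0 <- detect_turning(pts_track(pts), geom)
  deg <- 137
  geom_r <- neuron_geometry(
    soma = rotate_pts(geom$soma, deg),
    axon_entry = drop(rotate_pts(rbind(geom$axon_entry), deg)),
    dendrite_entries = lapply(geom$dendrite_entries,
                              function(p) drop(rotate_pts(rbind(p), deg))),
    frame_interval = 5, y_axis = "math")
  r1 <- detect_turning(pts_track(rotate_pts(pts, deg)), geom_r)
  expect_equal(r1$qualifies, r0$qualifies)
  expect_equal(r1$turned, r0$turned)
})
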