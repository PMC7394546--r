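test_that("fold_angle folds onto [0, 180], is idempotent, rejects out-of-range", {
  expect_equal(fold_angle(-135), 135)
  expect_equal(fold_angle(0), 0)
  expect_equal(fold_angle(180), 180)
  th <- seq(0, 180, by = 7.5)
  expect_equal(fold_angle(th), th)  # idempotent on [0, 180]
  expect_error(fold_angle(-180), "-180, 180")
  expect_error(fold_angle(200), "-180, 180")
})

test_that("initial growth angle matches the axon-referenced convention", {
  geom <- square_geometry()  # axon entry at (0, 5)
  # straight at the axon entry
  ga <- initial_growth_angle(line_track(c(0, 0), c(0, 2)), geom)
  expect_equal(ga$theta_signed, 0, tolerance = 1e-9)
  # diametrically away
  ga <- initial_growth_angle(line_track(c(0, 0), c(0, -2)), geom)
  expect_equal(ga$theta_folded, 180, tolerance = 1e-9)
  # perpendicular: growth along +x is clockwise from the +y axon ray
  ga <- initial_growth_angle(line_track(c(0, 0), c(2, 0)), geom)
  expect_equal(ga$theta_signed, -90, tolerance = 1e-9)
  expect_equal(ga$theta_folded, 90, tolerance = 1e-9)
  # counterclockwise positive
  ga <- initial_growth_angle(line_track(c(0, 0), c(-2, 0)), geom)
  expect_equal(ga$theta_signed, 90, tolerance = 1e-9)
})

test_that("growth angle errors on undefined direction or outside origin", {
  geom <- square_geometry()
  expect_error(initial_growth_angle(line_track(c(0, 8), c(0, 9)), geom),
               "outside the soma")
  still <- comet_track("s", "m", t = c(0, 5, 10), x = rep(1, 3), y = rep(1, 3))
  expect_error(initial_growth_angle(still, geom), "zero net displacement")
  short <- comet_track("s", "m", t = c(0, 5), x = c(0, 1), y = c(0, 1))
  expect_error(initial_growth_angle(short, geom, n_direction_points = 3),
               "fewer than 3")
})

test_that("growth angle is rotation-invariant and mirror-antisymmetric", {
  set.seed(42)
  for (rep in 1:20) {
    origin <- runif(2, -3, 3)
    step <- runif(2, -0.5, 0.5)
    pts <- rbind(origin, origin + step, origin + 2 * step)
    geom <- square_geometry()
    ga0 <- initial_growth_angle(pts_track(pts), geom)
    # common rotation of geometry and track about the origin
    deg <- runif(1, 0, 360)
    geom_r <- neuron_geometry(
      soma = rotate_pts(geom$soma, deg),
      axon_entry = drop(rotate_pts(rbind(geom$axon_entry), deg)),
      frame_interval = 5, y_axis = "math")
    ga_r <- initial_growth_angle(pts_track(rotate_pts(pts, deg)), geom_r)
    expect_equal(ga_r$theta_signed, ga0$theta_signed, tolerance = 1e-6)
    # mirror across the y axis (the origin-axon axis of the square geometry
    # lies along y only when origin is on x = 0, so mirror everything)
    geom_m <- neuron_geometry(
      soma = cbind(-geom$soma[, 1], geom$soma[, 2]),
      axon_entry = c(-geom$axon_entry[1], geom$axon_entry[2]),
      frame_interval = 5, y_axis = "math")
    ga_m <- initial_growth_angle(pts_track(cbind(-pts[, 1], pts[, 2])), geom_m)
    expect_equal(ga_m$theta_signed, -ga0$theta_signed, tolerance = 1e-6)
    expect_equal(ga_m$theta_folded, ga0$theta_folded, tolerance = 1e-6)
  }
})

test_that("origin is assigned to the nearest Golgi stack within its radius", {
  geom <- square_geometry(golgi = list(
    g_far = list(center = c(3, 3), radius = 1),
    g_near = list(center = c(0.4, 0), radius = 1),
    g_also = list(center = c(-0.6, 0), radius = 1)))
  ga <- initial_growth_angle(line_track(c(0, 0), c(0, 2)), geom)
  expect_equal(ga$origin_stack, "g_near")
  # no stack within radius
  ga2 <- initial_growth_angle(line_track(c(-3, -3), c(-3, -1)), geom)
  expect_true(is.na(ga2$origin_stack))
  # exact tie breaks lexicographically, with a message
  geom_tie <- square_geometry(golgi = list(
    b = list(center = c(0.5, 0), radius = 1),
    a = list(center = c(-0.5, 0), radius = 1)))
  expect_message(
    ga3 <- initial_growth_angle(line_track(c(0, 0), c(0, 2)), geom_tie),
    "lexicographically")
  expect_equal(ga3$origin_stack, "a")
})

test_that("entry zones straddle the boundary with parallel gates", {
  geom <- square_geometry()
  z <- build_entry_zone(geom, "axon", width = 0.5)
  # square top edge at y = 5: gates horizontal at y = 4.75 and 5.25
  expect_equal(unique(z$inner_gate[, 2]), 4.75, tolerance = 1e-9)
  expect_equal(unique(z$outer_gate[, 2]), 5.25, tolerance = 1e-9)
  expect_equal(z$normal, c(0, 1), tolerance = 1e-9)
  expect_error(build_entry_zone(geom, "axon", width = 0), "width")
  expect_error(build_entry_zone(geom, "no_such"), "no dendrite")
})

test_that("gates on a curved boundary are perpendicular to the analytic normal", {
  # circular soma: the boundary normal at angle phi is (cos phi, sin phi)
  angs <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(4 * cos(angs), 4 * sin(angs))
  phi <- 2 * pi * 50 / 360  # a dendrite entry at vertex 51
  geom <- neuron_geometry(soma = circ, axon_entry = c(0, 4),
                          dendrite_entries = list(d1 = circ[51, ]),
                          frame_interval = 5, y_axis = "math")
  z <- build_entry_zone(geom, "d1")
  analytic <- c(cos(phi), sin(phi))
  dev <- acos(min(1, abs(sum(z$normal * analytic))))
  # 1-degree polygon discretisation: normal within half the edge angle
  expect_lt(dev, 2 * pi / 360)
  gate_dir <- z$outer_gate[2, ] - z$outer_gate[1, ]
  expect_equal(abs(sum(gate_dir * z$normal)), 0, tolerance = 1e-9)
})

test_that("distance to cortex matches a brute-force boundary-sampling oracle", {
  geom <- square_geometry()
  d <- distance_to_cortex(c(0, 0), geom)
  expect_equal(unname(d["cortex"]), 5)
  expect_equal(unname(distance_to_cortex(c(4.8, 0), geom)["cortex"]), 0.2)
  expect_error(distance_to_cortex(c(9, 9), geom), "outside")

  # brute-force oracle: dense boundary sampling of an irregular polygon
  poly <- rbind(c(0, 0), c(6, -1), c(8, 3), c(4, 6), c(-1, 4))
  geom_i <- neuron_geometry(soma = poly, axon_entry = c(4, 6),
                            frame_interval = 5, y_axis = "math")
  dense <- do.call(rbind, lapply(seq_len(nrow(poly)), function(i) {
    a <- poly[i, ]; b <- poly[if (i == nrow(poly)) 1 else i + 1, ]
    s <- seq(0, 1, length.out = 4000)
    cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
  }))
  set.seed(7)
  n_checked <- 0
  while (n_checked < 25) {
    p <- c(runif(1, -1, 8), runif(1, -1, 6))
    inside <- tryCatch(distance_to_cortex(p, geom_i), error = function(e) NULL)
    if (is.null(inside)) next
    brute <- min(sqrt((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2))
    expect_equal(unname(inside["cortex"]), brute, tolerance = 1e-3)
    n_checked <- n_checked + 1
  }
})

test_that("nucleus distance is reported when a nucleus is present", {
  geom <- neuron_geometry(
    soma = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
    nucleus = rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
    axon_entry = c(0, 5), frame_interval = 5, y_axis = "math")
  d <- distance_to_cortex(c(3, 0), geom)
  expect_equal(unname(d["cortex"]), 2)
  expect_equal(unname(d["nucleus"]), 2)
})

test_that("point-in-polygon agrees with an independent implementation", {
  angs <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- cbind(6 * cos(angs), 5 * sin(angs))
  set.seed(11)
  pts <- cbind(runif(2000, -7, 7), runif(2000, -6, 6))
  ours <- eb1comet:::.point_in_poly(pts, poly)
  ref <- pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2],
                           boundary = TRUE)
  expect_equal(ours, ref)
})
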