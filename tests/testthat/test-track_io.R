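test_that("native CSV is read with px->um conversion and frame timing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("comet_id,movie_id,frame,x_px,y_px",
               "c1,m1,1,10,20", "c1,m1,2,11,21", "c1,m1,3,12,22",
               "c2,m1,0,5,5", "c2,m1,1,6,6"), path)
  trs <- read_tracks(path, "native", frame_interval = 5, pixel_size = 0.1)
  expect_length(trs, 2)
  # deterministic order: sorted by movie then comet id
  expect_equal(vapply(trs, `[[`, character(1), "comet_id"), c("c1", "c2"))
  expect_equal(trs[[1]]$x, c(1.0, 1.1, 1.2))
  expect_equal(trs[[1]]$t, c(5, 10, 15))
  expect_false(trs[[1]]$present_at_first_frame)  # starts at frame 1, not 0
  expect_true(trs[[2]]$present_at_first_frame)
})

test_that("frame gaps, duplicates and missing columns are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("comet_id,movie_id,frame,x_px,y_px",
               "c3,m1,1,0,0", "c3,m1,2,1,1", "c3,m1,4,2,2"), path)
  expect_error(read_tracks(path, "native"), "c3.*frame gap|frame gap.*c3")

  writeLines(c("comet_id,movie_id,frame,x_px,y_px",
               "c1,m1,1,0,0", "c1,m1,1,1,1"), path)
  expect_error(read_tracks(path, "native"), "duplicate")

  writeLines(c("comet_id,movie_id,x_px,y_px", "c1,m1,0,0"), path)
  expect_error(read_tracks(path, "native"), "missing required")
})

test_that("manual_tracking and trackmate dialects map their columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Track n°,Slice n°,X,Y",
               "1,1,100,200", "1,2,110,210", "1,3,120,220"), path)
  trs <- read_tracks(path, "manual_tracking", frame_interval = 5,
                     pixel_size = 0.1)
  expect_length(trs, 1)
  expect_equal(trs[[1]]$x, c(10, 11, 12))
  expect_true(trs[[1]]$present_at_first_frame)  # ImageJ slices start at 1

  writeLines(c("TRACK_ID\tFRAME\tPOSITION_X\tPOSITION_Y",
               "0\t3\t1\t2", "0\t4\t2\t3"), path)
  trs <- read_tracks(path, "trackmate", frame_interval = 2, pixel_size = 1)
  expect_equal(trs[[1]]$t, c(6, 8))
  expect_false(trs[[1]]$present_at_first_frame)
})

test_that("a z column is ignored with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("comet_id,movie_id,frame,x_px,y_px,z_px",
               "c1,m1,1,0,0,3", "c1,m1,2,1,1,3"), path)
  expect_warning(read_tracks(path, "native"), "single Z-plane")
})

test_that("track and geometry round-trips reproduce values to 1e-9", {
  trs <- list(line_track(c(0.123456789, -1.5), c(2.5, 3.25), n = 4, id = "a"),
              line_track(c(-2, -2), c(0, 1), n = 3, id = "b"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tracks(trs, tf, pixel_size = 0.1, frame_interval = 5)
  back <- read_tracks(tf, "native", frame_interval = 5, pixel_size = 0.1)
  for (i in 1:2) {
    expect_equal(back[[i]]$x, trs[[i]]$x, tolerance = 1e-9)
    expect_equal(back[[i]]$y, trs[[i]]$y, tolerance = 1e-9)
    expect_equal(back[[i]]$t, trs[[i]]$t)
    # tracks starting at t = 0 serialise to frame 0 and so are flagged
    expect_true(back[[i]]$present_at_first_frame)
  }
  # simulator output round-trips flag and all, since comets start at frame 1
  sim <- simulate_neuron(simulation_config(n_comets = 5, seed = 2))
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, tf2)
  back2 <- read_tracks(tf2, "native", frame_interval = 5, pixel_size = 1)
  expect_equal(lapply(back2, `[[`, "x"), lapply(sim$tracks, `[[`, "x"),
               tolerance = 1e-9)
  expect_false(any(vapply(back2, `[[`, logical(1), "present_at_first_frame")))

  geom <- square_geometry(golgi = list(g1 = list(center = c(1.1, 2.2),
                                                 radius = 0.987654321)))
  gf <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(geom, gf)
  back_g <- read_geometry(gf)
  expect_equal(back_g$soma, geom$soma, tolerance = 1e-9)
  expect_equal(back_g$axon_entry, geom$axon_entry, tolerance = 1e-9)
  expect_equal(back_g$dendrite_entries, geom$dendrite_entries, tolerance = 1e-9)
  expect_equal(back_g$golgi_stacks$g1$radius, 0.987654321, tolerance = 1e-9)
  expect_equal(back_g$y_axis, "math")
})

test_that("geometry invariants are enforced on construction and read", {
  # nucleus outside soma
  expect_error(
    neuron_geometry(soma = rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                    axon_entry = c(2, 4),
                    nucleus = rbind(c(5, 5), c(7, 5), c(6, 7))),
    "nucleus not contained")
  # entry point too far from the boundary
  expect_error(
    neuron_geometry(soma = rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                    axon_entry = c(2, 10)),
    "within 1 um")
  # fewer than 3 soma vertices
  expect_error(neuron_geometry(soma = rbind(c(0, 0), c(4, 0)),
                               axon_entry = c(2, 0)),
               "at least 3 vertices")
  # self-intersecting soma
  expect_error(
    neuron_geometry(soma = rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4)),
                    axon_entry = c(0, 0)),
    "self-intersecting")
  # zero golgi stacks is degenerate but legal
  g <- square_geometry()
  expect_s3_class(g, "neuron_geometry")
  expect_length(g$golgi_stacks, 0)
})

test_that("comet_track validates monotone, gap-free, finite points", {
  expect_error(comet_track("c", "m", t = 0, x = 0, y = 0), "at least 2")
  expect_error(comet_track("c", "m", t = c(0, 5, 5), x = 1:3, y = 1:3),
               "non-increasing")
  expect_error(comet_track("c", "m", t = c(0, 5, 15), x = 1:3, y = 1:3,
                           frame_interval = 5),
               "time gap")
  expect_error(comet_track("c", "m", t = c(0, 5), x = c(1, NA), y = c(1, 2)),
               "non-finite")
})

test_that("first-frame exclusion removes flagged comets and reports counts", {
  trs <- c(lapply(1:3, function(i) line_track(c(0, 0), c(1, 1), id = paste0("f", i),
                                              first_frame = TRUE)),
           lapply(1:7, function(i) line_track(c(0, 0), c(1, 1), id = paste0("n", i))))
  expect_message(out <- filter_first_frame(trs), "excluded 3")
  expect_length(out, 7)
  expect_length(filter_first_frame(list()), 0)
  all_first <- trs[1:3]
  expect_warning(expect_message(out2 <- filter_first_frame(all_first)),
                 "nothing remains")
  expect_length(out2, 0)
})

test_that("image-convention input is flipped into math convention", {
  geom_img <- neuron_geometry(
    soma = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
    axon_entry = c(0, -5),  # "top" of the image, y down
    frame_interval = 5, y_axis = "image")
  tr <- line_track(c(0, 0), c(0, -2))  # grows "up" in image convention
  conv <- as_math_convention(geom_img, list(tr))
  expect_equal(conv$geometry$y_axis, "math")
  expect_equal(conv$geometry$axon_entry, c(0, 5))
  expect_equal(conv$tracks[[1]]$y, -tr$y)
  # straight-at-axon after conversion
  ga <- initial_growth_angle(conv$tracks[[1]], conv$geometry)
  expect_equal(ga$theta_signed, 0, tolerance = 1e-9)
  # math-convention input is untouched
  g2 <- square_geometry()
  expect_identical(as_math_convention(g2)$geometry, g2)
})
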