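# Shared test fixtures, built in code.

# 10 x 10 square soma centred at the origin, axon entering mid-top,
# two dendrites mid-bottom-left/right
square_geometry <- function(golgi = list()) {
  neuron_geometry(
    soma = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
    axon_entry = c(0, 5),
    dendrite_entries = list(d_left = c(-2.5, -5), d_right = c(2.5, -5)),
    dendrite_branchpoints = list(d_left = c(-2.5, -8), d_right = c(2.5, -8)),
    golgi_stacks = golgi,
    frame_interval = 5, y_axis = "math")
}

# straight-line track from `from` to `to` sampled at n points every 5 s
line_track <- function(from, to, n = 5, id = "t1", movie = "m1",
                       first_frame = FALSE) {
  s <- seq(0, 1, length.out = n)
  comet_track(comet_id = id, movie_id = movie,
              t = (seq_len(n) - 1) * 5,
              x = from[1] + s * (to[1] - from[1]),
              y = from[2] + s * (to[2] - from[2]),
              present_at_first_frame = first_frame)
}

# track through an explicit point matrix
pts_track <- function(pts, id = "t1", movie = "m1") {
  comet_track(comet_id = id, movie_id = movie,
              t = (seq_len(nrow(pts)) - 1) * 5,
              x = pts[, 1], y = pts[, 2])
}

rotate_pts <- function(pts, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  t(R %*% t(pts))
}
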