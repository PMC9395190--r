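# Shared fixture builders; everything generated in code, no stored data.

# one-frame field data frame from vectors
make_frame <- function(x, y, u, v) data.frame(x = x, y = y, u = u, v = v)

# uniform-translation displacement-rate function (um/min)
translation_fun <- function(ux, vy) {
  function(x, y, t) list(u = rep(ux, length(x)), v = rep(vy, length(x)))
}

# small tracker configuration for 192 px test images
test_tracker_config <- function(n_features = 250L) {
  tracker_config(n_features = n_features, min_distance = 8L,
                 window_size = 24L, max_iterations = 20L, n_pyramids = 2L)
}

# field series with a single frame from an analytic function on a grid
fun_field <- function(fun, extent = 20, spacing = 2, dt = 1) {
  g <- expand.grid(x = seq(-extent, extent, by = spacing),
                   y = seq(-extent, extent, by = spacing))
  f <- fun(g$x, g$y)
  vector_field_series(
    data.frame(frame = 1L, x = g$x, y = g$y, u = f$u, v = f$v), dt = dt)
}
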