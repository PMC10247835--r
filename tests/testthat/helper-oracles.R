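# Independent oracles used across the suite.  These deliberately avoid the
# package's clipping engine: areas come from stratified Monte-Carlo point
# classification (crossing-number tests), angular extents from dense ray
# sampling, distances from brute-force boundary sampling.

# Stratified jittered Monte-Carlo estimate of the P-, A-, O-areas of a frame
# pair for a given prediction mode: one sample per cell of a sqrt(n) x
# sqrt(n) grid over the joint bounding box.
mc_frame_areas <- function(pair, mode = "catheter", n_points = 1e6) {
  pre <- pair$pre; post <- pair$post
  dev <- if (mode == "catheter") pre$catheter else pre$wire
  burr <- make_device_circle(dev$center, pre$burr_diameter, kind = "burr")
  xs <- c(burr$ring$x, pre$lumen$x, post$lumen$x)
  ys <- c(burr$ring$y, pre$lumen$y, post$lumen$y)
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  g <- floor(sqrt(n_points))
  eps <- (x1 - x0) / g
  gx <- rep(seq_len(g), g); gy <- rep(seq_len(g), each = g)
  px <- x0 + (gx - runif(g * g)) * (x1 - x0) / g
  py <- y0 + (gy - runif(g * g)) * (y1 - y0) / g
  in_burr <- point_in_region(px, py, burr)
  in_pre <- point_in_region(px, py, pre$lumen)
  in_post <- point_in_region(px, py, post$lumen)
  cell <- (x1 - x0) * (y1 - y0) / (g * g)
  c(p_area = sum(in_burr & !in_pre) * cell,
    a_area = sum(in_post & !in_pre) * cell,
    o_area = sum(in_burr & in_post & !in_pre) * cell)
}

# Ray-sampling angular extent oracle: fraction of rays from `center` (at
# `step_deg` spacing) that cross the region boundary at least once.
ray_angular_extent <- function(region, center, step_deg = 0.1) {
  rings <- if (inherits(region, "ra_region")) unclass(region)
           else if (inherits(region, "ra_circle")) list(region$ring)
           else list(unclass(region))
  if (length(rings) == 0L) return(0)
  th <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  hits <- integer(length(th))
  for (ring in rings)
    hits <- hits + rotadebulk:::.ray_crossings(center[1], center[2], th,
                                               ring$x, ring$y)
  step_deg * sum(hits > 0L)
}

# Brute-force min distance between densely sampled shape boundaries.
sampled_boundary <- function(shape, n = 2000) {
  if (inherits(shape, "ra_circle")) {
    th <- 2 * pi * seq_len(n) / n
    return(list(x = shape$center[1] + shape$diameter / 2 * cos(th),
                y = shape$center[2] + shape$diameter / 2 * sin(th)))
  }
  ring <- if (inherits(shape, "ra_polygon")) shape else shape[[1]]
  # resample each edge uniformly
  xs <- ring$x; ys <- ring$y
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  t <- seq(0, 1, length.out = max(3, ceiling(n / length(xs))))
  list(x = as.vector(outer(x2 - xs, t) + xs),
       y = as.vector(outer(y2 - ys, t) + ys))
}

brute_min_distance <- function(a, b, n = 1500) {
  pa <- sampled_boundary(a, n); pb <- sampled_boundary(b, n)
  d2 <- outer(pa$x, pb$x, "-")^2 + outer(pa$y, pb$y, "-")^2
  sqrt(min(d2))
}

# A blobby random lumen-like polygon (star-shaped about the origin), built
# without the package generator.
random_blob <- function(r_base = 1, wobble = 0.15, n = 96) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- r_base * (1 + wobble * (sin(3 * th + runif(1, 0, 2 * pi)) * runif(1) +
                                 cos(2 * th + runif(1, 0, 2 * pi)) * runif(1)))
  polygon2d(r * cos(th), r * sin(th))
}

# Small default cohort slices used by several tests (kept small for speed).
tiny_cohort <- function(seed = 5, n_lesions = 4) {
  generate_cohort(generator_config(seed = seed, n_lesions = n_lesions))
}
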