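# Seeded synthetic vessel cross-section generator.
#
# Emulates the geometry and statistical structure of a pre/post rotational
# atherectomy imaging cohort: Fourier-perturbed elliptical lumen contours with
# the published area distribution (median 2.91 mm^2), an imaging catheter
# usually resting against the intima (median catheter-intima clearance 0 mm),
# a guidewire in contact with the catheter on 75.3% of frames, burr sizes
# drawn with the published frequencies, and an ablation process whose
# effective center is the catheter when catheter and wire are in contact and
# the wire otherwise, with positional jitter and depth noise.  The
# post-procedural lumen is the union of the pre lumen and the ablation disc,
# so the pre lumen is contained in the post lumen by construction and ground
# truth is exact.

#' Generator configuration
#'
#' All tunable parameters of the synthetic cohort generator with their
#' defaults.  Distances in mm, areas in mm^2, angles in degrees.
#'
#' @param seed Integer master seed; per-lesion substreams are derived
#'   deterministically from it, so any lesion is reproducible in isolation.
#' @param n_lesions Number of lesions (default 55).
#' @param frames_per_lesion_mean Mean analyzable frames per lesion; frame
#'   counts are `5 + Poisson(mean - 5)` (default 8.6, about 474 frames over
#'   55 lesions).
#' @param spacing_mm Frame spacing (default 1).
#' @param lumen_area_median,lumen_area_sdlog Lognormal lesion-level lumen
#'   area (defaults 2.91 mm^2, 0.55), clamped to `lumen_area_range`.
#' @param lumen_area_range Admissible lesion lumen areas.
#' @param frame_area_sdlog Frame-to-frame lognormal wobble of the lumen area
#'   along the lesion.
#' @param ellipticity_max Uniform upper bound of the cos(2theta) ellipticity.
#' @param harmonic_sd Relative amplitude (sd) of shape harmonics 3-5.
#' @param n_vertices Lumen contour vertices per frame.
#' @param p_catheter_wall Probability the catheter rests on the intima
#'   (clearance 0); otherwise the clearance is exponential with mean
#'   `catheter_gap_mean`.
#' @param catheter_gap_mean Mean catheter-intima gap when off the wall.
#' @param contact_fraction Per-frame probability the wire touches the
#'   catheter (default 0.753).
#' @param gap_grid_step,gap_grid_max,gap_decay Non-contact catheter-wire
#'   clearances are drawn from the grid `seq(step, max, by = step)` with
#'   weights `exp(-d / decay)`.
#' @param wire_intima_median,wire_intima_sdlog Lognormal target for the
#'   wire-intima clearance used to choose the wire direction (default
#'   median 0.21 mm).
#' @param burr_sizes,burr_weights Burr diameters and sampling weights
#'   (defaults: 1.50/1.75/2.00/2.15/2.25 mm with weights 19/26/8/1/1).
#' @param burr_ratio_range Admissible burr / mean-lumen-diameter ratio; burrs
#'   are resampled until the ratio falls inside.
#' @param center_jitter_sd Isotropic sd of the ablation-center jitter
#'   (models wire/catheter shift during the run), capped at `jitter_cap`.
#' @param jitter_cap Maximum jitter norm.
#' @param depth_median,depth_sdlog Median and lognormal sd of the ablation
#'   depth factor multiplying the burr diameter (run-to-run variation in how
#'   deeply the burr engages the wall).
#' @param over_threshold Depth factor at or above which a frame has an
#'   over-ablation tendency.
#' @param irrelevant_gap,irrelevant_jitter Non-contact clearance and jitter
#'   norm at or above which a frame has an irrelevant-ablation tendency.
#' @param p_injury_risky,p_injury_base Deep-injury probability at full and at
#'   zero misablation; per frame the probability interpolates between them
#'   with the realized misablation weight (the larger of the outside-
#'   prediction ablation fraction and the ablation excess beyond the
#'   predicted area), so findings concentrate in over- and irrelevant-
#'   ablation frames.  Defaults keep the cohort rate at a few percent.
#' @param p_flap_risky,p_flap_base Same for intimal flaps outside the
#'   predicted area.
#' @param calc_arc_mean,calc_arc_sd Normal total calcium arc (degrees),
#'   clamped to (30, 360].
#' @param calc_depth_median_um,calc_depth_sdlog Lognormal minimum calcium
#'   depth.
#' @param p_nodular Per-frame probability of a nodular calcium annotation.
#' @param max_retries Frame regeneration cap on infeasible geometry.
#' @return A list of class `ra_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_lesions = 55L,
                             frames_per_lesion_mean = 8.6,
                             spacing_mm = 1.0,
                             lumen_area_median = 2.91,
                             lumen_area_sdlog = 0.55,
                             lumen_area_range = c(1.3, 8.5),
                             frame_area_sdlog = 0.06,
                             ellipticity_max = 0.12,
                             harmonic_sd = 0.02,
                             n_vertices = 128L,
                             p_catheter_wall = 0.65,
                             catheter_gap_mean = 0.12,
                             contact_fraction = 0.753,
                             gap_grid_step = 0.05,
                             gap_grid_max = 0.60,
                             gap_decay = 0.15,
                             wire_intima_median = 0.21,
                             wire_intima_sdlog = 0.5,
                             burr_sizes = c(1.50, 1.75, 2.00, 2.15, 2.25),
                             burr_weights = c(19, 26, 8, 1, 1),
                             burr_ratio_range = c(0.55, 1.40),
                             center_jitter_sd = 0.23,
                             jitter_cap = 0.50,
                             depth_median = 0.90,
                             depth_sdlog = 0.15,
                             over_threshold = 1.08,
                             irrelevant_gap = 0.15,
                             irrelevant_jitter = 0.35,
                             p_injury_risky = 0.075,
                             p_injury_base = 0.005,
                             p_flap_risky = 0.20,
                             p_flap_base = 0.02,
                             calc_arc_mean = 238,
                             calc_arc_sd = 85,
                             calc_depth_median_um = 430,
                             calc_depth_sdlog = 0.4,
                             p_nodular = 0.124,
                             max_retries = 20L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_lesions >= 1L, cfg$contact_fraction >= 0,
            cfg$contact_fraction <= 1, cfg$gap_grid_step > 0,
            all(cfg$burr_weights >= 0), cfg$spacing_mm > 0)
  structure(cfg, class = "ra_generator_config")
}

# deterministic per-lesion substream
lesion_seed <- function(seed, lesion_id) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(lesion_id) * 7919) %%
               2147483647)
}

# Fourier-perturbed ellipse contour with exact target area, centered near the
# origin.  Star-shaped about the origin by construction (shape floor 0.3).
lumen_contour <- function(area, e, phi, amps, phases, harmonics, n) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  shape <- 1 + e * cos(2 * (th - phi))
  for (i in seq_along(harmonics))
    shape <- shape + amps[i] * cos(harmonics[i] * th + phases[i])
  shape <- pmax(shape, 0.3)
  x <- shape * cos(th); y <- shape * sin(th)
  a0 <- abs(0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  s <- sqrt(area / a0)
  polygon2d(s * x, s * y, check_simple = FALSE)
}

# radius of a star-shaped contour (about origin) at angle psi
radial_at <- function(poly, psi) {
  ang <- atan2(poly$y, poly$x) %% (2 * pi)
  o <- order(ang)
  approx(x = c(ang[o], ang[o][1] + 2 * pi), y = c(sqrt(poly$x^2 + poly$y^2)[o],
         sqrt(poly$x^2 + poly$y^2)[o][1]), xout = psi %% (2 * pi),
         rule = 2)$y
}

# does a disc of radius r at center c fit strictly inside the contour?
disc_fits <- function(cx, cy, r, poly, slack = 1e-9) {
  point_in_region(cx, cy, poly) &&
    min(dist_points_to_ring(cx, cy, unclass(poly))) >= r - slack
}

# choose a direction for the wire center at fixed distance from the catheter
# center so the wire fits in the lumen, aiming at a target wire-intima gap
place_wire <- function(cath_center, dist, r_wire, poly, target_gap) {
  etas <- seq(0, 2 * pi, length.out = 73L)[-73L]
  wx <- cath_center[1] + dist * cos(etas)
  wy <- cath_center[2] + dist * sin(etas)
  gaps <- rep(NA_real_, length(etas))
  for (i in seq_along(etas)) {
    if (!point_in_region(wx[i], wy[i], poly)) next
    d <- min(dist_points_to_ring(wx[i], wy[i], unclass(poly)))
    if (d >= r_wire) gaps[i] <- d - r_wire
  }
  if (all(is.na(gaps))) return(NULL)
  i <- which.min(abs(gaps - target_gap))
  c(x = wx[i], y = wy[i])
}

#' Generate one synthetic lesion
#'
#' Builds registered pre/post frame pairs for one lesion plus the per-frame
#' ground truth (effective ablation center, depth factor, tendency flags,
#' true ablated area).  The post lumen is the union of the pre lumen and the
#' ablation disc, so `pre` is a subset of `post` exactly.  Infeasible frame
#' geometry (for example a lumen too small for the catheter) is regenerated
#' up to `config$max_retries` times.
#'
#' @param config An `ra_generator_config`.
#' @param lesion_id Positive integer lesion identifier.
#' @return List with `lesion_id`, `burr_diameter`, `spacing`, `pairs` (list
#'   of `ra_frame_pair`), and `truth` (`data.frame`).
#' @export
generate_lesion <- function(config, lesion_id) {
  stopifnot(inherits(config, "ra_generator_config"))
  set.seed(lesion_seed(config$seed, lesion_id))
  harmonics <- 3:5
  r_cath <- ra_catheter_diameter / 2
  r_wire <- ra_wire_diameter / 2
  touch_dist <- r_cath + r_wire

  n_frames <- 5L + rpois(1L, max(config$frames_per_lesion_mean - 5, 0.1))
  area_lesion <- min(max(rlnorm(1, log(config$lumen_area_median),
                                config$lumen_area_sdlog),
                         config$lumen_area_range[1]), config$lumen_area_range[2])
  mean_diam_est <- 2 * sqrt(area_lesion / pi)
  burr <- NA_real_
  for (k in seq_len(config$max_retries)) {
    burr <- sample(config$burr_sizes, 1L, prob = config$burr_weights)
    ratio <- burr / mean_diam_est
    if (ratio >= config$burr_ratio_range[1] && ratio <= config$burr_ratio_range[2])
      break
  }
  e <- runif(1, 0, config$ellipticity_max)
  phi <- runif(1, 0, 2 * pi)
  amps <- rnorm(length(harmonics), 0, config$harmonic_sd)
  phases <- runif(length(harmonics), 0, 2 * pi)
  psi_lesion <- runif(1, 0, 2 * pi)

  pairs <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    frame <- NULL
    for (attempt in seq_len(config$max_retries)) {
      frame <- try(generate_frame(config, fi - 1L, burr, area_lesion, e, phi,
                                  amps, phases, harmonics, psi_lesion,
                                  r_cath, r_wire, touch_dist),
                   silent = TRUE)
      if (!inherits(frame, "try-error")) break
    }
    if (inherits(frame, "try-error"))
      stop("could not generate feasible geometry for lesion ", lesion_id,
           " frame ", fi - 1L, ": ", attr(frame, "condition")$message)
    pairs[[fi]] <- frame$pair
    truth[[fi]] <- frame$truth
  }
  truth <- do.call(rbind, truth)
  truth$lesion_id <- as.integer(lesion_id)
  list(lesion_id = as.integer(lesion_id), burr_diameter = burr,
       spacing = config$spacing_mm, pairs = pairs, truth = truth)
}

generate_frame <- function(config, frame_index, burr, area_lesion, e, phi,
                           amps, phases, harmonics, psi_lesion,
                           r_cath, r_wire, touch_dist) {
  area_f <- area_lesion * rlnorm(1, 0, config$frame_area_sdlog)
  amps_f <- amps + rnorm(length(amps), 0, config$harmonic_sd / 4)
  lumen <- lumen_contour(area_f, e, phi, amps_f, phases, harmonics,
                         config$n_vertices)

  # catheter: along a lesion-stable direction, usually resting on the wall.
  # The radial position is solved against the measured boundary distance so
  # the realized surface clearance equals the drawn one.
  psi <- psi_lesion + rnorm(1, 0, 15 * pi / 180)
  gap_ci <- if (runif(1) < config$p_catheter_wall) 0 else
    rexp_capped(config$catheter_gap_mean, 0.5)
  ring <- unclass(lumen)
  f <- function(t) min(dist_points_to_ring(t * cos(psi), t * sin(psi), ring)) -
    r_cath - gap_ci
  if (f(0) < 0) stop("catheter does not fit")
  t_hi <- radial_at(lumen, psi)
  t_c <- if (f(t_hi) >= 0) t_hi else
    stats::uniroot(f, c(0, t_hi), tol = 1e-10)$root
  cath_center <- c(t_c * cos(psi), t_c * sin(psi))
  if (!disc_fits(cath_center[1], cath_center[2], r_cath, lumen, slack = 1e-7))
    stop("catheter does not fit")

  # wire: touching the catheter on contact frames, else on a gridded gap
  contact <- runif(1) < config$contact_fraction
  gap_cw <- if (contact) 0 else
    config$gap_grid_step * sample.int(round(config$gap_grid_max / config$gap_grid_step),
                                      1L, prob = exp(-seq(config$gap_grid_step,
                                                          config$gap_grid_max,
                                                          by = config$gap_grid_step) /
                                                       config$gap_decay))
  target_gap <- rlnorm(1, log(config$wire_intima_median), config$wire_intima_sdlog)
  wire_center <- NULL
  g <- gap_cw
  repeat {
    wire_center <- place_wire(cath_center, touch_dist + g, r_wire, lumen, target_gap)
    if (!is.null(wire_center)) break
    if (contact || g <= config$gap_grid_step) break
    g <- g - config$gap_grid_step
  }
  if (is.null(wire_center)) stop("wire does not fit")
  gap_cw <- g

  catheter <- make_device_circle(cath_center, kind = "catheter")
  wire <- make_device_circle(wire_center, kind = "wire")

  # ablation: effective center is the catheter when in contact, else the wire
  eff0 <- if (contact) cath_center else as.numeric(wire_center)
  jit <- rnorm(2, 0, config$center_jitter_sd)
  jn <- sqrt(sum(jit^2))
  if (jn > config$jitter_cap) jit <- jit * config$jitter_cap / jn
  depth <- rlnorm(1, log(config$depth_median), config$depth_sdlog)
  eff <- eff0 + jit
  notch <- make_device_circle(eff, burr * depth, kind = "burr")
  post_rings <- polyclip::polyclip(list(unclass(lumen)), list(notch$ring),
                                   "union", fillA = "evenodd", fillB = "evenodd")
  if (length(post_rings) != 1L) stop("ablation disc detached from lumen")
  post_lumen <- polygon2d(post_rings[[1]]$x, post_rings[[1]]$y,
                          check_simple = FALSE)

  over_t <- depth >= config$over_threshold
  irrel_t <- (!contact && gap_cw >= config$irrelevant_gap) ||
    sqrt(sum(jit^2)) >= config$irrelevant_jitter

  # Post-procedural findings track the realized misablation of the frame:
  # the probability of a deep injury or flap interpolates between the base
  # and risky rates with the fraction of ablation outside the (catheter-
  # based) prediction and the ablation excess beyond it.
  burr_cath <- make_device_circle(cath_center, burr, kind = "burr",
                                  n_vertices = 180L)
  Pc <- predicted_region(burr_cath, lumen)
  Ar <- region_clip(post_lumen, lumen, "minus")
  a_area <- region_area(Ar)
  o_area <- region_area(region_clip(Pc, Ar, "intersection"))
  p_area <- region_area(Pc)
  err_frac <- if (a_area > 0) (a_area - o_area) / a_area else 0
  over_excess <- if (p_area > 0) min(1, max(0, a_area / p_area - 1)) else 1
  w_risk <- max(err_frac, over_excess)
  deep_injury <- runif(1) < config$p_injury_base +
    (config$p_injury_risky - config$p_injury_base) * w_risk
  flap <- runif(1) < config$p_flap_base +
    (config$p_flap_risky - config$p_flap_base) * w_risk

  calcium <- synth_calcium(config)

  z <- frame_index * config$spacing_mm
  pre <- frame_pre(frame_index, z, lumen, catheter, wire, burr, calcium)
  post <- frame_post(frame_index, z, post_lumen, deep_injury, flap)
  list(pair = frame_pair(pre, post),
       truth = data.frame(frame_index = frame_index, contact = contact,
                          gap_catheter_wire = gap_cw * (!contact),
                          eff_x = eff[1], eff_y = eff[2],
                          jitter_norm = sqrt(sum(jit^2)), depth_factor = depth,
                          true_ablated_area = polygon_area(post_lumen) - polygon_area(lumen),
                          over_tendency = over_t, irrelevant_tendency = irrel_t,
                          err_frac = err_frac, over_excess = over_excess,
                          deep_injury = deep_injury, flap_outside_p = flap))
}

rexp_capped <- function(mean, cap) min(stats::rexp(1, 1 / mean), cap)

synth_calcium <- function(config) {
  total <- min(max(rnorm(1, config$calc_arc_mean, config$calc_arc_sd), 30), 360)
  depth <- rlnorm(1, log(config$calc_depth_median_um), config$calc_depth_sdlog)
  nodular <- runif(1) < config$p_nodular
  start <- runif(1, 0, 360)
  if (total < 200 || runif(1) < 0.5) {
    list(calcium_arc(start, start + total, depth, nodular))
  } else {
    split <- runif(1, 0.3, 0.7) * total
    gap <- runif(1, 10, 40)
    list(calcium_arc(start, start + split, depth, nodular),
         calcium_arc(start + split + gap, start + split + gap + (total - split),
                     depth * runif(1, 1, 1.5), FALSE))
  }
}

#' Generate a synthetic cohort
#'
#' @param config An `ra_generator_config`.
#' @return List of class `ra_cohort`: one element per lesion as returned by
#'   [generate_lesion()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ra_generator_config"))
  structure(lapply(seq_len(config$n_lesions),
                   function(i) generate_lesion(config, i)),
            class = "ra_cohort")
}

#' Ground-truth table of a cohort
#' @param cohort An `ra_cohort`.
#' @return `data.frame` with one row per frame.
#' @export
cohort_truth <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, `[[`, "truth"))
  rownames(out) <- NULL
  out
}

#' Per-frame metrics for a whole cohort
#'
#' Runs [compute_frame_metrics()] on every frame of every lesion, in one or
#' both prediction modes.
#'
#' @param cohort An `ra_cohort` (or a single lesion list in the same form).
#' @param mode `"both"`, `"catheter"`, or `"wire"`.
#' @param ... Passed to [compute_frame_metrics()].
#' @return `data.frame` with `lesion_id` and one row per frame per mode.
#' @export
compute_cohort_frames <- function(cohort, mode = c("both", "catheter", "wire"),
                                  ...) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("catheter", "wire") else mode
  if (!is.null(cohort$pairs)) cohort <- list(cohort)
  out <- lapply(cohort, function(lesion) {
    rows <- lapply(lesion$pairs, function(pair) {
      do.call(rbind, lapply(modes, function(m)
        compute_frame_metrics(pair, mode = m, ...)))
    })
    df <- do.call(rbind, rows)
    df$lesion_id <- lesion$lesion_id
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tabular frame simulator for statistical calibration
#'
#' Draws per-frame catheter-wire clearances from the generator's
#' device-placement model (a point mass of `contact_fraction` at zero plus a
#' gridded positive part) and a binary irrelevant-ablation outcome whose
#' log-odds increase linearly with the clearance.  This bypasses the
#' geometric pipeline and is intended for calibration and power studies of
#' the regression/ROC layer, where thousands of frames are needed.
#'
#' @param n Number of frames.
#' @param or_per_step True odds ratio per `scale_mm` of clearance
#'   (default 1.7 per 0.1 mm).
#' @param scale_mm Clearance unit for the odds ratio (default 0.1 mm).
#' @param base_rate Outcome probability at zero clearance.
#' @param contact_fraction,gap_grid_step,gap_grid_max,gap_decay As in
#'   [generator_config()].
#' @return `data.frame` with `d_catheter_wire` (mm), `contact`, and logical
#'   `irrelevant`.
#' @export
simulate_risk_table <- function(n, or_per_step = 1.7, scale_mm = 0.1,
                                base_rate = 0.2, contact_fraction = 0.753,
                                gap_grid_step = 0.05, gap_grid_max = 0.60,
                                gap_decay = 0.15) {
  grid <- seq(gap_grid_step, gap_grid_max, by = gap_grid_step)
  contact <- runif(n) < contact_fraction
  d <- numeric(n)
  k <- sum(!contact)
  if (k > 0)
    d[!contact] <- sample(grid, k, replace = TRUE, prob = exp(-grid / gap_decay))
  eta <- qlogis(base_rate) + log(or_per_step) * d / scale_mm
  data.frame(d_catheter_wire = d, contact = contact,
             irrelevant = runif(n) < plogis(eta))
}
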