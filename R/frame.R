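# Per-frame assembly: registered pre/post cross-section pairs and the
# ablation-prediction metrics computed from them in either prediction mode.

#' Calcium arc annotation
#'
#' @param start_deg,end_deg Arc limits in degrees, `[0, 360)`; the arc runs
#'   counter-clockwise from start to end, spanning `(end - start) mod 360`.
#' @param min_depth_um Minimum calcium depth in micrometers (>= 0).
#' @param nodular Protrusion of calcification into the lumen.
#' @return An object of class `ra_calcium_arc`.
#' @export
calcium_arc <- function(start_deg, end_deg, min_depth_um, nodular = FALSE) {
  if (!is.finite(start_deg) || !is.finite(end_deg))
    stop("arc limits must be finite")
  start_deg <- start_deg %% 360
  end_deg <- end_deg %% 360
  if (!is.finite(min_depth_um) || min_depth_um < 0)
    stop("min_depth_um must be >= 0")
  span <- (end_deg - start_deg) %% 360
  if (span == 0) span <- 360
  structure(list(start_deg = start_deg, end_deg = end_deg, span_deg = span,
                 min_depth_um = min_depth_um, nodular = isTRUE(nodular)),
            class = "ra_calcium_arc")
}

# union coverage (degrees) of a list of arcs on the circle
arc_coverage <- function(arcs) {
  if (length(arcs) == 0L) return(0)
  iv <- do.call(rbind, lapply(arcs, function(a)
    c(a$start_deg, a$start_deg + a$span_deg)))
  angular_union_measure(iv)
}

#' Classify the calcification pattern of a cross-section
#'
#' Nodular takes precedence (it is an explicit protrusion annotation);
#' otherwise the pattern is circumferential when the non-overlapping arc
#' coverage reaches 270 degrees, else eccentric.
#'
#' @param arcs Non-empty list of `ra_calcium_arc`.
#' @return One of `"nodular"`, `"circumferential"`, `"eccentric"`.
#' @export
classify_calcification <- function(arcs) {
  if (length(arcs) == 0L) stop("no calcium arcs to classify")
  if (any(vapply(arcs, function(a) a$nodular, logical(1)))) return("nodular")
  if (arc_coverage(arcs) >= 270) "circumferential" else "eccentric"
}

#' Burr-to-lumen ratio
#'
#' Burr diameter divided by the mean lumen diameter of the frame.
#'
#' @param burr_diameter,mean_lumen_diameter In mm; the denominator must be
#'   positive.
#' @return Unitless ratio.
#' @export
burr_lumen_ratio <- function(burr_diameter, mean_lumen_diameter) {
  if (!is.finite(mean_lumen_diameter) || mean_lumen_diameter <= 0)
    stop("mean lumen diameter must be > 0")
  burr_diameter / mean_lumen_diameter
}

## ---- frame containers --------------------------------------------------

#' Pre-procedural frame
#'
#' One registered 1-mm slice before atherectomy: lumen contour, device
#' positions, calcium annotations, and the burr diameter planned for the
#' lesion.
#'
#' @param frame_index Non-negative integer.
#' @param z_mm Longitudinal position (mm).
#' @param lumen `ra_polygon` lumen contour.
#' @param catheter,wire `ra_circle` devices; their centers must lie inside the
#'   lumen.
#' @param burr_diameter Burr diameter (mm, > 0).
#' @param calcium List of `ra_calcium_arc` (may be empty).
#' @return Object of class `ra_frame_pre`.
#' @export
frame_pre <- function(frame_index, z_mm, lumen, catheter, wire,
                      burr_diameter, calcium = list()) {
  stopifnot(inherits(lumen, "ra_polygon"), inherits(catheter, "ra_circle"),
            inherits(wire, "ra_circle"))
  if (frame_index < 0) stop("frame_index must be >= 0")
  if (!is.finite(burr_diameter) || burr_diameter <= 0)
    stop("burr_diameter must be > 0")
  for (dev in list(catheter, wire))
    if (!point_in_region(dev$center[1], dev$center[2], lumen))
      stop(sprintf("%s center lies outside the lumen (frame %d)",
                   dev$kind, frame_index))
  structure(list(frame_index = as.integer(frame_index), z_mm = z_mm,
                 lumen = lumen, catheter = catheter, wire = wire,
                 burr_diameter = burr_diameter, calcium = calcium),
            class = "ra_frame_pre")
}

#' Post-procedural frame
#'
#' @param frame_index,z_mm Must match the pre-procedural partner.
#' @param lumen `ra_polygon` lumen contour after atherectomy.
#' @param deep_injury Deep vessel injury extending beyond the media (observed
#'   finding, not derived from geometry).
#' @param flap_outside_p Intimal flap outside the predicted ablation area.
#' @return Object of class `ra_frame_post`.
#' @export
frame_post <- function(frame_index, z_mm, lumen, deep_injury = FALSE,
                       flap_outside_p = FALSE) {
  stopifnot(inherits(lumen, "ra_polygon"))
  structure(list(frame_index = as.integer(frame_index), z_mm = z_mm,
                 lumen = lumen, deep_injury = isTRUE(deep_injury),
                 flap_outside_p = isTRUE(flap_outside_p)),
            class = "ra_frame_post")
}

#' Registered pre/post frame pair
#'
#' @param pre,post Matching `ra_frame_pre` / `ra_frame_post` (same index and
#'   longitudinal position).
#' @param registered Registration flag; metrics refuse unregistered pairs.
#' @return Object of class `ra_frame_pair`.
#' @export
frame_pair <- function(pre, post, registered = TRUE) {
  stopifnot(inherits(pre, "ra_frame_pre"), inherits(post, "ra_frame_post"))
  if (pre$frame_index != post$frame_index ||
      abs(pre$z_mm - post$z_mm) > 1e-9)
    stop("pre and post frames are not the same slice")
  structure(list(pre = pre, post = post, registered = isTRUE(registered)),
            class = "ra_frame_pair")
}

## ---- per-frame metrics -------------------------------------------------

#' Compute per-frame ablation-prediction metrics
#'
#' Builds the predicted region (burr-sized circle at the catheter or wire
#' center, clipped to the wall), the actual ablated region (post minus pre
#' lumen), and their overlap, then scores the prediction:
#' \%Correct area = 100 O/P, \%Error area = 100 (A - O)/A, with angle
#' analogues measured about the pre-procedural lumen centroid.  Frames whose
#' predicted or actual area falls below `epsilon_area` are flagged excluded
#' and their percentage fields set to `NA` (the frame is reported, not
#' dropped silently).
#'
#' @param pair An `ra_frame_pair` with `registered = TRUE`.
#' @param mode `"catheter"` or `"wire"`: center of the burr-sized prediction
#'   circle.
#' @param n_circle_vertices Polygonization of the burr circle.
#' @param epsilon_area Exclusion threshold (mm^2) for "no predicted/actual
#'   ablation" frames (default 0.001).
#' @param contact_threshold Clearance (mm) at or below which the catheter and
#'   wire are considered in contact (default 1e-6).
#' @return One-row `data.frame` with areas (mm^2), angles (degrees),
#'   percentages, device clearances (mm), lumen measurements, calcium
#'   summary, and exclusion status.
#' @export
compute_frame_metrics <- function(pair, mode = c("catheter", "wire"),
                                  n_circle_vertices = 360L,
                                  epsilon_area = 0.001,
                                  contact_threshold = 1e-6) {
  mode <- match.arg(mode)
  if (!inherits(pair, "ra_frame_pair")) stop("pair must be an ra_frame_pair")
  if (!pair$registered) stop("frame pair is not registered")
  pre <- pair$pre; post <- pair$post

  center_dev <- if (mode == "catheter") pre$catheter else pre$wire
  burr <- make_device_circle(center_dev$center, pre$burr_diameter,
                             kind = "burr", n_vertices = n_circle_vertices)
  P <- predicted_region(burr, pre$lumen)
  A <- actual_region(pre$lumen, post$lumen)
  O <- overlap_region(P, A)
  p_area <- region_area(P); a_area <- region_area(A); o_area <- region_area(O)

  ctr <- polygon_centroid(pre$lumen)
  p_angle <- if (p_area > 0) angular_extent(P, ctr) else 0
  a_angle <- if (a_area > 0) angular_extent(A, ctr) else 0
  o_angle <- if (o_area > 0) angular_extent(O, ctr) else 0

  excluded <- FALSE; reason <- NA_character_
  if (p_area < epsilon_area) { excluded <- TRUE; reason <- "p_area_below_epsilon" }
  if (a_area < epsilon_area) {
    excluded <- TRUE
    reason <- if (is.na(reason)) "a_area_below_epsilon" else "p_and_a_area_below_epsilon"
  }
  pct <- function(num, den) if (excluded || den <= 0) NA_real_ else 100 * num / den

  # clearances at or below the contact threshold are reported as exact zeros
  snap0 <- function(d) if (d <= contact_threshold) 0 else d
  d_ci <- snap0(min_clearance(pre$catheter, pre$lumen))
  d_wi <- snap0(min_clearance(pre$wire, pre$lumen))
  d_cw <- snap0(min_clearance(pre$catheter, pre$wire))

  ld <- lumen_diameters(pre$lumen)
  has_ca <- length(pre$calcium) > 0L

  data.frame(
    frame_index = pre$frame_index, z_mm = pre$z_mm, mode = mode,
    p_area = p_area, a_area = a_area, o_area = o_area,
    p_angle = p_angle, a_angle = a_angle, o_angle = o_angle,
    pct_correct_area = pct(o_area, p_area),
    pct_error_area = pct(a_area - o_area, a_area),
    pct_correct_angle = pct(o_angle, p_angle),
    pct_error_angle = pct(a_angle - o_angle, a_angle),
    d_catheter_intima = d_ci, d_wire_intima = d_wi, d_catheter_wire = d_cw,
    contact = d_cw <= contact_threshold,
    min_lumen_diam = ld$min_diameter, mean_lumen_diam = ld$mean_diameter,
    lumen_area_pre = ld$area, lumen_area_post = polygon_area(post$lumen),
    lumen_loss_area = attr(A, "lumen_loss_area"),
    burr_diameter = pre$burr_diameter,
    burr_lumen_ratio = burr_lumen_ratio(pre$burr_diameter, ld$mean_diameter),
    calc_arc_deg = if (has_ca) arc_coverage(pre$calcium) else 0,
    calc_min_depth_um = if (has_ca)
      min(vapply(pre$calcium, function(a) a$min_depth_um, numeric(1))) else NA_real_,
    calc_type = if (has_ca) classify_calcification(pre$calcium) else NA_character_,
    deep_injury = post$deep_injury, flap_outside_p = post$flap_outside_p,
    excluded = excluded, exclude_reason = reason,
    stringsAsFactors = FALSE
  )
}
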