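# Lesion file format (JSON), schema validation, and the cohort report.
#
# Geometry travels as nested JSON (one file per lesion, schema-versioned);
# flat metric tables are CSV.  Frame indexing is 0-based; z increases in
# pullback direction.

ra_schema_version <- "1.0"

#' Write a lesion to a JSON file
#'
#' @param lesion A lesion list as produced by [generate_lesion()] (fields
#'   `lesion_id`, `burr_diameter`, `spacing`, `pairs`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lesion_json <- function(lesion, path) {
  frames <- lapply(lesion$pairs, function(pair) {
    pre <- pair$pre; post <- pair$post
    list(
      frame_index = pre$frame_index, z_mm = pre$z_mm,
      pre = list(
        lumen = list(x = pre$lumen$x, y = pre$lumen$y),
        catheter = list(x = unname(pre$catheter$center[1]),
                        y = unname(pre$catheter$center[2]),
                        diameter_mm = pre$catheter$diameter),
        wire = list(x = unname(pre$wire$center[1]),
                    y = unname(pre$wire$center[2]),
                    diameter_mm = pre$wire$diameter),
        calcium = lapply(pre$calcium, function(a)
          list(start_deg = a$start_deg, end_deg = a$end_deg,
               min_depth_um = a$min_depth_um, nodular = a$nodular))
      ),
      post = list(
        lumen = list(x = post$lumen$x, y = post$lumen$y),
        deep_injury = post$deep_injury,
        flap_outside_p = post$flap_outside_p
      )
    )
  })
  obj <- list(schema_version = ra_schema_version,
              lesion_id = lesion$lesion_id,
              burr_diameter_mm = lesion$burr_diameter,
              spacing_mm = lesion$spacing,
              frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("lesion file invalid: missing '", field, "' in ", where)
  x[[field]]
}

read_ring <- function(obj, where) {
  x <- as.numeric(need_field(obj, "x", where))
  y <- as.numeric(need_field(obj, "y", where))
  if (length(x) != length(y) || length(x) < 3L)
    stop("lesion file invalid: bad contour in ", where)
  a <- signed_ring_area(list(x = x, y = y))
  if (a < 0) {
    warning("clockwise contour reoriented in ", where)
    x <- rev(x); y <- rev(y)
  }
  tryCatch(polygon2d(x, y, check_simple = TRUE),
           error = function(e) stop("lesion file invalid: ", conditionMessage(e),
                                    " in ", where))
}

#' Read a lesion JSON file
#'
#' Validates the schema and all geometric invariants at load: contours must
#' be simple (self-intersection is an error naming the frame), clockwise
#' contours are reoriented with a warning, device records are mandatory, and
#' frame indices must be contiguous.
#'
#' @param path Path to a lesion JSON file.
#' @return A lesion list (`lesion_id`, `burr_diameter`, `spacing`, `pairs`).
#' @export
read_lesion <- function(path) {
  if (!file.exists(path)) stop("no such lesion file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  ver <- need_field(obj, "schema_version", "root")
  if (!identical(ver, ra_schema_version))
    stop("unsupported lesion schema version: ", ver)
  lesion_id <- need_field(obj, "lesion_id", "root")
  burr <- need_field(obj, "burr_diameter_mm", "root")
  spacing <- need_field(obj, "spacing_mm", "root")
  frames <- need_field(obj, "frames", "root")
  idx <- vapply(frames, function(f) as.integer(need_field(f, "frame_index", "frame")),
                integer(1))
  if (!identical(sort(idx), seq.int(min(idx), length.out = length(idx))))
    stop("lesion file invalid: frame indices not contiguous")
  pairs <- lapply(frames, function(f) {
    where <- sprintf("frame %d", f$frame_index)
    pre_o <- need_field(f, "pre", where)
    post_o <- need_field(f, "post", where)
    lumen <- read_ring(need_field(pre_o, "lumen", where), paste(where, "pre lumen"))
    cath_o <- need_field(pre_o, "catheter", where)
    wire_o <- need_field(pre_o, "wire", where)
    cath <- make_device_circle(c(need_field(cath_o, "x", where),
                                 need_field(cath_o, "y", where)),
                               need_field(cath_o, "diameter_mm", where), "catheter")
    wire <- make_device_circle(c(need_field(wire_o, "x", where),
                                 need_field(wire_o, "y", where)),
                               need_field(wire_o, "diameter_mm", where), "wire")
    calcium <- lapply(if (is.null(pre_o$calcium)) list() else pre_o$calcium,
                      function(a) calcium_arc(need_field(a, "start_deg", where),
                                              need_field(a, "end_deg", where),
                                              need_field(a, "min_depth_um", where),
                                              isTRUE(a$nodular)))
    post_lumen <- read_ring(need_field(post_o, "lumen", where),
                            paste(where, "post lumen"))
    pre <- frame_pre(f$frame_index, need_field(f, "z_mm", where), lumen,
                     cath, wire, burr, calcium)
    post <- frame_post(f$frame_index, f$z_mm, post_lumen,
                       isTRUE(post_o$deep_injury), isTRUE(post_o$flap_outside_p))
    frame_pair(pre, post)
  })
  list(lesion_id = lesion_id, burr_diameter = burr, spacing = spacing,
       pairs = pairs)
}

#' Write a cohort as a directory of lesion files
#' @param cohort An `ra_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lesion in cohort)
    write_lesion_json(lesion, file.path(dir, sprintf("lesion_%03d.json",
                                                     lesion$lesion_id)))
  invisible(dir)
}

#' Read a cohort directory
#' @param dir Directory of `lesion_*.json` files.
#' @return An `ra_cohort` list.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^lesion_.*\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no lesion files found in ", dir)
  structure(lapply(files, read_lesion), class = "ra_cohort")
}

#' Full cohort analysis report
#'
#' Runs the complete cohort-level analysis on a two-mode frame table:
#' catheter-based median split into the four prediction-quality groups,
#' cross-tabulation of post-procedural findings against the groups,
#' univariable screen and multivariable logistic regression for the good and
#' irrelevant groups, the ROC cutoff of the catheter-wire clearance for
#' irrelevant ablation, and the contact-stratified comparison of the two
#' prediction modes.
#'
#' @param frame_table Frame metrics with both modes
#'   (see [compute_cohort_frames()]).
#' @param candidates Candidate variables for the logistic screen.
#' @param alpha_in Univariable inclusion threshold.
#' @return A list of class `ra_report`.
#' @export
cohort_report <- function(frame_table,
                          candidates = c("lumen_area_pre", "burr_lumen_ratio",
                                         "d_catheter_intima", "d_wire_intima",
                                         "d_catheter_wire", "calc_arc_deg"),
                          alpha_in = 0.15) {
  cat_frames <- frame_table[frame_table$mode == "catheter", , drop = FALSE]
  split <- median_split_groups(cat_frames)
  adf <- cat_frames[split$analyzable, , drop = FALSE]
  adf$group <- split$labels
  adf$good <- adf$group == "good_prediction"
  adf$irrelevant <- adf$group == "irrelevant_ablation"

  crosstabs <- list(
    deep_injury = crosstab_findings(adf$group, adf$deep_injury),
    flap_outside_p = crosstab_findings(adf$group, adf$flap_outside_p))

  candidates <- candidates[candidates %in% names(adf)]
  logistic <- lapply(c(good = "good", irrelevant = "irrelevant"), function(oc) {
    screen <- univariable_screen(adf, oc, candidates, alpha_in = alpha_in)
    multi <- multivariable_logistic(adf, oc,
                                    screen$variable[screen$selected])
    list(screen = screen, multivariable = multi$results, status = multi$status)
  })

  roc <- roc_optimal_cutoff(adf$d_catheter_wire, adf$irrelevant)
  modes <- compare_prediction_modes(frame_table)

  structure(list(
    n_frames = nrow(cat_frames), n_analyzable = nrow(adf),
    median_correct = split$median_correct, median_error = split$median_error,
    group_counts = table(adf$group),
    contact_fraction = mean(adf$contact),
    crosstabs = crosstabs, logistic = logistic, roc = roc,
    mode_comparison = modes), class = "ra_report")
}

#' @export
print.ra_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d frames (%d analyzable)\n",
              x$n_frames, x$n_analyzable))
  cat(sprintf("  median %%Correct area %.1f, median %%Error area %.1f\n",
              x$median_correct, x$median_error))
  cat(sprintf("  contact fraction %.1f%%\n", 100 * x$contact_fraction))
  print(x$group_counts)
  print(x$roc)
  invisible(x)
}

#' Serialize a report to JSON (+ CSV tables)
#'
#' @param report An `ra_report`.
#' @param path Output JSON path; mode-comparison and screen tables are
#'   written as sibling CSV files with matching basenames.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stem <- sub("\\.json$", "", path)
  out <- list(
    schema_version = ra_schema_version,
    n_frames = report$n_frames, n_analyzable = report$n_analyzable,
    median_correct = report$median_correct, median_error = report$median_error,
    contact_fraction = report$contact_fraction,
    group_counts = as.list(report$group_counts),
    crosstabs = lapply(report$crosstabs, function(ct)
      list(method = ct$method, p_value = ct$p_value,
           table = unclass(ct$table))),
    roc = report$roc[c("auc", "cutoff", "sensitivity", "specificity",
                       "p_value")],
    logistic = lapply(report$logistic, function(l)
      list(status = l$status, screen = l$screen, multivariable = l$multivariable)),
    mode_comparison = report$mode_comparison)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(report$mode_comparison, paste0(stem, "_mode_comparison.csv"),
            row.names = FALSE)
  for (oc in names(report$logistic))
    write.csv(report$logistic[[oc]]$screen,
              paste0(stem, "_screen_", oc, ".csv"), row.names = FALSE)
  invisible(path)
}
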