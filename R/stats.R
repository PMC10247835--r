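# Cohort statistics: univariable screen -> multivariable logistic regression,
# ROC cutoff for the catheter-wire clearance, and contact-stratified
# comparison of the two prediction modes.  Frames are treated as independent
# observations; an optional per-lesion cluster-robust variance is available
# for the logistic fits but off by default.

# distance covariates are reported per 0.1 mm increase
is_distance_var <- function(v) startsWith(v, "d_")

prepare_predictor <- function(df, v, distance_scale = 0.1) {
  x <- df[[v]]
  if (is.null(x)) stop("candidate variable not found: ", v)
  if (is.logical(x)) x <- as.numeric(x)
  if (!is.numeric(x)) stop("candidate must be numeric or binary: ", v)
  if (is_distance_var(v))
    list(x = x / distance_scale, note = sprintf("per %.1f mm increase", distance_scale))
  else list(x = x, note = "per unit increase")
}

or_row <- function(variable, fit, term = 2L, scale_note, level = 0.95) {
  est <- coef(fit)[term]
  se <- sqrt(diag(vcov(fit)))[term]
  z <- qnorm(1 - (1 - level) / 2)
  p <- 2 * pnorm(-abs(est / se))
  data.frame(variable = variable, odds_ratio = exp(unname(est)),
             ci_low = exp(unname(est - z * se)),
             ci_high = exp(unname(est + z * se)),
             p_value = unname(p), scale_note = scale_note,
             stringsAsFactors = FALSE)
}

fit_is_separated <- function(fit) {
  eps <- 1e-8
  any(fit$fitted.values < eps) && any(fit$fitted.values > 1 - eps) &&
    max(abs(coef(fit)[-1])) > 10 ||
    any(sqrt(diag(vcov(fit)))[-1] > 1e3)
}

#' Univariable logistic screen
#'
#' Fits a one-predictor logistic regression of a binary outcome on each
#' candidate variable and selects those with Wald p below `alpha_in`
#' (default 0.15) for the multivariable model.  Distance variables (names
#' starting `d_`) are rescaled to per-0.1-mm units.  Candidates showing
#' complete separation are flagged and never selected.
#'
#' @param df Frame table (`data.frame`).
#' @param outcome Name of a logical/0-1 column, or a logical vector.
#' @param candidates Character vector of candidate column names.
#' @param alpha_in Inclusion threshold on the univariable p-value.
#' @param distance_scale Reporting unit for distance variables (mm).
#' @return `data.frame` with one row per candidate: odds ratio, 95% Wald CI,
#'   p-value, `scale_note`, `selected`, `flagged`.
#' @export
univariable_screen <- function(df, outcome, candidates, alpha_in = 0.15,
                               distance_scale = 0.1) {
  y <- if (is.character(outcome) && length(outcome) == 1L) df[[outcome]] else outcome
  y <- as.logical(y)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome must have both classes")
  rows <- lapply(candidates, function(v) {
    pr <- prepare_predictor(df, v, distance_scale)
    ok <- !is.na(y) & !is.na(pr$x)
    fit <- suppressWarnings(glm(y[ok] ~ pr$x[ok], family = binomial()))
    row <- or_row(v, fit, scale_note = if (is_distance_var(v)) pr$note else "per unit increase")
    row$flagged <- fit_is_separated(fit)
    if (row$flagged)
      warning("complete separation for candidate '", v, "'; excluded from selection")
    row$selected <- !row$flagged & row$p_value < alpha_in
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariable logistic regression with odds ratios
#'
#' Joint logistic fit of the outcome on the selected variables, reporting
#' exponentiated coefficients with Wald 95% confidence intervals.  Distance
#' variables are rescaled as in [univariable_screen()].  An empty selection
#' returns an explicit no-op status rather than an error.
#'
#' @inheritParams univariable_screen
#' @param selected Character vector of variables to fit jointly.
#' @param cluster Optional vector (e.g. lesion id) for a cluster-robust
#'   sandwich variance; default `NULL` keeps the model-based variance, as
#'   frames are treated as independent.
#' @return List with `status` ("ok" or "empty_selection"), `results`
#'   (`data.frame` of OR rows, one per variable), and `fit` (the `glm`).
#' @export
multivariable_logistic <- function(df, outcome, selected,
                                   distance_scale = 0.1, cluster = NULL) {
  y <- if (is.character(outcome) && length(outcome) == 1L) df[[outcome]] else outcome
  y <- as.logical(y)
  if (length(selected) == 0L)
    return(list(status = "empty_selection", results = NULL, fit = NULL))
  prs <- lapply(selected, function(v) prepare_predictor(df, v, distance_scale))
  X <- data.frame(lapply(prs, `[[`, "x"))
  names(X) <- selected
  dat <- cbind(data.frame(.y = y), X)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= 10 * length(selected))
    message("fewer than 10 observations per fitted variable")
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = dat))
  if (any(is.na(coef(fit)))) stop("singular fit: collinear predictors dropped by glm")
  mm <- stats::model.matrix(fit)
  if (kappa(mm) > 1e8) warning("ill-conditioned design (condition number > 1e8)")
  V <- if (is.null(cluster)) vcov(fit) else {
    cl <- cluster[as.integer(rownames(dat))]
    cluster_vcov(fit, cl)
  }
  z <- qnorm(0.975)
  est <- coef(fit)[-1]
  se <- sqrt(diag(V))[-1]
  res <- data.frame(variable = selected, odds_ratio = exp(unname(est)),
                    ci_low = exp(unname(est - z * se)),
                    ci_high = exp(unname(est + z * se)),
                    p_value = 2 * pnorm(-abs(unname(est / se))),
                    scale_note = vapply(seq_along(selected), function(i)
                      if (is_distance_var(selected[i])) prs[[i]]$note
                      else "per unit increase", character(1)),
                    stringsAsFactors = FALSE)
  list(status = "ok", results = res, fit = fit)
}

# CR0 cluster-robust sandwich variance for a glm
cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  r <- fit$y - fit$fitted.values
  U <- X * r
  Us <- rowsum(U, group = cluster)
  bread <- vcov(fit) / summary(fit)$dispersion
  meat <- crossprod(as.matrix(Us))
  bread %*% meat %*% bread
}

#' Empirical ROC with Youden-optimal cutoff
#'
#' Computes the empirical ROC of a continuous score against a binary label
#' (positive class = higher scores), the area under the curve via the
#' Mann-Whitney statistic (equivalent to the trapezoidal rule with tie
#' handling), the cutoff maximizing the Youden index (ties broken toward the
#' smaller cutoff; classification rule "positive when score > cutoff"), and a
#' p-value for AUC != 0.5 from the tie-corrected normal approximation of the
#' Mann-Whitney test.
#'
#' @param scores Numeric scores (mm for device clearances).
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @return List of class `ra_roc`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity` (percent), `p_value`, `n_pos`, `n_neg`, and the ROC
#'   `curve` (`data.frame` of cutoff, sens, spec).
#' @export
roc_optimal_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  # AUC from the rank-sum (Mann-Whitney) statistic; ties count 1/2
  rk <- rank(scores)
  U <- sum(rk[labels]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  # tie-corrected normal approximation for U
  nties <- table(scores)
  n <- n0 + n1
  sigma2 <- n0 * n1 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  p <- if (sigma2 > 0) 2 * pnorm(-abs((U - n0 * n1 / 2) / sqrt(sigma2))) else NA_real_
  # candidate cutoffs: each distinct score (rule: positive if score > c),
  # plus one below the minimum (classify everything positive)
  cand <- sort(unique(c(min(scores) - 1, scores)))
  sens <- vapply(cand, function(cc) sum(scores[labels] > cc) / n1, numeric(1))
  spec <- vapply(cand, function(cc) sum(scores[!labels] <= cc) / n0, numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))[1]  # smallest cutoff among ties
  structure(list(auc = auc, cutoff = cand[best],
                 sensitivity = 100 * sens[best], specificity = 100 * spec[best],
                 p_value = p, n_pos = n1, n_neg = n0,
                 curve = data.frame(cutoff = cand, sensitivity = 100 * sens,
                                    specificity = 100 * spec)),
            class = "ra_roc")
}

#' @export
print.ra_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (p = %.3g), cutoff > %.3g mm, sens %.1f%%, spec %.1f%%\n",
              x$auc, x$p_value, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Contact-stratified comparison of the two prediction modes
#'
#' Within each stratum (catheter-wire contact / non-contact), compares the
#' catheter-based and wire-based per-frame metrics with two-sided
#' Mann-Whitney U tests, reporting per-mode medians.  Frames excluded in
#' either mode are left out; an empty stratum is reported with status
#' "skipped".
#'
#' @param frame_table Frame metrics containing both modes (`mode` column) and
#'   a logical `contact` column.
#' @param metrics Metric columns to compare.
#' @return `data.frame`: stratum x metric rows with medians, n, p-value,
#'   status.
#' @export
compare_prediction_modes <- function(frame_table,
                                     metrics = c("pct_correct_area",
                                                 "pct_error_area",
                                                 "pct_correct_angle",
                                                 "pct_error_angle")) {
  if (!all(c("catheter", "wire") %in% unique(frame_table$mode)))
    stop("frame table must contain both prediction modes")
  out <- list()
  for (stratum in c(TRUE, FALSE)) {
    sdf <- frame_table[frame_table$contact == stratum, , drop = FALSE]
    sname <- if (stratum) "contact" else "non_contact"
    for (m in metrics) {
      xc <- sdf[[m]][sdf$mode == "catheter"]
      xw <- sdf[[m]][sdf$mode == "wire"]
      xc <- xc[!is.na(xc)]; xw <- xw[!is.na(xw)]
      if (length(xc) == 0L || length(xw) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          stratum = sname, metric = m, n_catheter = length(xc),
          n_wire = length(xw), median_catheter = NA_real_,
          median_wire = NA_real_, p_value = NA_real_, status = "skipped",
          stringsAsFactors = FALSE)
        next
      }
      p <- if (length(unique(c(xc, xw))) == 1L) 1 else
        suppressWarnings(wilcox.test(xc, xw, exact = FALSE)$p.value)
      out[[length(out) + 1L]] <- data.frame(
        stratum = sname, metric = m, n_catheter = length(xc),
        n_wire = length(xw), median_catheter = median(xc),
        median_wire = median(xw), p_value = p, status = "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
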