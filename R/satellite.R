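# Satellite-style column comparison: pixel filtering, model columns,
# air-mass-factor recalculation with model profiles, source-region
# classification and orthogonal distance regression.

#' Filter retrieval pixels on quality criteria
#'
#' Keeps pixels with `qa >= qa_min`, `cloud_fraction <= cf_max` and
#' `sza <= sza_max` (defaults follow common L2 user-guide practice).
#'
#' @param scene An `aq_scene` from [generate_satellite_scene()].
#' @param qa_min,cf_max,sza_max Thresholds.
#' @return The filtered `aq_scene`, with attribute `n_kept`.
#' @export
filter_pixels <- function(scene, qa_min = 0.75, cf_max = 0.3, sza_max = 70) {
  if (qa_min < 0 || cf_max < 0 || cf_max > 1 || sza_max < 0 || sza_max > 90) {
    stop("thresholds outside valid ranges")
  }
  px <- scene$pixels
  keep <- px$qa >= qa_min & px$cloud_fraction <= cf_max & px$sza <= sza_max
  out <- scene
  out$pixels <- px[keep, , drop = FALSE]
  out$scattering_weights <- scene$scattering_weights[keep, , drop = FALSE]
  out$apriori <- scene$apriori[keep, , drop = FALSE]
  out$model_profile <- scene$model_profile[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Tropospheric model column from a layered profile
#'
#' Sums partial columns over layers up to and including the tropopause
#' layer (1-based from the surface).
#'
#' @param profile Numeric vector (one profile) or matrix
#'   `[n_profiles, n_layers]` of partial columns (molec cm-2).
#' @param tropopause_layer 1-based index of the highest tropospheric layer.
#' @return Numeric column(s).
#' @export
model_column <- function(profile, tropopause_layer) {
  p <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1)
  if (tropopause_layer < 1 || tropopause_layer > ncol(p)) {
    stop("tropopause layer index out of range")
  }
  cols <- rowSums(p[, seq_len(tropopause_layer), drop = FALSE])
  if (!is.matrix(profile)) cols[[1]] else cols
}

#' Recompute air-mass factors with model profiles
#'
#' Replaces each pixel's a-priori-based AMF by the model-profile AMF,
#' `amf_model = sum(sw * m) / sum(m)` over tropospheric layers, and adjusts
#' the vertical column as `vcd * amf_orig / amf_model`, preserving the
#' implied slant column `vcd * amf`. The scattering-weight (TROPOMI/OMI)
#' and shape-factor (OMPS) pathways both reduce to this formula. When the
#' model profile is proportional to the a priori, the adjustment is an
#' exact no-op.
#'
#' @param scene An `aq_scene`.
#' @param model_profile Optional matrix `[n_pixels, n_layers]` of model
#'   partial columns on the pixels' layering; defaults to the scene's own
#'   stored model profiles.
#' @return The scene with `amf_model` and `vcd_adjusted` columns added to
#'   `pixels`.
#' @export
recompute_amf <- function(scene, model_profile = NULL) {
  if (is.null(model_profile)) model_profile <- scene$model_profile
  sw <- scene$scattering_weights
  if (any(sw < 0)) stop("scattering weights must be >= 0")
  tl <- scene$pixels$tropopause_layer
  n <- nrow(sw)
  amf_model <- numeric(n)
  for (k in seq_len(n)) {
    idx <- seq_len(tl[k])
    m <- model_profile[k, idx]
    if (sum(m) <= 0) stop("model profile sums to zero over the troposphere")
    amf_model[k] <- sum(sw[k, idx] * m) / sum(m)
  }
  out <- scene
  out$pixels$amf_model <- amf_model
  out$pixels$vcd_adjusted <- scene$pixels$vcd * scene$pixels$amf_orig / amf_model
  out
}

#' Classify grid cells by dominant NOx source sector
#'
#' A cell is labelled `urban` (mobile), `point` (industrial/power plant) or
#' `oil_and_gas` when that sector contributes at least `threshold` of the
#' cell's total NOx emissions under business-as-usual conditions (inclusive
#' threshold), and `other` when no sector does. With a threshold above 0.5
#' the label is necessarily unique.
#'
#' @param fractions Matrix or data frame `[n_cells, 3]` with columns
#'   `mobile`, `point`, `oil_and_gas`; per-cell fractions in `[0, 1]`
#'   summing to at most 1 (small tolerance).
#' @param threshold Dominance threshold, default 0.60.
#' @return Character vector of labels over cells.
#' @export
classify_source_region <- function(fractions, threshold = 0.60) {
  f <- as.matrix(as.data.frame(fractions)[c("mobile", "point", "oil_and_gas")])
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  if (any(rowSums(f) > 1 + 1e-8)) stop("per-cell fractions must sum to <= 1")
  labels <- c("urban", "point", "oil_and_gas")
  hit <- f >= threshold
  out <- rep("other", nrow(f))
  idx <- which(rowSums(hit) > 0)
  out[idx] <- labels[apply(f[idx, , drop = FALSE], 1, which.max)]
  out
}

#' Regional fractional column change
#'
#' `(mean_y2 - mean_y1) / mean_y1` over the cells carrying a given source
#' label.
#'
#' @param columns_y1,columns_y2 [exposure_surface()]s (or numeric vectors
#'   over cells) of period-mean columns for the two years.
#' @param labels Character labels per cell (see [classify_source_region()]).
#' @param region Label to aggregate over.
#' @return Fractional change (e.g. -0.2 for a 20% decrease).
#' @export
regional_change <- function(columns_y1, columns_y2, labels, region) {
  v1 <- if (inherits(columns_y1, "aq_surface")) columns_y1$values else columns_y1
  v2 <- if (inherits(columns_y2, "aq_surface")) columns_y2$values else columns_y2
  sel <- labels == region & !is.na(v1) & !is.na(v2)
  if (!any(sel)) stop(sprintf("no cells carry the label '%s'", region))
  m1 <- mean(v1[sel]); m2 <- mean(v2[sel])
  if (m1 <= 0) stop("reference-year regional mean is not positive")
  m2 / m1 - 1
}

#' Orthogonal distance regression
#'
#' Fits `y = a + b x` by minimising the sum of squared perpendicular
#' distances (both axes carry comparable error), via the principal axis of
#' the centred 2x2 covariance matrix. The slope's 95% CI uses a jackknife
#' variance estimate with normal quantiles, a large-sample approximation.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @return List with `slope`, `intercept`, `slope_ci95` (length-2).
#' @export
odr_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("odr_fit requires at least 3 points")
  slope_of <- function(xs, ys) {
    v <- stats::cov(cbind(xs, ys))
    if (v[1, 1] + v[2, 2] <= 0) stop("degenerate input: all points identical")
    e <- eigen(v, symmetric = TRUE)
    vec <- e$vectors[, 1]
    if (abs(vec[1]) < 1e-14) stop("degenerate input: vertical principal axis")
    vec[2] / vec[1]
  }
  b <- slope_of(x, y)
  a <- mean(y) - b * mean(x)
  bj <- vapply(seq_len(n), function(i) slope_of(x[-i], y[-i]), numeric(1))
  se <- sqrt((n - 1) / n * sum((bj - mean(bj))^2))
  list(slope = b, intercept = a,
       slope_ci95 = c(b - 1.959964 * se, b + 1.959964 * se))
}
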