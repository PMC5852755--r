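#' Construct a gradient object
#'
#' One isopycnic gradient: fractions in collection order (fraction 1
#' densest), their densities and RNA quantities. The trailing `n_excluded`
#' fractions (usually water) are kept but flagged as outside the analyzed
#' range.
#'
#' @param fractions Data frame with columns `fraction`, `density`
#'   (g/mL, strictly decreasing with fraction index) and `rna_concentration`
#'   (arbitrary units, nonnegative).
#' @param timepoint,replicate Labels for the gradient.
#' @param n_excluded Number of trailing fractions excluded from analysis.
#' @return A data frame of class `sip_gradient` with attributes `timepoint`,
#'   `replicate` and `analyzed_range`.
#' @export
as_gradient <- function(fractions, timepoint = NA, replicate = NA,
                        n_excluded = 0L) {
  stopifnot(is.data.frame(fractions),
            all(c("fraction", "density", "rna_concentration") %in%
                  names(fractions)))
  fractions <- fractions[order(fractions$fraction), , drop = FALSE]
  if (any(diff(fractions$density) >= 0))
    stop("density must decrease strictly with fraction index")
  if (any(fractions$rna_concentration < 0))
    stop("rna_concentration must be nonnegative")
  n <- nrow(fractions)
  n_excluded <- as.integer(n_excluded)
  if (n - n_excluded < 4L)
    stop("at least 4 analyzed fractions are required")
  fractions$analyzed <- fractions$fraction <= (n - n_excluded)
  rownames(fractions) <- NULL
  structure(fractions, class = c("sip_gradient", "data.frame"),
            timepoint = timepoint, replicate = replicate,
            analyzed_range = c(1L, n - n_excluded))
}

#' Fit a refractive-index to density calibration line
#'
#' Ordinary least-squares line mapping refractometer readings to CsTFA
#' solution density, as used to convert per-fraction refraction measurements
#' into buoyant densities.
#'
#' @param ri Refractive indices of the calibration standards.
#' @param density Known densities (g/mL) of the standards.
#' @return Object of class `density_calibration` with `slope`, `intercept`,
#'   the calibration `points` and the root-mean-square residual `rms`.
#' @export
fit_density_calibration <- function(ri, density) {
  if (length(ri) < 2L || length(density) != length(ri))
    stop("at least 2 (ri, density) calibration points are required")
  if (length(unique(ri)) < 2L)
    stop("calibration refractive indices are degenerate (all equal)")
  fit <- stats::lm(density ~ ri)
  res <- stats::residuals(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    points = data.frame(ri = ri, density = density),
    rms = sqrt(mean(res^2))
  ), class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat("Density calibration: density =", format(x$intercept), "+",
      format(x$slope), "* RI (", nrow(x$points), "points, residual RMS",
      format(x$rms, digits = 3), ")\n")
  invisible(x)
}

#' Apply a density calibration to refractive indices
#'
#' @param object A `density_calibration`.
#' @param ri Refractive indices.
#' @param ... Unused.
#' @return Densities in g/mL.
#' @export
predict.density_calibration <- function(object, ri, ...) {
  object$intercept + object$slope * ri
}

#' Relative RNA distribution across gradient fractions
#'
#' Expresses each analyzed fraction's RNA quantity as a percentage of the
#' maximum quantity detected among the analyzed fractions of the gradient,
#' so that gradients of different total yield are comparable. Idempotent.
#'
#' @param gradient A `sip_gradient`.
#' @return The gradient with a `relative_rna` column (percent of gradient
#'   maximum; `NA` for excluded fractions).
#' @export
relative_rna_distribution <- function(gradient) {
  stopifnot(inherits(gradient, "sip_gradient"))
  conc <- gradient$rna_concentration[gradient$analyzed]
  if (all(conc == 0))
    stop("empty gradient: all analyzed fractions have zero RNA")
  gradient$relative_rna <- NA_real_
  gradient$relative_rna[gradient$analyzed] <- 100 * conc / max(conc)
  gradient
}

#' Modal (peak) fraction of a gradient
#'
#' The analyzed fraction holding the bulk of RNA, operationalized as the
#' argmax of the relative RNA distribution; ties are broken toward the
#' lighter (higher-index) fraction.
#'
#' @param gradient A `sip_gradient` (relative RNA is computed if absent).
#' @return Integer fraction index.
#' @export
peak_fraction <- function(gradient) {
  if (is.null(gradient$relative_rna))
    gradient <- relative_rna_distribution(gradient)
  an <- gradient[gradient$analyzed, ]
  cand <- an$fraction[an$relative_rna >= max(an$relative_rna) - 1e-12]
  max(cand)
}

# Build a fraction -> class map for explicit windows.
window_map <- function(heavy, light, n_fractions) {
  m <- stats::setNames(rep("unassigned", n_fractions),
                       as.character(seq_len(n_fractions)))
  m[as.character(heavy)] <- "heavy"
  m[as.character(light)] <- "light"
  m
}

#' Classify gradient fractions into heavy and light windows
#'
#' The light window holds unlabeled RNA; the heavy window, three fractions
#' denser, holds RNA whose buoyant density increased through heavy-isotope
#' incorporation. The `fixed` policy returns the configured windows
#' (defaults heavy = fractions 5-7, light = 8-10). The `auto` policy centres
#' the light window on the peak fraction of an unlabeled control gradient
#' (peak +/- 1) and places the heavy window `shift` fractions denser.
#'
#' @param control A `sip_gradient` from unlabeled (baseline) material, used
#'   by the `auto` policy; must have `relative_rna` filled (see
#'   [relative_rna_distribution()]).
#' @param policy `"fixed"` or `"auto"`.
#' @param heavy,light Fraction indices for the `fixed` policy.
#' @param shift Heavy-window offset (denser, i.e. lower indices) for the
#'   `auto` policy.
#' @return Named character vector mapping fraction index to `"heavy"`,
#'   `"light"` or `"unassigned"`, with attributes `heavy` and `light`.
#' @export
classify_fractions <- function(control = NULL, policy = c("fixed", "auto"),
                               heavy = 5:7, light = 8:10, shift = 3L) {
  policy <- match.arg(policy)
  if (policy == "auto") {
    if (is.null(control) || !inherits(control, "sip_gradient"))
      stop("auto policy requires a control sip_gradient")
    if (is.null(control$relative_rna))
      stop("control gradient must have relative_rna filled")
    pk <- peak_fraction(control)
    light <- (pk - 1L):(pk + 1L)
    heavy <- light - as.integer(shift)
    rng <- attr(control, "analyzed_range")
    if (min(heavy) < rng[1L] || max(light) > rng[2L])
      stop("auto peak too close to the gradient edge to fit both windows")
    n_fr <- nrow(control)
  } else {
    if (length(heavy) != length(light))
      stop("heavy and light windows must have equal size")
    if (length(intersect(heavy, light)))
      stop("heavy and light windows must be disjoint")
    n_fr <- max(light, heavy)
    if (!is.null(control) && inherits(control, "sip_gradient")) {
      rng <- attr(control, "analyzed_range")
      if (min(heavy) < rng[1L] || max(light) > rng[2L])
        stop("windows fall outside the analyzed fraction range")
      n_fr <- rng[2L]
    }
  }
  if (length(intersect(heavy, light)))
    stop("heavy and light windows must be disjoint")
  out <- window_map(heavy, light, n_fr)
  attr(out, "heavy") <- as.integer(heavy)
  attr(out, "light") <- as.integer(light)
  out
}

#' Linearity of a fractionated gradient
#'
#' Regresses analyzed fraction densities on fraction index; a well-formed
#' isopycnic gradient fractionates into a linearly decreasing density series
#' (R-squared close to 1).
#'
#' @param gradient A `sip_gradient`.
#' @return List with `slope` (g/mL per fraction), `intercept` and
#'   `r_squared`.
#' @export
gradient_linearity <- function(gradient) {
  stopifnot(inherits(gradient, "sip_gradient"))
  an <- gradient[gradient$analyzed, ]
  fit <- stats::lm(density ~ fraction, data = an)
  # near-perfect fits are the expected case here; silence summary.lm's note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}
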