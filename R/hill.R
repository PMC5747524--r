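# Indicator calibration: four-parameter Hill binding model, ratio
# normalisation, fura-2-referenced Ca2+ conversion, nonlinear least-squares
# fitting, dynamic range, and G/R ratio images.

#' Four-parameter Hill model parameters
#'
#' Parameterises the equilibrium response of a ratiometric Ca2+ indicator as
#' `R(ca) = r_min + (r_max - r_min) * ca^n / (kd^n + ca^n)`: dissociation
#' constant `kd_nM` (Ca2+ at half-maximal response), Hill coefficient
#' `hill_n` (cooperativity/steepness), and the response floor and ceiling
#' `r_min`, `r_max`.
#'
#' @param kd_nM dissociation constant in nM; must be positive.
#' @param hill_n Hill coefficient; must be positive.
#' @param r_min,r_max minimal and maximal response; `r_max > r_min`.
#' @return An object of class `hill_params`.
#' @seealso [hill_ratio()], [fit_hill()], [salsa6f_hill()]
#' @export
hill_params <- function(kd_nM, hill_n, r_min = 0, r_max = 1) {
  .chk(is.numeric(kd_nM) && kd_nM > 0, "kd_nM must be positive")
  .chk(is.numeric(hill_n) && hill_n > 0, "hill_n must be positive")
  .chk(r_max > r_min, "r_max must exceed r_min")
  structure(list(kd_nM = kd_nM, hill_n = hill_n, r_min = r_min, r_max = r_max),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: Kd = %.4g nM, n = %.4g, Rmin = %.4g, Rmax = %.4g\n",
              x$kd_nM, x$hill_n, x$r_min, x$r_max))
  invisible(x)
}

#' In-situ Hill parameters of the Salsa6f indicator
#'
#' The tandem GCaMP6f-tdTomato indicator calibrated in T cells against a
#' fura-2 reference yields, on ratios normalised to `[0, 1]`, a steady-state
#' response with Kd = 301 nM and Hill coefficient 1.49, and a peak-response
#' calibration with Kd = 162 nM and Hill coefficient 0.93.
#'
#' @param which `"steady"` (default) or `"peak"`.
#' @return A [hill_params] object.
#' @export
salsa6f_hill <- function(which = c("steady", "peak")) {
  which <- match.arg(which)
  if (which == "steady") hill_params(301, 1.49, 0, 1) else hill_params(162, 0.93, 0, 1)
}

#' Hill response at given Ca2+ concentrations
#'
#' @param ca_nM numeric vector of Ca2+ concentrations (nM), non-negative.
#' @param params a [hill_params] object.
#' @return Ratio values; strictly increasing in `ca_nM`.
#' @examples
#' hill_ratio(301, hill_params(301, 1.49))  # half-occupancy at Kd -> 0.5
#' @export
hill_ratio <- function(ca_nM, params) {
  .chk(inherits(params, "hill_params"), "params must be hill_params")
  .chk(all(is.finite(ca_nM) | is.infinite(ca_nM)) && all(ca_nM >= 0),
       "ca_nM must be non-negative")
  occ <- ifelse(is.infinite(ca_nM), 1,
                ca_nM^params$hill_n /
                  (params$kd_nM^params$hill_n + ca_nM^params$hill_n))
  params$r_min + (params$r_max - params$r_min) * occ
}

#' Invert the Hill response
#'
#' Closed-form inverse of [hill_ratio()]: reads a Ca2+ concentration off a
#' fitted curve from an observed ratio. Ratios at or beyond the response
#' floor/ceiling are saturated and rejected.
#'
#' @param ratio numeric vector strictly inside `(r_min, r_max)`.
#' @param params a [hill_params] object.
#' @return Ca2+ concentrations in nM.
#' @export
invert_hill <- function(ratio, params) {
  .chk(inherits(params, "hill_params"), "params must be hill_params")
  .chk(all(ratio > params$r_min & ratio < params$r_max),
       "ratio outside (r_min, r_max): indicator saturated, Ca2+ not recoverable")
  occ <- (ratio - params$r_min) / (params$r_max - params$r_min)
  params$kd_nM * (occ / (1 - occ))^(1 / params$hill_n)
}

#' Normalise ratio values to an observed min/max
#'
#' Affine rescaling `(v - r_min_obs) / (r_max_obs - r_min_obs)` mapping the
#' observed minimum to 0 and maximum to 1, the normalisation applied to both
#' fura-2 and indicator ratios before calibration.
#'
#' @param values numeric vector.
#' @param r_min_obs,r_max_obs observed extremes; `r_max_obs > r_min_obs`.
#' @export
normalize_ratio <- function(values, r_min_obs, r_max_obs) {
  .chk(r_max_obs > r_min_obs, "degenerate range: r_max_obs must exceed r_min_obs")
  (values - r_min_obs) / (r_max_obs - r_min_obs)
}

#' Fura-2 calibration reference
#'
#' @param kd_nM in-situ dissociation constant of fura-2, default 225 nM
#'   (room-temperature in-situ value).
#' @return An object of class `fura2_reference`.
#' @export
fura2_reference <- function(kd_nM = 225) {
  .chk(kd_nM > 0, "kd_nM must be positive")
  structure(list(kd_nM = kd_nM), class = "fura2_reference")
}

#' Convert a normalised fura-2 ratio to Ca2+ concentration
#'
#' Uses the normalised single-site form `ca = Kd * r / (1 - r)`; with ratios
#' normalised to `Rmin = 0`, `Rmax = 1` the scaling factor of the classical
#' two-wavelength equation is absorbed into the normalisation.
#'
#' @param r_norm normalised ratio(s) in `[0, 1)`.
#' @param ref a [fura2_reference] object.
#' @return Ca2+ concentration(s) in nM.
#' @examples
#' fura2_to_ca(0.5, fura2_reference())  # 225 nM at half-saturation
#' @export
fura2_to_ca <- function(r_norm, ref = fura2_reference()) {
  .chk(inherits(ref, "fura2_reference"), "ref must be fura2_reference")
  .chk(all(r_norm >= 0), "r_norm must be non-negative")
  .chk(all(r_norm < 1), "r_norm >= 1: reference indicator saturated")
  ref$kd_nM * r_norm / (1 - r_norm)
}

#' Indicator dynamic range
#'
#' Ratio of maximal to minimal fluorescence (or ratio) across Ca2+
#' saturation, `DR = Fmax / Fmin`. The maximal fractional change
#' `dF/F0 = DR - 1` is exposed separately by [delta_f_f0()] to keep the two
#' conventions distinct.
#'
#' @param f_max,f_min maximal and minimal signal; `f_min > 0`.
#' @export
dynamic_range <- function(f_max, f_min) {
  .chk(all(f_min > 0), "f_min must be positive")
  f_max / f_min
}

#' @rdname dynamic_range
#' @export
delta_f_f0 <- function(f_max, f_min) dynamic_range(f_max, f_min) - 1

#' Green/red ratio image
#'
#' Per-pixel green divided by red, masked (`NA`) where the red channel falls
#' below `red_floor` so that dim pixels do not produce unstable ratios.
#' Works on vectors, matrices, or arrays of matching shape.
#'
#' @param green_stack,red_stack numeric arrays of identical shape.
#' @param red_floor positive intensity floor for the red channel.
#' @return Array of the same shape; `NA` where `red < red_floor`.
#' @export
gr_ratio <- function(green_stack, red_stack, red_floor) {
  .chk(identical(dim(green_stack), dim(red_stack)) &&
         length(green_stack) == length(red_stack),
       "green and red stacks must have identical shape")
  .chk(red_floor > 0, "red_floor must be positive")
  out <- green_stack / red_stack
  out[red_stack < red_floor] <- NA_real_
  out
}

#' Fit the four-parameter Hill equation to calibration points
#'
#' Least-squares fit of `ratio ~ r_min + (r_max - r_min) * ca^n / (kd^n + ca^n)`
#' to (Ca2+, ratio) calibration points by Levenberg-Marquardt with positivity
#' constraints on `kd` and `n`. Starting values default to the data extrema
#' for `r_min`/`r_max`, the Ca2+ value whose ratio is nearest mid-range for
#' `kd`, and 1 for `n`. Standard errors come from the local curvature at the
#' optimum. Non-convergence is reported, never silently returned as a fit.
#'
#' @param points data frame with columns `ca_nM` and `ratio` (a `replicate_id`
#'   column, if present, is carried along but not used by the fit), or a list
#'   of such data frames which are pooled.
#' @param init optional named list/vector with any of `kd_nM`, `hill_n`,
#'   `r_min`, `r_max` to override the default start.
#' @return An object of class `hill_fit` with components `params`
#'   ([hill_params]), `se` (named standard errors), `rss`, `converged`,
#'   `n_points`, `data`, and the underlying `nls` fit.
#' @examples
#' ca <- c(50, 100, 150, 225, 300, 450, 900, 2000)
#' pts <- data.frame(ca_nM = ca, ratio = hill_ratio(ca, salsa6f_hill()))
#' fit <- fit_hill(pts)
#' coef(fit)
#' @export
fit_hill <- function(points, init = NULL) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(ca_nM = p$ca_nM, ratio = p$ratio)))
  }
  .chk(is.data.frame(points) && all(c("ca_nM", "ratio") %in% names(points)),
       "points must have columns ca_nM and ratio")
  points <- points[is.finite(points$ca_nM) & is.finite(points$ratio), , drop = FALSE]
  .chk(all(points$ca_nM >= 0), "ca_nM must be non-negative")
  .chk(length(unique(points$ca_nM)) >= 4,
       "need >= 4 distinct Ca2+ concentrations for a four-parameter fit")
  .chk(length(unique(points$ratio)) > 1, "all ratios equal: nothing to fit")

  rng <- range(points$ratio)
  mid <- mean(rng)
  start <- list(
    r_min = rng[1],
    r_max = rng[2],
    kd_nM = max(points$ca_nM[which.min(abs(points$ratio - mid))], 1e-3),
    hill_n = 1
  )
  if (!is.null(init)) for (nm in names(init)) start[[nm]] <- init[[nm]]

  fit <- try(minpack.lm::nlsLM(
    ratio ~ r_min + (r_max - r_min) * ca_nM^hill_n / (kd_nM^hill_n + ca_nM^hill_n),
    data = points,
    start = start,
    lower = c(r_min = -Inf, r_max = -Inf, kd_nM = 1e-9, hill_n = 1e-9),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 1024)
  ), silent = TRUE)

  if (inherits(fit, "try-error")) {
    warning("Hill fit did not converge: ", attr(fit, "condition")$message)
    return(structure(list(params = NULL, se = NULL, rss = NA_real_,
                          converged = FALSE, n_points = nrow(points),
                          data = points, fit = NULL),
                     class = "hill_fit"))
  }

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  conv <- isTRUE(fit$convInfo$isConv)
  structure(list(
    params = hill_params(cf[["kd_nM"]], cf[["hill_n"]], cf[["r_min"]], cf[["r_max"]]),
    se = se[names(cf)],
    rss = sum(stats::resid(fit)^2),
    converged = conv,
    n_points = nrow(points),
    data = points,
    fit = fit
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Four-parameter Hill fit")
  if (!x$converged) cat("  [NOT CONVERGED]")
  cat("\n")
  if (!is.null(x$params)) {
    cat(sprintf("  Kd = %.4g +/- %.2g nM, n = %.3g +/- %.2g\n",
                x$params$kd_nM, x$se[["kd_nM"]],
                x$params$hill_n, x$se[["hill_n"]]))
    cat(sprintf("  Rmin = %.4g, Rmax = %.4g, RSS = %.4g, %d points\n",
                x$params$r_min, x$params$r_max, x$rss, x$n_points))
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  if (is.null(object$params)) return(stats::setNames(rep(NA_real_, 4),
    c("kd_nM", "hill_n", "r_min", "r_max")))
  with(object$params, c(kd_nM = kd_nM, hill_n = hill_n, r_min = r_min, r_max = r_max))
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- cbind(Estimate = coef(object), `Std. Error` = object$se[names(coef(object))])
  structure(list(coefficients = tab, rss = object$rss,
                 converged = object$converged, n_points = object$n_points),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat(sprintf("Four-parameter Hill fit on %d points (%s)\n", x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients)
  cat(sprintf("Residual sum of squares: %.5g\n", x$rss))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  .chk(!is.null(object$params), "cannot predict from a non-converged fit")
  ca <- if (is.null(newdata)) object$data$ca_nM
        else if (is.data.frame(newdata)) newdata$ca_nM else newdata
  hill_ratio(ca, object$params)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$ratio - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  .chk(!is.null(x$params), "cannot plot a non-converged fit")
  d <- x$data
  ca <- pmax(d$ca_nM, min(d$ca_nM[d$ca_nM > 0]) / 2)
  graphics::plot(ca, d$ratio, log = "x",
                 xlab = expression(paste("[", Ca^{2 + ''}, "] (nM)")),
                 ylab = "normalized ratio", ...)
  xx <- exp(seq(log(min(ca)), log(max(ca)), length.out = 200))
  graphics::lines(xx, hill_ratio(xx, x$params), col = "red3", lwd = 2)
  invisible(x)
}
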