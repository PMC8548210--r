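#' Fraction bound from band intensities
#'
#' Gel quantification yields bound and free band intensities per lane;
#' the bound fraction is `bound / (bound + free)`.
#'
#' @param bound_intensity,free_intensity Non-negative intensities
#'   (vectorized).
#' @return Fraction bound in `[0, 1]`.
#' @export
fraction_bound <- function(bound_intensity, free_intensity) {
  if (any(bound_intensity < 0) || any(free_intensity < 0)) {
    rlang::abort("band intensities must be non-negative",
                 class = "chromclip_validation_error")
  }
  tot <- bound_intensity + free_intensity
  if (any(tot == 0)) {
    rlang::abort("fraction bound undefined when both bands are zero",
                 class = "chromclip_undefined_rate_error")
  }
  bound_intensity / tot
}

# Specific-binding law with Hill slope.
.hill_y <- function(x, Bmax, Kd, h) Bmax * x^h / (Kd^h + x^h)

# Multi-start Levenberg-Marquardt fit of y ~ offset + sgn * hill(x).
# Binding: offset = 0, sgn = +1. Inhibition: offset = 100, sgn = -1.
.fit_hill_engine <- function(x, y, weight, offset, sgn, model) {
  if (length(x) < 4) {
    rlang::abort("Hill fit needs >= 4 points (3 free parameters)",
                 class = "chromclip_argument_error")
  }
  if (any(x <= 0)) {
    rlang::abort("concentrations must be strictly positive",
                 class = "chromclip_argument_error")
  }
  o <- order(x)
  x <- x[o]; y <- y[o]; weight <- weight[o]
  dat <- data.frame(x = x, y = y)
  span <- max(abs(y - offset), stats::sd(y), 1e-6)
  starts <- expand.grid(
    Kd0 = unname(stats::quantile(x, c(0.25, 0.5, 0.75))),
    h0 = c(0.5, 1, 2)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ offset + sgn * Bmax * x^h / (Kd^h + x^h),
        data = dat,
        start = list(Bmax = span, Kd = starts$Kd0[i], h = starts$h0[i]),
        weights = weight,
        lower = c(Bmax = 0, Kd = 1e-12, h = 1e-3),
        upper = c(Bmax = Inf, Kd = Inf, h = 50),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(
      list(coefficients = c(Bmax = NA_real_, Kd = NA_real_, h = NA_real_),
           std_errors = c(Bmax = NA_real_, Kd = NA_real_, h = NA_real_),
           rss = NA_real_, converged = FALSE, n = length(x),
           model = model, offset = offset, sgn = sgn,
           data = tibble::tibble(concentration_nM = x, response = y,
                                 weight = weight)),
      class = "hill_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) {
                   stats::setNames(rep(NA_real_, 3), names(cf))
                 })
  structure(
    list(coefficients = cf, std_errors = se[names(cf)], rss = best$rss,
         converged = TRUE, n = length(x), model = model,
         offset = offset, sgn = sgn,
         data = tibble::tibble(concentration_nM = x, response = y,
                               weight = weight)),
    class = "hill_fit"
  )
}

#' Fit a specific-binding curve with Hill slope
#'
#' Least-squares fit of `y = Bmax * x^h / (Kd^h + x^h)` to a titration
#' curve: `Bmax` is the plateau, `Kd` the half-saturation concentration
#' (by construction the predicted response at `x = Kd` is exactly
#' `Bmax / 2`), and `h` the Hill slope (cooperativity). Optimization is
#' Levenberg-Marquardt from a fixed grid of starts (`Kd` at the x
#' quartiles, `h` in 0.5/1/2, `Bmax` at the response span) because the
#' objective is multimodal at high `h`; the best start by residual sum
#' of squares wins. Standard errors come from the local curvature at
#' the optimum. Points are unweighted unless a `weight` column is
#' supplied.
#'
#' @param curve Tibble with columns `concentration_nM` (strictly
#'   positive, nM), `response` (fraction bound or percent of control),
#'   optional `weight`.
#' @return A `hill_fit` object; see [tidy.hill_fit()] and
#'   [glance.hill_fit()].
#' @examples
#' x <- 2^(0:7)
#' curve <- tibble::tibble(concentration_nM = x,
#'                         response = x / (10 + x))
#' fit_hill(curve)
#' @export
fit_hill <- function(curve) {
  curve <- tibble::as_tibble(curve)
  w <- if ("weight" %in% names(curve)) curve$weight else {
    rep(1, nrow(curve))
  }
  .fit_hill_engine(curve$concentration_nM, curve$response, w,
                   offset = 0, sgn = 1, model = "binding")
}

#' Remodeling efficiency as percent of the no-RNA control
#'
#' `100 * digested / control`, with 100% defined as the digested
#' fraction when no RNA is added. Values above 100 are permitted and
#' flagged.
#'
#' @param digested_fraction Digested fraction(s) in `[0, 1]`.
#' @param control_digested_fraction Digested fraction of the no-RNA
#'   control, in `(0, 1]`.
#' @return Tibble with `efficiency_pct` and `over_control`.
#' @export
remodeling_efficiency <- function(digested_fraction,
                                  control_digested_fraction) {
  if (any(control_digested_fraction <= 0)) {
    rlang::abort("control digested fraction must be positive",
                 class = "chromclip_argument_error")
  }
  pct <- 100 * digested_fraction / control_digested_fraction
  tibble::tibble(efficiency_pct = pct, over_control = pct > 100)
}

#' Fit a remodeling-inhibition curve
#'
#' Fits the complementary specific-binding form
#' `y = 100 - Bmax * x^h / (Kd^h + x^h)` to percent-of-control
#' remodeling efficiencies versus RNA concentration; `Kd` is then the
#' half-inhibition concentration and `Bmax` the maximal inhibition
#' depth. A flat curve near 100% (no inhibition) yields `Bmax` near 0
#' with a wide standard error rather than a spurious small `Kd`.
#'
#' @param curve Tibble with `concentration_nM` and `response`
#'   (percent of control), optional `weight`.
#' @return A `hill_fit` object with `model = "inhibition"`.
#' @export
fit_inhibition <- function(curve) {
  curve <- tibble::as_tibble(curve)
  w <- if ("weight" %in% names(curve)) curve$weight else {
    rep(1, nrow(curve))
  }
  .fit_hill_engine(curve$concentration_nM, curve$response, w,
                   offset = 100, sgn = -1, model = "inhibition")
}

#' Predict from a Hill fit
#'
#' @param object A `hill_fit`.
#' @param newdata Optional tibble with `concentration_nM`.
#' @param ... Unused.
#' @return Numeric predicted responses.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration_nM else {
    newdata$concentration_nM
  }
  cf <- object$coefficients
  unname(object$offset +
           object$sgn * .hill_y(x, cf[["Bmax"]], cf[["Kd"]], cf[["h"]]))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit: %s> %s\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  cf <- x$coefficients
  se <- x$std_errors
  for (p in names(cf)) {
    cat(sprintf("  %-5s %.6g (se %.3g)\n", p, cf[[p]], se[[p]]))
  }
  cat(sprintf("  rss %.4g on %d points\n", x$rss, x$n))
  invisible(x)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_errors))
}

#' One-row summary of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One-row tibble with estimates, standard errors, residual sum
#'   of squares, point count and convergence flag.
#' @export
glance.hill_fit <- function(x, ...) {
  cf <- x$coefficients
  se <- x$std_errors
  tibble::tibble(
    model = x$model,
    Bmax = unname(cf["Bmax"]), Bmax_se = unname(se["Bmax"]),
    Kd = unname(cf["Kd"]), Kd_se = unname(se["Kd"]),
    h = unname(cf["h"]), h_se = unname(se["h"]),
    rss = x$rss, n = x$n, converged = x$converged
  )
}
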