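# broom-style tidiers for the fitted objects.

#' @rdname fit_relaxation
#' @param x A `relaxation_fit`.
#' @param ... Unused.
#' @method tidy relaxation_fit
#' @export
tidy.relaxation_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov), 0))
  tibble::tibble(
    term = c("x0", "A", "tau"),
    estimate = c(x$x0, x$A, x$tau),
    std.error = if (length(se) == 3) se else rep(NA_real_, 3))
}

#' @rdname fit_relaxation
#' @method glance relaxation_fit
#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, tau = x$tau,
                 plateau = x$x0 - x$A, nobs = x$n)
}

#' @rdname fit_linear_region
#' @param x A `linear_region_fit`.
#' @param ... Unused.
#' @method tidy linear_region_fit
#' @export
tidy.linear_region_fit <- function(x, ...) {
  tb <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = tb[, 1], std.error = tb[, 2])
}

#' @rdname fit_linear_region
#' @method glance linear_region_fit
#' @export
glance.linear_region_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, nobs = x$n_bins,
                 region_lo = x$region[1], region_hi = x$region[2])
}

#' @rdname estimate_diffusion
#' @param x A `diffusion_estimate`.
#' @param ... Unused.
#' @method glance diffusion_estimate
#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble::tibble(D = x$D, dimensionality = x$dimensionality,
                 slope = x$slope, intercept = x$intercept)
}
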