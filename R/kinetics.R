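# Sorting kinetics: exponential relaxation fit of the ensemble-mean peptide
# position, x(t) = x0 - A*(1 - exp(-t/tau)), and lateral diffusion estimation
# from mean-squared displacement with overlapping time origins.

#' Fit the exponential sorting relaxation model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `x(t) = x0 - A * (1 - exp(-t / tau))` to an ensemble-mean path.
#' Initialisation: `x0` = first point, `A` = first - last, `tau` = time at
#' which half of `A` has been covered (linear interpolation). The plateau is
#' `x(Inf) = x0 - A`; `A > 0` means relaxation toward smaller x.
#'
#' @param times Strictly increasing time points (>= 4).
#' @param mean_positions Ensemble-mean positions at `times`.
#' @return A `relaxation_fit` with elements `x0`, `A`, `tau`, `r_squared`,
#'   `cov` (3x3 covariance of the estimates), `fitted`, `residuals`,
#'   `n`. Has [tidy()] and [glance()] methods. Non-convergence raises a
#'   classed error (`memgrad_fit_error`) carrying the initial values tried.
#' @examples
#' t <- seq(0, 20, length.out = 100)
#' x <- 20 - 8 * (1 - exp(-t / 2.8))
#' fit_relaxation(t, x)
#' @export
fit_relaxation <- function(times, mean_positions) {
  if (length(times) < 4L) {
    abort("Need at least 4 points.", class = "memgrad_validation_error")
  }
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.",
          class = "memgrad_validation_error")
  }
  x <- as.numeric(mean_positions)
  t <- as.numeric(times)

  x0_init <- x[1]
  A_init <- x[1] - x[length(x)]
  # time at which half of the total change has been covered
  half <- x0_init - A_init / 2
  covered <- if (A_init >= 0) x <= half else x >= half
  tau_init <- if (any(covered)) max(t[which(covered)[1]], diff(range(t)) / 100)
              else diff(range(t)) / 2
  if (abs(A_init) < 1e-12) A_init <- 1e-6  # flat input: nudge off the boundary

  start <- list(x0 = x0_init, A = A_init, tau = tau_init)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      x ~ x0 - A * (1 - exp(-t / tau)),
      data = data.frame(t = t, x = x), start = start,
      lower = c(-Inf, -Inf, .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) {
      abort(paste0("Relaxation fit failed to converge: ", conditionMessage(e)),
            class = "memgrad_fit_error", start = start)
    })
  cf <- coef(fit)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((x - mean(x))^2)
  cov <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  structure(list(
    x0 = unname(cf["x0"]), A = unname(cf["A"]), tau = unname(cf["tau"]),
    r_squared = r2, cov = cov, fitted = stats::fitted(fit),
    residuals = res, n = length(t), times = t, observed = x
  ), class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "<relaxation_fit> x0 = %.4g nm, A = %.4g nm, tau = %.4g, R^2 = %.4f (n = %d)\n",
    x$x0, x$A, x$tau, x$r_squared, x$n))
  cat(sprintf("  plateau x(Inf) = x0 - A = %.4g nm\n", x$x0 - x$A))
  invisible(x)
}

#' Lateral diffusion coefficient from mean-squared displacement
#'
#' MSD with overlapping time origins, lag-capped (default max lag 10% of the
#' trajectory length) to bound correlation bias, averaged over replicas;
#' `D = slope / (2 * dimensionality)` by OLS over the fit window.
#'
#' @param trajectories Long tibble with columns `replica`, `time` and one
#'   column per axis (e.g. `x`, and `y` for 2D). Coordinates must be
#'   unwrapped.
#' @param axes Character vector of coordinate columns, default `"x"`.
#' @param fit_window Numeric `c(t_lo, t_hi)` lag-time window for the OLS
#'   slope; default the first half of the available lags.
#' @param max_lag_frac Cap on the largest lag as a fraction of the
#'   trajectory duration, default 0.1.
#' @param box Optional box lengths named by axis; used to detect wrapped
#'   coordinates (single-step jumps > box/2 raise an error).
#' @return A `diffusion_estimate`: list with `D` (nm^2/ns), `dimensionality`,
#'   `fit_window`, `msd` (tibble lag vs msd), `slope`, `intercept`.
#' @export
estimate_diffusion <- function(trajectories, axes = "x", fit_window = NULL,
                               max_lag_frac = 0.1, box = NULL) {
  stopifnot(all(axes %in% names(trajectories)))
  dims <- length(axes)
  reps <- split(trajectories, trajectories$replica)
  times <- sort(unique(trajectories$time))
  dt <- diff(times[1:2])
  n_t <- length(times)
  max_lag <- max(1L, floor(n_t * max_lag_frac))

  if (!is.null(box)) {
    for (ax in axes) {
      L <- if (!is.null(names(box))) box[[ax]] else box[1]
      jumps <- vapply(reps, function(r) max(abs(diff(r[[ax]]))), numeric(1))
      if (any(jumps > L / 2)) {
        abort(sprintf(
          "Coordinate `%s` looks wrapped (jump > box/2); unwrap before estimating D.",
          ax), class = "memgrad_validation_error")
      }
    }
  }

  msd_sum <- numeric(max_lag)
  msd_cnt <- numeric(max_lag)
  for (r in reps) {
    r <- r[order(r$time), , drop = FALSE]
    V <- as.matrix(r[, axes, drop = FALSE])
    for (k in seq_len(max_lag)) {
      dv <- V[(1 + k):nrow(V), , drop = FALSE] - V[1:(nrow(V) - k), , drop = FALSE]
      msd_sum[k] <- msd_sum[k] + sum(rowSums(dv^2))
      msd_cnt[k] <- msd_cnt[k] + nrow(dv)
    }
  }
  msd <- tibble::tibble(lag = seq_len(max_lag) * dt,
                        msd = msd_sum / msd_cnt)
  if (is.null(fit_window)) fit_window <- c(0, max(msd$lag) / 2)
  sub <- dplyr::filter(msd, .data$lag >= fit_window[1],
                       .data$lag <= fit_window[2])
  if (nrow(sub) < 2L) {
    abort("Fit window contains fewer than 2 MSD lags.",
          class = "memgrad_fit_error")
  }
  fit <- lm(msd ~ lag, data = sub)
  D <- max(0, unname(coef(fit)[2]) / (2 * dims))
  structure(list(D = D, dimensionality = dims,
                 fit_window = as.numeric(fit_window), msd = msd,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g nm^2/ns (%dD, lags %.3g-%.3g ns)\n",
              x$D, x$dimensionality, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}
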