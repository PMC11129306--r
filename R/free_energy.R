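# Free-energy machinery. All profiles and surfaces are expressed in units of
# kBT and referenced so that their minimum is exactly 0. Undefined (unsampled)
# bins stay NA and are never imputed.

new_free_energy_profile <- function(coord, delta_F, coordinate = "x",
                                    extra = list()) {
  ref <- suppressWarnings(min(delta_F, na.rm = TRUE))
  df <- tibble::tibble(coord = coord, delta_F = delta_F - ref)
  names(df)[1] <- coordinate
  out <- structure(df, coordinate = coordinate,
                   class = c("free_energy_profile", class(tibble::tibble())))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Boltzmann inversion of a density profile
#'
#' `delta_F = -ln(rho / rho_max)` in kBT units, referenced to the density
#' maximum; zero-density bins are undefined (NA).
#'
#' @param density Tibble with a coordinate column (first) and a `density`
#'   column, or a numeric vector of densities with coordinates in names.
#' @param coordinate Name for the coordinate column of the result.
#' @return A `free_energy_profile` tibble (`coordinate` column, `delta_F`
#'   in kBT).
#' @examples
#' d <- tibble::tibble(x = 1:3, density = c(1, exp(-1), exp(-2)))
#' boltzmann_invert_density(d)
#' @export
boltzmann_invert_density <- function(density, coordinate = NULL) {
  if (is.numeric(density)) {
    density <- tibble::tibble(x = as.numeric(names(density)) %||%
                                seq_along(density), density = density)
  }
  coordinate <- coordinate %||% names(density)[1]
  rho <- density$density
  if (any(rho < 0, na.rm = TRUE) || all(rho == 0 | is.na(rho))) {
    abort("Densities must be >= 0 and not all zero.",
          class = "memgrad_validation_error")
  }
  dF <- -log(rho / max(rho, na.rm = TRUE))
  dF[rho == 0] <- NA_real_
  new_free_energy_profile(density[[1]], dF, coordinate)
}

# umbrella windows -----------------------------------------------------------

#' Define an umbrella-sampling window
#'
#' Harmonic bias `0.5 * stiffness * (x - center)^2` on the reaction
#' coordinate (peptide centre-of-mass position along the gradient).
#'
#' @param center Bias centre (nm).
#' @param stiffness Bias stiffness (kJ mol^-1 nm^-2); 0 is allowed and means
#'   an unbiased window.
#' @param samples Reaction-coordinate samples collected under the bias.
#' @param theta Optional paired tilt samples (degrees).
#' @param label Window label.
#' @return A list of class `umbrella_window`.
#' @export
umbrella_window <- function(center, stiffness, samples, theta = NULL,
                            label = NULL) {
  assert_scalar_number(center, "center")
  assert_scalar_number(stiffness, "stiffness", nonneg = TRUE)
  if (length(samples) < 10L) {
    abort("An umbrella window needs at least 10 samples.",
          class = "memgrad_validation_error")
  }
  structure(list(center = center, stiffness = stiffness,
                 samples = as.numeric(samples), theta = theta,
                 label = label %||% sprintf("w%.3g", center)),
            class = "umbrella_window")
}

#' 1D potential of mean force by WHAM
#'
#' Standard weighted-histogram self-consistent iteration: with `M_b` total
#' counts in bin b, `N_i` samples in window i and bias factors
#' `c_ib = exp(-U_i(x_b)/kBT)`, iterate
#' `P_b = M_b / sum_i N_i f_i c_ib`, `1/f_i = sum_b c_ib P_b` until the
#' window free-energy constants move less than `tol` (in kBT). The profile
#' is `-ln P` referenced to its minimum. A single unbiased window reduces
#' exactly to Boltzmann inversion of its histogram.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param grid Bin-centre grid for the reaction coordinate; default: 81
#'   bins spanning all samples.
#' @param kbt Thermal energy (kJ/mol) matching the stiffness units; default
#'   [kBT()] at 300 K.
#' @param tol Convergence tolerance on the window constants (kBT), default
#'   1e-8.
#' @param max_iter Iteration cap, default 1e5.
#' @param min_overlap Warn when adjacent windows share less than this
#'   fraction of histogram support, default 0.05.
#' @return A `free_energy_profile` over the grid with attributes
#'   `n_iter`, `window_constants` (f_i in kBT), `counts`.
#' @export
wham_1d <- function(windows, grid = NULL, kbt = kBT(), tol = 1e-8,
                    max_iter = 1e5, min_overlap = 0.05) {
  if (length(windows) < 1L) {
    abort("Need at least one umbrella window.", class = "memgrad_validation_error")
  }
  all_x <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(grid)) {
    grid <- seq(min(all_x), max(all_x), length.out = 81L)
  }
  bw <- diff(grid[1:2])
  edges <- c(grid - bw / 2, grid[length(grid)] + bw / 2)

  counts <- vapply(windows, function(w) {
    # samples outside the grid are simply not counted
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE,
                        left.open = FALSE)
    tabulate(idx[idx >= 1L & idx <= length(grid)], nbins = length(grid))
  }, numeric(length(grid)))
  counts <- matrix(counts, nrow = length(grid))
  check_window_overlap(windows, counts, min_overlap)

  M <- rowSums(counts)              # bins x 1
  N <- colSums(counts)              # windows
  U <- vapply(windows, function(w) {
    0.5 * w$stiffness * (grid - w$center)^2 / kbt
  }, numeric(length(grid)))         # bias in kBT, bins x windows
  U <- matrix(U, nrow = length(grid))
  C <- exp(-U)

  f <- rep(0, length(windows))      # -ln of the normalisation constants, kBT
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(C %*% (N * exp(f)))
    P <- ifelse(denom > 0, M / denom, 0)
    f_new <- -log(pmax(colSums(P * C), .Machine$double.xmin))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (it >= max_iter) {
      abort(sprintf("WHAM did not converge in %d iterations (delta %.3g kBT).",
                    as.integer(max_iter), delta),
            class = "memgrad_fit_error")
    }
  }
  dF <- -log(P)
  dF[M == 0] <- NA_real_
  prof <- new_free_energy_profile(grid, dF, "x",
                                  extra = list(n_iter = it,
                                               window_constants = f,
                                               counts = counts,
                                               kbt = kbt))
  prof
}

check_window_overlap <- function(windows, counts, min_overlap) {
  if (length(windows) < 2L) return(invisible())
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  for (j in seq_len(length(windows) - 1L)) {
    a <- counts[, ord[j]] > 0
    b <- counts[, ord[j + 1L]] > 0
    shared <- sum(a & b)
    if (shared == 0L) {
      abort(sprintf(
        "Umbrella windows at %.3g and %.3g have no overlapping histogram support.",
        centers[ord[j]], centers[ord[j + 1L]]),
        class = "memgrad_validation_error")
    }
    frac <- shared / min(sum(a), sum(b))
    if (frac < min_overlap) {
      warn(sprintf("Windows at %.3g and %.3g overlap on only %.1f%% of bins.",
                   centers[ord[j]], centers[ord[j + 1L]], 100 * frac))
    }
  }
  invisible()
}

#' Tilt free-energy profile of an umbrella window
#'
#' `delta_F(theta) = -ln(P(theta) / P(theta_0))` with `theta_0` the most
#' likely tilt in the window; `delta_F(theta_0) = 0` exactly, unsampled bins
#' NA. By default the raw marginal histogram is used (no sin-theta Jacobian
#' division); set `jacobian = TRUE` for the solid-angle-corrected profile.
#'
#' @param theta_samples Tilt angles (degrees) in `[0, 90]`.
#' @param bin_width Bin width (degrees), default 1.
#' @param min_samples Minimum number of samples, default 50.
#' @param jacobian Divide the histogram by sin(theta) before inverting.
#' @return A `free_energy_profile` over `theta` with attribute `theta0`.
#' @export
tilt_free_energy <- function(theta_samples, bin_width = 1, min_samples = 50L,
                             jacobian = FALSE) {
  th <- theta_samples[!is.na(theta_samples)]
  if (length(th) < min_samples) {
    abort(sprintf("Need at least %d tilt samples.", min_samples),
          class = "memgrad_validation_error")
  }
  if (any(th < 0 | th > 90)) {
    abort("Tilt samples must lie in [0, 90] degrees.",
          class = "memgrad_validation_error")
  }
  edges <- seq(0, 90, by = bin_width)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  h <- graphics::hist(th, breaks = edges, plot = FALSE, include.lowest = TRUE,
                      right = FALSE)
  p <- h$counts / sum(h$counts)
  if (jacobian) {
    jac <- sin(pmax(h$mids, bin_width / 4) * pi / 180)
    p <- ifelse(p > 0, p / jac, 0)
  }
  i0 <- which.max(p)
  dF <- -log(p / p[i0])
  dF[p == 0] <- NA_real_
  prof <- new_free_energy_profile(h$mids, dF, "theta",
                                  extra = list(theta0 = h$mids[i0],
                                               counts = h$counts))
  prof
}

#' Monotone x-to-thickness coordinate mapping
#'
#' Converts gradient-axis positions into local membrane thickness through
#' the linear-region fit (the one-to-one map that makes peptide position a
#' thickness reaction coordinate).
#'
#' @param fit A `linear_region_fit` (or list with `slope`, `intercept`).
#' @return A function `x -> d` of class `coordinate_mapping` with the fit
#'   stored in attributes; errors if the slope is 0 (non-monotone map).
#' @export
thickness_mapping <- function(fit) {
  if (fit$slope == 0) {
    abort("Mapping is not monotone: fitted slope is 0.",
          class = "memgrad_validation_error")
  }
  f <- function(x) fit$intercept + fit$slope * x
  structure(f, slope = fit$slope, intercept = fit$intercept,
            class = c("coordinate_mapping", "function"))
}

#' Compose an additive 2D free-energy surface
#'
#' `delta_F(d, theta) = delta_F(d) + delta_F(theta | window at d)`,
#' re-referenced so the global minimum is 0, and masked (NA) above
#' `cutoff` kBT. The thickness support points are the umbrella-window
#' centres mapped through `mapping`; the sum is an approximation that
#' neglects d-theta correlation inside a window.
#'
#' @param pmf_d A `free_energy_profile` over x (from [wham_1d()]).
#' @param tilt_profiles Named-or-ordered list of per-window tilt
#'   `free_energy_profile`s, one per entry of `window_centers`.
#' @param window_centers Umbrella centres (nm, x coordinate) at which the
#'   tilt profiles were measured.
#' @param mapping A [thickness_mapping()]; identity when NULL (surface over
#'   x instead of d).
#' @param cutoff Mask level in kBT, default 10.
#' @return A `free_energy_surface` tibble: `d`, `theta`, `delta_F` (NA where
#'   masked or unsampled), with attributes `minimum` (list `d`, `theta`) and
#'   `cutoff`.
#' @export
compose_surface_2d <- function(pmf_d, tilt_profiles, window_centers,
                               mapping = NULL, cutoff = 10) {
  if (length(tilt_profiles) != length(window_centers)) {
    abort("One tilt profile per window centre is required.",
          class = "memgrad_validation_error")
  }
  d_vals <- if (is.null(mapping)) window_centers else mapping(window_centers)
  dd <- diff(d_vals[order(window_centers)])
  if (length(dd) > 0 && !(all(dd > 0) || all(dd < 0))) {
    abort("Mapping is not monotone over the window centres.",
          class = "memgrad_validation_error")
  }
  pmf_fun <- function(xq) {
    ok <- !is.na(pmf_d$delta_F)
    if (!any(ok)) abort("PMF has no defined bins.", class = "memgrad_validation_error")
    stats::approx(pmf_d[[1]][ok], pmf_d$delta_F[ok], xout = xq, rule = 1)$y
  }
  f_at_window <- pmf_fun(window_centers)
  if (any(is.na(f_at_window))) {
    abort("Every window centre needs a PMF support point.",
          class = "memgrad_validation_error")
  }
  theta_grid <- tilt_profiles[[1]]$theta
  rows <- purrr::map2(seq_along(d_vals), f_at_window, function(i, fd) {
    tp <- tilt_profiles[[i]]
    if (!isTRUE(all.equal(tp$theta, theta_grid))) {
      abort("All tilt profiles must share one theta grid.",
            class = "memgrad_validation_error")
    }
    tibble::tibble(d = d_vals[i], theta = tp$theta,
                   delta_F = fd + tp$delta_F)
  })
  surf <- dplyr::bind_rows(rows)
  ref <- min(surf$delta_F, na.rm = TRUE)
  surf$delta_F <- surf$delta_F - ref
  imin <- which.min(surf$delta_F)
  minimum <- list(d = surf$d[imin], theta = surf$theta[imin])
  surf$delta_F[surf$delta_F > cutoff] <- NA_real_
  ord <- order(surf$d)  # sort rows so the d grid is increasing
  structure(surf[ord, , drop = FALSE], minimum = minimum, cutoff = cutoff,
            class = c("free_energy_surface", class(tibble::tibble())))
}

#' Thermally accessible regions of a free-energy surface
#'
#' For each threshold (multiples of kBT above the global minimum) the set
#' `{delta_F <= threshold}` is decomposed into 4-connected components on the
#' (d, theta) grid, and each component is projected onto d and theta as an
#' interval reported at bin-edge resolution. Components are ordered by their
#' minimum free energy, so component 1 always contains the global minimum;
#' regions are nested across increasing thresholds.
#'
#' @param surface A `free_energy_surface` (long tibble `d`, `theta`,
#'   `delta_F`); NA treated as inaccessible.
#' @param thresholds Energy thresholds in kBT, default `c(1, 2, 5, 10)`.
#' @return Tibble with columns `threshold`, `component`, `d_lo`, `d_hi`,
#'   `theta_lo`, `theta_hi`, `min_F`.
#' @export
accessible_regions <- function(surface, thresholds = c(1, 2, 5, 10)) {
  d_grid <- sort(unique(surface$d))
  t_grid <- sort(unique(surface$theta))
  Fm <- matrix(NA_real_, nrow = length(d_grid), ncol = length(t_grid))
  Fm[cbind(match(surface$d, d_grid), match(surface$theta, t_grid))] <-
    surface$delta_F
  if (all(is.na(Fm))) {
    abort("Surface has no defined values.", class = "memgrad_validation_error")
  }
  d_step <- if (length(d_grid) > 1) stats::median(diff(d_grid)) else 0
  t_step <- if (length(t_grid) > 1) stats::median(diff(t_grid)) else 0

  out <- purrr::map(thresholds, function(thr) {
    mask <- !is.na(Fm) & Fm <= thr
    if (!any(mask)) return(NULL)
    lab <- label_components(mask)
    comp_ids <- sort(unique(lab[lab > 0]))
    comp_rows <- purrr::map(comp_ids, function(id) {
      cells <- which(lab == id, arr.ind = TRUE)
      tibble::tibble(
        threshold = thr,
        d_lo = d_grid[min(cells[, 1])] - d_step / 2,
        d_hi = d_grid[max(cells[, 1])] + d_step / 2,
        theta_lo = t_grid[min(cells[, 2])] - t_step / 2,
        theta_hi = t_grid[max(cells[, 2])] + t_step / 2,
        min_F = min(Fm[cells]))
    })
    res <- dplyr::bind_rows(comp_rows)
    res <- dplyr::arrange(res, .data$min_F)
    res$component <- seq_len(nrow(res))
    res
  })
  dplyr::bind_rows(out)[, c("threshold", "component", "d_lo", "d_hi",
                            "theta_lo", "theta_hi", "min_F")]
}

# 4-neighbour connected-component labelling by flood fill (grids are small)
label_components <- function(mask) {
  lab <- matrix(0L, nrow = nrow(mask), ncol = ncol(mask))
  next_id <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        next_id <- next_id + 1L
        queue <- list(c(i, j))
        lab[i, j] <- next_id
        while (length(queue) > 0L) {
          cur <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (nb in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            ii <- cur[1] + nb[1]; jj <- cur[2] + nb[2]
            if (ii >= 1L && ii <= nrow(mask) && jj >= 1L && jj <= ncol(mask) &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- next_id
              queue[[length(queue) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

#' Report accessible regions in the lo-hi per-threshold style
#'
#' @param regions Output of [accessible_regions()].
#' @param digits Rounding for the printed interval bounds, default 2.
#' @return Tibble with columns `threshold`, `d_kT`, `theta_kT`; multiple
#'   components are joined with "/".
#' @export
format_accessible_regions <- function(regions, digits = 2) {
  fmt <- function(lo, hi) sprintf("%.*f-%.*f", digits, lo, digits, hi)
  dplyr::summarise(
    dplyr::group_by(regions, .data$threshold),
    d_kT = paste(fmt(.data$d_lo, .data$d_hi), collapse = "/"),
    theta_kT = paste(fmt(.data$theta_lo, .data$theta_hi), collapse = "/"),
    .groups = "drop")
}
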