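# Peptide geometry and sorting observables: tilt (polar angle of the helix
# axis from the membrane normal, folded to [0, 90] degrees), azimuth (in-plane
# direction of the tilted axis relative to the gradient axis), projected
# hydrophobic length, hydrophobic mismatch, lateral densities, equilibrium
# statistics and the azimuth-uniformity test.

#' Hydrophobic length of a polyleucine transmembrane segment
#'
#' 0.15 nm of hydrophobic length per leucine residue.
#'
#' @param n_leucines Number of leucines, a positive integer.
#' @return Hydrophobic length l_TM in nm.
#' @examples
#' hydrophobic_length(17)  # 2.55 nm
#' hydrophobic_length(29)  # 4.35 nm
#' @export
hydrophobic_length <- function(n_leucines) {
  if (any(n_leucines <= 0) || any(n_leucines != round(n_leucines))) {
    abort("`n_leucines` must be a positive integer.",
          class = "memgrad_validation_error")
  }
  0.15 * n_leucines
}

#' Tilt and azimuth of a rigid helix from backbone bead coordinates
#'
#' The peptide axis is the principal axis (largest-variance direction) of the
#' backbone bead coordinates. Tilt is its angle from the membrane normal,
#' folded to `[0, 90]` degrees (the axis sign is immaterial); azimuth is the
#' angle of the in-plane projection measured from the gradient axis,
#' counter-clockwise in `[0, 360)`, taken with the axis oriented toward
#' positive normal. For an untilted rod the azimuth is undefined and
#' returned as `NaN`.
#'
#' @param backbone_positions Matrix or data frame with columns x, y, z (>= 2
#'   non-coincident beads).
#' @param gradient_axis,normal_axis Axis labels among `"x"`, `"y"`, `"z"`;
#'   defaults `"x"` and `"z"`.
#' @return Named list `theta` (deg), `phi` (deg or NaN), `axis` (unit vector).
#' @examples
#' rod <- cbind(x = c(0, 1), y = 0, z = c(0, sqrt(3)))  # 30 deg in xz plane
#' tilt_and_azimuth(rod)
#' @export
tilt_and_azimuth <- function(backbone_positions, gradient_axis = "x",
                             normal_axis = "z") {
  pos <- as.matrix(backbone_positions[, 1:3, drop = FALSE])
  if (nrow(pos) < 2L) {
    abort("Need at least 2 backbone beads.", class = "memgrad_validation_error")
  }
  ctr <- sweep(pos, 2, colMeans(pos))
  if (all(abs(ctr) < 1e-12)) {
    abort("Backbone beads are coincident; axis undefined.",
          class = "memgrad_validation_error")
  }
  sv <- svd(ctr)
  axis <- sv$v[, 1]
  idx <- c(x = 1L, y = 2L, z = 3L)
  i_n <- idx[[normal_axis]]
  i_g <- idx[[gradient_axis]]
  i_p <- setdiff(1:3, c(i_n, i_g))  # remaining in-plane axis
  if (axis[i_n] < 0) axis <- -axis  # orient toward +normal before projecting
  cos_t <- min(1, abs(axis[i_n]))
  theta <- acos(cos_t) * 180 / pi
  in_plane <- sqrt(axis[i_g]^2 + axis[i_p]^2)
  phi <- if (in_plane < 1e-10) NaN else {
    (atan2(axis[i_p], axis[i_g]) * 180 / pi) %% 360
  }
  list(theta = theta, phi = phi, axis = axis)
}

#' Projected length and hydrophobic mismatch
#'
#' The projected hydrophobic length along the membrane normal is
#' `l_proj = l_TM * cos(theta)`. Mismatch follows the convention
#' `l_mis = l_proj - d` (negative when the peptide is shorter than its local
#' membrane); set `convention = "thickness_minus_projected"` for the
#' opposite sign.
#'
#' @param l_TM Hydrophobic length (nm), > 0.
#' @param theta Tilt angle (degrees).
#' @param local_d Local membrane thickness (nm); may be NA (mismatch NA).
#' @param convention Sign convention for the mismatch.
#' @return Tibble with columns `l_proj` and `l_mis` (nm).
#' @examples
#' projected_length_and_mismatch(4.35, 23, 5.1)
#' @export
projected_length_and_mismatch <- function(l_TM, theta, local_d = NA_real_,
                                          convention = c("projected_minus_thickness",
                                                         "thickness_minus_projected")) {
  convention <- match.arg(convention)
  if (any(l_TM <= 0, na.rm = TRUE)) {
    abort("`l_TM` must be > 0.", class = "memgrad_validation_error")
  }
  l_proj <- l_TM * cos(theta * pi / 180)
  l_mis <- switch(convention,
                  projected_minus_thickness = l_proj - local_d,
                  thickness_minus_projected = local_d - l_proj)
  tibble::tibble(l_proj = l_proj, l_mis = l_mis)
}

#' Per-frame peptide observations from bead frames
#'
#' Extracts, per frame: peptide centre of mass, tilt and azimuth from the
#' backbone beads, the local membrane thickness at the peptide (interleaflet
#' phosphate distance within an in-plane radius of the centre of mass, or
#' the supplied reference profile when too few phosphates are nearby), the
#' projected length and the mismatch.
#'
#' @param frames A `synthetic_frames` tibble (or compatible bead table).
#' @param l_TM Hydrophobic length (nm); taken from the frames attribute when
#'   NULL.
#' @param local_radius In-plane radius (nm) for the local thickness
#'   estimate, default 0.75 (a 1.5 nm window, matching the 3x3-cell map
#'   neighbourhood at 0.5 nm cells).
#' @param min_local Minimum phosphates per leaflet within the radius before
#'   falling back to `profile`, default 5.
#' @param profile Optional fallback `thickness_profile` or function of x.
#' @param convention Mismatch sign convention, see
#'   [projected_length_and_mismatch()].
#' @return A tibble with one row per frame: `frame`, `x`, `y`, `z`,
#'   `theta_deg`, `phi_deg`, `d_nm`, `lproj_nm`, `lmis_nm`.
#' @export
peptide_observations <- function(frames, l_TM = NULL, local_radius = 0.75,
                                 min_local = 5L, profile = NULL,
                                 convention = "projected_minus_thickness") {
  l_TM <- l_TM %||% attr(frames, "l_TM")
  if (is.null(l_TM)) {
    abort("`l_TM` not supplied and not recorded on `frames`.",
          class = "memgrad_validation_error")
  }
  box <- attr(frames, "box")
  fallback <- if (!is.null(profile)) as_thickness_function(profile) else NULL
  split_frames <- split(frames, frames$frame)
  rows <- purrr::map(split_frames, function(fr) {
    bb <- fr[fr$role == "backbone", c("x", "y", "z")]
    geom <- tilt_and_azimuth(as.matrix(bb))
    com <- colMeans(as.matrix(bb))
    ph <- fr[fr$role == "phosphate", ]
    dx <- ph$x - com[1]
    dy <- ph$y - com[2]
    if (!is.null(box)) dy <- dy - box[2] * round(dy / box[2])
    near <- sqrt(dx^2 + dy^2) <= local_radius
    up <- ph$z[near & ph$leaflet == "upper"]
    lo <- ph$z[near & ph$leaflet == "lower"]
    d <- if (length(up) >= min_local && length(lo) >= min_local) {
      mean(up) - mean(lo)
    } else if (!is.null(fallback)) {
      fallback(com[1])
    } else NA_real_
    pl <- projected_length_and_mismatch(l_TM, geom$theta, d, convention)
    tibble::tibble(frame = fr$frame[1], x = com[1], y = com[2], z = com[3],
                   theta_deg = geom$theta, phi_deg = geom$phi, d_nm = d,
                   lproj_nm = pl$l_proj, lmis_nm = pl$l_mis)
  })
  dplyr::bind_rows(rows)
}

#' Lateral peptide density profile along the gradient
#'
#' Histogram of the peptide centre-of-mass x within the analysis window,
#' normalized so that `sum(density) * bin_width = 1`.
#'
#' @param observations Tibble with columns `frame` (or `time`) and `x`.
#' @param bin_width Bin width (nm), default 0.5.
#' @param window Analysis window: `"last-half"` (default), `"all"`, or a
#'   numeric `c(lo, hi)` range of the frame/time column.
#' @return Tibble with columns `x` (bin centre), `density` (1/nm), `n`.
#' @export
lateral_density_profile <- function(observations, bin_width = 0.5,
                                    window = "last-half") {
  obs <- apply_window(observations, window)
  if (nrow(obs) == 0L) {
    abort("No observations inside the window.", class = "memgrad_validation_error")
  }
  bins <- floor(obs$x / bin_width)
  tab <- table(bins)
  n <- as.integer(tab)
  tibble::tibble(
    x = (as.numeric(names(tab)) + 0.5) * bin_width,
    density = n / (sum(n) * bin_width),
    n = n)
}

apply_window <- function(observations, window) {
  tcol <- if ("time" %in% names(observations)) "time" else "frame"
  tt <- observations[[tcol]]
  if (is.character(window)) {
    if (window == "all") return(observations)
    if (window == "last-half") {
      return(observations[tt >= (min(tt) + max(tt)) / 2, , drop = FALSE])
    }
    abort("`window` must be \"all\", \"last-half\" or c(lo, hi).",
          class = "memgrad_validation_error")
  }
  observations[tt >= window[1] & tt <= window[2], , drop = FALSE]
}

#' Equilibrium sorting statistics
#'
#' Means and standard deviations of the local thickness, tilt, projected
#' length and mismatch over the analysis window (default: last half of the
#' trajectory, once sorting has equilibrated).
#'
#' @param observations Tibble as returned by [peptide_observations()].
#' @param window See [lateral_density_profile()].
#' @return One-row tibble: `d_eq`, `d_sd`, `theta_eq`, `theta_sd`, `lproj`,
#'   `lproj_sd`, `lmis`, `lmis_sd`, `n_frames`.
#' @export
equilibrium_stats <- function(observations, window = "last-half") {
  obs <- apply_window(observations, window)
  if (nrow(obs) == 0L) {
    abort("No observations inside the window.", class = "memgrad_validation_error")
  }
  msd <- function(v) c(mean(v, na.rm = TRUE),
                       if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  d <- msd(obs$d_nm); th <- msd(obs$theta_deg)
  lp <- msd(obs$lproj_nm); lmv <- msd(obs$lmis_nm)
  tibble::tibble(d_eq = d[1], d_sd = d[2], theta_eq = th[1], theta_sd = th[2],
                 lproj = lp[1], lproj_sd = lp[2], lmis = lmv[1],
                 lmis_sd = lmv[2], n_frames = nrow(obs))
}

#' One-sample Kolmogorov-Smirnov test of azimuth uniformity
#'
#' Tests whether the azimuth angles are compatible with the uniform
#' distribution on `[0, 360)` — i.e. whether there is a directional tilt
#' bias along the gradient. Angles are rescaled to `[0, 1)` and compared to
#' the standard uniform.
#'
#' @param phi_samples Azimuth angles in degrees, within `[0, 360)`; NaN
#'   values (untilted frames) are dropped.
#' @return Tibble with `ks_statistic`, `p_value`, `n`.
#' @export
azimuth_uniformity_test <- function(phi_samples) {
  phi <- phi_samples[!is.na(phi_samples)]
  if (any(phi < 0 | phi >= 360)) {
    abort("Azimuth samples must lie in [0, 360).",
          class = "memgrad_validation_error")
  }
  if (length(phi) < 5L) {
    abort("Need at least 5 azimuth samples.", class = "memgrad_validation_error")
  }
  ks <- suppressWarnings(ks.test(phi / 360, "punif"))
  tibble::tibble(ks_statistic = unname(ks$statistic),
                 p_value = ks$p.value, n = length(phi))
}

#' Reference polyleucine peptide table
#'
#' Reference values for the seven K2LnK2 polyleucine peptides (n = 17-29)
#' characterised in gradient-membrane coarse-grained simulations: hydrophobic
#' length, equilibrium local thickness, tilt, projected length and mismatch
#' from unbiased sorting runs, used as worked-example inputs throughout the
#' package.
#'
#' @return Tibble with columns `peptide`, `n_leucines`, `l_TM`, `d_eq`,
#'   `d_sd`, `theta_eq`, `theta_sd`, `lproj`, `lproj_sd`, `lmis`, `lmis_sd`
#'   (lengths nm, angles degrees).
#' @examples
#' polyleucine_table()
#' @export
polyleucine_table <- function() {
  tibble::tribble(
    ~peptide, ~n_leucines, ~d_eq, ~d_sd, ~theta_eq, ~theta_sd, ~lproj, ~lproj_sd, ~lmis, ~lmis_sd,
    "Leu17", 17L, 3.3, 0.5, 23, 10, 2.3, 0.4, -1.0, 0.9,
    "Leu19", 19L, 3.5, 0.6, 25, 11, 2.6, 0.5, -0.9, 1.1,
    "Leu21", 21L, 3.8, 0.6, 26, 12, 2.8, 0.6, -1.0, 1.2,
    "Leu23", 23L, 4.3, 0.4, 17,  8, 3.3, 0.3, -1.0, 0.7,
    "Leu25", 25L, 4.5, 0.4, 23,  9, 3.4, 0.5, -1.1, 0.9,
    "Leu27", 27L, 4.8, 0.6, 16,  8, 3.9, 0.3, -0.9, 0.9,
    "Leu29", 29L, 5.1, 0.2, 23,  8, 4.0, 0.5, -1.1, 0.7
  ) |>
    dplyr::mutate(l_TM = hydrophobic_length(.data$n_leucines),
                  .after = "n_leucines")
}
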