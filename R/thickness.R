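# Local membrane thickness from phosphate-marker beads. Thickness is the
# interleaflet phosphate distance: per bin, the difference between the mean z
# of the upper-leaflet and lower-leaflet phosphates pooled over frames. Bins
# where either leaflet has fewer than `min_count` samples are reported as NA,
# never imputed.

new_thickness_profile <- function(df, bin_width, min_count = NA_integer_) {
  structure(df, bin_width = bin_width, min_count = min_count,
            class = c("thickness_profile", class(tibble::tibble())))
}

#' 1D thickness profile along the gradient axis
#'
#' @param frames Bead records: a `synthetic_frames` tibble (or any tibble
#'   with columns `role`, `leaflet`, `x`, `z`).
#' @param bin_width Bin width along x (nm), default 0.5.
#' @param min_count Minimum phosphate count per leaflet per bin for the bin
#'   to be defined, default 10.
#' @return A `thickness_profile` tibble: `x` (bin centre, nm), `thickness`
#'   (nm, NA where undefined), `n` (min of the two leaflet counts).
#' @export
thickness_profile_1d <- function(frames, bin_width = 0.5, min_count = 10L) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  ph <- dplyr::filter(frames, .data$role == "phosphate")
  if (nrow(ph) == 0L || length(unique(ph$leaflet)) < 2L) {
    abort("Frames must contain phosphate beads in both leaflets.",
          class = "memgrad_validation_error")
  }
  ph <- dplyr::mutate(ph, bin = floor(.data$x / bin_width))
  agg <- dplyr::summarise(
    dplyr::group_by(ph, .data$bin, .data$leaflet),
    mz = mean(.data$z), n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "leaflet",
                             values_from = c("mz", "n"))
  for (col in c("mz_upper", "mz_lower", "n_upper", "n_lower")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- dplyr::arrange(wide, .data$bin)
  n_min <- pmin(tidyr::replace_na(wide$n_upper, 0L),
                tidyr::replace_na(wide$n_lower, 0L))
  d <- wide$mz_upper - wide$mz_lower
  d[n_min < min_count] <- NA_real_
  new_thickness_profile(
    tibble::tibble(x = (wide$bin + 0.5) * bin_width, thickness = d,
                   n = as.integer(n_min)),
    bin_width = bin_width, min_count = min_count)
}

#' Ordinary least-squares fit of the linear gradient region
#'
#' @param profile A `thickness_profile`.
#' @param region Length-2 numeric `[x_lo, x_hi]` (nm) delimiting the fit.
#' @return A `linear_region_fit` object with elements `slope` (nm/nm),
#'   `intercept` (nm), `r_squared`, `region`, `n_bins` and the underlying
#'   `lm` fit. Has [tidy()] and [glance()] methods.
#' @examples
#' prof <- new_thickness_profile(
#'   tibble::tibble(x = 0:30, thickness = 3 + 0.077 * (0:30), n = 100L), 1)
#' fit_linear_region(prof, c(8, 32))
#' @export
fit_linear_region <- function(profile, region) {
  if (length(region) != 2L || region[1] >= region[2]) {
    abort("`region` must be c(x_lo, x_hi) with x_lo < x_hi.",
          class = "memgrad_validation_error")
  }
  sub <- dplyr::filter(profile, .data$x >= region[1], .data$x <= region[2],
                       !is.na(.data$thickness))
  if (nrow(sub) < 3L) {
    abort("Need at least 3 defined bins inside the fit region.",
          class = "memgrad_fit_error")
  }
  fit <- lm(thickness ~ x, data = sub)
  # summary.lm warns on an exactly linear profile; that input is legitimate
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, region = as.numeric(region), n_bins = nrow(sub),
    fit = fit
  ), class = "linear_region_fit")
}

#' @export
print.linear_region_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_region_fit> slope %.4g nm/nm, intercept %.4g nm, R^2 %.4f over [%g, %g] nm (%d bins)\n",
    x$slope, x$intercept, x$r_squared, x$region[1], x$region[2], x$n_bins))
  invisible(x)
}

# 2D peptide-centred maps ----------------------------------------------------

#' 2D thickness map around the peptide
#'
#' Phosphate beads are rebinned in peptide-centred in-plane coordinates
#' (minimum image in y; x is left unwrapped inside the gradient region) and
#' the interleaflet-distance estimator applied per cell. For each cell a
#' reference thickness is also accumulated by evaluating `reference` (the
#' unperturbed field) at the beads' absolute x, so `thickness - reference`
#' is the peptide-induced perturbation.
#'
#' @param frames Bead records (must include phosphates and, unless
#'   `peptide_com` is given, peptide beads to locate the centre of mass).
#' @param peptide_com Optional tibble `frame`, `x`, `y` of the peptide
#'   centre of mass per frame; computed from backbone beads when NULL.
#' @param half_extent Half-size of the map window (nm), default 3.
#' @param cell Cell edge (nm), default 0.5.
#' @param min_count Minimum per-leaflet count per cell, default 10.
#' @param reference Reference thickness field: a `thickness_profile`, a
#'   function of x, or NULL (reference column NA).
#' @return A `thickness_map` tibble: `dx`, `dy` (cell centres, nm),
#'   `thickness`, `n`, `reference`, `perturbation`.
#' @export
thickness_map_2d <- function(frames, peptide_com = NULL, half_extent = 3,
                             cell = 0.5, min_count = 10L, reference = NULL) {
  assert_scalar_number(cell, "cell", positive = TRUE)
  box <- attr(frames, "box")
  if (is.null(peptide_com)) {
    pep <- dplyr::filter(frames, .data$role == "backbone")
    if (nrow(pep) == 0L) {
      abort("No backbone beads found; supply `peptide_com`.",
            class = "memgrad_validation_error")
    }
    peptide_com <- dplyr::summarise(dplyr::group_by(pep, .data$frame),
                                    x = mean(.data$x), y = mean(.data$y),
                                    .groups = "drop")
  }
  ph <- dplyr::filter(frames, .data$role == "phosphate")
  ph <- dplyr::inner_join(ph, peptide_com, by = "frame",
                          suffix = c("", "_com"))
  ph <- dplyr::mutate(ph, dx = .data$x - .data$x_com,
                      dy = .data$y - .data$y_com)
  if (!is.null(box)) {
    ph$dy <- ph$dy - box[2] * round(ph$dy / box[2])
  }
  ph <- dplyr::filter(ph, abs(.data$dx) <= half_extent,
                      abs(.data$dy) <= half_extent)
  ref_fun <- if (is.null(reference)) function(x) rep(NA_real_, length(x))
             else as_thickness_function(reference)
  ph <- dplyr::mutate(ph,
    ix = floor((.data$dx + half_extent) / cell),
    iy = floor((.data$dy + half_extent) / cell),
    ref = ref_fun(.data$x))

  agg <- dplyr::summarise(
    dplyr::group_by(ph, .data$ix, .data$iy, .data$leaflet),
    mz = mean(.data$z), n = dplyr::n(), mref = mean(.data$ref),
    .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "leaflet",
                             values_from = c("mz", "n", "mref"))
  for (col in c("mz_upper", "mz_lower", "n_upper", "n_lower")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  n_min <- pmin(tidyr::replace_na(wide$n_upper, 0L),
                tidyr::replace_na(wide$n_lower, 0L))
  d <- wide$mz_upper - wide$mz_lower
  d[n_min < min_count] <- NA_real_
  ref <- rowMeans(cbind(wide$mref_upper, wide$mref_lower), na.rm = TRUE)
  out <- tibble::tibble(
    dx = (wide$ix + 0.5) * cell - half_extent,
    dy = (wide$iy + 0.5) * cell - half_extent,
    thickness = d, n = as.integer(n_min),
    reference = ref, perturbation = d - ref)
  structure(dplyr::arrange(out, .data$dx, .data$dy),
            cell = cell, half_extent = half_extent, min_count = min_count,
            class = c("thickness_map", class(tibble::tibble())))
}

#' Thickness perturbation at the peptide position
#'
#' Mean of `thickness - reference` over the central neighbourhood of a
#' peptide-centred map (default 3x3 cells around the origin). This is the
#' "diagonal" value of the perturbation maps: how much the peptide locally
#' thins (negative) or thickens (positive) its host membrane.
#'
#' @param map A `thickness_map` with a defined `reference`.
#' @param neighborhood Half-width of the averaging neighbourhood in cells
#'   (1 = 3x3), default 1.
#' @return Signed perturbation (nm).
#' @export
perturbation_at_peptide <- function(map, neighborhood = 1L) {
  cell <- attr(map, "cell")
  r <- (neighborhood + 0.5) * cell
  ctr <- dplyr::filter(map, abs(.data$dx) <= r, abs(.data$dy) <= r,
                       !is.na(.data$perturbation))
  if (nrow(ctr) == 0L) {
    abort("Central cells of the map are undefined.",
          class = "memgrad_validation_error")
  }
  mean(ctr$perturbation)
}

#' Marginalize a 2D map over y
#'
#' Count-weighted average over `dy`, for consistency checks against the 1D
#' profile restricted to the same window.
#'
#' @param map A `thickness_map`.
#' @return Tibble with columns `dx` and `thickness`.
#' @export
marginalize_map_y <- function(map) {
  ok <- dplyr::filter(map, !is.na(.data$thickness))
  dplyr::summarise(dplyr::group_by(ok, .data$dx),
                   thickness = sum(.data$thickness * .data$n) / sum(.data$n),
                   .groups = "drop")
}
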