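# Gradient-membrane blueprints: ordered lipid patches along the x axis, each
# confined by a flat-bottom positional restraint, with a piecewise-linear
# expected thickness profile (constant inside a pure patch, linear across the
# overlap shared by two adjacent patches).

#' Lipid patch specifications
#'
#' Builds the table of lipid types used to assemble a thickness gradient.
#' Each lipid anchors the membrane thickness of its pure, single-component
#' patch at `reference_thickness`.
#'
#' @param name Character vector of unique lipid labels.
#' @param reference_thickness Thickness (nm) of the pure single-component
#'   membrane of each lipid; must be positive.
#' @param count_per_leaflet Optional lipid counts per leaflet (default 0,
#'   i.e. unspecified); used only by downstream structure generators.
#' @return A tibble with one row per lipid, columns `name`,
#'   `reference_thickness`, `count_per_leaflet`.
#' @examples
#' lipid_specs(c("DYPC", "DOPC", "DGPC", "DNPC"), c(3.34, 4.11, 4.56, 4.95))
#' @export
lipid_specs <- function(name, reference_thickness, count_per_leaflet = 0L) {
  if (length(name) < 1L) {
    abort("At least one lipid is required.", class = "memgrad_validation_error")
  }
  if (anyDuplicated(name)) {
    abort("Lipid names must be unique.", class = "memgrad_validation_error")
  }
  if (any(!is.finite(reference_thickness)) || any(reference_thickness <= 0)) {
    abort("`reference_thickness` must be finite and > 0.",
          class = "memgrad_validation_error")
  }
  tibble::tibble(
    name = as.character(name),
    reference_thickness = as.numeric(reference_thickness),
    count_per_leaflet = as.integer(rep_len(count_per_leaflet, length(name)))
  )
}

#' Flat-bottom restraint specification
#'
#' Restraints are zero inside a half-width interval around the patch centre
#' and harmonic (one-sided wall, energy 0.5*k*(excess)^2) outside; this is
#' what keeps each lipid type inside its x interval while leaving it free to
#' mix within it.
#'
#' @param force_constant Wall stiffness in kJ mol^-1 nm^-2 (default 1000).
#' @param axis Gradient axis label, default `"x"`.
#' @return A list of class `restraint_spec`.
#' @export
restraint_spec <- function(force_constant = 1000, axis = "x") {
  assert_scalar_number(force_constant, "force_constant", nonneg = TRUE)
  structure(list(force_constant = force_constant, axis = axis),
            class = "restraint_spec")
}

#' Lay out lipid patches along the gradient axis
#'
#' Orders the lipids by increasing reference thickness along +x and assigns
#' each an equal-width pure interval, with the requested overlap widths
#' shared between adjacent patches. Pure widths are
#' `(box_length_x - sum(overlaps)) / n_lipids`.
#'
#' @param lipids Tibble from [lipid_specs()].
#' @param box_length_x Box length along the gradient axis (nm).
#' @param overlap_widths Numeric vector of `n_lipids - 1` overlap widths (nm);
#'   may be zero.
#' @param restraint A [restraint_spec()].
#' @return A `patch_layout`: a tibble with one row per patch (columns `name`,
#'   `reference_thickness`, `x_lo`, `x_hi` delimiting the pure interval, and
#'   `overlap_left`, `overlap_right`), with the box length and restraint
#'   spec stored as attributes. Intervals are half-open `[x_lo, x_hi)`.
#' @examples
#' lip <- lipid_specs(c("DYPC", "DOPC", "DGPC", "DNPC"), c(3.34, 4.11, 4.56, 4.95))
#' layout_patches(lip, box_length_x = 40, overlap_widths = c(2, 2, 2))
#' @export
layout_patches <- function(lipids, box_length_x, overlap_widths = numeric(),
                           restraint = restraint_spec()) {
  assert_scalar_number(box_length_x, "box_length_x", positive = TRUE)
  n <- nrow(lipids)
  if (is.null(n) || n < 1L) {
    abort("`lipids` must have at least one row.", class = "memgrad_validation_error")
  }
  if (anyDuplicated(lipids$name)) {
    abort("Lipid names must be unique.", class = "memgrad_validation_error")
  }
  if (length(overlap_widths) != n - 1L) {
    abort(sprintf("`overlap_widths` must have length %d (n_lipids - 1).", n - 1L),
          class = "memgrad_validation_error")
  }
  if (any(overlap_widths < 0)) {
    abort("Overlap widths must be >= 0.", class = "memgrad_validation_error")
  }
  pure_total <- box_length_x - sum(overlap_widths)
  pure_w <- pure_total / n
  if (pure_w <= 0) {
    abort(sprintf(
      "Box of %.3g nm too short for %d patches with %.3g nm total overlap.",
      box_length_x, n, sum(overlap_widths)), class = "memgrad_sizing_error")
  }

  ord <- order(lipids$reference_thickness)
  lipids <- lipids[ord, , drop = FALSE]
  ov <- c(0, overlap_widths, 0)  # overlap to the left/right of patch i
  x_lo <- numeric(n)
  x_hi <- numeric(n)
  pos <- 0
  for (i in seq_len(n)) {
    x_lo[i] <- pos
    x_hi[i] <- pos + pure_w
    pos <- x_hi[i] + ov[i + 1L]
  }

  out <- tibble::tibble(
    name = lipids$name,
    reference_thickness = lipids$reference_thickness,
    x_lo = x_lo,
    x_hi = x_hi,
    overlap_left = ov[seq_len(n)],
    overlap_right = ov[seq_len(n) + 1L]
  )
  new_patch_layout(out, box_length_x = box_length_x, restraint = restraint)
}

new_patch_layout <- function(df, box_length_x, restraint) {
  structure(df,
            box_length_x = box_length_x,
            restraint = restraint,
            class = c("patch_layout", class(tibble::tibble())))
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("<patch_layout> %d patches, box %.3g nm along x\n",
              nrow(x), attr(x, "box_length_x")))
  NextMethod()
}

#' Predicted thickness profile of a patch layout
#'
#' The blueprint model: thickness equals the lipid's reference thickness
#' inside each pure interval and interpolates linearly across each overlap
#' region, giving a continuous piecewise-linear profile.
#'
#' @param layout A `patch_layout`.
#' @param bin_width Spacing of the evaluation grid (nm), default 0.5.
#' @return A `thickness_profile` tibble (`x`, `thickness`, `n` = NA for a
#'   predicted profile) with `bin_width` attribute.
#' @export
predict_thickness_profile <- function(layout, bin_width = 0.5) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  box <- attr(layout, "box_length_x")
  x <- seq(bin_width / 2, box - bin_width / 2 + 1e-12, by = bin_width)
  d <- blueprint_thickness_at(layout, x)
  new_thickness_profile(
    tibble::tibble(x = x, thickness = d, n = NA_integer_),
    bin_width = bin_width
  )
}

#' Evaluate the blueprint thickness model at arbitrary x
#'
#' @param layout A `patch_layout`.
#' @param x Positions (nm) inside `[0, box_length_x)`.
#' @return Thickness (nm) at each `x`.
#' @export
blueprint_thickness_at <- function(layout, x) {
  n <- nrow(layout)
  d <- rep(NA_real_, length(x))
  for (i in seq_len(n)) {
    in_pure <- x >= layout$x_lo[i] & (x < layout$x_hi[i] | i == n)
    d[in_pure] <- layout$reference_thickness[i]
  }
  # linear ramp across each overlap [x_hi[i], x_lo[i+1])
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      lo <- layout$x_hi[i]
      hi <- layout$x_lo[i + 1L]
      if (hi > lo) {
        in_ov <- x >= lo & x < hi
        f <- (x[in_ov] - lo) / (hi - lo)
        d[in_ov] <- (1 - f) * layout$reference_thickness[i] +
          f * layout$reference_thickness[i + 1L]
      }
    }
  }
  # outside the patch span (margins at box edges): clamp to nearest patch
  d[x < layout$x_lo[1L]] <- layout$reference_thickness[1L]
  d[x >= layout$x_hi[n]] <- layout$reference_thickness[n]
  d
}

#' Target for overlap optimization
#'
#' @param slope Target thickness gradient (nm/nm).
#' @param linear_region Length-2 numeric `[x_lo, x_hi]` (nm) over which the
#'   profile should be linear.
#' @return A list of class `thickness_target`.
#' @export
thickness_target <- function(slope, linear_region) {
  assert_scalar_number(slope, "slope")
  if (length(linear_region) != 2L || linear_region[1] >= linear_region[2]) {
    abort("`linear_region` must be c(x_lo, x_hi) with x_lo < x_hi.",
          class = "memgrad_validation_error")
  }
  structure(list(slope = slope, linear_region = as.numeric(linear_region)),
            class = "thickness_target")
}

#' Choose the overlap width that makes the gradient most linear
#'
#' Grid search over candidate uniform overlap widths: for each candidate the
#' layout is built, its predicted profile restricted to the target's linear
#' region, and the objective is the maximum absolute deviation from the
#' ordinary-least-squares line through those points. The candidate with the
#' smallest objective wins; ties break toward the smaller overlap.
#'
#' @param lipids Tibble from [lipid_specs()].
#' @param box_length_x Box length (nm).
#' @param target A [thickness_target()].
#' @param candidate_overlaps Numeric vector of candidate overlap widths (nm).
#' @param bin_width Evaluation grid spacing (nm), default 0.1.
#' @param restraint A [restraint_spec()].
#' @return The winning `patch_layout`, with attributes `objective` (nm) and
#'   `candidates` (tibble of overlap width vs objective).
#' @export
optimize_overlap <- function(lipids, box_length_x, target, candidate_overlaps,
                             bin_width = 0.1, restraint = restraint_spec()) {
  if (length(candidate_overlaps) < 1L) {
    abort("`candidate_overlaps` must be non-empty.",
          class = "memgrad_validation_error")
  }
  candidate_overlaps <- sort(unique(as.numeric(candidate_overlaps)))
  objective <- vapply(candidate_overlaps, function(w) {
    lay <- layout_patches(lipids, box_length_x,
                          rep(w, nrow(lipids) - 1L), restraint)
    overlap_objective(lay, target, bin_width)
  }, numeric(1))
  best <- which.min(objective)  # which.min takes first minimum = smallest overlap
  lay <- layout_patches(lipids, box_length_x,
                        rep(candidate_overlaps[best], nrow(lipids) - 1L),
                        restraint)
  attr(lay, "objective") <- objective[best]
  attr(lay, "candidates") <- tibble::tibble(
    overlap = candidate_overlaps, objective = objective)
  lay
}

overlap_objective <- function(layout, target, bin_width) {
  prof <- predict_thickness_profile(layout, bin_width)
  reg <- target$linear_region
  sub <- dplyr::filter(prof, .data$x >= reg[1], .data$x <= reg[2])
  if (nrow(sub) < 3L) return(Inf)
  fit <- lm(thickness ~ x, data = sub)
  max(abs(stats::residuals(fit)))
}

# flat-bottom restraints ----------------------------------------------------

#' Flat-bottom wall energy
#'
#' Zero for `|x - center| <= half_width`, harmonic in the excess outside:
#' `0.5 * k * (|x - center| - half_width)^2`.
#'
#' @param x Positions (nm).
#' @param center Centre of the zero-force interval (nm).
#' @param half_width Half-width of the zero-force interval (nm), > 0.
#' @param force_constant Wall stiffness k (kJ mol^-1 nm^-2).
#' @return Energies (kJ/mol).
#' @export
flat_bottom_energy <- function(x, center, half_width, force_constant) {
  assert_scalar_number(half_width, "half_width", positive = TRUE)
  excess <- pmax(abs(x - center) - half_width, 0)
  0.5 * force_constant * excess^2
}

restraint_table <- function(layout) {
  rs <- attr(layout, "restraint")
  # zero-force region covers the pure interval plus both shared overlaps
  lo <- layout$x_lo - layout$overlap_left
  hi <- layout$x_hi + layout$overlap_right
  tibble::tibble(
    name = layout$name,
    center = (lo + hi) / 2,
    half_width = (hi - lo) / 2,
    force_constant = rs$force_constant,
    axis = rs$axis
  )
}

#' Write flat-bottom restraints in a GROMACS-style text dialect
#'
#' Emits one restraint record per lipid type: the zero-force interval spans
#' the patch's pure interval plus its shared overlaps, with a harmonic wall
#' outside. The dialect is a GROMACS-style include-topology table
#' (`[ flat_bottom_posres_x ]` section, one line per lipid:
#' `name center_nm half_width_nm force_constant_kj_mol_nm2`), bit-stable
#' across runs.
#'
#' @param layout A `patch_layout`.
#' @param sink File path or connection to write to.
#' @return Invisibly, the restraint table that was written.
#' @seealso [read_flat_bottom_restraints()] for the inverse.
#' @export
write_flat_bottom_restraints <- function(layout, sink) {
  tab <- restraint_table(layout)
  lines <- c(
    "; memgrad flat-bottom positional restraints (GROMACS-style include dialect)",
    "; V(x) = 0 for |x - center| <= half_width; 0.5*k*(|x-center|-half_width)^2 outside",
    sprintf("[ flat_bottom_posres_%s ]", tab$axis[1]),
    "; name  center_nm  half_width_nm  force_constant_kj_mol_nm2",
    sprintf("%s  %.10g  %.10g  %.10g",
            tab$name, tab$center, tab$half_width, tab$force_constant)
  )
  writeLines(lines, sink)
  invisible(tab)
}

#' Read back a flat-bottom restraint file
#'
#' @param path File written by [write_flat_bottom_restraints()].
#' @return Tibble with columns `name`, `center`, `half_width`,
#'   `force_constant`, `axis`.
#' @export
read_flat_bottom_restraints <- function(path) {
  lines <- readLines(path)
  axis <- sub(".*\\[ flat_bottom_posres_(\\w+) \\].*", "\\1",
              grep("^\\[ flat_bottom_posres_", lines, value = TRUE)[1])
  rows <- lines[!grepl("^;", lines) & !grepl("^\\[", lines) & nzchar(lines)]
  parts <- strsplit(trimws(rows), "\\s+")
  tibble::tibble(
    name = vapply(parts, `[`, character(1), 1L),
    center = as.numeric(vapply(parts, `[`, character(1), 2L)),
    half_width = as.numeric(vapply(parts, `[`, character(1), 3L)),
    force_constant = as.numeric(vapply(parts, `[`, character(1), 4L)),
    axis = axis
  )
}

#' Write a thickness profile as CSV
#'
#' Columns `x_nm`, `thickness_nm` (and `n` when counts are present).
#'
#' @param profile A `thickness_profile`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_thickness_profile <- function(profile, path) {
  out <- data.frame(x_nm = profile$x, thickness_nm = profile$thickness)
  if (!all(is.na(profile$n))) out$n <- profile$n
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a thickness profile CSV
#'
#' @param path CSV with columns `x_nm`, `thickness_nm` (optional `n`).
#' @return A `thickness_profile` tibble.
#' @export
read_thickness_profile <- function(path) {
  df <- utils::read.csv(path)
  xs <- sort(df$x_nm)
  bw <- if (length(xs) > 1) stats::median(diff(xs)) else 0.5
  new_thickness_profile(
    tibble::tibble(x = df$x_nm, thickness = df$thickness_nm,
                   n = if ("n" %in% names(df)) df$n else NA_integer_),
    bin_width = bw
  )
}
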