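# Desk-scale surrogate of mismatch-driven sorting. The peptide centre of mass
# along the gradient follows a mean-reverting (Ornstein-Uhlenbeck) overdamped
# Langevin equation: the lateral force is proportional to the distance from
# the equilibrium position, mirroring the observation that sorting velocity is
# proportional to the hydrophobic mismatch. Also generates synthetic
# bead-level membrane + peptide frames so every analysis is testable without
# an MD engine.

#' Parameters of the stochastic sorting model
#'
#' The unbiased model is `dx = -(x - x_eq)/tau dt + sqrt(2 D) dW`, i.e. an
#' Ornstein-Uhlenbeck process with stationary mean `x_eq` and variance
#' `D * tau`. An optional harmonic umbrella bias `0.5 k_b (x - x_c)^2`
#' contributes the drift `-(k_b / gamma_eff) (x - x_c)` with the effective
#' friction fixed by fluctuation-dissipation, `gamma_eff = kBT / D`.
#'
#' @param x_eq Equilibrium position (nm).
#' @param tau Relaxation time constant (ns), > 0.
#' @param diffusion Diffusion coefficient D (nm^2/ns), >= 0.
#' @param x0 Initial position (nm).
#' @param dt Integration timestep (ns); default `tau / 100`.
#' @param n_steps Number of steps per replica.
#' @param n_replicas Number of independent replicas, >= 1.
#' @param seed Integer seed for reproducibility.
#' @param bias Optional umbrella bias, `list(center =, stiffness =)` with
#'   stiffness in kJ mol^-1 nm^-2.
#' @param temperature Temperature (K) defining kBT for the bias mobility.
#' @return A list of class `sorting_params`.
#' @export
sorting_params <- function(x_eq, tau, diffusion, x0,
                           dt = tau / 100, n_steps = 1000L, n_replicas = 1L,
                           seed = 1L, bias = NULL, temperature = 300) {
  assert_scalar_number(tau, "tau", positive = TRUE)
  assert_scalar_number(diffusion, "diffusion", nonneg = TRUE)
  assert_scalar_number(dt, "dt", positive = TRUE)
  if (n_replicas < 1L) {
    abort("`n_replicas` must be >= 1.", class = "memgrad_validation_error")
  }
  if (!is.null(bias)) {
    if (!all(c("center", "stiffness") %in% names(bias)) || bias$stiffness <= 0) {
      abort("`bias` must be list(center=, stiffness=) with stiffness > 0.",
            class = "memgrad_validation_error")
    }
  }
  structure(list(
    x_eq = x_eq, tau = tau, diffusion = diffusion, x0 = x0, dt = dt,
    n_steps = as.integer(n_steps), n_replicas = as.integer(n_replicas),
    seed = as.integer(seed), bias = bias, temperature = temperature
  ), class = "sorting_params")
}

#' Simulate an ensemble of sorting trajectories
#'
#' Euler-Maruyama integration of the mean-reverting sorting model, vectorised
#' over replicas. Deterministic given the seed. A timestep of `tau / 10` or
#' coarser triggers a warning (the integrator's documented accuracy
#' contract); `dt >= tau` is an error.
#'
#' @param params A [sorting_params()] object.
#' @return An `ensemble_trajectory`: a long tibble with columns `replica`,
#'   `time` (ns) and `x` (nm), carrying `params` as an attribute. Time 0 is
#'   the initial condition, so each replica has `n_steps + 1` rows.
#' @examples
#' p <- sorting_params(x_eq = 20, tau = 100, diffusion = 0.02, x0 = 28,
#'                     n_steps = 200, n_replicas = 5, seed = 42)
#' ens <- simulate_sorting_ensemble(p)
#' @export
simulate_sorting_ensemble <- function(params) {
  stopifnot(inherits(params, "sorting_params"))
  if (params$dt >= params$tau) {
    abort("`dt` must be smaller than `tau` for a stable integration.",
          class = "memgrad_validation_error")
  }
  if (params$dt >= params$tau / 10) {
    warn("`dt` >= tau/10: integration error may exceed the documented tolerance.")
  }
  n_rep <- params$n_replicas
  n_stp <- params$n_steps
  dt <- params$dt
  withr_seed <- params$seed
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(withr_seed)

  drift_bias <- 0
  bias_center <- 0
  if (!is.null(params$bias)) {
    gamma_eff <- kBT(params$temperature) / params$diffusion
    drift_bias <- params$bias$stiffness / gamma_eff
    bias_center <- params$bias$center
  }
  noise_sd <- sqrt(2 * params$diffusion * dt)

  x <- matrix(NA_real_, nrow = n_rep, ncol = n_stp + 1L)
  x[, 1L] <- params$x0
  for (s in seq_len(n_stp)) {
    xi <- x[, s]
    drift <- -(xi - params$x_eq) / params$tau
    if (drift_bias > 0) drift <- drift - drift_bias * (xi - bias_center)
    x[, s + 1L] <- xi + drift * dt + noise_sd * stats::rnorm(n_rep)
  }

  out <- tibble::tibble(
    replica = rep(seq_len(n_rep), times = n_stp + 1L),
    time = rep(seq(0, n_stp) * dt, each = n_rep),
    x = as.vector(x)
  )
  out <- dplyr::arrange(out, .data$replica, .data$time)
  structure(out, params = params,
            class = c("ensemble_trajectory", class(tibble::tibble())))
}

#' Ensemble-mean path of a trajectory ensemble
#'
#' @param ensemble An `ensemble_trajectory` (or any tibble with `time`, `x`).
#' @return Tibble with columns `time` and `mean_x`.
#' @export
ensemble_mean_path <- function(ensemble) {
  dplyr::summarise(dplyr::group_by(ensemble, .data$time),
                   mean_x = mean(.data$x), .groups = "drop")
}

# synthetic bead-level frames ------------------------------------------------

#' Synthesize bead-level membrane + peptide frames
#'
#' Generates coarse-grained-like frames realizing a prescribed thickness
#' profile: phosphate marker beads on each leaflet at `z = +/- d(x)/2` plus
#' Gaussian positional noise, and (optionally) a rigid helical rod peptide of
#' hydrophobic length `l_TM` whose tilt and azimuth are drawn independently
#' per frame from user-supplied samplers. A local thickness perturbation
#' around the peptide (for example a dimple caused by a short peptide) can be
#' encoded via `perturbation`.
#'
#' @param profile A `thickness_profile` (or a function of x returning d) that
#'   defines the unperturbed thickness field; evaluated by interpolation.
#' @param n_lipids_per_leaflet Number of phosphate beads per leaflet per frame.
#' @param n_frames Number of frames.
#' @param positional_noise_sd Gaussian noise (nm) added to each phosphate
#'   z coordinate, >= 0.
#' @param box Numeric `c(Lx, Ly, Lz)` box dimensions (nm).
#' @param peptide Optional `list(l_TM =, x_com =, y_com =, tilt_sampler =,
#'   azimuth_sampler =, bead_spacing =)`. Samplers are functions `n ->
#'   degrees`; defaults: tilt 0, azimuth uniform, bead spacing 0.3 nm.
#' @param perturbation Optional function `(dx, dy) -> delta_d` (nm) added to
#'   the thickness field at in-plane displacement (dx, dy) from the peptide.
#' @param seed Integer seed.
#' @return A `synthetic_frames` tibble: columns `frame`, `bead_id`, `role`
#'   (`"phosphate"`/`"backbone"`/`"anchor"`), `leaflet` (`"upper"`/`"lower"`/
#'   `"peptide"`), `x`, `y`, `z`. Attributes: `box`, `profile`, `l_TM`,
#'   `seed`.
#' @examples
#' frames <- synthesize_membrane_trajectory(
#'   function(x) rep(4, length(x)), n_lipids_per_leaflet = 100, n_frames = 5,
#'   positional_noise_sd = 0, box = c(40, 10, 10), seed = 1)
#' @export
synthesize_membrane_trajectory <- function(profile, n_lipids_per_leaflet,
                                           n_frames, positional_noise_sd,
                                           box = c(40, 10, 10),
                                           peptide = NULL,
                                           perturbation = NULL,
                                           seed = 1L) {
  assert_scalar_number(positional_noise_sd, "positional_noise_sd", nonneg = TRUE)
  d_fun <- as_thickness_function(profile)
  if (!is.null(peptide)) {
    peptide$bead_spacing <- peptide$bead_spacing %||% 0.3
    peptide$y_com <- peptide$y_com %||% (box[2] / 2)
    peptide$tilt_sampler <- peptide$tilt_sampler %||% function(n) rep(0, n)
    peptide$azimuth_sampler <- peptide$azimuth_sampler %||%
      function(n) stats::runif(n, 0, 360)
    if (peptide$l_TM > box[3]) {
      abort("Peptide longer than the box z dimension.",
            class = "memgrad_validation_error")
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n_l <- as.integer(n_lipids_per_leaflet)
  frames <- vector("list", n_frames)
  theta_all <- if (!is.null(peptide)) peptide$tilt_sampler(n_frames) else NULL
  phi_all <- if (!is.null(peptide)) peptide$azimuth_sampler(n_frames) else NULL

  for (f in seq_len(n_frames)) {
    x <- stats::runif(2L * n_l, 0, box[1])
    y <- stats::runif(2L * n_l, 0, box[2])
    d <- d_fun(x)
    if (!is.null(perturbation) && !is.null(peptide)) {
      dxy <- cbind(x - peptide$x_com, y - peptide$y_com)
      # minimum image in y (the box is periodic in-plane)
      dxy[, 2] <- dxy[, 2] - box[2] * round(dxy[, 2] / box[2])
      d <- d + perturbation(dxy[, 1], dxy[, 2])
    }
    leaflet <- rep(c("upper", "lower"), each = n_l)
    z_mid <- ifelse(leaflet == "upper", d / 2, -d / 2)
    z <- z_mid + if (positional_noise_sd > 0) {
      stats::rnorm(2L * n_l, 0, positional_noise_sd)
    } else 0
    memb <- tibble::tibble(
      frame = f, bead_id = seq_len(2L * n_l), role = "phosphate",
      leaflet = leaflet, x = x, y = y, z = z)

    if (!is.null(peptide)) {
      rod <- render_rod(peptide, theta_all[f], phi_all[f])
      rod$frame <- f
      rod$bead_id <- 2L * n_l + seq_len(nrow(rod))
      memb <- dplyr::bind_rows(memb, rod[, names(memb)])
    }
    frames[[f]] <- memb
  }
  out <- dplyr::bind_rows(frames)
  structure(out, box = box, profile = profile,
            l_TM = if (!is.null(peptide)) peptide$l_TM else NULL,
            seed = as.integer(seed),
            class = c("synthetic_frames", class(tibble::tibble())))
}

# rigid rod of backbone beads along the tilted axis, plus terminal anchors
render_rod <- function(peptide, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  n_beads <- max(2L, as.integer(round(peptide$l_TM / peptide$bead_spacing)) + 1L)
  s <- seq(-peptide$l_TM / 2, peptide$l_TM / 2, length.out = n_beads)
  anchor_s <- c(min(s) - peptide$bead_spacing, max(s) + peptide$bead_spacing)
  pos <- outer(c(s, anchor_s), axis)
  tibble::tibble(
    role = c(rep("backbone", n_beads), rep("anchor", 2L)),
    leaflet = "peptide",
    x = peptide$x_com + pos[, 1],
    y = peptide$y_com + pos[, 2],
    z = pos[, 3]
  )
}

as_thickness_function <- function(profile) {
  if (is.function(profile)) return(profile)
  ok <- !is.na(profile$thickness)
  xs <- profile$x[ok]
  ds <- profile$thickness[ok]
  function(x) stats::approx(xs, ds, xout = x, rule = 2)$y
}

#' Write synthetic frames in the columnar fallback format
#'
#' Plain-text columnar trajectory (CSV with columns `frame`, `bead_id`,
#' `role`, `leaflet`, `x`, `y`, `z`), the documented engine-independent
#' interchange format for bead trajectories.
#'
#' @param frames A `synthetic_frames` tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_frames_csv <- function(frames, path) {
  utils::write.csv(as.data.frame(frames), path, row.names = FALSE)
  invisible(path)
}

#' Read a columnar bead trajectory
#'
#' @param path CSV written by [write_frames_csv()].
#' @param box Box dimensions `c(Lx, Ly, Lz)` (nm), attached as an attribute.
#' @return A `synthetic_frames` tibble.
#' @export
read_frames_csv <- function(path, box = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path))
  structure(df, box = box,
            class = c("synthetic_frames", class(tibble::tibble())))
}
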