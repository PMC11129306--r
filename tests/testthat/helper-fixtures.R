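# Shared fixtures, built in code.

four_lipids <- function() {
  lipid_specs(c("DYPC", "DOPC", "DGPC", "DNPC"), c(3.34, 4.11, 4.56, 4.95))
}

flat_frames <- function(d = 4, n_lip = 400, n_frames = 4, noise = 0,
                        box = c(40, 10, 10), seed = 7, peptide = NULL,
                        perturbation = NULL) {
  synthesize_membrane_trajectory(
    function(x) rep(d, length(x)), n_lipids_per_leaflet = n_lip,
    n_frames = n_frames, positional_noise_sd = noise, box = box,
    peptide = peptide, perturbation = perturbation, seed = seed)
}

# rod with exact tilt/azimuth (degrees), centred at the origin
rod_at <- function(theta, phi, length = 4, n = 10) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  s <- seq(-length / 2, length / 2, length.out = n)
  outer(s, axis)
}

# biased-OU umbrella windows over the quadratic well kBT x^2 / (2 D tau)
ou_umbrella_windows <- function(centers, tau = 5, D = 0.1, kb_factor = 2.5,
                                n_replicas = 24, n_steps = 12000,
                                seed = 7, burn_in = 25) {
  kappa <- kBT() / (D * tau)
  kb <- kb_factor * kappa
  lapply(seq_along(centers), function(i) {
    p <- sorting_params(x_eq = 0, tau = tau, diffusion = D, x0 = centers[i],
                        dt = tau / 100, n_steps = n_steps,
                        n_replicas = n_replicas, seed = seed + i,
                        bias = list(center = centers[i], stiffness = kb))
    ens <- simulate_sorting_ensemble(p)
    umbrella_window(centers[i], kb, ens$x[ens$time > burn_in])
  })
}
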