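test_that("Boltzmann inversion matches its definition", {
  # uniform density -> flat profile at 0
  u <- boltzmann_invert_density(tibble::tibble(x = 1:5, density = rep(2, 5)))
  expect_true(all(u$delta_F == 0))
  # density ratio e:1 -> exactly 1 kBT difference
  two <- boltzmann_invert_density(tibble::tibble(x = 1:2,
                                                 density = c(exp(1), 1)))
  expect_equal(two$delta_F, c(0, 1))
  # zero-density bins undefined, min is 0 at the reference
  z <- boltzmann_invert_density(tibble::tibble(x = 1:3, density = c(1, 0, 2)))
  expect_true(is.na(z$delta_F[2]))
  expect_equal(min(z$delta_F, na.rm = TRUE), 0)
  expect_error(boltzmann_invert_density(tibble::tibble(x = 1, density = 0)),
               class = "memgrad_validation_error")
})

test_that("OU stationary samples invert to the quadratic well", {
  tau <- 10; D <- 0.05  # well (x - x_eq)^2 / (2 D tau) in kBT
  p <- sorting_params(x_eq = 0, tau = tau, diffusion = D, x0 = 0,
                      n_steps = 40000, n_replicas = 16, seed = 6)
  ens <- simulate_sorting_ensemble(p)
  st <- dplyr::filter(ens, time > 5 * tau)
  dens <- lateral_density_profile(dplyr::rename(st, frame = "time"),
                                  bin_width = 0.15, window = "all")
  prof <- boltzmann_invert_density(dens)
  truth <- prof$x^2 / (2 * D * tau)
  ok <- !is.na(prof$delta_F) & abs(prof$x) < 1.8
  expect_gt(sum(ok), 15)
  expect_lt(max(abs(prof$delta_F[ok] - (truth[ok] - min(truth[ok])))), 0.35)
})

test_that("single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(10)
  s <- rnorm(4000)
  grid <- seq(-3, 3, length.out = 41)
  pmf <- wham_1d(list(umbrella_window(0, 0, s)), grid = grid)
  expect_equal(attr(pmf, "n_iter"), 1L)
  counts <- rowSums(attr(pmf, "counts"))
  direct <- boltzmann_invert_density(tibble::tibble(x = grid,
                                                    density = counts))
  expect_equal(pmf$delta_F, direct$delta_F)
})

test_that("WHAM constants match a brute-force fixed point on a 3-bin toy", {
  # two windows, 3 bins: solve the self-consistency equations independently
  # by direct fixed-point iteration on the closed-form expressions
  set.seed(14)
  w1 <- umbrella_window(-0.5, 5, rnorm(500, -0.4, 0.5))
  w2 <- umbrella_window(0.5, 5, rnorm(500, 0.4, 0.5))
  grid <- c(-1, 0, 1)
  pmf <- wham_1d(list(w1, w2), grid = grid, tol = 1e-14)

  kbt <- kBT()
  edges <- c(grid - 0.5, grid[3] + 0.5)
  cnt <- vapply(list(w1, w2), function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1 & idx <= 3], nbins = 3)
  }, numeric(3))
  M <- rowSums(cnt); N <- colSums(cnt)
  C <- exp(-vapply(list(w1, w2),
                   function(w) 0.5 * w$stiffness * (grid - w$center)^2 / kbt,
                   numeric(3)))
  g <- c(1, 1)  # normalisation constants exp(f)
  for (i in 1:50000) {
    P <- M / as.vector(C %*% (N * g))
    g_new <- 1 / colSums(P * C)
    g_new <- g_new / g_new[1]
    if (max(abs(g_new - g)) < 1e-15) { g <- g_new; break }
    g <- g_new
  }
  P <- M / as.vector(C %*% (N * g))
  oracle <- -log(P); oracle <- oracle - min(oracle)
  expect_equal(pmf$delta_F, oracle, tolerance = 1e-10)
  expect_equal(exp(attr(pmf, "window_constants")),
               g / g[1], tolerance = 1e-8)
})

test_that("WHAM recovers the quadratic well from biased OU windows", {
  tau <- 5; D <- 0.1
  wins <- ou_umbrella_windows(seq(-2, 2, length.out = 5), tau = tau, D = D)
  grid <- seq(-2.2, 2.2, length.out = 89)
  pmf <- wham_1d(wins, grid = grid)
  truth <- grid^2 / (2 * D * tau)
  counts <- rowSums(attr(pmf, "counts"))
  ok <- !is.na(pmf$delta_F) & abs(grid) <= 2 & counts >= 50
  expect_lt(max(abs(pmf$delta_F[ok] - (truth[ok] - min(truth[ok])))), 0.2)
  expect_equal(min(pmf$delta_F, na.rm = TRUE), 0)
})

test_that("non-overlapping windows raise an informative error", {
  set.seed(15)
  w1 <- umbrella_window(-5, 50, rnorm(200, -5, 0.1))
  w2 <- umbrella_window(5, 50, rnorm(200, 5, 0.1))
  expect_error(wham_1d(list(w1, w2), grid = seq(-6, 6, length.out = 61)),
               "overlap", class = "memgrad_validation_error")
})

test_that("tilt free energy matches the isotropic-rod closed form", {
  set.seed(16)
  theta <- acos(runif(2e5)) * 180 / pi  # isotropic: p(theta) ~ sin(theta)
  theta <- theta[theta <= 90]
  prof <- tilt_free_energy(theta, bin_width = 1)
  theta0 <- attr(prof, "theta0")
  expect_equal(prof$delta_F[prof$theta == theta0], 0)  # exact zero at mode
  truth <- -log(sin(prof$theta * pi / 180) / sin(theta0 * pi / 180))
  counts <- attr(prof, "counts")
  ok <- counts >= 500
  expect_lt(max(abs(prof$delta_F[ok] - truth[ok])), 0.15)
  # constant-theta fixture: single defined bin at 0
  const <- tilt_free_energy(rep(23.2, 100), bin_width = 1)
  expect_equal(sum(!is.na(const$delta_F)), 1L)
  expect_equal(const$delta_F[!is.na(const$delta_F)], 0)
})

test_that("additive surface composition and masking behave exactly", {
  # flat PMF + one tilt profile broadcast over d
  grid_x <- seq(0, 10, length.out = 11)
  pmf <- memgrad:::new_free_energy_profile(grid_x, rep(0, 11), "x")
  set.seed(17)
  tiltp <- tilt_free_energy(acos(runif(5000)) * 180 / pi, bin_width = 5)
  centers <- c(2, 5, 8)
  surf <- compose_surface_2d(pmf, list(tiltp, tiltp, tiltp), centers)
  for (dv in unique(surf$d)) {
    col <- dplyr::filter(surf, d == dv)
    expect_equal(col$delta_F, tiltp$delta_F[match(col$theta, tiltp$theta)],
                 tolerance = 1e-12)
  }

  # global minimum at (argmin pmf, theta0 of that window); exhaustive
  # re-addition check including the global offset
  pmf2 <- memgrad:::new_free_energy_profile(grid_x, (grid_x - 6)^2 / 4, "x")
  tilt_list <- list(tiltp, tiltp, tiltp)
  surf2 <- compose_surface_2d(pmf2, tilt_list, centers)
  m <- attr(surf2, "minimum")
  expect_equal(m$d, 5)  # centre nearest the pmf minimum among windows
  expect_equal(m$theta, attr(tiltp, "theta0"))
  pmf_at <- stats::approx(grid_x, pmf2$delta_F, xout = centers)$y
  offset <- min(outer(pmf_at, tiltp$delta_F, "+"), na.rm = TRUE)
  for (i in seq_along(centers)) {
    col <- dplyr::filter(surf2, d == centers[i])
    expect_equal(col$delta_F,
                 pmf_at[i] + tiltp$delta_F[match(col$theta, tiltp$theta)] -
                   offset,
                 tolerance = 1e-12)
  }
  expect_equal(min(surf2$delta_F, na.rm = TRUE), 0)

  # masking: values above the cutoff are NA, minimum survives
  surf3 <- compose_surface_2d(pmf2, tilt_list, centers, cutoff = 1)
  expect_true(all(surf3$delta_F <= 1, na.rm = TRUE))
  expect_true(any(surf3$delta_F == 0, na.rm = TRUE))
})

test_that("x-to-thickness mapping is monotone and linear", {
  fit <- list(slope = 0.077, intercept = 3.0)
  mp <- thickness_mapping(fit)
  expect_equal(mp(c(8, 32)), c(3.616, 5.464))
  expect_error(thickness_mapping(list(slope = 0, intercept = 3)),
               class = "memgrad_validation_error")
})

test_that("accessible regions match the closed-form quadratic level set", {
  # 0.5 kappa_d (d - d*)^2 + 0.5 kappa_t (theta - t*)^2 in kBT
  kappa_d <- 200; kappa_t <- 0.02
  d_grid <- seq(3.5, 4.5, by = 0.005)
  t_grid <- seq(0, 60, by = 0.25)
  surf <- tidyr::expand_grid(d = d_grid, theta = t_grid)
  surf$delta_F <- 0.5 * kappa_d * (surf$d - 4)^2 +
    0.5 * kappa_t * (surf$theta - 25)^2
  surf <- structure(surf, class = c("free_energy_surface", class(surf)))
  reg <- accessible_regions(surf, thresholds = c(1, 2, 5, 10))
  one <- dplyr::filter(reg, threshold == 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$d_hi - one$d_lo, 2 * sqrt(2 * 1 / kappa_d),
               tolerance = 0.05)
  expect_equal(one$theta_hi - one$theta_lo, 2 * sqrt(2 * 1 / kappa_t),
               tolerance = 0.05)
})

test_that("regions are nested in threshold on random rough surfaces", {
  set.seed(18)
  for (rep in 1:5) {
    d_grid <- seq(3, 5, by = 0.05)
    t_grid <- seq(0, 90, by = 2)
    surf <- tidyr::expand_grid(d = d_grid, theta = t_grid)
    base <- 3 * (surf$d - runif(1, 3.5, 4.5))^2 +
      0.004 * (surf$theta - runif(1, 20, 60))^2
    surf$delta_F <- base + runif(nrow(surf), 0, 2)
    surf$delta_F <- surf$delta_F - min(surf$delta_F)
    reg <- accessible_regions(surf, thresholds = c(1, 2, 5, 10))
    spans <- dplyr::summarise(dplyr::group_by(reg, threshold),
                              d_lo = min(d_lo), d_hi = max(d_hi),
                              t_lo = min(theta_lo), t_hi = max(theta_hi),
                              .groups = "drop")
    expect_true(all(diff(spans$d_hi) >= 0))
    expect_true(all(diff(spans$d_lo) <= 0))
    expect_true(all(diff(spans$t_hi) >= 0))
    expect_true(all(diff(spans$t_lo) <= 0))
  }
})

test_that("a double well splits at low threshold and merges above the barrier", {
  d_grid <- seq(0, 4, by = 0.02)
  t_grid <- seq(0, 10, by = 1)
  surf <- tidyr::expand_grid(d = d_grid, theta = t_grid)
  # two minima at d = 1 and d = 3 separated by a 3 kBT barrier at d = 2
  well <- 3 * (1 - ((surf$d - 2) / 1)^2)^2
  surf$delta_F <- well
  reg <- accessible_regions(surf, thresholds = c(1, 5))
  expect_equal(nrow(dplyr::filter(reg, threshold == 1)), 2L)
  expect_equal(nrow(dplyr::filter(reg, threshold == 5)), 1L)
})
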