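# Synthetic model systems with known free-energy structure.
#
# Every potential is evaluated by the same compiled kernels the dynamics
# engine integrates, so the energies the oracles integrate are bit-identical
# to the energies the simulations see.

#' Construct a model potential
#'
#' Internal constructor shared by the `make_*` generators. A model potential
#' is a differentiable energy over flattened particle coordinates together
#' with the bookkeeping the rest of the package needs: coordinate layout,
#' a declared domain (used to bound quadrature), an optional axial reduction
#' for transversally separable systems, and a default starting configuration.
#'
#' @param kind integer code of the compiled kernel.
#' @param params flat numeric parameter vector for the kernel.
#' @param n_particles,dim_per_particle coordinate layout.
#' @param label free-text label.
#' @param domain matrix (n_coords x 2) of lower/upper bounds per coordinate.
#' @param x0 default starting coordinates.
#' @param axial optional list(flat_idx, energy) giving the indices of the
#'   axial (z) coordinates and an R function computing the energy restricted
#'   to them (transverse terms at their minimum), for separable systems.
#' @param extra named list merged into the object (e.g. generator settings).
#' @return An object of class `model_potential` with closures `energy(x)`,
#'   `gradient(x)` and `energy_batch(X)`.
#' @keywords internal
model_potential <- function(kind, params, n_particles, dim_per_particle,
                            label, domain, x0, axial = NULL, extra = list()) {
  n_coords <- n_particles * dim_per_particle
  stopifnot(nrow(domain) == n_coords, length(x0) == n_coords)
  obj <- c(list(
    kind = kind, params = params,
    n_particles = n_particles, dim_per_particle = dim_per_particle,
    n_coords = n_coords, label = label, domain = domain, x0 = x0,
    axial = axial,
    energy = function(x) cpp_potential_eval(kind, params, as.numeric(x))$energy,
    gradient = function(x) cpp_potential_eval(kind, params, as.numeric(x))$gradient,
    energy_batch = function(X) cpp_potential_energy_batch(kind, params, as.matrix(X))
  ), extra)
  class(obj) <- "model_potential"
  obj
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("<model_potential '%s': %d particle(s) x %dD>\n",
              x$label, x$n_particles, x$dim_per_particle))
  invisible(x)
}

#' Two-dimensional double-well potential
#'
#' \eqn{V(x, y) = h ((x/a)^2 - 1)^2 + (k_y/2) y^2}: two minima at
#' \eqn{x = \pm a}, barrier height `height` at \eqn{x = 0}, and an
#' independent harmonic transverse coordinate, so the marginal free energy
#' along x equals the x-term up to an additive constant at any temperature.
#'
#' @param height barrier height h (kcal/mol), > 0.
#' @param half_separation minima at +/- this value (Angstrom), > 0.
#' @param transverse_stiffness harmonic stiffness of y (kcal/mol/A^2), > 0.
#' @return A [model_potential] (1 particle, 2 coordinates: x, y).
#' @export
make_double_well <- function(height = 6, half_separation = 2,
                             transverse_stiffness = 1) {
  if (height <= 0 || half_separation <= 0 || transverse_stiffness <= 0)
    .stopf("height, half_separation and transverse_stiffness must be positive")
  a <- half_separation
  dom <- rbind(c(-4 * a, 4 * a), c(-15, 15))
  model_potential(
    kind = 2L, params = c(height, a, transverse_stiffness),
    n_particles = 1L, dim_per_particle = 2L,
    label = "double_well", domain = dom, x0 = c(-a, 0),
    extra = list(height = height, half_separation = a,
                 transverse_stiffness = transverse_stiffness))
}

#' Mueller-Brown benchmark surface
#'
#' The conventional four-Gaussian 2D benchmark potential (three minima,
#' two saddles) with its standard published constants, used to validate
#' the string method. The constants are carried in `$constants` and echoed
#' by [write_potential_config()].
#'
#' @return A [model_potential] (1 particle, 2 coordinates).
#' @export
make_benchmark_surface <- function() {
  constants <- list(
    A  = c(-200, -100, -170, 15),
    a  = c(-1, -1, -6.5, 0.7),
    b  = c(0, 0, 11, 0.6),
    cc = c(-10, -10, -6.5, 0.7),
    x0 = c(1, 0, -0.5, -1),
    y0 = c(0, 0.5, 1.5, 1))
  dom <- rbind(c(-1.8, 1.4), c(-0.5, 2.3))
  model_potential(
    kind = 3L, params = numeric(0),
    n_particles = 1L, dim_per_particle = 2L,
    label = "benchmark_surface", domain = dom, x0 = c(-0.5, 1.5),
    extra = list(constants = constants))
}

#' Toy selectivity-filter system
#'
#' `n_ions` ions move inside a cylinder of radius `radius` (half-harmonic
#' radial wall) with Gaussian attractive wells along z at `well_centers`,
#' axial Gaussian pair repulsion, soft container walls at the z-domain
#' edges, and a "gate" particle (a surrogate for a charged side-chain tip)
#' whose z coordinate lives in its own double well and repels the ions
#' through a Gaussian coupling, so the joint (ion z, gate z) free energy
#' has at least two metastable basins.
#'
#' All transverse (x, y) terms are independent of z, so the axial reduction
#' `$axial` is exact: the marginal free energy over any set of z coordinates
#' is the axial energy integrated over the remaining axial coordinates, up
#' to an additive constant.
#'
#' @param n_ions 1 or 2.
#' @param well_centers z positions of the attractive wells (Angstrom),
#'   inside `z_domain`; centers closer than 0.5 A are rejected.
#' @param well_depths well depths (kcal/mol), recycled to the centers.
#' @param radius cylinder radius (Angstrom).
#' @param gate_coupling height of the ion-gate repulsive coupling (kcal/mol).
#' @param well_sigma Gaussian well width (Angstrom).
#' @param rep_height,rep_sigma axial ion-ion Gaussian repulsion.
#' @param z_domain container interval along z.
#' @param gate_centers the two gate metastable z positions.
#' @param gate_height gate double-well barrier (kcal/mol).
#' @param couple_sigma width of the ion-gate coupling (Angstrom).
#' @return A [model_potential] with `3 * (n_ions + 1)` coordinates; the
#'   gate is the last particle (its x, y are tightly harmonic and separable).
#' @export
make_toy_filter <- function(n_ions = 1, well_centers = c(5, 12),
                            well_depths = 4, radius = 7, gate_coupling = 4,
                            well_sigma = 1.0, rep_height = 30, rep_sigma = 2,
                            z_domain = c(-2, 22), gate_centers = c(6, 10),
                            gate_height = 3, couple_sigma = 1.5) {
  if (!n_ions %in% c(1L, 2L)) .stopf("n_ions must be 1 or 2")
  if (any(well_centers < z_domain[1]) || any(well_centers > z_domain[2]))
    .stopf("well_centers must lie inside z_domain [%g, %g]",
           z_domain[1], z_domain[2])
  if (length(well_centers) > 1 && min(diff(sort(well_centers))) < 0.5)
    .stopf("well centers closer than 0.5 A are rejected")
  well_depths <- rep_len(well_depths, length(well_centers))
  k_zdom <- 10; k_rad <- 100; gate_kxy <- 10
  params <- c(n_ions, radius, k_rad, length(well_centers),
              well_centers, well_depths, well_sigma,
              rep_height, rep_sigma, z_domain[1], z_domain[2], k_zdom,
              gate_centers[1], gate_centers[2], gate_height, gate_kxy,
              gate_coupling, couple_sigma)
  np <- n_ions + 1L
  dom <- matrix(NA_real_, 3 * np, 2)
  for (p in seq_len(np)) {
    dom[3 * p - 2, ] <- c(-radius - 3, radius + 3)
    dom[3 * p - 1, ] <- c(-radius - 3, radius + 3)
    dom[3 * p, ] <- z_domain + c(-4, 4)
  }
  # axial energy: must mirror the compiled kernel term-by-term
  axial_energy <- function(Z) {
    Z <- as.matrix(Z)
    stopifnot(ncol(Z) == np)
    e <- numeric(nrow(Z))
    s2c <- couple_sigma^2
    for (p in seq_len(n_ions)) {
      z <- Z[, p]
      for (w in seq_along(well_centers))
        e <- e - well_depths[w] *
          exp(-(z - well_centers[w])^2 / (2 * well_sigma^2))
      e <- e + 0.5 * k_zdom * pmin(z - z_domain[1], 0)^2 +
        0.5 * k_zdom * pmax(z - z_domain[2], 0)^2
      e <- e + gate_coupling * exp(-(z - Z[, np])^2 / (2 * s2c))
    }
    if (n_ions == 2)
      e <- e + rep_height * exp(-(Z[, 1] - Z[, 2])^2 / (2 * rep_sigma^2))
    mid <- mean(gate_centers); half <- diff(gate_centers) / 2
    u <- (Z[, np] - mid) / half
    e + gate_height * (u^2 - 1)^2
  }
  x0 <- numeric(3 * np)
  for (p in seq_len(n_ions)) x0[3 * p] <- well_centers[min(p, length(well_centers))]
  x0[3 * np] <- gate_centers[2]
  model_potential(
    kind = 4L, params = params, n_particles = np, dim_per_particle = 3L,
    label = "toy_filter", domain = dom, x0 = x0,
    axial = list(flat_idx = c(3 * seq_len(n_ions), 3 * np),
                 energy = axial_energy),
    extra = list(n_ions = n_ions, well_centers = well_centers,
                 well_depths = well_depths, radius = radius,
                 gate_coupling = gate_coupling, z_domain = z_domain,
                 gate_centers = gate_centers))
}

#' Harmonic test potential
#'
#' \eqn{V = \sum_i (k_i/2) x_i^2} over `n_coords` independent coordinates;
#' the identity-CV free energy is the potential itself, exactly.
#'
#' @param k stiffness (kcal/mol/A^2), recycled over coordinates.
#' @param n_coords number of coordinates (particles of dimension 1).
#' @export
make_harmonic <- function(k = 2, n_coords = 1) {
  k <- rep_len(k, n_coords)
  sd3 <- 3 * sqrt(1 / min(k))  # generous domain for quadrature bounds
  dom <- matrix(rep(c(-8 * sd3, 8 * sd3), each = n_coords), n_coords, 2)
  model_potential(
    kind = 1L, params = k, n_particles = as.integer(n_coords),
    dim_per_particle = 1L, label = "harmonic", domain = dom,
    x0 = numeric(n_coords), extra = list(k = k))
}

#' Check analytic gradients against central finite differences
#'
#' @param potential a [model_potential].
#' @param n_points random interior points to test.
#' @param rel_tol relative tolerance on the gradient mismatch, scaled by
#'   the gradient norm at the point (absolute floor 1e-6).
#' @param h finite-difference step.
#' @param seed RNG seed for the sampled points.
#' @return TRUE invisibly; errors with the worst offender otherwise.
#' @export
check_gradient <- function(potential, n_points = 20, rel_tol = 1e-5,
                           h = 1e-5, seed = 42) {
  set.seed(seed)
  n <- potential$n_coords
  worst <- 0
  for (i in seq_len(n_points)) {
    lo <- potential$domain[, 1]; hi <- potential$domain[, 2]
    # sample well inside the declared domain
    x <- lo + (0.25 + 0.5 * runif(n)) * (hi - lo)
    g <- potential$gradient(x)
    gfd <- vapply(seq_len(n), function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (potential$energy(xp) - potential$energy(xm)) / (2 * h)
    }, numeric(1))
    scale <- max(sqrt(sum(g^2)), 1e-6 / rel_tol)
    worst <- max(worst, max(abs(g - gfd)) / scale)
  }
  if (worst > rel_tol)
    .stopf("gradient check failed: relative error %.3g > %.3g", worst, rel_tol)
  invisible(TRUE)
}

#' Deterministic quadrature oracle for marginal free energies
#'
#' Computes \eqn{G(z) = -(1/\beta) \log \int e^{-\beta U} \delta(\theta(x)-z)\,dx}
#' on a grid of CV values by trapezoid quadrature over the orthogonal
#' complement of the (linear) CV, min-shifted to zero. For potentials with
#' an exact axial reduction (e.g. the toy filter) the integral is taken in
#' the axial subspace; otherwise over all non-CV coordinates, which must
#' number at most 3.
#'
#' @param potential a [model_potential].
#' @param cv a [cv_map] with linear components only.
#' @param beta inverse temperature (mol/kcal).
#' @param grid CV grid: a numeric vector (1 CV) or a list of two vectors
#'   (2 CVs, tensor grid).
#' @param restraints optional restraint list included in the energy
#'   (e.g. confinement walls, so the oracle matches a restrained run).
#' @param n_quad quadrature nodes per complement dimension.
#' @param check_convergence recompute at doubled resolution and warn if the
#'   result moves by more than 1e-3 kcal/mol.
#' @return An object of class `marginal_fe_oracle`: `cv_grid`, `fe_values`
#'   (vector or matrix, min = 0), `beta`, `method`, `max_refine_diff`.
#' @export
marginal_fe_oracle <- function(potential, cv, beta, grid,
                               restraints = list(), n_quad = 161,
                               check_convergence = TRUE) {
  stopifnot(inherits(cv, "cv_map"))
  if (is.null(cv$J)) .stopf("marginal_fe_oracle requires linear CVs")
  two_d <- is.list(grid)
  fe <- .quadrature_fe(potential, cv, beta, grid, restraints, n_quad)
  max_diff <- NA_real_
  if (check_convergence) {
    fe2 <- .quadrature_fe(potential, cv, beta, grid, restraints, 2L * n_quad - 1L)
    max_diff <- max(abs((fe - min(fe)) - (fe2 - min(fe2))))
    if (max_diff > 1e-3)
      warning(sprintf(
        "quadrature not converged: refinement moved the FE by %.3g kcal/mol",
        max_diff))
  }
  fe <- fe - min(fe)
  structure(list(cv_grid = grid, fe_values = fe, beta = beta,
                 method = "quadrature", max_refine_diff = max_diff),
            class = "marginal_fe_oracle")
}

# Core quadrature: parametrize coordinates as u = Cplus %*% zcv + B %*% w,
# where theta = C u is the linear CV; integrate exp(-beta U) over a w-grid.
.quadrature_fe <- function(potential, cv, beta, grid, restraints, n_quad) {
  axial <- potential$axial
  use_axial <- !is.null(axial) &&
    all(abs(cv$J[, setdiff(seq_len(potential$n_coords), axial$flat_idx),
             drop = FALSE]) == 0)
  if (use_axial) {
    C <- cv$J[, axial$flat_idx, drop = FALSE]
    energy_fun <- function(U) {
      e <- axial$energy(U)
      if (length(restraints))
        e <- e + .axial_restraint_energy(restraints, U, potential)
      e
    }
    dom <- potential$domain[axial$flat_idx, , drop = FALSE]
  } else {
    C <- cv$J
    if (length(restraints))
      .stopf("restraints in the oracle require an axial-reducible potential")
    energy_fun <- function(U) potential$energy_batch(U)
    dom <- potential$domain
  }
  M <- nrow(C); n <- ncol(C)
  d_comp <- n - M
  if (d_comp > 3) .stopf("quadrature infeasible: %d non-CV coordinates", d_comp)
  Cplus <- t(C) %*% solve(C %*% t(C))
  B <- if (d_comp > 0) {
    ns <- svd(C, nu = 0, nv = n)$v[, (M + 1):n, drop = FALSE]
    ns
  } else NULL

  zpts <- if (is.list(grid)) {
    as.matrix(expand.grid(grid[[1]], grid[[2]]))
  } else matrix(grid, ncol = 1)

  if (d_comp == 0) {
    U <- zpts %*% t(Cplus)
    return(.fe_shape(energy_fun(U), grid))
  }
  L <- max(dom[, 2] - dom[, 1]) / 2 * sqrt(2) + 2
  w1 <- seq(-L, L, length.out = n_quad)
  W <- as.matrix(expand.grid(rep(list(w1), d_comp)))
  nW <- nrow(W)
  fe <- numeric(nrow(zpts))
  WB <- W %*% t(B)
  for (i in seq_len(nrow(zpts))) {
    base <- as.numeric(Cplus %*% zpts[i, ])
    U <- sweep(WB, 2, base, "+")
    e <- energy_fun(U)
    emin <- min(e)
    fe[i] <- emin - log(sum(exp(-beta * (e - emin)))) / beta
  }
  .fe_shape(fe, grid)
}

.fe_shape <- function(fe, grid) {
  if (is.list(grid)) matrix(fe, length(grid[[1]]), length(grid[[2]]))
  else fe
}

# Evaluate wall restraints on axial coordinates (z of 3D particles).
.axial_restraint_energy <- function(restraints, U, potential) {
  e <- numeric(nrow(U))
  ax_idx <- potential$axial$flat_idx
  for (r in restraints) {
    if (!inherits(r, "half_harmonic_wall"))
      .stopf("only wall restraints are supported in the axial oracle")
    if (r$axis != "z") .stopf("axial oracle supports z walls only")
    for (p in r$selection) {
      col <- match(3 * p, ax_idx)
      if (is.na(col)) .stopf("wall selection particle %d is not axial", p)
      d <- if (r$side == "above") pmax(U[, col] - r$bound, 0)
           else pmin(U[, col] - r$bound, 0)
      e <- e + 0.5 * r$kappa * d^2
    }
  }
  e
}

#' @export
print.marginal_fe_oracle <- function(x, ...) {
  cat(sprintf("<marginal_fe_oracle: %s, beta = %.4g, %s grid>\n", x$method,
              x$beta, if (is.matrix(x$fe_values)) "2D" else "1D"))
  invisible(x)
}

#' Programmed synthetic occupancy trajectory
#'
#' Generates a trajectory whose per-frame occupancy of a cylindrical region
#' is drawn from a prescribed distribution: `probs[k]` is the probability
#' that exactly k of the particles are inside the region in a frame.
#' In-region particles are placed uniformly in the cylinder (or at
#' `z_modes` with Gaussian jitter); the rest are parked outside.
#'
#' @param n_frames number of frames.
#' @param probs named or ordered probabilities for occupancy 0, 1, 2, ...
#' @param region an [occupancy_region].
#' @param z_modes optional z positions for in-region particles.
#' @param z_jitter Gaussian sd around `z_modes`.
#' @param seed RNG seed.
#' @return An `md_trajectory` with `length(probs) - 1` particles.
#' @export
make_occupancy_trajectory <- function(n_frames, probs, region,
                                      z_modes = NULL, z_jitter = 0.3,
                                      seed = 1) {
  stopifnot(inherits(region, "occupancy_region"))
  probs <- probs / sum(probs)
  kmax <- length(probs) - 1L
  if (kmax < 1) .stopf("probs must cover occupancies 0..k with k >= 1")
  set.seed(seed)
  occ <- sample(0:kmax, n_frames, replace = TRUE, prob = probs)
  n_part <- kmax
  X <- matrix(NA_real_, n_frames, 3 * n_part)
  zl <- region$z_lower; zu <- region$z_upper
  for (t in seq_len(n_frames)) {
    k <- occ[t]
    for (p in seq_len(n_part)) {
      ix <- 3 * (p - 1) + 1
      if (p <= k) {
        r <- region$radius * sqrt(runif(1)) * 0.95
        phi <- runif(1, 0, 2 * pi)
        z <- if (is.null(z_modes)) runif(1, zl, zu) else {
          zz <- sample(z_modes, 1) + rnorm(1, 0, z_jitter)
          min(max(zz, zl), zu)
        }
        X[t, ix:(ix + 2)] <- c(region$center[1] + r * cos(phi),
                               region$center[2] + r * sin(phi), z)
      } else {
        X[t, ix:(ix + 2)] <- c(region$center[1] + region$radius + 8 + p,
                               region$center[2], zu + 10)
      }
    }
  }
  new_trajectory(times = seq_len(n_frames), x_frames = X,
                 metadata = list(kind = "programmed_occupancy", seed = seed,
                                 probs = probs))
}
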