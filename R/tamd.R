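# Temperature-accelerated MD: auxiliary variables z tethered by springs to
# collective variables theta(x), evolving overdamped at an artificial
# temperature so they diffuse on the physical-temperature free energy
# surface and cross its barriers quickly.

# collective variables -------------------------------------------------------

#' Collective variable components
#'
#' `cv_z(particle)` is the z coordinate of a 3D particle (e.g. one ion in
#' the filter); `cv_com_z(particles)` the z of the centre of mass of
#' several equal-mass particles; `cv_coordinate(index)` an arbitrary flat
#' coordinate (useful for low-dimensional test systems).
#'
#' @param particle,particles 1-based particle indices (3D layout).
#' @param index 1-based flat coordinate index.
#' @name cv_components
NULL

#' @rdname cv_components
#' @export
cv_z <- function(particle) {
  structure(list(kind = "coordinate_z", selection = as.integer(particle)),
            class = "cv_component")
}

#' @rdname cv_components
#' @export
cv_com_z <- function(particles) {
  structure(list(kind = "com_z", selection = as.integer(particles)),
            class = "cv_component")
}

#' @rdname cv_components
#' @export
cv_coordinate <- function(index) {
  structure(list(kind = "coordinate", selection = as.integer(index)),
            class = "cv_component")
}

#' Map coordinates to collective variables
#'
#' Assembles M linear CV components into a weight matrix J so that
#' theta(x) = J x; J is also the (constant) linear response used to
#' project spring forces back onto the particles. COM weights sum to 1.
#'
#' @param potential the [model_potential] the map applies to (fixes the
#'   coordinate layout).
#' @param ... `cv_component` objects.
#' @return An object of class `cv_map` with fields `M`, `J`, `theta(x)`.
#' @export
cv_map <- function(potential, ...) {
  comps <- list(...)
  if (length(comps) == 1 && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "cv_component")) comps <- comps[[1]]
  stopifnot(length(comps) >= 1,
            all(vapply(comps, inherits, TRUE, "cv_component")))
  n <- potential$n_coords
  d <- potential$dim_per_particle
  J <- matrix(0, length(comps), n)
  for (j in seq_along(comps)) {
    cm <- comps[[j]]
    if (cm$kind == "coordinate_z") {
      if (d != 3L) .stopf("cv_z requires 3D particles")
      J[j, 3L * cm$selection] <- 1
    } else if (cm$kind == "com_z") {
      if (d != 3L) .stopf("cv_com_z requires 3D particles")
      J[j, 3L * cm$selection] <- 1 / length(cm$selection)
    } else if (cm$kind == "coordinate") {
      J[j, cm$selection] <- 1
    }
  }
  structure(list(components = comps, M = nrow(J), J = J,
                 theta = function(x) as.numeric(J %*% as.numeric(x))),
            class = "cv_map")
}

#' @export
print.cv_map <- function(x, ...) {
  cat(sprintf("<cv_map: %d CV(s): %s>\n", x$M,
              paste(vapply(x$components, `[[`, "", "kind"), collapse = ", ")))
  invisible(x)
}

# TAMD ----------------------------------------------------------------------

#' TAMD parameters
#'
#' Defaults follow the channel setups: spring 1500 kcal/mol/A^2, auxiliary
#' friction 800 (kcal/mol) ps/A^2, auxiliary temperature 6000 K over a
#' 310 K physical thermostat.
#'
#' @param kappa tether spring constant (kcal/mol/A^2), > 0.
#' @param gamma_bar auxiliary friction ((kcal/mol) ps/A^2), > 0.
#' @param T_bar artificial temperature (K), >= the physical temperature.
#' @param physical a [langevin_params] for the physical coordinates.
#' @param z_init optional initial auxiliary values; defaults to theta(x0)
#'   (zero initial spring energy).
#' @param z_walls optional list of [half_harmonic_wall]s applied to the
#'   physical particles that define the CVs (confinement).
#' @param seed RNG seed for the whole extended run.
#' @export
tamd_params <- function(kappa = 1500, gamma_bar = 800, T_bar = 6000,
                        physical = langevin_params(), z_init = NULL,
                        z_walls = list(), seed = 1) {
  if (kappa <= 0) .stopf("kappa must be > 0")
  if (gamma_bar <= 0) .stopf("gamma_bar must be > 0")
  if (T_bar < physical$temperature)
    .stopf("T_bar must be >= the physical temperature")
  structure(list(kappa = kappa, gamma_bar = gamma_bar, T_bar = T_bar,
                 physical = physical, z_init = z_init, z_walls = z_walls,
                 seed = as.integer(seed)),
            class = "tamd_params")
}

#' Extended-system energy
#'
#' \eqn{V(x) + (\kappa/2) \sum_j (\theta_j(x) - z_j)^2}.
#'
#' @param x physical coordinates.
#' @param z auxiliary CV values.
#' @param potential a [model_potential].
#' @param cv a [cv_map].
#' @param kappa tether spring constant.
#' @return list(energy, grad_x, grad_z); grad_z = -kappa (theta - z).
#' @export
extended_energy <- function(x, z, potential, cv, kappa) {
  theta <- cv$theta(x)
  stopifnot(length(z) == length(theta))
  d <- theta - z
  list(energy = potential$energy(x) + 0.5 * kappa * sum(d^2),
       grad_x = potential$gradient(x) + kappa * as.numeric(t(cv$J) %*% d),
       grad_z = -kappa * d)
}

#' Run temperature-accelerated dynamics
#'
#' The physical coordinates evolve by BAOAB Langevin at the physical
#' temperature under the extended energy (plus restraints and any
#' confinement walls in `params$z_walls`); each auxiliary variable evolves
#' by overdamped Euler-Maruyama,
#' \eqn{\bar\gamma \dot z_j = \kappa(\theta_j(x) - z_j) +
#' \sqrt{2\bar\gamma/\bar\beta}\,\eta_j}. The trajectory stores x, z and
#' theta(x) per saved frame.
#'
#' @param potential a [model_potential].
#' @param cv a [cv_map] (linear components only).
#' @param params a [tamd_params].
#' @param restraints additional restraints on the physical coordinates.
#' @param n_steps,save_every as in [simulate_langevin()].
#' @param x0,v0 optional initial state.
#' @return An `md_trajectory` with `z_frames` and `theta_frames`.
#' @export
tamd_run <- function(potential, cv, params, restraints = list(),
                     n_steps, save_every = 1, x0 = NULL, v0 = NULL) {
  stopifnot(inherits(potential, "model_potential"), inherits(cv, "cv_map"),
            inherits(params, "tamd_params"))
  if (is.null(cv$J)) .stopf("tamd_run requires linear CV components")
  n <- potential$n_coords
  if (is.null(x0)) x0 <- potential$x0
  z0 <- if (is.null(params$z_init)) cv$theta(x0) else params$z_init
  ph <- params$physical
  masses <- rep_len(ph$mass, n)
  all_restr <- c(restraints, params$z_walls)
  set.seed(params$seed)
  if (is.null(v0))
    v0 <- rnorm(n, 0, sqrt(kB_kcal * ph$temperature * .fconv / masses))
  res <- cpp_langevin(potential$kind, potential$params,
                      .restraints_to_cpp(all_restr, potential$dim_per_particle),
                      as.numeric(x0), as.numeric(v0), masses,
                      ph$timestep, ph$friction, ph$temperature,
                      as.integer(n_steps), as.integer(save_every),
                      cv$J, params$kappa, as.numeric(z0),
                      params$gamma_bar, params$T_bar)
  new_trajectory(res$times, res$x_frames, res$z_frames, res$theta_frames,
                 metadata = list(kind = "tamd", params = params,
                                 kappa = params$kappa,
                                 potential_label = potential$label,
                                 n_steps = n_steps, save_every = save_every,
                                 seed = params$seed,
                                 x_final = res$x_final, v_final = res$v_final))
}

#' Instantaneous mean-force samples
#'
#' Returns the spring-force samples \eqn{\kappa(\theta(x_t) - z_t)} whose
#' conditional average at fixed z converges to \eqn{-\nabla G(z)} as the
#' tether stiffens: they point from z toward theta(x). These are the
#' samples the OTFP assembly consumes.
#'
#' @param traj an `md_trajectory` from [tamd_run()].
#' @param kappa spring constant; defaults to the one stored in the
#'   trajectory metadata.
#' @return matrix (frames x M) of force samples (kcal/mol/A).
#' @export
mean_force_samples <- function(traj, kappa = NULL) {
  if (is.null(traj$z_frames) || is.null(traj$theta_frames))
    .stopf("trajectory has no auxiliary (z, theta) frames")
  if (is.null(kappa)) kappa <- traj$metadata$kappa
  if (is.null(kappa)) .stopf("kappa not given and absent from metadata")
  kappa * (traj$theta_frames - traj$z_frames)
}
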