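# Langevin dynamics over the physical coordinates, plus the restraint
# potentials: flat-bottom exclusion boxes, half-harmonic walls, and soft
# positional restraints.

#' Langevin thermostat parameters
#'
#' @param temperature target temperature (K), > 0 (0 allowed for the
#'   deterministic limit).
#' @param friction damping coefficient (1/ps), >= 0.
#' @param timestep integration step (ps), > 0.
#' @param mass particle mass (amu), recycled per coordinate at run time.
#' @param seed integer RNG seed; identical seeds give bit-identical runs.
#' @export
langevin_params <- function(temperature = 310, friction = 1,
                            timestep = 0.002, mass = 40, seed = 1) {
  if (temperature < 0) .stopf("temperature must be >= 0")
  if (timestep <= 0) .stopf("timestep must be > 0")
  if (friction < 0) .stopf("friction must be >= 0")
  if (any(mass <= 0)) .stopf("mass must be > 0")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, mass = mass, seed = as.integer(seed)),
            class = "langevin_params")
}

#' Flat-bottom exclusion bias
#'
#' Adds, for each excluded particle, \eqn{k\,S(x)S(y)S(z)} where S is a
#' smooth plateau equal to 1 in the box interior (inset by `ramp_width`),
#' 0 outside, with a C1 smoothstep ramp. With k large (600 kcal/mol in the
#' channel setups) the box is a prohibitive barrier: particles outside
#' cannot enter.
#'
#' @param x_min,x_max,y_min,y_max,z_min,z_max box bounds (Angstrom).
#' @param k plateau height (kcal/mol), > 0.
#' @param ramp_width C1 ramp width (Angstrom), > 0 and less than half the
#'   smallest box extent.
#' @param excluded particle indices (1-based, 3D layout) the bias acts on.
#' @export
flat_bottom_exclusion <- function(x_min = -6, x_max = 6, y_min = -6,
                                  y_max = 6, z_min = -4, z_max = 18,
                                  k = 600, ramp_width = 1, excluded) {
  ext <- c(x_max - x_min, y_max - y_min, z_max - z_min)
  if (any(ext <= 0)) .stopf("box must satisfy min < max on every axis")
  if (k <= 0) .stopf("k must be > 0")
  if (ramp_width <= 0 || ramp_width >= min(ext) / 2)
    .stopf("ramp_width must be in (0, half the smallest box extent)")
  structure(list(box = c(x_min, x_max, y_min, y_max, z_min, z_max),
                 k = k, ramp_width = ramp_width,
                 excluded = as.integer(excluded)),
            class = c("flat_bottom_exclusion", "tamd_restraint"))
}

#' Half-harmonic wall
#'
#' \eqn{E = (\kappa/2)(c - b)^2} when coordinate c is beyond bound b on the
#' penalized side, else 0.
#'
#' @param axis "x", "y" or "z".
#' @param bound wall position (Angstrom).
#' @param side "above" (penalize coordinate > bound) or "below".
#' @param kappa stiffness (kcal/mol/A^2), > 0.
#' @param selection particle indices the wall acts on.
#' @export
half_harmonic_wall <- function(axis = "z", bound, side = c("above", "below"),
                               kappa, selection) {
  side <- match.arg(side)
  if (kappa <= 0) .stopf("kappa must be > 0")
  structure(list(axis = axis, bound = bound, side = side, kappa = kappa,
                 selection = as.integer(selection)),
            class = c("half_harmonic_wall", "tamd_restraint"))
}

#' Soft positional restraint
#'
#' Harmonic tether of selected particles to reference coordinates, as used
#' to keep helix C-alpha scaffolds from drifting.
#'
#' @param selection particle indices.
#' @param reference reference coordinates, one row (or 3 values) per
#'   selected particle.
#' @param kappa stiffness (kcal/mol/A^2), >= 0.
#' @export
positional_restraint <- function(selection, reference, kappa) {
  if (kappa < 0) .stopf("kappa must be >= 0")
  reference <- matrix(as.numeric(reference), ncol = 3, byrow = FALSE)
  if (nrow(reference) != length(selection))
    .stopf("need one reference row per selected particle")
  structure(list(selection = as.integer(selection), reference = reference,
                 kappa = kappa),
            class = c("positional_restraint", "tamd_restraint"))
}

# Lower a restraint to the 0-based flat-index form the engine consumes.
.restraint_to_cpp <- function(r, dim_per_particle = 3L) {
  if (inherits(r, "flat_bottom_exclusion")) {
    if (dim_per_particle != 3L)
      .stopf("flat-bottom exclusion requires 3D particles")
    list(type = "exclusion", offsets = as.integer((r$excluded - 1L) * 3L),
         box = r$box, k = r$k, ramp_width = r$ramp_width)
  } else if (inherits(r, "half_harmonic_wall")) {
    ax <- match(r$axis, c("x", "y", "z"))
    if (is.na(ax) || ax > dim_per_particle)
      .stopf("axis '%s' not valid for %dD particles", r$axis, dim_per_particle)
    list(type = "wall",
         idx = as.integer((r$selection - 1L) * dim_per_particle + ax - 1L),
         bound = r$bound, kappa = r$kappa,
         side = if (r$side == "above") 1L else -1L)
  } else if (inherits(r, "positional_restraint")) {
    if (dim_per_particle != 3L)
      .stopf("positional restraint requires 3D particles")
    idx <- as.integer(t(outer((r$selection - 1L) * 3L, 0:2, "+")))
    list(type = "positional", idx = idx,
         ref = as.numeric(t(r$reference)), kappa = r$kappa)
  } else .stopf("unknown restraint class")
}

.restraints_to_cpp <- function(restraints, dim_per_particle = 3L) {
  lapply(restraints, .restraint_to_cpp, dim_per_particle = dim_per_particle)
}

#' Flat-bottom exclusion energy and forces
#'
#' @param coords flat coordinate vector (3D layout).
#' @param restraint a [flat_bottom_exclusion].
#' @param dim_per_particle coordinate layout (must be 3).
#' @return list(energy, forces) with forces = -gradient.
#' @export
exclusion_energy <- function(coords, restraint, dim_per_particle = 3L) {
  ev <- cpp_restraint_eval(list(.restraint_to_cpp(restraint, dim_per_particle)),
                           as.numeric(coords))
  list(energy = ev$energy, forces = -ev$gradient)
}

#' Half-harmonic wall energy and forces
#'
#' @inheritParams exclusion_energy
#' @param wall a [half_harmonic_wall].
#' @export
wall_energy <- function(coords, wall, dim_per_particle = 3L) {
  ev <- cpp_restraint_eval(list(.restraint_to_cpp(wall, dim_per_particle)),
                           as.numeric(coords))
  list(energy = ev$energy, forces = -ev$gradient)
}

#' Total restraint energy and forces
#'
#' @inheritParams exclusion_energy
#' @param restraints list of restraint objects.
#' @export
restraint_energy <- function(coords, restraints, dim_per_particle = 3L) {
  ev <- cpp_restraint_eval(.restraints_to_cpp(restraints, dim_per_particle),
                           as.numeric(coords))
  list(energy = ev$energy, forces = -ev$gradient)
}

# trajectory container -------------------------------------------------------

new_trajectory <- function(times, x_frames, z_frames = NULL,
                           theta_frames = NULL, metadata = list()) {
  stopifnot(length(times) == nrow(x_frames))
  if (!is.null(z_frames)) stopifnot(nrow(z_frames) == nrow(x_frames))
  structure(list(times = times, x_frames = x_frames, z_frames = z_frames,
                 theta_frames = theta_frames, metadata = metadata),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d frames x %d coords%s>\n",
              nrow(x$x_frames), ncol(x$x_frames),
              if (!is.null(x$z_frames))
                sprintf(", %d auxiliary CV(s)", ncol(x$z_frames)) else ""))
  invisible(x)
}

#' Integrate Langevin dynamics
#'
#' Evolves the physical coordinates under the model potential plus
#' restraints with a BAOAB splitting Langevin integrator (exact
#' Ornstein-Uhlenbeck velocity noise). At `friction = 0` and
#' `temperature = 0` the scheme reduces to velocity Verlet and conserves
#' energy to integrator order.
#'
#' @param potential a [model_potential].
#' @param restraints list of restraint objects.
#' @param params a [langevin_params].
#' @param n_steps number of steps.
#' @param save_every save a frame every this many steps.
#' @param x0 starting coordinates (defaults to the potential's `x0`).
#' @param v0 starting velocities; by default drawn from Maxwell-Boltzmann
#'   at the target temperature (under the run's seed).
#' @return An `md_trajectory`.
#' @export
simulate_langevin <- function(potential, restraints = list(), params,
                              n_steps, save_every = 10, x0 = NULL,
                              v0 = NULL) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "langevin_params"))
  n <- potential$n_coords
  if (is.null(x0)) x0 <- potential$x0
  masses <- rep_len(params$mass, n)
  set.seed(params$seed)
  if (is.null(v0))
    v0 <- rnorm(n, 0, sqrt(kB_kcal * params$temperature * .fconv / masses))
  res <- cpp_langevin(potential$kind, potential$params,
                      .restraints_to_cpp(restraints, potential$dim_per_particle),
                      as.numeric(x0), as.numeric(v0), masses,
                      params$timestep, params$friction, params$temperature,
                      as.integer(n_steps), as.integer(save_every),
                      NULL, 0, numeric(0), 1, 0)
  new_trajectory(res$times, res$x_frames,
                 metadata = list(kind = "langevin", params = params,
                                 potential_label = potential$label,
                                 n_steps = n_steps, save_every = save_every,
                                 seed = params$seed,
                                 x_final = res$x_final, v_final = res$v_final,
                                 final_energy = res$final_energy))
}
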