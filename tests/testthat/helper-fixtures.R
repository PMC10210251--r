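# Shared fixtures and independent oracles used across the test files.

beta310 <- 1 / (kB_kcal * 310)

# Write a minimal, standards-conforming PDB file from an atom table.
# Used to build synthetic structures for parser and geometry tests.
write_test_pdb <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, a$elety, a$alt %||% "", a$resid %||% "ALA",
      a$chain %||% "A", a$resno, a$insert %||% "",
      a$x, a$y, a$z, a$o %||% 1, 0)
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# A small helix-like synthetic backbone with CA atoms at given residues.
synthetic_ca_structure <- function(resnos, jitter = 0, seed = 1) {
  set.seed(seed)
  t <- seq_along(resnos)
  df <- data.frame(
    chain = "A", resno = resnos, insert = "", resid = "ALA", elety = "CA",
    x = 2.3 * cos(t) + jitter * rnorm(length(t)),
    y = 2.3 * sin(t) + jitter * rnorm(length(t)),
    z = 1.5 * t + jitter * rnorm(length(t)), o = 1)
  structure_model(df, source = "synthetic")
}

# Brute-force rigid superposition oracle: numerical optimisation over
# Euler angles + translation, independent of the SVD route.
brute_force_rmsd <- function(P, Q) {
  rotmat <- function(a) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
                c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
                c(-sin(a[2]), 0, cos(a[2])))
    Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0),
                c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rotmat(par[1:3])
    Pm <- sweep(P %*% t(R), 2, par[4:6], "+")
    mean(rowSums((Pm - Q)^2))
  }
  best <- Inf
  for (init in list(rep(0, 6), c(0.5, -0.3, 0.8, 0, 0, 0))) {
    o <- optim(init, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# rotation matrix about z by angle
rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# apply rigid motion to a structure_model
transform_structure <- function(s, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# Standard TAMD settings used by several tests (channel defaults, with a
# thermostat strong enough for adiabatic conditional sampling).
test_tamd_params <- function(T_bar = 6000, kappa = 1500, gamma_bar = 800,
                             seed = 1, z_walls = list()) {
  tamd_params(kappa = kappa, gamma_bar = gamma_bar, T_bar = T_bar,
              physical = langevin_params(310, 10, 0.002, 40, seed),
              z_walls = z_walls, seed = seed)
}

filter_walls <- function(particles = 1) {
  list(half_harmonic_wall("z", 17, "above", 300, particles),
       half_harmonic_wall("z", 4, "below", 300, particles))
}
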