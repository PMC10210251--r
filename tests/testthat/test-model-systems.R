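# Synthetic model systems and their free-energy oracles.

test_that("double well has the designed minima, barrier and separable marginal", {
  p <- make_double_well(height = 6, half_separation = 2,
                        transverse_stiffness = 1)
  expect_equal(p$energy(c(2, 0)), 0)
  expect_equal(p$energy(c(-2, 0)), 0)
  expect_equal(p$energy(c(0, 0)) - p$energy(c(2, 0)), 6)
  # marginal FE along x is the x-term at any temperature
  cv <- cv_map(p, cv_coordinate(1))
  for (beta in c(beta310, 0.5)) {
    o <- marginal_fe_oracle(p, cv, beta, c(-2, 0, 2),
                            check_convergence = FALSE)
    expect_equal(o$fe_values[2] - o$fe_values[1], 6, tolerance = 1e-9)
    expect_equal(o$fe_values[3], o$fe_values[1], tolerance = 1e-9)
  }
  expect_error(make_double_well(height = -1), "positive")
  expect_error(make_double_well(half_separation = 0), "positive")
})

test_that("generated potentials have gradients consistent with finite differences", {
  for (p in list(make_double_well(), make_benchmark_surface(),
                 make_toy_filter(), make_toy_filter(n_ions = 2),
                 make_harmonic(k = c(1, 3), n_coords = 2)))
    expect_true(check_gradient(p, n_points = 10, rel_tol = 1e-5))
})

test_that("benchmark surface stationary points match the dense grid-search oracle", {
  mb <- make_benchmark_surface()
  dense <- fes_from_function(mb$energy_batch, mins = c(-1.8, -0.5),
                             maxs = c(1.4, 2.3),
                             spacing = c(3.2, 2.8) / 999)
  mins <- fes_minima(dense)
  expect_gte(nrow(mins), 3)
  # three minima, the deepest in the upper-left basin
  expect_equal(unlist(mins[1, c("z1", "z2")]), c(z1 = -0.558, z2 = 1.442),
               tolerance = 0.01)
  # gradient nearly vanishes at every oracle-located minimum
  gmax <- max(sqrt(rowSums(apply(as.matrix(
    expand.grid(seq(-1.5, 1.2, 0.1), seq(-0.2, 2, 0.1))), 1,
    function(p) mb$gradient(p))^2)))
  for (k in 1:3) {
    g <- mb$gradient(unlist(mins[k, c("z1", "z2")]))
    expect_lt(sqrt(sum(g^2)), 1e-3 * gmax)
  }
  # saddle between the two lowest minima, by the minimax oracle
  sad <- fes_saddle(dense, unlist(mins[1, 1:2]), unlist(mins[2, 1:2]))
  expect_equal(sad$point, c(-0.822, 0.624), tolerance = 0.01)
})

test_that("toy filter marginals behave as designed", {
  beta <- beta310
  # equal wells: two near-degenerate minima near the well centers
  tf <- make_toy_filter(n_ions = 1, well_centers = c(5, 12), well_depths = 4)
  cv <- cv_map(tf, cv_z(1))
  o <- marginal_fe_oracle(tf, cv, beta, seq(3, 18, 0.05),
                          check_convergence = FALSE)
  fe <- o$fe_values; z <- o$cv_grid
  loc_min <- which(diff(sign(diff(fe))) > 0) + 1L
  zmins <- z[loc_min]
  expect_true(any(abs(zmins - 5) < 0.5))
  expect_true(any(abs(zmins - 12) < 0.5))
  # zero gate coupling: joint (ion z, gate z) FE factorizes
  tf0 <- make_toy_filter(gate_coupling = 0)
  cv2 <- cv_map(tf0, cv_z(1), cv_z(2))
  g1 <- seq(4, 13, 0.5); g2 <- seq(4, 12, 0.5)
  o2 <- marginal_fe_oracle(tf0, cv2, beta, list(g1, g2),
                           check_convergence = FALSE)
  G <- o2$fe_values
  Gsep <- outer(G[, 1], G[1, ], "+") - G[1, 1]
  expect_lt(max(abs(G - Gsep)), 1e-9)
  # two strongly repelling ions: COM FE minimum between the two centers
  tf2 <- make_toy_filter(n_ions = 2, rep_height = 60, rep_sigma = 3)
  cvc <- cv_map(tf2, cv_com_z(c(1, 2)))
  oc <- marginal_fe_oracle(tf2, cvc, beta, seq(4, 13, 0.25), n_quad = 121,
                           check_convergence = FALSE)
  zstar <- oc$cv_grid[which.min(oc$fe_values)]
  expect_gt(zstar, 5); expect_lt(zstar, 12)
  # input validation
  expect_error(make_toy_filter(n_ions = 3), "1 or 2")
  expect_error(make_toy_filter(well_centers = c(5, 5.2)), "0.5")
  expect_error(make_toy_filter(well_centers = c(5, 30)), "z_domain")
})

test_that("quadrature oracle is exact for identity and separable CVs and stable under refinement", {
  # identity CV on a harmonic system: G(x) = (k/2) x^2 exactly
  hp <- make_harmonic(k = 2)
  cv <- cv_map(hp, cv_coordinate(1))
  grid <- seq(-3, 3, 0.25)
  o <- marginal_fe_oracle(hp, cv, beta310, grid, check_convergence = FALSE)
  expect_equal(o$fe_values, grid^2 - min(grid^2), tolerance = 1e-12)
  expect_equal(min(o$fe_values), 0)
  # separable double well: marginal equals the restricted potential
  dw <- make_double_well()
  cvd <- cv_map(dw, cv_coordinate(1))
  od <- marginal_fe_oracle(dw, cvd, beta310, grid, check_convergence = TRUE)
  ref <- 6 * ((grid / 2)^2 - 1)^2
  expect_equal(od$fe_values, ref - min(ref), tolerance = 1e-6)
  # refinement invariance reported by the convergence check
  expect_lt(od$max_refine_diff, 1e-3)
})

test_that("programmed occupancy trajectories reproduce their distribution", {
  reg <- occupancy_region(radius = 7, z_lower = 3, z_upper = 18)
  tr <- make_occupancy_trajectory(5000, probs = c(0.2, 0.5, 0.3), reg,
                                  seed = 9)
  oc <- count_occupancy(tr, reg, species = 1:2)
  tab <- occupancy_table(oc, max_count = 2)
  # binomial 3-sigma bands at n = 5000
  for (k in 0:2) {
    pk <- c(0.2, 0.5, 0.3)[k + 1]
    expect_lt(abs(tab$percent[[as.character(k)]] / 100 - pk),
              3 * sqrt(pk * (1 - pk) / 5000) + 1e-9)
  }
})
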