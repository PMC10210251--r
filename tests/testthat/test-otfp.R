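# Chapeau basis, normal-equation accumulation, FES solve/average/lookup.

test_that("chapeau basis interpolates, sums to one, and has constant cell gradients", {
  g1 <- chapeau_grid(0, 10, 0.5)
  # node interpolation property
  b <- basis_eval(g1, 3.0)
  expect_equal(b$values[b$idx == 7], 1)        # node 7 sits at z = 3
  expect_equal(sum(b$values), 1)
  # midpoint of a cell: two values of 0.5
  b <- basis_eval(g1, 3.25)
  expect_equal(sort(b$values), c(0.5, 0.5))
  # partition of unity at random interior points, 1D and 2D
  set.seed(2)
  for (z in runif(50, 0.01, 9.99))
    expect_equal(sum(basis_eval(g1, z)$values), 1, tolerance = 1e-12)
  g2 <- chapeau_grid(c(0, 0), c(4, 3), 0.5)
  for (i in 1:50) {
    z <- c(runif(1, 0.01, 3.99), runif(1, 0.01, 2.99))
    bb <- basis_eval(g2, z)
    expect_equal(sum(bb$values), 1, tolerance = 1e-12)
    expect_equal(length(bb$idx), 3L)
  }
  expect_error(basis_eval(g1, 11), class = "tamdotfp_out_of_domain")
})

test_that("accumulation has hat-gradient support and is linear", {
  g <- chapeau_grid(0, 10, 1)
  g <- otfp_accumulate(g, 3.4, -2.0)
  sys <- chapeau_system(g)
  A <- as.matrix(sys$A)
  nz <- which(A != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] %in% c(4, 5)), all(nz[, 2] %in% c(4, 5)))
  expect_equal(A[4, 4], 1); expect_equal(A[4, 5], -1)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) >= 0))
  # two identical samples exactly double A and b
  g2 <- otfp_accumulate(chapeau_grid(0, 10, 1), c(3.4, 3.4), c(-2, -2))
  sys2 <- chapeau_system(g2)
  expect_equal(as.matrix(sys2$A), 2 * A)
  expect_equal(sys2$b, 2 * sys$b)
  # out-of-range samples are discarded and counted
  g3 <- otfp_accumulate(g, c(-5, 20, 4.2), c(1, 1, 1))
  expect_equal(g3$n_discarded, 2L)
  expect_equal(g3$n_samples, 2L)
})

test_that("a dense exact-gradient sweep recovers a quadratic FE to solver precision", {
  # deterministic sweep: symmetric pairs about every cell midpoint
  centers <- seq(-3 + 0.125, 3 - 0.125, by = 0.25)
  z <- rep(c(centers - 0.06, centers + 0.06), 100)
  f <- -2 * z                       # f_t = -G'(z) for G = z^2
  g <- otfp_accumulate(chapeau_grid(-3, 3, 0.25), z, f)
  fes <- solve_fes(g, min_support = 1)
  ax <- fes_axis(fes, 1)
  err <- fes$values - (ax^2 - min(ax^2))
  expect_lt(max(abs(err - mean(err))), 1e-4)
})

test_that("solve_fes masks unsupported nodes and is invariant to sample duplication", {
  set.seed(4)
  z <- runif(5000, 2, 8)            # leaves [0,2) and (8,10] unsampled
  f <- -z
  g0 <- chapeau_grid(0, 10, 0.5)
  g <- otfp_accumulate(g0, z, f)
  fes <- solve_fes(g)
  ax <- fes_axis(fes, 1)
  expect_true(all(!fes$defined[ax < 1.5]))
  expect_true(all(is.na(fes$values[!fes$defined])))
  expect_true(all(fes$defined[ax > 3 & ax < 7]))
  expect_equal(min(fes$values[fes$defined]), 0)
  # doubling the sample stream leaves the solution unchanged
  g2 <- otfp_accumulate(g, z, f)
  fes2 <- solve_fes(g2)
  expect_equal(fes2$values, fes$values, tolerance = 1e-9)
  expect_error(solve_fes(g0), "no samples")
})

test_that("replica averaging is idempotent, masks by intersection, and is gauge-invariant", {
  set.seed(5)
  z <- runif(20000, -3, 3)
  g <- otfp_accumulate(chapeau_grid(-3, 3, 0.25), z, -2 * z)
  fes <- solve_fes(g)
  avg <- average_fes(list(fes, fes))
  expect_equal(avg$values, fes$values)
  # one replica missing a region: the average is undefined there
  z2 <- z[z < 2]
  g2 <- otfp_accumulate(chapeau_grid(-3, 3, 0.25), z2, -2 * z2)
  fes2 <- solve_fes(g2)
  avg2 <- average_fes(list(fes, fes2))
  expect_true(all(avg2$defined == (fes$defined & fes2$defined)))
  # adding a gauge constant does not change the average
  fes3 <- fes
  fes3$values <- fes3$values + 2.5
  avg3 <- average_fes(list(fes, fes3))
  expect_equal(avg3$values, fes$values, tolerance = 1e-12)
  bad <- solve_fes(otfp_accumulate(chapeau_grid(-4, 4, 0.25), z, -2 * z))
  expect_error(average_fes(list(fes, bad)), "grids")
})

test_that("FES lookup is exact at nodes and for linear fields", {
  lin <- fes_from_function(function(P) 3 * P[, 1] + 1 * P[, 2],
                           mins = c(0, 0), maxs = c(4, 4), spacing = 0.5)
  lk <- fes_lookup(lin, c(1.5, 2))               # a node
  expect_equal(lk$values, 3 * 1.5 + 2 - min(lin$values) - 0)
  set.seed(6)
  P <- cbind(runif(20, 0.1, 3.9), runif(20, 0.1, 3.9))
  lk2 <- fes_lookup(lin, P)
  expect_equal(lk2$gradients[, 1], rep(3, 20), tolerance = 1e-9)
  expect_equal(lk2$gradients[, 2], rep(1, 20), tolerance = 1e-9)
  expect_error(fes_lookup(lin, c(10, 10)), class = "tamdotfp_out_of_domain")
})

test_that("TAMD + OTFP recovers the effective harmonic FE", {
  hp <- make_harmonic(k = 2)
  cv <- cv_map(hp, cv_coordinate(1))
  tp <- test_tamd_params(T_bar = 2000, seed = 11)
  run <- tamd_run(hp, cv, tp, n_steps = 2e5, save_every = 1)
  g <- otfp_accumulate(chapeau_grid(-3.5, 3.5, 0.25), run$z_frames,
                       mean_force_samples(run))
  fes <- solve_fes(g)
  keff <- 2 * 1500 / 1502
  ax <- fes_axis(fes, 1)
  m <- fes$defined & abs(ax) <= 2
  d <- fes$values[m] - keff / 2 * ax[m]^2
  expect_lt(sqrt(mean((d - mean(d))^2)), 0.3)
})

test_that("double-well FES error shrinks as samples accumulate", {
  dw <- make_double_well()
  cv <- cv_map(dw, cv_coordinate(1))
  rms_at <- function(n) {
    tp <- test_tamd_params(T_bar = 6000, seed = 12)
    run <- tamd_run(dw, cv, tp, n_steps = n, save_every = 1)
    g <- otfp_accumulate(chapeau_grid(-4, 4, 0.25), run$z_frames,
                         mean_force_samples(run))
    fes <- solve_fes(g)
    ax <- fes_axis(fes, 1)
    ref <- 6 * ((ax / 2)^2 - 1)^2
    fes_rms(fes, ref - min(ref))
  }
  expect_lte(rms_at(4e5), rms_at(1e5))
})
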