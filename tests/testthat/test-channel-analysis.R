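# Occupancy statistics, conditional histograms, cross distances and
# superposition RMSD.

test_that("occupancy counting follows the inclusive cylinder rule", {
  reg <- occupancy_region(radius = 7, z_lower = 3, z_upper = 18)
  # 3 frames with 0, 1, 2 ions placed inside
  X <- rbind(
    c(0, 0, 30,   10, 0, 10),
    c(0, 0, 10,   10, 0, 10),
    c(0, 0, 10,   1, 1, 12))
  tr <- structure(list(times = 1:3, x_frames = X, metadata = list()),
                  class = "md_trajectory")
  oc <- count_occupancy(tr, reg, species = 1:2)
  expect_equal(oc$counts, c(0L, 1L, 2L))
  # boundary inclusive: radius exactly 7, z exactly at the bounds
  Xb <- rbind(c(7, 0, 3), c(0, 7, 18), c(7.0001, 0, 10))
  trb <- structure(list(times = 1:3, x_frames = Xb, metadata = list()),
                   class = "md_trajectory")
  expect_equal(count_occupancy(trb, reg, species = 1)$counts, c(1L, 1L, 0L))
  expect_error(count_occupancy(tr, reg, species = integer(0)), "empty")
  expect_error(occupancy_region(radius = 7, z_lower = 5, z_upper = 5),
               "z_lower")
})

test_that("occupancy tables have exact percentages, mean and population sd", {
  mk <- function(counts) structure(list(counts = counts,
                                        times = seq_along(counts)),
                                   class = "occupancy_series")
  tab <- occupancy_table(mk(c(0, 1, 1, 2)), max_count = 4)
  expect_equal(unname(tab$percent), c(25, 50, 25, 0, 0))
  expect_equal(tab$mean, 1.0)
  expect_equal(tab$sd, sqrt(mean((c(0, 1, 1, 2) - 1)^2)))  # ~0.707
  expect_equal(sum(tab$percent), 100)
  tab0 <- occupancy_table(mk(rep(0L, 10)))
  expect_equal(unname(tab0$percent[1]), 100)
  expect_equal(tab0$mean, 0); expect_equal(tab0$sd, 0)
  # counts above the top bin pool into it
  expect_message(tab6 <- occupancy_table(mk(c(6L, 0L)), max_count = 4),
                 "pooled")
  expect_equal(unname(tab6$percent[["4"]]), 50)
  expect_equal(sum(tab6$percent), 100)
})

test_that("a programmed 60/40 trajectory reproduces its occupancy within binomial error", {
  reg <- occupancy_region(radius = 7, z_lower = 3, z_upper = 18)
  tr <- make_occupancy_trajectory(1e4, probs = c(0, 0.6, 0.4), reg,
                                  z_modes = c(5, 12), seed = 4)
  tab <- occupancy_table(count_occupancy(tr, reg, species = 1:2))
  expect_lt(abs(tab$percent[["1"]] - 60), 300 * sqrt(0.6 * 0.4 / 1e4))
  expect_lt(abs(tab$percent[["2"]] - 40), 300 * sqrt(0.6 * 0.4 / 1e4))
  expect_equal(sum(tab$percent), 100, tolerance = 1e-4)
})

test_that("conditional z histograms bin the right frames and selections", {
  reg <- occupancy_region(radius = 7, z_lower = 3, z_upper = 18)
  X <- matrix(rep(c(0, 0, 10), 5), 5, 3, byrow = TRUE)
  tr <- structure(list(times = 1:5, x_frames = X, metadata = list()),
                  class = "md_trajectory")
  h <- z_histogram(tr, selection = 1, z_range = c(3, 18), n_bins = 15)
  expect_equal(sum(h$counts), 5)
  expect_equal(sum(h$counts > 0), 1)
  expect_true(h$mids[h$counts > 0] > 9 & h$mids[h$counts > 0] < 11)
  # condition excluding every frame: empty histogram with a warning
  expect_warning(h0 <- z_histogram(tr, 1, frames = rep(FALSE, 5)),
                 "empty")
  expect_true(all(h0$counts == 0))
  # histogram integrates to the conditional frame count
  h2 <- z_histogram(tr, 1, frames = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(h2$counts), 2)
  # two-particle COM variant
  X2 <- cbind(X, matrix(rep(c(0, 0, 14), 5), 5, 3, byrow = TRUE))
  tr2 <- structure(list(times = 1:5, x_frames = X2, metadata = list()),
                   class = "md_trajectory")
  hc <- z_histogram(tr2, selection = 1:2, com = TRUE, n_bins = 15)
  expect_equal(sum(hc$counts[abs(hc$mids - 12) <= 0.6]), 5)
})

test_that("pooled toy-filter runs put histogram modes at the oracle minima", {
  tf <- make_toy_filter()
  walls <- filter_walls(1)
  x0b <- tf$x0; x0b[3] <- 12
  runs <- list(
    simulate_langevin(tf, walls, langevin_params(310, 1, 0.002, 40, 8),
                      n_steps = 1e6, save_every = 2),
    simulate_langevin(tf, walls, langevin_params(310, 1, 0.002, 40, 9),
                      n_steps = 1e6, save_every = 2, x0 = x0b))
  h <- z_histogram(runs, selection = 1, z_range = c(3, 18), n_bins = 60)
  expect_true(h$pooled)
  # oracle minima of the ion-z marginal under the same confinement
  cvz <- cv_map(tf, cv_z(1))
  orc <- marginal_fe_oracle(tf, cvz, beta310, seq(3, 18, 0.05),
                            restraints = walls, check_convergence = FALSE)
  fe <- orc$fe_values
  lm_ <- which(diff(sign(diff(fe))) > 0) + 1L
  zmins <- orc$cv_grid[lm_][order(fe[lm_])][1:2]
  for (zm in zmins) {
    half <- h$mids[abs(h$mids - zm) < 3]
    cnts <- h$counts[abs(h$mids - zm) < 3]
    expect_lt(abs(half[which.max(cnts)] - zm), 0.5)
  }
})

test_that("cross distances are exact, symmetric and rigid-motion invariant", {
  at <- data.frame(chain = "A", resno = c(1, 2), insert = "",
                   resid = "GLY", elety = "CA",
                   x = c(0, 3), y = c(0, 4), z = c(0, 0), o = 1)
  s <- structure_model(at)
  def <- cross_distance_def("d", list(resno = 1, elety = "CA"),
                            list(resno = 2, elety = "CA"))
  expect_equal(as.numeric(cross_distance(s, def)), 5.00)
  defr <- cross_distance_def("d", def$atom_b, def$atom_a)
  expect_equal(as.numeric(cross_distance(s, defr)),
               as.numeric(cross_distance(s, def)))
  s2 <- transform_structure(s, rot_z(1.1), c(5, -2, 7))
  expect_equal(attr(cross_distance(s2, def), "exact"),
               attr(cross_distance(s, def), "exact"), tolerance = 1e-9)
  expect_error(cross_distance(s, cross_distance_def(
    "x", list(resno = 9, elety = "CA"), list(resno = 1, elety = "CA"))),
    "residue 9")
  # presets resolve on a synthetic structure carrying the filter numbering
  resnos <- c(384, 387, 942, 945, 1422, 1426, 1714, 1717)
  ats <- do.call(rbind, lapply(seq_along(resnos), function(i)
    data.frame(chain = "A", resno = resnos[i], insert = "", resid = "ALA",
               elety = c("CA", "CD", "CG", "CE", "CB"),
               x = i, y = i * 2, z = seq(0, 4) + i, o = 1)))
  sf <- structure_model(ats, source = "synthetic")
  for (nm in names(cross_distance_presets()))
    expect_true(is.finite(cross_distance(sf, nm)))
})

test_that("superposition RMSD matches the brute-force oracle and rigid invariance", {
  s <- synthetic_ca_structure(1:100)
  expect_equal(superpose_rmsd(s, s)$rmsd, 0, tolerance = 1e-10)
  # rigidly moved copy: zero after superposition, despite large unaligned RMSD
  s_rot <- transform_structure(s, rot_z(pi / 2), c(10, 0, -5))
  sp <- superpose_rmsd(s_rot, s)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_gt(sp$rmsd_unaligned, 1)
  # one atom displaced by 1 A among 100: compare to the brute-force optimum
  s_disp <- s
  s_disp$atoms$x[50] <- s_disp$atoms$x[50] + 1
  sp2 <- superpose_rmsd(s_disp, s)
  P <- as.matrix(s_disp$atoms[, c("x", "y", "z")])
  Q <- as.matrix(s$atoms[, c("x", "y", "z")])
  expect_equal(sp2$rmsd, brute_force_rmsd(P, Q), tolerance = 1e-5)
  expect_lt(sp2$rmsd, sqrt(1 / 100))
  expect_lte(sp2$rmsd, sp2$rmsd_unaligned)
  # independent route: bio3d fitting reproduces the same RMSD
  xyz_m <- as.numeric(t(P)); xyz_r <- as.numeric(t(Q))
  fit <- bio3d::fit.xyz(xyz_r, xyz_m, fixed.inds = 1:300, mobile.inds = 1:300)
  rmsd_bio3d <- sqrt(mean(colSums(matrix((fit - xyz_r)^2, nrow = 3))))
  expect_equal(sp2$rmsd, rmsd_bio3d, tolerance = 1e-6)
  # mismatched selections name the unmatched addresses
  s_sub <- s; s_sub$atoms <- s_sub$atoms[-10, ]
  expect_error(superpose_rmsd(s_sub, s), "unmatched")
})

test_that("PDB structures parse with altloc resolution and chain selection", {
  tmp <- tempfile(fileext = ".pdb")
  at <- data.frame(chain = c("A", "A", "A", "B"), resno = c(1, 1, 2, 1),
                   insert = "", resid = "ALA",
                   elety = c("CA", "CA", "CA", "CA"),
                   alt = c("A", "B", "", ""),
                   x = c(0, 5, 1, 9), y = 0, z = c(0, 0, 3, 9),
                   o = c(0.3, 0.7, 1, 1))
  write_test_pdb(at, tmp)
  s <- read_structure(tmp, chain = "A")
  expect_equal(nrow(s$atoms), 2)
  # altloc B kept (higher occupancy)
  expect_equal(s$atoms$x[s$atoms$resno == 1], 5)
  expect_message(s2 <- read_structure(tmp), "chain 'A'")
  # region bounds from reference atoms
  reg <- occupancy_region_from_structure(
    s, upper = list(resno = 2, elety = "CA"),
    lower = list(resno = 1, elety = "CA"), lower_shift = -4)
  expect_equal(reg$z_upper, 3)
  expect_equal(reg$z_lower, -4)
  # P-loop preset table is complete
  pl <- p_loop_residues()
  expect_setequal(names(pl), c("Nav1.1", "Nav1.2", "Nav1.6"))
  expect_true(all(vapply(pl, length, 0L) == 4))
})
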