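# String method: initialisation, convergence, and saddle location on the
# benchmark surface.

mb_fes <- local({
  mb <- make_benchmark_surface()
  fes_from_function(mb$energy_batch, mins = c(-1.8, -0.5),
                    maxs = c(1.4, 2.3), spacing = 0.05)
})

mb_oracle <- local({
  mb <- make_benchmark_surface()
  dense <- fes_from_function(mb$energy_batch, mins = c(-1.8, -0.5),
                             maxs = c(1.4, 2.3), spacing = c(3.2, 2.8) / 999)
  mins <- fes_minima(dense)
  sad <- fes_saddle(dense, unlist(mins[1, 1:2]), unlist(mins[2, 1:2]))
  list(minima = mins, saddle = sad)
})

test_that("init_string concatenates linear interpolations and deduplicates junctions", {
  # the two-segment filter construction: 8 + 50 points sharing one junction
  s <- init_string(list(
    list(start = c(5.0, 11.4), end = c(3, 10), n = 8),
    list(start = c(3.0, 10.0), end = c(15.0, 7.8), n = 50)))
  expect_equal(nrow(s$points), 57)
  expect_equal(s$points[1, ], c(5.0, 11.4))
  expect_equal(s$points[57, ], c(15.0, 7.8))
  expect_true(any(apply(s$points, 1, function(p)
    sqrt(sum((p - c(3, 10))^2)) < 1e-9)))
  expect_equal(s$arclengths[1], 0)
  expect_equal(s$arclengths[57], 1)
  expect_true(all(diff(s$arclengths) > 0))
  # single segment
  s2 <- init_string(list(list(start = c(0, 0), end = c(1, 0), n = 3)))
  expect_equal(s2$points, rbind(c(0, 0), c(0.5, 0), c(1, 0)))
  # error cases
  expect_error(init_string(list()), "empty")
  expect_error(init_string(list(list(start = c(1, 1), end = c(1, 1), n = 5))),
               "degenerate")
})

test_that("strings converge into the minimum of a quadratic bowl", {
  bowl <- fes_from_function(function(P) (P[, 1]^2 + P[, 2]^2) / 2,
                            mins = c(-2, -2), maxs = c(2, 2), spacing = 0.05)
  s0 <- init_string(list(list(start = c(-1.5, 1), end = c(1.5, 1), n = 25)))
  s <- evolve_string(bowl, s0, step_size = 0.05, tol = 1e-7,
                     max_iter = 50000)
  expect_true(s$converged)
  expect_lt(s$mean_displacement, 1e-7)
  expect_true(all(sqrt(rowSums(s$points^2)) < 0.1))
  # equal spacing after reparametrization
  seg <- sqrt(rowSums(diff(s$points)^2))
  if (mean(seg) > 1e-12)
    expect_lt(sd(seg) / mean(seg), 1e-6)
  # a converged string re-evolved stops immediately
  s2 <- evolve_string(bowl, s, step_size = 0.05, tol = 1e-7)
  expect_equal(s2$iteration, 1L)
  expect_true(s2$converged)
})

test_that("the converged MFEP passes through the benchmark saddle", {
  two <- mb_oracle$minima[1:2, ]
  s0 <- init_string(list(list(start = unlist(two[1, 1:2]),
                              end = unlist(two[2, 1:2]), n = 101)))
  path <- evolve_string(mb_fes, s0, step_size = 5e-4, tol = 1e-7,
                        max_iter = 100000)
  expect_true(path$converged)
  dmin <- min(sqrt(rowSums(sweep(path$points, 2, mb_oracle$saddle$point)^2)))
  expect_lt(dmin, 0.05 * sqrt(2))
  # profile maximum approximates the saddle height within one-cell error
  prof <- profile_along_path(mb_fes, path)
  cell_tol <- local({       # FE spread over the saddle's grid cell corners
    sp <- mb_oracle$saddle$point
    i <- findInterval(sp[1], fes_axis(mb_fes, 1))
    j <- findInterval(sp[2], fes_axis(mb_fes, 2))
    diff(range(mb_fes$values[i:(i + 1), j:(j + 1)]))
  })
  expect_lt(abs(max(prof$free_energy) - mb_oracle$saddle$value), cell_tol)
  # endpoints slide into the basin minima
  expect_lt(sqrt(sum((path$points[1, ] - unlist(two[1, 1:2]))^2)), 0.1)
  # profile endpoints equal the FES at the path endpoints
  expect_equal(prof$free_energy[1],
               fes_lookup(mb_fes, path$points[1, ])$values)
})

test_that("the FES gradient is nearly perpendicular-free along the MFEP", {
  two <- mb_oracle$minima[1:2, ]
  s0 <- init_string(list(list(start = unlist(two[1, 1:2]),
                              end = unlist(two[2, 1:2]), n = 101)))
  path <- evolve_string(mb_fes, s0, step_size = 5e-4, tol = 1e-7,
                        max_iter = 100000)
  pts <- path$points
  g <- fes_lookup(mb_fes, pts)$gradients
  K <- nrow(pts)
  tang <- pts[c(2:K, K), ] - pts[c(1, 1:(K - 1)), ]
  tang <- tang / sqrt(rowSums(tang^2))
  perp <- g - tang * rowSums(g * tang)
  interior <- 5:(K - 4)
  scale <- max(sqrt(rowSums(g[interior, ]^2)))
  expect_lt(mean(sqrt(rowSums(perp[interior, ]^2))), 0.05 * scale)
})

test_that("the MFEP is stable under halving the descent step", {
  two <- mb_oracle$minima[1:2, ]
  s0 <- init_string(list(list(start = unlist(two[1, 1:2]),
                              end = unlist(two[2, 1:2]), n = 101)))
  p1 <- evolve_string(mb_fes, s0, step_size = 5e-4, tol = 1e-7,
                      max_iter = 100000)
  p2 <- evolve_string(mb_fes, s0, step_size = 2.5e-4, tol = 1e-7,
                      max_iter = 100000)
  rmsd <- sqrt(mean(rowSums((p1$points - p2$points)^2)))
  expect_lt(rmsd, 0.05)
  # constant surface: flat profile, nothing to descend
  flat <- fes_from_function(function(P) rep(1, nrow(P)),
                            mins = c(0, 0), maxs = c(1, 1), spacing = 0.05)
  s <- evolve_string(flat, init_string(list(list(start = c(0.2, 0.2),
                                                 end = c(0.8, 0.8), n = 11))),
                     step_size = 1e-3, tol = 1e-7)
  expect_true(s$converged)
  prof <- profile_along_path(flat, s)
  expect_true(all(prof$free_energy == 0))
})
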