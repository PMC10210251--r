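# On-the-fly free energy parametrization: reconstruct G(z) from TAMD
# spring-force samples on a piecewise-linear chapeau (hat) finite-element
# basis by gradient matching,
#   E(lambda) = 1/2 < | grad G_lambda(z_t) + f_t |^2 >,
# whose normal equations are A lambda = b with
#   A_mn = < grad phi_m . grad phi_n >,  b_m = - < grad phi_m . f_t >.
# Basis gradients are element-wise constant (1D cells; 2D triangles from
# the lower-left-diagonal split of a regular grid), so A and b accumulate
# exactly from per-element sample counts and force sums.

#' Chapeau finite-element grid
#'
#' 1D (hat functions on intervals) or 2D (piecewise-linear elements on a
#' regular grid, each cell split along its lower-left diagonal into two
#' triangles). Nodes carry the basis coefficients; samples accumulate per
#' element.
#'
#' @param mins,maxs grid bounds (length 1 or 2).
#' @param spacing node spacing per dimension (recycled).
#' @return An object of class `chapeau_grid`.
#' @export
chapeau_grid <- function(mins, maxs, spacing = 0.25) {
  dim <- length(mins)
  stopifnot(dim %in% c(1L, 2L), length(maxs) == dim, all(maxs > mins))
  spacing <- rep_len(spacing, dim)
  n <- round((maxs - mins) / spacing) + 1L
  h <- (maxs - mins) / (n - 1L)
  n_elem <- if (dim == 1L) n[1] - 1L else 2L * (n[1] - 1L) * (n[2] - 1L)
  structure(list(dim = dim, mins = mins, maxs = maxs, n = as.integer(n),
                 h = h, counts = numeric(n_elem),
                 fsum = matrix(0, n_elem, dim),
                 n_samples = 0L, n_discarded = 0L),
            class = "chapeau_grid")
}

#' @export
print.chapeau_grid <- function(x, ...) {
  cat(sprintf("<chapeau_grid %dD: %s nodes, %d samples (%d discarded)>\n",
              x$dim, paste(x$n, collapse = " x "), x$n_samples,
              x$n_discarded))
  invisible(x)
}

# element id per sample; NA if out of range. z: matrix ns x dim
.element_of <- function(grid, z) {
  z <- .as_cv_matrix(z, grid$dim)
  inr <- rep(TRUE, nrow(z))
  for (d in seq_len(grid$dim))
    inr <- inr & z[, d] >= grid$mins[d] & z[, d] <= grid$maxs[d]
  if (grid$dim == 1L) {
    c1 <- pmin(floor((z[, 1] - grid$mins[1]) / grid$h[1]) + 1L, grid$n[1] - 1L)
    ifelse(inr, c1, NA_integer_)
  } else {
    i <- pmin(floor((z[, 1] - grid$mins[1]) / grid$h[1]) + 1L, grid$n[1] - 1L)
    j <- pmin(floor((z[, 2] - grid$mins[2]) / grid$h[2]) + 1L, grid$n[2] - 1L)
    u <- (z[, 1] - grid$mins[1]) / grid$h[1] - (i - 1L)
    v <- (z[, 2] - grid$mins[2]) / grid$h[2] - (j - 1L)
    t_ <- ifelse(u + v <= 1, 1L, 2L)
    id <- ((j - 1L) * (grid$n[1] - 1L) + (i - 1L)) * 2L + t_
    ifelse(inr, id, NA_integer_)
  }
}

.as_cv_matrix <- function(z, dim) {
  if (is.matrix(z)) {
    stopifnot(ncol(z) == dim)
    z
  } else {
    if (dim == 1L) matrix(as.numeric(z), ncol = 1)
    else matrix(as.numeric(z), ncol = dim, byrow = TRUE)
  }
}

# nodes (1-based ids) and constant gradients of the elements.
# 2D node id = i + (j-1)*nx.
.element_tables <- function(grid) {
  if (grid$dim == 1L) {
    n <- grid$n[1]; h <- grid$h[1]
    cells <- seq_len(n - 1L)
    list(nodes = cbind(cells, cells + 1L),
         grads = list(matrix(c(-1 / h, 1 / h), ncol = 1)))  # per-node grad, 1D
  } else {
    nx <- grid$n[1]; ny <- grid$n[2]
    hx <- grid$h[1]; hy <- grid$h[2]
    ij <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L))
    n00 <- ij$i + (ij$j - 1L) * nx
    n10 <- n00 + 1L
    n01 <- n00 + nx
    n11 <- n01 + 1L
    # element ids: cell-major, triangle 1 then 2
    list(nodes_t1 = cbind(n00, n10, n01),
         nodes_t2 = cbind(n10, n01, n11),
         grads_t1 = rbind(c(-1 / hx, -1 / hy), c(1 / hx, 0), c(0, 1 / hy)),
         grads_t2 = rbind(c(0, -1 / hy), c(-1 / hx, 0), c(1 / hx, 1 / hy)))
  }
}

#' Evaluate the chapeau basis at a point
#'
#' Returns the nonzero basis values and (element-wise constant) gradients:
#' 2 hat functions in 1D, 3 triangle vertices in 2D.
#'
#' @param grid a [chapeau_grid].
#' @param z a CV point inside the grid bounds.
#' @return list(idx, values, gradients); `gradients` is length(idx) x dim.
#' @export
basis_eval <- function(grid, z) {
  z <- as.numeric(z)
  stopifnot(length(z) == grid$dim)
  el <- .element_of(grid, matrix(z, 1))
  if (is.na(el))
    .out_of_domain(sprintf("point (%s) outside chapeau grid",
                           paste(signif(z, 6), collapse = ", ")))
  if (grid$dim == 1L) {
    c1 <- el
    t_ <- (z[1] - (grid$mins[1] + (c1 - 1) * grid$h[1])) / grid$h[1]
    list(idx = c(c1, c1 + 1L), values = c(1 - t_, t_),
         gradients = matrix(c(-1, 1) / grid$h[1], ncol = 1))
  } else {
    et <- .element_tables(grid)
    nx <- grid$n[1]
    cell <- (el - 1L) %/% 2L
    tri <- (el - 1L) %% 2L + 1L
    i <- cell %% (nx - 1L) + 1L
    j <- cell %/% (nx - 1L) + 1L
    u <- (z[1] - grid$mins[1]) / grid$h[1] - (i - 1L)
    v <- (z[2] - grid$mins[2]) / grid$h[2] - (j - 1L)
    cr <- cell + 1L
    if (tri == 1L) {
      list(idx = as.integer(et$nodes_t1[cr, ]),
           values = c(1 - u - v, u, v), gradients = et$grads_t1)
    } else {
      list(idx = as.integer(et$nodes_t2[cr, ]),
           values = c(1 - v, 1 - u, u + v - 1), gradients = et$grads_t2)
    }
  }
}

#' Accumulate TAMD force samples into the normal-equation system
#'
#' Adds each sample's contribution — outer products of the nonzero basis
#' gradients into A, and \eqn{-\nabla\phi_m \cdot f_t} into b — as running
#' sums; because the gradients are constant per element, only per-element
#' counts and force sums are stored. Out-of-range samples are discarded
#' and counted.
#'
#' @param grid a [chapeau_grid].
#' @param z CV samples: vector (1D) or matrix samples x dim.
#' @param f force samples \eqn{\kappa(\theta - z)}, same shape as `z`.
#' @return The updated grid.
#' @export
otfp_accumulate <- function(grid, z, f) {
  z <- .as_cv_matrix(z, grid$dim)
  f <- .as_cv_matrix(f, grid$dim)
  stopifnot(nrow(z) == nrow(f))
  el <- .element_of(grid, z)
  ok <- !is.na(el)
  n_elem <- length(grid$counts)
  if (any(ok)) {
    grid$counts <- grid$counts + tabulate(el[ok], nbins = n_elem)
    fs <- rowsum(f[ok, , drop = FALSE], group = el[ok])
    rows <- as.integer(rownames(fs))
    grid$fsum[rows, ] <- grid$fsum[rows, , drop = FALSE] + fs
  }
  grid$n_samples <- grid$n_samples + sum(ok)
  grid$n_discarded <- grid$n_discarded + sum(!ok)
  grid
}

#' Assemble the accumulated normal-equation system
#'
#' @param grid a [chapeau_grid] after [otfp_accumulate()].
#' @return list(A, b): A a sparse symmetric node x node matrix of summed
#'   gradient outer products, b the node vector of summed force
#'   projections.
#' @export
chapeau_system <- function(grid) {
  n_nodes <- prod(grid$n)
  et <- .element_tables(grid)
  if (grid$dim == 1L) {
    cnt <- grid$counts
    h <- grid$h[1]
    cells <- seq_along(cnt)
    ii <- c(cells, cells + 1L, cells, cells + 1L)
    jj <- c(cells, cells + 1L, cells + 1L, cells)
    xx <- c(cnt, cnt, -cnt, -cnt) / h^2
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_nodes, n_nodes))
    b <- numeric(n_nodes)
    fs <- grid$fsum[, 1]
    # b_m = -sum grad phi_m . f : left node grad -1/h, right node +1/h
    b_add <- fs / h
    for (k in seq_along(cells)) {
      b[cells[k]] <- b[cells[k]] + b_add[k]
      b[cells[k] + 1L] <- b[cells[k] + 1L] - b_add[k]
    }
    list(A = A, b = b)
  } else {
    ncell <- (grid$n[1] - 1L) * (grid$n[2] - 1L)
    ids <- seq_len(ncell)
    cnt1 <- grid$counts[2L * ids - 1L]
    cnt2 <- grid$counts[2L * ids]
    fs1 <- grid$fsum[2L * ids - 1L, , drop = FALSE]
    fs2 <- grid$fsum[2L * ids, , drop = FALSE]
    ii <- jj <- integer(0); xx <- numeric(0)
    b <- numeric(n_nodes)
    for (tri in 1:2) {
      nodes <- if (tri == 1) et$nodes_t1 else et$nodes_t2
      gr <- if (tri == 1) et$grads_t1 else et$grads_t2
      cnt <- if (tri == 1) cnt1 else cnt2
      fs <- if (tri == 1) fs1 else fs2
      G <- gr %*% t(gr)  # 3x3 Gram of the triangle's gradients
      for (a_ in 1:3) for (b_ in 1:3) {
        ii <- c(ii, nodes[, a_]); jj <- c(jj, nodes[, b_])
        xx <- c(xx, cnt * G[a_, b_])
      }
      for (a_ in 1:3) {
        badd <- -(fs[, 1] * gr[a_, 1] + fs[, 2] * gr[a_, 2])
        b <- b + tabulate_weighted(nodes[, a_], badd, n_nodes)
      }
    }
    keep <- xx != 0
    A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                              dims = c(n_nodes, n_nodes))
    list(A = A, b = b)
  }
}

# sum weights w by integer index into a length-n vector
tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, group = idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Per-node sample support
#'
#' Number of accumulated samples falling in elements incident to each node.
#'
#' @param grid a [chapeau_grid].
#' @export
node_support <- function(grid) {
  n_nodes <- prod(grid$n)
  et <- .element_tables(grid)
  sup <- numeric(n_nodes)
  if (grid$dim == 1L) {
    cells <- seq_along(grid$counts)
    sup <- tabulate_weighted(c(cells, cells + 1L),
                             c(grid$counts, grid$counts), n_nodes)
  } else {
    ncell <- (grid$n[1] - 1L) * (grid$n[2] - 1L)
    ids <- seq_len(ncell)
    for (tri in 1:2) {
      nodes <- if (tri == 1) et$nodes_t1 else et$nodes_t2
      cnt <- grid$counts[2L * ids - (2L - tri)]
      for (a_ in 1:3)
        sup <- sup + tabulate_weighted(nodes[, a_], cnt, n_nodes)
    }
  }
  sup
}

#' Solve the OTFP system for the free energy surface
#'
#' Restricts A, b to nodes with sampled support, solves the (gauge-fixed)
#' linear system, marks the remaining nodes undefined, and min-shifts the
#' defined values to zero. A singular restricted system falls back to a
#' ridge-regularised smallest-norm solution with a warning.
#'
#' @param grid a [chapeau_grid] with accumulated samples.
#' @param min_support smallest per-node sample support regarded as defined.
#' @param provenance optional list recorded in the surface (replica ids,
#'   sample counts).
#' @return A `free_energy_surface`.
#' @export
solve_fes <- function(grid, min_support = 10, provenance = NULL) {
  if (grid$n_samples <= 0) .stopf("no samples accumulated")
  sys <- chapeau_system(grid)
  sup <- node_support(grid)
  defined <- sup >= min_support & Matrix::diag(sys$A) > 0
  idx <- which(defined)
  if (length(idx) < 2) .stopf("fewer than 2 nodes with sampled support")
  Ar <- sys$A[idx, idx, drop = FALSE]
  br <- sys$b[idx]
  ridge <- 1e-9 * mean(Matrix::diag(Ar))
  lam <- tryCatch(
    as.numeric(Matrix::solve(Ar + ridge * Matrix::Diagonal(length(idx)), br)),
    error = function(e) {
      warning("singular restricted system; returning a ridge-regularised ",
              "smallest-norm solution")
      as.numeric(Matrix::solve(Ar + 1e-6 * mean(Matrix::diag(Ar)) *
                                 Matrix::Diagonal(length(idx)), br))
    })
  values <- rep(NA_real_, prod(grid$n))
  values[idx] <- lam - min(lam)
  if (is.null(provenance))
    provenance <- list(replicas = list(list(id = 1L,
                                            n_samples = grid$n_samples)))
  new_fes(grid, values, defined, provenance)
}

new_fes <- function(grid, values, defined, provenance = NULL) {
  shape <- function(x) if (grid$dim == 2L) matrix(x, grid$n[1], grid$n[2]) else x
  structure(list(dim = grid$dim, mins = grid$mins, maxs = grid$maxs,
                 n = grid$n, h = grid$h, values = shape(values),
                 defined = shape(defined),
                 n_samples = grid$n_samples, provenance = provenance),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("<free_energy_surface %dD: %s nodes, %d defined>\n", x$dim,
              paste(x$n, collapse = " x "), sum(x$defined)))
  invisible(x)
}

#' Node coordinates of an FES or chapeau grid axis
#'
#' @param fes a `free_energy_surface` or [chapeau_grid].
#' @param d axis (1 or 2).
#' @export
fes_axis <- function(fes, d = 1) {
  seq(fes$mins[d], fes$maxs[d], length.out = fes$n[d])
}

#' Build an FES by evaluating a function on grid nodes
#'
#' Used to grid analytic surfaces (e.g. the benchmark potential) for the
#' string method and for oracle comparisons.
#'
#' @param f function taking a matrix of points (rows) and returning values.
#' @param mins,maxs,spacing grid geometry, as in [chapeau_grid()].
#' @return A fully defined, min-shifted `free_energy_surface`.
#' @export
fes_from_function <- function(f, mins, maxs, spacing) {
  grid <- chapeau_grid(mins, maxs, spacing)
  pts <- if (grid$dim == 1L) matrix(fes_axis(grid, 1), ncol = 1) else
    as.matrix(expand.grid(fes_axis(grid, 1), fes_axis(grid, 2)))
  vals <- f(pts)
  vals <- vals - min(vals)
  new_fes(grid, vals, rep(TRUE, prod(grid$n)),
          provenance = list(source = "function"))
}

#' Average replica free energy surfaces
#'
#' Pointwise mean over nodes defined in every input (intersection mask),
#' re-min-shifted; the gauge constant of each replica is irrelevant.
#'
#' @param surfaces list of `free_energy_surface`s on identical grids.
#' @return A `free_energy_surface`.
#' @export
average_fes <- function(surfaces) {
  stopifnot(length(surfaces) >= 1,
            all(vapply(surfaces, inherits, TRUE, "free_energy_surface")))
  f1 <- surfaces[[1]]
  for (s in surfaces[-1])
    if (!isTRUE(all.equal(s$mins, f1$mins)) ||
        !isTRUE(all.equal(s$maxs, f1$maxs)) || !identical(s$n, f1$n))
      .stopf("mismatched FES grids")
  mask <- Reduce(`&`, lapply(surfaces, `[[`, "defined"))
  vals <- Reduce(`+`, lapply(surfaces, function(s) {
    v <- s$values
    v[!mask] <- 0
    v
  })) / length(surfaces)
  vals[!mask] <- NA_real_
  if (!any(mask)) .stopf("intersection of defined regions is empty")
  vals <- vals - min(vals[mask])
  out <- f1
  out$values <- vals
  out$defined <- mask
  out$n_samples <- sum(vapply(surfaces, `[[`, 0L, "n_samples"))
  out$provenance <- list(replicas = unlist(lapply(surfaces, function(s)
    s$provenance$replicas), recursive = FALSE))
  out
}

# node gradients by central differences (one-sided at edges / next to
# undefined nodes); NA where no defined neighbour exists.
.fes_node_gradients <- function(fes) {
  v <- fes$values
  if (fes$dim == 1L) {
    g <- .axis_diff(v, fes$h[1])
    matrix(g, ncol = 1)
  } else {
    gx <- apply(v, 2, .axis_diff, h = fes$h[1])
    gy <- t(apply(v, 1, .axis_diff, h = fes$h[2]))
    list(gx = gx, gy = gy)
  }
}

.axis_diff <- function(v, h) {
  n <- length(v)
  vp <- c(v[-1], NA)
  vm <- c(NA, v[-n])
  g <- (vp - vm) / (2 * h)
  fwd <- (vp - v) / h
  bwd <- (v - vm) / h
  g[is.na(g)] <- fwd[is.na(g)]
  g[is.na(g)] <- bwd[is.na(g)]
  g
}

#' Interpolate an FES (value and gradient)
#'
#' Linear (1D) / bilinear (2D) interpolation of node values; the gradient
#' interpolates central-difference node gradients through the same
#' interpolant, so it is exact for linear surfaces. Points in cells with
#' any undefined corner raise an out-of-domain condition.
#'
#' @param fes a `free_energy_surface`.
#' @param z a point (length `dim`) or a matrix of points (rows).
#' @return list(values, gradients).
#' @export
fes_lookup <- function(fes, z) {
  P <- .as_cv_matrix(z, fes$dim)
  ng <- .fes_node_gradients(fes)
  .fes_interp(fes, P, ng)
}

.fes_interp <- function(fes, P, ng) {
  ns <- nrow(P)
  if (fes$dim == 1L) {
    ax <- fes_axis(fes, 1)
    i <- pmin(pmax(floor((P[, 1] - fes$mins[1]) / fes$h[1]) + 1L, 1L),
              fes$n[1] - 1L)
    out <- P[, 1] < fes$mins[1] | P[, 1] > fes$maxs[1]
    t_ <- (P[, 1] - ax[i]) / fes$h[1]
    v0 <- fes$values[i]; v1 <- fes$values[i + 1L]
    bad <- out | is.na(v0) | is.na(v1)
    if (any(bad))
      .out_of_domain(sprintf("FES lookup outside defined region at z = %g",
                             P[which(bad)[1], 1]))
    vals <- (1 - t_) * v0 + t_ * v1
    g <- (1 - t_) * ng[i, 1] + t_ * ng[i + 1L, 1]
    list(values = vals, gradients = matrix(g, ncol = 1))
  } else {
    i <- pmin(pmax(floor((P[, 1] - fes$mins[1]) / fes$h[1]) + 1L, 1L),
              fes$n[1] - 1L)
    j <- pmin(pmax(floor((P[, 2] - fes$mins[2]) / fes$h[2]) + 1L, 1L),
              fes$n[2] - 1L)
    out <- P[, 1] < fes$mins[1] | P[, 1] > fes$maxs[1] |
      P[, 2] < fes$mins[2] | P[, 2] > fes$maxs[2]
    u <- (P[, 1] - fes$mins[1]) / fes$h[1] - (i - 1L)
    v <- (P[, 2] - fes$mins[2]) / fes$h[2] - (j - 1L)
    id00 <- cbind(i, j); id10 <- cbind(i + 1L, j)
    id01 <- cbind(i, j + 1L); id11 <- cbind(i + 1L, j + 1L)
    v00 <- fes$values[id00]; v10 <- fes$values[id10]
    v01 <- fes$values[id01]; v11 <- fes$values[id11]
    bad <- out | is.na(v00) | is.na(v10) | is.na(v01) | is.na(v11)
    if (any(bad))
      .out_of_domain(sprintf(
        "FES lookup outside defined region at (%g, %g)",
        P[which(bad)[1], 1], P[which(bad)[1], 2]))
    w00 <- (1 - u) * (1 - v); w10 <- u * (1 - v)
    w01 <- (1 - u) * v; w11 <- u * v
    vals <- w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11
    gx <- w00 * ng$gx[id00] + w10 * ng$gx[id10] +
      w01 * ng$gx[id01] + w11 * ng$gx[id11]
    gy <- w00 * ng$gy[id00] + w10 * ng$gy[id10] +
      w01 * ng$gy[id01] + w11 * ng$gy[id11]
    list(values = vals, gradients = cbind(gx, gy))
  }
}

#' Root-mean-square deviation between two surfaces
#'
#' RMS of the difference over the mutually defined region after removing
#' the mean offset (the FES gauge constant is arbitrary).
#'
#' @param fes a `free_energy_surface`.
#' @param reference a second surface on the same grid, or a matrix/vector
#'   of reference values on the same nodes.
#' @param mask optional additional logical mask.
#' @export
fes_rms <- function(fes, reference, mask = NULL) {
  ref_vals <- if (inherits(reference, "free_energy_surface"))
    reference$values else reference
  ref_def <- if (inherits(reference, "free_energy_surface"))
    reference$defined else !is.na(ref_vals)
  m <- fes$defined & ref_def
  if (!is.null(mask)) m <- m & mask
  if (!any(m)) .stopf("no mutually defined nodes")
  d <- fes$values[m] - ref_vals[m]
  d <- d - mean(d)
  sqrt(mean(d^2))
}
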