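# Zero-temperature string method over a gridded free energy surface:
# iterate steepest-descent displacement of a discretised curve with
# equal-arclength reparametrization until the mean displacement between
# consecutive parametrized strings falls below tolerance.

new_string_path <- function(points, iteration = 0L, converged = FALSE,
                            mean_displacement = NA_real_, extra = list()) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  arc <- arc / arc[length(arc)]
  structure(c(list(points = points, arclengths = arc,
                   iteration = iteration, converged = converged,
                   mean_displacement = mean_displacement), extra),
            class = "string_path")
}

#' @export
print.string_path <- function(x, ...) {
  cat(sprintf("<string_path: %d points, iteration %d, %s>\n",
              nrow(x$points), x$iteration,
              if (x$converged) sprintf("converged (mean displacement %.2e)",
                                       x$mean_displacement) else "not converged"))
  invisible(x)
}

#' Initialise a string as a union of linear interpolations
#'
#' Each segment is a linear interpolation from `start` to `end` with `n`
#' points; segments are concatenated in order, and a junction point shared
#' by consecutive segments (within 1e-6 A) is kept once.
#'
#' @param segments list of `list(start =, end =, n =)`; `n >= 2` and
#'   `start != end` per segment.
#' @return A `string_path`.
#' @export
init_string <- function(segments) {
  if (!length(segments)) .stopf("empty segment list")
  pts <- NULL
  for (s in segments) {
    stopifnot(!is.null(s$start), !is.null(s$end), !is.null(s$n))
    if (s$n < 2) .stopf("segments need at least 2 points")
    if (sqrt(sum((s$end - s$start)^2)) < 1e-12)
      .stopf("degenerate segment: start equals end")
    tt <- seq(0, 1, length.out = s$n)
    seg <- outer(1 - tt, as.numeric(s$start)) + outer(tt, as.numeric(s$end))
    if (is.null(pts)) pts <- seg
    else {
      if (sqrt(sum((pts[nrow(pts), ] - seg[1, ])^2)) < 1e-6)
        seg <- seg[-1, , drop = FALSE]
      pts <- rbind(pts, seg)
    }
  }
  new_string_path(pts)
}

# equal-arclength reparametrization by piecewise-linear interpolation
.reparametrize <- function(points) {
  K <- nrow(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-K, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[K] == 0) return(points)
  s <- s / s[K]
  target <- seq(0, 1, length.out = K)
  out <- points
  for (d in seq_len(ncol(points)))
    out[, d] <- approx(s, points[, d], xout = target, ties = "ordered")$y
  out
}

#' Evolve a string to the minimum free energy path
#'
#' Iterates (i) steepest-descent displacement of every point by
#' `-step_size * grad G` from [fes_lookup()], (ii) equal-arclength
#' reparametrization; stops when the mean point displacement between
#' consecutive parametrized strings drops below `tol`, or at `max_iter`.
#' Endpoints evolve freely (they slide into the basin minima). If the mean
#' string energy rises for 5 consecutive iterations the step size is
#' halved (overshoot guard).
#'
#' @param fes a `free_energy_surface` covering the whole path.
#' @param path a `string_path`.
#' @param step_size steepest-descent step (A^2 mol/kcal).
#' @param tol convergence threshold on the mean displacement (A).
#' @param max_iter iteration cap.
#' @return The evolved `string_path` with convergence metadata
#'   (`iteration`, `converged`, `mean_displacement`, `step_size_final`).
#' @export
evolve_string <- function(fes, path, step_size = 1e-3, tol = 1e-7,
                          max_iter = 100000L) {
  stopifnot(inherits(fes, "free_energy_surface"),
            inherits(path, "string_path"))
  pts <- path$points
  ng <- .fes_node_gradients(fes)
  prev_e <- Inf
  rising <- 0L
  disp <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lk <- tryCatch(.fes_interp(fes, pts, ng),
                   tamdotfp_out_of_domain = function(e)
                     .stopf("string left the defined FES region at iteration %d: %s",
                            it, conditionMessage(e)))
    newp <- .reparametrize(pts - step_size * lk$gradients)
    disp <- mean(sqrt(rowSums((newp - pts)^2)))
    e <- mean(.fes_interp(fes, newp, ng)$values)
    if (e > prev_e) {
      rising <- rising + 1L
      if (rising >= 5L) { step_size <- step_size / 2; rising <- 0L }
    } else rising <- 0L
    prev_e <- e
    pts <- newp
    if (disp < tol) break
  }
  new_string_path(pts, iteration = it, converged = disp < tol,
                  mean_displacement = disp,
                  extra = list(step_size_final = step_size, tol = tol))
}

#' Free energy profile along a path
#'
#' FES values at the path points (via [fes_lookup()]) paired with the
#' normalized arclength.
#'
#' @param fes a `free_energy_surface`.
#' @param path a `string_path`.
#' @return data.frame(arclength, free_energy).
#' @export
profile_along_path <- function(fes, path) {
  vals <- fes_lookup(fes, path$points)$values
  data.frame(arclength = path$arclengths, free_energy = vals)
}

#' Local minima of a gridded surface
#'
#' Nodes not exceeded by any defined neighbour (8-neighbourhood in 2D),
#' optionally refined to sub-grid positions by per-axis parabolic
#' interpolation. Serves as the exhaustive grid-search oracle against
#' which the string method is checked.
#'
#' @param fes a `free_energy_surface`.
#' @param refine parabolic sub-grid refinement of interior minima.
#' @return data.frame with the minima positions and values, sorted by
#'   value.
#' @export
fes_minima <- function(fes, refine = TRUE) {
  if (fes$dim == 1L) {
    v <- fes$values
    n <- length(v)
    ax <- fes_axis(fes, 1)
    is_min <- vapply(seq_len(n), function(i) {
      if (is.na(v[i])) return(FALSE)
      nb <- v[c(max(1, i - 1), min(n, i + 1))]
      all(v[i] <= nb, na.rm = TRUE)
    }, TRUE)
    # suppress plateaus: keep strict minima vs at least one neighbour
    idx <- which(is_min)
    pos <- ax[idx]; val <- v[idx]
    if (refine) {
      for (k in seq_along(idx)) {
        i <- idx[k]
        if (i > 1 && i < n && !anyNA(v[(i - 1):(i + 1)])) {
          den <- v[i - 1] - 2 * v[i] + v[i + 1]
          if (den > 0) {
            d <- 0.5 * (v[i - 1] - v[i + 1]) / den
            pos[k] <- ax[i] + d * fes$h[1]
            val[k] <- v[i] - 0.25 * (v[i - 1] - v[i + 1]) * d
          }
        }
      }
    }
    out <- data.frame(z = pos, value = val)
    out[order(out$value), , drop = FALSE]
  } else {
    v <- fes$values
    nx <- fes$n[1]; ny <- fes$n[2]
    ax <- fes_axis(fes, 1); ay <- fes_axis(fes, 2)
    big <- ifelse(is.na(v), Inf, v)
    pad <- matrix(Inf, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- big
    nbmin <- matrix(Inf, nx, ny)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nbmin <- pmin(nbmin, pad[(2:(nx + 1)) + di, (2:(ny + 1)) + dj])
    }
    isl <- which(big <= nbmin & is.finite(big), arr.ind = TRUE)
    pos1 <- ax[isl[, 1]]; pos2 <- ay[isl[, 2]]; val <- big[isl]
    if (refine && nrow(isl)) {
      for (k in seq_len(nrow(isl))) {
        i <- isl[k, 1]; j <- isl[k, 2]
        if (i > 1 && i < nx && all(is.finite(big[(i - 1):(i + 1), j]))) {
          den <- big[i - 1, j] - 2 * big[i, j] + big[i + 1, j]
          if (den > 0)
            pos1[k] <- ax[i] + 0.5 * (big[i - 1, j] - big[i + 1, j]) / den *
              fes$h[1]
        }
        if (j > 1 && j < ny && all(is.finite(big[i, (j - 1):(j + 1)]))) {
          den <- big[i, j - 1] - 2 * big[i, j] + big[i, j + 1]
          if (den > 0)
            pos2[k] <- ay[j] + 0.5 * (big[i, j - 1] - big[i, j + 1]) / den *
              fes$h[2]
        }
      }
    }
    out <- data.frame(z1 = pos1, z2 = pos2, value = val)
    out[order(out$value), , drop = FALSE]
  }
}

#' Minimax saddle between two basins of a gridded surface
#'
#' The saddle of the path between `from` and `to` whose highest point is
#' lowest, found exhaustively: grid nodes are activated in order of
#' increasing value with union-find connectivity (4-neighbourhood); the
#' node whose activation first connects the two endpoints is the saddle.
#'
#' @param fes a 2D `free_energy_surface`.
#' @param from,to points in CV space (snapped to the nearest node).
#' @return list(point, value, node = c(i, j)).
#' @export
fes_saddle <- function(fes, from, to) {
  stopifnot(fes$dim == 2L)
  V <- fes$values
  V[is.na(V)] <- Inf
  ax <- fes_axis(fes, 1); ay <- fes_axis(fes, 2)
  snap <- function(p) c(which.min(abs(ax - p[1])), which.min(abs(ay - p[2])))
  a <- snap(from); b <- snap(to)
  res <- cpp_minimax_saddle(V, a[1], a[2], b[1], b[2])
  list(point = c(ax[res$i], ay[res$j]), value = res$value,
       node = c(res$i, res$j))
}
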