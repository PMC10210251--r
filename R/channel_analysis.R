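# Trajectory and structure analyses for ion-channel selectivity filters:
# cylindrical-region occupancy statistics, conditional z histograms,
# cross distances between conserved residues of opposite repeats, and
# superposition RMSD over P-loop selections.

#' Cylindrical occupancy region
#'
#' The conductivity/selectivity filter volume: a cylinder around the pore
#' (z) axis. Boundary convention: inclusive on the radius and on both z
#' bounds.
#'
#' @param radius cylinder radius (Angstrom), > 0. 7 A in the channel
#'   analyses.
#' @param z_lower,z_upper axial bounds, `z_lower < z_upper`.
#' @param center x, y of the pore axis.
#' @param provenance how the bounds were derived ("explicit" or a
#'   reference-atom rule description).
#' @export
occupancy_region <- function(radius = 7, z_lower, z_upper, center = c(0, 0),
                             provenance = "explicit") {
  if (radius <= 0) .stopf("radius must be > 0")
  if (z_lower >= z_upper) .stopf("z_lower must be < z_upper")
  structure(list(radius = radius, z_lower = z_lower, z_upper = z_upper,
                 center = center, provenance = provenance),
            class = "occupancy_region")
}

#' Occupancy region bounds from reference atoms of a structure
#'
#' Evaluates the reference-atom rule used for the filter region: the upper
#' bound is the z coordinate of one reference atom, the lower bound the z
#' of another, shifted by `lower_shift` (e.g. -4 A below the C-alpha of
#' the residue under the filter).
#'
#' @param structure a `structure_model`.
#' @param upper,lower lists `list(resno =, elety = "CA")` addressing the
#'   reference atoms.
#' @param lower_shift added to the lower reference z.
#' @param radius,center as in [occupancy_region()].
#' @export
occupancy_region_from_structure <- function(structure, upper, lower,
                                            lower_shift = -4, radius = 7,
                                            center = c(0, 0)) {
  zu <- .resolve_atom(structure, upper)$z
  zl <- .resolve_atom(structure, lower)$z + lower_shift
  occupancy_region(radius = radius, z_lower = zl, z_upper = zu,
                   center = center,
                   provenance = sprintf(
                     "reference atoms: upper resno %s %s, lower resno %s %s %+g A",
                     upper$resno, upper$elety %||% "CA",
                     lower$resno, lower$elety %||% "CA", lower_shift))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-frame occupancy counts
#'
#' Counts, per frame, how many of the tracked particles are inside the
#' region (radial distance from the axis <= radius and z within bounds,
#' all inclusive).
#'
#' @param traj an `md_trajectory` with 3D coordinates.
#' @param region an [occupancy_region].
#' @param species particle indices to track (3D layout).
#' @return An `occupancy_series`: list(counts, times).
#' @export
count_occupancy <- function(traj, region, species) {
  if (!length(species)) .stopf("empty species selection")
  X <- traj$x_frames
  counts <- integer(nrow(X))
  for (p in species) {
    ix <- 3L * (p - 1L) + 1L
    if (ix + 2L > ncol(X)) .stopf("particle %d outside trajectory layout", p)
    r <- sqrt((X[, ix] - region$center[1])^2 +
                (X[, ix + 1L] - region$center[2])^2)
    z <- X[, ix + 2L]
    counts <- counts + as.integer(r <= region$radius & z >= region$z_lower &
                                    z <= region$z_upper)
  }
  structure(list(counts = counts, times = traj$times,
                 species = as.integer(species), region = region),
            class = "occupancy_series")
}

#' Occupancy distribution table
#'
#' Percentages of frames at occupancy 0..`max_count` (counts above the top
#' bin are pooled into it, with a message), plus the mean and population
#' standard deviation of the raw counts (sample sd also reported).
#'
#' @param series an `occupancy_series`.
#' @param max_count top occupancy bin.
#' @return list(percent, mean, sd, sd_sample, n_frames, pooled_above).
#' @export
occupancy_table <- function(series, max_count = 4) {
  cnt <- series$counts
  if (!length(cnt)) .stopf("need at least one frame")
  pooled <- sum(cnt > max_count)
  if (pooled) message(pooled, " frame(s) above occupancy ", max_count,
                      " pooled into the top bin")
  cc <- pmin(cnt, max_count)
  pct <- 100 * tabulate(cc + 1L, nbins = max_count + 1L) / length(cc)
  names(pct) <- as.character(0:max_count)
  m <- mean(cnt)
  sd_pop <- sqrt(mean((cnt - m)^2))
  sd_smp <- if (length(cnt) > 1) stats::sd(cnt) else 0
  list(percent = pct, mean = m, sd = sd_pop, sd_sample = sd_smp,
       n_frames = length(cnt), pooled_above = pooled)
}

#' Conditional z-coordinate histogram
#'
#' Histogram of the z coordinates of selected particles over the frames
#' satisfying a condition (e.g. exactly one ion in the filter region).
#' With `com = TRUE` the z of the selection's centre of mass is binned
#' instead (the two-ion COM variant); otherwise the z of every selected
#' particle is pooled.
#'
#' @param traj an `md_trajectory` (3D layout), or a list of trajectories
#'   pooled with provenance recorded.
#' @param selection particle indices.
#' @param z_range histogram range; the default [3, 18] matches the sampled
#'   filter interval, the extended range is c(-2, 22).
#' @param n_bins number of bins, >= 1.
#' @param frames optional logical/integer frame subset (the condition);
#'   for pooled trajectories, a list of subsets.
#' @param com bin the selection COM z instead of individual z values.
#' @param density normalize to a density instead of raw counts.
#' @return list(breaks, counts, mids, n_frames_used); empty conditional
#'   frame sets yield an all-zero histogram with a warning.
#' @export
z_histogram <- function(traj, selection, z_range = c(3, 18), n_bins = 60,
                        frames = NULL, com = FALSE, density = FALSE) {
  if (n_bins < 1) .stopf("need at least one bin")
  trajs <- if (inherits(traj, "md_trajectory")) list(traj) else traj
  frames_list <- if (is.null(frames)) vector("list", length(trajs))
  else if (is.list(frames)) frames else list(frames)
  zs <- numeric(0)
  n_used <- 0L
  for (k in seq_along(trajs)) {
    X <- trajs[[k]]$x_frames
    sel_frames <- frames_list[[k]] %||% seq_len(nrow(X))
    if (is.logical(sel_frames)) sel_frames <- which(sel_frames)
    n_used <- n_used + length(sel_frames)
    if (!length(sel_frames)) next
    Zm <- sapply(selection, function(p) X[sel_frames, 3L * (p - 1L) + 3L])
    Zm <- matrix(Zm, nrow = length(sel_frames))
    zs <- c(zs, if (com) rowMeans(Zm) else as.numeric(Zm))
  }
  breaks <- seq(z_range[1], z_range[2], length.out = n_bins + 1L)
  if (!length(zs)) {
    warning("condition excludes every frame; returning an empty histogram")
    counts <- numeric(n_bins)
  } else {
    zs <- zs[zs >= z_range[1] & zs <= z_range[2]]
    counts <- if (length(zs))
      tabulate(pmin(findInterval(zs, breaks, rightmost.closed = TRUE),
                    n_bins), nbins = n_bins)
    else numeric(n_bins)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (density) {
    bw <- diff(breaks)[1]
    total <- sum(counts)
    counts <- if (total > 0) counts / (total * bw) else counts
  }
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 n_frames_used = n_used, density = density,
                 pooled = length(trajs) > 1),
            class = "z_histogram")
}

# structures -----------------------------------------------------------------

#' Read an atomic structure from a PDB file
#'
#' Parses the standard PDB format via bio3d; keeps the first model,
#' resolves alternate locations to the highest occupancy, preserves
#' insertion codes in the addressing. If no chain is given, the chain with
#' most residues is used (reported with a message).
#'
#' @param path PDB file.
#' @param chain optional chain identifier.
#' @return A `structure_model`: list(atoms, source) where `atoms` has
#'   columns chain, resno, insert, resid, elety, x, y, z, o.
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  df <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                   resid = at$resid, elety = at$elety,
                   x = at$x, y = at$y, z = at$z, o = at$o,
                   stringsAsFactors = FALSE)
  df$chain[is.na(df$chain)] <- ""
  if (is.null(chain)) {
    tab <- tapply(df$resno, df$chain, function(r) length(unique(r)))
    chain <- names(tab)[which.max(tab)]
    message("using chain '", chain, "' (most residues)")
  }
  df <- df[df$chain == chain, , drop = FALSE]
  # alternate locations: keep highest occupancy per (resno, insert, elety)
  key <- paste(df$resno, df$insert, df$elety, sep = "|")
  ord <- order(key, -df$o)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$resno, df$insert, df$elety, sep = "|")), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure_model(df, source = path)
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with at least resno, elety, x, y, z (chain,
#'   insert, resid, o optional).
#' @param source identifier recorded in the object.
#' @export
structure_model <- function(atoms, source = "in-memory") {
  for (col in c("chain", "insert")) if (is.null(atoms[[col]])) atoms[[col]] <- ""
  if (is.null(atoms$resid)) atoms$resid <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    .stopf("atom addressing not unique: duplicated (chain, resno, atom) keys")
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model: %d atoms, %d residues (%s)>\n",
              nrow(x$atoms), length(unique(x$atoms$resno)), x$source))
  invisible(x)
}

.resolve_atom <- function(structure, addr) {
  a <- structure$atoms
  elety <- addr$elety %||% "CA"
  hit <- a$resno == addr$resno & a$elety == elety
  if (!is.null(addr$chain)) hit <- hit & a$chain == addr$chain
  if (!is.null(addr$insert)) hit <- hit & a$insert == addr$insert
  w <- which(hit)
  if (!length(w))
    .stopf("atom not found: residue %s atom %s", addr$resno, elety)
  if (length(w) > 1)
    .stopf("ambiguous atom address: residue %s atom %s matches %d atoms",
           addr$resno, elety, length(w))
  a[w, , drop = FALSE]
}

#' Cross-distance definition
#'
#' @param label e.g. "d1A".
#' @param a,b atom addresses: lists `list(resno =, elety =)`.
#' @export
cross_distance_def <- function(label, a, b) {
  structure(list(label = label, atom_a = a, atom_b = b),
            class = "cross_distance_def")
}

#' Cross distance between two addressed atoms
#'
#' Euclidean distance, reported to 0.01 A (the exact value is kept in the
#' `"exact"` attribute). Symmetric in its atoms and invariant under rigid
#' motion of the structure.
#'
#' @param structure a `structure_model`.
#' @param def a [cross_distance_def] (or the name of a preset, see
#'   [cross_distance_presets()]).
#' @export
cross_distance <- function(structure, def) {
  if (is.character(def)) {
    presets <- cross_distance_presets()
    if (!def %in% names(presets)) .stopf("unknown preset '%s'", def)
    def <- presets[[def]]
  }
  pa <- .resolve_atom(structure, def$atom_a)
  pb <- .resolve_atom(structure, def$atom_b)
  d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2 + (pa$z - pb$z)^2)
  structure(round(d, 2), exact = d, label = def$label)
}

#' Filter cross-distance presets (d1A..d4B)
#'
#' Atom pairs between the outer charged ring and the signature ring of the
#' four repeats, in the channel's residue numbering: d1A E387CA-D1426CA,
#' d1B E387CD-D1426CG, d2A E945CA-D1717CA, d2B E945CD-D1717CG,
#' d3A D384CA-K1422CA, d3B D384CG-K1422CE, d4A E942CA-A1714CA,
#' d4B E942CD-A1714CB.
#'
#' @return Named list of [cross_distance_def]s.
#' @export
cross_distance_presets <- function() {
  mk <- function(lbl, r1, a1, r2, a2)
    cross_distance_def(lbl, list(resno = r1, elety = a1),
                       list(resno = r2, elety = a2))
  list(
    d1A = mk("d1A", 387, "CA", 1426, "CA"),
    d1B = mk("d1B", 387, "CD", 1426, "CG"),
    d2A = mk("d2A", 945, "CA", 1717, "CA"),
    d2B = mk("d2B", 945, "CD", 1717, "CG"),
    d3A = mk("d3A", 384, "CA", 1422, "CA"),
    d3B = mk("d3B", 384, "CG", 1422, "CE"),
    d4A = mk("d4A", 942, "CA", 1714, "CA"),
    d4B = mk("d4B", 942, "CD", 1714, "CB"))
}

#' P-loop residue ranges per repeat
#'
#' Residue intervals forming the P-loop domains used in filter-stability
#' RMSD calculations, per channel isoform.
#'
#' @return Nested named list: channel -> repeat -> c(from, to).
#' @export
p_loop_residues <- function() {
  list(
    Nav1.1 = list(DI = c(368, 395), DII = c(938, 962),
                  DIII = c(1417, 1443), DIV = c(1710, 1734)),
    Nav1.2 = list(DI = c(370, 397), DII = c(929, 955),
                  DIII = c(1408, 1434), DIV = c(1700, 1724)),
    Nav1.6 = list(DI = c(354, 383), DII = c(922, 947),
                  DIII = c(1399, 1424), DIV = c(1690, 1714)))
}

# Kabsch optimal rotation (SVD, with reflection correction)
.kabsch <- function(P, Q) {
  # P, Q: n x 3, centered; returns rotation R with P %*% R ~ Q
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

#' Optimal superposition RMSD
#'
#' Least-squares rigid-body superposition (Kabsch rotation + translation)
#' of matched atoms, and the RMSD over the selection. Atoms are matched by
#' (chain, resno, insert, elety); a count mismatch lists the unmatched
#' addresses.
#'
#' @param mobile,reference `structure_model`s.
#' @param selection optional data.frame with columns resno and elety
#'   (chain optional) restricting the match, or a list
#'   `list(resno_range = c(from, to))`.
#' @return list(rmsd, rmsd_unaligned, rotation, translation, n_atoms).
#' @export
superpose_rmsd <- function(mobile, reference, selection = NULL) {
  sel_filter <- function(a) {
    if (is.null(selection)) return(a)
    if (is.data.frame(selection)) {
      key <- paste(a$resno, a$elety)
      want <- paste(selection$resno, selection$elety)
      a[key %in% want, , drop = FALSE]
    } else if (!is.null(selection$resno_range)) {
      rr <- selection$resno_range
      keep <- a$resno >= rr[1] & a$resno <= rr[2]
      if (!is.null(selection$elety)) keep <- keep & a$elety %in% selection$elety
      a[keep, , drop = FALSE]
    } else .stopf("unsupported selection")
  }
  am <- sel_filter(mobile$atoms)
  ar <- sel_filter(reference$atoms)
  keym <- paste(am$chain, am$resno, am$insert, am$elety)
  keyr <- paste(ar$chain, ar$resno, ar$insert, ar$elety)
  common <- intersect(keym, keyr)
  unmatched <- c(setdiff(keym, keyr), setdiff(keyr, keym))
  if (length(unmatched))
    .stopf("atom-count mismatch; unmatched addresses: %s",
           paste(head(unmatched, 10), collapse = "; "))
  # consistent ordering by (resno, insert, elety)
  am <- am[match(common, keym), , drop = FALSE]
  ar <- ar[match(common, keyr), , drop = FALSE]
  ord <- order(am$chain, am$resno, am$insert, am$elety)
  am <- am[ord, , drop = FALSE]; ar <- ar[ord, , drop = FALSE]
  P <- as.matrix(am[, c("x", "y", "z")])
  Q <- as.matrix(ar[, c("x", "y", "z")])
  rmsd0 <- sqrt(mean(rowSums((P - Q)^2)))
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  R <- .kabsch(Pc, Qc)
  Pr <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rmsd = rmsd, rmsd_unaligned = rmsd0, rotation = R,
       translation = cq - as.numeric(cp %*% R), n_atoms = nrow(P))
}
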