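# Delimited-text IO: trajectories, free energy surfaces, oracle FE tables
# and potential configs. All formats are plain text with '#'-prefixed
# headers; FES round-trips are lossless (full double precision).

.fmt <- function(x) sprintf("%.17g", x)

#' Write a trajectory as delimited text
#'
#' One row per frame: time, coordinates, then (if present) auxiliary z and
#' instantaneous theta values; '#'-prefixed header records the layout.
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nz <- if (is.null(traj$z_frames)) 0L else ncol(traj$z_frames)
  writeLines(c(
    sprintf("# tamdotfp trajectory"),
    sprintf("# n_coords: %d", ncol(traj$x_frames)),
    sprintf("# n_cv: %d", nz),
    sprintf("# seed: %s", traj$metadata$seed %||% NA),
    sprintf("# kind: %s", traj$metadata$kind %||% "unknown")), con)
  M <- cbind(traj$times, traj$x_frames)
  if (nz > 0) M <- cbind(M, traj$z_frames, traj$theta_frames)
  apply(M, 1, function(r) writeLines(paste(.fmt(r), collapse = "\t"), con))
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path file path.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  nc <- as.integer(getv("n_coords"))
  nz <- as.integer(getv("n_cv"))
  M <- as.matrix(read.table(path, comment.char = "#"))
  times <- M[, 1]
  X <- M[, 1 + seq_len(nc), drop = FALSE]
  Z <- TH <- NULL
  if (nz > 0) {
    Z <- M[, 1 + nc + seq_len(nz), drop = FALSE]
    TH <- M[, 1 + nc + nz + seq_len(nz), drop = FALSE]
  }
  new_trajectory(times, X, Z, TH,
                 metadata = list(kind = getv("kind"), seed = getv("seed"),
                                 source = path))
}

#' Write a free energy surface as delimited text
#'
#' Node coordinates, value and defined flag per row; header records grid
#' geometry, sample count and replica provenance. Values keep full double
#' precision, so [read_fes()] round-trips losslessly.
#'
#' @param fes a `free_energy_surface`.
#' @param path output file.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- fes$provenance$replicas
  prov_str <- if (is.null(prov)) "none" else
    paste(vapply(prov, function(r)
      sprintf("%s:%s", r$id %||% "?", r$n_samples %||% NA), ""),
      collapse = ",")
  writeLines(c(
    "# tamdotfp free_energy_surface",
    sprintf("# dim: %d", fes$dim),
    sprintf("# mins: %s", paste(.fmt(fes$mins), collapse = " ")),
    sprintf("# maxs: %s", paste(.fmt(fes$maxs), collapse = " ")),
    sprintf("# n: %s", paste(fes$n, collapse = " ")),
    sprintf("# n_samples: %s", fes$n_samples %||% NA),
    sprintf("# replicas: %s", prov_str)), con)
  if (fes$dim == 1L) {
    coords <- matrix(fes_axis(fes, 1), ncol = 1)
  } else {
    coords <- as.matrix(expand.grid(fes_axis(fes, 1), fes_axis(fes, 2)))
  }
  vals <- as.numeric(fes$values)
  def <- as.integer(fes$defined)
  vals_s <- ifelse(is.na(vals), "NA", .fmt(vals))
  rows <- apply(cbind(apply(coords, 2, .fmt), vals_s, def), 1,
                paste, collapse = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read a free energy surface written by [write_fes()]
#'
#' @param path file path.
#' @return A `free_energy_surface`.
#' @export
read_fes <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  dim <- as.integer(getv("dim"))
  mins <- as.numeric(strsplit(getv("mins"), " +")[[1]])
  maxs <- as.numeric(strsplit(getv("maxs"), " +")[[1]])
  n <- as.integer(strsplit(getv("n"), " +")[[1]])
  ns <- suppressWarnings(as.integer(getv("n_samples")))
  M <- read.table(path, comment.char = "#", na.strings = "NA")
  vals <- as.numeric(M[[dim + 1]])
  def <- as.logical(as.integer(M[[dim + 2]]))
  grid <- chapeau_grid(mins, maxs, spacing = (maxs - mins) / (n - 1L))
  grid$n_samples <- if (is.na(ns)) 0L else ns
  reps <- getv("replicas")
  prov <- if (identical(reps, "none")) NULL else {
    parts <- strsplit(strsplit(reps, ",")[[1]], ":")
    list(replicas = lapply(parts, function(p)
      list(id = p[1], n_samples = suppressWarnings(as.integer(p[2])))))
  }
  fes <- new_fes(grid, vals, def, prov)
  fes$n_samples <- grid$n_samples
  fes
}

#' Write an oracle FE table
#'
#' 2-column (1D) or 3-column (2D) delimited text with a comment header
#' recording beta and method.
#'
#' @param oracle a `marginal_fe_oracle`.
#' @param path output file.
#' @export
write_fe_table <- function(oracle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# beta: %s", .fmt(oracle$beta)),
               sprintf("# method: %s", oracle$method)), con)
  if (is.matrix(oracle$fe_values)) {
    g1 <- oracle$cv_grid[[1]]; g2 <- oracle$cv_grid[[2]]
    pts <- as.matrix(expand.grid(g1, g2))
    rows <- paste(.fmt(pts[, 1]), .fmt(pts[, 2]),
                  .fmt(as.numeric(oracle$fe_values)), sep = "\t")
  } else {
    rows <- paste(.fmt(oracle$cv_grid), .fmt(oracle$fe_values), sep = "\t")
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read an oracle FE table written by [write_fe_table()]
#'
#' @param path file path.
#' @return A `marginal_fe_oracle` (grid and values; method from header).
#' @export
read_fe_table <- function(path) {
  hdr <- readLines(path, n = 5)
  hdr <- hdr[startsWith(hdr, "#")]
  beta <- as.numeric(trimws(sub("^# beta:", "",
                                grep("^# beta:", hdr, value = TRUE)[1])))
  method <- trimws(sub("^# method:", "",
                       grep("^# method:", hdr, value = TRUE)[1]))
  M <- read.table(path, comment.char = "#")
  if (ncol(M) == 2) {
    out <- list(cv_grid = M[[1]], fe_values = M[[2]], beta = beta,
                method = method, max_refine_diff = NA_real_)
  } else {
    g1 <- sort(unique(M[[1]])); g2 <- sort(unique(M[[2]]))
    vals <- matrix(NA_real_, length(g1), length(g2))
    vals[cbind(match(M[[1]], g1), match(M[[2]], g2))] <- M[[3]]
    out <- list(cv_grid = list(g1, g2), fe_values = vals, beta = beta,
                method = method, max_refine_diff = NA_real_)
  }
  structure(out, class = "marginal_fe_oracle")
}

#' Write a potential declaration as a key-value config
#'
#' Schema: one `key = value` pair per line; `label` selects the generator
#' and the remaining keys are its arguments. The benchmark surface's
#' standard constants are echoed as comments for reproducibility.
#'
#' @param potential a `model_potential` created by one of the `make_*`
#'   generators.
#' @param path output file.
#' @export
write_potential_config <- function(potential, path) {
  lines <- c(sprintf("label = %s", potential$label))
  emit <- function(key, val)
    sprintf("%s = %s", key, paste(.fmt(val), collapse = " "))
  if (potential$label == "double_well") {
    lines <- c(lines,
               emit("height", potential$height),
               emit("half_separation", potential$half_separation),
               emit("transverse_stiffness", potential$transverse_stiffness))
  } else if (potential$label == "toy_filter") {
    lines <- c(lines,
               emit("n_ions", potential$n_ions),
               emit("well_centers", potential$well_centers),
               emit("well_depths", potential$well_depths),
               emit("radius", potential$radius),
               emit("gate_coupling", potential$gate_coupling))
  } else if (potential$label == "benchmark_surface") {
    cst <- potential$constants
    lines <- c(lines, vapply(names(cst), function(nm)
      sprintf("# %s = %s", nm, paste(cst[[nm]], collapse = " ")), ""))
  } else if (potential$label == "harmonic") {
    lines <- c(lines, emit("k", potential$k),
               emit("n_coords", potential$n_coords))
  } else .stopf("no config schema for label '%s'", potential$label)
  writeLines(lines, path)
  invisible(path)
}

#' Read a potential config written by [write_potential_config()]
#'
#' @param path file path.
#' @return A `model_potential`.
#' @export
read_potential_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(trimws(ln), "#") & nzchar(trimws(ln))]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) return(default)
    as.numeric(strsplit(vals[i], " +")[[1]])
  }
  label <- vals[match("label", keys)]
  switch(label,
    double_well = make_double_well(get("height", 6),
                                   get("half_separation", 2),
                                   get("transverse_stiffness", 1)),
    toy_filter = make_toy_filter(n_ions = get("n_ions", 1),
                                 well_centers = get("well_centers", c(5, 12)),
                                 well_depths = get("well_depths", 4),
                                 radius = get("radius", 7),
                                 gate_coupling = get("gate_coupling", 4)),
    benchmark_surface = make_benchmark_surface(),
    harmonic = make_harmonic(get("k", 2), get("n_coords", 1)),
    .stopf("unknown potential label '%s'", label))
}
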