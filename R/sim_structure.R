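#' Specification for a synthetic atom-cloud structure
#'
#' Describes geometric stand-ins for protein structures with known void
#' topology: \code{sealed_cage} (atoms quasi-uniform on a sphere enclosing a
#' void), \code{aperture_cage} (the same shell with atoms removed inside a
#' polar cone, opening one mouth), \code{surface_dent} (a dense blob with a
#' spherical bite taken out of its surface) and \code{convex_blob} (a dense
#' cluster with no void).
#'
#' @param kind one of \code{"sealed_cage"}, \code{"aperture_cage"},
#'   \code{"surface_dent"}, \code{"convex_blob"}.
#' @param cage_radius sphere (or blob) radius, Angstrom.
#' @param n_shell_atoms atom count on the shell (>= 12) or in the blob.
#' @param aperture_solid_angle aperture size in steradians
#'   (\code{aperture_cage} only).
#' @param atom_radius atom van der Waals radius, Angstrom.
#' @param probe_radius probe radius used by the ground-truth oracle,
#'   Angstrom (water probe 1.4 by default).
#' @param jitter_sd isotropic positional jitter (Angstrom) applied to lattice
#'   points so the point set is in general position for triangulation.
#' @param column_offset alignment column assigned to residue i is
#'   \code{column_offset + i} (used to wire structures to an alignment).
#' @param seed integer seed.
#' @return object of class \code{structure_spec}.
#' @export
structure_spec <- function(kind = c("sealed_cage", "aperture_cage",
                                    "surface_dent", "convex_blob"),
                           cage_radius = 8,
                           n_shell_atoms = 200L,
                           aperture_solid_angle = NULL,
                           atom_radius = 1.8,
                           probe_radius = 1.4,
                           jitter_sd = 1e-3,
                           column_offset = 0L,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (cage_radius <= atom_radius)
    stop("invalid spec: cage_radius must exceed atom_radius")
  if (n_shell_atoms < 12L)
    stop("invalid spec: n_shell_atoms must be >= 12")
  if (!is.null(aperture_solid_angle) && kind != "aperture_cage")
    stop("invalid spec: aperture_solid_angle applies only to aperture_cage")
  if (kind == "aperture_cage" && is.null(aperture_solid_angle))
    aperture_solid_angle <- 0.8
  structure(list(kind = kind, cage_radius = cage_radius,
                 n_shell_atoms = as.integer(n_shell_atoms),
                 aperture_solid_angle = aperture_solid_angle,
                 atom_radius = atom_radius, probe_radius = probe_radius,
                 jitter_sd = jitter_sd,
                 column_offset = as.integer(column_offset),
                 seed = as.integer(seed)),
            class = "structure_spec")
}

#' Atom-cloud structure container
#'
#' @param xyz numeric matrix n x 3 of atom centers (Angstrom).
#' @param radius per-atom radii (recycled).
#' @param residue_index 1-based residue index per atom.
#' @param element element symbols.
#' @param chain chain identifiers.
#' @param residue_columns optional named integer vector mapping residue
#'   index (as name) to a 1-based alignment codon column.
#' @return object of class \code{atom_structure} with an \code{atoms}
#'   data.frame and the residue-to-column map.
#' @export
atom_structure <- function(xyz, radius = 1.8,
                           residue_index = seq_len(nrow(xyz)),
                           element = "C", chain = "A",
                           residue_columns = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 4L)
  atoms <- data.frame(id = seq_len(nrow(xyz)), element = element,
                      radius = radius, x = xyz[, 1L], y = xyz[, 2L],
                      z = xyz[, 3L],
                      residue_index = as.integer(residue_index),
                      chain = chain)
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  structure(list(atoms = atoms, residue_columns = residue_columns),
            class = "atom_structure")
}

#' @export
print.atom_structure <- function(x, ...) {
  cat("Atom structure: ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$residue_index)), " residues\n", sep = "")
  invisible(x)
}

#' Generate a synthetic structure with ground-truth void geometry
#'
#' Shell atoms are placed on a Fibonacci lattice (deterministic coverage,
#' reproducible mouth topology) with a small seeded jitter; blob atoms fill
#' a cubic lattice inside a ball. The reference void volume is computed by
#' the independent flood-fill Monte-Carlo oracle
#' (\code{\link{mc_void_volume}}), which knows nothing of the
#' alpha-complex detector.
#'
#' @param spec a \code{structure_spec}.
#' @param oracle_samples Monte-Carlo sample count for the reference volume.
#' @return list with \code{structure} (an \code{atom_structure}) and
#'   \code{ground_truth} (\code{reference_void_volume} in cubic Angstrom,
#'   \code{reference_mouth_count}, and the spec).
#' @export
generate_structure <- function(spec, oracle_samples = 1e6) {
  stopifnot(inherits(spec, "structure_spec"))
  R <- spec$cage_radius
  xyz <- .with_seed(spec$seed + 7L, {
    pts <- switch(spec$kind,
      sealed_cage = .fibonacci_sphere(spec$n_shell_atoms, R),
      aperture_cage = {
        p <- .fibonacci_sphere(spec$n_shell_atoms, R)
        cos_theta <- 1 - spec$aperture_solid_angle / (2 * pi)
        p[p[, 3L] / R < cos_theta, , drop = FALSE]
      },
      surface_dent = {
        p <- .lattice_ball(R, spacing = 2.0)
        dent_c <- c(0, 0, R)
        keep <- sqrt(rowSums(sweep(p, 2L, dent_c)^2)) > 0.55 * R
        p[keep, , drop = FALSE]
      },
      convex_blob = .lattice_ball(R, spacing = 2.0))
    pts + matrix(stats::rnorm(length(pts), 0, spec$jitter_sd), ncol = 3L)
  })
  cols <- stats::setNames(spec$column_offset + seq_len(nrow(xyz)),
                          seq_len(nrow(xyz)))
  st <- atom_structure(xyz, radius = spec$atom_radius,
                       residue_columns = cols)
  vol <- mc_void_volume(xyz, rep(spec$atom_radius, nrow(xyz)),
                        probe_radius = spec$probe_radius,
                        n_samples = oracle_samples, seed = spec$seed + 13L)
  mouth <- switch(spec$kind, sealed_cage = 0L, aperture_cage = 1L,
                  surface_dent = 1L, convex_blob = 0L)
  list(structure = st,
       ground_truth = list(reference_void_volume = vol$volume,
                           reference_volume_se = vol$se,
                           reference_mouth_count = mouth,
                           spec = spec))
}

# deterministic quasi-uniform points on a sphere
.fibonacci_sphere <- function(n, R) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  R * cbind(r * cos(phi), r * sin(phi), z)
}

# cubic lattice points inside a ball of the given radius
.lattice_ball <- function(R, spacing = 2.0) {
  g <- seq(-R, R, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts[sqrt(rowSums(pts^2)) <= R, , drop = FALSE]
}

#' Monte-Carlo oracle for probe-excluded void volume
#'
#' Independent reference measurement used to validate the alpha-complex
#' cavity detector. Atom spheres are inflated by the probe radius; space is
#' voxelised, voxels whose centers clear all inflated spheres are
#' flood-filled from the bounding-box boundary (6-connectivity), and the
#' unreached ("insulated") region is measured by uniform Monte-Carlo
#' sampling with an exact point-in-sphere test.
#'
#' @param xyz n x 3 atom centers.
#' @param radii per-atom radii.
#' @param probe_radius probe radius added to every atom.
#' @param n_samples Monte-Carlo samples (>= 1e5 recommended for reported
#'   volumes).
#' @param voxel voxel edge length for the reachability grid, Angstrom.
#' @param seed integer seed.
#' @return list with \code{volume} (cubic Angstrom), \code{se} (Monte-Carlo
#'   standard error) and \code{n_region_voxels}.
#' @export
mc_void_volume <- function(xyz, radii, probe_radius = 1.4,
                           n_samples = 1e6, voxel = 0.4, seed = 99L) {
  xyz <- as.matrix(xyz)
  rad <- radii + probe_radius
  lo <- apply(xyz, 2L, min) - max(rad) - voxel
  hi <- apply(xyz, 2L, max) + max(rad) + voxel
  dims <- pmax(2L, ceiling((hi - lo) / voxel))
  centers <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 0.5) * voxel)

  blocked <- array(FALSE, dims)
  for (a in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(k) {
      which(abs(centers[[k]] - xyz[a, k]) <= rad[a] + voxel)
    })
    if (any(lengths(rng) == 0L)) next
    sub <- as.matrix(expand.grid(rng[[1L]], rng[[2L]], rng[[3L]]))
    pc <- cbind(centers[[1L]][sub[, 1L]], centers[[2L]][sub[, 2L]],
                centers[[3L]][sub[, 3L]])
    inside <- rowSums(sweep(pc, 2L, xyz[a, ])^2) <= rad[a]^2
    blocked[sub[inside, , drop = FALSE]] <- TRUE
  }

  outside <- .flood_from_boundary(blocked, dims)
  # insulated void voxels, dilated one voxel into the blocking shell so the
  # sampler sees the sphere-bounded rim of the void (but never the shell's
  # outer surface)
  void <- !outside & !blocked
  region <- .dilate26(void, dims) & !outside
  n_region <- sum(region)
  if (n_region == 0L) return(list(volume = 0, se = 0, n_region_voxels = 0L))

  idx <- which(region, arr.ind = TRUE)
  hits <- .with_seed(seed, {
    pick <- sample.int(nrow(idx), n_samples, replace = TRUE)
    pts <- cbind(centers[[1L]][idx[pick, 1L]],
                 centers[[2L]][idx[pick, 2L]],
                 centers[[3L]][idx[pick, 3L]]) +
      matrix(stats::runif(3 * n_samples, -voxel / 2, voxel / 2), ncol = 3L)
    free <- rep(TRUE, n_samples)
    for (a in seq_len(nrow(xyz))) {
      sel <- which(free)
      if (length(sel) == 0L) break
      d2 <- rowSums(sweep(pts[sel, , drop = FALSE], 2L, xyz[a, ])^2)
      free[sel[d2 <= rad[a]^2]] <- FALSE
    }
    sum(free)
  })
  p <- hits / n_samples
  V_region <- n_region * voxel^3
  list(volume = V_region * p,
       se = V_region * sqrt(p * (1 - p) / n_samples),
       n_region_voxels = n_region)
}

# one-voxel 26-connected dilation of a logical mask
.dilate26 <- function(mask, dims) {
  out <- mask
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    xs <- max(1L, 1L + dx):min(nx, nx + dx)
    ys <- max(1L, 1L + dy):min(ny, ny + dy)
    zs <- max(1L, 1L + dz):min(nz, nz + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] |
      mask[xs - dx, ys - dy, zs - dz]
  }
  out
}

# 6-connected flood fill of unblocked voxels from the array boundary
.flood_from_boundary <- function(blocked, dims) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  blocked_v <- as.vector(blocked)
  outside_v <- logical(length(blocked_v))
  ii <- rep.int(seq_len(nx), ny * nz)
  jj <- rep.int(rep(seq_len(ny), each = nx), nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  edge <- ii == 1L | ii == nx | jj == 1L | jj == ny | kk == 1L | kk == nz
  frontier <- which(edge & !blocked_v)
  outside_v[frontier] <- TRUE
  offs <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    fi <- ii[frontier]; fj <- jj[frontier]; fk <- kk[frontier]
    for (o in offs) {
      ci <- fi + o[1L]; cj <- fj + o[2L]; ck <- fk + o[3L]
      ok <- ci >= 1L & ci <= nx & cj >= 1L & cj <= ny & ck >= 1L & ck <= nz
      cand <- ci[ok] + nx * (cj[ok] - 1L) + nx * ny * (ck[ok] - 1L)
      cand <- cand[!blocked_v[cand] & !outside_v[cand]]
      outside_v[cand] <- TRUE
      nxt <- c(nxt, cand)
    }
    frontier <- unique(nxt)
  }
  array(outside_v, dims)
}
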