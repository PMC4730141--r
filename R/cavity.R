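#' Geometry parameters for cavity detection
#'
#' @param probe_radius probe sphere radius, Angstrom (1.4 = water).
#' @param uniform_atom_radius single radius applied to all atoms, or NULL
#'   to use per-atom radii carried by the structure (with the per-element
#'   table C 1.7, N 1.55, O 1.52, S 1.8, Se 1.9 applied by the PDB reader).
#' @param volume_mc_samples Monte-Carlo samples for volume/area measurement
#'   (>= 1e4 enforced at measurement time, >= 1e5 recommended for reported
#'   volumes).
#' @param seed integer seed for the measurement sampler.
#' @param min_volume smallest cavity volume reported (cubic Angstrom); the
#'   default is the probe-sphere volume, since a void that cannot host the
#'   probe is not a solvent-accessible cavity. Interstitial slivers between
#'   atoms fall below this floor and are discarded.
#' @return object of class \code{geometry_params}.
#' @export
geometry_params <- function(probe_radius = 1.4, uniform_atom_radius = NULL,
                            volume_mc_samples = 1e5, seed = 1L,
                            min_volume = NULL) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (is.null(min_volume))
    min_volume <- 4 / 3 * pi * max(probe_radius, 1e-3)^3
  structure(list(probe_radius = probe_radius,
                 uniform_atom_radius = uniform_atom_radius,
                 volume_mc_samples = volume_mc_samples,
                 seed = as.integer(seed), min_volume = min_volume),
            class = "geometry_params")
}

.structure_geometry <- function(structure, params) {
  stopifnot(inherits(structure, "atom_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  radii <- if (!is.null(params$uniform_atom_radius))
    rep(params$uniform_atom_radius, nrow(xyz)) else structure$atoms$radius
  list(xyz = xyz, radii = radii)
}

#' Build the probe-dependent alpha complex of a structure
#'
#' Delaunay tetrahedralisation of the atom centers; a tetrahedron belongs
#' to the alpha complex iff its circumsphere radius is at most the mean of
#' its four atom radii plus the probe radius. Complement ("empty")
#' tetrahedra host potential cavities. A facet is "open" when its
#' circumradius exceeds the mean of its three atom radii plus the probe
#' radius, i.e. a probe disc fits through it. Empty tetrahedra meeting the
#' convex hull through an open facet are labelled exterior.
#'
#' @param structure an \code{atom_structure}.
#' @param params a \code{geometry_params}.
#' @param jitter opt-in seeded jitter magnitude (Angstrom) applied before
#'   triangulation for degenerate inputs; 0 disables.
#' @return object of class \code{alpha_complex}.
#' @export
build_alpha_complex <- function(structure, params = geometry_params(),
                                jitter = 0) {
  g <- .structure_geometry(structure, params)
  xyz <- g$xyz
  if (jitter > 0)
    xyz <- xyz + .with_seed(params$seed,
      matrix(stats::rnorm(length(xyz), 0, jitter), ncol = 3L))
  dt <- delaunay3d(xyz)
  m <- nrow(dt$tets)
  tet_thr <- rowMeans(matrix(g$radii[dt$tets], m, 4L)) + params$probe_radius
  in_alpha <- sqrt(dt$r2) <= tet_thr
  # facet table: each facet knows its 1 or 2 incident tetrahedra
  fac <- rbind(dt$tets[, c(1, 2, 3), drop = FALSE],
               dt$tets[, c(1, 2, 4), drop = FALSE],
               dt$tets[, c(1, 3, 4), drop = FALSE],
               dt$tets[, c(2, 3, 4), drop = FALSE])
  fac <- t(apply(fac, 1L, sort.int))
  tet_of <- rep(seq_len(m), 4L)
  key <- fac[, 1L] * 1e10 + fac[, 2L] * 1e5 + fac[, 3L]
  ord <- order(key)
  fac <- fac[ord, , drop = FALSE]; tet_of <- tet_of[ord]; key <- key[ord]
  first <- !duplicated(key)
  fid <- cumsum(first)
  nf <- fid[length(fid)]
  facets <- fac[first, , drop = FALSE]
  tet1 <- tet2 <- rep(NA_integer_, nf)
  tet1[fid[first]] <- tet_of[first]
  tet2[fid[!first]] <- tet_of[!first]
  fr <- .facet_circumradius(xyz, facets)
  f_thr <- rowMeans(matrix(g$radii[facets], nf, 3L)) + params$probe_radius
  open <- fr > f_thr
  hull <- is.na(tet2)
  # exterior: empty tetra whose hull facet is wide enough to admit a probe
  exterior <- rep(FALSE, m)
  ext_candidates <- tet1[hull & open]
  exterior[ext_candidates[!in_alpha[ext_candidates]]] <- TRUE
  # free-space crossing: does sphere-free area exist on the facet? governs
  # void connectivity (contiguous empty space), while `open` (probe disc
  # fits) governs exterior access and mouth identification
  free_cross <- rep(FALSE, nf)
  inter <- which(!hull & !in_alpha[tet1] &
                   !in_alpha[ifelse(is.na(tet2), tet1, tet2)])
  if (length(inter) > 0L) {
    grid <- .triangle_grid(8L)
    inflated <- g$radii + params$probe_radius
    for (f in inter) {
      v <- xyz[facets[f, ], , drop = FALSE]
      pts <- grid %*% v
      if (any(.outside_spheres(pts, xyz, inflated)))
        free_cross[f] <- TRUE
    }
  }
  free_cross[open] <- TRUE
  structure(list(xyz = xyz, radii = g$radii, tets = dt$tets,
                 centers = dt$centers, r2 = dt$r2, in_alpha = in_alpha,
                 facets = facets, facet_tet1 = tet1, facet_tet2 = tet2,
                 facet_open = open, facet_free = free_cross,
                 facet_hull = hull,
                 exterior = exterior, params = params,
                 atoms = structure$atoms,
                 residue_columns = structure$residue_columns),
            class = "alpha_complex")
}

#' @export
print.alpha_complex <- function(x, ...) {
  cat("Alpha complex: ", nrow(x$tets), " tetrahedra (",
      sum(x$in_alpha), " in complex, ", sum(!x$in_alpha), " empty, ",
      sum(x$exterior), " exterior)\n", sep = "")
  invisible(x)
}

#' Find voids: connected components of empty, non-exterior tetrahedra
#'
#' Adjacency runs through shared facets that sphere-free space crosses, so
#' a contiguous void is reported as one cavity even where the probe disc
#' itself cannot pass between two of its tetrahedra.
#' Each component's mouth count is the number of edge-connected patches of
#' open facets it shares with exterior tetrahedra; a component with no such
#' facet is an insulated internal cavity.
#'
#' @param ac an \code{alpha_complex}.
#' @return list of unmeasured cavities: each a list with \code{id},
#'   \code{tetrahedra} (row indices into \code{ac$tets}),
#'   \code{mouth_count} and \code{mouth_facets}.
#' @export
find_voids <- function(ac) {
  stopifnot(inherits(ac, "alpha_complex"))
  m <- nrow(ac$tets)
  member <- which(!ac$in_alpha & !ac$exterior)
  if (length(member) == 0L) return(list())
  # adjacency among member tets wherever free space crosses the facet
  fi <- which(ac$facet_free & !ac$facet_hull)
  a <- ac$facet_tet1[fi]; b <- ac$facet_tet2[fi]
  keep <- a %in% member & b %in% member
  comp <- .components(member, cbind(a[keep], b[keep]))
  cavities <- vector("list", length(comp))
  for (i in seq_along(comp)) {
    tets_i <- comp[[i]]
    # facets between this component and exterior tets, open ones only
    mf <- which(ac$facet_open & !ac$facet_hull &
                  ((ac$facet_tet1 %in% tets_i & ac$exterior[ac$facet_tet2]) |
                   (ac$facet_tet2 %in% tets_i & ac$exterior[ac$facet_tet1])))
    mouth_count <- .facet_patches(ac$facets[mf, , drop = FALSE])
    cavities[[i]] <- list(id = i, tetrahedra = tets_i,
                          mouth_count = mouth_count, mouth_facets = mf)
  }
  cavities
}

# connected components of `nodes` given an edge list (matrix of node pairs)
.components <- function(nodes, edges) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges) > 0L) for (e in seq_len(nrow(edges))) {
    i <- find(idx[[as.character(edges[e, 1L])]])
    j <- find(idx[[as.character(edges[e, 2L])]])
    if (i != j) parent[i] <- j
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  split(nodes, roots)
}

# number of edge-connected patches among a set of triangles
.facet_patches <- function(facets) {
  nf <- nrow(facets)
  if (nf == 0L) return(0L)
  if (nf == 1L) return(1L)
  ekey <- function(u, v) paste(pmin(u, v), pmax(u, v))
  edges <- list()
  for (f in seq_len(nf)) {
    v <- facets[f, ]
    for (k in list(c(1,2), c(1,3), c(2,3))) {
      ky <- ekey(v[k[1]], v[k[2]])
      edges[[ky]] <- c(edges[[ky]], f)
    }
  }
  pairs <- do.call(rbind, lapply(edges, function(fs) {
    if (length(fs) < 2L) return(NULL)
    t(utils::combn(fs, 2L))
  }))
  comp <- .components(seq_len(nf),
                      if (is.null(pairs)) matrix(0L, 0L, 2L) else pairs)
  length(comp)
}

#' Measure a cavity's probe-excluded volume and boundary area
#'
#' Volume is estimated by stratified Monte-Carlo over the member
#' tetrahedra: uniform points per tetrahedron (count proportional to its
#' volume), counting the fraction clear of all probe-inflated atom
#' spheres. Area sums sphere-free area over the component's boundary
#' facets with the same sampler.
#'
#' @param cavity one element of the \code{\link{find_voids}} result.
#' @param ac the \code{alpha_complex} it came from.
#' @param params a \code{geometry_params}; \code{volume_mc_samples < 1e4}
#'   is refused.
#' @return the cavity augmented with \code{volume}, \code{volume_se},
#'   \code{area}, \code{area_se} and \code{lining_residues}.
#' @export
measure_cavity <- function(cavity, ac, params = ac$params) {
  if (params$volume_mc_samples < 1e4)
    stop("volume_mc_samples below 1e4: refusing to report noisy volumes")
  tets <- ac$tets[cavity$tetrahedra, , drop = FALSE]
  vols <- .tet_volume(ac$xyz, tets)
  inflated <- ac$radii + params$probe_radius
  total <- sum(vols)
  nsam <- pmax(10L, round(params$volume_mc_samples * vols / total))
  lining_margin <- 0.5
  near_atoms <- rep(FALSE, nrow(ac$xyz))
  res <- .with_seed(params$seed + cavity$id, {
    vhat <- vse <- 0
    for (t in seq_len(nrow(tets))) {
      pts <- .sample_tet(ac$xyz[tets[t, ], , drop = FALSE], nsam[t])
      free <- .outside_spheres(pts, ac$xyz, inflated)
      p <- mean(free)
      vhat <- vhat + vols[t] * p
      vse <- vse + vols[t]^2 * p * (1 - p) / nsam[t]
      if (any(free)) {
        fp <- pts[free, , drop = FALSE]
        for (a in which(!near_atoms)) {
          d2 <- (fp[, 1L] - ac$xyz[a, 1L])^2 + (fp[, 2L] - ac$xyz[a, 2L])^2 +
            (fp[, 3L] - ac$xyz[a, 3L])^2
          if (any(d2 <= (inflated[a] + lining_margin)^2))
            near_atoms[a] <- TRUE
        }
      }
    }
    # boundary facets: facets of member tets not shared between two members
    bf <- which((ac$facet_tet1 %in% cavity$tetrahedra) !=
                  (!is.na(ac$facet_tet2) &
                     ac$facet_tet2 %in% cavity$tetrahedra))
    ahat <- ase <- 0
    for (f in bf) {
      v <- ac$xyz[ac$facets[f, ], , drop = FALSE]
      A <- 0.5 * sqrt(sum(.cross(rbind(v[2, ] - v[1, ]),
                                 rbind(v[3, ] - v[1, ]))^2))
      nf <- 200L
      w <- matrix(stats::runif(2 * nf), ncol = 2L)
      flip <- rowSums(w) > 1
      w[flip, ] <- 1 - w[flip, , drop = FALSE]
      pts <- outer(rep(1, nf), v[1, ]) +
        w[, 1L] %o% (v[2, ] - v[1, ]) + w[, 2L] %o% (v[3, ] - v[1, ])
      free <- .outside_spheres(pts, ac$xyz, inflated)
      p <- mean(free)
      ahat <- ahat + A * p
      ase <- ase + A^2 * p * (1 - p) / nf
    }
    list(v = vhat, vs = sqrt(vse), a = ahat, as = sqrt(ase))
  })
  cavity$volume <- res$v
  cavity$volume_se <- res$vs
  cavity$area <- res$a
  cavity$area_se <- res$as
  # lining: member-tetra vertices plus atoms whose probe-inflated sphere
  # bounds the sampled void (within the sampling margin)
  cavity$lining_residues <-
    sort(unique(c(lining_residues(cavity, ac),
                  ac$atoms$residue_index[near_atoms])))
  cavity
}

# fixed barycentric grid over a triangle (deterministic, so the free-space
# crossing test is exactly isometry-invariant)
.triangle_grid <- function(levels) {
  w <- list()
  for (i in 0:levels) for (j in 0:(levels - i)) {
    k <- levels - i - j
    w[[length(w) + 1L]] <- c(i, j, k) / levels
  }
  do.call(rbind, w)
}

.sample_tet <- function(v, n) {
  # uniform in a tetrahedron via sorted-uniform barycentric weights
  u <- matrix(stats::runif(3 * n), ncol = 3L)
  u <- t(apply(u, 1L, sort.int))
  w <- cbind(u[, 1L], u[, 2L] - u[, 1L], u[, 3L] - u[, 2L], 1 - u[, 3L])
  w %*% v
}

.outside_spheres <- function(pts, xyz, radii) {
  free <- rep(TRUE, nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    sel <- which(free)
    if (length(sel) == 0L) break
    d2 <- (pts[sel, 1L] - xyz[a, 1L])^2 + (pts[sel, 2L] - xyz[a, 2L])^2 +
      (pts[sel, 3L] - xyz[a, 3L])^2
    free[sel[d2 <= radii[a]^2]] <- FALSE
  }
  free
}

#' Residues lining a cavity
#'
#' @param cavity a cavity from \code{\link{find_voids}}.
#' @param ac the \code{alpha_complex}.
#' @return sorted integer vector of residue indices owning any atom that is
#'   a vertex of a member tetrahedron.
#' @export
lining_residues <- function(cavity, ac) {
  verts <- unique(as.vector(ac$tets[cavity$tetrahedra, , drop = FALSE]))
  sort(unique(ac$atoms$residue_index[verts]))
}

#' Classify a cavity from its volume and mouth count
#'
#' Mouthless cavities are insulated internal voids regardless of size;
#' mouth-bearing cavities are dents below 500 cubic Angstrom, cracks from
#' 500 (inclusive) to 1000 (exclusive), crevices at 1000 and above.
#'
#' @param volume cavity volume, cubic Angstrom (>= 0).
#' @param mouth_count number of mouths (0 = insulated).
#' @return one of \code{"internal"}, \code{"dent"}, \code{"crack"},
#'   \code{"crevice"}.
#' @export
classify_cavity <- function(volume, mouth_count) {
  if (volume < 0) stop("negative cavity volume")
  if (mouth_count == 0L) return("internal")
  if (volume < 500) "dent" else if (volume < 1000) "crack" else "crevice"
}

#' Detect, measure and classify all cavities of a structure
#'
#' @param structure an \code{atom_structure}.
#' @param params a \code{geometry_params}.
#' @param jitter passed to \code{\link{build_alpha_complex}}.
#' @return object of class \code{cavity_set}: list with \code{cavities}
#'   (each measured, classified, with lining residues and lining alignment
#'   columns when the structure carries a residue-to-column map) and
#'   \code{table} (one row per cavity).
#' @export
detect_cavities <- function(structure, params = geometry_params(),
                            jitter = 0) {
  ac <- build_alpha_complex(structure, params, jitter = jitter)
  voids <- find_voids(ac)
  # sum of member-tetra volumes bounds the cavity volume from above: skip
  # measuring components that cannot reach the reporting floor
  voids <- Filter(function(cv)
    sum(.tet_volume(ac$xyz, ac$tets[cv$tetrahedra, , drop = FALSE])) >=
      params$min_volume, voids)
  cavities <- lapply(voids, function(cv) {
    cv <- measure_cavity(cv, ac, params)
    cv
  })
  cavities <- Filter(function(cv) cv$volume >= params$min_volume, cavities)
  for (i in seq_along(cavities)) {
    cv <- cavities[[i]]
    cv$id <- i
    cv$class_label <- classify_cavity(cv$volume, cv$mouth_count)
    if (!is.null(ac$residue_columns)) {
      cv$lining_columns <-
        sort(unique(as.integer(
          ac$residue_columns[as.character(cv$lining_residues)])))
    }
    cavities[[i]] <- cv
  }
  tab <- if (length(cavities) == 0L)
    data.frame(id = integer(), class = character(), volume = numeric(),
               volume_se = numeric(), area = numeric(),
               mouth_count = integer(), n_lining_residues = integer())
  else data.frame(
    id = vapply(cavities, `[[`, 0L, "id"),
    class = vapply(cavities, `[[`, "", "class_label"),
    volume = vapply(cavities, `[[`, 0, "volume"),
    volume_se = vapply(cavities, `[[`, 0, "volume_se"),
    area = vapply(cavities, `[[`, 0, "area"),
    mouth_count = vapply(cavities, `[[`, 0L, "mouth_count"),
    n_lining_residues = vapply(cavities,
                               function(c) length(c$lining_residues), 0L))
  structure(list(cavities = cavities, table = tab,
                 params = params, n_atoms = nrow(structure$atoms)),
            class = "cavity_set")
}

#' @export
print.cavity_set <- function(x, ...) {
  cat("Cavity set: ", length(x$cavities), " cavities in ", x$n_atoms,
      "-atom structure\n", sep = "")
  if (nrow(x$table) > 0L) print(x$table, row.names = FALSE)
  invisible(x)
}
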