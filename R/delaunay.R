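#' 3D Delaunay tetrahedralisation (Bowyer-Watson)
#'
#' Incremental insertion with vectorised circumsphere tests. Input points
#' must be in general position (no 5 points cospherical, no 4 coplanar
#' among neighbours); degenerate inputs raise an error suggesting a seeded
#' jitter of magnitude ~1e-6.
#'
#' @param xyz numeric matrix n x 3 (n >= 4).
#' @return list with \code{tets} (m x 4 matrix of 1-based vertex indices),
#'   \code{centers} (m x 3 circumcenters), \code{r2} (squared circumradii)
#'   and \code{n} (input point count).
#' @export
delaunay3d <- function(xyz) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 4L) stop("need at least 4 points")
  ctr <- colMeans(xyz)
  span <- max(apply(xyz, 2L, function(v) diff(range(v))), 1)
  s <- 50 * span
  super <- rbind(ctr + s * c( 1,  1,  1), ctr + s * c( 1, -1, -1),
                 ctr + s * c(-1,  1, -1), ctr + s * c(-1, -1,  1))
  P <- rbind(xyz, super)
  tets <- matrix(n + 1:4, nrow = 1L)
  cc <- .circumsphere(P, tets)
  centers <- cc$centers; r2 <- cc$r2

  for (p in seq_len(n)) {
    d2 <- (centers[, 1L] - P[p, 1L])^2 + (centers[, 2L] - P[p, 2L])^2 +
      (centers[, 3L] - P[p, 3L])^2
    bad <- which(d2 < r2 * (1 + 1e-12))
    if (length(bad) == 0L)
      stop("point ", p, " inside no circumsphere: degenerate or ",
           "inconsistent geometry; consider jittering coordinates")
    # boundary facets of the star-shaped cavity: appear exactly once
    ft <- tets[bad, , drop = FALSE]
    facets <- rbind(ft[, c(1, 2, 3), drop = FALSE],
                    ft[, c(1, 2, 4), drop = FALSE],
                    ft[, c(1, 3, 4), drop = FALSE],
                    ft[, c(2, 3, 4), drop = FALSE])
    facets <- t(apply(facets, 1L, sort.int))
    key <- facets[, 1L] * 1e10 + facets[, 2L] * 1e5 + facets[, 3L]
    once <- !(key %in% key[duplicated(key)])
    newf <- facets[once, , drop = FALSE]
    newt <- cbind(newf, p)
    keep <- setdiff(seq_len(nrow(tets)), bad)
    tets <- rbind(tets[keep, , drop = FALSE], newt)
    ncc <- .circumsphere(P, newt)
    centers <- rbind(centers[keep, , drop = FALSE], ncc$centers)
    r2 <- c(r2[keep], ncc$r2)
  }
  real <- rowSums(tets > n) == 0L
  list(tets = tets[real, , drop = FALSE],
       centers = centers[real, , drop = FALSE],
       r2 = r2[real], n = n)
}

# circumcenters and squared radii for a set of tetrahedra (vectorised)
.circumsphere <- function(P, tets) {
  m <- nrow(tets)
  centers <- matrix(NA_real_, m, 3L)
  r2 <- numeric(m)
  for (t in seq_len(m)) {
    v <- P[tets[t, ], , drop = FALSE]
    A <- 2 * sweep(v[2:4, , drop = FALSE], 2L, v[1L, ])
    b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1L, ]^2)
    c0 <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(c0)) {
      centers[t, ] <- v[1L, ]
      r2[t] <- Inf              # flat tetrahedron: treat as always-bad
    } else {
      centers[t, ] <- c0
      r2[t] <- sum((c0 - v[1L, ])^2)
    }
  }
  list(centers = centers, r2 = r2)
}

# circumradius of each triangle facet (rows of idx) in 3D
.facet_circumradius <- function(P, idx) {
  a <- P[idx[, 1L], , drop = FALSE]
  b <- P[idx[, 2L], , drop = FALSE]
  c <- P[idx[, 3L], , drop = FALSE]
  la <- sqrt(rowSums((b - c)^2))
  lb <- sqrt(rowSums((a - c)^2))
  lc <- sqrt(rowSums((a - b)^2))
  cr <- .cross(b - a, c - a)
  K <- 0.5 * sqrt(rowSums(cr^2))
  ifelse(K > 1e-12, la * lb * lc / (4 * K), Inf)
}

.cross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

.tet_volume <- function(P, tets) {
  a <- P[tets[, 1L], , drop = FALSE]
  b <- P[tets[, 2L], , drop = FALSE]
  c <- P[tets[, 3L], , drop = FALSE]
  d <- P[tets[, 4L], , drop = FALSE]
  abs(rowSums(.cross(b - a, c - a) * (d - a))) / 6
}
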