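#' General time-reversible nucleotide model with discrete-gamma rates and
#' invariant sites
#'
#' Exchangeabilities follow the usual order AC, AG, AT, CG, CT, GT; bases are
#' ordered A, C, G, T throughout the package. The rate matrix is scaled so
#' the expected substitution rate is 1 at relative rate 1 (branch lengths are
#' expected substitutions per site). Rate heterogeneity uses the discrete
#' gamma with equal-probability categories and category means ("mean"
#' method); an invariant-site class of weight \code{p_invariant} has rate 0,
#' and the gamma category rates are rescaled by 1/(1 - p_invariant) so the
#' overall expected rate stays 1.
#'
#' @param exchangeabilities 6 nonnegative relative rates (AC, AG, AT, CG,
#'   CT, GT).
#' @param base_frequencies 4 proportions (A, C, G, T) summing to 1.
#' @param gamma_shape positive gamma shape; \code{Inf} means rate homogeneity.
#' @param n_rate_categories discrete gamma category count.
#' @param p_invariant proportion of invariant sites in [0, 1).
#' @return object of class \code{subst_model} with the scaled rate matrix
#'   \code{Q}, its symmetric eigendecomposition, and the mixture
#'   \code{rates}/\code{weights} including the invariant class.
#' @export
subst_model <- function(exchangeabilities = rep(1, 6),
                        base_frequencies = rep(0.25, 4),
                        gamma_shape = Inf,
                        n_rate_categories = 4L,
                        p_invariant = 0) {
  r <- as.numeric(exchangeabilities)
  pi <- as.numeric(base_frequencies)
  if (length(r) != 6L || any(r < 0)) stop("need 6 nonnegative exchangeabilities")
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9)
    stop("base frequencies must be 4 positive proportions summing to 1")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  if (p_invariant < 0 || p_invariant >= 1) stop("p_invariant must be in [0, 1)")

  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  idx <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (k in 1:6) {
    i <- idx[k,1]; j <- idx[k,2]
    Q[i,j] <- r[k] * pi[j]
    Q[j,i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))             # expected rate before scaling
  if (mu <= 0) stop("degenerate rate matrix (all exchangeabilities zero?)")
  Q <- Q / mu

  # symmetric decomposition: B = D^{1/2} Q D^{-1/2} with D = diag(pi)
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1/sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)

  if (is.finite(gamma_shape)) {
    g <- discrete_gamma_rates(gamma_shape, n_rate_categories)
  } else {
    g <- 1
    n_rate_categories <- 1L
  }
  if (p_invariant > 0) {
    rates <- c(0, g / (1 - p_invariant))
    weights <- c(p_invariant, rep((1 - p_invariant) / length(g), length(g)))
  } else {
    rates <- g
    weights <- rep(1 / length(g), length(g))
  }

  structure(list(exchangeabilities = r, base_frequencies = pi,
                 gamma_shape = gamma_shape,
                 n_rate_categories = n_rate_categories,
                 p_invariant = p_invariant,
                 Q = Q, eig_values = eig$values,
                 eig_vectors = eig$vectors, sqrt_pi = sp,
                 rates = rates, weights = weights),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("GTR substitution model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      signif(x$exchangeabilities, 4), "\n")
  cat("  base frequencies (A C G T):", signif(x$base_frequencies, 4), "\n")
  cat("  gamma shape:", x$gamma_shape, " categories:",
      x$n_rate_categories, " p_invariant:", x$p_invariant, "\n")
  invisible(x)
}

#' Discrete-gamma category rates (equal-probability bins, category means)
#'
#' The gamma density with mean 1 (shape = rate = alpha) is cut into
#' \code{n} equal-probability bins; each category rate is the conditional
#' mean within its bin, so the category rates always average to exactly 1.
#'
#' @param shape gamma shape alpha > 0.
#' @param n number of categories.
#' @return numeric vector of \code{n} rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, n = 4L) {
  stopifnot(shape > 0, n >= 1L)
  if (n == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = n + 1L), shape = shape, rate = shape)
  # conditional means via the incomplete-gamma identity
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  r <- n * diff(p)
  r / mean(r) * 1  # guard against roundoff; mean is already 1 analytically
}

#' Transition probability matrix P(t) for one rate category
#' @param model a \code{subst_model}.
#' @param t branch length (expected substitutions/site at rate 1).
#' @param rate relative rate multiplier.
#' @return 4x4 row-stochastic matrix, rows/cols in A, C, G, T order.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  if (rate == 0 || t == 0) return(diag(4))
  E <- model$eig_vectors
  P <- diag(1/model$sqrt_pi) %*% E %*%
    diag(exp(model$eig_values * rate * t)) %*% t(E) %*% diag(model$sqrt_pi)
  P[P < 0] <- 0
  P / rowSums(P)
}
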