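# The L0 machinery.  The cardinality constraint ||beta||_0 <= K is exactly
# equivalent to ||beta||_1 - |||beta|||_[K] = 0, where |||.|||_[K] is the
# largest-K norm (sum of the K largest absolute values).  Adding
# rho * (||beta||_1 - |||beta|||_[K]) to a convex loss gives a DC
# (difference-of-convex) objective f = f1 - f2 with
#   f1 = loss + rho ||beta||_1     and     f2 = rho |||beta|||_[K].

#' L0 pseudonorm
#'
#' Number of components with absolute value above \code{zero_tol}.
#'
#' @param beta numeric vector.
#' @param zero_tol nonnegative threshold; default 0 (exact zeros).
#' @return Integer count.
#' @export
l0_pseudonorm <- function(beta, zero_tol = 0) {
  stopifnot(zero_tol >= 0)
  sum(abs(as.numeric(beta)) > zero_tol)
}

#' Largest-k norm
#'
#' Sum of the k largest absolute values; a proper convex norm for fixed k.
#' At \code{k = length(beta)} it equals the L1 norm.
#'
#' @param beta numeric vector of length p.
#' @param k integer in 1..p.
#' @return Nonnegative real.
#' @export
largest_k_norm <- function(beta, k) {
  beta <- as.numeric(beta)
  p <- length(beta)
  if (length(k) != 1 || k < 1 || k > p || k != round(k))
    stop("k must be an integer in 1..", p)
  a <- sort(abs(beta), decreasing = TRUE)
  sum(a[seq_len(k)])
}

#' DC penalty value
#'
#' The exact cardinality penalty \eqn{\rho(\|\beta\|_1 - |||\beta|||_{[K]})}
#' for per-feature selection, or its kit-grouped analogue when a
#' \code{grouping} is supplied (see \code{\link{kit_penalty_value}}).  The
#' value is always nonnegative and equals 0 exactly when at most K features
#' (kits) are active.
#'
#' @param beta numeric vector (named when \code{grouping} is used).
#' @param K cardinality bound.
#' @param rho positive penalty parameter.
#' @param grouping optional \code{\link{kit_structure}}.
#' @param feature_names names for \code{beta} in grouped mode.
#' @return Nonnegative penalty value.
#' @export
dc_penalty_value <- function(beta, K, rho, grouping = NULL,
                             feature_names = names(beta)) {
  stopifnot(rho > 0)
  if (!is.null(grouping))
    return(kit_penalty_value(beta, K, rho, grouping, feature_names))
  beta <- as.numeric(beta)
  max(rho * (sum(abs(beta)) - largest_k_norm(beta, K)), 0)
}

#' Subgradient of the concave part of the DC penalty
#'
#' Returns one subgradient of \eqn{f_2(\beta) = \rho |||\beta|||_{[K]}}:
#' \eqn{\rho\,\mathrm{sign}(\beta_j)} on a deterministically chosen set of K
#' top-absolute-value indices (ties broken toward the lowest index), 0
#' elsewhere and for zero coefficients inside the chosen set.
#'
#' @param beta numeric vector.
#' @param K cardinality bound.
#' @param rho positive penalty parameter.
#' @return Numeric vector of the same length as \code{beta}.
#' @export
f2_subgradient <- function(beta, K, rho) {
  beta <- as.numeric(beta)
  p <- length(beta)
  if (K < 1 || K > p) stop("K must be in 1..", p)
  # order by decreasing |beta|, ties by lowest index (order() is stable)
  top <- order(-abs(beta))[seq_len(K)]
  g <- numeric(p)
  g[top] <- rho * sign(beta[top])
  g
}

#' Kit-grouped cardinality penalty
#'
#' Aggregates coefficient magnitude within each kit,
#' \eqn{v_g = \sum_{j \in g} |\beta_j|}, and penalizes the mass outside the
#' \code{K_kits} largest kits: \eqn{\rho(\sum_g v_g - |||v|||_{[K_{kits}]})}.
#' Zero exactly when at most \code{K_kits} kits are active.
#'
#' @param beta named numeric vector (or supply \code{feature_names}).
#' @param K_kits bound on the number of active kits.
#' @param rho positive penalty parameter.
#' @param kits a \code{\link{kit_structure}}.
#' @param feature_names names for unnamed \code{beta}.
#' @return Nonnegative penalty value.
#' @export
kit_penalty_value <- function(beta, K_kits, rho, kits,
                              feature_names = names(beta)) {
  stopifnot(inherits(kits, "kit_structure"), rho > 0)
  if (is.null(feature_names))
    stop("beta must be named or feature_names supplied")
  idx <- kit_index(kits, feature_names)
  v <- kit_magnitudes(beta, idx)
  if (K_kits < 1 || K_kits > length(v))
    stop("K_kits must be in 1..", length(v))
  max(rho * (sum(v) - largest_k_norm(v, K_kits)), 0)
}

# v_g = within-kit L1 mass, indexed over the kits that occur among the
# features of beta (in kit_index id order, compressed to occurring ids)
kit_magnitudes <- function(beta, idx) {
  occurring <- sort(unique(idx$id))
  v <- vapply(occurring,
              function(g) sum(abs(as.numeric(beta))[idx$id == g]),
              numeric(1))
  names(v) <- idx$kits$kit_names[occurring]
  v
}

# Subgradient of the grouped f2 = rho * largest-K norm of kit magnitudes:
# rho * sign(beta_j) for features in the chosen top-K kits, 0 elsewhere.
kit_f2_subgradient <- function(beta, K_kits, rho, idx) {
  beta <- as.numeric(beta)
  occurring <- sort(unique(idx$id))
  v <- vapply(occurring,
              function(g) sum(abs(beta)[idx$id == g]), numeric(1))
  top_kits <- occurring[order(-v)[seq_len(K_kits)]]
  g <- numeric(length(beta))
  in_top <- idx$id %in% top_kits
  g[in_top] <- rho * sign(beta[in_top])
  g
}
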