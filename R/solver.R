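# Nonsmooth DC descent for the penalized objective
#   f(beta) = loss(beta) + rho * ( ||beta||_1 - |||beta|||_[K] )
#           = f1(beta) - f2(beta),
#   f1 = loss + rho ||.||_1 (convex, nonsmooth),  f2 = rho |||.|||_[K]
#   (convex).
#
# Outer loop (DCA): linearize f2 at the current iterate via a subgradient g
# and solve the convex surrogate  loss(b) + rho ||b||_1 - g'b  with an
# accelerated proximal-gradient method (soft-thresholding prox, backtracking
# line search, restart on objective increase).  Because the surrogate
# majorizes f at the expansion point, every accepted outer step decreases f;
# the inner prox produces exact zeros, so supports are read off directly.

#' Solver configuration
#'
#' @param max_outer_iters maximum DCA (outer) iterations per rho value.
#' @param inner_tol stopping tolerance of the convex inner solver
#'   (max-norm change between iterates).
#' @param outer_tol relative objective-decrease threshold ending the DCA
#'   loop.
#' @param rho_initial first value of the penalty parameter rho.
#' @param rho_multiplier geometric escalation factor (> 1) of the rho grid.
#' @param rho_max largest rho tried before declaring failure.
#' @param zero_tol magnitude below which a fitted coefficient counts as
#'   zero (standardized scale).
#' @param inner_max_iters iteration cap of the inner solver.
#' @param gamma fraction of starting points retained by the acceleration
#'   screen (1 = keep all; see \code{\link{accelerate_starts}}).
#' @param seed integer seed recorded with the fit for reproducibility.
#' @return A list of class \code{"solver_config"}.
#' @export
solver_config <- function(max_outer_iters = 50, inner_tol = 1e-7,
                          outer_tol = 1e-9, rho_initial = 1,
                          rho_multiplier = 5, rho_max = 1e6,
                          zero_tol = 1e-6, inner_max_iters = 500,
                          gamma = 1, seed = 1L) {
  stopifnot(inner_tol > 0, outer_tol > 0, rho_initial > 0,
            rho_multiplier > 1, rho_max >= rho_initial, zero_tol >= 0,
            gamma > 0, gamma <= 1)
  structure(list(max_outer_iters = as.integer(max_outer_iters),
                 inner_tol = inner_tol, outer_tol = outer_tol,
                 rho_initial = rho_initial,
                 rho_multiplier = rho_multiplier, rho_max = rho_max,
                 zero_tol = zero_tol,
                 inner_max_iters = as.integer(inner_max_iters),
                 gamma = gamma, seed = as.integer(seed)),
            class = "solver_config")
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Accelerated proximal gradient on  s(b) + rho * ||b[1:npen]||_1, where
# s(b) = value(b) - g'b.  Monotone by construction: returns the best of the
# iterate sequence and the start.
prox_solve <- function(value, grad, g, rho, b0, npen, config, L0 = 1) {
  Fobj <- function(b) value(b) - sum(g * b) + rho * sum(abs(b[seq_len(npen)]))
  b <- b0
  z_prev <- b0
  y <- b0
  tk <- 1
  L <- L0
  F_best <- Fobj(b0)
  b_best <- b0
  F_prev <- F_best
  for (it in seq_len(config$inner_max_iters)) {
    sy <- value(y) - sum(g * y)
    gy <- grad(y) - g
    repeat {
      z <- y - gy / L
      z[seq_len(npen)] <- soft_threshold(z[seq_len(npen)], rho / L)
      dz <- z - y
      sz <- value(z) - sum(g * z)
      if (sz <= sy + sum(gy * dz) + (L / 2) * sum(dz * dz) + 1e-12) break
      L <- L * 2
      if (L > 1e15) break
    }
    Fz <- sz + rho * sum(abs(z[seq_len(npen)]))
    if (Fz < F_best) { F_best <- Fz; b_best <- z }
    step <- max(abs(z - z_prev))
    if (Fz > F_prev) {            # restart momentum on objective increase
      y <- z
      tk <- 1
    } else {
      t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- z + ((tk - 1) / t_next) * (z - z_prev)
      tk <- t_next
    }
    F_prev <- Fz
    z_prev <- z
    if (step < config$inner_tol && it > 1) break
    if (it %% 5 == 0) L <- max(L / 2, 1e-8)
  }
  list(b = b_best, value = F_best, L = L)
}

# DCA loop on a prepared objective.  `kit_idx` switches the concave part to
# the kit-grouped largest-K norm.  Returns the final iterate (exact zeros
# from the prox) and the penalized objective trace.
dca_solve <- function(obj, K, rho, beta0, config, kit_idx = NULL) {
  npen <- obj$npen
  nb <- length(beta0)
  pen_val <- function(b) {
    bp <- b[seq_len(npen)]
    if (is.null(kit_idx)) {
      rho * (sum(abs(bp)) - largest_k_norm(bp, K))
    } else {
      v <- vapply(sort(unique(kit_idx$id)),
                  function(g) sum(abs(bp)[kit_idx$id == g]), numeric(1))
      rho * (sum(v) - largest_k_norm(v, K))
    }
  }
  f <- function(b) obj$value(b) + max(pen_val(b), 0)
  b <- beta0
  f_cur <- f(b)
  trace <- f_cur
  L0 <- 1
  for (outer in seq_len(config$max_outer_iters)) {
    bp <- b[seq_len(npen)]
    g <- dc_linearization(bp, K, rho, kit_idx,
                          obj$grad(b)[seq_len(npen)])
    if (nb > npen) g <- c(g, rep(0, nb - npen))
    inner <- prox_solve(obj$value, obj$grad, g, rho, b, npen, config, L0)
    L0 <- inner$L
    f_new <- f(inner$b)
    if (f_new > f_cur + 1e-8 * (1 + abs(f_cur)))
      stop("DC descent failed: objective rose from ", f_cur, " to ", f_new,
           " at outer iteration ", outer)
    moved <- max(abs(inner$b - b))
    if (f_new <= f_cur) {
      b <- inner$b
      trace <- c(trace, f_new)
    }
    done <- (f_cur - f_new) <= config$outer_tol * (1 + abs(f_cur)) ||
      moved < config$inner_tol
    f_cur <- min(f_cur, f_new)
    if (done) break
  }
  list(b = b, objective = f_cur, trace = trace)
}

# Subgradient of f2 used inside the DCA loop.  Same top-K selection as
# f2_subgradient / kit_f2_subgradient, but at a zero coordinate inside the
# chosen set the subgradient of |.| is picked as sign(-loss gradient):
# still a valid subgradient in [-1, 1], and it un-shrinks the most
# promising coordinate instead of leaving the origin a spurious fixed
# point (e.g. beta0 = 0 with K >= 1).
dc_linearization <- function(bp, K, rho, kit_idx, loss_grad) {
  g <- if (is.null(kit_idx)) f2_subgradient(bp, K, rho)
       else kit_f2_subgradient(bp, K, rho, kit_idx)
  if (is.null(kit_idx)) {
    chosen <- order(-abs(bp))[seq_len(K)]
  } else {
    occurring <- sort(unique(kit_idx$id))
    v <- vapply(occurring, function(gg) sum(abs(bp)[kit_idx$id == gg]),
                numeric(1))
    top_kits <- occurring[order(-v)[seq_len(K)]]
    chosen <- which(kit_idx$id %in% top_kits)
  }
  zero_in <- chosen[bp[chosen] == 0]
  g[zero_in] <- -rho * sign(loss_grad[zero_in])
  g
}

#' Minimize a DC-penalized convex loss
#'
#' Local descent on \code{loss(beta) + rho * (||beta||_1 -
#' |||beta|||_[K])} (or the kit-grouped analogue) from a given start.  The
#' returned point never has a larger penalized objective than the start.
#'
#' @param loss_and_grad list with functions \code{value(beta)} and
#'   \code{grad(beta)} of a smooth convex loss.
#' @param K cardinality bound (features, or kits when \code{grouping}
#'   given).
#' @param rho positive penalty parameter.
#' @param beta0 numeric starting point.
#' @param config a \code{\link{solver_config}}.
#' @param grouping optional \code{\link{kit_structure}}.
#' @param feature_names names of the coordinates of \code{beta0}
#'   (needed in grouped mode).
#' @return Numeric vector: the located stationary point.
#' @export
minimize_dc <- function(loss_and_grad, K, rho, beta0,
                        config = solver_config(), grouping = NULL,
                        feature_names = names(beta0)) {
  stopifnot(is.function(loss_and_grad$value), is.function(loss_and_grad$grad))
  beta0 <- as.numeric(beta0)
  obj <- list(value = loss_and_grad$value, grad = loss_and_grad$grad,
              npen = length(beta0))
  kit_idx <- NULL
  if (!is.null(grouping)) {
    if (is.null(feature_names))
      stop("grouped mode needs feature names for beta0")
    kit_idx <- kit_index(grouping, feature_names)
  }
  dca_solve(obj, K, rho, beta0, config, kit_idx)$b
}

# rho escalation on a prepared objective: solve at increasing rho, always
# from the ORIGINAL starting point, until the support satisfies the
# cardinality (or kit-count) bound.
escalate_rho <- function(obj, K, beta0, config, kit_idx = NULL) {
  rho <- config$rho_initial
  last <- NULL
  nnz_of <- function(b) {
    bp <- b[seq_len(obj$npen)]
    if (is.null(kit_idx)) l0_pseudonorm(bp, config$zero_tol)
    else {
      active <- abs(bp) > config$zero_tol
      length(unique(kit_idx$id[active]))
    }
  }
  while (rho <= config$rho_max) {
    sol <- dca_solve(obj, K, rho, beta0, config, kit_idx)
    nnz <- nnz_of(sol$b)
    last <- list(b = sol$b, nnz = nnz, rho = rho,
                 loss = obj$value(sol$b))
    if (nnz <= K) {
      last$converged <- TRUE
      return(last)
    }
    rho <- rho * config$rho_multiplier
  }
  last$converged <- FALSE
  last
}

fit_result <- function(coefficients, intercept, objective,
                       penalty_residual, nnz, converged, rho_used, family) {
  structure(list(coefficients = coefficients, intercept = intercept,
                 objective = objective, penalty_residual = penalty_residual,
                 nnz = as.integer(nnz), converged = converged,
                 rho_used = rho_used, family = family),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Cardinality-penalized fit (", x$family, "): ", x$nnz,
      " nonzero coefficient(s), loss ", signif(x$objective, 6),
      ", rho ", x$rho_used,
      if (!x$converged) " [NOT converged]", "\n", sep = "")
  invisible(x)
}

#' Solve the cardinality-penalized problem with rho escalation
#'
#' Runs the DC solver over the geometric grid \code{rho_initial *
#' rho_multiplier^t}, restarting each solve from the original
#' \code{beta0} (never from the previous rho's solution, so the information
#' in the start is not washed out by a too-small rho), until the fitted
#' support has at most K active features (kits) or the grid is exhausted.
#'
#' @param data a \code{survdata} or \code{labdata}.
#' @param family model family name.
#' @param K cardinality bound.
#' @param beta0 starting coefficient vector of length p on the data scale;
#'   default zeros.
#' @param config a \code{\link{solver_config}}.
#' @param grouping optional \code{\link{kit_structure}}.
#' @param standardize z-score the features internally (coefficients are
#'   reported on the original scale); default TRUE.
#' @return A \code{fit_result} with elements \code{coefficients} (named,
#'   original scale), \code{intercept}, \code{objective} (loss at the
#'   solution), \code{penalty_residual}, \code{nnz}, \code{converged},
#'   \code{rho_used}.
#' @export
solve_penalized <- function(data, family = c("cox", "logistic", "gaussian"),
                            K, beta0 = NULL, config = solver_config(),
                            grouping = NULL, standardize = TRUE) {
  family <- match.arg(family)
  obj <- make_objective(data, family, standardize)
  kit_idx <- if (is.null(grouping)) NULL
             else kit_index(grouping, obj$feature_names)
  if (!is.null(kit_idx) && (K < 1 || K > kit_idx$n_kits))
    stop("K must be in 1..", kit_idx$n_kits, " (number of kits)")
  if (is.null(kit_idx) && (K < 1 || K > obj$p))
    stop("K must be in 1..", obj$p)
  b0 <- numeric(obj$nb)
  if (!is.null(beta0)) {
    stopifnot(length(beta0) == obj$p)
    b0[seq_len(obj$p)] <- to_internal_scale(beta0, data, standardize)
  }
  res <- escalate_rho(obj, K, b0, config, kit_idx)
  finalize_fit(res, obj, K, config, kit_idx)
}

to_internal_scale <- function(beta, data, standardize) {
  if (!standardize) return(as.numeric(beta))
  sd_ <- apply(data$features, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  as.numeric(beta) * sd_
}

finalize_fit <- function(res, obj, K, config, kit_idx) {
  bp <- res$b[seq_len(obj$npen)]
  bp[abs(bp) <= config$zero_tol] <- 0
  res$b[seq_len(obj$npen)] <- bp
  pen <- if (is.null(kit_idx)) {
    sum(abs(bp)) - largest_k_norm(bp, K)
  } else {
    v <- vapply(sort(unique(kit_idx$id)),
                function(g) sum(abs(bp)[kit_idx$id == g]), numeric(1))
    sum(v) - largest_k_norm(v, K)
  }
  orig <- obj$to_original(res$b)
  fit_result(coefficients = orig$coefficients, intercept = orig$intercept,
             objective = obj$value(res$b), penalty_residual = max(pen, 0),
             nnz = res$nnz, converged = res$converged,
             rho_used = res$rho, family = obj$family)
}

# Smooth unregularized optimum (Step 0 of the path algorithm) by BFGS with
# the analytic gradient.
smooth_optimum <- function(obj, start = NULL, maxit = 500) {
  b0 <- if (is.null(start)) numeric(obj$nb) else start
  fit <- stats::optim(b0, fn = obj$value, gr = obj$grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  fit$par
}
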