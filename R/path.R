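# Incremental multi-start cardinality path.  Stage i solves the
# cardinality-constrained problem with at most i active features (kits),
# seeding the nonconvex solver with perturbations of the stage i-1 solution:
# each candidate replaces one coordinate (kit) of the previous solution with
# its value in the unregularized optimum, and candidates that do not enlarge
# the support are dropped.  The best candidate solution by unpenalized loss
# wins the stage.

#' Starting points for one path stage
#'
#' Candidate j equals \code{beta_prev} with coordinate j (all coordinates
#' of kit j in grouped mode) replaced by the corresponding entries of the
#' unregularized optimum \code{beta_mle}; candidates whose support does not
#' exceed \code{stage - 1} features (kits) are dropped.  Stage 1 uses
#' \code{beta_prev = 0}, so the candidates are the p single-coordinate
#' vectors.
#'
#' @param beta_prev solution of the previous stage (zeros at stage 1).
#' @param beta_mle the unregularized optimum.
#' @param stage stage number i >= 1.
#' @param grouping optional \code{\link{kit_structure}} for kit-wise
#'   substitution.
#' @param feature_names coordinate names (required in grouped mode).
#' @param zero_tol threshold for counting a coordinate as active.
#' @return List of class \code{"starting_points"} with \code{points} (list
#'   of vectors), \code{js} (substituted coordinate or kit index per
#'   candidate), \code{stage}, and \code{beta_prev}.
#' @export
generate_starting_points <- function(beta_prev, beta_mle, stage,
                                     grouping = NULL,
                                     feature_names = names(beta_prev),
                                     zero_tol = 0) {
  beta_prev <- as.numeric(beta_prev)
  beta_mle <- as.numeric(beta_mle)
  p <- length(beta_prev)
  stopifnot(length(beta_mle) == p, stage >= 1)
  points <- list()
  js <- integer(0)
  if (is.null(grouping)) {
    for (j in seq_len(p)) {
      cand <- beta_prev
      cand[j] <- beta_mle[j]
      if (l0_pseudonorm(cand, zero_tol) > stage - 1) {
        points[[length(points) + 1L]] <- cand
        js <- c(js, j)
      }
    }
  } else {
    if (is.null(feature_names))
      stop("grouped mode needs feature names")
    idx <- kit_index(grouping, feature_names)
    for (j in seq_len(idx$n_kits)) {
      members <- which(idx$id == j)
      if (length(members) == 0) next
      cand <- beta_prev
      cand[members] <- beta_mle[members]
      active <- abs(cand) > zero_tol
      if (length(unique(idx$id[active])) > stage - 1) {
        points[[length(points) + 1L]] <- cand
        js <- c(js, j)
      }
    }
  }
  structure(list(points = points, js = js, stage = stage,
                 beta_prev = beta_prev),
            class = "starting_points")
}

# Screen candidates by the one-dimensional subproblem: minimize the loss
# along the segment from beta_prev towards each candidate and keep the
# ceil(gamma * m) best scores (candidate order preserved).
screen_starts_internal <- function(value_fn, beta_prev_full, starts, gamma) {
  m <- length(starts$points)
  if (gamma >= 1 || m <= 1) return(starts)
  keep_n <- max(1L, as.integer(ceiling(gamma * m)))
  scores <- vapply(seq_len(m), function(k) {
    d <- c(starts$points[[k]] - starts$beta_prev,
           rep(0, length(beta_prev_full) - length(starts$beta_prev)))
    stats::optimize(function(t) value_fn(beta_prev_full + t * d),
                    interval = c(-20, 20))$objective
  }, numeric(1))
  keep <- sort(order(scores)[seq_len(keep_n)])
  starts$points <- starts$points[keep]
  starts$js <- starts$js[keep]
  starts
}

#' Screen starting points with the one-dimensional acceleration heuristic
#'
#' For each candidate, scores the coordinate (kit) it introduces by solving
#' the one-dimensional problem of optimizing the loss along the direction
#' from the previous solution to the candidate, and keeps the
#' \code{ceiling(gamma * m)} best-scoring of the m candidates.
#' \code{gamma = 1} is the identity.  Intended for high-dimensional
#' problems where solving the full penalized problem from every start is
#' too expensive.
#'
#' @param candidates a \code{starting_points} set.
#' @param data the dataset the loss is evaluated on.
#' @param family model family name.
#' @param gamma fraction of candidates retained, in (0, 1].
#' @return A filtered \code{starting_points} set.
#' @export
accelerate_starts <- function(candidates, data,
                              family = c("cox", "logistic", "gaussian"),
                              gamma = 1) {
  family <- match.arg(family)
  stopifnot(inherits(candidates, "starting_points"),
            gamma > 0, gamma <= 1)
  value_fn <- function(b) family_loss(b, data, family)
  screen_starts_internal(value_fn, candidates$beta_prev, candidates, gamma)
}

#' Fit the full cardinality path
#'
#' Runs the incremental multi-start algorithm: Stage 0 computes the
#' unregularized optimum; stage i (i = 1..K_max) builds starting points
#' from the stage i-1 solution, solves the rho-escalated DC-penalized
#' problem from each, and keeps the converged candidate with the smallest
#' unpenalized loss.  The previous stage's solution additionally enters the
#' stage-i comparison (it is feasible for K = i), which guarantees that the
#' loss sequence along the path is non-increasing.
#'
#' @param data a \code{survdata} (cox) or \code{labdata}
#'   (logistic/gaussian).
#' @param family model family name.
#' @param K_max largest cardinality solved for.
#' @param config a \code{\link{solver_config}}; its \code{gamma} < 1
#'   activates start screening (applied automatically for p >= 100).
#' @param grouping optional \code{\link{kit_structure}}: bound the number
#'   of kits instead of single features.
#' @param standardize z-score features internally; coefficients are
#'   reported on the original scale.  Default TRUE.
#' @param verbose print per-stage diagnostics.
#' @return An object of class \code{"card_path"}: list with \code{mle}
#'   (unregularized coefficients, original scale), \code{solutions} (one
#'   \code{fit_result} per cardinality), \code{K_max}, \code{family},
#'   \code{feature_names}, and echoes of the configuration.
#' @export
fit_path <- function(data, family = c("cox", "logistic", "gaussian"),
                     K_max, config = solver_config(), grouping = NULL,
                     standardize = TRUE, verbose = FALSE) {
  family <- match.arg(family)
  obj <- make_objective(data, family, standardize)
  p <- obj$p
  kit_idx <- if (is.null(grouping)) NULL
             else kit_index(grouping, obj$feature_names)
  max_card <- if (is.null(kit_idx)) p else kit_idx$n_kits
  if (K_max < 1 || K_max > max_card)
    stop("K_max must be in 1..", max_card)
  gamma <- if (p >= 100 || config$gamma < 1) config$gamma else 1
  mle_int <- smooth_optimum(obj)
  prev <- numeric(obj$nb)
  solutions <- vector("list", K_max)
  prev_loss <- Inf
  for (i in seq_len(K_max)) {
    starts <- generate_starting_points(
      prev[seq_len(p)], mle_int[seq_len(p)], i,
      grouping = grouping, feature_names = obj$feature_names,
      zero_tol = config$zero_tol)
    if (gamma < 1)
      starts <- screen_starts_internal(obj$value, prev, starts, gamma)
    cand_fits <- list()
    for (k in seq_along(starts$points)) {
      b0 <- prev
      b0[seq_len(p)] <- starts$points[[k]]
      res <- escalate_rho(obj, i, b0, config, kit_idx)
      if (res$converged) cand_fits[[length(cand_fits) + 1L]] <- res
    }
    # monotonicity guard: the previous solution is feasible for K = i
    if (i > 1 || length(cand_fits) == 0) {
      if (is.finite(prev_loss))
        cand_fits[[length(cand_fits) + 1L]] <-
          list(b = prev, nnz = count_active(prev, p, config$zero_tol,
                                            kit_idx),
               rho = NA_real_, loss = prev_loss, converged = TRUE)
    }
    if (length(cand_fits) == 0)
      stop("no converged candidate at stage ", i,
           ": rho grid exhausted (rho_max = ", config$rho_max, ")")
    losses <- vapply(cand_fits, function(z) z$loss, numeric(1))
    best <- cand_fits[[which.min(losses)]]
    bb <- best$b
    bb[seq_len(p)][abs(bb[seq_len(p)]) <= config$zero_tol] <- 0
    prev <- bb
    prev_loss <- best$loss
    solutions[[i]] <- finalize_fit(best, obj, i, config, kit_idx)
    if (verbose)
      message(sprintf("stage %d: nnz=%d loss=%.6f rho=%s", i,
                      solutions[[i]]$nnz, solutions[[i]]$objective,
                      format(best$rho)))
  }
  orig_mle <- obj$to_original(mle_int)
  structure(list(mle = orig_mle$coefficients,
                 mle_intercept = orig_mle$intercept,
                 solutions = solutions, K_max = as.integer(K_max),
                 family = family, grouping = grouping,
                 config = config, standardize = standardize,
                 feature_names = obj$feature_names),
            class = "card_path")
}

count_active <- function(b, p, zero_tol, kit_idx) {
  bp <- b[seq_len(p)]
  if (is.null(kit_idx)) l0_pseudonorm(bp, zero_tol)
  else length(unique(kit_idx$id[abs(bp) > zero_tol]))
}

#' @export
print.card_path <- function(x, ...) {
  cat("Cardinality path (", x$family, "), K = 1..", x$K_max,
      if (!is.null(x$grouping)) " (kit-grouped)", ":\n", sep = "")
  print(path_summary(x), row.names = FALSE)
  invisible(x)
}

#' Selected support at one cardinality
#'
#' @param path a \code{card_path}.
#' @param K cardinality stage.
#' @param zero_tol threshold for "selected"; default 1e-6.
#' @return Character vector of selected feature names.
#' @export
path_support <- function(path, K, zero_tol = 1e-6) {
  stopifnot(inherits(path, "card_path"), K >= 1, K <= path$K_max)
  cf <- path$solutions[[K]]$coefficients
  names(cf)[abs(cf) > zero_tol]
}

#' Tabular summary of a cardinality path
#'
#' One row per stage: cardinality, number of active features, loss at the
#' solution, rho used, selected feature names and coefficients
#' (semicolon-joined).  Written with \code{\link{write_path_summary}} this
#' round-trips losslessly through delimited text.
#'
#' @param path a \code{card_path}.
#' @return A data.frame.
#' @export
path_summary <- function(path) {
  stopifnot(inherits(path, "card_path"))
  rows <- lapply(seq_len(path$K_max), function(i) {
    s <- path$solutions[[i]]
    sel <- which(abs(s$coefficients) > 0)
    data.frame(stage = i, nnz = s$nnz,
               objective = s$objective,
               rho_used = s$rho_used,
               features = paste(names(s$coefficients)[sel],
                                collapse = ";"),
               coefficients = paste(
                 formatC(s$coefficients[sel], digits = 17, format = "g"),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a path summary as delimited text
#'
#' @param path a \code{card_path}.
#' @param file output file.
#' @param sep field separator.
#' @return \code{file} invisibly (\code{write_path_summary}); a data.frame
#'   (\code{read_path_summary}).
#' @export
write_path_summary <- function(path, file, sep = "\t") {
  utils::write.table(path_summary(path), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_path_summary
#' @export
read_path_summary <- function(file, sep = "\t") {
  utils::read.table(file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE,
                    colClasses = c("integer", "integer", "numeric",
                                   "numeric", "character", "character"))
}

#' Linear risk scores from a path stage
#'
#' @param path a \code{card_path}.
#' @param K cardinality stage.
#' @param newdata a \code{survdata}/\code{labdata} or numeric matrix with
#'   the same feature columns.
#' @return Numeric vector \code{intercept + X beta_K}.
#' @export
predict_risk <- function(path, K, newdata) {
  stopifnot(inherits(path, "card_path"), K >= 1, K <= path$K_max)
  X <- if (is.matrix(newdata)) newdata else newdata$features
  X <- X[, path$feature_names, drop = FALSE]
  s <- path$solutions[[K]]
  drop(X %*% s$coefficients) + s$intercept
}
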