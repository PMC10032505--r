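# Model assessment: K-fold cross-validation with per-cardinality mean/SEM
# accuracy, bootstrap selection frequencies, Pareto front of measurement
# cost versus accuracy, the SEM rule for picking a final cardinality, and a
# greedy forward-selection baseline.

stratified_folds <- function(strata, folds, seed) {
  n <- length(strata)
  assign <- integer(n)
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' K-fold cross-validation of the cardinality path
#'
#' Folds are stratified on the event indicator (cox) or the class label
#' (logistic).  Each fold fits the full path on the training split and
#' scores every cardinality on the held-out split: Harrell's C-index of the
#' linear risk for cox, ROC-AUC for logistic.  A fold on which the metric
#' is undefined (no events, no comparable pairs) triggers a re-randomized
#' fold assignment; after 5 failed attempts an error is raised.
#'
#' @param data a \code{survdata} or \code{labdata}.
#' @param family \code{"cox"} or \code{"logistic"}.
#' @param K_max largest cardinality evaluated.
#' @param folds number of folds (>= 2); default 5.
#' @param config a \code{\link{solver_config}}.
#' @param seed integer seed controlling fold assignment.
#' @param grouping optional \code{\link{kit_structure}}.
#' @param standardize passed to \code{\link{fit_path}}.
#' @return Object of class \code{"cv_summary"}: data.frame with columns
#'   \code{cardinality}, \code{mean}, \code{sem}, \code{folds},
#'   \code{metric}.
#' @export
cross_validate <- function(data, family = c("cox", "logistic"), K_max,
                           folds = 5, config = solver_config(),
                           seed = 1L, grouping = NULL,
                           standardize = TRUE) {
  family <- match.arg(family)
  stopifnot(folds >= 2)
  strata <- if (family == "cox") data$events else data$outcome
  n <- length(strata)
  metric <- if (family == "cox") "cindex" else "auc"
  for (attempt in seq_len(5)) {
    fold_id <- stratified_folds(strata, folds, seed + (attempt - 1L) * 1000L)
    acc <- matrix(NA_real_, nrow = folds, ncol = K_max)
    ok <- TRUE
    for (f in seq_len(folds)) {
      test <- which(fold_id == f)
      train <- setdiff(seq_len(n), test)
      res <- tryCatch({
        tr <- subset_rows(data, train)
        te <- subset_rows(data, test)
        fit <- fit_path(tr, family, K_max, config, grouping, standardize)
        vapply(seq_len(K_max), function(i) {
          risk <- predict_risk(fit, i, te)
          if (family == "cox")
            concordance_index(risk, te$times, te$events)
          else roc_auc(risk, te$outcome)
        }, numeric(1))
      }, error = function(e) e)
      if (inherits(res, "error")) { ok <- FALSE; break }
      acc[f, ] <- res
    }
    if (ok) {
      means <- colMeans(acc)
      sems <- apply(acc, 2, stats::sd) / sqrt(folds)
      out <- data.frame(cardinality = seq_len(K_max), mean = means,
                        sem = sems, folds = folds, metric = metric,
                        stringsAsFactors = FALSE)
      class(out) <- c("cv_summary", "data.frame")
      attr(out, "fold_accuracies") <- acc
      return(out)
    }
  }
  stop("cross-validation failed on 5 fold randomizations (degenerate folds)")
}

subset_rows <- function(data, idx) {
  if (inherits(data, "survdata")) {
    survival_dataset(data$features[idx, , drop = FALSE],
                     data$times[idx], data$events[idx],
                     data$feature_names)
  } else {
    labeled_dataset(data$features[idx, , drop = FALSE],
                    data$outcome[idx], data$feature_names)
  }
}

#' Bootstrap selection frequencies
#'
#' Draws B bootstrap resamples of the rows (with replacement, size n),
#' refits the full cardinality path on each, and tabulates how often each
#' feature is selected at each cardinality, together with the modal
#' coefficient sign.  Resamples without any event are redrawn (budget of
#' 5 B redraws).
#'
#' @inheritParams cross_validate
#' @param B number of bootstrap refits; default 100.
#' @return Object of class \code{"bootstrap_summary"}: list with
#'   \code{frequency} (features x cardinalities, entries in [0, 1]),
#'   \code{sign} (modal sign matrix with entries -1/0/1), \code{B}.
#' @export
bootstrap_selection <- function(data, family = c("cox", "logistic",
                                                 "gaussian"),
                                K_max, B = 100, config = solver_config(),
                                seed = 1L, grouping = NULL,
                                standardize = TRUE) {
  family <- match.arg(family)
  stopifnot(B >= 1)
  p <- ncol(data$features)
  n <- nrow(data$features)
  freq <- matrix(0, p, K_max,
                 dimnames = list(data$feature_names, seq_len(K_max)))
  pos <- neg <- freq
  draws <- with_seed(seed,
                     replicate(5 * B, sample.int(n, n, replace = TRUE),
                               simplify = FALSE))
  done <- 0
  used <- 0
  while (done < B && used < length(draws)) {
    used <- used + 1
    idx <- draws[[used]]
    if (inherits(data, "survdata") && sum(data$events[idx]) == 0) next
    boot <- subset_rows(data, idx)
    fit <- fit_path(boot, family, K_max, config, grouping, standardize)
    for (i in seq_len(K_max)) {
      cf <- fit$solutions[[i]]$coefficients
      freq[, i] <- freq[, i] + (abs(cf) > 0)
      pos[, i] <- pos[, i] + (cf > 0)
      neg[, i] <- neg[, i] + (cf < 0)
    }
    done <- done + 1
  }
  if (done < B)
    stop("bootstrap retry budget exhausted: only ", done,
         " usable replicates")
  sgn <- sign(pos - neg)
  sgn[freq == 0] <- 0
  structure(list(frequency = freq / B, sign = sgn, B = B,
                 family = family),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Bootstrap selection frequencies (", x$B, " refits, ",
      x$family, " family)\n", sep = "")
  print(round(x$frequency, 3))
  invisible(x)
}

#' Pareto front of cost versus accuracy
#'
#' Flags the non-dominated subset: a model is dominated if another model
#' has no higher cost and no lower accuracy, with at least one strict
#' inequality.  Models tied on both coordinates are all kept.
#'
#' @param points data.frame with numeric columns \code{cost} and
#'   \code{accuracy} (other columns, e.g. a model id, pass through).
#' @return The input data.frame with a logical column \code{dominated};
#'   the front is \code{points[!points$dominated, ]}, returned in
#'   increasing cost order as attribute \code{"front"}.
#' @export
pareto_front <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("cost", "accuracy") %in% names(points)))
  n <- nrow(points)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    dominated[i] <- any(points$cost <= points$cost[i] &
                          points$accuracy >= points$accuracy[i] &
                          (points$cost < points$cost[i] |
                             points$accuracy > points$accuracy[i]))
  }
  points$dominated <- dominated
  front <- points[!dominated, , drop = FALSE]
  attr(points, "front") <- front[order(front$cost, front$accuracy), ,
                                 drop = FALSE]
  points
}

#' Choose a cardinality by the SEM rule
#'
#' Locates the cardinality with maximal mean CV accuracy (ties broken
#' toward the sparser model) and returns the smallest cardinality whose
#' mean accuracy is within one standard error of the mean of that maximum.
#'
#' @param cv a \code{\link{cross_validate}} summary.
#' @return Selected cardinality (integer).
#' @export
select_cardinality_sem <- function(cv) {
  stopifnot(nrow(cv) >= 1, all(c("mean", "sem") %in% names(cv)))
  istar <- which.max(cv$mean)
  thr <- cv$mean[istar] - cv$sem[istar]
  cv$cardinality[which(cv$mean >= thr)[1]]
}

# Unpenalized fit restricted to a support (plus intercept when present).
restricted_fit <- function(obj, support) {
  nb <- obj$nb
  free <- c(support, if (obj$has_intercept) nb)
  if (length(free) == 0) return(list(b = numeric(nb),
                                     loss = obj$value(numeric(nb))))
  embed <- function(bf) { b <- numeric(nb); b[free] <- bf; b }
  fit <- stats::optim(numeric(length(free)),
                      fn = function(bf) obj$value(embed(bf)),
                      gr = function(bf) obj$grad(embed(bf))[free],
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(b = embed(fit$par), loss = fit$value)
}

#' Greedy forward selection baseline
#'
#' Stage i adds the single feature whose inclusion in the current support
#' minimizes the loss of the refitted unpenalized restricted model.
#' Returns a path in the same shape as \code{\link{fit_path}}; supports are
#' nested by construction, so the loss is non-increasing along the path.
#'
#' @inheritParams fit_path
#' @return A \code{card_path}.
#' @export
greedy_forward_selection <- function(data,
                                     family = c("cox", "logistic",
                                                "gaussian"),
                                     K_max, config = solver_config(),
                                     standardize = TRUE) {
  family <- match.arg(family)
  obj <- make_objective(data, family, standardize)
  p <- obj$p
  stopifnot(K_max >= 1, K_max <= p)
  mle_int <- smooth_optimum(obj)
  support <- integer(0)
  solutions <- vector("list", K_max)
  for (i in seq_len(K_max)) {
    cand <- setdiff(seq_len(p), support)
    fits <- lapply(cand, function(j) restricted_fit(obj, c(support, j)))
    losses <- vapply(fits, function(z) z$loss, numeric(1))
    kbest <- which.min(losses)
    support <- c(support, cand[kbest])
    bb <- fits[[kbest]]$b
    res <- list(b = bb, nnz = l0_pseudonorm(bb[seq_len(p)],
                                            config$zero_tol),
                rho = NA_real_, loss = fits[[kbest]]$loss,
                converged = TRUE)
    solutions[[i]] <- finalize_fit(res, obj, i, config, NULL)
  }
  orig_mle <- obj$to_original(mle_int)
  structure(list(mle = orig_mle$coefficients,
                 mle_intercept = orig_mle$intercept,
                 solutions = solutions, K_max = as.integer(K_max),
                 family = family, grouping = NULL, config = config,
                 standardize = standardize,
                 feature_names = obj$feature_names,
                 method = "greedy_fs"),
            class = "card_path")
}

#' Cost/accuracy table for a fitted path
#'
#' Convenience builder joining per-cardinality CV accuracy with kit costs
#' of the selected supports, ready for \code{\link{pareto_front}}.
#'
#' @param path a \code{card_path}.
#' @param cv matching \code{cv_summary}.
#' @param kits a \code{\link{kit_structure}}.
#' @return data.frame with \code{model_id}, \code{cost}, \code{accuracy}.
#' @export
cost_accuracy_table <- function(path, cv, kits) {
  stopifnot(inherits(path, "card_path"), nrow(cv) == path$K_max)
  costs <- vapply(seq_len(path$K_max), function(i)
    kit_cost(path_support(path, i), kits), numeric(1))
  data.frame(model_id = paste0("K", seq_len(path$K_max)),
             cost = costs, accuracy = cv$mean,
             stringsAsFactors = FALSE)
}
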