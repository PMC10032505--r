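# Model families: loss value + gradient oracles used by the DC solver.
#
# The Cox loss is the scaled negative log partial likelihood with Breslow
# handling of tied failure times,
#   -l(beta) = -(2/n) sum_i { sum_{j in D_i} x_j'beta
#                             - d_i * log( sum_{j in R_i} exp(x_j'beta) ) },
# computed through reverse cumulative sums over time-sorted rows so a single
# evaluation is O(n p), with max-subtraction for overflow-safe log-sum-exp.

# Precompute sort order and failure-time bookkeeping for repeated Cox
# loss/gradient evaluations on one dataset.
cox_workspace <- function(X, times, events) {
  n <- nrow(X)
  if (sum(events) < 1) stop("no events: partial likelihood undefined")
  ord <- order(times, decreasing = TRUE)          # descending follow-up
  Xs <- X[ord, , drop = FALSE]
  ts <- times[ord]
  es <- events[ord]
  ft <- sort(unique(ts[es == 1]))                 # ascending failure times
  m <- length(ft)
  # |R_i| = count of subjects with y >= t_i = prefix length in sorted order
  r_size <- vapply(ft, function(t) sum(ts >= t), integer(1))
  d_pos <- which(es == 1)                         # sorted positions of events
  d_grp <- match(ts[d_pos], ft)                   # failure-time id per event
  d_cnt <- as.integer(tabulate(d_grp, nbins = m))
  # column sums of x over each D_i  (m x p)
  ev_x <- rowsum(Xs[d_pos, , drop = FALSE], group = d_grp)
  list(n = n, p = ncol(X), Xs = Xs, r_size = r_size, d_pos = d_pos,
       d_grp = d_grp, d_cnt = d_cnt, ev_x = ev_x, m = m)
}

cox_loss_ws <- function(beta, ws) {
  eta <- drop(ws$Xs %*% beta)
  M <- max(eta)
  w <- exp(eta - M)
  cw <- cumsum(w)                                 # prefix sums = risk-set sums
  S <- cw[ws$r_size]
  ev_eta <- sum(eta[ws$d_pos])
  l <- (2 / ws$n) * (ev_eta - sum(ws$d_cnt * (M + log(S))))
  out <- -l
  if (!is.finite(out)) stop("non-finite partial likelihood value")
  out
}

cox_grad_ws <- function(beta, ws) {
  eta <- drop(ws$Xs %*% beta)
  M <- max(eta)
  w <- exp(eta - M)
  cw <- cumsum(w)
  S <- cw[ws$r_size]
  cxw <- apply(ws$Xs * w, 2, cumsum)
  if (is.null(dim(cxw))) cxw <- matrix(cxw, nrow = 1)
  num <- cxw[ws$r_size, , drop = FALSE]           # m x p risk-set x-sums
  g <- unname((2 / ws$n) * (colSums(num * (ws$d_cnt / S)) -
                              colSums(ws$ev_x)))
  if (any(!is.finite(g))) stop("non-finite partial likelihood gradient")
  g
}

#' Scaled negative log partial likelihood (Cox, Breslow ties)
#'
#' Evaluates \eqn{-l(\beta)} where \eqn{l} is the log partial likelihood
#' scaled by \eqn{2/n}, with Breslow's approximation for tied failure times.
#' Overflow-safe via max-subtraction in the log-sum-exp terms.
#'
#' @param beta numeric coefficient vector of length p.
#' @param data a \code{\link{survival_dataset}}.
#' @return A single finite number; an error is raised on non-finite results.
#' @export
neg_log_partial_likelihood <- function(beta, data) {
  stopifnot(inherits(data, "survdata"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$features) || any(!is.finite(beta)))
    stop("beta must be a finite vector of length p")
  ws <- cox_workspace(data$features, data$times, data$events)
  cox_loss_ws(beta, ws)
}

#' Gradient of the scaled negative log partial likelihood
#'
#' @inheritParams neg_log_partial_likelihood
#' @return Numeric vector of length p.
#' @export
neg_log_partial_likelihood_gradient <- function(beta, data) {
  stopifnot(inherits(data, "survdata"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$features) || any(!is.finite(beta)))
    stop("beta must be a finite vector of length p")
  ws <- cox_workspace(data$features, data$times, data$events)
  cox_grad_ws(beta, ws)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 30
  out[hi] <- x[hi]
  out[!hi] <- log1p(exp(x[!hi]))
  out
}

#' Family loss: Cox, logistic or gaussian
#'
#' Logistic: mean negative Bernoulli log-likelihood of the outcomes given
#' logits \code{intercept + X beta}.  Gaussian: mean squared error.  Cox
#' (no intercept): the scaled negative log partial likelihood.
#'
#' @param beta numeric coefficient vector of length p.
#' @param data a \code{survdata} (cox) or \code{labdata}
#'   (logistic/gaussian).
#' @param family one of \code{"cox"}, \code{"logistic"}, \code{"gaussian"}.
#' @param intercept unpenalized intercept (logistic/gaussian only);
#'   default 0.
#' @return A single number.
#' @export
family_loss <- function(beta, data, family = c("cox", "logistic", "gaussian"),
                        intercept = 0) {
  family <- match.arg(family)
  if (family == "cox") return(neg_log_partial_likelihood(beta, data))
  stopifnot(inherits(data, "labdata"))
  beta <- as.numeric(beta)
  eta <- drop(data$features %*% beta) + intercept
  y <- data$outcome
  if (family == "logistic") {
    if (!all(y %in% c(0, 1)))
      stop("logistic family requires a binary 0/1 outcome")
    mean(log1pexp(eta) - y * eta)
  } else {
    mean((y - eta)^2)
  }
}

#' Gradient of the family loss with respect to the coefficients
#'
#' @inheritParams family_loss
#' @return Numeric vector of length p (the intercept derivative is not
#'   included; see \code{\link{family_loss}}).
#' @export
family_gradient <- function(beta, data,
                            family = c("cox", "logistic", "gaussian"),
                            intercept = 0) {
  family <- match.arg(family)
  if (family == "cox")
    return(neg_log_partial_likelihood_gradient(beta, data))
  stopifnot(inherits(data, "labdata"))
  beta <- as.numeric(beta)
  eta <- drop(data$features %*% beta) + intercept
  y <- data$outcome
  n <- length(y)
  if (family == "logistic") {
    if (!all(y %in% c(0, 1)))
      stop("logistic family requires a binary 0/1 outcome")
    unname(drop(crossprod(data$features, stats::plogis(eta) - y)) / n)
  } else {
    unname(drop(crossprod(data$features, -2 * (y - eta))) / n)
  }
}

#' Model family descriptor
#'
#' @param name one of \code{"cox"}, \code{"logistic"}, \code{"gaussian"}.
#' @return A list with \code{name}, and closures \code{loss(beta, data)}
#'   and \code{gradient(beta, data)}.
#' @export
model_family <- function(name = c("cox", "logistic", "gaussian")) {
  name <- match.arg(name)
  list(name = name,
       loss = function(beta, data) family_loss(beta, data, name),
       gradient = function(beta, data) family_gradient(beta, data, name))
}

# Internal smooth objective used by the solver.  Parameter vector is
# c(beta_std, intercept?) on standardized features; `npen` leading
# coordinates carry the L1/largest-k machinery.  `to_original` maps back to
# the raw feature scale.
make_objective <- function(data, family, standardize = TRUE) {
  if (family == "cox") {
    X <- data$features
    has_int <- FALSE
  } else {
    stopifnot(inherits(data, "labdata"))
    X <- data$features
    has_int <- TRUE
    if (family == "logistic" && !all(data$outcome %in% c(0, 1)))
      stop("logistic family requires a binary 0/1 outcome")
  }
  p <- ncol(X)
  n <- nrow(X)
  if (standardize) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  } else {
    mu <- rep(0, p); sd_ <- rep(1, p)
    Xs <- X
  }
  if (family == "cox") {
    ws <- cox_workspace(Xs, data$times, data$events)
    value <- function(b) cox_loss_ws(b, ws)
    grad <- function(b) cox_grad_ws(b, ws)
    nb <- p
  } else {
    y <- data$outcome
    nb <- p + 1L
    if (family == "logistic") {
      value <- function(b) {
        eta <- drop(Xs %*% b[1:p]) + b[nb]
        mean(log1pexp(eta) - y * eta)
      }
      grad <- function(b) {
        eta <- drop(Xs %*% b[1:p]) + b[nb]
        r <- stats::plogis(eta) - y
        unname(c(drop(crossprod(Xs, r)) / n, sum(r) / n))
      }
    } else {
      value <- function(b) {
        eta <- drop(Xs %*% b[1:p]) + b[nb]
        mean((y - eta)^2)
      }
      grad <- function(b) {
        r <- y - drop(Xs %*% b[1:p]) - b[nb]
        unname(c(drop(crossprod(Xs, -2 * r)) / n, -2 * sum(r) / n))
      }
    }
  }
  to_original <- function(b) {
    beta <- b[1:p] / sd_
    names(beta) <- colnames(X)
    if (has_int) {
      list(coefficients = beta,
           intercept = b[nb] - sum(b[1:p] * mu / sd_))
    } else {
      list(coefficients = beta, intercept = 0)
    }
  }
  list(value = value, grad = grad, p = p, nb = nb, npen = p,
       has_intercept = has_int, to_original = to_original,
       family = family, n = n,
       feature_names = colnames(X))
}
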