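# Shared fixtures and independent oracles for the test suite.

# A tiny deterministic survival dataset.
tiny_surv <- function(n = 20, p = 4, seed = 42, cens = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  times <- rexp(n) + 0.05
  events <- rbinom(n, 1, 1 - cens)
  if (sum(events) == 0) events[1] <- 1
  survival_dataset(X, times, events)
}

# Independent, naive evaluation of the scaled log partial likelihood with
# Breslow ties: explicit loops over failure times, risk sets as index sets.
naive_neg_logpl <- function(beta, X, times, events) {
  n <- nrow(X)
  eta <- drop(X %*% beta)
  ft <- sort(unique(times[events == 1]))
  l <- 0
  for (t in ft) {
    D <- which(events == 1 & times == t)
    R <- which(times >= t)
    l <- l + sum(eta[D]) - length(D) * log(sum(exp(eta[R])))
  }
  -(2 / n) * l
}

# Exhaustive pairwise C-index oracle (comparable iff y_i < y_j & d_i = 1).
naive_cindex <- function(risk, times, events) {
  num <- den <- 0
  n <- length(times)
  for (i in 1:n) for (j in 1:n) {
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Brute-force AUC over all positive-negative pairs.
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Best unpenalized Cox loss over all supports of size <= K, via
# survival::coxph (Breslow ties) as an independent restricted-fit oracle.
# Returns the minimal scaled negative log partial likelihood.
best_subset_loss <- function(data, K) {
  p <- ncol(data$features)
  n <- nrow(data$features)
  best <- Inf
  y <- survival::Surv(data$times, data$events)
  for (k in 1:K) {
    for (s in utils::combn(p, k, simplify = FALSE)) {
      fit <- survival::coxph(y ~ data$features[, s, drop = FALSE],
                             ties = "breslow")
      ll <- fit$loglik[2]
      best <- min(best, -(2 / n) * ll)
    }
  }
  best
}

# Scaled loss of one support refit by coxph.
support_loss <- function(data, support) {
  n <- nrow(data$features)
  y <- survival::Surv(data$times, data$events)
  if (length(support) == 0)
    return(-(2 / n) * survival::coxph(y ~ 1)$loglik[1])
  fit <- survival::coxph(y ~ data$features[, support, drop = FALSE],
                         ties = "breslow")
  -(2 / n) * fit$loglik[2]
}

kit_fixture_path <- function() {
  system.file("extdata", "clinical_kits.csv", package = "cardsel")
}

fast_config <- function(...) solver_config(...)
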