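# Synthetic data with known ground truth.  Censored survival data follow a
# sparse linear risk model: features are standard normal with exchangeable
# pairwise correlation, event times are exponential with rate
# baseline * exp(x' beta_true), and independent exponential censoring is
# calibrated by root finding so the realized censoring fraction matches the
# target.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's global RNG state is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a synthetic survival simulation
#'
#' @param n subjects (>= 10).
#' @param p features.
#' @param true_support indices of nonzero true coefficients.
#' @param true_effects their values (recycled to the support length).
#' @param feature_correlation exchangeable pairwise correlation in [0, 1).
#' @param censoring_fraction target fraction of right-censored subjects in
#'   [0, 1); default 0.3, typical of advanced-cancer registry cohorts.
#' @param baseline exponential baseline hazard rate; default 1 (arbitrary
#'   time unit).
#' @param seed integer seed; all randomness of the generators flows from
#'   it.
#' @param kit_layout optional list(kits_count, cost_range) to also emit a
#'   synthetic kit structure over the features.
#' @return A list of class \code{"sim_spec"}.
#' @export
simulation_spec <- function(n, p, true_support = integer(0),
                            true_effects = numeric(0),
                            feature_correlation = 0,
                            censoring_fraction = 0.3, baseline = 1,
                            seed = 1L, kit_layout = NULL) {
  stopifnot(n >= 10, p >= 1, length(true_support) <= p,
            all(true_support %in% seq_len(p)),
            feature_correlation >= 0, feature_correlation < 1,
            censoring_fraction >= 0, censoring_fraction < 1,
            baseline > 0)
  if (length(true_support) > 0)
    true_effects <- rep_len(true_effects, length(true_support))
  structure(list(n = as.integer(n), p = as.integer(p),
                 true_support = as.integer(true_support),
                 true_effects = as.numeric(true_effects),
                 feature_correlation = feature_correlation,
                 censoring_fraction = censoring_fraction,
                 baseline = baseline, seed = as.integer(seed),
                 kit_layout = kit_layout),
            class = "sim_spec")
}

sim_features <- function(spec) {
  r <- spec$feature_correlation
  Z <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p)
  if (r > 0) {
    z0 <- stats::rnorm(spec$n)
    Z <- sqrt(r) * z0 + sqrt(1 - r) * Z
  }
  colnames(Z) <- paste0("x", seq_len(spec$p))
  Z
}

sim_beta <- function(spec) {
  beta <- numeric(spec$p)
  beta[spec$true_support] <- spec$true_effects
  beta
}

sim_kits <- function(spec) {
  if (is.null(spec$kit_layout)) return(NULL)
  kc <- spec$kit_layout$kits_count
  cr <- spec$kit_layout$cost_range %||% c(0, 100)
  feats <- paste0("x", seq_len(spec$p))
  kit_id <- rep_len(seq_len(kc), spec$p)
  kit_names <- paste0("kit", seq_len(kc))
  costs <- stats::runif(kc, cr[1], cr[2])
  kit_structure(stats::setNames(kit_names[kit_id], feats),
                stats::setNames(costs, kit_names))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate right-censored survival data
#'
#' Event times are exponential with rate
#' \code{baseline * exp(x' beta_true)}.  Censoring times are independent
#' exponentials whose rate is calibrated by bisection on the realized
#' censoring fraction; the calibration errors out if it cannot come within
#' 0.05 of the target.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return A \code{\link{survival_dataset}} with attribute \code{"truth"}:
#'   list(beta, support, realized_censoring, kits).
#' @export
simulate_cox_data <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    X <- sim_features(spec)
    beta <- sim_beta(spec)
    rate <- spec$baseline * exp(drop(X %*% beta))
    Tev <- stats::rexp(spec$n, rate = rate)
    if (spec$censoring_fraction <= 0) {
      y <- Tev
      delta <- rep(1, spec$n)
      realized <- 0
    } else {
      E <- stats::rexp(spec$n, rate = 1)
      frac <- function(logc) mean(E / exp(logc) < Tev)
      lo <- -30; hi <- 30
      if (frac(lo) > spec$censoring_fraction ||
          frac(hi) < spec$censoring_fraction)
        stop("censoring calibration failed: target unreachable")
      for (it in 1:200) {             # bisection on the (step) function
        mid <- (lo + hi) / 2
        if (frac(mid) < spec$censoring_fraction) lo <- mid else hi <- mid
        if (hi - lo < 1e-10) break
      }
      cand <- c(lo, hi)
      err <- abs(vapply(cand, frac, numeric(1)) - spec$censoring_fraction)
      logc <- cand[which.min(err)]
      C <- E / exp(logc)
      y <- pmin(Tev, C)
      delta <- as.numeric(Tev <= C)
      realized <- 1 - mean(delta)
      if (abs(realized - spec$censoring_fraction) > 0.05)
        stop("censoring calibration failed: realized fraction ",
             round(realized, 3), " vs target ", spec$censoring_fraction)
    }
    if (sum(delta) == 0)
      stop("simulated dataset has no events")
    kits <- sim_kits(spec)
    d <- survival_dataset(X, y, delta)
    attr(d, "truth") <- list(beta = beta, support = spec$true_support,
                             realized_censoring = realized, kits = kits)
    d
  })
}

#' Simulate binary-outcome data for the logistic family
#'
#' Labels are Bernoulli with logit \code{intercept + x' beta_true}.  A
#' degenerate single-class draw is redrawn with a warning; after 10 retries
#' an error is raised.
#'
#' @param spec a \code{\link{simulation_spec}} (censoring fields ignored).
#' @param intercept logit intercept; default 0.
#' @return A \code{\link{labeled_dataset}} with attribute \code{"truth"}.
#' @export
simulate_binary_data <- function(spec, intercept = 0) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    beta <- sim_beta(spec)
    for (try in 1:10) {
      X <- sim_features(spec)
      pr <- stats::plogis(intercept + drop(X %*% beta))
      ylab <- stats::rbinom(spec$n, 1, pr)
      if (length(unique(ylab)) == 2) {
        d <- labeled_dataset(X, ylab)
        attr(d, "truth") <- list(beta = beta,
                                 support = spec$true_support,
                                 intercept = intercept,
                                 kits = sim_kits(spec))
        return(d)
      }
      warning("single-class draw; redrawing (attempt ", try, ")")
    }
    stop("could not draw a two-class outcome in 10 attempts")
  })
}
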