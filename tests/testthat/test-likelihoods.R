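test_that("risk-set index handles ties and censoring", {
  X <- matrix(0, 3, 1)
  ri <- build_risk_index(survival_dataset(X, c(1, 2, 3), c(1, 1, 1)))
  expect_equal(ri$unique_failure_times, c(1, 2, 3))
  expect_equal(lengths(ri$risk_sets), c(3L, 2L, 1L))
  expect_equal(ri$failure_counts, c(1L, 1L, 1L))

  ri2 <- build_risk_index(survival_dataset(X, c(1, 1, 2), c(1, 1, 1)))
  expect_equal(length(ri2$unique_failure_times), 2L)
  expect_equal(ri2$failure_counts, c(2L, 1L))
  expect_equal(lengths(ri2$risk_sets), c(3L, 1L))

  ri3 <- build_risk_index(survival_dataset(X, c(1, 2, 3), c(1, 0, 1)))
  expect_equal(ri3$unique_failure_times, c(1, 3))
  expect_equal(lengths(ri3$risk_sets), c(3L, 1L))
  # nested risk sets, D_i subset of R_i
  for (i in seq_along(ri3$risk_sets)) {
    expect_true(all(ri3$failure_sets[[i]] %in% ri3$risk_sets[[i]]))
    if (i > 1)
      expect_true(all(ri3$risk_sets[[i]] %in% ri3$risk_sets[[i - 1]]))
  }
  expect_error(survival_dataset(X, c(1, 2, 3), c(0, 0, 0)), "event")
})

test_that("negative log partial likelihood matches closed forms at zero", {
  X <- matrix(rnorm(9), 3, 3)
  d <- survival_dataset(X, c(1, 2, 3), c(1, 1, 1))
  expect_equal(neg_log_partial_likelihood(rep(0, 3), d),
               (2 / 3) * (log(3) + log(2)), tolerance = 1e-12)
  d2 <- survival_dataset(X, c(1, 1, 2), c(1, 1, 1))
  expect_equal(neg_log_partial_likelihood(rep(0, 3), d2),
               (4 / 3) * log(3), tolerance = 1e-12)
})

test_that("likelihood and gradient agree with the naive oracle and FD", {
  for (seed in c(7, 8, 9)) {
    d <- tiny_surv(n = 20, p = 4, seed = seed)
    set.seed(seed + 100)
    b <- rnorm(4)
    expect_equal(neg_log_partial_likelihood(b, d),
                 naive_neg_logpl(b, d$features, d$times, d$events),
                 tolerance = 1e-10)
    g <- neg_log_partial_likelihood_gradient(b, d)
    fd <- vapply(1:4, function(j) {
      h <- 1e-6; e <- numeric(4); e[j] <- h
      (neg_log_partial_likelihood(b + e, d) -
         neg_log_partial_likelihood(b - e, d)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("gradient structure: zero feature, first-order optimality", {
  d <- tiny_surv(n = 30, p = 3, seed = 5)
  d$features[, 2] <- 0
  d <- survival_dataset(d$features, d$times, d$events)
  g <- neg_log_partial_likelihood_gradient(c(0.3, 1, -0.2), d)
  expect_equal(g[2], 0)
  # at the unregularized optimum the gradient vanishes
  fit <- optim(numeric(3), function(b) neg_log_partial_likelihood(b, d),
               function(b) neg_log_partial_likelihood_gradient(b, d),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(max(abs(neg_log_partial_likelihood_gradient(fit$par, d))),
            1e-4)
})

test_that("loss is convex and depends on times only through ranks", {
  d <- tiny_surv(n = 25, p = 3, seed = 12)
  set.seed(1)
  for (rep in 1:20) {
    b1 <- rnorm(3); b2 <- rnorm(3); lam <- runif(1)
    lhs <- neg_log_partial_likelihood(lam * b1 + (1 - lam) * b2, d)
    rhs <- lam * neg_log_partial_likelihood(b1, d) +
      (1 - lam) * neg_log_partial_likelihood(b2, d)
    expect_lte(lhs, rhs + 1e-9)
  }
  shifted <- survival_dataset(d$features, d$times + 5, d$events)
  b <- rnorm(3)
  expect_equal(neg_log_partial_likelihood(b, d),
               neg_log_partial_likelihood(b, shifted), tolerance = 1e-12)
})

test_that("logistic and gaussian losses behave as defined", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rbinom(20, 1, 0.5)
  d <- labeled_dataset(X, y)
  expect_equal(family_loss(c(0, 0), d, "logistic"), log(2),
               tolerance = 1e-12)
  b <- c(0.5, -1)
  eta <- drop(X %*% b)
  direct <- -mean(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  expect_equal(family_loss(b, d, "logistic"), direct, tolerance = 1e-10)
  dg <- labeled_dataset(X, drop(X %*% b))
  expect_equal(family_loss(b, dg, "gaussian"), 0, tolerance = 1e-12)
  expect_error(family_loss(b, dg, "logistic"), "binary")
  # gradients vs finite differences
  for (fam in c("logistic", "gaussian")) {
    dd <- if (fam == "logistic") d else dg
    g <- family_gradient(b, dd, fam)
    fd <- vapply(1:2, function(j) {
      h <- 1e-6; e <- numeric(2); e[j] <- h
      (family_loss(b + e, dd, fam) - family_loss(b - e, dd, fam)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("concordance index matches exhaustive pair counting", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(concordance_index(c(2, 2, 1, 0), c(1, 2, 3, 4),
                                 c(1, 1, 0, 1)), 0.9)
  set.seed(21)
  n <- 60
  risk <- rnorm(n); times <- rexp(n); ev <- rbinom(n, 1, 0.7)
  expect_equal(concordance_index(risk, times, ev),
               naive_cindex(risk, times, ev), tolerance = 1e-12)
  expect_error(concordance_index(1, 1, 0), "comparable")
  # random scores on large data concentrate near 1/2
  set.seed(31)
  n <- 2000
  cc <- concordance_index(rnorm(n), rexp(n), rbinom(n, 1, 0.7))
  expect_lt(abs(cc - 0.5), 0.05)
})

test_that("ROC-AUC is the Mann-Whitney statistic with ties at 1/2", {
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(4)
  s <- sample(1:5, 30, replace = TRUE)
  lab <- rbinom(30, 1, 0.5)
  if (length(unique(lab)) == 2)
    expect_equal(roc_auc(s, lab), naive_auc(s, lab), tolerance = 1e-12)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})
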