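test_that("kit costs charge each kit once", {
  kits <- read_kits(kit_fixture_path())
  expect_equal(kit_cost("PSA", kits), 100)
  expect_equal(kit_cost(c("HB", "PLT"), kits), 40)
  expect_equal(kit_cost(c("PSA", "HB", "ALP", "AGEGRP", "CREAT", "PULSE"),
                        kits), 180)
  expect_equal(kit_cost(character(0), kits), 0)
  # unmapped features are free singletons; cost is monotone in the set
  expect_equal(kit_cost(c("PSA", "UNKNOWN1"), kits), 100)
  set.seed(41)
  feats <- sample(names(kits$kit_of), 6)
  for (k in 1:5)
    expect_lte(kit_cost(feats[1:k], kits), kit_cost(feats[1:(k + 1)], kits))
})

test_that("pareto front matches the quadratic dominance oracle", {
  pts <- data.frame(cost = c(100, 50, 120), accuracy = c(0.70, 0.65, 0.69))
  res <- pareto_front(pts)
  expect_equal(which(!res$dominated), c(1L, 2L))
  one <- pareto_front(data.frame(cost = 5, accuracy = 0.5))
  expect_false(one$dominated)
  set.seed(42)
  big <- data.frame(cost = round(runif(200, 0, 100)),
                    accuracy = round(runif(200), 2))
  res2 <- pareto_front(big)
  # O(n^2) oracle
  dom <- vapply(seq_len(200), function(i) {
    any(big$cost <= big$cost[i] & big$accuracy >= big$accuracy[i] &
          (big$cost < big$cost[i] | big$accuracy > big$accuracy[i]))
  }, logical(1))
  expect_equal(res2$dominated, dom)
  # invariant to input order
  perm <- sample(200)
  res3 <- pareto_front(big[perm, ])
  expect_equal(res3$dominated, dom[perm])
})

test_that("SEM rule picks the sparsest model within one SEM of the max", {
  cv <- data.frame(cardinality = 1:4, mean = c(0.60, 0.70, 0.71, 0.705),
                   sem = c(0.01, 0.015, 0.02, 0.02))
  expect_equal(select_cardinality_sem(cv), 2L)
  cv2 <- data.frame(cardinality = 1:3, mean = c(0.5, 0.6, 0.7),
                    sem = c(0.1, 0.1, 0))
  expect_equal(select_cardinality_sem(cv2), 3L)
  cv3 <- data.frame(cardinality = 1:3, mean = rep(0.6, 3),
                    sem = rep(0.02, 3))
  expect_equal(select_cardinality_sem(cv3), 1L)
})

test_that("greedy forward selection refits nested supports", {
  skip_if_not_installed("survival")
  spec <- simulation_spec(n = 150, p = 2, true_support = 1,
                          true_effects = 1.5, censoring_fraction = 0.2,
                          seed = 43)
  d <- simulate_cox_data(spec)
  g <- greedy_forward_selection(d, "cox", K_max = 2)
  expect_equal(path_support(g, 1), "x1")
  expect_lte(support_loss(d, 1), support_loss(d, 2))
  # K_max = p reaches the unregularized optimum
  expect_equal(g$solutions[[2]]$objective,
               neg_log_partial_likelihood(g$mle, d), tolerance = 1e-6)
  obj <- vapply(g$solutions, function(s) s$objective, numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
  # supports are nested
  expect_true(all(path_support(g, 1) %in% path_support(g, 2)))
})

test_that("bootstrap frequencies count selections per cardinality", {
  spec <- simulation_spec(n = 100, p = 4, true_support = 1,
                          true_effects = 2, censoring_fraction = 0.2,
                          seed = 44)
  d <- simulate_cox_data(spec)
  bs1 <- bootstrap_selection(d, "cox", K_max = 2, B = 1, seed = 7)
  expect_true(all(bs1$frequency %in% c(0, 1)))
  for (i in 1:2) expect_lte(sum(bs1$frequency[, i]), i)
  bs <- bootstrap_selection(d, "cox", K_max = 2, B = 10, seed = 8)
  expect_true(all(bs$frequency >= 0 & bs$frequency <= 1))
  # the dominant feature is picked essentially always at K = 1
  expect_gte(bs$frequency["x1", 1], 0.9)
  expect_true(all(bs$sign %in% c(-1, 0, 1)))
  # determinism under the seed
  bs_again <- bootstrap_selection(d, "cox", K_max = 2, B = 10, seed = 8)
  expect_identical(bs, bs_again)
})

test_that("cross-validation yields per-cardinality means and SEMs", {
  spec <- simulation_spec(n = 150, p = 5, true_support = 2,
                          true_effects = 1.5, censoring_fraction = 0.25,
                          seed = 45)
  d <- simulate_cox_data(spec)
  cv <- cross_validate(d, "cox", K_max = 2, folds = 3, seed = 9)
  expect_equal(nrow(cv), 2L)
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  expect_true(all(cv$sem >= 0))
  acc <- attr(cv, "fold_accuracies")
  expect_equal(cv$sem, apply(acc, 2, sd) / sqrt(3), tolerance = 1e-12)
  # a strong single-feature signal clearly beats chance at K = 1
  expect_gte(cv$mean[1], 0.5 + 0.15)
  # logistic branch with ROC-AUC
  spb <- simulation_spec(n = 160, p = 4, true_support = 1,
                         true_effects = 2, seed = 46)
  db <- simulate_binary_data(spb)
  cvb <- cross_validate(db, "logistic", K_max = 2, folds = 3, seed = 10)
  expect_equal(unique(cvb$metric), "auc")
  expect_gt(cvb$mean[1], 0.6)
})

test_that("cost/accuracy table feeds the pareto front", {
  spec <- simulation_spec(n = 120, p = 4, true_support = 1,
                          true_effects = 1.5, censoring_fraction = 0.2,
                          seed = 47, kit_layout = list(kits_count = 2))
  d <- simulate_cox_data(spec)
  kits <- attr(d, "truth")$kits
  fit <- fit_path(d, "cox", K_max = 2)
  cv <- cross_validate(d, "cox", K_max = 2, folds = 3, seed = 11)
  tab <- cost_accuracy_table(fit, cv, kits)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$cost >= 0))
  res <- pareto_front(tab)
  expect_true(any(!res$dominated))
})
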