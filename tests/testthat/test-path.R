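test_that("starting points implement the substitution-and-filter rule", {
  sp <- generate_starting_points(c(0.5, 0, 0), c(0.4, 0.3, -0.2), stage = 2)
  expect_equal(sp$points, list(c(0.5, 0.3, 0), c(0.5, 0, -0.2)))
  expect_equal(sp$js, c(2L, 3L))
  # stage 1 from zero: the p single-coordinate vectors
  sp1 <- generate_starting_points(numeric(3), c(0.4, 0.3, -0.2), stage = 1)
  expect_equal(length(sp1$points), 3L)
  expect_equal(sp1$points[[2]], c(0, 0.3, 0))
  # a zero MLE coordinate yields a filtered-out candidate
  sp2 <- generate_starting_points(numeric(3), c(0.4, 0, -0.2), stage = 1)
  expect_equal(sp2$js, c(1L, 3L))
  # every retained point has support larger than stage - 1
  for (pt in sp$points) expect_gt(l0_pseudonorm(pt), 1)
})

test_that("kit-wise starting points substitute whole kits", {
  kits <- kit_structure(c(x1 = "A", x2 = "A", x3 = "B"),
                        c(A = 1, B = 2))
  sp <- generate_starting_points(c(0, 0, 0.7), c(0.4, 0.3, -0.2),
                                 stage = 2, grouping = kits,
                                 feature_names = c("x1", "x2", "x3"))
  expect_equal(sp$points, list(c(0.4, 0.3, 0.7)))  # kit B alone filtered
  expect_equal(sp$js, 1L)
})

test_that("path recovers the exhaustive best subset on a clean signal", {
  skip_if_not_installed("survival")
  spec <- simulation_spec(n = 200, p = 6, true_support = c(1, 2),
                          true_effects = c(1, -1),
                          censoring_fraction = 0.2, seed = 31)
  d <- simulate_cox_data(spec)
  fit <- fit_path(d, "cox", K_max = 2)
  sup <- match(path_support(fit, 2), d$feature_names)
  oracle <- Inf
  best_sup <- NULL
  for (s in utils::combn(6, 2, simplify = FALSE)) {
    v <- support_loss(d, s)
    if (v < oracle) { oracle <- v; best_sup <- s }
  }
  expect_setequal(sup, best_sup)
})

test_that("K_max = p reaches the unregularized optimum", {
  d <- tiny_surv(n = 120, p = 4, seed = 32, cens = 0.2)
  fit <- fit_path(d, "cox", K_max = 4)
  expect_equal(fit$solutions[[4]]$objective,
               neg_log_partial_likelihood(fit$mle, d), tolerance = 1e-4)
})

test_that("logistic path selects the informative feature at K = 1", {
  spec <- simulation_spec(n = 200, p = 4, true_support = 3,
                          true_effects = 2.5, seed = 33)
  d <- simulate_binary_data(spec)
  fit <- fit_path(d, "logistic", K_max = 1)
  expect_equal(path_support(fit, 1), "x3")
  # oracle: x3 gives the lowest single-feature deviance
  obj1 <- vapply(1:4, function(j) {
    o <- optim(c(0, 0), function(b)
      family_loss(replace(numeric(4), j, b[1]), d, "logistic", b[2]),
      method = "BFGS")
    o$value
  }, numeric(1))
  expect_equal(which.min(obj1), 3L)
})

test_that("acceleration screen keeps the best-scoring candidates", {
  d <- tiny_surv(n = 100, p = 10, seed = 34, cens = 0.2)
  mle <- optim(numeric(10),
               function(b) neg_log_partial_likelihood(b, d),
               function(b) neg_log_partial_likelihood_gradient(b, d),
               method = "BFGS")$par
  sp <- generate_starting_points(numeric(10), mle, stage = 1)
  expect_identical(accelerate_starts(sp, d, "cox", gamma = 1), sp)
  half <- accelerate_starts(sp, d, "cox", gamma = 0.5)
  expect_equal(length(half$points), 5L)
  expect_true(all(half$js %in% sp$js))
  # a strongly informative feature always survives the screen
  spec <- simulation_spec(n = 300, p = 8, true_support = 5,
                          true_effects = 2, censoring_fraction = 0.2,
                          seed = 35)
  ds <- simulate_cox_data(spec)
  mle2 <- optim(numeric(8),
                function(b) neg_log_partial_likelihood(b, ds),
                function(b) neg_log_partial_likelihood_gradient(b, ds),
                method = "BFGS")$par
  sp2 <- generate_starting_points(numeric(8), mle2, stage = 1)
  kept <- accelerate_starts(sp2, ds, "cox", gamma = 1 / length(sp2$points))
  expect_equal(kept$js, 5L)
})

test_that("path objective is non-increasing and runs are deterministic", {
  spec <- simulation_spec(n = 150, p = 6, true_support = c(2, 4),
                          true_effects = c(0.8, -0.8),
                          censoring_fraction = 0.3, seed = 36)
  d <- simulate_cox_data(spec)
  f1 <- fit_path(d, "cox", K_max = 4)
  obj <- vapply(f1$solutions, function(s) s$objective, numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
  for (i in 1:4) expect_lte(f1$solutions[[i]]$nnz, i)
  f2 <- fit_path(d, "cox", K_max = 4)
  expect_identical(f1, f2)
})

test_that("kit-grouped path bounds the kit count", {
  spec <- simulation_spec(n = 150, p = 6, true_support = c(1, 4),
                          true_effects = c(1, -1),
                          censoring_fraction = 0.2, seed = 37)
  d <- simulate_cox_data(spec)
  kits <- kit_structure(
    setNames(c("A", "A", "B", "B", "C", "C"), paste0("x", 1:6)),
    c(A = 10, B = 20, C = 30))
  fit <- fit_path(d, "cox", K_max = 2, grouping = kits)
  for (i in 1:2) {
    cf <- fit$solutions[[i]]$coefficients
    expect_lte(kit_l0(cf, kits, 1e-12), i)
    expect_equal(fit$solutions[[i]]$nnz, kit_l0(cf, kits, 1e-12))
  }
})

test_that("path summary round-trips through delimited text", {
  d <- tiny_surv(n = 80, p = 3, seed = 38)
  fit <- fit_path(d, "cox", K_max = 2)
  tmp <- tempfile(fileext = ".tsv")
  write_path_summary(fit, tmp)
  back <- read_path_summary(tmp)
  expect_equal(back, path_summary(fit))
})
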