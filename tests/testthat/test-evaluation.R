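test_that("leave-one-replicate-out splits partition every class evenly", {
  d <- tiny_dataset(classes = c("a", "b"), replicates = 2)
  plan <- make_loo_replicate_splits(d)
  expect_s3_class(plan, "split_plan")
  expect_length(plan$splits, 2)
  for (s in plan$splits) {
    expect_length(s$train, 2)
    expect_length(s$test, 2)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_len(4))
    # one held-out sample per class
    expect_setequal(d$labels[s$test], c("a", "b"))
  }
  # each sample tested exactly once
  tested <- sort(unlist(lapply(plan$splits, `[[`, "test")))
  expect_identical(tested, seq_len(n_samples(d)))

  unb <- labeled_dataset(d$samples[1:3], d$labels[1:3])
  expect_error(make_loo_replicate_splits(unb), "same number of samples")
})

test_that("fourfold splits are stratified, disjoint and exhaustive", {
  d <- tiny_dataset(classes = letters[1:4], replicates = 4)  # 16 samples
  plan <- make_fourfold_splits(d, seed = 3)
  expect_length(plan$splits, 4)
  for (s in plan$splits) {
    expect_length(s$test, 4)
    expect_setequal(d$labels[s$test], letters[1:4])  # one per class
  }
  tested <- sort(unlist(lapply(plan$splits, `[[`, "test")))
  expect_identical(tested, seq_len(16))

  # uneven totals: 5 classes x 8 = 40 -> all groups of 10, every class in each
  d2 <- tiny_dataset(classes = letters[1:5], replicates = 8)
  plan2 <- make_fourfold_splits(d2, seed = 1)
  sizes <- vapply(plan2$splits, function(s) length(s$test), integer(1))
  expect_equal(sum(sizes), 40)
  for (s in plan2$splits)
    expect_setequal(unique(d2$labels[s$test]), letters[1:5])

  small <- tiny_dataset(classes = c("a", "b"), replicates = 3)
  expect_error(make_fourfold_splits(small), ">= 4 samples per class")
})

test_that("evaluate_model reaches 100%/0 STD on separable data and reports in percent", {
  mod <- electrode_model(class_gain_sdlog = 1.2, class_magnitude_decades = 0,
                         class_gain_shared = 0, noise_sd = 0,
                         common_mode_gain = 5)
  d <- simulate_beverage_dataset(class_names = letters[1:4],
                                 concentrations = 1, replicates = 3,
                                 excitation = tiny_excitation(),
                                 model = mod, seed = 8)
  r <- evaluate_model(d, make_loo_replicate_splits(d), "fse", "kelm",
                      sigma = 1)
  expect_equal(r$mean_accuracy, 100)
  expect_equal(r$std_accuracy, 0)
  expect_true(all(r$per_split_accuracy == 1))

  # single split, all correct (every class represented in training)
  test1 <- c(3, 6, 9, 12)
  plan1 <- structure(list(splits = list(list(train = setdiff(1:12, test1),
                                             test = test1)),
                          protocol = "manual"), class = "split_plan")
  r1 <- evaluate_model(d, plan1, "fse", "kelm", sigma = 1)
  expect_equal(r1$mean_accuracy, 100)
  expect_equal(r1$std_accuracy, 0)
  expect_length(r1$per_split_accuracy, 1)
})

test_that("accuracy aggregation matches recomputation from predictions", {
  d <- tiny_dataset(classes = letters[1:3], replicates = 3, seed = 5)
  plan <- make_loo_replicate_splits(d)
  r <- evaluate_model(d, plan, "fse", "kelm", sigma = 1)
  per_split <- vapply(r$predictions, function(p) mean(p$truth == p$predicted),
                      numeric(1))
  expect_equal(per_split, r$per_split_accuracy)
  expect_equal(r$mean_accuracy, 100 * mean(per_split))
  expect_equal(r$std_accuracy, 100 * sd(per_split))
})

test_that("uninformative labels drop accuracy to chance level", {
  # all 7 "classes" share one generating distribution, so the labels carry
  # no information by construction and accuracy must sit near 1/7
  flat <- electrode_model(class_gain_sdlog = 0, class_tau_sdlog = 0,
                          class_magnitude_decades = 0, class_gain_shared = 0,
                          replicate_sdlog = 0.2, noise_sd = 0.05,
                          common_mode_gain = 5)
  accs <- vapply(1:10, function(i) {
    d <- simulate_beverage_dataset(class_names = letters[1:7],
                                   concentrations = 1, replicates = 3,
                                   excitation = tiny_excitation(),
                                   model = flat, seed = 200 + i)
    evaluate_model(d, make_loo_replicate_splits(d), "fse", "kelm",
                   sigma = 1)$mean_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 100 / 7 - 8)
  expect_lt(mean(accs), 100 / 7 + 8)
})

test_that("classifier training reads training rows only (no leakage)", {
  d <- tiny_dataset(classes = letters[1:3], replicates = 3, seed = 6)
  plan <- make_loo_replicate_splits(d)
  # poison one held-out sample of split 1; all other predictions of that
  # split must be unchanged
  j <- plan$splits[[1]]$test[1]
  poisoned <- d$samples
  poisoned[[j]] <- matrix(rnorm(length(d$samples[[j]]), sd = 100),
                          nrow = nrow(d$samples[[j]]))
  dp <- labeled_dataset(poisoned, d$labels, concentration = d$concentration,
                        replicate = d$replicate)
  r1 <- evaluate_model(d, plan, "fse", "kelm", sigma = 1)
  r2 <- evaluate_model(dp, plan, "fse", "kelm", sigma = 1)
  p1 <- r1$predictions[[1]]; p2 <- r2$predictions[[1]]
  keep <- p1$index != j
  expect_identical(p1$predicted[keep], p2$predicted[keep])
  # and the other splits never train on their own test rows either:
  # poisoning j only affects splits whose *test* set contains j
  for (s in 2:length(plan$splits)) {
    if (j %in% plan$splits[[s]]$train) next
    expect_identical(r1$predictions[[s]]$predicted,
                     r2$predictions[[s]]$predicted)
  }
})

test_that("baseline classifier adapters run with the stated settings", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("randomForest")
  skip_if_not_installed("MASS")
  mod <- electrode_model(class_gain_sdlog = 0.8, class_magnitude_decades = 0,
                         class_gain_shared = 0, common_mode_gain = 5,
                         noise_sd = 0.005)
  d <- simulate_beverage_dataset(class_names = letters[1:3],
                                 concentrations = 1, replicates = 3,
                                 excitation = tiny_excitation(),
                                 model = mod, seed = 9)
  plan <- make_loo_replicate_splits(d)
  for (cls in c("svm", "rf", "lda", "nb")) {
    r <- evaluate_model(d, plan, "fse", cls, sigma = 1)
    expect_true(r$mean_accuracy >= 0 && r$mean_accuracy <= 100)
  }
})

test_that("sensitivity sweeps cover the grid and record failures", {
  d <- tiny_dataset(classes = letters[1:3], replicates = 3, seed = 7)
  plan <- make_loo_replicate_splits(d)
  grid <- c(0.1, 1, 10)
  sw <- sensitivity_sweep("sigma", grid, d, plan)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$value, grid)
  expect_true(all(sw$ok))

  # single-point grid equals a direct evaluation, for every parameter
  r_ref <- evaluate_model(d, plan, "fse", "kelm", sigma = 2, mu = 50,
                          theta = 3)
  for (par in c("sigma", "gamma", "theta")) {
    v <- switch(par, sigma = 2, gamma = 50, theta = 3)
    one <- sensitivity_sweep(par, v, d, plan, sigma = 2, mu = 50, theta = 3)
    expect_equal(one$mean_accuracy, r_ref$mean_accuracy)
    expect_equal(one$std_accuracy, r_ref$std_accuracy)
  }

  # permuting the grid permutes the rows identically
  sw2 <- sensitivity_sweep("sigma", rev(grid), d, plan)
  expect_equal(sw2[3:1, -1], sw[, -1], ignore_attr = TRUE)

  # degenerate features at extreme parameters (all saturate to 0/1, so
  # within-group variance vanishes) are recorded, not dropped
  skip_if_not_installed("MASS")
  mod <- electrode_model(class_gain_sdlog = 0.8, class_magnitude_decades = 0,
                         class_gain_shared = 0, common_mode_gain = 5,
                         noise_sd = 0.005)
  dl <- simulate_beverage_dataset(class_names = letters[1:3],
                                  concentrations = 1, replicates = 3,
                                  excitation = tiny_excitation(),
                                  model = mod, seed = 10)
  bad <- sensitivity_sweep("sigma", c(1e-12, 1), dl,
                           make_loo_replicate_splits(dl), classifier = "lda")
  expect_false(bad$ok[1])
  expect_match(bad$note[1], ".+")
  expect_true(bad$ok[2])
})
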