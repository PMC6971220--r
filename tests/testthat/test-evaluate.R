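test_that("stratified k-fold balances classes, covers all subjects, is seeded", {
  labels <- rep(c("ASD", "TC"), each = 10)
  plan <- stratified_kfold(labels, k = 10, seed = 3)
  expect_equal(nrow(plan), 10L)
  for (f in 1:10) {
    te <- plan$test[[f]]
    expect_equal(length(te), 2L)
    expect_equal(sum(labels[te] == "ASD"), 1L)    # exact divisibility
    expect_equal(length(intersect(plan$train[[f]], te)), 0L)
  }
  all_test <- sort(unlist(plan$test))
  expect_equal(all_test, 1:20)                     # disjoint cover

  plan2 <- stratified_kfold(labels, k = 10, seed = 3)
  expect_identical(plan$test, plan2$test)

  # uneven classes stay within one subject of global proportions
  labels2 <- c(rep("ASD", 13), rep("TC", 8))
  plan3 <- stratified_kfold(labels2, k = 4, seed = 1)
  asd_counts <- vapply(plan3$test, function(i) sum(labels2[i] == "ASD"), 1L)
  expect_lte(diff(range(asd_counts)), 1L)
  expect_error(stratified_kfold(labels2, k = 10), class = "conncnn_data_error")
})

test_that("leave-site-out builds one lexicographically ordered fold per site", {
  sites <- c("B", "A", "B", "A", "B", "C")
  plan <- leave_site_out(sites)
  expect_equal(plan$fold_label, c("A", "B", "C"))
  expect_equal(lengths(plan$test), c(2L, 3L, 1L))
  expect_equal(plan$test[[1]], which(sites == "A"))
  expect_error(leave_site_out(rep("A", 5)), class = "conncnn_data_error")
  expect_equal(nrow(leave_site_out(paste0("S", rep(1:17, each = 2)))), 17L)
})

test_that("compute_metrics reproduces a hand-built confusion matrix", {
  y <- c(1, 1, 0, 0)
  pred <- c(1, 0, 0, 0)            # TP=1, FN=1, TN=2, FP=0
  probs <- cbind(1 - pred, pred)
  fr <- compute_metrics(y, probs)
  expect_equal(fr$accuracy, 0.75)
  expect_equal(fr$sensitivity, 0.5)
  expect_equal(fr$specificity, 1.0)
  expect_equal(fr$f_score, 2 / 3)
  expect_equal(c(fr$tn, fr$fp, fr$fn, fr$tp), c(2L, 0L, 1L, 1L))
  expect_equal(fr$tn + fr$fp + fr$fn + fr$tp, fr$n)
})

test_that("perfect, uninformative and single-class cases behave", {
  y <- c(1, 1, 0, 0)
  perfect <- cbind(1 - y, y)
  fr <- compute_metrics(y, perfect)
  expect_equal(unlist(fr[c("accuracy", "sensitivity", "specificity",
                           "f_score", "auc")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 f_score = 1, auc = 1))

  flat <- matrix(0.5, 4, 2)
  expect_equal(compute_metrics(y, flat)$auc, 0.5)   # ties handled by midrank

  one_class <- compute_metrics(c(1, 1, 1), matrix(c(0.4, 0.6), 3, 2,
                                                  byrow = TRUE))
  expect_true(is.na(one_class$specificity))
  expect_true(is.na(one_class$auc))
  expect_false(is.na(one_class$sensitivity))
})

test_that("accuracy times n equals TP + TN exactly across random folds", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p1 <- runif(n)
    fr <- compute_metrics(y, cbind(1 - p1, p1))
    expect_equal(fr$accuracy * fr$n, fr$tp + fr$tn)
  }
})

test_that("rank AUC equals pROC and is invariant to monotone transforms", {
  set.seed(5)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(60) + 0.3 * y
  fr <- compute_metrics(y, cbind(1 - s, s))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(fr$auc, ref, tolerance = 1e-12)

  warped <- compute_metrics(y, cbind(1 - plogis(5 * s), plogis(5 * s)))
  expect_equal(warped$auc, fr$auc, tolerance = 1e-12)
  expect_equal(compute_metrics(y, cbind(1 - y, y))$auc, 1)

  # area under the roc_points polyline equals the rank AUC
  pts <- roc_points(y, s)
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, fr$auc, tolerance = 1e-12)
})

test_that("Wald CI matches hand values, peaks at p = 0.5, shrinks with n", {
  expect_equal(wald_ci(0.5, 100), 1.96 * 0.05)
  expect_equal(wald_ci(0, 10), 0)
  expect_equal(wald_ci(1, 10), 0)
  expect_equal(round(wald_ci(0.65, 175), 2), 0.07)
  p_grid <- seq(0.05, 0.95, by = 0.05)
  expect_equal(p_grid[which.max(wald_ci(p_grid, 50))], 0.5)
  expect_true(all(diff(wald_ci(0.3, c(10, 50, 100, 500))) < 0))
})

test_that("mean rows aggregate folds unweighted (and size-weighted on request)", {
  folds <- tibble::tibble(
    fold_label = c("1", "2"), n = c(10L, 30L),
    accuracy = c(0.6, 0.8), ci_halfwidth = c(0.1, 0.1),
    sensitivity = c(0.5, 0.9), specificity = c(0.7, 0.7),
    f_score = c(0.55, 0.85), auc = c(0.6, 0.9))
  mean_row <- aggregate_mean_row(folds)
  expect_equal(mean_row$accuracy, 0.7)
  expect_equal(mean_row$f_score, 0.7)
  weighted <- aggregate_mean_row(folds, "size")
  expect_equal(weighted$accuracy, (0.6 * 10 + 0.8 * 30) / 40)

  single <- aggregate_mean_row(folds[1, ])
  expect_equal(single$accuracy, folds$accuracy[1])

  # NA metrics are dropped per column, not propagated
  folds$specificity[2] <- NA
  expect_equal(aggregate_mean_row(folds)$specificity, 0.7)
})

test_that("cross_validate with the constant-majority stub matches the closed form", {
  sim <- simulate_connectomes(sim_config(n_per_group = 15, n_rois = 8,
                                         planted_rois = 1:2, seed = 6))
  # unbalance the cohort so the majority class is nontrivial
  cohort <- sim$cohort[c(1:15, 16:25), ]
  conns <- sim$connectomes[c(1:15, 16:25)]
  plan <- stratified_kfold(cohort$diagnosis, k = 5, seed = 2)
  rep <- cross_validate(cohort, conns, plan, classifier = majority_classifier)
  y <- as.integer(cohort$diagnosis == "ASD")
  for (f in 1:5) {
    tr <- plan$train[[f]]; te <- plan$test[[f]]
    maj <- as.integer(mean(y[tr]) >= 0.5)
    expect_equal(rep$folds$accuracy[f], mean(y[te] == maj))
  }
  # the mean row is exactly the unweighted mean of fold metrics
  expect_equal(rep$mean_row$accuracy, mean(rep$folds$accuracy), tolerance = 0)
  expect_equal(rep$mean_row$f_score, mean(rep$folds$f_score), tolerance = 0)

  # tidy/glance expose the fold table and the summary
  expect_equal(nrow(tidy(rep)), 5L)
  expect_equal(glance(rep)$n_folds, 5L)
})

test_that("planted-effect CV accuracy is monotone in effect size", {
  mc <- model_config(n_rois = 32, branch_lengths = 1:2, n_filters = 16)
  mean_acc <- vapply(c(0, 0.6, 1.2), function(delta) {
    accs <- vapply(0:1, function(seed) {
      sim <- simulate_connectomes(sim_config(n_per_group = 50, n_rois = 32,
                                             planted_rois = 1:6,
                                             delta = delta, seed = seed))
      plan <- stratified_kfold(sim$cohort$diagnosis, k = 3, seed = seed)
      cross_validate(sim$cohort, sim$connectomes, plan, mc,
                     train_config(epochs = 20, batch_size = 8,
                                  seed = seed))$mean_row$accuracy
    }, 0)
    mean(accs)
  }, 0)
  expect_gte(mean_acc[2], mean_acc[1] - 0.1)   # monotone up to seed noise
  expect_gte(mean_acc[3], mean_acc[2] - 0.1)
  expect_gt(mean_acc[3], 0.8)
  expect_lt(mean_acc[1], 0.65)
})

test_that("leave-site-out stays at chance when only site effects exist", {
  sim <- simulate_connectomes(sim_config(n_per_group = 50, n_rois = 32,
                                         planted_rois = 1:6, delta = 0,
                                         n_sites = 4, site_sd = 0.5,
                                         seed = 8))
  plan <- leave_site_out(sim$cohort$site_id)
  mc <- model_config(n_rois = 32, branch_lengths = 1:2, n_filters = 16)
  rep <- cross_validate(sim$cohort, sim$connectomes, plan, mc,
                        train_config(epochs = 15, seed = 8))
  expect_gt(rep$mean_row$accuracy, 0.3)
  expect_lt(rep$mean_row$accuracy, 0.7)
})
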