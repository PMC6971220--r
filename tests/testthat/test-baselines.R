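test_that("default specs reproduce the reference settings and grids", {
  specs <- default_specs()
  expect_equal(specs$before$svm$fixed_params, list(kernel = "rbf", C = 8))
  expect_equal(specs$before$knn$fixed_params, list(k = 20))
  expect_equal(specs$before$rf$fixed_params,
               list(max_nodes = 300, n_trees = 100))

  expect_equal(specs$after$knn$grid$k, seq(4L, 40L, by = 4L))
  expect_length(specs$after$knn$grid$k, 10L)
  expect_equal(specs$after$svm$grid$kernel,
               c("linear", "rbf", "poly", "sigmoid"))
  rf_grid <- expand.grid(specs$after$rf$grid)
  expect_equal(nrow(rf_grid), 81L)                 # 9 x 9
  expect_equal(range(rf_grid$max_nodes), c(120L, 600L))
  expect_equal(range(rf_grid$n_trees), c(20L, 180L))
})

# small, linearly separable feature construction shared below: a planted
# block of edges keeps the signal subspace dominant after standardization
separable_sim <- function(n = 20, R = 10, gap = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(c("ASD", "TC"), each = n / 2)
  conns <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(R * R, sd = 0.1), R, R)
    m <- (m + t(m)) / 2
    if (labels[i] == "ASD") m[1:4, 1:4] <- m[1:4, 1:4] + gap
    diag(m) <- 1
    m
  })
  cohort <- tibble::tibble(subject_id = paste0("s", seq_len(n)),
                           site_id = rep_len(c("A", "B"), n),
                           diagnosis = factor(labels, levels = c("TC", "ASD")),
                           mean_fd = 0.1)
  list(cohort = cohort, connectomes = conns)
}

test_that("grid search returns a grid member, perfect accuracy when separable", {
  dat <- separable_sim()
  features <- do.call(rbind, lapply(dat$connectomes, vectorize_upper_triangle))
  plan <- stratified_kfold(dat$cohort$diagnosis, k = 4, seed = 1)
  spec <- baseline_spec("svm", grid = list(kernel = "linear", C = c(1, 4)),
                        seed = 1)
  gs <- grid_search(spec, features, dat$cohort$diagnosis, plan)
  expect_true(gs$best_params$C %in% c(1, 4))
  expect_equal(gs$best_params$kernel, "linear")
  expect_equal(gs$report$mean_row$accuracy, 1.0)
  expect_equal(nrow(gs$search), 2L)

  gs2 <- grid_search(spec, features, dat$cohort$diagnosis, plan)
  expect_identical(gs$best_params, gs2$best_params)
  expect_identical(gs$report$folds, gs2$report$folds)
})

test_that("knn fold metrics are invariant to a joint feature/label shuffle", {
  dat <- separable_sim(n = 16, seed = 3)
  features <- do.call(rbind, lapply(dat$connectomes, vectorize_upper_triangle))
  y <- dat$cohort$diagnosis
  plan <- stratified_kfold(y, k = 4, seed = 5)
  spec <- baseline_spec("knn", fixed_params = list(k = 3), seed = 2)

  run_knn <- function(features, y, plan) {
    fold_seeds <- conncnn:::with_seed(2L, sample.int(1e6, nrow(plan)))
    conncnn:::baseline_cv("knn", list(k = 3), features,
                          conncnn:::encode_labels(y), plan, fold_seeds)
  }
  base <- run_knn(features, y, plan)

  set.seed(9)
  perm <- sample(nrow(features))
  plan_perm <- plan
  inv <- match(seq_along(perm), perm)
  plan_perm$train <- lapply(plan$train, function(i) inv[i])
  plan_perm$test <- lapply(plan$test, function(i) inv[i])
  shuffled <- run_knn(features[perm, ], y[perm], plan_perm)
  expect_equal(base$folds$accuracy, shuffled$folds$accuracy)
})

test_that("evaluate_baselines reports mean and variance; tuning does not hurt", {
  sim <- simulate_connectomes(sim_config(n_per_group = 20, n_rois = 16,
                                         planted_rois = 1:4, delta = 1.2,
                                         seed = 4))
  plan <- stratified_kfold(sim$cohort$diagnosis, k = 3, seed = 4)
  # compact grids keep the search cheap while exercising the machinery
  specs <- list(
    before = default_specs(seed = 4)$before,
    after = list(
      svm = baseline_spec("svm", grid = list(kernel = c("linear", "rbf"),
                                             C = c(1, 8)), seed = 4),
      knn = baseline_spec("knn", grid = list(k = c(4, 12, 20)), seed = 4),
      rf = baseline_spec("rf", grid = list(max_nodes = c(120, 300),
                                           n_trees = c(60, 100)), seed = 4)))
  res <- evaluate_baselines(sim$cohort, sim$connectomes, plan, specs)
  expect_equal(nrow(res), 6L)
  expect_setequal(res$classifier, c("svm", "knn", "rf"))
  expect_true(all(c("mean_accuracy", "var_accuracy", "mean_sensitivity",
                    "var_sensitivity", "mean_specificity", "var_specificity",
                    "mean_auc", "var_auc", "mean_f_score", "var_f_score")
                  %in% names(res)))
  for (k in c("svm", "knn", "rf")) {
    bo <- res$mean_accuracy[res$classifier == k & res$stage == "before"]
    ao <- res$mean_accuracy[res$classifier == k & res$stage == "after"]
    expect_gte(ao, bo - 0.05)
  }
})

test_that("baselines sit in the chance band on a null simulation", {
  sim <- simulate_connectomes(sim_config(n_per_group = 30, n_rois = 16,
                                         planted_rois = 1:4, delta = 0,
                                         seed = 5))
  plan <- stratified_kfold(sim$cohort$diagnosis, k = 3, seed = 5)
  res <- evaluate_baselines(sim$cohort, sim$connectomes, plan,
                            default_specs(seed = 5), stages = "before")
  expect_true(all(res$mean_accuracy > 0.3 & res$mean_accuracy < 0.7))
})

test_that("degenerate single-class training folds error", {
  dat <- separable_sim(n = 8, seed = 6)
  features <- do.call(rbind, lapply(dat$connectomes, vectorize_upper_triangle))
  plan <- stratified_kfold(dat$cohort$diagnosis, k = 2, seed = 1)
  plan$train[[1]] <- which(dat$cohort$diagnosis == "ASD")  # force one class
  fold_seeds <- c(1L, 2L)
  expect_error(
    conncnn:::baseline_cv("svm", list(kernel = "rbf", C = 8), features,
                          conncnn:::encode_labels(dat$cohort$diagnosis),
                          plan, fold_seeds),
    class = "conncnn_data_error")
})
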