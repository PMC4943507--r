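test_that("auto fold count follows the small-class rule", {
  labs_small <- rep(c("a", "b"), c(9, 30))
  folds <- stratified_folds(labs_small, "auto", seed = 1)
  expect_length(folds, 3)
  labs_big <- rep(c("a", "b"), c(12, 30))
  expect_length(stratified_folds(labs_big, "auto", seed = 1), 10)
})

test_that("folds partition the samples and stratify perfectly when possible", {
  labs <- rep(c("a", "b", "c"), each = 10)
  folds <- stratified_folds(labs, 10, seed = 2)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_along(labs))
  expect_equal(sum(lengths(tests)), length(labs))   # disjoint + exhaustive
  for (f in folds) {
    expect_length(f$test, 3)
    expect_equal(sort(labs[f$test]), c("a", "b", "c"))
    expect_setequal(c(f$train, f$test), seq_along(labs))
  }
})

test_that("classes below the fold count trigger the leave-one-out fallback", {
  labs <- rep(c("a", "b"), c(2, 20))
  expect_warning(folds <- stratified_folds(labs, "auto", seed = 1),
                 "leave-one-out")
  expect_length(folds, 22)
  expect_error(stratified_folds(labs, 5, seed = 1), "auto")
})

test_that("folds are reproducible from the seed", {
  labs <- rep(c("a", "b", "c"), c(12, 15, 20))
  expect_identical(stratified_folds(labs, 3, seed = 5),
                   stratified_folds(labs, 3, seed = 5))
})

test_that("accuracy is the percentage of exact matches", {
  expect_equal(accuracy_pct(c("a", "b"), c("a", "b")), 100)
  expect_equal(accuracy_pct(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy_pct(rep("a", 10), rep(c("a", "b"), c(7, 3))), 70)
  expect_error(accuracy_pct("a", c("a", "b")), "lengths differ")
})

test_that("macro AUC handles perfect, uninformative and random scorers", {
  y <- rep(c("a", "b", "c"), each = 4)
  perfect <- sapply(c("a", "b", "c"), function(cl) as.numeric(y == cl))
  expect_equal(as.numeric(multiclass_auc(y, perfect)), 100)
  flat <- matrix(0.5, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(as.numeric(multiclass_auc(y, flat)), 50)
  set.seed(3)
  for (rep in 1:10) {
    conf <- matrix(runif(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
    got <- multiclass_auc(y, conf)
    want <- 100 * mean(sapply(c("a", "b", "c"), function(cl)
      oracle_auc(y == cl, conf[, cl])))
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
})

test_that("macro AUC skips absent classes with a warning and reads conf_ names", {
  y <- rep(c("a", "b"), each = 5)
  conf <- matrix(runif(30), 10, 3,
                 dimnames = list(NULL, c("conf_a", "conf_b", "conf_c")))
  expect_warning(auc <- multiclass_auc(y, conf), "no true samples.*c")
  expect_length(attr(auc, "per_class"), 2)
})

test_that("metrics are invariant to class renaming", {
  y <- rep(c("a", "b"), c(4, 6))
  set.seed(4)
  conf <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  pred <- ifelse(conf[, 1] > conf[, 2], "a", "b")
  y2 <- ifelse(y == "a", "x", "y")
  conf2 <- conf; colnames(conf2) <- c("x", "y")
  pred2 <- ifelse(pred == "a", "x", "y")
  expect_equal(accuracy_pct(y, pred), accuracy_pct(y2, pred2))
  expect_equal(as.numeric(multiclass_auc(y, conf)),
               as.numeric(multiclass_auc(y2, conf2)))
})

test_that("per-class recall reports one entry per true class", {
  y <- c("a", "a", "b", "b", "b")
  p <- c("a", "b", "b", "b", "a")
  r <- per_class_recall(y, p)
  expect_equal(r, c(a = 50, b = 200 / 3))
})

test_that("cross-validated evaluation returns sane, reproducible rows", {
  sim <- simulate_expression(c(16, 8, 8), n_features = 60, n_informative = 5,
                             effect_size = 3, seed = 14)
  cfg <- run_config(n_features = 6, cv_folds = 3, seed = 9)
  row <- iefs_cv(sim$data, cfg)
  expect_gte(row$accuracy, 0); expect_lte(row$accuracy, 100)
  expect_gte(row$auc, 0); expect_lte(row$auc, 100)
  expect_length(row$per_class_recall[[1]], 3)
  expect_equal(iefs_cv(sim$data, cfg), row)
  # strong planted signal should classify well above chance
  expect_gt(row$accuracy, 60)
})

test_that("a one-cell benchmark grid equals the directly computed CV row plus baseline", {
  sim <- simulate_expression(c(14, 7), n_features = 40, n_informative = 4,
                             effect_size = 3, seed = 15)
  rep <- iefs_benchmark(sim$data, selectors = "ranking", samplers = "none",
                        T_steps = 1, n_features = 10, classifiers = "knn",
                        cv_folds = 3, seed = 4)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$selector, c("ranking", "baseline-all-features"))
  direct <- iefs_cv(sim$data,
                    run_config(selector = "ranking", sampler = "none",
                               T_steps = 1, n_features = 10, cv_folds = 3,
                               seed = 4 + 13),
                    folds = stratified_folds(sim$data$class, 3, seed = 4))
  expect_equal(rep$accuracy[1], direct$accuracy)
  expect_equal(rep$auc[1], direct$auc)
})

test_that("benchmark reports re-run byte-identically and write as TSV", {
  sim <- simulate_expression(c(10, 6, 6), n_features = 30, n_informative = 3,
                             effect_size = 2.5, seed = 16)
  run <- function() {
    iefs_benchmark(sim$data, selectors = "ranking",
                   samplers = c("none", "oversample"),
                   T_steps = 1, n_features = c(5, 10), classifiers = "knn",
                   cv_folds = 3, seed = 2)
  }
  r1 <- run(); r2 <- run()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(r1, p1); write_benchmark(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  tab <- readr::read_tsv(p1, show_col_types = FALSE)
  expect_equal(nrow(tab), 5)   # 2 samplers x 2 sizes + baseline
  expect_true(all(c("selector", "sampler", "n_features", "accuracy", "auc")
                  %in% names(tab)))
})

test_that("benchmark records per-cell failures without aborting the run", {
  sim <- simulate_expression(c(10, 6), n_features = 20, n_informative = 3,
                             effect_size = 2, seed = 17)
  # n_features = 19 with fcbf forces short signatures but should not error;
  # build an error instead via an impossible mrmr window by shrinking data
  rep <- iefs_benchmark(sim$data, selectors = c("ranking"),
                        samplers = "none", T_steps = 1,
                        n_features = c(5, 50), classifiers = "knn",
                        cv_folds = 3, seed = 1)
  # 50 > 20 features is filtered out of the grid rather than failing
  expect_true(all(is.na(rep$error)))
  expect_setequal(rep$n_features[rep$selector == "ranking"], 5)
})

test_that("autoplot and tidy work on a benchmark report", {
  sim <- simulate_expression(c(10, 6), n_features = 20, n_informative = 3,
                             effect_size = 2.5, seed = 18)
  rep <- iefs_benchmark(sim$data, selectors = "ranking", samplers = "none",
                        T_steps = 1, n_features = c(5, 10),
                        classifiers = "knn", cv_folds = 3, seed = 3)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  long <- generics::tidy(rep)
  expect_true(all(c("class", "recall") %in% names(long)))
  expect_equal(nrow(long), 3 * 2)   # 3 rows x 2 classes
})
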