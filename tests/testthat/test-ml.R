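separable_data <- function(n = 60, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 5), ncol = 5),
             matrix(rnorm(n * 5, mean = 8), ncol = 5))
  colnames(x) <- paste0("f", 1:5)
  list(x = x, y = factor(rep(c("A", "B"), each = n)))
}

test_that("every classifier family is perfect on separable classes", {
  d <- separable_data()
  for (alg in vm4:::vm_algorithms()) {
    r <- run_task(d$x, d$y, task = c("A", "B"), algorithm = alg,
                  n_repeats = 2, seed = 1)
    expect_equal(r$mean, 1, info = alg)
  }
})

test_that("shuffled four-way labels drop precision to chance", {
  coh <- default_cohort()
  views <- ml_feature_views(coh$otu, default_metrics())
  set.seed(4)
  shuffled <- sample(as.character(cohort_types(coh)))
  r <- run_task(views$metric10, shuffled, 7, "random_forest",
                n_repeats = 3, seed = 2)
  expect_lt(abs(r$mean - 0.25), 0.05)
})

test_that("repeated runs with one seed reproduce the precision sequence", {
  coh <- default_cohort()
  views <- ml_feature_views(coh$otu, default_metrics())
  truth <- cohort_types(coh)
  r1 <- run_task(views$metric10, truth, "task4_HS_vs_BVS", "random_forest",
                 n_repeats = 3, seed = 11)
  r2 <- run_task(views$metric10, truth, "task4_HS_vs_BVS", "random_forest",
                 n_repeats = 3, seed = 11)
  expect_identical(r1$precision, r2$precision)
})

test_that("task selection enforces minimum class sizes", {
  d <- separable_data(n = 10)
  expect_error(run_task(d$x, d$y, c("A", "B"), "knn", n_repeats = 1),
               "at least 20 samples")
})

test_that("external evaluation predicts a copy of training data perfectly", {
  d <- separable_data()
  model <- fit_classifier(d$x, d$y, "random_forest", seed = 1)
  ev <- external_eval(model, d$x, d$y)
  expect_equal(ev$precision, 1)
  expect_error(external_eval(model, d$x[0, ], character(0)), "empty external")
})

test_that("external cohorts from another seed generalize on the metric view", {
  coh <- default_cohort()
  views <- ml_feature_views(coh$otu, default_metrics())
  truth <- cohort_types(coh)
  model <- fit_classifier(views$metric10, truth, "random_forest", seed = 1)
  internal <- run_task(views$metric10, truth, 7, "random_forest",
                       n_repeats = 3, seed = 5)
  coh2 <- generate_cohort(seed = 99)
  v2 <- ml_feature_views(coh2$otu)
  ev <- external_eval(model, v2$metric10, cohort_types(coh2))
  expect_lt(abs(ev$precision - internal$mean), 0.05)
})

test_that("OTU-view prediction aligns external taxa by name with zero fill", {
  coh <- default_cohort()
  views <- ml_feature_views(coh$otu)
  truth <- cohort_types(coh)
  model <- fit_classifier(views$otu, truth, "random_forest", seed = 1)
  coh2 <- generate_cohort(seed = 99)
  v2 <- ml_feature_views(coh2$otu)
  set.seed(6)
  sub <- v2$otu[, sample(colnames(v2$otu), 150)]
  ev <- external_eval(model, sub, cohort_types(coh2)[rownames(sub)])
  expect_gte(ev$precision, 0.9)
})

test_that("the dense net learns a nonlinear boundary and is reproducible", {
  set.seed(8)
  n <- 120
  x <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("u", "v")))
  y <- factor(ifelse(x[, 1]^2 + x[, 2]^2 > 1.2, "out", "in"))
  m1 <- mlp_train(x, y, max_epochs = 200, seed = 4)
  expect_gte(mean(predict(m1, x) == y), 0.9)
  m2 <- mlp_train(x, y, max_epochs = 200, seed = 4)
  expect_identical(predict(m1, x), predict(m2, x))
  pr <- predict(m1, x, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, n))
})
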