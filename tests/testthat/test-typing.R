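make_blobs <- function(n = 40, sep = 6, seed = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 10), ncol = 10),
             matrix(rnorm(n * 10, mean = sep), ncol = 10))
  colnames(x) <- vm4:::metric10_names()
  list(x = as.data.frame(x), truth = rep(1:2, each = n))
}

test_that("dichotomize separates two well-separated blobs exactly", {
  b <- make_blobs()
  cl <- dichotomize(b$x, seed = 11)
  expect_equal(mclust::adjustedRandIndex(cl, b$truth), 1)
})

test_that("dichotomize is deterministic and duplication-invariant", {
  b <- make_blobs(seed = 4)
  cl1 <- dichotomize(b$x, seed = 7)
  cl2 <- dichotomize(b$x, seed = 7)
  expect_identical(as.integer(cl1), as.integer(cl2))
  dup <- rbind(b$x, b$x)
  cld <- dichotomize(dup, seed = 7)
  n <- nrow(b$x)
  # same partition structure on both copies
  expect_equal(mclust::adjustedRandIndex(cld[seq_len(n)], cld[n + seq_len(n)]), 1)
  expect_equal(mclust::adjustedRandIndex(cld[seq_len(n)], b$truth), 1)
})

test_that("identical rows degrade to a single cluster with a warning", {
  x <- as.data.frame(matrix(1, 6, 10,
                            dimnames = list(NULL, vm4:::metric10_names())))
  expect_warning(cl <- dichotomize(x), "single cluster")
  expect_equal(unique(as.integer(cl)), 1L)
})

test_that("complex/simple labelling follows diversity then dominance", {
  met <- data.frame(hill_q1 = c(8.1, 8.0, 2.3, 2.4),
                    D_c = c(126, 130, 314, 310))
  lab <- label_complex_simple(c(1, 1, 2, 2), met)
  expect_equal(unname(lab["1"]), "complex")
  expect_equal(unname(lab["2"]), "simple")
  # tie on hill_q1 breaks toward lower dominance
  met2 <- data.frame(hill_q1 = c(5, 5, 5, 5), D_c = c(126, 126, 314, 314))
  lab2 <- label_complex_simple(c(1, 1, 2, 2), met2)
  expect_equal(unname(lab2["1"]), "complex")
  # relabelled cluster ids: labels follow the statistics, not the ids
  lab3 <- label_complex_simple(c(2, 2, 1, 1), met)
  expect_equal(unname(lab3["2"]), "complex")
})

test_that("four-type assignment crisscrosses health and structure", {
  md <- data.frame(sample_id = c("a", "b", "c", "d"),
                   health_status = c("healthy", "healthy", "BV", "BV"))
  st <- c(a = "complex", b = "simple", c = "complex", d = "simple")
  out <- assign_four_types(md, st)
  expect_equal(as.character(out$vm_type), c("HC", "HS", "BVC", "BVS"))
  expect_error(assign_four_types(md, st[1:3]), "missing structure label")
})

test_that("typing recovers the planted four types on the synthetic cohort", {
  coh <- default_cohort()
  ty <- vm_type_samples(coh$otu, coh$metadata, seed = 42,
                        metrics = default_metrics())
  truth <- cohort_types(coh)[ty$sample_id]
  agreement <- mean(as.character(ty$vm_type) == truth)
  expect_gte(agreement, 0.95)
  # recovered complex groups are more diverse and less dominant than simple
  met <- attr(ty, "metrics")
  for (hs in c("healthy", "BV")) {
    idx <- ty$health_status == hs
    cx <- ty$structure[idx] == "complex"
    expect_lt(stats::wilcox.test(met$hill_q1[idx][cx],
                                 met$hill_q1[idx][!cx],
                                 alternative = "greater")$p.value, 0.05)
    expect_lt(stats::wilcox.test(met$D_c[idx][cx], met$D_c[idx][!cx],
                                 alternative = "less")$p.value, 0.05)
  }
})
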