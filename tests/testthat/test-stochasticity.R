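test_that("the neutral fit recovers the migration parameter it simulates", {
  neu <- generate_neutral_metacommunity(n_samples = 60, Nm = 500,
                                        depth = 20000, seed = 3)
  fit <- fit_sloan_neutral(neu)
  expect_lt(abs(fit$Nm - 500) / 500, 0.20)
  expect_gte(fit$fractions[["f_neutral"]], 0.9)
  expect_equal(sum(fit$fractions), 1)
  expect_gte(fit$r_squared, 0.8)
})

test_that("two seeds give different tables but compatible Nm estimates", {
  n1 <- generate_neutral_metacommunity(n_samples = 50, Nm = 300, seed = 11)
  n2 <- generate_neutral_metacommunity(n_samples = 50, Nm = 300, seed = 12)
  expect_false(identical(unclass(n1), unclass(n2)))
  f1 <- fit_sloan_neutral(n1); f2 <- fit_sloan_neutral(n2)
  expect_lt(abs(f1$Nm - f2$Nm) / 300, 0.4)
  expect_lt(abs(f1$Nm - 300) / 300, 0.2)
})

test_that("species forced present everywhere are classified above-neutral", {
  neu <- unclass(generate_neutral_metacommunity(n_samples = 60, Nm = 200,
                                                depth = 5000, seed = 5))
  # force 30% of the taxa to occur in every sample regardless of abundance
  set.seed(44)
  forced <- sample(nrow(neu), 30)
  neu[forced, ] <- pmax(neu[forced, ], 1L)
  fit <- fit_sloan_neutral(neu)
  sub <- fit$species[match(rownames(neu)[forced], fit$species$taxon), ]
  # abundant taxa are expected near frequency 1 anyway; the planted signal
  # is detectable where the neutral expectation is clearly below 1
  informative <- sub$predicted < 0.7
  expect_gte(sum(informative), 5)
  expect_gte(mean(sub$class[informative] == "above"), 0.8)
})

test_that("degenerate neutral-model inputs are rejected", {
  one <- matrix(5L, 1, 12, dimnames = list("t1", sprintf("s%02d", 1:12)))
  expect_error(fit_sloan_neutral(one), "fewer than 2 detected taxa")
  expect_error(fit_sloan_neutral(homogeneous_pool(5, 100)), "at least 10 samples")
})

test_that("fisher class test is symmetric, exact, and null on identical fits", {
  fake_fit <- function(n_below, n_neutral, n_above) {
    cls <- rep(c("below", "neutral", "above"), c(n_below, n_neutral, n_above))
    structure(list(species = data.frame(class = cls)), class = "neutral_fit")
  }
  expect_equal(fisher_species_class_test(fake_fit(10, 30, 10),
                                         fake_fit(10, 30, 10))$p_value, 1)
  r <- fisher_species_class_test(fake_fit(100, 0, 0), fake_fit(0, 100, 0))
  expect_lte(r$p_value, 1e-6)
  a <- fake_fit(12, 40, 8); b <- fake_fit(30, 20, 10)
  expect_equal(fisher_species_class_test(a, b)$p_value,
               fisher_species_class_test(b, a)$p_value)
})

test_that("NSR separates stochastic from deterministic assembly", {
  iid <- homogeneous_pool(40, 5000, n_taxa = 80, conc = 0.4, seed = 17)
  r1 <- nsr(iid, n_sim = 60, seed = 5)
  expect_gte(r1$nsr, 0.7)
  blk <- block_metacommunity()
  r2 <- nsr(blk, n_sim = 60, seed = 5)
  expect_lte(r2$nsr, 0.3)
  for (r in list(r1, r2)) {
    expect_gte(r$nsr, 0); expect_lte(r$nsr, 1)
  }
  # bray-curtis route stays in bounds and keeps the ordering
  r1b <- nsr(iid, "bray-curtis", n_sim = 30, seed = 5)
  r2b <- nsr(blk, "bray-curtis", n_sim = 30, seed = 5)
  expect_gte(r1b$nsr, 0); expect_lte(r1b$nsr, 1)
  expect_gt(r1b$nsr, r2b$nsr)
})

test_that("identical samples trigger the degenerate-similarity warning", {
  m <- matrix(rep(c(5L, 3L, 2L, 0L), 4), 4,
              dimnames = list(letters[1:4], sprintf("s%d", 1:4)))
  expect_warning(nsr(m, n_sim = 10, seed = 1), "identical")
})
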