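spec_fixture <- function() {
  # 4 types x 3 samples each; crafted presence/abundance patterns
  types <- rep(c("T1", "T2", "T3", "T4"), each = 3)
  m <- matrix(0L, 4, 12,
              dimnames = list(c("specialist", "generalist", "absent_t2", "patchy"),
                              sprintf("s%02d", 1:12)))
  m["specialist", types == "T1"] <- 50L
  m["generalist", ] <- 50L
  m["absent_t2", types != "T2"] <- 30L
  m["patchy", c(1, 4, 7, 10)] <- 20L
  list(m = m, types = types)
}

test_that("specificity hits its analytic anchors", {
  fx <- spec_fixture()
  sp <- species_specificity(fx$m, fx$types)
  # extreme specialist: always and only in its type
  expect_equal(unname(sp$delta["specialist", ]), c(1, 0, 0, 0))
  # absent species scores exactly 0
  expect_equal(unname(sp$delta["absent_t2", "T2"]), 0)
  expect_true(all(sp$delta >= 0 & sp$delta <= 1))
  # B rows sum to 1 for species present anywhere; delta = A * B elementwise
  expect_equal(unname(rowSums(sp$abundance_share)), rep(1, 4))
  expect_equal(sp$delta, sp$prevalence * sp$abundance_share)
})

test_that("an extreme generalist scores exactly 1/H in every habitat", {
  # generalist plus a type-specific filler at equal share: the generalist
  # has prevalence 1 and identical mean relative abundance in all 4 types
  types <- rep(c("T1", "T2", "T3", "T4"), each = 2)
  m <- matrix(0L, 5, 8,
              dimnames = list(c("generalist", paste0("fill", 1:4)),
                              sprintf("s%02d", 1:8)))
  m["generalist", ] <- 50L
  for (k in 1:4) m[paste0("fill", k), types == paste0("T", k)] <- 50L
  sp <- species_specificity(m, types)
  expect_equal(unname(sp$delta["generalist", ]), rep(0.25, 4))
})

test_that("a pure product example evaluates as A x B", {
  # one species present in 1 of 2 samples of type A (A = 0.5) with the
  # abundance split making B = 0.4
  m <- matrix(c(40, 0, 30, 30,
                60, 100, 70, 70), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), sprintf("s%d", 1:4)))
  sp <- species_specificity(m, c("A", "A", "B", "B"))
  expect_equal(unname(sp$prevalence["x", "A"]), 0.5)
  expect_equal(unname(sp$abundance_share["x", "A"]), 0.4)
  expect_equal(unname(sp$delta["x", "A"]), 0.2)
})

test_that("specificity diversity follows the Renyi form", {
  expect_equal(specificity_diversity(rep(0.2, 7), q = 0), 7)
  expect_equal(specificity_diversity(rep(0.2, 7), q = 2), 7)
  expect_equal(specificity_diversity(c(0.8, 0.2), q = 2), 1 / 0.68)
  # q = 0 counts the positive-specificity species only
  expect_equal(specificity_diversity(c(0.5, 0.3, 0, 0), q = 0), 2)
  prof <- sd_profile(c(0.5, 0.2, 0.1, 0.05), q = seq(0, 4, 0.5))
  expect_true(all(diff(prof$qSD) <= 1e-8))
  expect_error(specificity_diversity(c(0, 0), q = 1), "all-zero")
})

test_that("sp_test recovers planted unique and enriched species", {
  coh <- default_cohort()
  truth <- cohort_types(coh)
  ct <- sp_test(coh$otu, truth, c("HC", "HS"), n_perm = 499, seed = 3)
  pl <- coh$truth
  cat_of <- function(sp) ct$category[match(sp, ct$species)]
  expect_true(all(cat_of(pl$unique_species$HC) == "US_former"))
  expect_true(all(cat_of(pl$unique_species$HS) == "US_latter"))
  expect_gte(mean(cat_of(pl$enriched_species$HC) == "ES_former"), 0.8)
  expect_gte(mean(cat_of(pl$enriched_species$HS) == "ES_latter"), 0.8)
  expect_true(all(ct$q_value >= ct$p_value))
})

test_that("swapping the pair mirrors categories and inverts fold changes", {
  coh <- default_cohort()
  truth <- cohort_types(coh)
  a <- sp_test(coh$otu, truth, c("HC", "HS"), n_perm = 199, seed = 9)
  b <- sp_test(coh$otu, truth, c("HS", "HC"), n_perm = 199, seed = 9)
  stopifnot(identical(a$species, b$species))
  swap <- c(US_former = "US_latter", US_latter = "US_former",
            ES_former = "ES_latter", ES_latter = "ES_former", NS = "NS")
  expect_equal(unname(swap[a$category]), b$category)
  both <- is.finite(a$fold_change) & a$fold_change > 0
  expect_equal(b$fold_change[both], 1 / a$fold_change[both])
  expect_equal(a$delta_former, b$delta_latter)
})

test_that("a homogeneous pool split in half yields almost no discoveries", {
  pool <- homogeneous_pool(60, 5000, n_taxa = 30, seed = 21)
  lab <- rep(c("A", "B"), each = 30)
  ct <- sp_test(pool, lab, c("A", "B"), n_perm = 499, seed = 5)
  expect_gte(mean(ct$category == "NS"), 0.95)
})

test_that("sdp_test flags strongly different profiles but not identical ones", {
  set.seed(2)
  even <- rep(0.5, 24)
  skew <- 0.9^(1:24)
  r <- sdp_test(even, skew, q = 0:4, n_perm = 299, seed = 4)
  expect_true(all(r$p_value[r$q >= 1] <= 0.01))
  expect_equal(r$sd_a[r$q == 0], 24)     # q = 0 is a richness comparison
  same <- sdp_test(even, even, q = c(0, 2), n_perm = 99, seed = 4)
  expect_true(all(same$p_value > 0.5))
  expect_error(sdp_test(numeric(0), skew), "empty species category")
})

test_that("volcano export caps unique-species fold changes at a sentinel", {
  coh <- default_cohort()
  truth <- cohort_types(coh)
  ct <- sp_test(coh$otu, truth, c("HC", "HS"), n_perm = 199, seed = 9)
  v <- volcano_export(ct)
  expect_equal(nrow(v), nrow(ct))
  s <- attr(v, "sentinel")
  expect_true(all(v$log_fold_change[v$category == "US_former"] == s))
  expect_true(all(v$log_fold_change[v$category == "US_latter"] == -s))
  expect_true(all(is.finite(v$log_fold_change) & is.finite(v$neg_log10_p)))
  expect_true(all(abs(v$log_fold_change[!v$capped]) < s))
  empty <- volcano_export(ct[0, ])
  expect_equal(nrow(empty), 0)
})
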