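#' Shared-species composition permutation test
#'
#' Counts the taxa with positive total reads in both groups and compares
#' this against a permutation null. Two null models are available:
#' `samples` shuffles group labels over samples; `reads` redistributes each
#' taxon's pooled reads across all samples with probabilities proportional
#' to sample depths (for shared-species presence this marginalizes to a
#' binomial split of each taxon's pool between the groups). The
#' composition is flagged as changed when the observed number of shared
#' species falls below the null expectation with one-sided P <= alpha.
#'
#' @param group_a,group_b count matrices (taxa x samples) over the same
#'   taxon rows, e.g. column slices of one [otu_table()].
#' @param mode `"samples"` or `"reads"` randomization.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alpha significance level for the composition-changed flag.
#' @return a `vm_test_report` with extra fields `p_lower` (one-sided) and
#'   `composition_changed`.
#' @export
shared_species_test <- function(group_a, group_b, mode = c("samples", "reads"),
                                n_perm = 1000L, seed = 1L, alpha = 0.05) {
  mode <- match.arg(mode)
  group_a <- unclass(group_a) + 0; group_b <- unclass(group_b) + 0
  if (!identical(rownames(group_a), rownames(group_b)))
    stop("groups must share the same taxon rows")
  if (ncol(group_a) < 2L || ncol(group_b) < 2L)
    stop("each group needs at least 2 samples")
  if (n_perm < 100L) warning("fewer than 100 permutations; P-values are coarse")
  na <- ncol(group_a)
  observed <- sum(rowSums(group_a) > 0 & rowSums(group_b) > 0)
  set.seed(as.integer(seed))
  if (mode == "samples") {
    all_counts <- cbind(group_a, group_b)
    n <- ncol(all_counts)
    null <- vapply(seq_len(n_perm), function(k) {
      ia <- sample.int(n, na)
      sum(rowSums(all_counts[, ia, drop = FALSE]) > 0 &
            rowSums(all_counts[, -ia, drop = FALSE]) > 0)
    }, numeric(1))
  } else {
    pool <- rowSums(group_a) + rowSums(group_b)
    p_a <- sum(colSums(group_a)) / (sum(colSums(group_a)) + sum(colSums(group_b)))
    null <- vapply(seq_len(n_perm), function(k) {
      ra <- stats::rbinom(length(pool), size = pool, prob = p_a)
      sum(ra > 0 & (pool - ra) > 0)
    }, numeric(1))
  }
  p_two <- perm_p_two_sided(observed, null)
  p_lower <- (sum(null <= observed) + 1) / (n_perm + 1)
  new_test_report("shared_species", observed, null, p_two, n_perm,
                  p_lower = p_lower,
                  composition_changed = observed < mean(null) && p_lower <= alpha,
                  mode = mode)
}
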