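# fixtures are generated in code and memoized across test files
.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) .fixtures$cohort <- generate_cohort(seed = 7L)
  .fixtures$cohort
}

cohort_types <- function(coh) coh$truth$vm_type[colnames(coh$otu)]

default_metrics <- function() {
  if (is.null(.fixtures$metrics))
    .fixtures$metrics <- compute_metrics(default_cohort()$otu)
  .fixtures$metrics
}

tiny_otu <- function() {
  otu_table(matrix(c(10L, 0L, 5L, 3L, 7L, 2L), nrow = 3,
                   dimnames = list(c("taxA", "taxB", "taxC"), c("s1", "s2"))))
}

# homogeneous pool: i.i.d. multinomial samples from one shared profile
homogeneous_pool <- function(n_samples, depth, n_taxa = 30L, conc = 3,
                             seed = 21L) {
  set.seed(seed)
  p <- stats::rgamma(n_taxa, conc); p <- p / sum(p)
  m <- vapply(seq_len(n_samples), function(j)
    stats::rmultinom(1L, depth, p)[, 1L], integer(n_taxa))
  dimnames(m) <- list(sprintf("t%03d", seq_len(n_taxa)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

# two internally identical, mutually disjoint blocks (pure selection);
# abundances spread geometrically so presence is decoupled from abundance
block_metacommunity <- function(n_per_block = 20L, n_taxa_per_block = 40L) {
  counts <- as.integer(round(400 * 0.85^(seq_len(n_taxa_per_block) - 1))) + 1L
  b1 <- c(counts, rep(0L, n_taxa_per_block))
  b2 <- rev(b1)
  m <- cbind(matrix(rep(b1, n_per_block), ncol = n_per_block),
             matrix(rep(b2, n_per_block), ncol = n_per_block))
  dimnames(m) <- list(sprintf("t%03d", seq_len(2L * n_taxa_per_block)),
                      sprintf("s%03d", seq_len(2L * n_per_block)))
  m
}

# count groups following a type-I Taylor law V = a * m^b by construction:
# per sample, species counts are gamma draws with mean m_j, variance a*m_j^b
taylor_group <- function(n_samples, a, b, n_species = 30L, seed = 1L,
                         m_range = c(20, 2000)) {
  set.seed(seed)
  m <- vapply(seq_len(n_samples), function(j) {
    mj <- exp(stats::runif(1, log(m_range[1]), log(m_range[2])))
    v <- a * mj^b
    x <- stats::rgamma(n_species, shape = mj^2 / v, rate = mj / v)
    pmax(1L, as.integer(round(x)))
  }, integer(n_species))
  dimnames(m) <- list(sprintf("t%03d", seq_len(n_species)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}
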