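#' Configuration for the synthetic VM cohort generator
#'
#' The generator emulates the structural signature of the four VM types:
#' simple communities (HS, BVS) dominated by a single taxon (top-1 relative
#' abundance around 0.65 and 0.78 with a substantial vs. collapsed
#' runner-up), complex communities (HC, BVC) with flatter profiles (top-1
#' around 0.35-0.38) and higher richness (around 28-30 taxa vs. 13-14).
#' Each type owns its top-3 dominant taxa plus planted unique (US) and
#' enriched (ES) background species; the remaining background is a shared
#' core pool with geometrically decaying draw weights. Counts are drawn by
#' Dirichlet-multinomial sampling at a lognormal read depth, giving the
#' over-dispersion typical of 16S count data. A dominance-depth coupling
#' tilts the dominant share with read depth (positively for simple types,
#' negatively for complex ones), which induces Taylor-law heterogeneity
#' exponents above 2 in simple and below 2 in complex groups.
#'
#' @param n_per_type named integer vector of samples per type.
#' @param n_taxa size of the taxon pool.
#' @param top_shares named list of length-3 numeric vectors: mean relative
#'   abundances of the top-3 taxa per type.
#' @param richness named numeric vector of mean per-sample richness per
#'   type.
#' @param depth_median,depth_sdlog lognormal read-depth parameters.
#' @param n_unique,n_enriched planted US/ES species per type.
#' @param enrich_fold weight elevation of an ES species in its own type.
#' @param coupling dominance-depth coupling coefficient (share change per
#'   unit log depth; applied +coupling to simple, -coupling to complex
#'   types).
#' @param richness_sd standard deviation of the per-sample richness draw
#'   around the type mean.
#' @param top_concentration Dirichlet concentration of the top-share draw.
#' @param bg_concentration Dirichlet concentration of background shares.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_type = c(HC = 250L, HS = 250L,
                                         BVC = 250L, BVS = 250L),
                          n_taxa = 200L,
                          top_shares = list(HC  = c(0.354, 0.229, 0.120),
                                            HS  = c(0.646, 0.286, 0.036),
                                            BVC = c(0.378, 0.209, 0.119),
                                            BVS = c(0.783, 0.136, 0.034)),
                          richness = c(HC = 29, HS = 13, BVC = 30, BVS = 14),
                          depth_median = 30000, depth_sdlog = 0.5,
                          n_unique = 5L, n_enriched = 10L, enrich_fold = 8,
                          coupling = 0.18, richness_sd = 1.0,
                          top_concentration = 2000, bg_concentration = 50) {
  types <- c("HC", "HS", "BVC", "BVS")
  stopifnot(all(types %in% names(n_per_type)),
            all(types %in% names(top_shares)),
            all(types %in% names(richness)))
  for (h in types) {
    if (sum(top_shares[[h]]) >= 1) stop("top-3 shares must sum to < 1 for ", h)
    if (any(top_shares[[h]] <= 0)) stop("top shares must be positive")
  }
  n_planted <- 4L * (n_unique + n_enriched) + 12L
  if (n_taxa < n_planted + 20L)
    stop("taxon pool too small for the planted species layout")
  structure(list(n_per_type = n_per_type, n_taxa = n_taxa,
                 top_shares = top_shares, richness = richness,
                 depth_median = depth_median, depth_sdlog = depth_sdlog,
                 n_unique = as.integer(n_unique),
                 n_enriched = as.integer(n_enriched),
                 enrich_fold = enrich_fold, coupling = coupling,
                 richness_sd = richness_sd,
                 top_concentration = top_concentration,
                 bg_concentration = bg_concentration, types = types),
            class = "cohort_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a labeled synthetic VM cohort
#'
#' Draws a four-type cohort under a [cohort_config()]: per sample, a
#' type-specific top-3 share vector (Dirichlet around the type's means,
#' dominant share tilted by the dominance-depth coupling), a background
#' taxon set drawn by weighted sampling at the type's richness (unique
#' species only available to their own type, enriched species at elevated
#' weight in theirs), background shares from a Dirichlet, and finally
#' multinomial read counts at a lognormal depth. Deterministic given
#' `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `otu` (an [otu_table()]), `metadata` (sample_id,
#'   health_status, study_id), and `truth` (class `cohort_truth`: per-sample
#'   true type, planted US/ES taxa per type, dominant taxa, config).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  types <- config$types
  taxa <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  # pool layout: 12 type-owned dominant taxa, then planted US/ES, then core
  dom_idx <- matrix(seq_len(12L), nrow = 3L,
                    dimnames = list(NULL, types))    # top-3 slots per type
  cursor <- 12L
  us_idx <- es_idx <- list()
  for (h in types) {
    us_idx[[h]] <- cursor + seq_len(config$n_unique); cursor <- cursor + config$n_unique
    es_idx[[h]] <- cursor + seq_len(config$n_enriched); cursor <- cursor + config$n_enriched
  }
  core_idx <- (cursor + 1L):config$n_taxa
  # base background weights: geometric decay; planted species sit at a
  # high-rank core weight so their own type carries them at high prevalence
  # while foreign types still pick them up occasionally (ES) or never (US)
  core_w <- 0.92^seq_along(core_idx)
  base_w <- unname(stats::quantile(core_w, 0.9))

  n_total <- sum(config$n_per_type)
  counts <- matrix(0L, config$n_taxa, n_total)
  sample_type <- character(n_total)
  depths <- numeric(n_total)
  col <- 0L
  for (h in types) {
    simple <- h %in% c("HS", "BVS")
    gamma_h <- if (simple) config$coupling else -config$coupling
    # per-type background weight vector over the pool
    w <- numeric(config$n_taxa)
    w[core_idx] <- core_w
    for (g in types) {
      w[es_idx[[g]]] <- base_w * if (g == h) config$enrich_fold else 1
      w[us_idx[[g]]] <- if (g == h) base_w * config$enrich_fold else 0
    }
    ts <- config$top_shares[[h]]
    for (s in seq_len(config$n_per_type[[h]])) {
      col <- col + 1L
      depth <- stats::rlnorm(1L, log(config$depth_median), config$depth_sdlog)
      z <- log(depth / config$depth_median)
      t1 <- min(max(ts[1L] + gamma_h * z, 0.02), 0.95)
      base <- c(t1, ts[2L], ts[3L])
      base <- c(base, max(1 - sum(base), 0.02))
      tops <- rdirichlet1(config$top_concentration * base)
      r_bg <- max(2L, as.integer(round(stats::rnorm(1L, config$richness[[h]] - 3,
                                                    config$richness_sd))))
      r_bg <- min(r_bg, sum(w > 0))
      bg <- sample.int(config$n_taxa, r_bg, prob = w)
      bg_share <- rdirichlet1(config$bg_concentration * w[bg] / sum(w[bg]))
      prof <- numeric(config$n_taxa)
      prof[dom_idx[, h]] <- tops[1:3]
      prof[bg] <- prof[bg] + tops[4L] * bg_share
      counts[, col] <- stats::rmultinom(1L, round(depth), prof)
      sample_type[col] <- h
      depths[col] <- depth
    }
  }
  sample_ids <- sprintf("S%04d", seq_len(n_total))
  otu <- otu_table(counts, taxa = taxa, samples = sample_ids)
  metadata <- data.frame(
    sample_id = sample_ids,
    health_status = ifelse(sample_type %in% c("HC", "HS"), "healthy", "BV"),
    study_id = "synthetic", stringsAsFactors = FALSE)
  truth <- structure(list(
    vm_type = stats::setNames(sample_type, sample_ids),
    structure = stats::setNames(ifelse(sample_type %in% c("HC", "BVC"),
                                       "complex", "simple"), sample_ids),
    dominant_taxa = lapply(stats::setNames(types, types),
                           function(h) taxa[dom_idx[, h]]),
    unique_species = lapply(us_idx, function(i) taxa[i]),
    enriched_species = lapply(es_idx, function(i) taxa[i]),
    depths = stats::setNames(depths, sample_ids),
    seed = as.integer(seed), config = config), class = "cohort_truth")
  list(otu = otu, metadata = metadata, truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("synthetic cohort truth: %d samples (%s), seed %d\n",
              length(x$vm_type),
              paste(sprintf("%s=%d", names(table(x$vm_type)),
                            table(x$vm_type)), collapse = ", "),
              x$seed))
  cat(sprintf("  planted per type: %d unique, %d enriched species\n",
              x$config$n_unique, x$config$n_enriched))
  invisible(x)
}

#' Generate a neutral-model metacommunity
#'
#' Samples are drawn from the sampling scheme the Sloan near-neutral fit
#' assumes: a fixed regional pool of relative abundances, per-sample local
#' relative abundances from a Dirichlet with concentration `Nm * p`
#' (whose marginals are the model's Beta(Nm*p_i, Nm*(1 - p_i))), and
#' multinomial read counts at the given depth. The composite migration
#' parameter `Nm` is therefore recoverable by [fit_sloan_neutral()].
#'
#' @param n_samples number of samples.
#' @param Nm composite migration parameter (> 0).
#' @param depth reads per sample (scalar or per-sample vector).
#' @param n_taxa regional pool size.
#' @param seed integer seed.
#' @return an [otu_table()] with the regional pool in attribute
#'   `"regional_p"`.
#' @export
generate_neutral_metacommunity <- function(n_samples = 60L, Nm = 500,
                                           depth = 20000L, n_taxa = 100L,
                                           seed = 1L) {
  stopifnot(Nm > 0, n_samples >= 3L)
  set.seed(as.integer(seed))
  # regional pool spanning ~2.5 decades of abundance
  p <- exp(seq(0, -6, length.out = n_taxa))
  p <- p / sum(p)
  depth <- rep_len(depth, n_samples)
  counts <- vapply(seq_len(n_samples), function(j) {
    local <- rdirichlet1(Nm * p)
    stats::rmultinom(1L, depth[j], local)[, 1L]
  }, integer(n_taxa))
  otu <- otu_table(counts, taxa = sprintf("taxon_%03d", seq_len(n_taxa)),
                   samples = sprintf("N%03d", seq_len(n_samples)))
  attr(otu, "regional_p") <- p
  otu
}
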