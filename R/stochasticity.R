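#' Fit the Sloan near-neutral community model
#'
#' Fits the neutral expectation of occurrence frequency as a function of
#' mean relative abundance across the samples of a metacommunity. Under the
#' neutral sampling model a taxon with regional relative abundance p has a
#' local relative abundance distributed Beta(N*m*p, N*m*(1 - p)), where N
#' is the community size (read depth here) and m the migration rate. Its
#' expected occurrence frequency is, under `detection = "sampling"` (the
#' default), the exact beta-binomial probability of drawing at least one
#' read at depth N; under `detection = "threshold"` it is the upper beta
#' tail above a fixed relative-abundance detection limit (the common
#' approximation, which understates detection of rare taxa and biases the
#' N*m estimate upward). The single composite parameter N*m is estimated by
#' nonlinear least squares. Taxa whose observed frequency falls above the
#' upper binomial confidence bound of the neutral prediction are classed
#' `above` (positively selected), below the lower bound `below`
#' (negatively selected), and `neutral` otherwise.
#'
#' @param meta count matrix (taxa x samples) of the metacommunity; at
#'   least 10 samples.
#' @param detection `"sampling"` (beta-binomial occurrence, default) or
#'   `"threshold"` (beta tail above `detection_limit`).
#' @param detection_limit relative-abundance threshold used when
#'   `detection = "threshold"`; default `1 / mean(sample depth)`.
#' @param ci_level confidence level for the classification bands.
#' @return a list of class `neutral_fit` with `Nm`, `migration_m`,
#'   `detection_limit`, `r_squared`, a per-taxon data.frame `species`
#'   (mean abundance, frequency, prediction, class), and `fractions`
#'   (f_below, f_neutral, f_above summing to 1 over detected taxa).
#' @export
fit_sloan_neutral <- function(meta, detection = c("sampling", "threshold"),
                              detection_limit = NULL, ci_level = 0.95) {
  detection <- match.arg(detection)
  m <- unclass(meta) + 0
  if (ncol(m) < 10L) stop("need at least 10 samples to fit the neutral model")
  depth <- colSums(m)
  if (any(depth == 0)) stop("sample(s) with zero reads")
  N <- mean(depth)
  if (is.null(detection_limit)) detection_limit <- 1 / N
  rel <- sweep(m, 2L, depth, "/")
  keep <- rowSums(m) > 0
  if (sum(keep) < 2L) stop("degenerate table: fewer than 2 detected taxa")
  p <- rowMeans(rel)[keep]
  freq <- rowMeans(m[keep, , drop = FALSE] > 0)
  d <- detection_limit
  pred_fun <- if (detection == "threshold") {
    function(Nm) stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
  } else {
    # P(count > 0) when the local abundance is Beta(Nm p, Nm (1 - p)) and
    # N reads are drawn: one minus the beta-binomial zero probability
    function(Nm) {
      a <- Nm * p; b <- Nm * (1 - p)
      1 - exp(lbeta(a, b + round(N)) - lbeta(a, b))
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(freq ~ pred_fun(Nm),
                      start = list(Nm = N / 10),
                      lower = 1e-3, upper = 1e9,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("neutral-model fit failed: ", conditionMessage(e)))
  Nm <- stats::coef(fit)[["Nm"]]
  pred <- pred_fun(Nm)
  r2 <- 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)
  S <- ncol(m)
  a2 <- (1 - ci_level) / 2
  lo <- stats::qbinom(a2, S, pmin(pmax(pred, 0), 1)) / S
  hi <- stats::qbinom(1 - a2, S, pmin(pmax(pred, 0), 1)) / S
  cls <- ifelse(freq > hi, "above", ifelse(freq < lo, "below", "neutral"))
  fr <- c(f_below = mean(cls == "below"), f_neutral = mean(cls == "neutral"),
          f_above = mean(cls == "above"))
  structure(list(Nm = Nm, migration_m = Nm / N, detection = detection,
                 detection_limit = d, r_squared = r2,
                 species = data.frame(taxon = rownames(m)[keep],
                                      mean_abundance = p, frequency = freq,
                                      predicted = pred, lower = lo, upper = hi,
                                      class = cls, stringsAsFactors = FALSE),
                 fractions = fr, n_samples = S),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan near-neutral fit: Nm = %.1f (m = %.4g), R^2 = %.3f, %d taxa\n",
              x$Nm, x$migration_m, x$r_squared, nrow(x$species)))
  cat(sprintf("  below %.1f%% / neutral %.1f%% / above %.1f%%\n",
              100 * x$fractions[1], 100 * x$fractions[2], 100 * x$fractions[3]))
  invisible(x)
}

#' Fisher's exact test on neutral-model species classes
#'
#' Compares the below/neutral/above class counts of two neutral fits with
#' Fisher's exact test on the 2 x 3 contingency table.
#'
#' @param fit_a,fit_b `neutral_fit` objects from [fit_sloan_neutral()].
#' @return a `vm_test_report` (null fields degenerate; exact P).
#' @export
fisher_species_class_test <- function(fit_a, fit_b) {
  lv <- c("below", "neutral", "above")
  ca <- table(factor(fit_a$species$class, levels = lv))
  cb <- table(factor(fit_b$species$class, levels = lv))
  if (sum(ca) == 0 || sum(cb) == 0) stop("a fit contains zero species")
  tab <- rbind(A = as.integer(ca), B = as.integer(cb))
  colnames(tab) <- lv
  keep <- colSums(tab) > 0
  ft <- stats::fisher.test(tab[, keep, drop = FALSE])
  structure(list(statistic_name = "neutral_class_fisher",
                 observed = ft$p.value, table = tab, p_value = ft$p.value),
            class = "vm_fisher_report")
}

#' @export
print.vm_fisher_report <- function(x, ...) {
  cat("Fisher exact test on neutral-model class counts:\n")
  print(x$table)
  cat(sprintf("  P = %.4g\n", x$p_value))
  invisible(x)
}

#' Normalized stochasticity ratio (NSR)
#'
#' Quantifies the balance between stochastic and deterministic community
#' assembly by comparing observed pairwise community similarity with a null
#' expectation. The null model redraws each sample's taxa from the regional
#' pool, preserving observed per-sample richness, with draw probabilities
#' proportional to regional relative abundance (for Bray-Curtis, the
#' sample's observed positive counts are reassigned to the drawn taxa in
#' regional-abundance rank order, preserving the rank-abundance
#' structure while randomizing taxon identity). For
#' each sample pair the stochasticity ratio is `C_exp / C_obs` when the
#' pair is more similar than expected (deterministic convergence) and
#' `(1 - C_exp) / (1 - C_obs)` when less similar (deterministic
#' divergence); both equal 1 under pure stochasticity. Because the mean
#' ratio tends to 1/2 rather than 0 under extreme determinism, it is
#' normalized as `2 * ratio - 1` and clamped to [0, 1], so 0 indicates
#' fully deterministic and 1 fully stochastic assembly.
#'
#' @param meta count matrix (taxa x samples), at least 3 samples.
#' @param similarity `"jaccard"` (presence/absence, default) or
#'   `"bray-curtis"` (relative abundance).
#' @param n_sim number of null metacommunities.
#' @param seed integer seed.
#' @return a list of class `nsr_result` with `nsr` in [0, 1], `n_pairs`,
#'   `mean_similarity`, and `mean_null_similarity`.
#' @export
nsr <- function(meta, similarity = c("jaccard", "bray-curtis"),
                n_sim = 100L, seed = 1L) {
  similarity <- match.arg(similarity)
  m <- unclass(meta) + 0
  if (ncol(m) < 3L) stop("need at least 3 samples")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  n <- ncol(m)
  sim_mat <- function(x) {
    if (similarity == "jaccard") {
      1 - as.matrix(vegan::vegdist(t(x > 0), method = "jaccard"))
    } else {
      1 - as.matrix(vegan::vegdist(t(sweep(x, 2L, pmax(colSums(x), 1), "/")),
                                   method = "bray"))
    }
  }
  c_obs <- sim_mat(m)
  if (all(c_obs[upper.tri(c_obs)] == 1))
    warning("all samples identical; NSR is not informative")
  pool_p <- rowSums(m) / sum(m)
  rich <- colSums(m > 0)
  set.seed(as.integer(seed))
  c_exp <- matrix(0, n, n)
  for (k in seq_len(n_sim)) {
    null <- matrix(0, nrow(m), n)
    for (j in seq_len(n)) {
      idx <- sample.int(nrow(m), rich[j], prob = pool_p)
      if (similarity == "jaccard") {
        null[idx, j] <- 1
      } else {
        ord <- idx[order(pool_p[idx], decreasing = TRUE)]
        null[ord, j] <- sort(m[m[, j] > 0, j], decreasing = TRUE)
      }
    }
    c_exp <- c_exp + sim_mat(null)
  }
  c_exp <- c_exp / n_sim
  ut <- upper.tri(c_obs)
  co <- c_obs[ut]; ce <- c_exp[ut]
  ratio <- ifelse(co >= ce,
                  ifelse(co == 0, 1, ce / co),
                  (1 - ce) / (1 - co))
  st <- mean(pmin(ratio, 1))
  structure(list(nsr = min(1, max(0, 2 * st - 1)), n_pairs = sum(ut),
                 mean_similarity = mean(co), mean_null_similarity = mean(ce),
                 similarity = similarity, stochasticity_ratio = st),
            class = "nsr_result")
}

#' @export
print.nsr_result <- function(x, ...) {
  cat(sprintf("NSR = %.3f (%s similarity, %d pairs; mean obs %.3f vs null %.3f)\n",
              x$nsr, x$similarity, x$n_pairs, x$mean_similarity,
              x$mean_null_similarity))
  invisible(x)
}
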