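#' Hill number (effective species count) of order q
#'
#' The Hill number of a relative-abundance vector `p` at diversity order
#' `q` is `(sum(p_i^q))^(1/(1-q))`, taken over taxa with positive
#' abundance. At `q = 0` this is species richness; at `q = 1` the formula
#' is replaced by its limit, `exp` of the Shannon entropy; at `q = 2` it is
#' the inverse Simpson concentration. Hill numbers are non-increasing in
#' `q`, and a perfectly even community of S species has Hill number S at
#' every order.
#'
#' @param p numeric vector of relative abundances, non-negative and summing
#'   to 1 (tolerance 1e-6).
#' @param q diversity order, a single non-negative number.
#' @return the effective number of species (a single number).
#' @examples
#' hill_number(c(0.25, 0.25, 0.25, 0.25), 2)  # 4: uniform community
#' hill_number(c(0.75, 0.25), 2)              # 1.6 = 1 / (0.75^2 + 0.25^2)
#' @export
hill_number <- function(p, q) {
  stopifnot(is.numeric(p), length(q) == 1L, q >= 0)
  if (length(p) == 0L || all(p == 0)) stop("empty or all-zero abundance vector")
  if (any(p < 0)) stop("negative relative abundance")
  if (abs(sum(p) - 1) > 1e-6) stop("relative abundances must sum to 1")
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Community dominance from mean crowding
#'
#' Community dominance follows the mean-crowding construction: with mean
#' per-species abundance `m_c` and abundance variance `sigma_c^2` across
#' the species of one community, community mean crowding is
#' `m_c* = m_c + sigma_c^2 / m_c - 1` and community dominance is
#' `D_c = m_c* / m_c = 1 + sigma_c^2 / m_c^2 - 1 / m_c`.
#'
#' Under the population (divide-by-N) variance convention `D_c` is an exact
#' linear function of Simpson's concentration: `D_c = N * sum(p_i^2) - N/T`
#' for N species and T total reads. The default uses the sample (n-1)
#' convention common in mean-crowding practice; set `var_method =
#' "population"` for the exact Simpson identity.
#'
#' @param counts numeric vector of species abundances (reads); zeros are
#'   dropped (species absent from the community carry no crowding).
#' @param var_method `"sample"` (n-1 denominator, default) or
#'   `"population"` (n denominator).
#' @return a list of class `dominance_summary` with elements `m_c`,
#'   `var_c`, `crowding_mstar`, `D_c`, `n_species`, `total`.
#' @examples
#' community_dominance(c(10, 10, 10, 10))$D_c  # 0.9: zero variance
#' community_dominance(c(30, 10))$D_c          # 1.45 with sample variance
#' @export
community_dominance <- function(counts, var_method = c("sample", "population")) {
  var_method <- match.arg(var_method)
  x <- as.numeric(counts[counts > 0])
  if (length(x) == 0L) stop("no positive counts")
  n <- length(x)
  m <- mean(x)
  v <- if (n == 1L) 0 else if (var_method == "sample") stats::var(x) else
    sum((x - m)^2) / n
  mstar <- m + v / m - 1
  structure(list(m_c = m, var_c = v, crowding_mstar = mstar,
                 D_c = mstar / m, n_species = n, total = sum(x),
                 var_method = var_method),
            class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf("dominance: %d species, %s reads; m_c = %.3f, m_c* = %.3f, D_c = %.4f (%s variance)\n",
              x$n_species, format(x$total, big.mark = ","), x$m_c,
              x$crowding_mstar, x$D_c, x$var_method))
  invisible(x)
}

#' Species dominance of a focal species
#'
#' The species dominance distance is `D_sd = m_c* / m_s` (community mean
#' crowding over the focal species' abundance) and the species dominance is
#' `D_s = D_c - D_sd`. Within a fixed community `D_s` is strictly
#' increasing in the focal abundance, so more dominant species carry larger
#' `D_s`.
#'
#' @param counts numeric vector of species abundances (reads).
#' @param focal index (into `counts`) of the focal species; its count must
#'   be positive.
#' @inheritParams community_dominance
#' @return a list with `D_sd` and `D_s` (both `NA` when the focal count is
#'   zero).
#' @export
species_dominance <- function(counts, focal, var_method = c("sample", "population")) {
  var_method <- match.arg(var_method)
  ms <- as.numeric(counts[focal])
  if (length(ms) != 1L) stop("focal must select exactly one species")
  if (ms <= 0) return(list(D_sd = NA_real_, D_s = NA_real_))
  cd <- community_dominance(counts, var_method)
  dsd <- cd$crowding_mstar / ms
  list(D_sd = dsd, D_s = cd$D_c - dsd)
}

#' The 10-metric typing vector of one sample
#'
#' Computes the feature vector used to dichotomize cohorts into complex
#' vs. simple communities: Hill numbers at q = 0, 1, 2 (on relative
#' abundances), community dominance `D_c` (on raw counts), the species
#' dominance `D_s` of the top three most dominant species, and the relative
#' abundances of the top three most abundant species. Samples with fewer
#' than three taxa have their missing top-k slots padded with 0. Ties in
#' top-3 selection break by taxon identifier for determinism.
#'
#' @param counts named numeric vector of read counts for one sample (names
#'   are taxon identifiers; unnamed vectors are indexed positionally).
#' @inheritParams community_dominance
#' @return a named numeric vector with elements `hill_q0`, `hill_q1`,
#'   `hill_q2`, `D_c`, `Ds_top1..3`, `abund_top1..3`.
#' @export
metric10 <- function(counts, var_method = c("sample", "population")) {
  var_method <- match.arg(var_method)
  x <- as.numeric(counts)
  names(x) <- if (is.null(names(counts))) as.character(seq_along(x)) else names(counts)
  x <- x[x > 0]
  if (length(x) == 0L) stop("empty sample")
  p <- x / sum(x)
  cd <- community_dominance(x, var_method)
  # D_s is strictly increasing in abundance, so the top-3 D_s species are
  # the top-3 most abundant; tie-break lexicographically by taxon id
  ord <- order(-x, names(x))
  top <- utils::head(ord, 3L)
  ds <- vapply(top, function(i) cd$D_c - cd$crowding_mstar / x[i], numeric(1))
  pad <- function(v) c(v, 0, 0, 0)[1:3]
  out <- c(hill_q0 = hill_number(p, 0), hill_q1 = hill_number(p, 1),
           hill_q2 = hill_number(p, 2), D_c = cd$D_c,
           Ds_top1 = 0, Ds_top2 = 0, Ds_top3 = 0,
           abund_top1 = 0, abund_top2 = 0, abund_top3 = 0)
  out[5:7] <- pad(ds)
  out[8:10] <- pad(sort(p, decreasing = TRUE))
  out
}

#' Per-sample 10-metric table for a cohort
#'
#' @param otu an [otu_table()].
#' @inheritParams community_dominance
#' @return a data.frame, one row per sample, with `sample_id` plus the ten
#'   metric columns of [metric10()].
#' @export
compute_metrics <- function(otu, var_method = c("sample", "population")) {
  var_method <- match.arg(var_method)
  m <- t(apply(unclass(otu) + 0, 2L, function(col) {
    names(col) <- rownames(otu)
    metric10(col, var_method)
  }))
  data.frame(sample_id = colnames(otu), m, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Diversity profile across a grid of orders
#'
#' @param p relative-abundance vector.
#' @param q numeric vector of diversity orders (default `0:2`).
#' @return a data.frame with columns `q` and `qD`.
#' @export
diversity_profile <- function(p, q = 0:2) {
  data.frame(q = q, qD = vapply(q, function(qq) hill_number(p, qq), numeric(1)))
}
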