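#' Species specificity across habitat (VM type) classes
#'
#' The specificity of species i for habitat h is `Delta_ih = A_ih * B_ih`,
#' where `A_ih = S_i^h / S^h` is the prevalence of the species among the
#' habitat's samples and `B_ih` is the habitat's share of the species'
#' total mean abundance: `B_ih = <a_i>_h / sum_h <a_i>_h`, with `<a_i>_h`
#' the mean relative abundance over all of the habitat's samples (zeros
#' included). Delta lies in [0, 1]: 1 marks an extreme specialist (present
#' in every sample of one habitat and nowhere else), 0 marks absence from
#' the habitat, and an extreme generalist (prevalence 1, equal mean
#' abundance everywhere) scores `1/H` in each of the H habitats.
#'
#' @param otu an [otu_table()] or count matrix (taxa x samples).
#' @param types habitat labels per sample: a character/factor vector in
#'   column order, or a data.frame with `sample_id` and `vm_type` columns.
#' @return a list of class `specificity_matrix` with matrices `delta`,
#'   `prevalence`, `abundance_share`, `mean_abundance` (taxa x H), and
#'   `type_sizes`.
#' @export
species_specificity <- function(otu, types) {
  m <- unclass(otu) + 0
  types <- resolve_types(types, colnames(m))
  lv <- levels(types)
  if (length(lv) < 2L) stop("need at least 2 habitat types")
  G <- stats::model.matrix(~ types - 1)
  colnames(G) <- lv
  sh <- colSums(G)
  if (any(sh == 0)) stop("type(s) with zero samples: ",
                         paste(lv[sh == 0], collapse = ", "))
  rel <- relative_abundance(m)
  A <- sweep((m > 0) %*% G, 2L, sh, "/")
  meanab <- sweep(rel %*% G, 2L, sh, "/")
  tot <- rowSums(meanab)
  B <- meanab / ifelse(tot > 0, tot, 1)
  delta <- A * B
  structure(list(delta = delta, prevalence = A, abundance_share = B,
                 mean_abundance = meanab, type_sizes = sh, H = length(lv)),
            class = "specificity_matrix")
}

resolve_types <- function(types, sample_ids) {
  if (is.data.frame(types)) {
    if (!all(c("sample_id", "vm_type") %in% names(types)))
      stop("type data.frame needs sample_id and vm_type columns")
    miss <- setdiff(sample_ids, types$sample_id)
    if (length(miss)) stop("samples without type label: ",
                           paste(miss, collapse = ", "))
    types <- types$vm_type[match(sample_ids, types$sample_id)]
  }
  if (length(types) != length(sample_ids))
    stop("one type label per sample required")
  droplevels(as.factor(types))
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("species specificity: %d taxa x %d types (samples per type: %s)\n",
              nrow(x$delta), x$H,
              paste(sprintf("%s=%d", colnames(x$delta), x$type_sizes),
                    collapse = ", ")))
  invisible(x)
}

# Renyi/Hill diversity of a specificity vector
qsd <- function(delta, q) {
  delta <- delta[delta > 0]
  if (length(delta) == 0L) stop("all-zero specificity vector")
  lambda <- delta / sum(delta)
  if (q == 0) return(length(lambda))
  if (abs(q - 1) < 1e-9) return(exp(-sum(lambda * log(lambda))))
  sum(lambda^q)^(1 / (1 - q))
}

#' Specificity diversity of one habitat
#'
#' Applies the Hill-number (Renyi) form to relative specificities
#' `lambda_i = Delta_ih / sum_i Delta_ih`: `qSD = (sum lambda_i^q)^(1/(1-q))`,
#' with the Shannon limit at q = 1. At q = 0 this is the number of species
#' with positive specificity in the habitat.
#'
#' @param spec a `specificity_matrix` from [species_specificity()], or a
#'   numeric vector of specificities.
#' @param h habitat name or column index (ignored when `spec` is a vector).
#' @param q diversity order (single non-negative number).
#' @return the specificity diversity (effective number of species).
#' @export
specificity_diversity <- function(spec, h = NULL, q = 1) {
  stopifnot(length(q) == 1L, q >= 0)
  delta <- if (inherits(spec, "specificity_matrix")) {
    if (is.null(h)) stop("h (habitat) required with a specificity_matrix")
    spec$delta[, h]
  } else as.numeric(spec)
  qsd(delta, q)
}

#' Specificity-diversity profile over a grid of orders
#'
#' @inheritParams specificity_diversity
#' @param q numeric vector of diversity orders (default `0:4`).
#' @return data.frame with columns `q` and `qSD`.
#' @export
sd_profile <- function(spec, h = NULL, q = 0:4) {
  data.frame(q = q, qSD = vapply(q, function(qq)
    specificity_diversity(spec, h, qq), numeric(1)))
}

#' Specificity permutation (SP) test between two VM types
#'
#' Computes per-species specificities within a pair of habitats (H = 2)
#' and tests, per species, the observed specificity difference
#' `Delta_i,1 - Delta_i,2` against a null obtained by randomly remixing
#' the two habitats' samples (group sizes preserved) and recomputing.
#' Two-sided P-values get Benjamini-Hochberg FDR adjustment across
#' species, and each species is cataloged: `US_former`/`US_latter` when
#' significant and structurally absent (prevalence 0) from the other type,
#' `ES_former`/`ES_latter` when significant and present in both, `NS`
#' otherwise. The specificity fold change `Delta_1 / Delta_2` is reported
#' for volcano plots (infinite for US).
#'
#' @param otu an [otu_table()] or count matrix.
#' @param types habitat labels (see [species_specificity()]).
#' @param pair length-2 character vector naming the (former, latter) types.
#' @param n_perm number of permutations (default 1000).
#' @param alpha FDR threshold for the catalog (default 0.05).
#' @param seed integer seed.
#' @return a data.frame of class `species_catalog` with one row per
#'   species present in at least one of the two types: `species`,
#'   `delta_former`, `delta_latter`, `fold_change`, `p_value`, `q_value`,
#'   `category`; excluded all-absent species are recorded in attribute
#'   `"excluded"`.
#' @export
sp_test <- function(otu, types, pair, n_perm = 1000L, alpha = 0.05, seed = 1L) {
  m <- unclass(otu) + 0
  types <- resolve_types(types, colnames(m))
  stopifnot(length(pair) == 2L, all(pair %in% levels(types)))
  sel <- types %in% pair
  m2 <- m[, sel, drop = FALSE]
  grp <- factor(as.character(types[sel]), levels = pair)
  n1 <- sum(grp == pair[1L]); n2 <- sum(grp == pair[2L])
  if (n1 < 5L || n2 < 5L) stop("both types need at least 5 samples")
  excluded <- rownames(m2)[rowSums(m2) == 0]
  keep <- rowSums(m2) > 0
  m2 <- m2[keep, , drop = FALSE]
  rel <- relative_abundance(m2)
  pa <- (m2 > 0) + 0
  delta_diff <- function(in1) {
    # in1: logical/0-1 vector over columns marking membership of the former type
    a1 <- (pa %*% in1) / sum(in1);  a2 <- (pa %*% (1 - in1)) / sum(1 - in1)
    b1 <- (rel %*% in1) / sum(in1); b2 <- (rel %*% (1 - in1)) / sum(1 - in1)
    tot <- b1 + b2
    tot[tot == 0] <- 1
    cbind(d1 = a1 * b1 / tot, d2 = a2 * b2 / tot)
  }
  in1 <- as.numeric(grp == pair[1L])
  obs <- delta_diff(in1)
  obs_diff <- obs[, 1L] - obs[, 2L]
  set.seed(as.integer(seed))
  exceed <- numeric(nrow(m2))
  for (k in seq_len(n_perm)) {
    d <- delta_diff(as.numeric(seq_along(in1) %in% sample.int(length(in1), n1)))
    exceed <- exceed + (abs(d[, 1L] - d[, 2L]) >= abs(obs_diff))
  }
  p <- (exceed + 1) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")
  present1 <- rowSums(m2[, grp == pair[1L], drop = FALSE]) > 0
  present2 <- rowSums(m2[, grp == pair[2L], drop = FALSE]) > 0
  sig <- q <= alpha
  category <- rep("NS", nrow(m2))
  category[sig & present1 & !present2] <- "US_former"
  category[sig & !present1 & present2] <- "US_latter"
  category[sig & present1 & present2 & obs_diff > 0] <- "ES_former"
  category[sig & present1 & present2 & obs_diff < 0] <- "ES_latter"
  out <- data.frame(species = rownames(m2),
                    delta_former = obs[, 1L], delta_latter = obs[, 2L],
                    fold_change = ifelse(obs[, 2L] > 0, obs[, 1L] / obs[, 2L],
                                         ifelse(obs[, 1L] > 0, Inf, NA_real_)),
                    p_value = p, q_value = q, category = category,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "excluded") <- excluded
  class(out) <- c("species_catalog", class(out))
  out
}

#' Specificity-diversity permutation (SDP) test
#'
#' Tests, at each diversity order, whether two species categories differ
#' in their specificity diversity. The observed statistic is the qSD
#' difference; the null shuffles species (with their specificities)
#' between the two categories.
#'
#' @param delta_a,delta_b numeric vectors of specificities for the two
#'   species categories (e.g. US of the former vs. US of the latter type).
#' @param q numeric vector of diversity orders (default `0:4`).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame with one row per order: `q`, `sd_a`, `sd_b`,
#'   `observed` (difference), `p_value`.
#' @export
sdp_test <- function(delta_a, delta_b, q = 0:4, n_perm = 1000L, seed = 1L) {
  delta_a <- as.numeric(delta_a); delta_b <- as.numeric(delta_b)
  if (length(delta_a) == 0L || length(delta_b) == 0L)
    stop("empty species category")
  na <- length(delta_a)
  pool <- c(delta_a, delta_b)
  set.seed(as.integer(seed))
  perm_idx <- replicate(n_perm, sample.int(length(pool), na))
  out <- lapply(q, function(qq) {
    sa <- qsd(delta_a, qq); sb <- qsd(delta_b, qq)
    obs <- sa - sb
    null <- vapply(seq_len(n_perm), function(k) {
      ia <- perm_idx[, k]
      da <- pool[ia]; db <- pool[-ia]
      if (all(da == 0) || all(db == 0)) return(NA_real_)
      qsd(da, qq) - qsd(db, qq)
    }, numeric(1))
    null <- null[!is.na(null)]
    data.frame(q = qq, sd_a = sa, sd_b = sb, observed = obs,
               p_value = perm_p_abs(obs, null))
  })
  do.call(rbind, out)
}

#' Volcano-plot export of an SP-test catalog
#'
#' One row per species with the log10 specificity fold change and
#' `-log10(P)`. Infinite fold changes (unique species) are capped at a
#' sentinel one decade beyond the largest finite magnitude; the sentinel
#' is recorded in attribute `"sentinel"`.
#'
#' @param catalog a `species_catalog` from [sp_test()].
#' @return data.frame with `species`, `log_fold_change`, `neg_log10_p`,
#'   `category`, `capped`.
#' @export
volcano_export <- function(catalog) {
  if (nrow(catalog) == 0L)
    return(data.frame(species = character(), log_fold_change = numeric(),
                      neg_log10_p = numeric(), category = character(),
                      capped = logical(), stringsAsFactors = FALSE))
  lfc <- log10(catalog$fold_change)
  finite <- is.finite(lfc)
  sentinel <- if (any(finite)) max(abs(lfc[finite])) + 1 else 1
  capped <- !finite & !is.na(lfc)
  lfc[capped] <- sentinel * sign(ifelse(catalog$fold_change[capped] > 0, 1, -1))
  lfc[is.na(lfc)] <- 0
  # US_latter species have fold change 0 -> log FC -Inf -> capped negative
  neg0 <- catalog$fold_change == 0 & !is.na(catalog$fold_change)
  lfc[neg0] <- -sentinel
  out <- data.frame(species = catalog$species, log_fold_change = lfc,
                    neg_log10_p = -log10(catalog$p_value),
                    category = catalog$category,
                    capped = capped | neg0, stringsAsFactors = FALSE)
  attr(out, "sentinel") <- sentinel
  out
}
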