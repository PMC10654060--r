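#' Dichotomize one health group into two clusters on the 10 metrics
#'
#' Runs K-means (Hartigan-Wong, k = 2, multiple restarts) on the 10-metric
#' feature matrix of a single health-status group. Metrics are
#' z-standardized by default: the raw scales differ by about two orders of
#' magnitude and unstandardized distances would be dominated by community
#' dominance.
#'
#' @param metrics data.frame or matrix whose columns are the ten metric
#'   columns of [compute_metrics()] (a `sample_id` column is ignored).
#' @param seed integer seed controlling the restarts.
#' @param standardize z-score each column first (default `TRUE`).
#' @param nstart number of random restarts (best within-cluster sum of
#'   squares kept).
#' @return integer vector of cluster ids (1 or 2), one per row, with the
#'   fitted `kmeans` object in attribute `"fit"`. Degenerate input (all
#'   rows identical) yields a single cluster with a warning.
#' @export
dichotomize <- function(metrics, seed = 42L, standardize = TRUE, nstart = 10L) {
  x <- as.matrix(metrics[, intersect(colnames(metrics), metric10_names()),
                         drop = FALSE])
  if (ncol(x) == 0L) x <- as.matrix(metrics)
  storage.mode(x) <- "double"
  if (nrow(x) < 4L) stop("need at least 4 samples to dichotomize")
  if (anyNA(x) || any(!is.finite(x))) stop("metric matrix contains non-finite values")
  if (all(apply(x, 2L, function(col) diff(range(col)) == 0))) {
    warning("all samples identical; single cluster returned")
    out <- rep(1L, nrow(x))
    attr(out, "fit") <- NULL
    return(out)
  }
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0   # constant columns carry no signal
  }
  set.seed(as.integer(seed))
  fit <- stats::kmeans(x, centers = 2L, nstart = nstart,
                       algorithm = "Hartigan-Wong", iter.max = 100L)
  out <- fit$cluster
  attr(out, "fit") <- fit
  out
}

metric10_names <- function() {
  c("hill_q0", "hill_q1", "hill_q2", "D_c",
    "Ds_top1", "Ds_top2", "Ds_top3",
    "abund_top1", "abund_top2", "abund_top3")
}

#' Label two clusters as complex vs. simple
#'
#' The cluster with the higher mean Hill number at q = 1 is labeled
#' `complex` (high diversity), the other `simple` (high dominance). Ties
#' break toward the cluster with the lower mean community dominance.
#'
#' @param clusters integer cluster ids (exactly two distinct values).
#' @param metrics the metric table the clusters were fit on (must contain
#'   `hill_q1` and `D_c`).
#' @return named character vector mapping each cluster id to `"complex"`
#'   or `"simple"`.
#' @export
label_complex_simple <- function(clusters, metrics) {
  ids <- sort(unique(clusters))
  if (length(ids) != 2L) stop("exactly 2 clusters required")
  h1 <- tapply(metrics$hill_q1, clusters, mean)[as.character(ids)]
  dc <- tapply(metrics$D_c, clusters, mean)[as.character(ids)]
  complex_id <- if (h1[1L] != h1[2L]) ids[which.max(h1)] else ids[which.min(dc)]
  out <- ifelse(ids == complex_id, "complex", "simple")
  names(out) <- as.character(ids)
  out
}

#' Assign the four VM types
#'
#' Crisscrosses health status with community structure:
#' healthy x complex -> `HC`, healthy x simple -> `HS`,
#' BV x complex -> `BVC`, BV x simple -> `BVS`.
#'
#' @param metadata data.frame with `sample_id` and `health_status`.
#' @param structure named character vector (`"complex"`/`"simple"`) indexed
#'   by sample_id, or unnamed in metadata row order.
#' @return data.frame with `sample_id`, `health_status`, `structure`,
#'   `vm_type`.
#' @export
assign_four_types <- function(metadata, structure) {
  metadata <- validate_metadata(metadata)
  if (!is.null(names(structure))) {
    miss <- setdiff(metadata$sample_id, names(structure))
    if (length(miss)) stop("missing structure label for sample(s): ",
                           paste(miss, collapse = ", "))
    structure <- structure[metadata$sample_id]
  } else if (length(structure) != nrow(metadata)) {
    stop("structure labels and metadata rows differ in length")
  }
  stopifnot(all(structure %in% c("complex", "simple")))
  vm <- ifelse(metadata$health_status == "healthy",
               ifelse(structure == "complex", "HC", "HS"),
               ifelse(structure == "complex", "BVC", "BVS"))
  data.frame(sample_id = metadata$sample_id,
             health_status = metadata$health_status,
             structure = unname(structure),
             vm_type = factor(vm, levels = c("HC", "HS", "BVC", "BVS")),
             stringsAsFactors = FALSE)
}

#' Full VM typing pipeline
#'
#' Computes the 10-metric table, dichotomizes each health-status group
#' separately with K-means, orients the clusters as complex vs. simple,
#' and returns the four-type labels.
#'
#' @param otu an [otu_table()].
#' @param metadata data.frame with `sample_id` and `health_status`
#'   covering every sample.
#' @param seed integer seed for the K-means restarts.
#' @param metrics optional precomputed [compute_metrics()] table.
#' @return data.frame with `sample_id`, `health_status`, `structure`,
#'   `vm_type`, `cluster_id`, plus the metric table in attribute
#'   `"metrics"`.
#' @export
vm_type_samples <- function(otu, metadata, seed = 42L, metrics = NULL) {
  metadata <- align_cohort(otu, metadata)
  if (is.null(metrics)) metrics <- compute_metrics(otu)
  stopifnot(identical(metrics$sample_id, metadata$sample_id))
  structure_lab <- character(nrow(metadata))
  cluster_id <- integer(nrow(metadata))
  for (hs in unique(metadata$health_status)) {
    idx <- which(metadata$health_status == hs)
    cl <- dichotomize(metrics[idx, , drop = FALSE], seed = seed)
    if (length(unique(cl)) == 1L) {
      structure_lab[idx] <- "simple"      # degenerate: no diversity contrast
      cluster_id[idx] <- 1L
      next
    }
    lab <- label_complex_simple(cl, metrics[idx, , drop = FALSE])
    structure_lab[idx] <- lab[as.character(cl)]
    cluster_id[idx] <- as.integer(cl)
  }
  out <- assign_four_types(metadata, stats::setNames(structure_lab, metadata$sample_id))
  out$cluster_id <- cluster_id
  attr(out, "metrics") <- metrics
  out
}
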