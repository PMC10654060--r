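#' Construct an OTU table
#'
#' An `otu_table` is a non-negative integer count matrix with taxa as rows
#' and samples as columns. All analysis stages in the package consume this
#' canonical orientation; relative abundances are computed per sample on
#' demand and never stored destructively.
#'
#' @param counts numeric matrix (taxa x samples) of read counts; coerced to
#'   integer storage. Row names are taxon identifiers, column names are
#'   sample identifiers (required, duplicate-free).
#' @param taxa,samples optional character vectors overriding dimnames.
#' @return an object of class `otu_table` (an integer matrix with dimnames).
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 3L, 7L, 2L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, taxa = NULL, samples = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(taxa)) rownames(counts) <- taxa
  if (!is.null(samples)) colnames(counts) <- samples
  validate_otu_table(counts)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", class(matrix())))
}

validate_otu_table <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("otu_table requires taxon row names and sample column names")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("otu_table needs at least 1 taxon and 2 samples")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("otu_table contains missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  if (any(abs(counts - round(counts)) > 1e-8))
    warning("non-integer counts rounded to integers")
  invisible(counts)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d taxa x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  k <- min(nrow(x), 6L); j <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

#' Read an OTU table from disk
#'
#' TSV dialect: header row of sample identifiers, first column of taxon
#' identifiers, numeric body. BIOM dialect uses the biomformat package.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"biom"`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for dialect = 'biom'")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(otu_table(m))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("malformed OTU table: need taxon column plus >= 2 samples")
  taxa <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d (taxon '%s'), column '%s'",
                   i, taxa[i], names(body)[j]))
    }
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- taxa
  otu_table(m)
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]: `read_otu_table(write_otu_table(x, f))`
#' reproduces `x` bit-identically.
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(taxon = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with at least the columns `sample_id` and `health_status`
#' (values `healthy` or `BV`); an optional `study_id` column records
#' provenance.
#'
#' @param path file path.
#' @return a data.frame with columns `sample_id`, `health_status`, and
#'   `study_id` if present.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "health_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$health_status), c("healthy", "BV"))
  if (length(bad)) stop("health_status must be 'healthy' or 'BV'; found: ",
                        paste(bad, collapse = ", "))
  df
}

#' Check that an OTU table and metadata describe the same cohort
#'
#' @param otu an [otu_table()].
#' @param metadata a metadata data.frame (see [read_sample_metadata()]).
#' @return the metadata rows reordered to match the table's samples,
#'   invisibly usable downstream.
#' @export
align_cohort <- function(otu, metadata) {
  metadata <- validate_metadata(metadata)
  miss <- setdiff(colnames(otu), metadata$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  metadata[match(colnames(otu), metadata$sample_id), , drop = FALSE]
}

#' Merge genus- and species-level OTU tables
#'
#' Species rows are kept as-is. For each genus, a residual genus row carries
#' the reads not accounted for by its annotated species:
#' `max(0, genus - sum(species))` per sample. Genera whose residual is zero
#' in every sample are dropped; genera with no mapped species are carried
#' through unchanged.
#'
#' @param genus_table,species_table [otu_table()] objects sharing the same
#'   samples (same order).
#' @param genus_of named character vector mapping each species taxon (names)
#'   to its genus taxon (values).
#' @return the merged [otu_table()].
#' @export
reconcile_genus_species <- function(genus_table, species_table, genus_of) {
  if (!identical(colnames(genus_table), colnames(species_table)))
    stop("genus and species tables must share the same samples in the same order")
  sp <- rownames(species_table)
  unmapped <- setdiff(sp, names(genus_of))
  if (length(unmapped))
    stop("species without genus mapping: ", paste(unmapped, collapse = ", "))
  absent <- setdiff(unique(genus_of[sp]), rownames(genus_table))
  if (length(absent))
    stop("species mapped to genus absent from genus table: ",
         paste(absent, collapse = ", "))
  # per-sample sums of species counts within each genus
  spsum <- matrix(0, nrow(genus_table), ncol(genus_table),
                  dimnames = dimnames(genus_table))
  part <- rowsum(unclass(species_table) + 0, group = genus_of[sp])
  spsum[rownames(part), ] <- part
  residual <- pmax(unclass(genus_table) - spsum, 0)
  keep <- rowSums(residual) > 0
  out <- rbind(unclass(species_table), residual[keep, , drop = FALSE])
  otu_table(out)
}

#' Per-sample relative abundances
#'
#' @param otu an [otu_table()] or numeric matrix (taxa x samples).
#' @return a numeric matrix of the same shape whose columns sum to 1
#'   (all-zero samples rejected).
#' @export
relative_abundance <- function(otu) {
  m <- unclass(otu) + 0
  depth <- colSums(m)
  if (any(depth == 0)) stop("sample(s) with zero total reads: ",
                            paste(colnames(m)[depth == 0], collapse = ", "))
  sweep(m, 2L, depth, "/")
}
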