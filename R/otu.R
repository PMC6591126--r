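#' @keywords internal
#' @noRd
as_count_matrix <- function(table, allow_numeric = FALSE) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table))
    stop("OTU table must be a numeric matrix (samples x OTUs)")
  if (anyNA(table)) stop("OTU table contains missing values")
  if (any(table < 0)) stop("OTU table contains negative counts")
  if (!allow_numeric && any(table != round(table)))
    stop("OTU table must contain integer counts")
  if (is.null(rownames(table)))
    rownames(table) <- paste0("S", seq_len(nrow(table)))
  if (is.null(colnames(table)))
    colnames(table) <- paste0("OTU_", seq_len(ncol(table)))
  if (anyDuplicated(rownames(table))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(table))) stop("duplicate OTU ids")
  table
}

check_not_empty <- function(table, context) {
  if (ncol(table) == 0 || nrow(table) == 0)
    stop("empty OTU table after ", context)
  invisible(table)
}

#' Remove low-abundance OTUs
#'
#' An OTU is removed iff its global count fraction (over all samples) is
#' below `global_frac` AND its within-sample fraction is below `sample_frac`
#' in every sample (the joint rule; an OR mode removing OTUs that fail
#' either condition is available via `mode = "or"`).  Column order of the
#' retained OTUs is preserved.
#'
#' @param table OTU count table, samples x OTUs.
#' @param global_frac Global abundance threshold (default 0.001, i.e. 0.1%).
#' @param sample_frac Within-sample abundance threshold (default 0.005).
#' @param mode `"and"` (default) or `"or"` combination of the two removal
#'   conditions.
#' @return Filtered OTU table.
#' @export
filter_low_abundance <- function(table, global_frac = 0.001,
                                 sample_frac = 0.005,
                                 mode = c("and", "or")) {
  mode <- match.arg(mode)
  stopifnot(global_frac >= 0, global_frac < 1,
            sample_frac >= 0, sample_frac < 1)
  m <- as_count_matrix(table)
  gf <- colSums(m) / sum(m)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("sample(s) with zero total counts: ",
                         paste(rownames(m)[rs == 0], collapse = ", "))
  within_max <- apply(m / rs, 2, max)
  low_global <- gf < global_frac
  low_sample <- within_max < sample_frac
  drop <- if (mode == "and") low_global & low_sample
          else low_global | low_sample
  out <- m[, !drop, drop = FALSE]
  check_not_empty(out, "low-abundance filtering")
  out
}

#' Rarefy samples to a common depth
#'
#' Each sample row is replaced by a uniform subsample of its reads without
#' replacement, summing exactly to `depth`.  Reproducible under `seed`.
#'
#' @param table OTU count table, samples x OTUs; every sample total must be
#'   at least `depth`.
#' @param depth Target reads per sample (default 1000).
#' @param seed Integer seed.
#' @return Rarefied OTU table (every row sums to `depth`).
#' @export
rarefy <- function(table, depth = 1000, seed = 1L) {
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  short <- totals < depth
  if (any(short))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(rownames(m)[short], collapse = ", "))
  withr_seed(seed, {
    out <- m
    for (i in seq_len(nrow(m))) {
      if (totals[i] == depth) next
      reads <- rep.int(seq_len(ncol(m)), m[i, ])
      keep <- sample(reads, depth)
      out[i, ] <- tabulate(keep, nbins = ncol(m))
    }
    out
  })
}

#' Prevalence filter
#'
#' Retains OTUs with nonzero counts in at least `min_samples` samples.
#'
#' @param table OTU count table.
#' @param min_samples Minimum number of samples with a nonzero count
#'   (default 2).
#' @return Filtered OTU table (column order preserved).
#' @export
prevalence_filter <- function(table, min_samples = 2) {
  stopifnot(min_samples >= 1)
  m <- as_count_matrix(table)
  keep <- colSums(m != 0) >= min_samples
  out <- m[, keep, drop = FALSE]
  check_not_empty(out, "prevalence filtering")
  out
}

#' Relative abundances
#'
#' @param table OTU count table with positive row sums.
#' @return Matrix of per-sample fractions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- as_count_matrix(table, allow_numeric = TRUE)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-sum sample(s): ", paste(rownames(m)[rs == 0], collapse = ", "))
  m / rs
}

#' Read an OTU count table
#'
#' Tab-separated, samples as rows, OTUs as columns, first column the sample
#' id; `transpose = TRUE` accepts the OTU-as-rows dialect.
#'
#' @param path File path.
#' @param transpose Set `TRUE` if the file stores OTUs as rows.
#' @return Integer count matrix (samples x OTUs).
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (transpose) m <- t(m)
  as_count_matrix(m)
}

#' Write an OTU count table
#'
#' @param table Count matrix (samples x OTUs).
#' @param path Output file; tab-separated, first column `sample_id`.
#' @export
write_otu_table <- function(table, path) {
  m <- as_count_matrix(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a taxonomy table
#'
#' Tab-separated with columns `otu_id`, `kingdom`, `phylum`, `class`,
#' `order`, `family`, `genus`.
#'
#' @param path File path.
#' @return Data frame with the ranks as character columns, row names the
#'   OTU ids.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, colClasses = "character")
  needed <- c("otu_id", "kingdom", "phylum", "class", "order",
              "family", "genus")
  if (!all(needed %in% names(df)))
    stop("taxonomy table must have columns: ", paste(needed, collapse = ", "))
  rownames(df) <- df$otu_id
  df
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy data frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write sample metadata
#'
#' One row per sample: `sample_id`, `farm`, `system`, `region`,
#' `intensity_index` and soil covariates.
#'
#' @param path File path.
#' @return Data frame, row names the sample ids.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  rownames(df) <- df$sample_id
  df
}

#' @rdname read_metadata
#' @param metadata Metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
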