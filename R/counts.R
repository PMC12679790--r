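#' Bundle of the three isoform count matrices
#'
#' Long-read isoform quantification yields three complementary tallies per
#' isoform and sample: *total* counts (every assigned read, split 1/k over
#' its k compatible isoforms), *full-length* counts (restricted to reads
#' carrying a complete junction chain of some isoform), and *unique* counts
#' (reads compatible with exactly one isoform). A `counts_bundle` keeps the
#' three matrices on one shared isoform x sample index.
#'
#' Unique counts can never exceed total counts and this is enforced.
#' Full-length counts are *not* bounded elementwise by total counts: a
#' truncated read can be compatible with k isoforms while carrying the
#' complete junction chain of only m < k of them, crediting those m with
#' 1/m full-length but only 1/k total. Per sample the full-length column
#' sum is still bounded by the total column sum, which is checked instead.
#'
#' @param total numeric matrix, isoforms x samples, with dimnames.
#' @param full_length,unique optional matrices on the same index; `NULL`
#'   marks a metric as absent (never silently zero-filled).
#' @param gene_ids optional named character vector mapping isoform ids to
#'   gene ids, carried along for gene-level summaries.
#' @return an object of class `"counts_bundle"`
#' @export
counts_bundle <- function(total, full_length = NULL, unique = NULL,
                          gene_ids = NULL) {
  total <- as.matrix(total)
  if (is.null(rownames(total)) || is.null(colnames(total)))
    stop("total counts matrix needs isoform rownames and sample colnames")
  if (any(total < 0)) stop("negative counts")
  check_metric <- function(m, name, tol = 1e-9) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(total)) ||
        !identical(rownames(m), rownames(total)) ||
        !identical(colnames(m), colnames(total)))
      stop(name, " matrix does not share the total matrix's index")
    if (any(m < 0)) stop("negative ", name, " counts")
    if (name == "unique" && any(m > total + tol))
      stop("unique counts exceed total counts for some isoform/sample")
    if (name == "full_length" && any(colSums(m) > colSums(total) + tol))
      stop("full-length column sums exceed total column sums")
    m
  }
  out <- list(total = total,
              full_length = check_metric(full_length, "full_length"),
              unique = check_metric(unique, "unique"),
              gene_ids = gene_ids)
  class(out) <- "counts_bundle"
  out
}

#' @export
print.counts_bundle <- function(x, ...) {
  present <- c("total",
               if (!is.null(x$full_length)) "full_length",
               if (!is.null(x$unique)) "unique")
  cat(sprintf("counts_bundle: %d isoforms x %d samples [%s]\n",
              nrow(x$total), ncol(x$total), paste(present, collapse = ", ")))
  invisible(x)
}

#' @export
dim.counts_bundle <- function(x) dim(x$total)

#' Subset a counts bundle by isoforms and/or samples
#' @param x a `counts_bundle`
#' @param isoforms,samples row / column selectors (ids or indices)
#' @return a `counts_bundle`
#' @export
subset_bundle <- function(x, isoforms = NULL, samples = NULL) {
  pick <- function(m) {
    if (is.null(m)) return(NULL)
    if (!is.null(isoforms)) m <- m[isoforms, , drop = FALSE]
    if (!is.null(samples)) m <- m[, samples, drop = FALSE]
    m
  }
  g <- x$gene_ids
  if (!is.null(g) && !is.null(isoforms)) g <- g[rownames(pick(x$total))]
  counts_bundle(pick(x$total), pick(x$full_length), pick(x$unique), g)
}

read_counts_one <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  id_col <- names(dt)[1]
  gene_col <- intersect(c("gene_id", "GENEID", "gene"), names(dt))[1]
  sample_cols <- setdiff(names(dt), c(id_col, gene_col))
  m <- as.matrix(dt[, sample_cols, drop = FALSE])
  rownames(m) <- dt[[id_col]]
  genes <- if (!is.na(gene_col)) stats::setNames(dt[[gene_col]], dt[[id_col]]) else NULL
  list(matrix = m, gene_ids = genes)
}

#' Read isoform count matrices from TSV files
#'
#' Each file has an isoform-id first column (optionally a `gene_id` column)
#' followed by one column per sample. The three metrics arrive as up to
#' three files sharing the same isoforms and samples; a missing metric stays
#' absent in the bundle.
#'
#' @param total path to the total-counts TSV (required).
#' @param full_length,unique optional paths for the other two metrics.
#' @return a [counts_bundle()]
#' @export
read_counts_tsv <- function(total, full_length = NULL, unique = NULL) {
  tot <- read_counts_one(total)
  align <- function(path, name) {
    if (is.null(path)) return(NULL)
    x <- read_counts_one(path)$matrix
    miss_s <- setdiff(colnames(tot$matrix), colnames(x))
    extra_s <- setdiff(colnames(x), colnames(tot$matrix))
    if (length(miss_s) || length(extra_s))
      stop(name, " matrix sample set differs from total: ",
           if (length(miss_s)) paste("missing", paste(miss_s, collapse = ", ")),
           if (length(miss_s) && length(extra_s)) "; ",
           if (length(extra_s)) paste("extra", paste(extra_s, collapse = ", ")))
    miss_i <- setdiff(rownames(tot$matrix), rownames(x))
    if (length(miss_i))
      stop(name, " matrix missing isoform(s): ",
           paste(utils::head(miss_i, 5), collapse = ", "))
    x[rownames(tot$matrix), colnames(tot$matrix), drop = FALSE]
  }
  counts_bundle(tot$matrix,
                full_length = align(full_length, "full_length"),
                unique = align(unique, "unique"),
                gene_ids = tot$gene_ids)
}

#' Write a counts bundle to per-metric TSV files
#'
#' @param bundle a `counts_bundle`
#' @param dir output directory (created if needed); files are
#'   `counts_total.tsv`, `counts_full_length.tsv`, `counts_unique.tsv`.
#' @return named character vector of the files written, invisibly
#' @export
write_counts_tsv <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (metric in c("total", "full_length", "unique")) {
    m <- bundle[[metric]]
    if (is.null(m)) next
    df <- data.frame(transcript_id = rownames(m), check.names = FALSE)
    if (!is.null(bundle$gene_ids))
      df$gene_id <- unname(bundle$gene_ids[rownames(m)])
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    path <- file.path(dir, sprintf("counts_%s.tsv", metric))
    data.table::fwrite(df, path, sep = "\t")
    written[metric] <- path
  }
  invisible(written)
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns `sample_id`, `subject_id`, `tissue`,
#' `total_reads`, and optionally `replicate_group` and
#' `experimental_condition` (empty string / NA = none).
#'
#' @param path TSV path
#' @return data.frame of sample metadata
#' @export
read_sample_meta <- function(path) {
  meta <- data.table::fread(path, sep = "\t", data.table = FALSE,
                            na.strings = c("", "NA"))
  req <- c("sample_id", "subject_id", "tissue", "total_reads")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  if (is.null(meta$replicate_group)) meta$replicate_group <- NA_character_
  if (is.null(meta$experimental_condition))
    meta$experimental_condition <- NA_character_
  meta
}
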