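#' Transcript annotation container
#'
#' Builds the in-memory annotation used throughout the package: a transcript
#' table, a per-transcript exon list, and a derived gene table. All exon
#' coordinates are 0-based half-open; GTF input/output converts at the
#' boundary ([read_gtf()], [write_gtf()]).
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `transcript_biotype`, and optionally
#'   `is_novel` (logical).
#' @param exons named list (one entry per `transcript_id`) of two-column
#'   integer matrices of exon `start`,`end` in 0-based half-open
#'   coordinates, sorted ascending and pairwise disjoint.
#' @param gene_biotypes optional named character vector `gene_id -> biotype`;
#'   defaults to the biotype of the gene's first transcript.
#' @param novel_gene_pattern regex marking novel gene identifiers.
#'
#' @return An object of class `"iso_annotation"`: a list with elements
#'   `transcripts` (data.frame, one row per transcript with `length`,
#'   `n_exons` and genomic extent `start`/`end` added), `exons` (the exon
#'   list), and `genes` (data.frame with `gene_length` = genomic span of the
#'   union of the gene's transcripts).
#' @export
annotation <- function(transcripts, exons, gene_biotypes = NULL,
                       novel_gene_pattern = "^BambuGene") {
  stopifnot(is.data.frame(transcripts), is.list(exons))
  req <- c("transcript_id", "gene_id", "chrom", "strand", "transcript_biotype")
  missing_cols <- setdiff(req, names(transcripts))
  if (length(missing_cols))
    stop("transcripts table lacks column(s): ", paste(missing_cols, collapse = ", "))
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id in annotation")
  if (!all(transcripts$transcript_id %in% names(exons)))
    stop("exon list missing entries for some transcripts")
  exons <- exons[transcripts$transcript_id]
  for (i in seq_along(exons)) {
    ex <- exons[[i]]
    id <- transcripts$transcript_id[i]
    if (!is.matrix(ex) || ncol(ex) != 2 || nrow(ex) < 1)
      stop("transcript ", id, ": exons must be a non-empty two-column matrix")
    storage.mode(ex) <- "integer"
    colnames(ex) <- c("start", "end")
    if (any(ex[, 2] <= ex[, 1]))
      stop("transcript ", id, ": exon with non-positive width")
    if (nrow(ex) > 1) {
      if (is.unsorted(ex[, 1], strictly = TRUE))
        stop("transcript ", id, ": exons not sorted ascending")
      if (any(ex[-1, 1] < ex[-nrow(ex), 2]))
        stop("transcript ", id, ": overlapping exons")
    }
    exons[[i]] <- ex
  }
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(transcripts$is_novel)) transcripts$is_novel <- FALSE
  transcripts$length <- vapply(exons, function(e) sum(e[, 2] - e[, 1]), integer(1))
  transcripts$n_exons <- vapply(exons, nrow, integer(1))
  transcripts$start <- vapply(exons, function(e) e[1, 1], integer(1))
  transcripts$end <- vapply(exons, function(e) e[nrow(e), 2], integer(1))
  rownames(transcripts) <- transcripts$transcript_id

  genes <- build_gene_table(transcripts, gene_biotypes, novel_gene_pattern)
  structure(list(transcripts = transcripts, exons = exons, genes = genes),
            class = "iso_annotation")
}

build_gene_table <- function(tx, gene_biotypes, novel_gene_pattern) {
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  gene_id <- names(sp)
  gene_length <- vapply(sp, function(i) {
    max(tx$end[i]) - min(tx$start[i])
  }, integer(1))
  biotype <- vapply(sp, function(i) tx$transcript_biotype[i[1]], character(1))
  if (!is.null(gene_biotypes)) {
    hit <- gene_id %in% names(gene_biotypes)
    biotype[hit] <- gene_biotypes[gene_id[hit]]
  }
  genes <- data.frame(
    gene_id = gene_id,
    gene_biotype = biotype,
    n_transcripts = lengths(sp),
    gene_length = gene_length,
    is_novel_gene = grepl(novel_gene_pattern, gene_id),
    row.names = gene_id,
    stringsAsFactors = FALSE
  )
  genes
}

#' @export
print.iso_annotation <- function(x, ...) {
  cat(sprintf("iso_annotation: %d transcripts in %d genes on %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$genes),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

#' Transcripts of a gene
#' @param ann an `iso_annotation`
#' @param gene_id gene identifier
#' @return character vector of transcript ids
#' @export
gene_transcripts <- function(ann, gene_id) {
  ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
}

#' Map transcript ids to gene ids
#' @param ann an `iso_annotation`
#' @param transcript_ids transcript identifiers (default: all)
#' @return named character vector `transcript_id -> gene_id`
#' @export
transcript_genes <- function(ann, transcript_ids = NULL) {
  tx <- ann$transcripts
  if (is.null(transcript_ids)) transcript_ids <- tx$transcript_id
  out <- tx[transcript_ids, "gene_id"]
  names(out) <- transcript_ids
  out
}

#' Query transcripts overlapping a genomic window
#'
#' @param ann an `iso_annotation`
#' @param chrom chromosome name
#' @param start,end 0-based half-open window
#' @param strand optional strand filter (`"+"`/`"-"`)
#' @return character vector of transcript ids whose genomic extent overlaps
#'   the window
#' @export
transcripts_overlapping <- function(ann, chrom, start, end, strand = NULL) {
  tx <- ann$transcripts
  keep <- tx$chrom == chrom & tx$start < end & tx$end > start
  if (!is.null(strand)) keep <- keep & tx$strand == strand
  tx$transcript_id[keep]
}
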