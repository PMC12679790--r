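#' Read a transcript annotation from GTF
#'
#' Parses exon features from an Ensembl-dialect GTF and assembles an
#' [annotation()] object. GTF's 1-based closed coordinates are converted to
#' the package's internal 0-based half-open convention. Transcripts whose
#' identifier matches `novel_tx_pattern` are flagged `is_novel` (the default
#' matches Bambu-discovered isoform ids such as `BambuTx977`); gene ids
#' matching `novel_gene_pattern` are flagged `is_novel_gene`.
#'
#' @param path GTF file path.
#' @param novel_tx_pattern,novel_gene_pattern regexes for novel identifiers.
#' @return an `iso_annotation`
#' @export
read_gtf <- function(path, novel_tx_pattern = "^BambuTx",
                     novel_gene_pattern = "^BambuGene") {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    stop("malformed GTF line ", bad, " in ", path, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("no exon features in ", path)
  for (col in c("gene_id", "transcript_id"))
    if (is.null(ex[[col]]) || anyNA(ex[[col]]))
      stop("GTF exon features missing attribute ", col)
  tx_biotype <- if (!is.null(ex$transcript_biotype)) ex$transcript_biotype else
    rep(NA_character_, nrow(ex))
  tx_biotype[is.na(tx_biotype)] <- "unknown"
  gene_biotype <- if (!is.null(ex$gene_biotype)) ex$gene_biotype else
    rep(NA_character_, nrow(ex))

  ord <- order(ex$transcript_id, ex$start)
  ex <- ex[ord, , drop = FALSE]
  tx_biotype <- tx_biotype[ord]
  gene_biotype <- gene_biotype[ord]
  idx <- split(seq_len(nrow(ex)), ex$transcript_id)

  exons <- lapply(idx, function(i)
    cbind(start = ex$start[i] - 1L, end = ex$end[i]))
  first <- vapply(idx, `[`, integer(1), 1L)
  transcripts <- data.frame(
    transcript_id = names(idx),
    gene_id = ex$gene_id[first],
    chrom = as.character(ex$seqnames[first]),
    strand = as.character(ex$strand[first]),
    transcript_biotype = tx_biotype[first],
    is_novel = grepl(novel_tx_pattern, names(idx)),
    stringsAsFactors = FALSE
  )
  gb <- gene_biotype[first]
  gene_biotypes <- NULL
  if (!all(is.na(gb))) {
    gene_biotypes <- tapply(gb, transcripts$gene_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[1] else "unknown"
    })
    gene_biotypes <- stats::setNames(as.character(gene_biotypes), names(gene_biotypes))
  }
  annotation(transcripts, exons, gene_biotypes = gene_biotypes,
             novel_gene_pattern = novel_gene_pattern)
}

#' Write an annotation to GTF
#'
#' Emits one `transcript` and per-exon `exon` features per transcript, with
#' `gene_id`, `transcript_id`, `gene_biotype` and `transcript_biotype`
#' attributes, converting back to GTF's 1-based closed coordinates.
#' `read_gtf(write_gtf(ann))` round-trips all fields the annotation carries.
#'
#' @param ann an `iso_annotation`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gtf <- function(ann, path) {
  tx <- ann$transcripts
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    e <- ann$exons[[id]]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
      tx$gene_id[i], id, ann$genes[tx$gene_id[i], "gene_biotype"],
      tx$transcript_biotype[i])
    lines <- c(
      sprintf("%s\tisodiver\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom[i], tx$start[i] + 1L, tx$end[i], tx$strand[i], attrs),
      sprintf("%s\tisodiver\texon\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom[i], e[, 1] + 1L, e[, 2], tx$strand[i], attrs))
    writeLines(lines, con)
  }
  invisible(path)
}
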