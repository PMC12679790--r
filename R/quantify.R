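#' Junction chain of an exon or block chain
#'
#' The junction chain — the ordered list of intron intervals between
#' consecutive exons (or aligned blocks) — is the identity key for
#' read-to-isoform compatibility: two spliced alignments agree structurally
#' exactly when their junction chains match.
#'
#' @param blocks two-column matrix of 0-based half-open intervals, sorted
#'   ascending and disjoint (a transcript's exons or a read's aligned
#'   blocks).
#' @return two-column matrix of (donor, acceptor) intron intervals; zero
#'   rows for a mono-exon/mono-block chain.
#' @export
junction_chain <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks)
  if (n < 2) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = blocks[-n, 2], end = blocks[-1, 1])
}

chain_key <- function(junctions) {
  if (nrow(junctions) == 0) return("|")
  paste0("|", paste(junctions[, 1], junctions[, 2], sep = "-", collapse = "|"), "|")
}

# Precomputed per-transcript lookup used by compatibility(); built once per
# annotation and cached on the object by quantify_reads().
build_tx_index <- function(ann) {
  tx <- ann$transcripts
  chains <- lapply(ann$exons, junction_chain)
  list(
    tx = tx,
    chains = chains,
    keys = vapply(chains, chain_key, character(1)),
    exons = ann$exons
  )
}

blocks_within_exons <- function(blocks, exons) {
  # every read block must lie inside some exon of the transcript
  for (i in seq_len(nrow(blocks))) {
    hit <- exons[, 1] <= blocks[i, 1] & exons[, 2] >= blocks[i, 2]
    if (!any(hit)) return(FALSE)
  }
  TRUE
}

#' Read-to-isoform compatibility
#'
#' A spliced read is compatible with transcript T when its junction chain is
#' a contiguous sub-chain of T's junction chain (exact coordinates, same
#' strand) and every aligned block lies within T's exons. A mono-block read
#' is compatible when its span lies within a single exon of T (same
#' strand). Full-length matches are the transcripts whose *entire* junction
#' chain equals the read's chain; a read is unique when exactly one
#' transcript is compatible.
#'
#' @param read a list with `chrom`, `strand`, and `blocks` (two-column
#'   matrix of 0-based half-open aligned intervals, sorted, disjoint).
#' @param ann an [annotation()] object.
#' @param index optional precomputed index (internal; built from `ann` when
#'   absent).
#' @return list with `compatible_ids`, `full_length_ids`
#'   (subset of `compatible_ids`), and `unique` (logical).
#' @export
compatibility <- function(read, ann, index = NULL) {
  if (is.null(index)) index <- build_tx_index(ann)
  tx <- index$tx
  blocks <- as.matrix(read$blocks)
  span <- c(blocks[1, 1], blocks[nrow(blocks), 2])
  cand <- which(tx$chrom == read$chrom & tx$strand == read$strand &
                  tx$start < span[2] & tx$end > span[1])
  compatible <- character(0)
  full_length <- character(0)
  if (length(cand)) {
    if (nrow(blocks) == 1) {
      for (j in cand) {
        ex <- index$exons[[j]]
        if (any(ex[, 1] <= span[1] & ex[, 2] >= span[2])) {
          id <- tx$transcript_id[j]
          compatible <- c(compatible, id)
          if (nrow(index$chains[[j]]) == 0) full_length <- c(full_length, id)
        }
      }
    } else {
      rkey <- chain_key(junction_chain(blocks))
      keys <- index$keys[cand]
      sub <- cand[grepl(rkey, keys, fixed = TRUE)]
      for (j in sub) {
        if (blocks_within_exons(blocks, index$exons[[j]])) {
          id <- tx$transcript_id[j]
          compatible <- c(compatible, id)
          if (index$keys[j] == rkey) full_length <- c(full_length, id)
        }
      }
    }
  }
  list(compatible_ids = compatible, full_length_ids = full_length,
       unique = length(compatible) == 1L)
}

#' Quantify reads into total, full-length and unique counts
#'
#' Assigns each read to its compatible isoforms and accumulates, per
#' sample: `total[T] += 1/k` over the k compatible isoforms; `full_length[T]
#' += 1/m` over the m isoforms whose complete junction chain equals the
#' read's (nothing when m = 0); `unique[T] += 1` only when k = 1. Reads with
#' no compatible isoform are tallied per sample in the `unassigned`
#' attribute — reported, never fatal.
#'
#' @param reads data.frame with columns `read_id`, `sample_id`, `chrom`,
#'   `strand` and a list-column `blocks` of two-column matrices (the
#'   interchange written by [write_reads()] / [simulate_reads()]).
#' @param ann an [annotation()] object.
#' @return a [counts_bundle()] over all annotated isoforms and the samples
#'   present in `reads`, with attribute `unassigned` (named integer vector
#'   per sample).
#' @export
quantify_reads <- function(reads, ann) {
  index <- build_tx_index(ann)
  iso <- ann$transcripts$transcript_id
  samples <- sort(unique(reads$sample_id))
  zero <- matrix(0, nrow = length(iso), ncol = length(samples),
                 dimnames = list(iso, samples))
  total <- zero; fl <- zero; uniq <- zero
  unassigned <- stats::setNames(integer(length(samples)), samples)
  for (r in seq_len(nrow(reads))) {
    cm <- compatibility(list(chrom = reads$chrom[r], strand = reads$strand[r],
                             blocks = reads$blocks[[r]]), ann, index)
    s <- reads$sample_id[r]
    k <- length(cm$compatible_ids)
    if (k == 0) {
      unassigned[s] <- unassigned[s] + 1L
      next
    }
    total[cm$compatible_ids, s] <- total[cm$compatible_ids, s] + 1 / k
    m <- length(cm$full_length_ids)
    if (m > 0)
      fl[cm$full_length_ids, s] <- fl[cm$full_length_ids, s] + 1 / m
    if (k == 1) uniq[cm$compatible_ids, s] <- uniq[cm$compatible_ids, s] + 1
  }
  out <- counts_bundle(total, full_length = fl, unique = uniq,
                       gene_ids = transcript_genes(ann))
  attr(out, "unassigned") <- unassigned
  out
}

#' Read/write the per-read interchange format
#'
#' Reads travel between the simulator and the quantifier as JSON lines, one
#' object per read with fields `read_id`, `sample_id`, `chrom`, `strand`,
#' and `blocks` (list of `[start, end)` pairs, 0-based).
#'
#' @param reads data.frame with a `blocks` list-column
#' @param path output file
#' @return `path` invisibly
#' @export
write_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(reads))) {
    b <- reads$blocks[[r]]
    obj <- list(read_id = reads$read_id[r], sample_id = reads$sample_id[r],
                chrom = reads$chrom[r], strand = reads$strand[r],
                blocks = lapply(seq_len(nrow(b)), function(i) unname(b[i, ])))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    read_id = vapply(recs, `[[`, character(1), "read_id"),
    sample_id = vapply(recs, `[[`, character(1), "sample_id"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    blocks = I(lapply(recs, function(x) {
      b <- x$blocks
      if (is.list(b)) b <- do.call(rbind, b)
      b <- matrix(as.integer(b), ncol = 2)
      colnames(b) <- c("start", "end")
      b
    })),
    stringsAsFactors = FALSE
  )
}
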