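#' Build a transcript catalog
#'
#' The catalog is the indexing backbone of the package: an ordered list of
#' genes, each with an ordered list of transcripts and their lengths in
#' nucleotides. Genes and transcripts are sorted lexicographically by
#' (gene_id, transcript_id) in the C locale, so indices are stable across
#' runs and input row order.
#'
#' @param gene_id character vector, one entry per transcript.
#' @param transcript_id character vector, globally unique transcript ids.
#' @param length positive integer vector of transcript lengths (nt).
#' @param segments optional synthetic segment structure used by the
#'   simulator: a list with `gene_segment_lengths` (per gene, numeric vector
#'   of segment lengths along the gene's segment chain) and `tx_segments`
#'   (per transcript, integer vector `c(first, last)` of the contiguous
#'   segment range the isoform retains).
#'
#' @return An object of class `transcript_catalog` with components
#'   `transcripts` (data.frame with gene_id, transcript_id, length and the
#'   integer gene index), `gene_ids`, and `tx_by_gene` (per gene, integer
#'   row indices into `transcripts`).
#' @export
transcript_catalog <- function(gene_id, transcript_id, length, segments = NULL) {
  gene_id <- as.character(gene_id)
  transcript_id <- as.character(transcript_id)
  length <- as.numeric(length)
  if (!(base::length(gene_id) == base::length(transcript_id) &&
        base::length(gene_id) == base::length(length))) {
    stop("gene_id, transcript_id and length must have equal length")
  }
  if (base::length(transcript_id) == 0L) stop("catalog must contain at least one transcript")
  dup <- transcript_id[duplicated(transcript_id)]
  if (base::length(dup) > 0L) {
    stop("duplicate transcript_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(!is.finite(length) | length < 1 | length != floor(length))
  if (base::length(bad) > 0L) {
    stop("transcript lengths must be positive integers; offending ids: ",
         paste(transcript_id[bad], collapse = ", "))
  }
  ord <- order(gene_id, transcript_id, method = "radix")
  gene_id <- gene_id[ord]
  transcript_id <- transcript_id[ord]
  length <- as.integer(length[ord])
  gene_ids <- unique(gene_id)
  gene <- match(gene_id, gene_ids)
  tx_by_gene <- split(seq_along(transcript_id), gene)
  names(tx_by_gene) <- NULL
  if (!is.null(segments)) {
    segments$tx_segments <- segments$tx_segments[transcript_id]
  }
  structure(list(
    transcripts = data.frame(gene_id = gene_id, transcript_id = transcript_id,
                             length = length, gene = gene,
                             stringsAsFactors = FALSE),
    gene_ids = gene_ids,
    tx_by_gene = tx_by_gene,
    segments = segments
  ), class = "transcript_catalog")
}

#' Number of genes in a catalog
#' @param catalog a `transcript_catalog`.
#' @return integer count.
#' @export
n_genes <- function(catalog) length(catalog$gene_ids)

#' Number of transcripts in a catalog
#' @param catalog a `transcript_catalog`.
#' @return integer count.
#' @export
n_transcripts <- function(catalog) nrow(catalog$transcripts)

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("transcript_catalog: %d genes, %d transcripts\n",
              n_genes(x), n_transcripts(x)))
  k <- table(x$transcripts$gene)
  cat(sprintf("  isoforms per gene: min %d, median %s, max %d\n",
              min(k), format(stats::median(k)), max(k)))
  invisible(x)
}

#' Read a transcript catalog from disk
#'
#' TSV input requires a header with columns `gene_id`, `transcript_id`,
#' `length`. GTF input uses exon features; a transcript's length is the sum
#' of its exon widths (1-based inclusive coordinates, strand ignored).
#'
#' @param path input file.
#' @param format `"tsv"` or `"gtf"`.
#' @return a [transcript_catalog()].
#' @export
read_catalog <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "length")
    if (!all(need %in% names(df))) {
      stop("catalog TSV must have columns: ", paste(need, collapse = ", "))
    }
    transcript_catalog(df$gene_id, df$transcript_id, df$length)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("GTF import requires the rtracklayer package")
    }
    gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
    gr <- gr[gr$type == "exon", , drop = FALSE]
    if (nrow(gr) == 0L) stop("GTF contains no exon features")
    tx <- as.character(gr$transcript_id)
    gn <- as.character(gr$gene_id)
    w <- gr$width
    len <- tapply(w, tx, sum)
    gene_of <- tapply(gn, tx, function(g) {
      u <- unique(g)
      if (length(u) > 1L) stop("transcript assigned to multiple genes: ",
                               paste(u, collapse = ", "))
      u
    })
    ids <- names(len)
    transcript_catalog(as.character(gene_of[ids]), ids, as.numeric(len))
  }
}

#' Write a transcript catalog as TSV
#' @param catalog a `transcript_catalog`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog$transcripts[, c("gene_id", "transcript_id", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
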