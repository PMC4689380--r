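#' Per-base read sampling probability
#'
#' Probability of drawing one specific read of length `read_length` from a
#' transcript of length `tx_length` under uniform start positions:
#' `1 / (tx_length - read_length + 1)`. A transcript shorter than the read
#' cannot generate it and gets probability 0.
#'
#' @param tx_length transcript length (nt), positive.
#' @param read_length read length (nt), positive.
#' @return numeric vector of sampling probabilities, recycled over inputs.
#' @export
sampling_probability <- function(tx_length, read_length) {
  if (any(!is.finite(tx_length)) || any(tx_length < 1) ||
      any(!is.finite(read_length)) || any(read_length < 1)) {
    stop("lengths must be positive")
  }
  q <- ifelse(tx_length >= read_length, 1 / (tx_length - read_length + 1), 0)
  as.numeric(q)
}

## Internal constructor. `genes` is a list (one per catalog gene) of
## list(counts = numeric(E), Q = E x K matrix of per-transcript q values,
## 0 where incompatible). Columns of Q follow the catalog's within-gene
## transcript order.
new_compat <- function(genes, catalog) {
  n_reads <- vapply(genes, function(g) sum(g$counts), numeric(1))
  structure(list(genes = genes, n_reads = n_reads, catalog = catalog),
            class = "compat_matrix")
}

#' @export
print.compat_matrix <- function(x, ...) {
  ncls <- vapply(x$genes, function(g) length(g$counts), integer(1))
  cat(sprintf("compat_matrix: %d genes, %d classes, %s reads\n",
              length(x$genes), sum(ncls), format(sum(x$n_reads))))
  invisible(x)
}

#' Build a compatibility matrix from an equivalence-class table
#'
#' One row per (class, transcript) pair. Reads with identical compatible
#' transcript sets are summarized by a class with a multiplicity `count`;
#' `q` is the per-base sampling probability of the class reads from that
#' transcript.
#'
#' @param df data.frame with columns `gene_id`, `class_id`, `count`,
#'   `transcript_id`, `q`.
#' @param catalog a [transcript_catalog()].
#' @return a `compat_matrix` with one slot per catalog gene (genes with no
#'   rows get zero classes).
#' @export
compat_from_classes <- function(df, catalog) {
  need <- c("gene_id", "class_id", "count", "transcript_id", "q")
  if (!all(need %in% names(df))) {
    stop("compat table must have columns: ", paste(need, collapse = ", "))
  }
  tx <- catalog$transcripts
  row_of_tx <- stats::setNames(seq_len(nrow(tx)), tx$transcript_id)
  genes <- vector("list", n_genes(catalog))
  for (gi in seq_len(n_genes(catalog))) {
    rows <- catalog$tx_by_gene[[gi]]
    K <- length(rows)
    sub <- df[df$gene_id == catalog$gene_ids[gi], , drop = FALSE]
    if (nrow(sub) == 0L) {
      genes[[gi]] <- list(counts = numeric(0), Q = matrix(0, 0, K))
      next
    }
    unknown <- setdiff(sub$transcript_id, tx$transcript_id[rows])
    if (length(unknown) > 0L) {
      stop("gene ", catalog$gene_ids[gi],
           ": class references transcript outside the gene: ",
           paste(unknown, collapse = ", "))
    }
    if (any(!is.finite(sub$q) | sub$q <= 0)) stop("q values must be finite and > 0")
    if (any(sub$q > 1)) stop("q values must be <= 1")
    cls_ids <- sort(unique(as.character(sub$class_id)))
    E <- length(cls_ids)
    Q <- matrix(0, E, K)
    counts <- numeric(E)
    e_of <- match(as.character(sub$class_id), cls_ids)
    k_of <- match(row_of_tx[sub$transcript_id], rows)
    for (r in seq_len(nrow(sub))) {
      Q[e_of[r], k_of[r]] <- sub$q[r]
    }
    cnt <- tapply(sub$count, e_of, function(v) {
      u <- unique(v)
      if (length(u) > 1L) stop("inconsistent counts within a class")
      u
    })
    counts[as.integer(names(cnt))] <- as.numeric(cnt)
    if (any(!is.finite(counts) | counts < 1 | counts != floor(counts))) {
      stop("class counts must be positive integers")
    }
    genes[[gi]] <- list(counts = counts, Q = Q)
  }
  new_compat(genes, catalog)
}

#' Read an equivalence-class table from TSV
#'
#' @param path TSV with header columns `gene_id`, `class_id`, `count`,
#'   `transcript_id`, `q`.
#' @param catalog a [transcript_catalog()].
#' @return a `compat_matrix`.
#' @export
read_compat_table <- function(path, catalog) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  compat_from_classes(df, catalog)
}

#' Write an equivalence-class table as TSV
#' @param compat a `compat_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_compat_table <- function(compat, path) {
  catalog <- compat$catalog
  out <- vector("list", length(compat$genes))
  for (gi in seq_along(compat$genes)) {
    g <- compat$genes[[gi]]
    if (length(g$counts) == 0L) next
    rows <- catalog$tx_by_gene[[gi]]
    recs <- which(g$Q > 0, arr.ind = TRUE)
    out[[gi]] <- data.frame(
      gene_id = catalog$gene_ids[gi],
      class_id = sprintf("c%d", recs[, 1]),
      count = g$counts[recs[, 1]],
      transcript_id = catalog$transcripts$transcript_id[rows[recs[, 2]]],
      q = g$Q[recs],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), class_id = character(0),
                      count = numeric(0), transcript_id = character(0),
                      q = numeric(0))
  }
  out$q <- sprintf("%.12g", out$q)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a compatibility matrix from SAM alignments against transcripts
#'
#' Alignments must be in transcriptome coordinates, i.e. reference names are
#' catalog transcript ids. Each read contributes one equivalence-class entry
#' per compatible transcript with `q = sampling_probability(l, read_length)`;
#' reads with identical compatible sets within a gene are collapsed into one
#' weighted class. Reads hitting several gene loci are handled by
#' `multimap_policy`: under `primary_only` the read is assigned to the gene
#' of its primary alignment and other-gene alignments are dropped; under
#' `split_by_loci` every hit is kept and `q` is divided by the number of
#' distinct gene loci the read aligns to.
#'
#' @param path SAM (or BAM) file.
#' @param catalog a [transcript_catalog()].
#' @param read_length read length in nt used for the sampling probability.
#' @param multimap_policy `"primary_only"` (default) or `"split_by_loci"`.
#' @return a `compat_matrix`. Reads aligned to no catalog transcript are
#'   dropped; their count is stored in attribute `dropped_reads` and
#'   reported via [message()].
#' @export
compat_from_alignments <- function(path, catalog, read_length,
                                   multimap_policy = c("primary_only", "split_by_loci")) {
  multimap_policy <- match.arg(multimap_policy)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM/BAM import requires the Rsamtools package")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             indexDestination = FALSE))
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = prm)[[1]]
  qname <- rec$qname
  flag <- rec$flag
  rname <- as.character(rec$rname)
  tx <- catalog$transcripts
  tx_row <- match(rname, tx$transcript_id)
  known <- !is.na(tx_row)
  all_reads <- unique(qname)
  keep_reads <- unique(qname[known])
  n_dropped <- length(setdiff(all_reads, keep_reads))
  if (n_dropped > 0L) {
    message(n_dropped, " read(s) aligned to no catalog transcript; dropped")
  }
  qname <- qname[known]; flag <- flag[known]; tx_row <- tx_row[known]
  genes <- lapply(catalog$tx_by_gene, function(rows)
    list(keys = character(0), counts = numeric(0), sets = list(), div = numeric(0)))
  if (length(qname) > 0L) {
    by_read <- split(seq_along(qname), qname)
    for (idx in by_read) {
      rows_hit <- tx_row[idx]
      genes_hit <- unique(tx$gene[rows_hit])
      if (multimap_policy == "primary_only" && length(genes_hit) > 1L) {
        primary <- idx[bitwAnd(flag[idx], 0x100L) == 0L & bitwAnd(flag[idx], 0x800L) == 0L]
        if (length(primary) == 0L) primary <- idx[1]
        g <- tx$gene[tx_row[primary[1]]]
        sel <- tx$gene[rows_hit] == g
        rows_hit <- rows_hit[sel]
        genes_hit <- g
      }
      div <- if (multimap_policy == "split_by_loci") length(genes_hit) else 1
      for (g in genes_hit) {
        rg <- sort(unique(rows_hit[tx$gene[rows_hit] == g]))
        key <- paste(c(div, rg), collapse = ",")
        slot <- genes[[g]]
        pos <- match(key, slot$keys)
        if (is.na(pos)) {
          slot$keys <- c(slot$keys, key)
          slot$counts <- c(slot$counts, 1)
          slot$sets <- c(slot$sets, list(rg))
          slot$div <- c(slot$div, div)
        } else {
          slot$counts[pos] <- slot$counts[pos] + 1
        }
        genes[[g]] <- slot
      }
    }
  }
  out <- vector("list", n_genes(catalog))
  for (gi in seq_len(n_genes(catalog))) {
    rows <- catalog$tx_by_gene[[gi]]
    K <- length(rows)
    slot <- genes[[gi]]
    E <- length(slot$counts)
    ord <- order(slot$keys, method = "radix")
    Q <- matrix(0, E, K)
    counts <- numeric(E)
    for (e in seq_len(E)) {
      src <- ord[e]
      rg <- slot$sets[[src]]
      k <- match(rg, rows)
      Q[e, k] <- sampling_probability(tx$length[rg], read_length) / slot$div[src]
      counts[e] <- slot$counts[src]
    }
    out[[gi]] <- list(counts = counts, Q = Q)
  }
  res <- new_compat(out, catalog)
  attr(res, "dropped_reads") <- n_dropped
  res
}
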