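#' Construct a transcript interaction network
#'
#' Nodes are catalog transcripts (by catalog row index); edges are an
#' unordered, deduplicated set of cross-gene pairs. Within-gene pairs and
#' self-loops are never stored: the model only uses positive co-expression
#' between transcripts of *different* genes, and within-gene interactions
#' are assumed not to change a gene's own quantification.
#'
#' @param edges two-column matrix/data.frame of catalog row indices, or a
#'   zero-row object for an empty network.
#' @param catalog a [transcript_catalog()].
#' @param tag optional character vector of per-edge provenance tags
#'   (`"structure"` or `"predicted"`), recycled.
#' @return an object of class `transcript_network` with components `n_nodes`,
#'   `edges` (data.frame `from`, `to`, `tag`; `from < to`), `neighbors`
#'   (per node, integer vector of adjacent nodes), and `gene` (per node,
#'   gene index). Attributes `dropped_within_gene` and `dropped_duplicate`
#'   count discarded input pairs.
#' @export
transcript_network <- function(edges, catalog, tag = "structure") {
  n <- n_transcripts(catalog)
  gene <- catalog$transcripts$gene
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) storage.mode(edges) <- "integer"
  dropped_within <- 0L
  dropped_dup <- 0L
  if (nrow(edges) > 0L) {
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (any(edges < 1L | edges > n)) stop("edge index out of range")
    tag <- rep_len(as.character(tag), nrow(edges))
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    same <- gene[a] == gene[b]
    dropped_within <- sum(same)
    a <- a[!same]; b <- b[!same]; tag <- tag[!same]
    key <- (a - 1) * as.double(n) + b
    dup <- duplicated(key)
    dropped_dup <- sum(dup)
    ord <- order(key[!dup])
    a <- a[!dup][ord]; b <- b[!dup][ord]; tag <- tag[!dup][ord]
    ed <- data.frame(from = a, to = b, tag = tag, stringsAsFactors = FALSE,
                     row.names = NULL)
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(from = integer(0), to = integer(0), tag = character(0),
                     stringsAsFactors = FALSE)
  }
  nb <- vector("list", n)
  if (nrow(ed) > 0L) {
    inc <- split(c(ed$to, ed$from), c(ed$from, ed$to))
    for (nm in names(inc)) nb[[as.integer(nm)]] <- sort(inc[[nm]])
  }
  for (i in seq_len(n)) if (is.null(nb[[i]])) nb[[i]] <- integer(0)
  structure(list(n_nodes = n, edges = ed, neighbors = nb, gene = gene),
            class = "transcript_network",
            dropped_within_gene = dropped_within,
            dropped_duplicate = dropped_dup)
}

#' Number of edges in a transcript network
#' @param net a `transcript_network`.
#' @return integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.transcript_network <- function(x, ...) {
  cat(sprintf("transcript_network: %d nodes, %d edges\n", x$n_nodes, n_edges(x)))
  invisible(x)
}

#' Read a transcript network from an edge-list TSV
#'
#' Two columns of transcript ids, with or without a header line. Edges
#' naming transcripts absent from the catalog and within-gene pairs are
#' dropped with a reported count; duplicates (in either orientation)
#' collapse to one undirected edge.
#'
#' @param path edge-list TSV.
#' @param catalog a [transcript_catalog()].
#' @return a [transcript_network()].
#' @export
read_network_edges <- function(path, catalog) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  known <- catalog$transcripts$transcript_id
  if (length(lines) > 0L) {
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    looks_like_header <- !any(first %in% known) &&
      any(grepl("transcript|^tx|node|from|to|source|target", first,
                ignore.case = TRUE))
    if (looks_like_header) lines <- lines[-1]
  }
  if (length(lines) == 0L) {
    warning("empty edge list; returning an empty network")
    return(transcript_network(matrix(integer(0), 0, 2), catalog))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  ia <- match(a, known)
  ib <- match(b, known)
  unknown <- is.na(ia) | is.na(ib)
  if (any(unknown)) {
    warning(sum(unknown), " edge(s) name unknown transcripts; dropped")
  }
  net <- transcript_network(cbind(ia[!unknown], ib[!unknown]), catalog)
  if (attr(net, "dropped_within_gene") > 0L) {
    message(attr(net, "dropped_within_gene"), " within-gene edge(s) dropped")
  }
  attr(net, "dropped_unknown") <- sum(unknown)
  net
}

#' Write a transcript network as an edge-list TSV
#' @param net a `transcript_network`.
#' @param catalog the catalog the network is indexed against.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network_edges <- function(net, catalog, path) {
  ids <- catalog$transcripts$transcript_id
  df <- data.frame(transcript_a = ids[net$edges$from],
                   transcript_b = ids[net$edges$to],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the transcript network from domain annotations and DDI tables
#'
#' Two transcripts of *different* genes are connected if any pair of their
#' Pfam domains (hits with e-value at or below `evalue_cutoff`) is a known
#' domain-domain interaction. Edges whose only supporting DDIs come from
#' predicted tiers are kept only when a gene-level protein-protein
#' interaction table is supplied and contains the gene pair; with
#' `ppi_pairs = NULL` predicted tiers are excluded entirely.
#'
#' @param annot data.frame with columns `transcript_id`, `domain_id`,
#'   `evalue` (>= 0).
#' @param ddi data.frame with columns `domain_a`, `domain_b`, `tier`
#'   (`"structural"`, `"predicted_high"` or `"predicted_medium"`).
#' @param catalog a [transcript_catalog()].
#' @param evalue_cutoff e-value threshold applied to domain hits before
#'   joining (default `1e-5`).
#' @param ppi_pairs optional data.frame with columns `gene_a`, `gene_b` of
#'   gene-level interactions used to admit predicted-tier edges.
#' @return a [transcript_network()] with per-edge provenance tags
#'   (`"structure"` if any supporting DDI is structural, else `"predicted"`).
#' @export
build_transcript_network <- function(annot, ddi, catalog, evalue_cutoff = 1e-5,
                                     ppi_pairs = NULL) {
  if (!all(c("transcript_id", "domain_id", "evalue") %in% names(annot))) {
    stop("annot must have columns transcript_id, domain_id, evalue")
  }
  if (!all(c("domain_a", "domain_b", "tier") %in% names(ddi))) {
    stop("ddi must have columns domain_a, domain_b, tier")
  }
  if (any(annot$evalue < 0)) stop("e-values must be >= 0")
  annot <- annot[annot$evalue <= evalue_cutoff, , drop = FALSE]
  annot <- annot[annot$transcript_id %in% catalog$transcripts$transcript_id, , drop = FALSE]
  if (nrow(annot) == 0L) {
    warning("no domain annotations after filtering; returning an empty network")
    return(transcript_network(matrix(integer(0), 0, 2), catalog))
  }
  tx_row <- match(annot$transcript_id, catalog$transcripts$transcript_id)
  gene <- catalog$transcripts$gene
  gene_ids <- catalog$gene_ids
  ## unordered DDI key -> structural? flag
  ddi_key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  kk <- ddi_key(as.character(ddi$domain_a), as.character(ddi$domain_b))
  structural <- tapply(ddi$tier == "structural", kk, any)
  ppi_key <- NULL
  if (!is.null(ppi_pairs)) {
    ppi_key <- ddi_key(as.character(ppi_pairs$gene_a), as.character(ppi_pairs$gene_b))
  }
  by_tx <- split(as.character(annot$domain_id), tx_row)
  tx_idx <- as.integer(names(by_tx))
  m <- length(tx_idx)
  from <- integer(0); to <- integer(0); tag <- character(0)
  for (i in seq_len(m - 1L)) {
    di <- unique(by_tx[[i]])
    for (j in (i + 1L):m) {
      ti <- tx_idx[i]; tj <- tx_idx[j]
      if (gene[ti] == gene[tj]) next
      dj <- unique(by_tx[[j]])
      keys <- ddi_key(rep(di, each = length(dj)), rep(dj, length(di)))
      hit <- structural[keys]
      hit <- hit[!is.na(hit)]
      if (length(hit) == 0L) next
      any_struct <- any(hit)
      if (!any_struct) {
        gk <- ddi_key(gene_ids[gene[ti]], gene_ids[gene[tj]])
        if (is.null(ppi_key) || !(gk %in% ppi_key)) next
      }
      from <- c(from, ti); to <- c(to, tj)
      tag <- c(tag, if (any_struct) "structure" else "predicted")
    }
  }
  transcript_network(cbind(from, to), catalog, tag = tag)
}

#' Summary statistics of a transcript network
#'
#' Density uses unordered pairs: `E / (V (V - 1) / 2)`, reported in percent.
#' The diameter is the unweighted eccentricity maximum of the largest
#' connected component. The clustering coefficient is the mean local
#' clustering over all nodes, with nodes of degree < 2 contributing 0.
#'
#' @param net a `transcript_network` with at least one node.
#' @return list with `n_nodes`, `n_edges`, `density_pct`, `diameter`,
#'   `avg_neighbors`, `avg_clustering`.
#' @export
network_statistics <- function(net) {
  V <- net$n_nodes
  if (V == 0L) stop("network has no nodes")
  E <- n_edges(net)
  g <- igraph::make_empty_graph(n = V, directed = FALSE)
  if (E > 0L) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
  }
  diam <- 0
  if (E > 0L) {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    diam <- igraph::diameter(sub, unconnected = FALSE)
  }
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  list(n_nodes = V, n_edges = E,
       density_pct = network_summary_from_counts(V, E)$density_pct,
       diameter = as.numeric(diam),
       avg_neighbors = network_summary_from_counts(V, E)$avg_neighbors,
       avg_clustering = mean(cc))
}

#' Density and average neighbor count from node/edge counts
#'
#' The closed-form pieces of [network_statistics()]: density in percent over
#' unordered pairs and average degree `2 E / V`.
#'
#' @param n_nodes node count V (>= 2).
#' @param n_edges edge count E.
#' @return list with `density_pct` and `avg_neighbors`.
#' @export
network_summary_from_counts <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("need at least two nodes")
  list(density_pct = 100 * n_edges / (n_nodes * (n_nodes - 1) / 2),
       avg_neighbors = 2 * n_edges / n_nodes)
}

#' Co-membership / interaction-coverage arithmetic for pathway overlap
#'
#' Summarizes how gene-level interactions distribute over pathway co-member
#' gene pairs. The pair denominator is the full ordered-pair count
#' `n_genes^2` (self-pairs included), matching the convention of published
#' pathway co-membership percentages.
#'
#' @param n_genes number of genes.
#' @param comember_pairs number of gene pairs co-occurring in >= 1 pathway.
#' @param ddi_comember number of interactions between co-member pairs.
#' @param ddi_noncomember number of interactions between non-co-member pairs.
#' @return list with `comember_pct`, `noncomember_pairs`,
#'   `ddi_coverage_pct` (share of interactions falling in co-member pairs)
#'   and `fold_enrichment` (interaction rate ratio, co-member vs not).
#' @export
comembership_summary <- function(n_genes, comember_pairs, ddi_comember,
                                 ddi_noncomember) {
  total_pairs <- as.double(n_genes)^2
  noncomember_pairs <- total_pairs - comember_pairs
  list(
    comember_pct = 100 * comember_pairs / total_pairs,
    noncomember_pairs = noncomember_pairs,
    ddi_coverage_pct = 100 * ddi_comember / (ddi_comember + ddi_noncomember),
    fold_enrichment = (ddi_comember / comember_pairs) /
      (ddi_noncomember / noncomember_pairs)
  )
}

## Run fn with a private RNG stream; restores .Random.seed afterwards.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## Degree-preserving repair: edges that violate the cross-gene or
## uniqueness constraints are fixed by 2-swaps with random partner edges
## ((a_i, b_i), (a_j, b_j) -> (a_i, b_j), (a_j, b_i)), which leave every
## node's degree unchanged.
repair_edges <- function(a, b, gene, n) {
  key_of <- function(x, y) (pmin(x, y) - 1) * as.double(n) + pmax(x, y)
  offenders <- which(gene[a] == gene[b] | duplicated(key_of(a, b)))
  tries <- 0L
  while (length(offenders) > 0L) {
    tries <- tries + 1L
    if (tries > 5000L) stop("could not repair randomized edges without collisions")
    i <- offenders[1]
    j <- sample.int(length(a), 1)
    na_i <- a[i]; nb_i <- b[j]; na_j <- a[j]; nb_j <- b[i]
    a2 <- a; b2 <- b
    a2[i] <- na_i; b2[i] <- nb_i; a2[j] <- na_j; b2[j] <- nb_j
    k2 <- key_of(a2, b2)
    ok <- gene[a2[i]] != gene[b2[i]] && gene[a2[j]] != gene[b2[j]] &&
      a2[i] != b2[i] && a2[j] != b2[j] && !anyDuplicated(k2)
    if (ok) { a <- a2; b <- b2
      offenders <- which(gene[a] == gene[b] | duplicated(key_of(a, b)))
    }
  }
  cbind(a, b)
}

## Sample m distinct unordered cross-gene pairs among nodes; uses rejection
## sampling with a retry cap so the edge count is exact.
sample_cross_gene_edges <- function(n, gene, m, exclude_key = numeric(0)) {
  a <- integer(0); b <- integer(0)
  key <- exclude_key
  tries <- 0L
  while (length(a) < m) {
    tries <- tries + 1L
    if (tries > 200L) stop("could not draw enough distinct cross-gene pairs")
    need <- m - length(a)
    ca <- sample.int(n, 2 * need + 10, replace = TRUE)
    cb <- sample.int(n, 2 * need + 10, replace = TRUE)
    lo <- pmin(ca, cb); hi <- pmax(ca, cb)
    ok <- lo != hi & gene[lo] != gene[hi]
    lo <- lo[ok]; hi <- hi[ok]
    k <- (lo - 1) * as.double(n) + hi
    fresh <- !(k %in% key) & !duplicated(k)
    lo <- lo[fresh]; hi <- hi[fresh]; k <- k[fresh]
    if (length(lo) > need) { lo <- lo[1:need]; hi <- hi[1:need]; k <- k[1:need] }
    a <- c(a, lo); b <- c(b, hi); key <- c(key, k)
  }
  cbind(a, b)
}

#' Randomize or ablate a transcript network
#'
#' Three null models used in robustness experiments:
#' `permute_labels` relabels nodes by a uniform random permutation; pairs
#' that land within one gene are fixed up by degree-preserving 2-swaps with
#' random partner edges, so the degree multiset and edge count are
#' preserved exactly while the no-within-gene-edge invariant holds.
#' `shuffle_edges` redraws the same number of edges uniformly among distinct
#' cross-gene pairs; `remove_fraction` deletes `floor(fraction * E)` edges
#' uniformly at random.
#'
#' @param net a `transcript_network`.
#' @param mode `"permute_labels"`, `"shuffle_edges"` or `"remove_fraction"`.
#' @param fraction required for `remove_fraction`, in `[0, 1]`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param catalog the catalog the network is indexed against.
#' @return a `transcript_network`.
#' @export
randomize_network <- function(net, catalog,
                              mode = c("permute_labels", "shuffle_edges", "remove_fraction"),
                              fraction = NULL, seed = NULL) {
  mode <- match.arg(mode)
  n <- net$n_nodes
  E <- n_edges(net)
  with_seed(seed, function() {
    if (mode == "permute_labels") {
      perm <- sample.int(n)
      if (E == 0L) return(transcript_network(matrix(integer(0), 0, 2), catalog))
      ed <- repair_edges(perm[net$edges$from], perm[net$edges$to], net$gene, n)
      transcript_network(ed, catalog, tag = net$edges$tag)
    } else if (mode == "shuffle_edges") {
      if (E == 0L) return(transcript_network(matrix(integer(0), 0, 2), catalog))
      transcript_network(sample_cross_gene_edges(n, net$gene, E), catalog)
    } else {
      if (is.null(fraction) || !is.finite(fraction) || fraction < 0 || fraction > 1) {
        stop("fraction must be in [0, 1]")
      }
      drop_n <- floor(fraction * E)
      keep <- if (drop_n > 0L) -sample.int(E, drop_n) else seq_len(E)
      transcript_network(as.matrix(net$edges[keep, c("from", "to"), drop = FALSE]),
                         catalog, tag = net$edges$tag[keep])
    }
  })
}

#' Overlap between transcript co-expression and network proximity
#'
#' For every cross-gene transcript pair with defined expression correlation,
#' computes the Pearson correlation across samples, sorts pairs by
#' decreasing correlation (ties broken by the lexicographic pair id), groups
#' them into consecutive bins, and counts per bin how many pairs are close
#' in the network: direct neighbors (`max_distance = 1`) or connected by a
#' path of length <= 2 (`max_distance = 2`, via the boolean square of the
#' adjacency matrix; the diagonal and within-gene pairs are excluded).
#' A 2x2 chi-square test (no continuity correction) compares connectivity in
#' the first `head_bins` bins against the remaining pairs.
#'
#' @param expr numeric matrix, transcripts x samples; rownames are transcript
#'   ids matching the catalog.
#' @param net a `transcript_network`.
#' @param catalog a [transcript_catalog()].
#' @param bin_size pairs per bin (default 1000).
#' @param max_distance 1 or 2.
#' @param head_bins bins in the "high co-expression" group of the test
#'   (default 10).
#' @return list with `bins` (data.frame `bin`, `n_pairs`, `n_connected`),
#'   `chisq_p`, `n_pairs`, `n_connected`, `n_excluded` (pairs dropped for
#'   undefined correlations).
#' @export
coexpression_overlap <- function(expr, net, catalog, bin_size = 1000,
                                 max_distance = 1, head_bins = 10) {
  if (ncol(expr) < 2L) stop("need at least two samples")
  if (!max_distance %in% c(1, 2)) stop("max_distance must be 1 or 2")
  ids <- catalog$transcripts$transcript_id
  row <- match(rownames(expr), ids)
  if (anyNA(row)) stop("expression rows not matched to catalog transcripts")
  n <- n_transcripts(catalog)
  gene <- catalog$transcripts$gene
  sds <- apply(expr, 1, stats::sd)
  ok <- is.finite(sds) & sds > 0
  n_const <- sum(!ok)
  if (n_const > 0L) {
    message(n_const, " constant expression row(s); their pairs excluded")
  }
  keep <- row[ok]
  C <- stats::cor(t(expr[ok, , drop = FALSE]))
  ## connectivity matrix at the requested distance
  A <- Matrix::sparseMatrix(i = net$edges$from, j = net$edges$to,
                            dims = c(n, n), x = 1, symmetric = TRUE)
  conn <- A
  if (max_distance == 2) {
    conn <- A + A %*% A
  }
  conn <- conn != 0
  m <- length(keep)
  if (m < 2L) stop("fewer than two usable transcripts")
  pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ti <- keep[pr[, 1]]; tj <- keep[pr[, 2]]
  cross <- gene[ti] != gene[tj]
  ti <- ti[cross]; tj <- tj[cross]
  rho <- C[cbind(pr[cross, 1], pr[cross, 2])]
  def <- is.finite(rho)
  n_excluded <- n_const  # rows, plus any residual NA pairs below
  n_excluded_pairs <- sum(!def)
  ti <- ti[def]; tj <- tj[def]; rho <- rho[def]
  id_a <- pmin(ids[ti], ids[tj])
  id_b <- pmax(ids[ti], ids[tj])
  ord <- order(-rho, id_a, id_b, method = "radix")
  ti <- ti[ord]; tj <- tj[ord]
  is_conn <- as.logical(conn[cbind(pmin(ti, tj), pmax(ti, tj))])
  npair <- length(is_conn)
  bin <- ceiling(seq_len(npair) / bin_size)
  bins <- data.frame(bin = sort(unique(bin)))
  bins$n_pairs <- as.integer(table(bin))
  nc <- tapply(is_conn, bin, sum)
  bins$n_connected <- as.integer(nc[as.character(bins$bin)])
  chisq_p <- NA_real_
  if (sum(is_conn) == 0L) {
    warning("no connected pairs; chi-square test skipped")
  } else {
    head <- bin <= head_bins
    tab <- matrix(c(sum(is_conn & head), sum(!is_conn & head),
                    sum(is_conn & !head), sum(!is_conn & !head)), 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chisq_p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  list(bins = bins, chisq_p = chisq_p, n_pairs = npair,
       n_connected = sum(is_conn), n_excluded = n_excluded_pairs)
}
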