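## Shared fixtures and independent oracles for the test suite.

## A tiny two-gene catalog used throughout the unit tests.
tiny_catalog <- function() {
  transcript_catalog(
    gene_id = c("GA", "GA", "GB", "GB"),
    transcript_id = c("A1", "A2", "B1", "B2"),
    length = c(100, 200, 100, 100)
  )
}

## Single-gene compat slice from explicit classes.
## classes: list of list(count=, q= named numeric over transcript positions 1..K)
gene_compat <- function(classes, K) {
  E <- length(classes)
  Q <- matrix(0, E, K)
  counts <- numeric(E)
  for (e in seq_len(E)) {
    counts[e] <- classes[[e]]$count
    q <- classes[[e]]$q
    Q[e, as.integer(names(q))] <- as.numeric(q)
  }
  list(counts = counts, Q = Q)
}

## Full compat_matrix for one catalog from a per-gene list of class specs.
make_compat <- function(catalog, per_gene_classes) {
  genes <- vector("list", n_genes(catalog))
  for (gi in seq_len(n_genes(catalog))) {
    K <- length(catalog$tx_by_gene[[gi]])
    cls <- per_gene_classes[[gi]]
    genes[[gi]] <- if (is.null(cls)) list(counts = numeric(0), Q = matrix(0, 0, K))
                   else gene_compat(cls, K)
  }
  netquant:::new_compat(genes, catalog)
}

## Random single-gene compat instance (positive q, each class hits >= 1 tx).
random_gene_instance <- function(K = NULL, E = NULL) {
  if (is.null(K)) K <- sample(2:6, 1)
  if (is.null(E)) E <- sample(5:200, 1)
  Q <- matrix(0, E, K)
  for (e in seq_len(E)) {
    ks <- sample.int(K, sample.int(K, 1))
    Q[e, ks] <- stats::runif(length(ks), 0.001, 0.02)
  }
  ## ensure every transcript hits at least one class (not required, but
  ## keeps instances non-degenerate)
  for (k in seq_len(K)) if (all(Q[, k] == 0)) Q[sample.int(E, 1), k] <- 0.01
  list(counts = sample(1:20, E, replace = TRUE), Q = Q)
}

## Wrap a single-gene instance as a compat_matrix over a 1-gene catalog.
single_gene_compat <- function(g, length_nt = 500) {
  K <- ncol(g$Q)
  catalog <- transcript_catalog(rep("G1", K), sprintf("T%d", seq_len(K)),
                                rep(length_nt, K))
  netquant:::new_compat(list(g), catalog)
}

## ---- independent graph oracles (no igraph) --------------------------------

## adjacency list from an edge matrix over n nodes
adj_list <- function(edges, n) {
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
  }
  nb
}

bfs_dist <- function(nb, src, n) {
  d <- rep(NA_integer_, n)
  d[src] <- 0L
  queue <- src
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in nb[[v]]) if (is.na(d[u])) { d[u] <- d[v] + 1L; queue <- c(queue, u) }
  }
  d
}

## diameter of the largest connected component by all-pairs BFS
oracle_diameter <- function(edges, n) {
  nb <- adj_list(edges, n)
  comp <- rep(0L, n); cid <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    cid <- cid + 1L
    reach <- which(!is.na(bfs_dist(nb, v, n)))
    comp[reach] <- cid
  }
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  if (length(big) == 1L) return(0)
  max(vapply(big, function(v) max(bfs_dist(nb, v, n)[big]), numeric(1)))
}

## mean local clustering; degree < 2 contributes 0
oracle_clustering <- function(edges, n) {
  nb <- adj_list(edges, n)
  has_edge <- function(a, b) b %in% nb[[a]]
  cc <- vapply(seq_len(n), function(v) {
    k <- length(nb[[v]])
    if (k < 2) return(0)
    links <- 0
    vs <- nb[[v]]
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (has_edge(vs[i], vs[j])) links <- links + 1
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

## ---- independent likelihood oracles ---------------------------------------

## Eq-style direct evaluation of the per-gene posterior objective
oracle_posterior <- function(p, alpha, counts, Q) {
  lp <- log(pmax(p, 1e-12))
  const <- lgamma(sum(alpha)) - sum(lgamma(alpha))
  lik <- if (length(counts) > 0) sum(counts * log(as.vector(Q %*% p))) else 0
  const + sum((alpha - 1) * lp) + lik
}

## grid argmax of f over the 2-simplex with step h (returns p1)
grid_argmax_2 <- function(f, h = 1e-3) {
  ps <- seq(0, 1, by = h)
  vals <- vapply(ps, function(p1) f(c(p1, 1 - p1)), numeric(1))
  ps[which.max(vals)]
}

## ---- SAM fixture -----------------------------------------------------------

## Write a SAM file over the given catalog transcripts; aln is a data.frame
## with columns qname, flag, rname, pos.
write_sam <- function(catalog, aln, path) {
  tx <- catalog$transcripts
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", tx$transcript_id, tx$length))
  seq34 <- paste(rep("A", 34), collapse = "")
  body <- sprintf("%s\t%d\t%s\t%d\t60\t34M\t*\t0\t0\t%s\t*",
                  aln$qname, aln$flag, aln$rname, aln$pos, seq34)
  writeLines(c(hdr, body), path)
  path
}
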