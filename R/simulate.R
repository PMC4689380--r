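#' Simulate a transcript catalog with segment structure
#'
#' Each gene is a chain of `segments` exon-like segments with independent
#' lengths; every isoform retains a contiguous segment range. All isoforms
#' of a gene contain the middle segment of the chain, so any two isoforms
#' of a gene overlap and ambiguous reads exist -- the phenomenon the
#' quantifier has to resolve.
#'
#' @param n_genes number of genes.
#' @param isoform_prob probability weights for 1..length(isoform_prob)
#'   isoforms per gene; the default gives about 2.5 isoforms per gene.
#' @param segments range of segments per gene (inclusive).
#' @param segment_length range of segment lengths in nt.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return a [transcript_catalog()] carrying the synthetic segment
#'   structure needed by [simulate_reads()].
#' @export
simulate_catalog <- function(n_genes = 100,
                             isoform_prob = c(0.20, 0.35, 0.25, 0.20),
                             segments = c(3, 10),
                             segment_length = c(40, 120),
                             seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  with_seed(seed, function() {
    gene_id <- character(0); transcript_id <- character(0); length_nt <- numeric(0)
    gene_segment_lengths <- list()
    tx_segments <- list()
    for (gi in seq_len(n_genes)) {
      gid <- sprintf("G%04d", gi)
      S <- sample(segments[1]:segments[2], 1)
      seg_len <- sample(segment_length[1]:segment_length[2], S, replace = TRUE)
      gene_segment_lengths[[gid]] <- seg_len
      K <- sample(seq_along(isoform_prob), 1, prob = isoform_prob)
      anchor <- ceiling(S / 2)
      ranges <- list(c(1L, S))  # first isoform: full chain
      guard <- 0L
      while (length(ranges) < K && guard < 200L) {
        guard <- guard + 1L
        a <- sample(seq_len(anchor), 1)
        b <- sample(anchor:S, 1)
        if (b - a < 1L) next   # at least two segments
        r <- c(as.integer(a), as.integer(b))
        if (!any(vapply(ranges, identical, logical(1), r))) {
          ranges <- c(ranges, list(r))
        }
      }
      for (k in seq_along(ranges)) {
        tid <- sprintf("%s.T%d", gid, k)
        gene_id <- c(gene_id, gid)
        transcript_id <- c(transcript_id, tid)
        r <- ranges[[k]]
        length_nt <- c(length_nt, sum(seg_len[r[1]:r[2]]))
        tx_segments[[tid]] <- r
      }
    }
    transcript_catalog(gene_id, transcript_id, length_nt,
                       segments = list(gene_segment_lengths = gene_segment_lengths,
                                       tx_segments = tx_segments))
  })
}

#' Simulate a random cross-gene transcript network
#'
#' Draws `round(avg_neighbors * T / 2)` distinct cross-gene edges uniformly;
#' used as the "true" network a simulated ground truth is correlated with.
#'
#' @param catalog a [transcript_catalog()].
#' @param avg_neighbors target mean degree (default 8).
#' @param seed integer seed.
#' @return a [transcript_network()].
#' @export
simulate_network <- function(catalog, avg_neighbors = 8, seed = NULL) {
  n <- n_transcripts(catalog)
  m <- round(avg_neighbors * n / 2)
  with_seed(seed, function() {
    transcript_network(sample_cross_gene_edges(n, catalog$transcripts$gene, m),
                       catalog)
  })
}

#' Simulate network-correlated ground-truth transcript expressions
#'
#' Generation follows the structure the joint model assumes:
#' (1) gene read totals are Poisson(`mu`); (2) initial isoform expressions
#' come from power-law shares within each gene (Pareto weights with
#' exponent `gamma`) scaled to the gene total and length-normalized, with
#' multiplicative Gaussian noise of sd `sigma` times the value, truncated
#' at 0; (3) one sequential pass over transcripts in catalog order adds
#' `w` times the mean expression of each transcript's network neighbors,
#' using already-updated neighbor values where available; (4) expressions
#' are converted to per-gene read-origin proportions.
#'
#' @param catalog a [transcript_catalog()].
#' @param net a `transcript_network`.
#' @param mu Poisson mean of gene read totals (default 500).
#' @param gamma power-law exponent of isoform shares (default 1.5).
#' @param sigma Gaussian noise sd as a fraction of the initial value
#'   (default 0.1).
#' @param w neighbor-mixing weight (default 0.5; 0 switches the network
#'   influence off).
#' @param seed integer seed.
#' @return object of class `simulation_truth`: data.frame `transcripts`
#'   (gene_id, transcript_id, pi_true in reads per base, proportion),
#'   `gene_totals`, and the generation parameters.
#' @export
simulate_truth <- function(catalog, net, mu = 500, gamma = 1.5, sigma = 0.1,
                           w = 0.5, seed = NULL) {
  if (mu < 0 || sigma < 0 || w < 0) stop("mu, sigma and w must be >= 0")
  tx <- catalog$transcripts
  n <- nrow(tx)
  with_seed(seed, function() {
    N <- n_genes(catalog)
    totals <- stats::rpois(N, mu)
    expr <- numeric(n)
    for (gi in seq_len(N)) {
      rows <- catalog$tx_by_gene[[gi]]
      v <- stats::runif(length(rows))^(-1 / gamma)  # Pareto(gamma) weights
      share <- v / sum(v)
      e0 <- totals[gi] * share / tx$length[rows]
      e0 <- e0 * (1 + stats::rnorm(length(rows), 0, sigma))
      expr[rows] <- pmax(e0, 0)
    }
    ## sequential neighbor-average update in catalog order
    if (w > 0) {
      for (t in seq_len(n)) {
        nb <- net$neighbors[[t]]
        if (length(nb) > 0L) expr[t] <- expr[t] + w * mean(expr[nb])
      }
    }
    prop <- numeric(n); pi_true <- numeric(n)
    for (gi in seq_len(N)) {
      rows <- catalog$tx_by_gene[[gi]]
      wts <- expr[rows] * tx$length[rows]   # read-generating weight
      if (sum(wts) <= 0) wts <- rep(1, length(rows))
      prop[rows] <- wts / sum(wts)
      pi_true[rows] <- totals[gi] * prop[rows] / tx$length[rows]
    }
    structure(list(
      transcripts = data.frame(gene_id = tx$gene_id,
                               transcript_id = tx$transcript_id,
                               pi_true = pi_true, proportion = prop,
                               stringsAsFactors = FALSE),
      gene_totals = totals,
      params = list(mu = mu, gamma = gamma, sigma = sigma, w = w, seed = seed)
    ), class = "simulation_truth")
  })
}

## For one transcript, enumerate the distinct (first segment, last segment)
## windows a read of length l_r can cover, with the number of start
## positions in each. Returns a data.frame(a, b, starts) in the gene's
## segment-chain coordinates.
enumerate_windows <- function(seg_len, rng, l_r) {
  segs <- rng[1]:rng[2]
  lens <- seg_len[segs]
  l <- sum(lens)
  n_start <- l - l_r + 1
  if (n_start < 1) return(data.frame(a = integer(0), b = integer(0), starts = integer(0)))
  ends <- cumsum(lens)
  begins <- c(1, utils::head(ends, -1) + 1)
  out <- list()
  for (ai in seq_along(segs)) {
    x_lo <- begins[ai]
    x_hi <- min(ends[ai], n_start)
    if (x_lo > x_hi) next
    e_lo <- x_lo + l_r - 1
    e_hi <- x_hi + l_r - 1
    bi_lo <- findInterval(e_lo - 1, ends) + 1
    bi_hi <- findInterval(e_hi - 1, ends) + 1
    for (bi in bi_lo:bi_hi) {
      ## starts x with end position inside segment bi
      lo <- max(x_lo, begins[bi] - l_r + 1)
      hi <- min(x_hi, ends[bi] - l_r + 1)
      if (lo > hi) next
      out[[length(out) + 1L]] <- data.frame(a = segs[ai], b = segs[bi],
                                            starts = hi - lo + 1)
    }
  }
  if (length(out) == 0L) return(data.frame(a = integer(0), b = integer(0), starts = integer(0)))
  do.call(rbind, out)
}

#' Simulate reads and collapse them into equivalence classes
#'
#' Each read picks a transcript with probability proportional to
#' `pi_true * (l - l_r + 1)` (expression times number of start positions)
#' and a uniform start. Its compatible set is every same-gene isoform whose
#' segment range contains the covered segments; `q` comes from
#' [sampling_probability()]. Sampling is performed exactly by a single
#' multinomial draw over (transcript, covered-segment-window) cells, which
#' is distributionally identical to per-read sampling. Transcripts shorter
#' than the read receive no reads.
#'
#' @param truth a `simulation_truth`.
#' @param catalog the catalog used to build `truth`; must carry the
#'   synthetic segment structure of [simulate_catalog()].
#' @param n_reads total reads (>= 1).
#' @param read_length read length in nt (default 76).
#' @param seed integer seed.
#' @return a `compat_matrix`; attribute `origin_counts` carries the latent
#'   per-transcript origin counts for sampler diagnostics.
#' @export
simulate_reads <- function(truth, catalog, n_reads = 2e5, read_length = 76,
                           seed = NULL) {
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (is.null(catalog$segments)) stop("catalog lacks the synthetic segment structure")
  tx <- catalog$transcripts
  pi_true <- truth$transcripts$pi_true[match(tx$transcript_id,
                                             truth$transcripts$transcript_id)]
  n <- nrow(tx)
  cells <- vector("list", n)
  for (t in seq_len(n)) {
    gid <- tx$gene_id[t]
    seg_len <- catalog$segments$gene_segment_lengths[[gid]]
    rng <- catalog$segments$tx_segments[[tx$transcript_id[t]]]
    wnd <- enumerate_windows(seg_len, rng, read_length)
    if (nrow(wnd) > 0L) {
      wnd$tx <- t
      cells[[t]] <- wnd
    }
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells) || nrow(cells) == 0L) stop("no transcript can generate reads")
  weight <- pi_true[cells$tx] * cells$starts
  if (sum(weight) <= 0) stop("all sampling weights are zero")
  counts <- with_seed(seed, function() {
    as.vector(stats::rmultinom(1, size = as.integer(n_reads), prob = weight))
  })
  origin_counts <- numeric(n)
  agg <- tapply(counts, cells$tx, sum)
  origin_counts[as.integer(names(agg))] <- as.numeric(agg)
  ## compatible set per cell: same-gene isoforms whose range contains [a, b]
  genes <- vector("list", n_genes(catalog))
  for (gi in seq_len(n_genes(catalog))) {
    rows <- catalog$tx_by_gene[[gi]]
    K <- length(rows)
    rngs <- do.call(rbind, catalog$segments$tx_segments[tx$transcript_id[rows]])
    cell_rows <- which(cells$tx %in% rows & counts > 0)
    if (length(cell_rows) == 0L) {
      genes[[gi]] <- list(counts = numeric(0), Q = matrix(0, 0, K))
      next
    }
    keys <- character(0); cls_counts <- numeric(0); sets <- list()
    for (cr in cell_rows) {
      compat_k <- which(rngs[, 1] <= cells$a[cr] & rngs[, 2] >= cells$b[cr])
      key <- paste(compat_k, collapse = ",")
      pos <- match(key, keys)
      if (is.na(pos)) {
        keys <- c(keys, key); cls_counts <- c(cls_counts, counts[cr])
        sets <- c(sets, list(compat_k))
      } else {
        cls_counts[pos] <- cls_counts[pos] + counts[cr]
      }
    }
    ord <- order(keys, method = "radix")
    E <- length(keys)
    Q <- matrix(0, E, K)
    cc <- numeric(E)
    for (e in seq_len(E)) {
      src <- ord[e]
      k <- sets[[src]]
      Q[e, k] <- sampling_probability(tx$length[rows[k]], read_length)
      cc[e] <- cls_counts[src]
    }
    genes[[gi]] <- list(counts = cc, Q = Q)
  }
  res <- new_compat(genes, catalog)
  ## latent per-transcript origin counts, useful for sampler diagnostics
  attr(res, "origin_counts") <- origin_counts
  res
}

#' Correlation between estimated and true expressions
#'
#' Pearson correlation of `log2(pi + 1)`-transformed estimated versus true
#' expressions, restricted to a transcript subset: `all_multi_isoform`
#' (transcripts of genes with more than one isoform) or
#' `different_neighbor_isoforms` (transcripts of genes whose isoforms have
#' non-identical network neighbor sets -- where the prior can differentiate
#' isoforms).
#'
#' @param result a `quant_result`.
#' @param truth a `simulation_truth` over the same catalog.
#' @param subset `"all_multi_isoform"` or `"different_neighbor_isoforms"`.
#' @param catalog the shared [transcript_catalog()].
#' @param net required for `different_neighbor_isoforms`.
#' @return scalar Pearson correlation.
#' @export
evaluate_recovery <- function(result, truth, catalog,
                              subset = c("all_multi_isoform", "different_neighbor_isoforms"),
                              net = NULL) {
  subset <- match.arg(subset)
  tx <- catalog$transcripts
  est <- result$pi[match(tx$transcript_id, result$transcript_id)]
  tru <- truth$transcripts$pi_true[match(tx$transcript_id,
                                         truth$transcripts$transcript_id)]
  if (anyNA(est) || anyNA(tru)) stop("result/truth do not cover the catalog")
  keep <- logical(nrow(tx))
  for (gi in seq_len(n_genes(catalog))) {
    rows <- catalog$tx_by_gene[[gi]]
    if (length(rows) < 2L) next
    if (subset == "all_multi_isoform") {
      keep[rows] <- TRUE
    } else {
      if (is.null(net)) stop("net is required for subset 'different_neighbor_isoforms'")
      nbsets <- lapply(net$neighbors[rows], identity)
      distinct <- length(unique(lapply(nbsets, paste, collapse = ","))) > 1L
      if (distinct) keep[rows] <- TRUE
    }
  }
  if (!any(keep)) stop("selected subset is empty")
  x <- log2(est[keep] + 1)
  y <- log2(tru[keep] + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant values in the selected subset")
  }
  stats::cor(x, y)
}

#' One-call simulated dataset
#'
#' Generates catalog, network, network-correlated truth and read
#' compatibility classes under a single seed; the component generators
#' consume one RNG stream, so the whole dataset is reproducible from
#' `seed`.
#'
#' @param n_genes number of genes (default 100, about 250 transcripts).
#' @param n_reads total reads (default 200000).
#' @param read_length read length nt (default 76).
#' @param avg_neighbors target network mean degree (default 8).
#' @param mu,gamma,sigma,w truth-generation parameters, see
#'   [simulate_truth()].
#' @param seed integer seed.
#' @return list with `catalog`, `net`, `truth`, `compat`.
#' @export
simulate_dataset <- function(n_genes = 100, n_reads = 2e5, read_length = 76,
                             avg_neighbors = 8, mu = 500, gamma = 1.5,
                             sigma = 0.1, w = 0.5, seed = NULL) {
  with_seed(seed, function() {
    catalog <- simulate_catalog(n_genes)
    net <- simulate_network(catalog, avg_neighbors = avg_neighbors)
    truth <- simulate_truth(catalog, net, mu = mu, gamma = gamma,
                            sigma = sigma, w = w)
    compat <- simulate_reads(truth, catalog, n_reads = n_reads,
                             read_length = read_length)
    list(catalog = catalog, net = net, truth = truth, compat = compat)
  })
}
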