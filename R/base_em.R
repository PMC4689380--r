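## Floor applied inside logarithms only; stored probabilities keep exact
## zeros (the uncommitted likelihood has plateaus where zeros are
## legitimate maximizers).
.LOG_FLOOR <- 1e-12

## Extract one gene's slice (list(counts, Q)) from a compat_matrix,
## accepting either the slice itself or (compat, gene index).
gene_slice <- function(compat, gene = NULL) {
  if (inherits(compat, "compat_matrix")) {
    if (is.null(gene)) stop("gene index required with a compat_matrix")
    compat$genes[[gene]]
  } else compat
}

#' Per-gene uncommitted log-likelihood
#'
#' The mixture log-likelihood of the observed reads of one gene,
#' marginalizing each read's unknown transcript of origin:
#' `sum_e c_e log(sum_k p_k q_ek)` over equivalence classes `e`. A class
#' whose compatible transcripts all have `p = 0` contributes `-Inf`.
#'
#' @param p probability vector over the gene's transcripts (simplex).
#' @param compat a `compat_matrix` (with `gene`) or a single-gene slice
#'   `list(counts, Q)`.
#' @param gene gene index when `compat` is a full matrix.
#' @return scalar log-likelihood (0 for a gene with no reads).
#' @export
gene_log_likelihood <- function(p, compat, gene = NULL) {
  g <- gene_slice(compat, gene)
  if (length(p) != ncol(g$Q)) stop("p has wrong length for this gene")
  if (length(g$counts) == 0L) return(0)
  mix <- as.vector(g$Q %*% p)
  if (any(mix <= 0)) return(-Inf)
  sum(g$counts * log(mix))
}

## Shared EM engine: maximizes
##   sum_k prior_k log p_k + sum_e c_e log(sum_k p_k q_ek)
## over the simplex. prior = lambda * phi (zero for the base model).
## E-step responsibilities and M-step are in closed form.
em_engine <- function(g, prior, p0, tol, max_iter) {
  K <- ncol(g$Q)
  if (K == 1L) return(list(p = 1, iterations = 1L))
  p <- p0
  E <- length(g$counts)
  total <- sum(prior) + sum(g$counts)
  if (total <= 0) {
    ## no reads, flat prior: likelihood is constant
    return(list(p = p, iterations = 0L))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (E > 0L) {
      mix <- as.vector(g$Q %*% p)
      mix[mix < .LOG_FLOOR] <- .LOG_FLOOR
      n_exp <- p * as.vector(crossprod(g$Q, g$counts / mix))
    } else {
      n_exp <- numeric(K)
    }
    p_new <- (prior + n_exp) / sum(prior + n_exp)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol || it >= max_iter) break
  }
  list(p = p, iterations = it)
}

init_p <- function(K, init, seed = NULL) {
  if (init == "uniform") return(rep(1 / K, K))
  with_seed(seed, function() {
    x <- stats::rgamma(K, shape = 1)  # flat Dirichlet draw
    x / sum(x)
  })
}

#' Single-gene EM on the uncommitted likelihood (base model)
#'
#' Iterates the E-step `a_ek = p_k q_ek / sum_k p_k q_ek` and M-step
#' `p_k = sum_e c_e a_ek / |r|` until the maximum absolute coordinate change
#' drops below `tol`. The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param compat a `compat_matrix` (with `gene`) or single-gene slice; the
#'   gene must have at least one class.
#' @param gene gene index when `compat` is a full matrix.
#' @param init `"uniform"` (default, deterministic) or `"random"` (flat
#'   Dirichlet draw).
#' @param seed seed for random initialization.
#' @param tol convergence tolerance on `max |delta p|` (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list with `p` (simplex vector) and `iterations`.
#' @export
base_em_fit <- function(compat, gene = NULL, init = c("uniform", "random"),
                        seed = NULL, tol = 1e-8, max_iter = 1000) {
  init <- match.arg(init)
  g <- gene_slice(compat, gene)
  if (length(g$counts) == 0L) stop("gene has no read classes; base EM needs reads")
  K <- ncol(g$Q)
  em_engine(g, prior = numeric(K), p0 = init_p(K, init, seed),
            tol = tol, max_iter = max_iter)
}

#' Relative transcript abundance within a gene
#'
#' Length-normalized molar proportions:
#' `rho_k = (p_k / l_k) / sum_k (p_k / l_k)`.
#'
#' @param p read-origin probabilities (simplex).
#' @param lengths positive transcript lengths.
#' @return simplex vector `rho`.
#' @export
relative_abundance <- function(p, lengths) {
  if (length(p) != length(lengths)) stop("p and lengths differ in length")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (sum(p) <= 0) stop("all p are zero; relative abundance undefined")
  w <- p / lengths
  w / sum(w)
}

#' Transcript expression in reads per base
#'
#' `pi_k = |r| p_k / l_k` where `|r|` is the gene's aligned read count.
#'
#' @param p read-origin probabilities (simplex).
#' @param read_count total reads aligned to the gene (>= 0).
#' @param lengths positive transcript lengths.
#' @return numeric vector `pi`.
#' @export
transcript_expression <- function(p, read_count, lengths) {
  if (length(p) != length(lengths)) stop("p and lengths differ in length")
  if (read_count < 0) stop("read_count must be >= 0")
  read_count * p / lengths
}
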