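# Kullback-Leibler divergence D(V || WH) with the 0 log 0 = 0 convention.
kl_divergence <- function(V, WH) {
  eps <- .Machine$double.eps
  pos <- V > 0
  sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
}

#' Nonnegative matrix factorization with Brunet multiplicative updates
#'
#' Factorizes a nonnegative matrix V (features x samples) as W H using the
#' KL-divergence multiplicative update rules of the Brunet variant, which
#' never increase the divergence. Iteration stops when the relative change
#' in divergence falls below \code{tol} or after \code{max_iter} updates.
#'
#' @param V Nonnegative numeric matrix without missing values.
#' @param k Factorization rank, 1 <= k < min(dim(V)).
#' @param max_iter Maximum update iterations (default 2000).
#' @param tol Relative divergence-change stopping tolerance (default 1e-6).
#' @param seed Seed for the random uniform initialization.
#' @return List of class \code{nmf_fit}: \code{W} (features x k), \code{H}
#'   (k x samples), \code{divergence_trace}, \code{k}.
#' @export
nmf_brunet <- function(V, k, max_iter = 2000L, tol = 1e-6, seed = NULL) {
  if (any(is.na(V))) stop2("V must not contain missing values")
  if (any(V < 0)) stop2("V must be nonnegative")
  if (k < 1L || k >= min(dim(V)))
    stop2("k must satisfy 1 <= k < min(dim(V))")
  n <- nrow(V); p <- ncol(V)
  eps <- .Machine$double.eps
  with_seed(seed, {
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    H <- matrix(stats::runif(k * p, 0.1, 1), k, p)
    trace <- numeric(0)
    d_prev <- Inf
    for (it in seq_len(max_iter)) {
      # H update
      Q <- V / pmax(W %*% H, eps)
      H <- H * (t(W) %*% Q) / pmax(colSums(W), eps)
      # W update
      Q <- V / pmax(W %*% H, eps)
      W <- W * (Q %*% t(H)) / pmax(rep(1, n) %o% rowSums(H), eps)
      d <- kl_divergence(V, W %*% H)
      trace <- c(trace, d)
      if (is.finite(d_prev) &&
          abs(d_prev - d) / max(abs(d_prev), eps) < tol) break
      d_prev <- d
    }
    structure(list(W = W, H = H, divergence_trace = trace, k = k),
              class = "nmf_fit")
  })
}

# Hard cluster labels: the dominant metagene per sample.
nmf_labels <- function(fit) apply(fit$H, 2L, which.max)

#' Consensus clustering over NMF restarts and cophenetic rank selection
#'
#' For each candidate rank k, runs \code{nrun} random restarts of
#' [nmf_brunet()], assigns each sample to its dominant metagene, and forms
#' the consensus matrix of co-clustering frequencies. Cluster stability at
#' rank k is summarized by the cophenetic correlation coefficient: the
#' correlation between the consensus dissimilarities (1 - consensus) and
#' the cophenetic distances of their average-linkage dendrogram. The
#' selected rank is the one with the largest cophenetic coefficient (ties
#' to the smaller k).
#'
#' @param V Nonnegative matrix (e.g. a [split_signed()] NES matrix).
#' @param ks Candidate ranks (default 2:7).
#' @param nrun Restarts per rank (default 50).
#' @param max_iter,tol Passed to [nmf_brunet()].
#' @param seed Master seed; restarts use derived seeds.
#' @return List of class \code{nmf_rank_selection}: \code{k_selected},
#'   \code{cophenetic} (named per k), \code{consensus} (list of consensus
#'   matrices per k).
#' @export
select_rank <- function(V, ks = 2:7, nrun = 50L, max_iter = 500L,
                        tol = 1e-5, seed = 1L) {
  p <- ncol(V)
  coph <- stats::setNames(rep(NA_real_, length(ks)), ks)
  consensus <- vector("list", length(ks))
  names(consensus) <- ks
  for (ki in seq_along(ks)) {
    k <- ks[[ki]]
    C <- matrix(0, p, p)
    for (r in seq_len(nrun)) {
      fit <- nmf_brunet(V, k, max_iter = max_iter, tol = tol,
                        seed = child_seed(seed, ki * 1000L + r))
      lab <- nmf_labels(fit)
      C <- C + outer(lab, lab, "==")
    }
    C <- C / nrun
    dimnames(C) <- list(colnames(V), colnames(V))
    consensus[[ki]] <- C
    coph[[ki]] <- cophenetic_coefficient(C)
  }
  k_selected <- ks[[which.max(coph)]]  # which.max takes the first maximum
  structure(list(k_selected = k_selected, cophenetic = coph,
                 consensus = consensus),
            class = "nmf_rank_selection")
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Correlates the consensus dissimilarities (1 - consensus) with the
#' cophenetic distances of their average-linkage dendrogram. A perfectly
#' block-structured consensus (all dissimilarities 0 or reproduced
#' exactly) returns 1.
#'
#' @param consensus Symmetric matrix of co-clustering frequencies in
#'   [0, 1] with unit diagonal.
#' @return The coefficient in [-1, 1].
#' @export
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(1)
  stats::cor(d, cd)
}

#' Final NMF clustering at the selected rank
#'
#' Runs \code{n_init} random restarts at the chosen rank, keeps the run
#' with the lowest final divergence and returns its sample labels
#' (dominant metagene per sample).
#'
#' @param V Nonnegative matrix.
#' @param k_star Selected rank.
#' @param n_init Random restarts (default 500).
#' @param max_iter,tol Passed to [nmf_brunet()].
#' @param seed Master seed.
#' @return List of class \code{nmf_clustering}: \code{labels} (named by
#'   sample), \code{fit} (best \code{nmf_fit}), \code{divergence}.
#' @export
final_clusters <- function(V, k_star, n_init = 500L, max_iter = 1000L,
                           tol = 1e-6, seed = 1L) {
  best <- NULL
  best_d <- Inf
  for (r in seq_len(n_init)) {
    fit <- nmf_brunet(V, k_star, max_iter = max_iter, tol = tol,
                      seed = child_seed(seed, 900000L + r))
    d <- utils::tail(fit$divergence_trace, 1L)
    if (d < best_d) {
      best_d <- d
      best <- fit
    }
  }
  labels <- stats::setNames(nmf_labels(best), colnames(V))
  structure(list(labels = labels, fit = best, divergence = best_d),
            class = "nmf_clustering")
}
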