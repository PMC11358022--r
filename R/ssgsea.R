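# Weighted area-under-running-enrichment-score statistic.
#
# For genes ordered by decreasing value, in-set genes at ordered position i
# add |r_i|^w / sum_set |r|^w to the running sum and out-of-set genes
# subtract 1/(N - m). The area (sum of the running sum over all N
# positions) telescopes to
#   sum_set w_i (N - i + 1)  -  [C - sum_set (N - i + 1)] / (N - m)
# with C = N(N+1)/2, which is O(m) per evaluation given the ordered
# weights. This makes permutation nulls cheap.
es_area <- function(pos, rw_pow, csum_c, N) {
  m <- length(pos)
  cvals <- N - pos + 1
  w <- rw_pow[pos]
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  sum(w / sw * cvals) - (csum_c - sum(cvals)) / (N - m)
}

# Permutation null of the area statistic for set size m: mean and sd over
# nperm random position draws. Shared by all sets of the same size within
# one ranked sample.
es_null <- function(m, rw_pow, csum_c, N, nperm) {
  stat <- numeric(nperm)
  for (b in seq_len(nperm)) {
    stat[[b]] <- es_area(sample.int(N, m), rw_pow, csum_c, N)
  }
  c(mean = mean(stat), sd = stats::sd(stat))
}

ssgsea_one <- function(values, sets, weight, min_overlap, nperm, seed,
                       warn_full = TRUE) {
  ok <- !is.na(values)
  values <- values[ok]
  N <- length(values)
  ord <- order(values, decreasing = TRUE)
  rw_pow <- abs(values[ord])^weight
  gene_pos <- stats::setNames(seq_len(N), names(values)[ord])
  csum_c <- N * (N + 1) / 2
  keep <- logical(length(sets))
  nes <- rep(NA_real_, length(sets))
  raw <- rep(NA_real_, length(sets))
  with_seed(seed, {
    null_cache <- new.env(parent = emptyenv())
    for (s in seq_along(sets)) {
      present <- intersect(sets[[s]], names(gene_pos))
      m <- length(present)
      if (m < min_overlap) next
      if (m >= N) {
        if (warn_full)
          warning("gene set '", names(sets)[s],
                  "' covers all genes; dropped")
        next
      }
      keep[[s]] <- TRUE
      pos <- unname(gene_pos[present])
      raw[[s]] <- es_area(pos, rw_pow, csum_c, N)
      key <- as.character(m)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- es_null(m, rw_pow, csum_c, N, nperm)
      nl <- null_cache[[key]]
      nes[[s]] <- (raw[[s]] - nl[["mean"]]) / nl[["sd"]]
    }
  })
  list(keep = keep, nes = nes, raw = raw)
}

#' Single-sample GSEA projection of a gene-level matrix
#'
#' Per sample, values are replaced by ascending ranks scaled to (0, 1]
#' (rank normalization, so the score depends only on each sample's gene
#' ordering), genes are ordered by decreasing normalized value, and each
#' gene set's enrichment is the area under the weighted running-sum curve
#' (weight exponent 0.75 on the normalized values). The normalized
#' enrichment score is the z-score of that area against a gene-label
#' permutation null of the same set size (\code{nperm} draws; the null is
#' shared between sets of equal size within a sample, which the z-score
#' permits because it depends only on set size). Sets with fewer than
#' \code{min_overlap} member genes present in the matrix are dropped.
#'
#' @param x Gene-level quant matrix (rownames = gene symbols).
#' @param sets Named list of gene-symbol vectors (see [read_gmt()]).
#' @param weight Rank weight exponent (default 0.75).
#' @param min_overlap Minimum genes of a set present (default 10).
#' @param nperm Permutations for the null (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return Gene-set x sample matrix of NES values (layer \code{"score"}),
#'   containing only retained sets.
#' @export
ssgsea_scores <- function(x, sets, weight = 0.75, min_overlap = 10L,
                          nperm = 1000L, seed = NULL) {
  if (anyDuplicated(rownames(x))) stop2("gene symbols must be unique")
  res <- matrix(NA_real_, nrow = length(sets), ncol = ncol(x),
                dimnames = list(names(sets), colnames(x)))
  kept <- rep(TRUE, length(sets))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v <- v[!is.na(v)]
    if (length(unique(v)) < 2L)
      stop2("sample ", colnames(x)[j], " has < 2 distinct values")
    r <- rank(v, ties.method = "average") / length(v)
    one <- ssgsea_one(r, sets, weight, min_overlap, nperm,
                      seed = if (is.null(seed)) NULL
                             else child_seed(seed, j),
                      warn_full = j == 1L)
    res[, j] <- one$nes
    kept <- kept & one$keep
  }
  quant_matrix(res[kept, , drop = FALSE], "score")
}

#' Single-sample GSEA of one pre-ranked gene statistic
#'
#' Projects a single named ranking vector (e.g. per-gene RNA-protein
#' correlations, or mean log2 fold changes) onto gene sets. The ranking is
#' z-scored first, genes are ordered by decreasing z, and the same
#' weighted area statistic and permutation NES as [ssgsea_scores()] are
#' applied.
#'
#' @param ranking Named numeric vector, one value per gene.
#' @param sets Named list of gene-symbol vectors.
#' @inheritParams ssgsea_scores
#' @return data.frame with \code{gene_set}, \code{nes}, \code{n_overlap}.
#' @export
ssgsea_preranked <- function(ranking, sets, weight = 0.75,
                             min_overlap = 10L, nperm = 1000L,
                             seed = NULL) {
  if (is.null(names(ranking))) stop2("'ranking' must be named by gene")
  ranking <- ranking[!is.na(ranking)]
  if (stats::sd(ranking) == 0) stop2("ranking is constant")
  z <- (ranking - mean(ranking)) / stats::sd(ranking)
  one <- ssgsea_one(z, sets, weight, min_overlap, nperm, seed = seed)
  n_ov <- vapply(sets, function(s) length(intersect(s, names(z))),
                 integer(1))
  data.frame(gene_set = names(sets)[one$keep],
             nes = one$nes[one$keep],
             n_overlap = n_ov[one$keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split a signed matrix into nonnegative positive/negative parts
#'
#' Prepares signed enrichment-score matrices for NMF: each row r becomes
#' two rows, max(r, 0) and max(-r, 0), suffixed \code{.pos} / \code{.neg}.
#' The original matrix is recoverable as (positive part - negative part).
#'
#' @param x Real matrix.
#' @return Nonnegative matrix with 2x the rows and attribute
#'   \code{source_row} mapping back to input rownames.
#' @export
split_signed <- function(x) {
  pos <- pmax(x, 0)
  neg <- pmax(-x, 0)
  rownames(pos) <- paste0(rownames(x), ".pos")
  rownames(neg) <- paste0(rownames(x), ".neg")
  out <- rbind(pos, neg)
  attr(out, "source_row") <- rep(rownames(x), 2L)
  out
}
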