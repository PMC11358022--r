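#' Collapse a feature-level matrix to gene level by median
#'
#' Per gene and sample, the median over that gene's features; missing
#' values are ignored and an all-missing cell stays missing. Idempotent on
#' already gene-level input.
#'
#' @param x Quant matrix.
#' @param meta Feature metadata with \code{feature_id} and
#'   \code{gene_symbol}.
#' @return Quant matrix with gene symbols as rownames.
#' @export
collapse_to_gene <- function(x, meta) {
  genes <- meta$gene_symbol[match(rownames(x), meta$feature_id)]
  if (anyNA(genes))
    stop2("features without gene symbol: ",
          paste(utils::head(rownames(x)[is.na(genes)], 5), collapse = ", "))
  idx <- split(seq_len(nrow(x)), genes)
  out <- matrix(NA_real_, nrow = length(idx), ncol = ncol(x),
                dimnames = list(names(idx), colnames(x)))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- x[rows, ]
    } else {
      out[g, ] <- apply(x[rows, , drop = FALSE], 2L, stats::median,
                        na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  quant_matrix(out, quant_layer(x))
}

#' Per-gene Pearson correlation between two matched matrices
#'
#' Correlates two gene-level matrices (e.g. RNA and protein) gene by gene
#' over the samples where both values are present. Genes with fewer than
#' \code{min_pairs} complete pairs, or a zero-variance vector, are reported
#' with a missing correlation.
#'
#' @param x,y Gene-level quant matrices (rownames = gene symbols).
#' @param min_pairs Minimum complete pairs required (default 10).
#' @return data.frame with \code{gene_symbol}, \code{r}, \code{n_pairs}.
#' @export
correlate_pairs <- function(x, y, min_pairs = 10L) {
  genes <- intersect(rownames(x), rownames(y))
  samples <- intersect(colnames(x), colnames(y))
  if (!length(samples)) stop2("no shared samples between the matrices")
  r <- rep(NA_real_, length(genes))
  np <- integer(length(genes))
  for (i in seq_along(genes)) {
    xv <- x[genes[[i]], samples]
    yv <- y[genes[[i]], samples]
    ok <- !is.na(xv) & !is.na(yv)
    np[[i]] <- sum(ok)
    if (np[[i]] >= min_pairs &&
        stats::sd(xv[ok]) > 0 && stats::sd(yv[ok]) > 0) {
      r[[i]] <- stats::cor(xv[ok], yv[ok])
    }
  }
  data.frame(gene_symbol = genes, r = r, n_pairs = np,
             stringsAsFactors = FALSE)
}

#' CNV buffering score for one gene
#'
#' Quantifies how much a copy-number alteration's effect is attenuated
#' from RNA to protein:
#' \deqn{[cor(RNA, CN) - cor(protein, CN)] \times |mean(CN) - 2|}
#' computed over samples with all three values present (the three
#' correlations must share one sample universe for the difference to be
#' meaningful). Pearson correlations; CN on the linear copy scale.
#'
#' @param rna,protein,cn Per-sample numeric vectors for one gene, aligned.
#' @param min_triples Minimum complete triples (default 10).
#' @return The score, or NA when undefined (constant CN or too few
#'   triples).
#' @export
buffering_score <- function(rna, protein, cn, min_triples = 10L) {
  ok <- !is.na(rna) & !is.na(protein) & !is.na(cn)
  if (sum(ok) < min_triples) return(NA_real_)
  rna <- rna[ok]; protein <- protein[ok]; cn <- cn[ok]
  if (stats::sd(cn) == 0 || stats::sd(rna) == 0 || stats::sd(protein) == 0)
    return(NA_real_)
  (stats::cor(rna, cn) - stats::cor(protein, cn)) * abs(mean(cn) - 2)
}

#' Gene-level correlation and buffering table
#'
#' Joins matched RNA, protein and copy-number matrices by gene symbol and
#' reports, per gene, the pairwise Pearson correlations, the mean copy
#' number and the buffering score (all over listwise-complete triples for
#' the CN columns, pairwise-complete for RNA-protein).
#'
#' @param rna,protein,cn Gene-level quant matrices; \code{cn} on the linear
#'   copy scale.
#' @param min_pairs Minimum complete observations for any reported value.
#' @return data.frame with one row per shared gene.
#' @export
buffering_table <- function(rna, protein, cn, min_pairs = 10L) {
  genes <- Reduce(intersect, list(rownames(rna), rownames(protein),
                                  rownames(cn)))
  samples <- Reduce(intersect, list(colnames(rna), colnames(protein),
                                    colnames(cn)))
  rp <- correlate_pairs(rna[genes, samples, drop = FALSE],
                        protein[genes, samples, drop = FALSE],
                        min_pairs = min_pairs)
  res <- data.frame(gene_symbol = genes,
                    r_rna_protein = rp$r[match(genes, rp$gene_symbol)],
                    r_rna_cn = NA_real_, r_protein_cn = NA_real_,
                    n_triples = 0L, mean_cn = NA_real_,
                    buffering_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    rv <- rna[genes[[i]], samples]
    pv <- protein[genes[[i]], samples]
    cv <- cn[genes[[i]], samples]
    ok <- !is.na(rv) & !is.na(pv) & !is.na(cv)
    res$n_triples[[i]] <- sum(ok)
    if (sum(ok) >= min_pairs) {
      res$mean_cn[[i]] <- mean(cv[ok])
      if (stats::sd(cv[ok]) > 0) {
        if (stats::sd(rv[ok]) > 0)
          res$r_rna_cn[[i]] <- stats::cor(rv[ok], cv[ok])
        if (stats::sd(pv[ok]) > 0)
          res$r_protein_cn[[i]] <- stats::cor(pv[ok], cv[ok])
        res$buffering_score[[i]] <-
          buffering_score(rv, pv, cv, min_triples = min_pairs)
      }
    }
  }
  res
}

#' Round a fractional copy number to an integer call
#'
#' Nearest natural number, except in the vicinity of the diploid state:
#' values within 0.35 of 2 are called 2, while values between 1 and 3 that
#' deviate from 2 by more than 0.35 are called away from 2 (a subclonal
#' gain or loss is called rather than flattened to diploid). Outside (1, 3)
#' plain half-up rounding applies.
#'
#' @param value Numeric vector of nonnegative fractional copy numbers.
#' @param diploid_margin Half-width of the diploid vicinity (default 0.35).
#' @param plain Use plain nearest-integer rounding everywhere (default
#'   FALSE).
#' @return Integer vector of copy-number calls.
#' @export
round_cn <- function(value, diploid_margin = 0.35, plain = FALSE) {
  if (any(value < 0, na.rm = TRUE)) stop2("copy numbers must be >= 0")
  half_up <- function(v) as.integer(floor(v + 0.5))
  if (plain) return(half_up(value))
  out <- integer(length(value))
  out[] <- NA_integer_
  ok <- !is.na(value)
  near2 <- ok & abs(value - 2) <= diploid_margin + 1e-9
  gain <- ok & !near2 & value > 2 & value < 3
  loss <- ok & !near2 & value > 1 & value < 2
  rest <- ok & !near2 & !gain & !loss
  out[near2] <- 2L
  out[gain] <- 3L
  out[loss] <- 1L
  out[rest] <- half_up(value[rest])
  out
}

#' Call band-level copy numbers from 1-Mb bins
#'
#' Each bin (0-based half-open coordinates) is assigned to the cytogenetic
#' band it overlaps most (ties to the earlier band), its fractional copy
#' number is rounded with [round_cn()], and the band call is the most
#' prevalent integer among its bins. Ties between equally frequent calls
#' go to the value nearer 2, then to the smaller value (conservative
#' against false aberration calls). Bands with fewer than \code{min_bins}
#' valid bins are NA.
#'
#' @param bins data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{cn} (fractional copy number; NA for
#'   failed bins).
#' @param band_map data.frame with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive) and \code{band}.
#' @param min_bins Minimum valid bins per band (default 3).
#' @param diploid_margin Passed to [round_cn()].
#' @return data.frame with \code{band} and integer \code{cn} (NA where
#'   insufficient), one row per band of the map.
#' @export
bins_to_bands <- function(bins, band_map, min_bins = 3L,
                          diploid_margin = 0.35) {
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(bins)),
            all(c("chrom", "start", "end", "band") %in% names(band_map)))
  # convert band map to 0-based half-open
  bm_start <- band_map$start - 1L
  bm_end <- band_map$end
  assign_band <- rep(NA_integer_, nrow(bins))
  for (i in seq_len(nrow(bins))) {
    cand <- which(band_map$chrom == bins$chrom[[i]] &
                    bm_start < bins$end[[i]] & bm_end > bins$start[[i]])
    if (!length(cand)) next
    ov <- pmin(bm_end[cand], bins$end[[i]]) -
      pmax(bm_start[cand], bins$start[[i]])
    assign_band[[i]] <- cand[[which.max(ov)]]
  }
  if (anyNA(assign_band))
    warning(sum(is.na(assign_band)), " bin(s) overlap no band; skipped")
  calls <- round_cn(bins$cn, diploid_margin = diploid_margin)
  out_cn <- rep(NA_integer_, nrow(band_map))
  for (b in seq_len(nrow(band_map))) {
    v <- calls[!is.na(assign_band) & assign_band == b]
    v <- v[!is.na(v)]
    if (length(v) < min_bins) next
    tab <- table(v)
    top <- as.integer(names(tab)[tab == max(tab)])
    top <- top[order(abs(top - 2L), top)]
    out_cn[[b]] <- top[[1L]]
  }
  data.frame(band = band_map$band, cn = out_cn, stringsAsFactors = FALSE)
}
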