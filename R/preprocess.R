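#' Filter protein groups on identification-quality metadata
#'
#' Applies the standard search-output filters before any quantification is
#' used: reverse (decoy) hits, potential contaminants and proteins only
#' identified by a modification site are removed, and remaining features
#' must be supported by at least two peptides, at least one of them unique
#' or razor.
#'
#' @param x Quant matrix of log2 intensities (features x samples).
#' @param meta Feature metadata data.frame with columns \code{feature_id},
#'   \code{is_reverse}, \code{is_contaminant}, \code{only_identified_by_site},
#'   \code{n_peptides}, \code{n_unique_razor}.
#' @param min_peptides Minimum peptide count (default 2).
#' @param min_unique_razor Minimum unique+razor peptide count (default 1).
#' @return The filtered quant matrix.
#' @export
filter_protein_groups <- function(x, meta, min_peptides = 2L,
                                  min_unique_razor = 1L) {
  missing_meta <- setdiff(rownames(x), meta$feature_id)
  if (length(missing_meta))
    stop2("features without metadata: ", paste(missing_meta, collapse = ", "))
  m <- meta[match(rownames(x), meta$feature_id), , drop = FALSE]
  keep <- !as.logical(m$is_reverse) &
    !as.logical(m$is_contaminant) &
    !as.logical(m$only_identified_by_site) &
    m$n_peptides >= min_peptides &
    m$n_unique_razor >= min_unique_razor
  x[keep, , drop = FALSE]
}

#' Describe the TMT plex structure of a cohort
#'
#' @param plex Named character/integer vector mapping sample id to plex id.
#'   Must cover every column of the matrix it is used with, including the
#'   internal-standard channels.
#' @param standard Named character vector mapping plex id to the sample id
#'   of that plex's internal-standard channel.
#' @return A list of class \code{plex_layout}.
#' @export
plex_layout <- function(plex, standard) {
  if (is.null(names(plex)) || is.null(names(standard)))
    stop2("'plex' and 'standard' must be named")
  plexes <- unique(as.character(plex))
  miss <- setdiff(plexes, names(standard))
  if (length(miss))
    stop2("plex without internal standard: ", paste(miss, collapse = ", "))
  for (p in plexes) {
    if (!standard[[p]] %in% names(plex)[plex == p])
      stop2("internal standard ", standard[[p]], " is not a member of plex ", p)
  }
  structure(list(plex = plex, standard = standard), class = "plex_layout")
}

# per-sample median centering + SD-consistent MAD scaling (constant 1.4826)
median_mad_scale <- function(x) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    med <- stats::median(v, na.rm = TRUE)
    s <- stats::mad(v, na.rm = TRUE)  # already scaled by 1.4826
    if (!is.finite(s) || s == 0)
      stop2("sample ", colnames(x)[j], " has zero MAD; cannot scale")
    x[, j] <- (v - med) / s
  }
  x
}

#' Form TMT ratios against the internal standard and normalize
#'
#' Per plex, the internal-standard channel is subtracted element-wise from
#' each member sample (log2 intensities, so subtraction forms log ratios);
#' a missing standard value makes the ratio missing. The standard channels
#' are then dropped, and each remaining sample is median-centered and
#' scaled by its SD-consistent MAD (1.4826 x raw MAD), so every output
#' sample has median 0 and scaled MAD 1.
#'
#' @param x Quant matrix of log2 reporter intensities, columns covering all
#'   channels including internal standards.
#' @param layout A [plex_layout()].
#' @return Quant matrix of normalized log2 ratios, standards removed.
#' @export
tmt_ratio_normalize <- function(x, layout) {
  stopifnot(inherits(layout, "plex_layout"))
  miss <- setdiff(colnames(x), names(layout$plex))
  if (length(miss))
    stop2("samples without plex assignment: ", paste(miss, collapse = ", "))
  out <- x
  for (p in unique(as.character(layout$plex))) {
    members <- intersect(colnames(x), names(layout$plex)[layout$plex == p])
    std <- layout$standard[[p]]
    if (!std %in% members)
      stop2("plex ", p, " has no internal-standard column in the matrix")
    out[, members] <- x[, members] - x[, std]
  }
  std_cols <- unname(layout$standard)
  out <- out[, setdiff(colnames(out), std_cols), drop = FALSE]
  out <- median_mad_scale(out)
  quant_matrix(out, quant_layer(x))
}

#' Keep features detected in more than a given fraction of samples
#'
#' The retention rule is strict: a feature is kept when
#' \code{valid / total > min_frac}, so with the default 0.49 a feature seen
#' in exactly half of the samples passes.
#'
#' @param x Quant matrix.
#' @param min_frac Fraction threshold in [0, 1); default 0.49.
#' @return Filtered quant matrix.
#' @export
filter_min_valid <- function(x, min_frac = 0.49) {
  if (min_frac < 0 || min_frac >= 1) stop2("'min_frac' must be in [0, 1)")
  frac <- rowSums(!is.na(x)) / ncol(x)
  x[frac > min_frac, , drop = FALSE]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Column-wise imputation for left-censored (abundance-dependent)
#' missingness: within each sample with observed mean m and standard
#' deviation s, every missing value is replaced by an independent draw from
#' Normal(m - downshift*s, (width*s)^2). Observed entries are never
#' altered.
#'
#' @param x Quant matrix.
#' @param width SD of the imputation distribution in observed-SD units
#'   (default 0.3).
#' @param downshift Location shift below the observed mean in observed-SD
#'   units (default 1.8).
#' @param seed Integer seed; equal seeds give identical imputations.
#' @return Quant matrix with no missing values.
#' @export
impute_downshifted_normal <- function(x, width = 0.3, downshift = 1.8,
                                      seed = NULL) {
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      obs <- !is.na(v)
      if (sum(obs) < 2L)
        stop2("sample ", colnames(x)[j],
              " has fewer than 2 observed values; cannot impute")
      k <- sum(!obs)
      if (k > 0L) {
        m <- mean(v[obs])
        s <- stats::sd(v[obs])
        x[!obs, j] <- stats::rnorm(k, mean = m - downshift * s,
                                   sd = width * s)
      }
    }
    x
  })
}

#' Normalize RNA TPM values for joint analysis with proteomic ratios
#'
#' TPM values are log2(TPM + 1) transformed, each gene is centered by its
#' median across samples, and each sample is then median-centered and
#' MAD-scaled as in [tmt_ratio_normalize()]. Genes with no observed value
#' are dropped with a warning.
#'
#' @param x Quant matrix of nonnegative linear-scale TPM values.
#' @param log_transform Apply log2(TPM+1) first (default TRUE; set FALSE if
#'   the input is already on the log scale).
#' @return Normalized quant matrix, layer \code{"rna"}.
#' @export
normalize_rna_tpm <- function(x, log_transform = TRUE) {
  if (log_transform) {
    if (any(x < 0, na.rm = TRUE)) stop2("TPM values must be nonnegative")
    x[] <- log2(x + 1)
  }
  all_na <- rowSums(!is.na(x)) == 0L
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " gene(s) with no observed value")
    x <- x[!all_na, , drop = FALSE]
  }
  gene_med <- apply(x, 1L, stats::median, na.rm = TRUE)
  x <- x - gene_med
  quant_matrix(median_mad_scale(x), "rna")
}

#' Median-center each sample
#'
#' Per-sample median subtraction on the log2 scale, the normalization used
#' for label-free intensities before differential expression.
#'
#' @param x Quant matrix (log2).
#' @return Quant matrix with per-sample median 0.
#' @export
median_normalize <- function(x) {
  meds <- apply(x, 2L, stats::median, na.rm = TRUE)
  out <- sweep(x, 2L, meds, "-")
  quant_matrix(out, quant_layer(x))
}
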