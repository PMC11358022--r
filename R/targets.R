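#' Dependency cutoff from reference therapeutic targets
#'
#' The nomination cutoff is derived from known targets at run time: for
#' each reference gene, take the median gene-effect score across disease
#' cell lines, then take the median over the reference genes (with the
#' canonical IKZF1/IKZF3 pair this reproduces a cutoff near -0.4 on public
#' dependency snapshots).
#'
#' @param dep Gene x cell-line matrix of gene-effect scores (more negative
#'   = more essential).
#' @param disease_lines Character vector of disease cell-line ids
#'   (columns of \code{dep}).
#' @param reference_genes Reference targets (default IKZF1, IKZF3).
#' @return The cutoff (a single number).
#' @export
dependency_cutoff <- function(dep, disease_lines,
                              reference_genes = c("IKZF1", "IKZF3")) {
  miss <- setdiff(reference_genes, rownames(dep))
  if (length(miss))
    stop2("reference gene(s) absent from dependency table: ",
          paste(miss, collapse = ", "))
  cols <- intersect(disease_lines, colnames(dep))
  if (!length(cols)) stop2("no disease cell lines found in the table")
  med <- vapply(reference_genes, function(g) {
    stats::median(dep[g, cols], na.rm = TRUE)
  }, numeric(1))
  stats::median(med)
}

#' Nominate therapeutic targets from dependency data
#'
#' A candidate gene is kept when (i) its median dependency across disease
#' lines is below the cutoff, (ii) it is not a common-essential gene, and
#' (iii) its median dependency in disease lines is lower than in
#' non-disease lines by more than \code{min_diff} (disease-selective
#' essentiality). Genes absent from the dependency table are reported as
#' unevaluable (all rule flags NA).
#'
#' @param candidate_genes Character vector (disease-upregulated or
#'   disease-selective proteins' genes).
#' @param dep Gene x cell-line gene-effect matrix.
#' @param disease_lines Character vector of disease cell-line ids.
#' @param common_essential Character vector of pan-essential genes to
#'   exclude.
#' @param cutoff Dependency cutoff (e.g. from [dependency_cutoff()]).
#' @param min_diff Minimum disease-vs-other median difference (default
#'   0.1).
#' @return data.frame with per-gene medians, per-rule flags and the final
#'   \code{nominated} flag.
#' @export
nominate_targets <- function(candidate_genes, dep, disease_lines,
                             common_essential = character(0),
                             cutoff = -0.4, min_diff = 0.1) {
  disease_lines <- intersect(disease_lines, colnames(dep))
  other_lines <- setdiff(colnames(dep), disease_lines)
  genes <- unique(candidate_genes)
  res <- data.frame(gene = genes,
                    median_dep_disease = NA_real_,
                    median_dep_other = NA_real_,
                    pass_cutoff = NA, pass_not_essential = NA,
                    pass_selectivity = NA, nominated = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (!g %in% rownames(dep)) next
    md <- stats::median(dep[g, disease_lines], na.rm = TRUE)
    mo <- stats::median(dep[g, other_lines], na.rm = TRUE)
    res$median_dep_disease[[i]] <- md
    res$median_dep_other[[i]] <- mo
    res$pass_cutoff[[i]] <- !is.na(md) && md < cutoff
    res$pass_not_essential[[i]] <- !(g %in% common_essential)
    res$pass_selectivity[[i]] <- !is.na(md) && !is.na(mo) &&
      (mo - md) > min_diff
    res$nominated[[i]] <- res$pass_cutoff[[i]] &&
      res$pass_not_essential[[i]] && res$pass_selectivity[[i]]
  }
  res
}

#' Surface-protein candidates from an MM-versus-healthy regression
#'
#' Regresses median-normalized MM surface-protein intensity on the
#' corresponding healthy intensity by ordinary least squares and computes,
#' at each gene's healthy value, the 95% confidence interval of the fitted
#' mean and the 95% prediction interval for a new observation. Candidates
#' are the genes whose MM intensity exceeds the upper prediction bound
#' (MM-high outliers); set \code{two_sided = TRUE} to also flag MM-low
#' outliers.
#'
#' @param mm,healthy Named numeric vectors of log-scale median-normalized
#'   intensities, matched by gene name.
#' @param level Interval coverage (default 0.95).
#' @param two_sided Also flag genes below the lower prediction bound.
#' @return data.frame per gene: intensities, fitted value, confidence and
#'   prediction bounds, \code{candidate} flag.
#' @export
surface_candidates <- function(mm, healthy, level = 0.95,
                               two_sided = FALSE) {
  genes <- intersect(names(mm), names(healthy))
  ok <- genes[!is.na(mm[genes]) & !is.na(healthy[genes])]
  if (length(ok) < 10L)
    stop2("need at least 10 genes with both intensities")
  df <- data.frame(gene = ok, healthy = unname(healthy[ok]),
                   mm = unname(mm[ok]), stringsAsFactors = FALSE)
  fit <- stats::lm(mm ~ healthy, data = df)
  ci <- stats::predict(fit, newdata = df, interval = "confidence",
                       level = level)
  pi <- stats::predict(fit, newdata = df, interval = "prediction",
                       level = level)
  df$fitted <- ci[, "fit"]
  df$ci_lower <- ci[, "lwr"]; df$ci_upper <- ci[, "upr"]
  df$pi_lower <- pi[, "lwr"]; df$pi_upper <- pi[, "upr"]
  df$candidate <- df$mm > df$pi_upper
  if (two_sided) df$candidate <- df$candidate | df$mm < df$pi_lower
  attr(df, "fit") <- fit
  df
}
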