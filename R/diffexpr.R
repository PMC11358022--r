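#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-test by
#' moment matching on log sample variances: under the hierarchical model
#' s2 ~ s0^2 * F(df, d0), the mean and variance of log(s2) have closed
#' forms in digamma/trigamma functions, which are inverted here. When the
#' empirical variance of log(s2) does not exceed what sampling alone
#' explains, the prior degrees of freedom are infinite and s0^2 is the
#' bias-corrected geometric mean of the sample variances.
#'
#' @param s2 Numeric vector of per-feature sample variances (> 0 retained).
#' @param df Residual degrees of freedom per feature (recycled if scalar).
#' @return List of class \code{variance_prior} with elements \code{d0}
#'   (prior df, possibly \code{Inf}) and \code{s0_sq} (prior variance).
#' @export
fit_variance_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df >= 1
  s2 <- s2[ok]; df <- df[ok]
  if (!length(s2)) stop2("no positive variances with df >= 1")
  if (length(s2) < 2L)
    return(structure(list(d0 = Inf, s0_sq = mean(s2)),
                     class = "variance_prior"))
  z <- log(s2)
  # E[log s2] = log s0^2 + psi(df/2) - log(df/2) - psi(d0/2) + log(d0/2)
  # Var[log s2] = psi'(df/2) + psi'(d0/2)
  e_adj <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) * (length(z) - 1) / length(z) -
    mean(trigamma(df / 2))
  if (evar <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e_adj))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e_adj) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

# Newton inversion of the trigamma function on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated two-sample t-test across a feature matrix
#'
#' Classical pooled two-sample t statistics with the per-feature variance
#' shrunk toward an empirical-Bayes prior: the posterior variance is
#' (d0*s0^2 + df*s2) / (d0 + df) and the statistic is referred to a t
#' distribution with d0 + df degrees of freedom (standard normal in the
#' limit of infinite prior df). Per-feature degrees of freedom use that
#' feature's valid counts, so matrices may retain missing values. Features
#' with fewer than two valid values in either group are reported untested
#' (statistics NA) rather than dropped.
#'
#' @param x Quant matrix (log2 values).
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param prior A \code{variance_prior}, or \code{NULL} to fit it from the
#'   tested features of this comparison. Pass \code{list(d0 = 0)} to
#'   disable moderation (classical t-test).
#' @return A data.frame of class \code{de_result} with columns
#'   \code{feature_id}, \code{log2_fc}, \code{s2}, \code{df_residual},
#'   \code{t_mod}, \code{p_value}, \code{fdr}, \code{n_a}, \code{n_b}.
#' @export
moderated_t_test <- function(x, group_a, group_b, prior = NULL) {
  group_a <- intersect(colnames(x), group_a)
  group_b <- intersect(colnames(x), group_b)
  if (length(intersect(group_a, group_b)))
    stop2("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop2("each group needs at least 2 samples")
  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  na <- rowSums(!is.na(xa))
  nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  va <- apply(xa, 1L, stats::var, na.rm = TRUE)
  vb <- apply(xb, 1L, stats::var, na.rm = TRUE)
  testable <- na >= 2L & nb >= 2L
  df <- ifelse(testable, na + nb - 2L, NA_real_)
  s2 <- ifelse(testable,
               ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2L),
               NA_real_)
  fc <- ifelse(testable, ma - mb, NA_real_)
  if (is.null(prior)) {
    prior <- fit_variance_prior(s2[testable], df[testable])
  }
  d0 <- prior$d0
  s0 <- prior$s0_sq %||% NA_real_
  if (is.infinite(d0)) {
    post <- rep(s0, length(s2))
    df_tot <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    post <- s2
    df_tot <- df
  } else {
    post <- (d0 * s0 + df * s2) / (d0 + df)
    df_tot <- d0 + df
  }
  se <- sqrt(post * (1 / na + 1 / nb))
  t_mod <- ifelse(testable & se > 0, fc / se,
                  ifelse(testable & fc == 0, 0, NA_real_))
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)
  p[testable & !is.na(t_mod) & t_mod == 0] <- 1
  res <- data.frame(feature_id = rownames(x),
                    log2_fc = fc, s2 = s2, df_residual = df,
                    t_mod = t_mod, p_value = p,
                    fdr = bh_adjust(p),
                    n_a = na, n_b = nb,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "prior") <- prior
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment over the non-missing p-values (missing entries are
#' propagated and do not count toward the number of tests).
#'
#' @param p Numeric vector of p-values in [0, 1]; NA allowed.
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop2("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Subgroup-versus-rest differential scan
#'
#' Runs the moderated t-test of a clinical subgroup against all other
#' samples in the matrix, the comparison behind per-subgroup volcano and
#' genomic-location plots.
#'
#' @param x Quant matrix.
#' @param clinical Clinical table with \code{sample_id} and the flag column.
#' @param subgroup_field Name of a logical/0-1 column of \code{clinical}
#'   (e.g. \code{"t_11_14"}), or \code{subgroup_samples} directly.
#' @param subgroup_samples Optional explicit character vector of member ids.
#' @param fdr_threshold Significance threshold for the hit count attribute.
#' @param prior Optional variance prior (see [moderated_t_test()]).
#' @return \code{de_result} with attribute \code{n_significant}.
#' @export
subgroup_scan <- function(x, clinical = NULL, subgroup_field = NULL,
                          subgroup_samples = NULL, fdr_threshold = 0.05,
                          prior = NULL) {
  if (is.null(subgroup_samples)) {
    if (is.null(clinical) || is.null(subgroup_field))
      stop2("provide 'clinical' + 'subgroup_field', or 'subgroup_samples'")
    if (!subgroup_field %in% names(clinical))
      stop2("unknown clinical column: ", subgroup_field)
    flag <- as.logical(clinical[[subgroup_field]])
    subgroup_samples <- clinical$sample_id[!is.na(flag) & flag]
  }
  members <- intersect(colnames(x), subgroup_samples)
  rest <- setdiff(colnames(x), members)
  if (!length(members)) stop2("subgroup is empty")
  if (!length(rest)) stop2("subgroup covers all samples; no comparison group")
  if (length(members) < 3L || length(rest) < 3L)
    stop2("need >= 3 samples in the subgroup and in the rest")
  res <- moderated_t_test(x, members, rest, prior = prior)
  attr(res, "n_significant") <- sum(res$fdr < fdr_threshold, na.rm = TRUE)
  attr(res, "subgroup_field") <- subgroup_field
  res
}

#' Annotate differential results as cis or trans to an altered arm
#'
#' A feature is cis when its cytogenetic band lies on the altered
#' chromosome arm (e.g. band "1q21.3" is cis to region "1q"); everything
#' else is trans. The summary attributes report the cis fraction among
#' significant up- and downregulated features.
#'
#' @param result \code{de_result}.
#' @param meta Feature metadata with \code{feature_id} and \code{cytoband}.
#' @param altered_region Chromosome arm string such as \code{"1q"} or
#'   \code{"13q"}.
#' @param fdr_threshold Threshold defining the significant sets.
#' @return \code{de_result} with a \code{cis_flag} column and attributes
#'   \code{cis_fraction_up}, \code{cis_fraction_down}.
#' @export
annotate_cis_trans <- function(result, meta, altered_region,
                               fdr_threshold = 0.05) {
  if (!grepl("^([0-9]{1,2}|X|Y)[pq]$", altered_region))
    stop2("'altered_region' must be a chromosome arm such as '1q'")
  band <- meta$cytoband[match(result$feature_id, meta$feature_id)]
  result$cis_flag <- !is.na(band) & startsWith(band, altered_region) &
    !grepl(paste0("^", altered_region, "[0-9]*[pq]"), band)
  sig <- !is.na(result$fdr) & result$fdr < fdr_threshold
  up <- sig & result$log2_fc > 0
  dn <- sig & result$log2_fc < 0
  attr(result, "cis_fraction_up") <-
    if (any(up)) mean(result$cis_flag[up]) else NA_real_
  attr(result, "cis_fraction_down") <-
    if (any(dn)) mean(result$cis_flag[dn]) else NA_real_
  result
}
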