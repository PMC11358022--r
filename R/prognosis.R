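surv_endpoint <- function(clinical, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  miss <- setdiff(c(tcol, ecol), names(clinical))
  if (length(miss))
    stop2("clinical table lacks survival column(s): ",
          paste(miss, collapse = ", "))
  list(time = clinical[[tcol]], event = clinical[[ecol]], name = endpoint)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Efron tie handling, Newton iterations
#' to a relative log-likelihood tolerance of 1e-9 (at most 100
#' iterations). A thin, validated wrapper around [survival::coxph()]
#' returning the quantities downstream steps need.
#'
#' @param x Numeric covariate matrix (samples x covariates) or vector.
#' @param time,event Survival time and 0/1 event indicator.
#' @return List: \code{coefficients}, \code{log_partial_likelihood} (at
#'   the estimate), \code{covariance}, \code{p_values} (Wald, NA when the
#'   fit is degenerate), \code{converged}.
#' @export
cox_fit <- function(x, time, event) {
  x <- as.matrix(x)
  if (sum(event, na.rm = TRUE) < 1) stop2("no events in the data")
  if (any(!is.finite(x))) stop2("covariates must be finite")
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(const))
    stop2("constant covariate(s): ",
          paste(which(const), collapse = ", "))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100L)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100L)))
      attr(f, "flagged") <- TRUE
      f
    })
  flagged <- isTRUE(attr(fit, "flagged"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  p <- if (flagged) rep(NA_real_, length(beta)) else
    2 * stats::pnorm(-abs(beta / se))
  list(coefficients = beta,
       log_partial_likelihood = fit$loglik[[2L]],
       covariance = as.matrix(stats::vcov(fit)),
       p_values = p,
       converged = !flagged)
}

# Fast single-covariate Cox Wald p-value used by the screen and the
# bootstrap loops; same Efron Newton fit as cox_fit but through
# survival::coxph.fit, skipping the formula machinery.
cox_p_uni <- function(v, y) {
  f <- tryCatch(
    survival::coxph.fit(matrix(v, ncol = 1L), y, strata = NULL,
                        offset = NULL, init = 0,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100L),
                        weights = NULL, method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  if (is.null(f) || !is.finite(f$coefficients[[1L]]) ||
      !is.finite(f$var[[1L]]) || f$var[[1L]] <= 0)
    return(c(NA_real_, NA_real_))
  beta <- f$coefficients[[1L]]
  c(beta, 2 * stats::pnorm(-abs(beta) / sqrt(f$var[[1L]])))
}

#' Univariate Cox screen over fully quantified features
#'
#' For each feature without any missing value across the analysis cohort,
#' fits a continuous single-covariate Cox model for the chosen endpoint
#' and adjusts the Wald p-values with Benjamini-Hochberg across features.
#'
#' @param x Quant matrix; only rows with zero missingness are screened.
#' @param clinical Clinical table with \code{sample_id} and survival
#'   columns (\code{pfs_months}/\code{pfs_event} or os equivalents).
#' @param endpoint \code{"pfs"} (default) or \code{"os"}.
#' @return data.frame of class \code{cox_screen}: \code{feature_id},
#'   \code{coefficient}, \code{hazard_ratio}, \code{p_value}, \code{fdr}.
#' @export
cox_screen <- function(x, clinical, endpoint = "pfs") {
  samples <- intersect(colnames(x), clinical$sample_id)
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  sv <- surv_endpoint(cl, endpoint)
  keep <- !is.na(sv$time) & !is.na(sv$event)
  samples <- samples[keep]
  time <- sv$time[keep]; event <- sv$event[keep]
  xm <- x[, samples, drop = FALSE]
  full <- rowSums(is.na(xm)) == 0L
  if (!any(full)) stop2("no fully quantified features to screen")
  feats <- rownames(xm)[full]
  if (sum(event) < 1) stop2("no events in the analysis cohort")
  y <- survival::Surv(time, event)
  coefs <- p <- rep(NA_real_, length(feats))
  for (i in seq_along(feats)) {
    v <- xm[feats[[i]], ]
    if (stats::sd(v) == 0) next
    bp <- cox_p_uni(v, y)
    coefs[[i]] <- bp[[1L]]
    p[[i]] <- bp[[2L]]
  }
  res <- data.frame(feature_id = feats, coefficient = coefs,
                    hazard_ratio = exp(coefs), p_value = p,
                    fdr = bh_adjust(p), stringsAsFactors = FALSE)
  attr(res, "endpoint") <- endpoint
  attr(res, "n_samples") <- length(samples)
  class(res) <- c("cox_screen", "data.frame")
  res
}

#' Bootstrap confidence intervals of univariate Cox p-values
#'
#' Draws B bootstrap cohorts of the same size by sampling patients with
#' replacement (each resample carries its survival times, events and all
#' feature values), refits every univariate Cox model per resample, and
#' reports the 2.5th and 97.5th percentiles of each feature's B p-values.
#' Degenerate resamples (no events, or a feature constant within the
#' resample) contribute p = 1, which keeps the upper confidence limit
#' conservative.
#'
#' @inheritParams cox_screen
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return data.frame: \code{feature_id}, \code{boot_p_lower},
#'   \code{boot_p_upper}.
#' @export
bootstrap_p_ci <- function(x, clinical, endpoint = "pfs", B = 1000L,
                           seed = NULL) {
  if (B < 2L) stop2("B must be at least 2")
  samples <- intersect(colnames(x), clinical$sample_id)
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  sv <- surv_endpoint(cl, endpoint)
  keep <- !is.na(sv$time) & !is.na(sv$event)
  samples <- samples[keep]
  time <- sv$time[keep]; event <- sv$event[keep]
  xm <- x[, samples, drop = FALSE]
  full <- rowSums(is.na(xm)) == 0L
  if (!any(full)) stop2("no fully quantified features")
  xm <- xm[full, , drop = FALSE]
  n <- length(samples)
  P <- matrix(1, nrow = nrow(xm), ncol = B,
              dimnames = list(rownames(xm), NULL))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      tb <- time[idx]; eb <- event[idx]
      if (sum(eb) < 1) next  # p = 1 for all features
      yb <- survival::Surv(tb, eb)
      xb <- xm[, idx, drop = FALSE]
      for (i in seq_len(nrow(xb))) {
        v <- xb[i, ]
        if (stats::sd(v) == 0) next
        pv <- cox_p_uni(v, yb)[[2L]]
        P[i, b] <- if (is.na(pv)) 1 else pv
      }
    }
  })
  ci <- t(apply(P, 1L, stats::quantile, probs = c(0.025, 0.975)))
  data.frame(feature_id = rownames(xm),
             boot_p_lower = unname(ci[, 1L]),
             boot_p_upper = unname(ci[, 2L]),
             stringsAsFactors = FALSE)
}

#' Select risk-score candidates from screen and bootstrap results
#'
#' A feature becomes a candidate when its screen FDR and the upper limit
#' of its bootstrap p-value confidence interval are both below their
#' thresholds. Candidates are returned ordered by screen p-value.
#'
#' @param screen \code{cox_screen} result.
#' @param boot Output of [bootstrap_p_ci()].
#' @param fdr_max FDR threshold (default 0.1).
#' @param upper_max Bootstrap upper-CI threshold (default 0.1).
#' @return Character vector of selected feature ids (ordered by p).
#' @export
select_candidates <- function(screen, boot, fdr_max = 0.1,
                              upper_max = 0.1) {
  m <- merge(as.data.frame(screen), boot, by = "feature_id")
  sel <- !is.na(m$fdr) & m$fdr < fdr_max &
    !is.na(m$boot_p_upper) & m$boot_p_upper < upper_max
  m <- m[sel, , drop = FALSE]
  m$feature_id[order(m$p_value)]
}

#' Forward AIC-optimal multi-protein Cox model
#'
#' Starting from the empty model, repeatedly fits every one-protein
#' extension of the current model and adds the protein that minimizes
#' AIC = -2 log partial likelihood + 2 (number of proteins), stopping when
#' no addition lowers the AIC. Ties are broken by the candidate's
#' univariate screen p-value (smaller first).
#'
#' @param candidates Character vector of candidate feature ids.
#' @param x Quant matrix containing the candidates (no missing values in
#'   candidate rows over the analysis cohort).
#' @param clinical Clinical table.
#' @param endpoint \code{"pfs"} (default) or \code{"os"}.
#' @param screen_p Optional named vector of screen p-values for
#'   tie-breaking (names = feature ids).
#' @return Object of class \code{risk_model}: ordered \code{proteins},
#'   \code{coefficients} (from the final joint fit), \code{aic_trace},
#'   \code{endpoint}.
#' @export
stepwise_aic <- function(candidates, x, clinical, endpoint = "pfs",
                         screen_p = NULL) {
  if (!length(candidates)) stop2("no candidates supplied")
  samples <- intersect(colnames(x), clinical$sample_id)
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  sv <- surv_endpoint(cl, endpoint)
  keep <- !is.na(sv$time) & !is.na(sv$event)
  samples <- samples[keep]
  time <- sv$time[keep]; event <- sv$event[keep]
  xm <- t(x[candidates, samples, drop = FALSE])  # samples x candidates
  if (anyNA(xm)) stop2("candidate features must be fully quantified")
  if (is.null(screen_p))
    screen_p <- stats::setNames(rep(NA_real_, length(candidates)),
                                candidates)
  chosen <- character(0)
  aic_trace <- numeric(0)
  aic_cur <- Inf  # empty model: no likelihood contribution to compare; any
  # single-protein model is admitted if it beats the 1-parameter penalty
  # relative to the null partial likelihood, handled below.
  # Null model AIC: -2 * logPL(beta = 0) + 0.
  null_fit <- survival::coxph(survival::Surv(time, event) ~ 1)
  aic_cur <- -2 * null_fit$loglik[[1L]]
  fit_cur <- NULL
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    aic_new <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cols <- c(chosen, remaining[[i]])
      f <- tryCatch(cox_fit(xm[, cols, drop = FALSE], time, event),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) next
      fits[[i]] <- f
      aic_new[[i]] <- -2 * f$log_partial_likelihood + 2 * length(cols)
    }
    if (all(is.na(aic_new))) break
    best_aic <- min(aic_new, na.rm = TRUE)
    if (best_aic >= aic_cur) break
    tied <- which(!is.na(aic_new) & aic_new <= best_aic + 1e-12)
    if (length(tied) > 1L) {
      pv <- screen_p[remaining[tied]]
      tied <- tied[order(pv, na.last = TRUE)]
    }
    pick <- tied[[1L]]
    chosen <- c(chosen, remaining[[pick]])
    fit_cur <- fits[[pick]]
    aic_cur <- aic_new[[pick]]
    aic_trace <- c(aic_trace, aic_cur)
  }
  coefs <- if (length(chosen))
    stats::setNames(fit_cur$coefficients, chosen) else numeric(0)
  structure(list(proteins = chosen, coefficients = coefs,
                 aic_trace = aic_trace, endpoint = endpoint),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Protein risk model (", x$endpoint, " endpoint, ",
      length(x$proteins), " proteins)\n", sep = "")
  if (length(x$proteins)) {
    print(data.frame(protein = x$proteins,
                     coefficient = unname(x$coefficients),
                     row.names = NULL))
  } else {
    cat("  <empty model>\n")
  }
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefficients

#' Compute per-sample protein risk scores
#'
#' The risk score is the linear combination of protein abundances scaled
#' by the model coefficients. Model proteins absent from the matrix are
#' omitted from the sum (with a message), as are per-sample missing
#' values, so the score transfers to external cohorts that lack some
#' model proteins.
#'
#' @param model A \code{risk_model}.
#' @param x Quant matrix (proteins x samples).
#' @return Named numeric vector of scores, one per sample.
#' @export
risk_scores <- function(model, x) {
  present <- intersect(model$proteins, rownames(x))
  if (!length(present)) stop2("no model protein present in the matrix")
  absent <- setdiff(model$proteins, present)
  if (length(absent))
    message("omitting model term(s) absent from the matrix: ",
            paste(absent, collapse = ", "))
  xv <- x[present, , drop = FALSE]
  cf <- model$coefficients[present]
  contrib <- xv * cf
  colSums(contrib, na.rm = TRUE)
}

#' @export
predict.risk_model <- function(object, newdata, ...) {
  risk_scores(object, newdata)
}

#' Stratify samples into quartile-based risk groups
#'
#' With k = round(n/4): the k smallest scores form the low group, the k
#' largest the high group, and the middle two quartiles the medium group
#' (so n = 100 gives 25/50/25). Ties are resolved by stable input order.
#'
#' @param scores Named numeric vector of risk scores.
#' @return Factor of levels low/medium/high, named like \code{scores}.
#' @export
stratify_quartiles <- function(scores) {
  n <- length(scores)
  if (n < 4L) stop2("need at least 4 scores")
  k <- round(n / 4)
  ord <- order(scores)  # stable for ties
  g <- rep("medium", n)
  g[ord[seq_len(k)]] <- "low"
  g[ord[seq.int(n - k + 1L, n)]] <- "high"
  stats::setNames(factor(g, levels = c("low", "medium", "high")),
                  names(scores))
}

#' Kaplan-Meier medians and k-group log-rank test
#'
#' Per-group Kaplan-Meier median survival (NA when the curve never falls
#' to 0.5) and the (k-1)-df log-rank chi-square comparing the groups.
#'
#' @param groups Factor of group memberships, one per sample.
#' @param time,event Survival time and 0/1 event indicator, aligned with
#'   \code{groups}.
#' @return List: \code{medians} (named), \code{chisq}, \code{df},
#'   \code{p_value}, \code{fit} (the \code{survfit} object).
#' @export
km_logrank <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop2("need at least 2 nonempty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  tab <- summary(fit)$table
  med <- if (is.matrix(tab)) tab[, "median"] else tab[["median"]]
  names(med) <- sub("^groups=", "", names(med) %||% levels(groups))
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  list(medians = med, chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       fit = fit)
}

#' Multivariable Cox model of the risk score against R-ISS
#'
#' Joint Cox fit of the continuous risk score (hazard ratio per 1-point
#' increase) and R-ISS stage coded as indicator contrasts against stage I.
#' Samples with missing R-ISS are dropped (count reported via message).
#'
#' @param score Named numeric vector of risk scores.
#' @param r_iss Character/factor vector of stages I/II/III, aligned with
#'   \code{score}; NA allowed.
#' @param time,event Survival data aligned with \code{score}.
#' @return data.frame with one row per term: \code{term}, \code{hr},
#'   \code{ci_lower}, \code{ci_upper}, \code{p_value}.
#' @export
multivariable_cox <- function(score, r_iss, time, event) {
  r_iss <- factor(as.character(r_iss), levels = c("I", "II", "III"))
  keep <- !is.na(r_iss) & !is.na(score) & !is.na(time) & !is.na(event)
  if (sum(!keep))
    message("dropping ", sum(!keep), " sample(s) with missing R-ISS or ",
            "survival data")
  score <- score[keep]; r_iss <- droplevels(r_iss[keep])
  time <- time[keep]; event <- event[keep]
  fit <- survival::coxph(survival::Surv(time, event) ~ score + r_iss,
                         ties = "efron")
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = s$conf.int[, "exp(coef)"],
             ci_lower = s$conf.int[, "lower .95"],
             ci_upper = s$conf.int[, "upper .95"],
             p_value = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transfer the risk model to an external cohort
#'
#' Computes risk scores on an external matrix, omitting model terms for
#' proteins the external cohort did not quantify, and splits the cohort
#' into two groups at its own median score.
#'
#' @param model \code{risk_model}.
#' @param x External quant matrix.
#' @return List: \code{scores}, \code{groups} (factor low/high),
#'   \code{omitted} (model proteins not in the matrix).
#' @export
transfer_external <- function(model, x) {
  sc <- risk_scores(model, x)
  med <- stats::median(sc)
  groups <- factor(ifelse(sc > med, "high", "low"),
                   levels = c("low", "high"))
  names(groups) <- names(sc)
  list(scores = sc, groups = groups,
       omitted = setdiff(model$proteins, rownames(x)))
}
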