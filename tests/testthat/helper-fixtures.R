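# Shared fixture builders. Everything is generated in code; no data files.

make_qm <- function(values, features = NULL, samples = NULL,
                    layer = "protein") {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(features))
  rownames(values) <- features %||% sprintf("F%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("S%02d", seq_len(ncol(values)))
  quant_matrix(values, layer)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random matrix with a given fraction of missing entries.
random_qm <- function(n_feat, n_samp, miss_frac = 0, seed = 1,
                      layer = "protein") {
  set.seed(seed)
  v <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp)
  if (miss_frac > 0) v[runif(length(v)) < miss_frac] <- NA
  make_qm(v, layer = layer)
}

# Minimal clinical table with survival for the given sample ids.
make_clinical <- function(sample_ids, time, event, r_iss = NULL) {
  data.frame(sample_id = sample_ids, stage = "MM",
             pfs_months = time, pfs_event = event,
             os_months = time * 2, os_event = event,
             r_iss = r_iss %||% rep("II", length(sample_ids)),
             stringsAsFactors = FALSE)
}

# Exponential survival with log-hazard lp and exponential censoring.
sim_surv <- function(lp, base = log(2) / 30, censor_rate = 0.3) {
  n <- length(lp)
  t_ev <- rexp(n, rate = base * exp(lp))
  if (censor_rate > 0) {
    t_c <- rexp(n, rate = base * censor_rate / (1 - censor_rate))
    list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
  } else {
    list(time = t_ev, event = rep(1L, n))
  }
}

# Brute-force BH step-up, straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# One small default cohort shared by tests that only need realistic shapes.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_mm = 60, n_mgus = 4, n_pcl = 6, n_healthy = 6,
        n_proteins = 400, n_phospho = 120, seed = 42))
    }
    cache
  }
})
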