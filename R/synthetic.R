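#' Default cytogenetic band map for the synthetic genome
#'
#' A compact band map over autosomes 1-22: two p-arm and four q-arm bands
#' per chromosome, with contiguous 1-based inclusive coordinates. It is a
#' deliberately simplified genome: enough positional structure to give
#' cis/trans and band-calling logic something real to chew on, without
#' simulating actual cytogenetics.
#'
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{band}, \code{arm}.
#' @export
default_band_map <- function() {
  rows <- list()
  for (c in 1:22) {
    len <- 250e6 - (c - 1) * 9e6
    cen <- round(0.4 * len)
    p_b <- c("p12", "p11")
    q_b <- c("q11", "q21", "q22", "q31")
    p_edges <- round(seq(0, cen, length.out = 3L))
    q_edges <- round(seq(cen, len, length.out = 5L))
    for (i in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(c), start = p_edges[[i]] + 1,
        end = p_edges[[i + 1L]], band = paste0(c, p_b[[i]]),
        arm = paste0(c, "p"), stringsAsFactors = FALSE)
    }
    for (i in 1:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(c), start = q_edges[[i]] + 1,
        end = q_edges[[i + 1L]], band = paste0(c, q_b[[i]]),
        arm = paste0(c, "q"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Configuration of the synthetic multiomics cohort
#'
#' Defaults describe a newly-diagnosed myeloma cohort of desk scale: 120
#' MM samples plus small MGUS/PCL/healthy groups, subgroup frequencies in
#' the range reported for NDMM (t(11;14) ~20%, t(4;14) ~15%, HRD ~45%,
#' 1q gain ~40%), a cis dosage slope of 0.5 log2 units per copy, and
#' RNA-to-protein attenuation calibrated so the median per-gene
#' RNA-protein Pearson correlation lands near the 0.29 observed in
#' patient cohorts (with attenuation a = 0.5, RNA noise SD 0.5 and
#' protein noise SD 0.82, a diploid gene has r = a*sd_rna /
#' sqrt(a^2 sd_rna^2 + sd_prot^2) = 0.29).
#'
#' @param n_mm,n_mgus,n_pcl,n_healthy Group sizes (healthy split evenly
#'   over CD138/CD19/CD34 stages).
#' @param prop_t_11_14,prop_t_4_14,prop_t_14_16,prop_hrd Mutually
#'   exclusive primary-subgroup proportions (must sum to <= 1).
#' @param prop_del_13q,prop_del_17p,prop_del_1p Secondary deletion
#'   frequencies.
#' @param gain1q_probs Probabilities of 0/1/2 extra 1q copies.
#' @param n_proteins,n_phospho Feature counts.
#' @param frac_detected Target fraction of non-missing protein entries.
#' @param cis_dosage_slope RNA log2 units per copy-number unit.
#' @param rna_protein_attenuation Multiplier from RNA to protein signal.
#' @param noise_sd_rna,noise_sd_protein Residual SDs (log2 units).
#' @param trans_n_genes,trans_effect_sd Trans-effect signature size and
#'   effect SD per translocation subgroup (magnitudes are free parameters
#'   of the generator; see the methods vignette).
#' @param site_sd Extra phosphosite noise SD around the parent protein.
#' @param planted_prognostic data.frame(\code{feature_id},
#'   \code{coefficient}): proteins given a real log-hazard effect.
#' @param censor_rate Expected censoring fraction under the null.
#' @param baseline_hazard Exponential baseline hazard per month.
#' @param mnar_strength Logistic slope of missingness in abundance
#'   (0 = missing completely at random).
#' @param subclonal_retain Probability an archetype band alteration is
#'   retained in a given sample (Bernoulli subclonal deviation).
#' @param seed Master seed.
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(n_mm = 120L, n_mgus = 7L, n_pcl = 17L,
                          n_healthy = 9L,
                          prop_t_11_14 = 0.20, prop_t_4_14 = 0.15,
                          prop_t_14_16 = 0.05, prop_hrd = 0.45,
                          prop_del_13q = 0.40, prop_del_17p = 0.10,
                          prop_del_1p = 0.10,
                          gain1q_probs = c(0.60, 0.25, 0.15),
                          n_proteins = 2000L, n_phospho = 600L,
                          frac_detected = 0.8,
                          cis_dosage_slope = 0.5,
                          rna_protein_attenuation = 0.5,
                          noise_sd_rna = 0.5, noise_sd_protein = 0.82,
                          trans_n_genes = 50L, trans_effect_sd = 0.8,
                          site_sd = 0.5,
                          planted_prognostic = data.frame(
                            feature_id = c("G0001", "G0002", "G0003"),
                            coefficient = c(0.8, -0.8, 0.6),
                            stringsAsFactors = FALSE),
                          censor_rate = 0.3,
                          baseline_hazard = log(2) / 30,
                          mnar_strength = 1.5,
                          subclonal_retain = 0.9,
                          seed = 1L) {
  cfg <- mget(names(formals()))
  if (prop_t_11_14 + prop_t_4_14 + prop_t_14_16 + prop_hrd > 1 + 1e-12)
    stop2("primary subgroup proportions sum to more than 1")
  props <- c(prop_t_11_14, prop_t_4_14, prop_t_14_16, prop_hrd,
             prop_del_13q, prop_del_17p, prop_del_1p, gain1q_probs,
             frac_detected, censor_rate)
  if (any(props < 0 | props > 1)) stop2("proportions must lie in [0, 1]")
  if (abs(sum(gain1q_probs) - 1) > 1e-9)
    stop2("gain1q_probs must sum to 1")
  if (n_mm < 4L) stop2("n_mm must be at least 4")
  if (baseline_hazard <= 0) stop2("baseline_hazard must be positive")
  if (mnar_strength < 0) stop2("mnar_strength must be >= 0")
  structure(cfg, class = "cohort_config")
}

# Solve the logistic missingness threshold so the expected missing
# fraction over the realized abundances equals the target.
mnar_threshold <- function(values, target, slope) {
  v <- values[is.finite(values)]
  if (target <= 0) return(-Inf)
  if (slope == 0) return(NA_real_)  # MCAR handled by caller
  f <- function(c) mean(stats::plogis(slope * (c - v))) - target
  stats::uniroot(f, lower = min(v) - 20, upper = max(v) + 20)$root
}

apply_mnar <- function(x, frac_detected, slope, protect = character(0)) {
  target <- 1 - frac_detected
  if (target <= 0) return(x)
  rows <- setdiff(rownames(x), protect)
  v <- x[rows, , drop = FALSE]
  p <- if (slope == 0) {
    matrix(target, nrow(v), ncol(v))
  } else {
    c0 <- mnar_threshold(v, target, slope)
    stats::plogis(slope * (c0 - v))
  }
  drop <- matrix(stats::runif(length(v)) < p, nrow(v), ncol(v))
  v[drop] <- NA_real_
  x[rows, ] <- v
  x
}

#' Generate a synthetic multiomics plasma-cell cohort
#'
#' Draws a cohort with the statistical structure the analysis pipeline
#' assumes: per-sample band copy numbers from subgroup archetypes (HRD
#' trisomies of odd chromosomes, 1q gains, 13q/17p/1p deletions, each
#' retained per sample with a subclonal Bernoulli), RNA driven by cis gene
#' dosage plus subgroup trans effects and noise, protein as attenuated
#' RNA plus noise, phosphopeptides inheriting their parent protein's
#' signal, intensity-dependent (MNAR) missingness on the proteomic
#' layers, and exponential survival with log-hazard equal to the planted
#' prognostic coefficients times the (centered) true protein values, with
#' independent exponential censoring. Planted prognostic proteins are
#' kept fully quantified so they remain eligible for the Cox screen.
#'
#' @param config A [cohort_config()].
#' @return List of class \code{synthetic_cohort}: quant matrices
#'   \code{protein}, \code{phospho}, \code{rna} (log2) and \code{rna_tpm}
#'   (linear), \code{clinical}, \code{band_cn} (band x sample integer
#'   matrix), \code{feature_meta}, \code{band_map} and
#'   \code{ground_truth}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    band_map <- default_band_map()
    n_bands <- nrow(band_map)

    stages <- c(rep(c("HEALTHY_CD138", "HEALTHY_CD19", "HEALTHY_CD34"),
                    length.out = cfg$n_healthy),
                rep("MGUS", cfg$n_mgus), rep("MM", cfg$n_mm),
                rep("PCL", cfg$n_pcl))
    n <- length(stages)
    sample_ids <- sprintf("S%03d", seq_len(n))
    malignant <- stages %in% c("MGUS", "MM", "PCL")

    # primary subgroup per malignant clone
    p_primary <- c(t_11_14 = cfg$prop_t_11_14, t_4_14 = cfg$prop_t_4_14,
                   t_14_16 = cfg$prop_t_14_16, hrd = cfg$prop_hrd)
    p_primary <- c(p_primary, none = 1 - sum(p_primary))
    subgroup <- rep("healthy", n)
    subgroup[malignant] <- sample(names(p_primary), sum(malignant),
                                  replace = TRUE, prob = p_primary)
    del_13q <- malignant & stats::runif(n) < cfg$prop_del_13q
    del_17p <- malignant & stats::runif(n) < cfg$prop_del_17p
    del_1p <- malignant & stats::runif(n) < cfg$prop_del_1p
    gain1q <- integer(n)
    gain1q[malignant] <- sample(0:2, sum(malignant), replace = TRUE,
                                prob = cfg$gain1q_probs)

    # band copy numbers
    odd_chroms <- as.character(c(3, 5, 7, 9, 11, 15, 19, 21))
    band_cn <- matrix(2L, n_bands, n,
                      dimnames = list(band_map$band, sample_ids))
    retain <- function(k) stats::runif(k) < cfg$subclonal_retain
    for (s in seq_len(n)) {
      if (!malignant[[s]]) next
      if (subgroup[[s]] == "hrd") {
        b <- which(band_map$chrom %in% odd_chroms)
        band_cn[b[retain(length(b))], s] <- 3L
      }
      if (gain1q[[s]] > 0L) {
        b <- which(band_map$arm == "1q")
        band_cn[b[retain(length(b))], s] <- 2L + gain1q[[s]]
      }
      if (del_13q[[s]]) {
        b <- which(band_map$arm == "13q")
        band_cn[b[retain(length(b))], s] <- 1L
      }
      if (del_17p[[s]]) {
        b <- which(band_map$arm == "17p")
        band_cn[b[retain(length(b))], s] <- 1L
      }
      if (del_1p[[s]]) {
        b <- which(band_map$arm == "1p")
        band_cn[b[retain(length(b))], s] <- 1L
      }
    }

    # genes on bands
    genes <- sprintf("G%04d", seq_len(cfg$n_proteins))
    gene_band_idx <- sample.int(n_bands, cfg$n_proteins, replace = TRUE)
    gene_cn <- band_cn[gene_band_idx, , drop = FALSE]
    rownames(gene_cn) <- genes

    # trans-effect signatures per translocation subgroup
    trans_groups <- c("t_11_14", "t_4_14", "t_14_16")
    trans_genes <- list()
    trans_mat <- matrix(0, cfg$n_proteins, n,
                        dimnames = list(genes, sample_ids))
    n_trans <- min(cfg$trans_n_genes, cfg$n_proteins)
    for (tg in trans_groups) {
      gi <- sample.int(cfg$n_proteins, n_trans)
      eff <- stats::rnorm(n_trans, 0, cfg$trans_effect_sd)
      trans_genes[[tg]] <- data.frame(feature_id = genes[gi],
                                      effect = eff,
                                      stringsAsFactors = FALSE)
      members <- subgroup == tg
      if (any(members)) trans_mat[gi, members] <-
          trans_mat[gi, members] + eff
    }

    rna <- cfg$cis_dosage_slope * (gene_cn - 2) + trans_mat +
      matrix(stats::rnorm(cfg$n_proteins * n, 0, cfg$noise_sd_rna),
             cfg$n_proteins, n)
    protein_true <- cfg$rna_protein_attenuation * rna +
      matrix(stats::rnorm(cfg$n_proteins * n, 0, cfg$noise_sd_protein),
             cfg$n_proteins, n)
    dimnames(rna) <- dimnames(protein_true) <- list(genes, sample_ids)

    # phosphopeptides inherit the parent protein signal
    parent <- sample.int(cfg$n_proteins, cfg$n_phospho, replace = TRUE)
    phospho_ids <- sprintf("%s_p%03d", genes[parent],
                           seq_len(cfg$n_phospho))
    phospho <- protein_true[parent, , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_phospho * n, 0, cfg$site_sd),
             cfg$n_phospho, n)
    rownames(phospho) <- phospho_ids

    # survival from the planted prognostic proteins (MM and PCL samples)
    planted <- cfg$planted_prognostic
    miss_pl <- setdiff(planted$feature_id, genes)
    if (length(miss_pl))
      stop2("planted prognostic feature(s) not among genes: ",
            paste(miss_pl, collapse = ", "))
    surv_samples <- stages %in% c("MM", "PCL")
    pl_vals <- protein_true[planted$feature_id, , drop = FALSE]
    pl_center <- rowMeans(pl_vals[, surv_samples, drop = FALSE])
    lp <- drop(crossprod(pl_vals - pl_center, planted$coefficient))
    names(lp) <- sample_ids
    draw_surv <- function(base) {
      t_ev <- stats::rexp(n, rate = base * exp(lp))
      if (cfg$censor_rate > 0) {
        c_rate <- base * cfg$censor_rate / (1 - cfg$censor_rate)
        t_c <- stats::rexp(n, rate = c_rate)
        list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
      } else {
        list(time = t_ev, event = rep(1L, n))
      }
    }
    pfs <- draw_surv(cfg$baseline_hazard)
    os <- draw_surv(cfg$baseline_hazard / 2.5)
    pfs$time[!surv_samples] <- NA_real_
    pfs$event[!surv_samples] <- NA_integer_
    os$time[!surv_samples] <- NA_real_
    os$event[!surv_samples] <- NA_integer_

    r_iss <- rep(NA_character_, n)
    r_iss[surv_samples] <- sample(c("I", "II", "III"), sum(surv_samples),
                                  replace = TRUE, prob = c(0.3, 0.5, 0.2))
    r_iss[surv_samples][stats::runif(sum(surv_samples)) < 0.1] <-
      NA_character_

    clinical <- data.frame(
      sample_id = sample_ids, stage = stages,
      t_11_14 = as.integer(subgroup == "t_11_14"),
      t_4_14 = as.integer(subgroup == "t_4_14"),
      t_14_16 = as.integer(subgroup == "t_14_16"),
      hrd = as.integer(subgroup == "hrd"),
      del_13q = as.integer(del_13q), del_17p = as.integer(del_17p),
      del_1p = as.integer(del_1p), gain1q_copies = gain1q,
      macs_sorted = as.integer(stats::runif(n) < 0.8),
      purity_pct = round(stats::runif(n, 70, 100), 1),
      pfs_months = round(pfs$time, 2), pfs_event = pfs$event,
      os_months = round(os$time, 2), os_event = os$event,
      r_iss = r_iss, stringsAsFactors = FALSE)

    # observed matrices: MNAR missingness on the proteomic layers
    protein_obs <- apply_mnar(protein_true, cfg$frac_detected,
                              cfg$mnar_strength,
                              protect = planted$feature_id)
    phospho_obs <- apply_mnar(phospho, cfg$frac_detected,
                              cfg$mnar_strength)

    gene_base <- stats::rnorm(cfg$n_proteins, 6, 1.5)
    rna_tpm <- 2^(rna + gene_base)
    dimnames(rna_tpm) <- dimnames(rna)

    meta_protein <- data.frame(
      feature_id = genes, gene_symbol = genes,
      feature_class = "protein",
      chrom = band_map$chrom[gene_band_idx],
      arm = band_map$arm[gene_band_idx],
      cytoband = band_map$band[gene_band_idx],
      n_peptides = pmax(2L, stats::rpois(cfg$n_proteins, 6)),
      n_unique_razor = pmax(1L, stats::rpois(cfg$n_proteins, 3)),
      is_reverse = FALSE, is_contaminant = FALSE,
      only_identified_by_site = FALSE, stringsAsFactors = FALSE)
    meta_phospho <- data.frame(
      feature_id = phospho_ids, gene_symbol = genes[parent],
      feature_class = "phosphopeptide",
      chrom = band_map$chrom[gene_band_idx[parent]],
      arm = band_map$arm[gene_band_idx[parent]],
      cytoband = band_map$band[gene_band_idx[parent]],
      n_peptides = 1L, n_unique_razor = 1L,
      is_reverse = FALSE, is_contaminant = FALSE,
      only_identified_by_site = FALSE, stringsAsFactors = FALSE)
    meta_phospho$phospho_site <- sprintf("S%d_1", sample.int(
      900, cfg$n_phospho, replace = TRUE) + 10L)

    ground_truth <- list(
      subgroup = stats::setNames(subgroup, sample_ids),
      band_cn = band_cn,
      gene_band = stats::setNames(band_map$band[gene_band_idx], genes),
      gene_arm = stats::setNames(band_map$arm[gene_band_idx], genes),
      planted_prognostic = planted,
      true_risk = lp,
      protein_true = protein_true,
      trans_genes = trans_genes,
      archetype_arms = list(gain1q = "1q", del_13q = "13q",
                            del_17p = "17p", del_1p = "1p",
                            hrd = c(paste0(odd_chroms, "p"),
                                    paste0(odd_chroms, "q"))),
      config = cfg)

    structure(list(
      protein = quant_matrix(protein_obs, "protein"),
      phospho = quant_matrix(phospho_obs, "phosphopeptide"),
      rna = quant_matrix(rna, "rna"),
      rna_tpm = rna_tpm,
      clinical = clinical,
      band_cn = band_cn,
      feature_meta = merge_meta(meta_protein, meta_phospho),
      band_map = band_map,
      ground_truth = ground_truth), class = "synthetic_cohort")
  })
}

merge_meta <- function(a, b) {
  a$phospho_site <- NA_character_
  rbind(a, b)
}

#' Machine-readable ground-truth report of a synthetic cohort
#'
#' Flattens the generator's ground truth into one long table usable for
#' recovery assertions: planted prognostic coefficients, cis features per
#' alteration archetype, and the true subgroup (cluster) label per
#' sample.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @return data.frame with \code{record}, \code{id}, \code{value}.
#' @export
truth_report <- function(cohort) {
  gt <- cohort$ground_truth
  planted <- data.frame(record = "planted_prognostic",
                        id = gt$planted_prognostic$feature_id,
                        value = as.character(
                          gt$planted_prognostic$coefficient),
                        stringsAsFactors = FALSE)
  cis <- do.call(rbind, lapply(names(gt$archetype_arms), function(a) {
    arms <- gt$archetype_arms[[a]]
    feats <- names(gt$gene_arm)[gt$gene_arm %in% arms]
    if (!length(feats)) return(NULL)
    data.frame(record = paste0("cis_", a), id = feats, value = "cis",
               stringsAsFactors = FALSE)
  }))
  labels <- data.frame(record = "subgroup", id = names(gt$subgroup),
                       value = unname(gt$subgroup),
                       stringsAsFactors = FALSE)
  rbind(planted, cis, labels)
}
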