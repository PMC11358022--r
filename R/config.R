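#' Default analysis configuration
#'
#' One flat key-value list holding every tunable parameter of the
#' pipeline stages, with defaults equal to the values used throughout the
#' package documentation. A YAML config file and command-line flags can
#' override individual keys; the effective values are logged by the CLI
#' so every run is reproducible from its log.
#'
#' @param ... Name-value overrides of defaults.
#' @return Named list of class \code{analysis_config}.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    min_frac = 0.49,          # valid-value filter: keep if frac > this
    impute_width = 0.3,       # imputation SD in observed-SD units
    impute_downshift = 1.8,   # imputation downshift in observed-SD units
    min_pairs = 10L,          # min complete pairs for correlations
    fdr_threshold = 0.05,     # significance for subgroup scans
    ssgsea_weight = 0.75,
    ssgsea_min_overlap = 10L,
    ssgsea_nperm = 1000L,
    nmf_k_min = 2L, nmf_k_max = 7L,
    nmf_nrun = 50L,
    nmf_final_init = 500L,
    boot_b = 1000L,           # bootstrap resamples of the Cox screen
    fdr_max = 0.1,            # candidate gate: screen FDR
    upper_max = 0.1,          # candidate gate: bootstrap upper p CI
    cn_diploid_margin = 0.35, # copy-number rounding vicinity of 2
    cn_min_bins = 3L,
    dep_min_diff = 0.1,       # disease-vs-other dependency difference
    master_seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop2("unknown config key(s): ",
                         paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(structure(cfg, class = "analysis_config"))
}

validate_config <- function(cfg) {
  chk <- function(cond, what) if (!cond) stop2("config: ", what)
  chk(cfg$min_frac >= 0 && cfg$min_frac < 1, "min_frac must be in [0,1)")
  chk(cfg$impute_width > 0, "impute_width must be > 0")
  chk(cfg$impute_downshift >= 0, "impute_downshift must be >= 0")
  chk(cfg$min_pairs >= 2, "min_pairs must be >= 2")
  chk(cfg$ssgsea_weight >= 0, "ssgsea_weight must be >= 0")
  chk(cfg$ssgsea_nperm >= 2, "ssgsea_nperm must be >= 2")
  chk(cfg$nmf_k_min >= 1 && cfg$nmf_k_max >= cfg$nmf_k_min,
      "nmf rank range is invalid")
  chk(cfg$boot_b >= 2, "boot_b must be >= 2")
  chk(cfg$cn_diploid_margin >= 0 && cfg$cn_diploid_margin < 0.5,
      "cn_diploid_margin must be in [0, 0.5)")
  cfg
}

#' Read an analysis configuration from a flat YAML file
#'
#' @param path Path to a YAML file of scalar key-value pairs; keys must
#'   be known configuration parameters.
#' @return \code{analysis_config} with file values overriding defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}
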