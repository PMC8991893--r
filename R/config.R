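#' Default analysis configuration
#'
#' Every tunable threshold of the pipeline in one nested list. Defaults are
#' the values the method is defined with: plasma calling needs >= 3
#' alt-supporting reads with at least one on each strand (one tumour-backed
#' read suffices when a matched tumour carries >= 3 alt reads at the locus);
#' base quality >= 25; germline sites must be covered >= 20x with zero alt
#' reads; kataegis is >= 6 mutations at mean inter-mutational distance
#' <= 1000 bp grouped within log10(IMD) <= 4, hypermutation score >= 5;
#' copy-number purity search is initialised at normal-contamination values
#' {0.2, 0.35, 0.5, 0.65, 0.8, 0.9, 0.99}.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    filtering = list(
      min_alt_reads = 3L,          # alt-supporting reads to call in plasma
      min_alt_per_strand = 1L,
      rescue_min_plasma_alt = 1L,  # plasma alt reads when tumour backs locus
      rescue_min_tumour_alt = 3L,
      min_alt_bq = 25,
      germline_min_depth = 20L,
      germline_undercovered = "drop",  # or "keep"
      strand_bias_p = 0.01,
      strand_bias_min_fraction = 0.1,
      pop_af_action = "flag"           # or "drop"
    ),
    kataegis = list(
      min_mutations = 6L,
      max_mean_imd = 1000,
      max_group_log10_imd = 4,
      min_hypermutation_score = 5,
      hypermutation_p = 0.05
    ),
    signatures = list(
      discard_threshold = 0.06,
      sse_rel_tol = 1e-3,
      instability_map = list(
        DSBR = "Signature.3",
        MMR  = c("Signature.6", "Signature.15", "Signature.20",
                 "Signature.21", "Signature.26"),
        POLN = "Signature.9"
      )
    ),
    copynumber = list(
      bin_size = 1e6,
      min_mappability = 0.9,
      normal_contamination_grid = c(0.2, 0.35, 0.5, 0.65, 0.8, 0.9, 0.99),
      self_transition = 0.99,
      max_state = 5L,              # states 0 (HOMD) .. 5 (HLAMP)
      # prior over copy states HOMD..HLAMP: extreme states are rare, which
      # also resolves the HOMD-at-t/2 vs HETD-at-t likelihood degeneracy
      state_prior = c(0.01, 0.2, 0.5, 0.2, 0.05, 0.04),
      logr_floor = -8
    ),
    clonal = list(
      max_exhaustive_clones = 10L,
      detection_eps = 0.005,
      decline_fraction = 0.5,
      em_restarts = 20L,
      em_max_iter = 200L,
      em_tol = 1e-6,
      k_range = 1:6
    ),
    tracking = list(
      ca199_max_day_gap = 14L,
      maf_undetected = "zero"          # or "drop"
    )
  )
}

#' Read a configuration YAML, merged over the defaults
#'
#' Keys present in the file override [default_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return nested named list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}
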