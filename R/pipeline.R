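#' Run the full longitudinal ctDNA pipeline on a synthetic patient
#'
#' `simulate -> filter -> kataegis -> signatures -> copy number -> clones ->
#' track` with a single seed, optionally writing every result as plain TSV.
#' Two runs with the same configuration produce identical outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory; when given, all tables are
#'   written there.
#' @param analysis_config analysis thresholds, see [default_config()].
#' @return list with the per-module results: `sim`, `report`
#'   (filter_report), `kataegis`, `exposures`, `cn`, `clusters`, `tree`,
#'   `stem`, `dynamics`, `maf`, `concordance`, `fragment_mode`,
#'   `actionability`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         analysis_config = default_config()) {
  sim <- simulate_patient(config)
  man <- sim$manifest
  plasma_ids <- man$sample_id[man$sample_class == "plasma"]
  cp_ids <- man$sample_id[man$sample_class == "cp_control"]
  tum_id <- man$sample_id[man$sample_class == "tumour"]
  germ_id <- man$sample_id[man$sample_class == "germline"]

  report <- run_cascade(sim$variants[plasma_ids],
                        tumour = sim$variants[[tum_id]],
                        germline = sim$variants[[germ_id]],
                        cp_tables = sim$variants[cp_ids],
                        blacklist = sim$blacklist,
                        config = analysis_config)
  cand <- report$candidates

  kat <- detect_kataegis(cand, analysis_config)
  spectrum <- trinucleotide_spectrum(cand)
  exposures <- if (sum(spectrum) > 0) {
    fit_exposures(spectrum, config$signature_matrix, analysis_config)
  } else NULL

  prof_sim <- simulate_bin_profile(config$tumour_fraction[1],
                                   aberrant = c(chr18 = 1L, chr17 = 4L,
                                                chr12 = 3L),
                                   chroms = paste0("chr", c(1:6, 12, 17, 18)),
                                   seed = config$seed + 1L)
  profile <- normalize_bins(prof_sim$sample, prof_sim$normal,
                            analysis_config)
  cn <- segment_and_estimate(profile, config = analysis_config)

  vm <- vaf_matrix(cand, man[man$patient_id == "PT01", ],
                   plasma_tables = sim$variants[plasma_ids])
  clusters <- NULL
  tree <- NULL
  stem <- NULL
  dynamics <- NULL
  if (nrow(vm$alt) >= 2) {
    clusters <- cluster_vafs(vm$alt, vm$depth, seed = config$seed + 2L,
                             config = analysis_config)
    tree <- infer_longitudinal_tree(clusters, analysis_config)
    stem <- identify_stem_clone(tree)
    days <- man$day[man$sample_class == "plasma"]
    dynamics <- call_dynamics(tree, timepoint_days = days,
                              treatment_days = days[1] + 1,
                              config = analysis_config)
  }

  maf <- mean_maf_series(cand, man[man$patient_id == "PT01", ],
                         plasma_tables = sim$variants[plasma_ids],
                         config = analysis_config)
  tum <- sim$variants[[tum_id]]
  tum <- tum[tum$alt_fwd + tum$alt_rev >= 3, , drop = FALSE]
  conc <- concordance(tum,
                      lapply(plasma_ids, function(id)
                        cand[cand$sample_id == id, , drop = FALSE]))
  frag <- modal_fragment_size(sim$fragments)
  act <- annotate_actionability(list(PT01 = cand), toy_gene_catalogue())

  out <- list(sim = sim, report = report, kataegis = kat,
              spectrum = spectrum, exposures = exposures, cn = cn,
              clusters = clusters, tree = tree, stem = stem,
              dynamics = dynamics, maf = maf, concordance = conc,
              fragment_mode = frag, actionability = act)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  write_variant_table(res$report$candidates,
                      file.path(dir, "candidates.tsv"))
  wt(res$report$stages, "filter_report.tsv")
  kat <- res$kataegis
  kat$members <- vapply(kat$members, paste, character(1), collapse = ",")
  wt(kat, "kataegis_events.tsv")
  wt(data.frame(channel = names(res$spectrum),
                count = as.integer(res$spectrum)), "spectrum.tsv")
  if (!is.null(res$exposures)) {
    wt(data.frame(signature = names(res$exposures$weights),
                  weight = unname(res$exposures$weights)),
       "exposures.tsv")
  }
  wt(res$cn$segments, "cn_segments.tsv")
  writeLines(sprintf("tumour_fraction\t%.6f", res$cn$tumour_fraction),
             file.path(dir, "tumour_fraction.tsv"))
  if (!is.null(res$tree)) {
    wt(data.frame(clone = seq_along(res$tree$parent),
                  parent = res$tree$parent,
                  dynamics = res$dynamics), "clone_tree.tsv")
    writeLines(tree_newick(res$tree), file.path(dir, "clone_tree.nwk"))
    wt(cbind(clone = rownames(res$tree$U), as.data.frame(res$tree$U)),
       "clone_prevalence.tsv")
    wt(cbind(clone = rownames(res$tree$proportions),
             as.data.frame(res$tree$proportions)),
       "clone_proportions.tsv")
  }
  wt(res$maf, "maf_series.tsv")
  wt(data.frame(metric = c("baseline", "combined"),
                value = c(res$concordance$baseline,
                          res$concordance$combined)),
     "concordance.tsv")
  writeLines(sprintf("modal_fragment_size\t%d",
                     as.integer(res$fragment_mode$mode)),
             file.path(dir, "fragment_mode.tsv"))
  wt(res$actionability$variants, "actionability.tsv")
  invisible(dir)
}
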