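#' Per-timepoint mean mutant allele fraction series
#'
#' The locus set is the union of the patient's filtered candidates (plus
#' any variants in driver genes when a catalogue is supplied upstream).
#' At each plasma timepoint, MAF per locus is `alt / (alt + ref)`; a locus
#' undetected at a covered site counts as 0 (keeping the series sensitive
#' to clearance; set `maf_undetected = "drop"` to average detected loci
#' only). Loci with no coverage at a timepoint are ignored there. CA19-9
#' measurements are joined by nearest day within the configured window.
#'
#' Duplicated candidate rows are collapsed, and the result is invariant to
#' row order.
#'
#' @param candidates filtered variant data.frame for one patient.
#' @param manifest manifest data.frame.
#' @param plasma_tables optional named list of full per-sample plasma
#'   tables (for zero-alt coverage at undetected timepoints).
#' @param ca199 optional data.frame with columns day, value.
#' @param config configuration list.
#' @return data.frame: timepoint, day, n_loci, n_detected, mean_maf (NA and
#'   `flagged = TRUE` when no locus is covered), ca199.
#' @export
mean_maf_series <- function(candidates, manifest, plasma_tables = NULL,
                            ca199 = NULL, config = default_config()) {
  plasma <- manifest[manifest$sample_class == "plasma", , drop = FALSE]
  plasma <- plasma[order(plasma$day), , drop = FALSE]
  keys <- sort(unique(variant_key(candidates)))
  rows <- lapply(seq_len(nrow(plasma)), function(j) {
    sid <- plasma$sample_id[j]
    src <- if (!is.null(plasma_tables) && !is.null(plasma_tables[[sid]])) {
      plasma_tables[[sid]]
    } else {
      candidates[candidates$sample_id == sid, , drop = FALSE]
    }
    src <- src[!duplicated(variant_key(src)), , drop = FALSE]
    idx <- match(keys, variant_key(src))
    alt <- (src$alt_fwd + src$alt_rev)[idx]
    dep <- variant_depth(src)[idx]
    covered <- !is.na(dep) & dep > 0
    maf <- ifelse(covered, alt / dep, NA_real_)
    if (config$tracking$maf_undetected == "drop") {
      use <- covered & !is.na(alt) & alt > 0
    } else {
      use <- covered
    }
    data.frame(timepoint = plasma$timepoint_label[j], day = plasma$day[j],
               n_loci = sum(covered),
               n_detected = sum(covered & alt > 0),
               mean_maf = if (any(use)) mean(maf[use]) else NA_real_,
               flagged = !any(use), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ca199 <- NA_real_
  if (!is.null(ca199) && nrow(ca199) > 0) {
    gap <- config$tracking$ca199_max_day_gap
    for (i in seq_len(nrow(out))) {
      d <- abs(ca199$day - out$day[i])
      if (min(d) <= gap) out$ca199[i] <- ca199$value[which.min(d)]
    }
  }
  out
}

#' Tumour-plasma variant concordance
#'
#' Baseline overlap is the fraction of tumour variants recovered in the
#' first plasma sample; combined overlap uses the union of all plasma
#' timepoints. Variant identity is (chrom, pos, ref, alt). Combined
#' overlap is always >= baseline (set monotonicity).
#'
#' @param tumour_keys character vector of tumour variant keys (or a
#'   variant data.frame).
#' @param plasma_sets list of per-timepoint key vectors (or data.frames),
#'   ordered by time.
#' @return list: `baseline`, `combined` (fractions in `[0,1]`, NA with
#'   `flagged` when the tumour set is empty), `n_tumour`,
#'   `plasma_specific` (count of combined-plasma keys absent from tumour).
#' @export
concordance <- function(tumour_keys, plasma_sets) {
  as_keys <- function(x) if (is.data.frame(x)) unique(variant_key(x))
                         else unique(x)
  tum <- as_keys(tumour_keys)
  plasma <- lapply(plasma_sets, as_keys)
  all_plasma <- unique(unlist(plasma))
  if (length(tum) == 0) {
    return(list(baseline = NA_real_, combined = NA_real_, flagged = TRUE,
                n_tumour = 0L,
                plasma_specific = length(all_plasma)))
  }
  list(baseline = length(intersect(tum, plasma[[1]])) / length(tum),
       combined = length(intersect(tum, all_plasma)) / length(tum),
       flagged = FALSE, n_tumour = length(tum),
       plasma_specific = length(setdiff(all_plasma, tum)))
}

#' Per-sample mutation load table with group comparison
#'
#' Counts unique candidate variants per plasma sample and, when a patient
#' grouping (e.g. resectable vs unresectable) is supplied, reports group
#' medians and a descriptive Mann-Whitney rank-test p-value.
#'
#' @param candidates_by_patient named list (patient -> filtered candidate
#'   data.frame).
#' @param manifest manifest data.frame covering all patients.
#' @param groups optional named character vector patient -> group label.
#' @return list: `table` (patient, sample_id, timepoint, n_mutations,
#'   group), `group_medians`, `p_value` (NA without two groups).
#' @export
mutation_load_table <- function(candidates_by_patient, manifest,
                                groups = NULL) {
  rows <- list()
  for (p in names(candidates_by_patient)) {
    cand <- candidates_by_patient[[p]]
    plasma <- manifest[manifest$patient_id == p &
                         manifest$sample_class == "plasma", , drop = FALSE]
    for (i in seq_len(nrow(plasma))) {
      sub <- cand[cand$sample_id == plasma$sample_id[i], , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        patient = p, sample_id = plasma$sample_id[i],
        timepoint = plasma$timepoint_label[i],
        n_mutations = length(unique(variant_key(sub))),
        group = if (is.null(groups)) NA_character_ else groups[[p]],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  med <- NULL
  pval <- NA_real_
  if (!is.null(groups) && length(unique(stats::na.omit(tab$group))) == 2) {
    med <- tapply(tab$n_mutations, tab$group, stats::median)
    gs <- split(tab$n_mutations, tab$group)
    pval <- suppressWarnings(
      stats::wilcox.test(gs[[1]], gs[[2]])$p.value)
  }
  list(table = tab, group_medians = med, p_value = pval)
}

#' Modal cfDNA fragment size
#'
#' Histogram mode at 1 bp resolution; ties resolve to the smallest length
#' and are flagged. Per-class modes are reported when allele labels
#' (e.g. mutant / wild-type) are supplied.
#'
#' @param lengths integer fragment lengths (>= 50).
#' @param labels optional per-fragment class labels.
#' @return list: `mode`, `tie`, and `by_class` (named vector) when labels
#'   are given.
#' @export
modal_fragment_size <- function(lengths, labels = NULL) {
  if (length(lengths) == 0) stop("no fragment lengths", call. = FALSE)
  mode1 <- function(x) {
    tab <- table(x)
    top <- as.integer(names(tab)[tab == max(tab)])
    list(mode = min(top), tie = length(top) > 1)
  }
  out <- mode1(lengths)
  if (!is.null(labels)) {
    out$by_class <- vapply(split(lengths, labels),
                           function(x) mode1(x)$mode, numeric(1))
  }
  out
}

#' Hypergeometric pathway enrichment
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the overlap `k` between the selected genes `n` and
#' the pathway `K` in a universe of `N` genes, with Benjamini-Hochberg
#' adjustment across pathways. Selected genes absent from the universe are
#' excluded and counted.
#'
#' @param selected_genes character vector.
#' @param pathway_db data.frame with columns pathway, gene.
#' @param universe gene universe; defaults to all genes in `pathway_db`.
#' @return data.frame: pathway, N, K, n, k, p, q; attribute
#'   `n_excluded_genes`.
#' @export
pathway_enrichment <- function(selected_genes, pathway_db,
                               universe = NULL) {
  if (is.null(universe)) universe <- unique(pathway_db$gene)
  universe <- unique(universe)
  sel <- unique(selected_genes)
  excluded <- setdiff(sel, universe)
  sel <- intersect(sel, universe)
  N <- length(universe)
  n <- length(sel)
  sets <- split(pathway_db$gene, pathway_db$pathway)
  rows <- lapply(names(sets), function(pw) {
    genes <- intersect(unique(sets[[pw]]), universe)
    K <- length(genes)
    k <- length(intersect(sel, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  structure(out[order(out$p), , drop = FALSE],
            n_excluded_genes = length(excluded))
}

#' Annotate candidates against a driver/actionability catalogue
#'
#' Builds an oncoprint-ready patient x gene matrix of hit classes
#' (PDAC-driver, RAS-family, DDR-biomarker, DDR-pathway) and flags
#' variants detected in at least 2 serial plasma samples as trackable.
#'
#' @param candidates_by_patient named list (patient -> candidate
#'   data.frame).
#' @param catalogue data.frame with columns gene, class, therapy (see the
#'   bundled `gene_catalogue.tsv` in `extdata`, a synthetic toy catalogue).
#' @return list: `matrix` (patient x gene, class strings or ""), `variants`
#'   (per-variant table with class and trackable flag).
#' @export
annotate_actionability <- function(candidates_by_patient, catalogue) {
  var_rows <- list()
  for (p in names(candidates_by_patient)) {
    cand <- candidates_by_patient[[p]]
    if (nrow(cand) == 0) next
    key <- variant_key(cand)
    n_samples <- tapply(cand$sample_id, key,
                        function(s) length(unique(s)))
    first <- cand[!duplicated(key), , drop = FALSE]
    k <- variant_key(first)
    cls <- catalogue$class[match(first$gene, catalogue$gene)]
    therapy <- catalogue$therapy[match(first$gene, catalogue$gene)]
    var_rows[[p]] <- data.frame(
      patient = p, key = k, gene = first$gene,
      class = ifelse(is.na(cls), "none", cls),
      therapy = ifelse(is.na(therapy), "", therapy),
      trackable = as.integer(n_samples[k]) >= 2L,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, c(var_rows, make.row.names = FALSE))
  if (is.null(variants)) {
    variants <- data.frame(patient = character(0), key = character(0),
                           gene = character(0), class = character(0),
                           therapy = character(0), trackable = logical(0))
  }
  genes <- unique(catalogue$gene)
  patients <- names(candidates_by_patient)
  m <- matrix("", nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  hit <- variants[variants$class != "none", , drop = FALSE]
  for (i in seq_len(nrow(hit))) {
    if (hit$gene[i] %in% genes) {
      m[hit$patient[i], hit$gene[i]] <- hit$class[i]
    }
  }
  list(matrix = m, variants = variants)
}

#' Load the bundled toy gene catalogue
#'
#' A small synthetic catalogue listing recurrent PDAC driver genes, RAS
#' family members and DDR genes with therapy hints; a stand-in for external
#' clinical annotation services, shipped for examples and tests.
#'
#' @return data.frame gene, class, therapy.
#' @export
toy_gene_catalogue <- function() {
  utils::read.delim(system.file("extdata", "gene_catalogue.tsv",
                                package = "ctlong"),
                    stringsAsFactors = FALSE)
}
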