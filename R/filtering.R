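#' Candidate ctDNA calling and filtering cascade
#'
#' The cascade reproduces a multi-sample plasma calling strategy followed by
#' eight artifact filters, in fixed order: strand-aware calling (with a
#' matched-tumour rescue branch), dbSNP-only removal, exonic-function
#' filtering, base-quality filtering, matched-germline exclusion, benign
#' (chronic pancreatitis) control exclusion, multi-allelic/serial-consistency
#' removal, blacklist-interval removal, and a Fisher-exact strand-bias
#' filter. Population allele-frequency hits are flagged, not removed (a
#' config switch can drop them). Each stage records input/output counts and
#' the dropped variant keys, so the report is a full audit trail.
#'
#' @name filtering
NULL

drop_attr <- function(survivors, dropped, reason) {
  attr(survivors, "dropped") <- dropped
  attr(survivors, "drop_reason") <- reason
  survivors
}

#' Call candidate plasma variants
#'
#' A plasma record is called when it has at least 3 alt-supporting reads
#' with at least one on each strand, or at least 1 alt read when the same
#' locus/allele carries >= 3 alt reads in the matched tumour sample (the
#' rescue branch; disabled when no tumour is supplied).
#'
#' @param plasma variant data.frame (rows across all plasma samples of one
#'   patient).
#' @param tumour optional tumour variant data.frame.
#' @param config a [default_config()]-shaped list.
#' @return survivors data.frame.
#' @export
call_plasma_candidates <- function(plasma, tumour = NULL,
                                   config = default_config()) {
  fc <- config$filtering
  alt <- plasma$alt_fwd + plasma$alt_rev
  direct <- alt >= fc$min_alt_reads &
    plasma$alt_fwd >= fc$min_alt_per_strand &
    plasma$alt_rev >= fc$min_alt_per_strand
  rescued <- rep(FALSE, nrow(plasma))
  if (!is.null(tumour) && nrow(tumour) > 0) {
    t_alt <- tumour$alt_fwd + tumour$alt_rev
    t_keys <- variant_key(tumour)[t_alt >= fc$rescue_min_tumour_alt]
    rescued <- alt >= fc$rescue_min_plasma_alt &
      variant_key(plasma) %in% t_keys
  }
  keep <- direct | rescued
  drop_attr(plasma[keep, , drop = FALSE],
            unique(variant_key(plasma[!keep, , drop = FALSE])), "not_called")
}

#' Remove dbSNP-only variants
#'
#' Drops a candidate iff it has no COSMIC identifier but does have a dbSNP
#' identifier (likely germline polymorphism, not somatic).
#' @param candidates variant data.frame with annotation columns.
#' @return survivors data.frame.
#' @export
filter_dbsnp_only <- function(candidates) {
  drop <- is.na(candidates$cosmic_id) & !is.na(candidates$dbsnp_id)
  drop_attr(candidates[!drop, , drop = FALSE],
            unique(variant_key(candidates[drop, , drop = FALSE])),
            "dbsnp_only")
}

#' Filter on exonic function
#'
#' Drops candidates classified `synonymous` or `unknown`; a missing
#' annotation is treated as unknown and counted separately in the report.
#' @inheritParams filter_dbsnp_only
#' @return survivors data.frame.
#' @export
filter_exonic_function <- function(candidates) {
  missing_anno <- is.na(candidates$exonic_function)
  drop <- missing_anno |
    candidates$exonic_function %in% c("synonymous", "unknown")
  out <- drop_attr(candidates[!drop, , drop = FALSE],
                   unique(variant_key(candidates[drop, , drop = FALSE])),
                   "exonic_function")
  attr(out, "n_missing_annotation") <- sum(missing_anno)
  out
}

#' Filter on mean alt base quality
#'
#' Drops candidates with `mean_alt_bq` < 25 (configurable).
#' @inheritParams call_plasma_candidates
#' @param candidates variant data.frame.
#' @return survivors data.frame.
#' @export
filter_base_quality <- function(candidates, config = default_config()) {
  drop <- !is.na(candidates$mean_alt_bq) &
    candidates$mean_alt_bq < config$filtering$min_alt_bq
  drop_attr(candidates[!drop, , drop = FALSE],
            unique(variant_key(candidates[drop, , drop = FALSE])),
            "base_quality")
}

#' Exclude variants with germline evidence or insufficient germline coverage
#'
#' A candidate is kept iff the matched germline sample covers its locus at
#' >= 20x with zero alt reads. Loci absent from the germline table count as
#' depth 0. Under-covered loci are dropped by default
#' (`germline_undercovered = "drop"`) because a germline origin cannot be
#' excluded there; set `"keep"` to retain them.
#'
#' @param candidates variant data.frame.
#' @param germline germline variant/pileup data.frame.
#' @param config configuration list.
#' @return survivors data.frame.
#' @export
filter_germline <- function(candidates, germline,
                            config = default_config()) {
  fc <- config$filtering
  if (is.null(germline) || nrow(germline) == 0) {
    g_depth <- rep(0, nrow(candidates))
    g_alt <- rep(0, nrow(candidates))
  } else {
    locus <- paste0(germline$chrom, ":", germline$pos)
    depth_by <- tapply(variant_depth(germline), locus, max)
    alt_by <- tapply(germline$alt_fwd + germline$alt_rev, locus, sum)
    c_locus <- paste0(candidates$chrom, ":", candidates$pos)
    g_depth <- as.numeric(depth_by[c_locus])
    g_alt <- as.numeric(alt_by[c_locus])
    g_depth[is.na(g_depth)] <- 0
    g_alt[is.na(g_alt)] <- 0
  }
  has_alt <- g_alt > 0
  undercov <- g_depth < fc$germline_min_depth
  drop <- has_alt | (undercov & fc$germline_undercovered == "drop")
  out <- drop_attr(candidates[!drop, , drop = FALSE],
                   unique(variant_key(candidates[drop, , drop = FALSE])),
                   "germline")
  attr(out, "n_undercovered") <- sum(undercov & !has_alt)
  out
}

#' Exclude variants present in benign control plasma
#'
#' Drops a candidate iff any chronic-pancreatitis control plasma sample
#' shows >= 1 alt read at the same locus/allele. With no control samples
#' supplied the filter is vacuous and a warning is issued.
#'
#' @param candidates variant data.frame.
#' @param cp_tables list of CP-control variant data.frames.
#' @return survivors data.frame.
#' @export
filter_cp_controls <- function(candidates, cp_tables = list()) {
  if (length(cp_tables) == 0) {
    warning("no CP control samples supplied; CP filter is vacuous",
            call. = FALSE)
    return(drop_attr(candidates, character(0), "cp_control"))
  }
  cp <- do.call(rbind, lapply(cp_tables, function(x)
    x[, VARIANT_REQUIRED_COLS]))
  cp_keys <- unique(variant_key(cp)[cp$alt_fwd + cp$alt_rev >= 1])
  drop <- variant_key(candidates) %in% cp_keys
  drop_attr(candidates[!drop, , drop = FALSE],
            unique(variant_key(candidates[drop, , drop = FALSE])),
            "cp_control")
}

#' Remove multi-allelic loci and serially inconsistent genotypes
#'
#' Drops every alt allele at any locus where more than one distinct alt
#' allele is observed across the patient's called plasma variants, keeping
#' only mutations with a single alternative genotype across serial plasma.
#' The multi-allelic locus set is computed on the called candidate set
#' (`called`, defaulting to `candidates`), which makes the stage a pure
#' per-variant predicate and hence order-independent with respect to the
#' other set filters.
#'
#' @param candidates variant data.frame.
#' @param called the stage-1 called set the locus census is computed on.
#' @return survivors data.frame.
#' @export
filter_multiallelic <- function(candidates, called = candidates) {
  if (nrow(called) == 0) {
    return(drop_attr(candidates, character(0), "multiallelic"))
  }
  locus <- paste0(called$chrom, ":", called$pos)
  n_alts <- tapply(called$alt, locus, function(a) length(unique(a)))
  bad_loci <- names(n_alts)[n_alts > 1]
  drop <- paste0(candidates$chrom, ":", candidates$pos) %in% bad_loci
  drop_attr(candidates[!drop, , drop = FALSE],
            unique(variant_key(candidates[drop, , drop = FALSE])),
            "multiallelic")
}

#' Remove variants inside blacklist intervals
#'
#' @param candidates variant data.frame.
#' @param blacklist GRanges from [read_blacklist()].
#' @return survivors data.frame.
#' @export
filter_blacklist <- function(candidates, blacklist) {
  drop <- in_blacklist(candidates$chrom, candidates$pos, blacklist)
  drop_attr(candidates[!drop, , drop = FALSE],
            unique(variant_key(candidates[drop, , drop = FALSE])),
            "blacklist")
}

#' Strand-bias (false-positive) filter
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[ref_fwd, ref_rev], [alt_fwd, alt_rev]]`. A candidate is dropped iff
#' p < 0.01 AND the minor-strand alt fraction
#' `min(alt_fwd, alt_rev) / max(1, alt_fwd + alt_rev)` is below 0.1 — both
#' conditions, so that low-depth variants are spared.
#'
#' @param candidates variant data.frame.
#' @param config configuration list.
#' @return survivors data.frame.
#' @export
filter_strand_bias <- function(candidates, config = default_config()) {
  fc <- config$filtering
  n <- nrow(candidates)
  if (n == 0) return(drop_attr(candidates, character(0), "strand_bias"))
  p <- vapply(seq_len(n), function(i) {
    m <- matrix(c(candidates$ref_fwd[i], candidates$ref_rev[i],
                  candidates$alt_fwd[i], candidates$alt_rev[i]),
                nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  alt <- candidates$alt_fwd + candidates$alt_rev
  frac <- pmin(candidates$alt_fwd, candidates$alt_rev) / pmax(1, alt)
  drop <- p < fc$strand_bias_p & frac < fc$strand_bias_min_fraction
  drop_attr(candidates[!drop, , drop = FALSE],
            unique(variant_key(candidates[drop, , drop = FALSE])),
            "strand_bias")
}

#' Flag candidates with non-zero population allele frequencies
#'
#' Sets the `pop_af` flag iff any of `af_1000g`/`af_gnomad`/`af_hapmap` is
#' strictly greater than 0. Flagged records are retained unless
#' `pop_af_action = "drop"`.
#'
#' @param candidates variant data.frame.
#' @param config configuration list.
#' @return candidates with the `flags` column updated (survivors only if
#'   dropping is configured).
#' @export
flag_population_af <- function(candidates, config = default_config()) {
  af <- cbind(candidates$af_1000g, candidates$af_gnomad,
              candidates$af_hapmap)
  hit <- if (nrow(candidates) == 0) logical(0)
         else apply(af, 1, function(a) any(!is.na(a) & a > 0))
  if (is.null(candidates$flags)) candidates$flags <- character(nrow(candidates))
  candidates$flags[hit] <- add_flag(candidates$flags[hit], "pop_af")
  if (config$filtering$pop_af_action == "drop") {
    return(drop_attr(candidates[!hit, , drop = FALSE],
                     unique(variant_key(candidates[hit, , drop = FALSE])),
                     "pop_af"))
  }
  drop_attr(candidates, character(0), "pop_af")
}

#' Run the full filtering cascade for one patient
#'
#' Applies the stages in fixed order (call, dbSNP/COSMIC, exonic function,
#' base quality, germline, CP controls, multi-allelic/consistency,
#' blacklist, strand bias, population-AF flag) and returns an auditable
#' per-stage report.
#'
#' @param plasma_tables named list of plasma variant data.frames (one per
#'   timepoint).
#' @param tumour optional tumour data.frame (enables the rescue branch).
#' @param germline germline data.frame.
#' @param cp_tables list of CP-control plasma data.frames.
#' @param blacklist GRanges blacklist.
#' @param config configuration list.
#' @param verbose print one line per stage.
#' @return object of class `filter_report`: list with `stages` (data.frame
#'   stage,n_in,n_out), `dropped` (named list of variant keys per stage) and
#'   `candidates` (the final data.frame).
#' @export
run_cascade <- function(plasma_tables, tumour = NULL, germline = NULL,
                        cp_tables = list(),
                        blacklist = GenomicRanges::GRanges(),
                        config = default_config(), verbose = FALSE) {
  plasma <- if (length(plasma_tables) == 0) {
    empty_variant_table()
  } else {
    do.call(rbind, c(unname(plasma_tables), make.row.names = FALSE))
  }
  ord <- order(plasma$chrom, plasma$pos, plasma$alt, plasma$sample_id)
  plasma <- plasma[ord, , drop = FALSE]

  stages <- list()
  dropped <- list()
  record <- function(name, n_in, out) {
    stages[[name]] <<- data.frame(stage = name, n_in = n_in,
                                  n_out = nrow(out))
    dropped[[name]] <<- attr(out, "dropped")
    if (verbose) {
      message(sprintf("%-14s %5d -> %5d", name, n_in, nrow(out)))
    }
    out
  }

  cur <- record("call", nrow(plasma),
                call_plasma_candidates(plasma, tumour, config))
  called <- cur
  cur <- record("dbsnp_only", nrow(cur), filter_dbsnp_only(cur))
  cur <- record("exonic_function", nrow(cur), filter_exonic_function(cur))
  cur <- record("base_quality", nrow(cur),
                filter_base_quality(cur, config))
  cur <- record("germline", nrow(cur),
                filter_germline(cur, germline, config))
  cur <- record("cp_control", nrow(cur),
                filter_cp_controls(cur, cp_tables))
  cur <- record("multiallelic", nrow(cur),
                filter_multiallelic(cur, called = called))
  cur <- record("blacklist", nrow(cur), filter_blacklist(cur, blacklist))
  cur <- record("strand_bias", nrow(cur),
                filter_strand_bias(cur, config))
  cur <- record("pop_af", nrow(cur), flag_population_af(cur, config))

  structure(list(stages = do.call(rbind, c(stages, make.row.names = FALSE)),
                 dropped = dropped, candidates = cur),
            class = "filter_report")
}

empty_variant_table <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   sample_id = character(0), ref_fwd = integer(0),
                   ref_rev = integer(0), alt_fwd = integer(0),
                   alt_rev = integer(0), mean_alt_bq = numeric(0),
                   cosmic_id = character(0), dbsnp_id = character(0),
                   exonic_function = character(0), af_1000g = numeric(0),
                   af_gnomad = numeric(0), af_hapmap = numeric(0),
                   gene = character(0), driver_class = character(0),
                   biomarker = character(0), context = character(0),
                   stringsAsFactors = FALSE)
  df
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filtering cascade report\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final candidates: %d rows, %d unique variants\n",
              nrow(x$candidates),
              length(unique(variant_key(x$candidates)))))
  invisible(x)
}

#' Which stage dropped each variant key
#'
#' @param report a `filter_report`.
#' @return data.frame key, stage (first stage at which the key was dropped).
#' @export
drop_stage_table <- function(report) {
  out <- do.call(rbind, lapply(names(report$dropped), function(s) {
    keys <- report$dropped[[s]]
    if (length(keys) == 0) return(NULL)
    data.frame(key = keys, stage = s, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(key = character(0), stage = character(0)))
  }
  out[!duplicated(out$key), , drop = FALSE]
}
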