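#' Approximate autosome lengths (hg38-scale, bp)
#'
#' Used as the coordinate space for simulated variants and copy-number bins.
#' @return named numeric vector chr1..chr22.
#' @export
autosome_lengths <- function() {
  c(chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622,
    chr12 = 133275309, chr13 = 114364328, chr14 = 107043718,
    chr15 = 101991189, chr16 = 90338345, chr17 = 83257441,
    chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a handful of clones in serial
#' plasma sampled at 4 timepoints over ~2 years, plasma exomes at 1000x
#' target depth, germline at 100x, tumour at 60x with pathology cellularity
#' 0.6, 3 chronic-pancreatitis (CP) control plasmas, a 167 bp modal cfDNA
#' fragment size with a dinucleosomal shoulder, and tumour fractions that
#' drop after treatment and partially rebound.
#'
#' Artifact rates are fractions of the number of true somatic loci; each
#' artifact class is labelled in the truth tables so every downstream filter
#' can be scored.
#'
#' @param seed integer seed for the single global RNG of a simulation run.
#' @param n_clones,muts_per_clone clone tree size.
#' @param n_timepoints number of serial plasma samples.
#' @param tumour_fraction per-timepoint ctDNA tumour fraction (recycled or
#'   truncated to `n_timepoints`).
#' @param plasma_depth,tumour_depth,germline_depth,cp_depth target depths.
#' @param tumour_cellularity pathology cellularity of the tumour sample.
#' @param n_cp_controls number of CP control plasmas.
#' @param artifact_rates named list of per-class rates in `[0,1]`:
#'   `germline_leak`, `cp_shared`, `strand_bias`, `blacklist`,
#'   `multiallelic`, `dbsnp_only`, `low_bq`, `synonymous`.
#' @param kataegis list: `n_clusters`, `cluster_size`, `spacing_max`,
#'   `substitution` (e.g. "T>G", or NA to draw from the signature model).
#' @param signature_matrix 96 x S matrix; default a seeded random
#'   3-signature catalogue.
#' @param exposures signature mixing weights (sum to 1).
#' @param fragment list: `modal_length`, `sd`, `dinucleosome_weight`, `n`.
#' @param chroms chromosomes used for variant placement.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 5L,
                       muts_per_clone = 40L,
                       n_timepoints = 4L,
                       tumour_fraction = c(0.30, 0.10, 0.20, 0.25),
                       plasma_depth = 1000L,
                       tumour_depth = 60L,
                       germline_depth = 100L,
                       cp_depth = 1000L,
                       tumour_cellularity = 0.6,
                       n_cp_controls = 3L,
                       artifact_rates = list(),
                       kataegis = list(),
                       signature_matrix = NULL,
                       exposures = c(0.6, 0.3, 0.1),
                       fragment = list(),
                       chroms = names(autosome_lengths())) {
  rates <- modifyList(list(germline_leak = 0.1, cp_shared = 0.1,
                           strand_bias = 0.1, blacklist = 0.1,
                           multiallelic = 0.05, dbsnp_only = 0.1,
                           low_bq = 0.1, synonymous = 0.1),
                      artifact_rates)
  bad <- unlist(rates) < 0 | unlist(rates) > 1
  if (any(bad)) {
    stop("artifact rate(s) outside [0,1]: ",
         paste(names(rates)[bad], collapse = ", "), call. = FALSE)
  }
  kat <- modifyList(list(n_clusters = 1L, cluster_size = 8L,
                         spacing_max = 1000, substitution = "T>G"),
                    kataegis)
  frag <- modifyList(list(modal_length = 167, sd = 10,
                          dinucleosome_weight = 0.15, n = 10000L),
                     fragment)
  if (frag$dinucleosome_weight < 0 || frag$dinucleosome_weight > 1) {
    stop("dinucleosome_weight must be in [0,1]", call. = FALSE)
  }
  if (n_clones < 1) stop("n_clones must be >= 1", call. = FALSE)
  if (muts_per_clone < 1) stop("muts_per_clone must be >= 1", call. = FALSE)
  tf <- rep_len(tumour_fraction, n_timepoints)
  if (any(tf < 0 | tf > 1)) {
    stop("tumour_fraction values must be in [0,1]", call. = FALSE)
  }
  if (is.null(signature_matrix)) {
    signature_matrix <- random_signature_matrix(length(exposures),
                                                seed = seed + 1000L)
  }
  if (abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 muts_per_clone = as.integer(muts_per_clone),
                 n_timepoints = as.integer(n_timepoints),
                 tumour_fraction = tf, plasma_depth = plasma_depth,
                 tumour_depth = tumour_depth,
                 germline_depth = germline_depth, cp_depth = cp_depth,
                 tumour_cellularity = tumour_cellularity,
                 n_cp_controls = as.integer(n_cp_controls),
                 artifact_rates = rates, kataegis = kat,
                 signature_matrix = signature_matrix,
                 exposures = exposures, fragment = frag, chroms = chroms),
            class = "sim_config")
}

#' Random sparse 96-channel signature catalogue
#'
#' Columns are independent Dirichlet draws with a small concentration
#' parameter, giving sparse, well-separated synthetic signatures for
#' refitting benchmarks.
#'
#' @param n_signatures number of columns.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration per channel.
#' @return 96 x S column-stochastic matrix.
#' @export
random_signature_matrix <- function(n_signatures, seed = 1L,
                                    concentration = 0.05) {
  set.seed(seed)
  m <- matrix(stats::rgamma(96 * n_signatures, shape = concentration),
              nrow = 96)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- sbs96_channels()
  colnames(m) <- paste0("Signature.", seq_len(n_signatures))
  m
}

# ---- clone tree -----------------------------------------------------------

#' Simulate a rooted clone tree with longitudinal prevalences
#'
#' Each non-root clone picks a uniformly random parent among earlier clones.
#' Cellular prevalences (subtree-inclusive, so a parent's prevalence bounds
#' the sum of its children's) are drawn top-down: the root draws from
#' U(0.6, 1) per timepoint and each child draws a random share of its
#' parent's remaining headroom, which satisfies the sum condition exactly by
#' construction. Share trajectories are asynchronous: every clone is
#' assigned a peak timepoint (spread across clones) where its share is high
#' (U(0.7, 0.95)) against a low off-peak baseline (U(0.03, 0.2)),
#' emulating the differential expansion and collapse of subclones across
#' serial treatment intervals. Prevalence configurations are additionally
#' required to be resolvable at the configured depths: every clone pair
#' must be separated by at least 0.02 on the plasma VAF-derived scale
#' (`tumour_fraction * |U_i - U_j|`, about 7 binomial standard errors at
#' depth 1000) at some timepoint, and every clone must reach the same
#' detectability floor at its peak; topology-plus-prevalence draws failing
#' this are rejected and redrawn (clones below the resolution of the assay
#' cannot carry information about the tree and would be merged by any
#' method). At realistic tumour fractions this disfavours deep linear
#' chains, whose terminal clones are unobservable in plasma.
#'
#' @param config a [sim_config()].
#' @return list with `clones` (data.frame clone_id, parent_id), `prevalence`
#'   (n_clones x n_timepoints matrix U) and `mutations` (truth table
#'   chrom,pos,ref,alt,gene,clone_id,context).
#' @export
simulate_clone_tree <- function(config) {
  set.seed(config$seed)
  K <- config$n_clones
  J <- config$n_timepoints
  tf <- config$tumour_fraction
  sep_min <- 0.02
  # resolvability is unattainable when the tumour fraction never exceeds
  # the separation floor (e.g. complete clearance); accept the first draw
  check_resolvable <- max(tf) > sep_min
  for (attempt in seq_len(500)) {
    parent <- c(NA_integer_,
                if (K > 1) vapply(2:K, function(i)
                  sample.int(i - 1L, 1L), integer(1)))
    U <- matrix(0, nrow = K, ncol = J,
                dimnames = list(paste0("clone", seq_len(K)),
                                paste0("P", seq_len(J))))
    U[1, ] <- stats::runif(J, 0.6, 1)
    if (K > 1) {
      peaks <- sample(rep_len(seq_len(J), K - 1))
      for (i in 2:K) {
        p <- parent[i]
        # headroom of the parent at each timepoint given already-placed
        # siblings (clones are processed in index order, so all earlier
        # children of p are final)
        sib <- which(parent == p & seq_len(K) < i)
        headroom <- U[p, ] -
          if (length(sib)) colSums(U[sib, , drop = FALSE]) else 0
        share <- stats::runif(J, 0.03, 0.2)
        share[peaks[i - 1]] <- stats::runif(1, 0.7, 0.95)
        U[i, ] <- pmax(0, headroom) * share
      }
    }
    Us <- sweep(U, 2, tf, "*")
    if (!check_resolvable) {
      resolvable <- TRUE
      break
    }
    resolvable <- all(apply(Us, 1, max) >= sep_min)
    if (resolvable && K > 1) {
      for (i in 2:K) for (j in seq_len(i - 1)) {
        if (max(abs(Us[i, ] - Us[j, ])) < sep_min) resolvable <- FALSE
      }
    }
    if (resolvable) break
  }
  if (!resolvable) {
    warning("could not draw a fully resolvable clone configuration; ",
            "using the last draw", call. = FALSE)
  }
  muts <- sim_mutation_set(K * config$muts_per_clone, config)
  muts$clone_id <- rep(seq_len(K), each = config$muts_per_clone)
  list(clones = data.frame(clone_id = seq_len(K), parent_id = parent),
       prevalence = U, mutations = muts)
}

# Sample n distinct genomic loci with signature-driven substitutions.
# Returns chrom,pos,ref,alt,gene,context (context written on the reported
# strand; ~half of sites are reported on the purine strand).
sim_mutation_set <- function(n, config) {
  lens <- autosome_lengths()[config$chroms]
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(stats::runif(n, 1, lens[chrom])) + 0
  p_channel <- as.vector(config$signature_matrix %*% config$exposures)
  ch_idx <- sample.int(96, n, replace = TRUE, prob = p_channel)
  dec <- decode_channel(sbs96_channels()[ch_idx])
  flip <- stats::runif(n) < 0.5
  ref <- ifelse(flip, revcomp(dec$ref), dec$ref)
  alt <- ifelse(flip, revcomp(dec$alt), dec$alt)
  context <- ifelse(flip, revcomp(dec$context), dec$context)
  gene_pool <- c(driver_gene_pool(),
                 sprintf("GENE%03d", seq_len(200)))
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = sample(gene_pool, n, replace = TRUE),
             context = context, stringsAsFactors = FALSE)
}

driver_gene_pool <- function() {
  c("KRAS", "TP53", "SMAD4", "CDKN2A", "NRAS", "HRAS", "BRCA1", "BRCA2",
    "PALB2", "MTOR", "ERBB2", "EGFR", "PBRM1", "KMT2D", "RNF43",
    "IDH1", "IDH2")
}

# "A[C>T]G" -> list(ref, alt, context = "ACG")
decode_channel <- function(label) {
  five <- substr(label, 1, 1)
  ref <- substr(label, 3, 3)
  alt <- substr(label, 5, 5)
  three <- substr(label, 7, 7)
  list(ref = ref, alt = alt, context = paste0(five, ref, three))
}

#' Reverse-complement a DNA string vector
#' @param x character vector of A/C/G/T strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- read simulation ------------------------------------------------------

#' Simulate per-sample variant read-count tables from a clone tree
#'
#' For a mutation private to clone `c`, the expected plasma VAF at timepoint
#' `j` is `0.5 * t_j * U[c, j]` (heterozygous, copy-neutral); alt counts are
#' Binomial(depth, VAF) with a fair per-strand split, depths are Poisson
#' around the configured targets, and `mean_alt_bq` is Normal(35, 3)
#' truncated to `[2, 60]`. The tumour sample uses pathology cellularity in
#' place of `t_j` (with baseline prevalences); the germline sample carries
#' zero alt reads at somatic loci.
#'
#' @param tree output of [simulate_clone_tree()].
#' @param config a [sim_config()].
#' @return list with `variants` (named list of per-sample data.frames),
#'   `manifest` (data.frame) and the truth tables carried through.
#' @export
simulate_reads <- function(tree, config) {
  muts <- tree$mutations
  U <- tree$prevalence
  J <- config$n_timepoints
  tf <- config$tumour_fraction
  plasma_days <- c(55, 84, 280, 540, 742, 900, 1100)[seq_len(J)]
  manifest <- data.frame(
    patient_id = "PT01",
    sample_id = c("PT01_T", "PT01_G", paste0("PT01_P", seq_len(J)),
                  if (config$n_cp_controls > 0)
                    paste0("CP", sprintf("%02d", seq_len(config$n_cp_controls)),
                           "_P1")),
    sample_class = c("tumour", "germline", rep("plasma", J),
                     rep("cp_control", config$n_cp_controls)),
    timepoint_label = c("T", "G", paste0("P", seq_len(J)),
                        rep("P1", config$n_cp_controls)),
    day = c(0L, 0L, plasma_days, rep(0L, config$n_cp_controls)),
    stringsAsFactors = FALSE)
  manifest$patient_id[manifest$sample_class == "cp_control"] <-
    sub("_P1$", "", manifest$sample_id[manifest$sample_class == "cp_control"])

  prev <- U[muts$clone_id, , drop = FALSE]
  tables <- list()
  for (j in seq_len(J)) {
    v <- 0.5 * tf[j] * prev[, j]
    tables[[paste0("PT01_P", j)]] <-
      sim_counts_at(muts, v, config$plasma_depth,
                    sample_id = paste0("PT01_P", j), somatic = TRUE)
  }
  v_t <- 0.5 * config$tumour_cellularity * prev[, 1]
  tables[["PT01_T"]] <- sim_counts_at(muts, v_t, config$tumour_depth,
                                      sample_id = "PT01_T", somatic = TRUE)
  tables[["PT01_G"]] <- sim_counts_at(muts, rep(0, nrow(muts)),
                                      config$germline_depth,
                                      sample_id = "PT01_G", somatic = TRUE)
  list(variants = tables, manifest = manifest,
       truth = list(clones = tree$clones, prevalence = U,
                    mutations = muts))
}

# Draw strand-split read counts for a set of loci at expected VAF v.
sim_counts_at <- function(muts, v, depth, sample_id, somatic = TRUE,
                          annotations = NULL) {
  n <- nrow(muts)
  d <- stats::rpois(n, depth)
  alt <- stats::rbinom(n, d, pmin(1, v))
  alt_fwd <- stats::rbinom(n, alt, 0.5)
  ref <- d - alt
  ref_fwd <- stats::rbinom(n, ref, 0.5)
  bq <- pmin(60, pmax(2, stats::rnorm(n, 35, 3)))
  bq[alt == 0] <- NA_real_
  out <- data.frame(
    chrom = muts$chrom, pos = muts$pos, ref = muts$ref, alt = muts$alt,
    sample_id = sample_id,
    ref_fwd = ref_fwd, ref_rev = ref - ref_fwd,
    alt_fwd = alt_fwd, alt_rev = alt - alt_fwd,
    mean_alt_bq = round(bq, 1), stringsAsFactors = FALSE)
  if (is.null(annotations)) {
    nf <- sample(c("nonsynonymous", "stopgain", "stoploss", "other"),
                 n, replace = TRUE, prob = c(0.7, 0.15, 0.05, 0.1))
    out$cosmic_id <- ifelse(stats::runif(n) < 0.3,
                            sprintf("COSV%06d", seq_len(n)), NA_character_)
    out$dbsnp_id <- NA_character_
    out$exonic_function <- nf
    out$af_1000g <- NA_real_
    out$af_gnomad <- NA_real_
    out$af_hapmap <- NA_real_
    out$gene <- muts$gene
    out$driver_class <- NA_character_
    out$biomarker <- NA_character_
    out$context <- muts$context
  } else {
    for (col in names(annotations)) out[[col]] <- annotations[[col]]
    out$gene <- muts$gene
    out$context <- muts$context
  }
  out
}

# Annotation sampling must be deterministic per-locus across samples of one
# run: simulate_reads draws annotations per sample table, so re-align them.
align_annotations <- function(tables, ref_sample) {
  ref <- tables[[ref_sample]]
  key <- variant_key(ref)
  for (nm in names(tables)) {
    idx <- match(variant_key(tables[[nm]]), key)
    keep <- !is.na(idx)
    for (col in c("cosmic_id", "dbsnp_id", "exonic_function", "af_1000g",
                  "af_gnomad", "af_hapmap", "gene", "driver_class",
                  "biomarker", "context")) {
      tables[[nm]][[col]][keep] <- ref[[col]][idx[keep]]
    }
  }
  tables
}

# ---- artifacts ------------------------------------------------------------

#' Inject labelled artifact variants into simulated tables
#'
#' Adds one cohort of loci per artifact class the filtering cascade is
#' designed to remove: germline leakage (alt reads in the matched germline
#' at >= 20x), CP-shared technical artifacts (alt reads in every CP control
#' plasma), strand-biased calls (all alt reads on the forward strand),
#' blacklist-region variants (placed inside generated blacklist intervals),
#' multi-allelic sites (two alt alleles at one locus), dbSNP-only
#' annotations, low base quality (`mean_alt_bq` < 25), and
#' synonymous/unknown exonic function. Counts per class are
#' `round(rate * n_true_loci)`. Every injected locus is recorded in the
#' returned `artifact_truth` table with its class.
#'
#' @param sim output of [simulate_reads()].
#' @param config a [sim_config()].
#' @return `sim` augmented with artifact rows, CP-control tables, a
#'   `blacklist` GRanges and `truth$artifacts`.
#' @export
inject_artifacts <- function(sim, config) {
  rates <- config$artifact_rates
  n_true <- nrow(sim$truth$mutations)
  plasma_ids <- sim$manifest$sample_id[sim$manifest$sample_class == "plasma"]
  cp_ids <- sim$manifest$sample_id[sim$manifest$sample_class == "cp_control"]
  germ_id <- sim$manifest$sample_id[sim$manifest$sample_class == "germline"]
  J <- length(plasma_ids)
  for (id in cp_ids) if (is.null(sim$variants[[id]])) {
    sim$variants[[id]] <- sim$variants[[plasma_ids[1]]][0, ]
  }

  # blacklist intervals (written regardless so the filter stage always runs)
  lens <- autosome_lengths()[config$chroms]
  bl_chrom <- sample(names(lens), 5, replace = TRUE)
  bl_start <- floor(stats::runif(5, 1, lens[bl_chrom] - 2e4))
  blacklist <- GenomicRanges::sort(GenomicRanges::GRanges(
    seqnames = bl_chrom,
    ranges = IRanges::IRanges(start = bl_start + 1, end = bl_start + 2e4)))

  truth <- list()
  clean_anno <- function(n) list(
    cosmic_id = NA_character_, dbsnp_id = NA_character_,
    exonic_function = "nonsynonymous", af_1000g = NA_real_,
    af_gnomad = NA_real_, af_hapmap = NA_real_,
    driver_class = NA_character_, biomarker = NA_character_)

  add_class <- function(sim, class, n, make_loci, plasma_tweak = NULL,
                        anno = NULL, germline_alt = FALSE,
                        to_cp = FALSE) {
    if (n == 0) return(sim)
    loci <- make_loci(n)
    vaf <- stats::runif(n, 0.03, 0.10)
    an <- if (is.null(anno)) clean_anno(n) else anno(n)
    for (id in plasma_ids) {
      rows <- sim_counts_at(loci, vaf, config$plasma_depth, id,
                            annotations = an)
      if (!is.null(plasma_tweak)) rows <- plasma_tweak(rows)
      sim$variants[[id]] <- rbind(sim$variants[[id]], rows)
    }
    if (to_cp) {
      for (id in cp_ids) {
        rows <- sim_counts_at(loci, pmax(vaf, 0.02), config$cp_depth, id,
                              annotations = an)
        # guarantee >= 1 alt read in each CP sample at these loci
        z <- rows$alt_fwd + rows$alt_rev == 0
        rows$alt_fwd[z] <- 1L
        rows$mean_alt_bq[z] <- 35
        sim$variants[[id]] <- rbind(sim$variants[[id]], rows)
      }
    }
    g_vaf <- if (germline_alt) stats::runif(n, 0.4, 0.6) else rep(0, n)
    g_rows <- sim_counts_at(loci, g_vaf, config$germline_depth, germ_id,
                            annotations = an)
    if (germline_alt) {
      z <- g_rows$alt_fwd + g_rows$alt_rev == 0
      g_rows$alt_fwd[z] <- 1L
    }
    sim$variants[[germ_id]] <- rbind(sim$variants[[germ_id]], g_rows)
    truth[[class]] <<- data.frame(key = variant_key(loci), class = class,
                                  stringsAsFactors = FALSE)
    sim
  }

  new_loci <- function(n) sim_mutation_set(n, config)

  sim <- add_class(sim, "germline_leak", round(rates$germline_leak * n_true),
                   new_loci, germline_alt = TRUE)
  sim <- add_class(sim, "cp_shared", round(rates$cp_shared * n_true),
                   new_loci, to_cp = TRUE)
  sim <- add_class(sim, "strand_bias", round(rates$strand_bias * n_true),
                   new_loci, plasma_tweak = function(rows) {
                     rows$alt_fwd <- rows$alt_fwd + rows$alt_rev
                     rows$alt_rev <- 0L
                     rows
                   })
  sim <- add_class(sim, "blacklist", round(rates$blacklist * n_true),
                   function(n) {
                     i <- sample.int(length(blacklist), n, replace = TRUE)
                     loci <- sim_mutation_set(n, config)
                     loci$chrom <- as.character(
                       GenomicRanges::seqnames(blacklist))[i]
                     loci$pos <- as.integer(
                       GenomicRanges::start(blacklist)[i] +
                         floor(stats::runif(n, 0, 2e4 - 1)))
                     loci
                   })
  sim <- add_class(sim, "dbsnp_only", round(rates$dbsnp_only * n_true),
                   new_loci, anno = function(n) {
                     a <- clean_anno(n)
                     a$dbsnp_id <- sprintf("rs%07d", sample.int(1e7, n))
                     a$af_gnomad <- ifelse(stats::runif(n) < 0.5,
                                           stats::runif(n, 1e-4, 1e-2),
                                           NA_real_)
                     a
                   })
  sim <- add_class(sim, "low_bq", round(rates$low_bq * n_true),
                   new_loci, plasma_tweak = function(rows) {
                     rows$mean_alt_bq <- round(stats::runif(nrow(rows),
                                                            10, 24.8), 1)
                     rows
                   })
  sim <- add_class(sim, "synonymous", round(rates$synonymous * n_true),
                   new_loci, anno = function(n) {
                     a <- clean_anno(n)
                     a$exonic_function <- sample(c("synonymous", "unknown"),
                                                 n, replace = TRUE)
                     a
                   })

  # multi-allelic: two alt alleles at one locus, split across timepoints
  n_ma <- round(rates$multiallelic * n_true)
  if (n_ma > 0) {
    loci <- sim_mutation_set(n_ma, config)
    alt2 <- vapply(seq_len(n_ma), function(i) {
      sample(setdiff(c("A", "C", "G", "T"), c(loci$ref[i], loci$alt[i])), 1)
    }, character(1))
    loci2 <- loci
    loci2$alt <- alt2
    an <- clean_anno(n_ma)
    vaf <- stats::runif(n_ma, 0.03, 0.10)
    for (j in seq_along(plasma_ids)) {
      use <- if (j %% 2 == 1) loci else loci2
      sim$variants[[plasma_ids[j]]] <- rbind(
        sim$variants[[plasma_ids[j]]],
        sim_counts_at(use, vaf, config$plasma_depth, plasma_ids[j],
                      annotations = an))
    }
    g_rows <- sim_counts_at(loci, rep(0, n_ma), config$germline_depth,
                            germ_id, annotations = an)
    sim$variants[[germ_id]] <- rbind(sim$variants[[germ_id]], g_rows)
    truth[["multiallelic"]] <- data.frame(
      key = c(variant_key(loci), variant_key(loci2)),
      class = "multiallelic", stringsAsFactors = FALSE)
  }

  sim$blacklist <- blacklist
  sim$truth$artifacts <- if (length(truth) == 0) {
    data.frame(key = character(0), class = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(truth, make.row.names = FALSE))
  }
  sim
}

# ---- kataegis injection ---------------------------------------------------

#' Inject localized hypermutation clusters with known truth
#'
#' Places `n_clusters` runs of `cluster_size` clonal SNVs with consecutive
#' spacings drawn uniform(100, `spacing_max`) on random chromosomes, with an
#' optional fixed substitution class (default T>G). Clusters with fewer than
#' 6 members are labelled sub-threshold in the truth table and must not be
#' detected.
#'
#' @param sim output of [simulate_reads()] / [inject_artifacts()].
#' @param config a [sim_config()].
#' @return `sim` with cluster rows added and `truth$kataegis` set.
#' @export
inject_kataegis <- function(sim, config) {
  kat <- config$kataegis
  events <- list()
  plasma_ids <- sim$manifest$sample_id[sim$manifest$sample_class == "plasma"]
  germ_id <- sim$manifest$sample_id[sim$manifest$sample_class == "germline"]
  tum_id <- sim$manifest$sample_id[sim$manifest$sample_class == "tumour"]
  tf <- config$tumour_fraction
  if (kat$n_clusters == 0) {
    sim$truth$kataegis <- data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), n = integer(0),
                                     mean_imd = numeric(0),
                                     meets_definition = logical(0))
    return(sim)
  }
  existing <- unlist(lapply(sim$variants, function(v) paste0(v$chrom, ":", v$pos)))
  lens <- autosome_lengths()[config$chroms]
  for (e in seq_len(kat$n_clusters)) {
    size <- kat$cluster_size
    repeat {
      chrom <- sample(names(lens), 1, prob = lens / sum(lens))
      start <- floor(stats::runif(1, 1e6, lens[chrom] - 1e7))
      gaps <- floor(stats::runif(size - 1, 100, kat$spacing_max))
      pos <- as.integer(start + cumsum(c(0, gaps)))
      if (!any(paste0(chrom, ":", pos) %in% existing)) break
    }
    existing <- c(existing, paste0(chrom, ":", pos))
    if (is.na(kat$substitution)) {
      base <- sim_mutation_set(size, config)
    } else {
      ra <- strsplit(kat$substitution, ">")[[1]]
      base <- sim_mutation_set(size, config)
      base$ref <- ra[1]
      base$alt <- ra[2]
      base$context <- paste0(substr(base$context, 1, 1), ra[1],
                             substr(base$context, 3, 3))
    }
    base$chrom <- chrom
    base$pos <- pos
    an <- list(cosmic_id = NA_character_, dbsnp_id = NA_character_,
               exonic_function = "nonsynonymous", af_1000g = NA_real_,
               af_gnomad = NA_real_, af_hapmap = NA_real_,
               driver_class = NA_character_, biomarker = NA_character_)
    for (j in seq_along(plasma_ids)) {
      sim$variants[[plasma_ids[j]]] <- rbind(
        sim$variants[[plasma_ids[j]]],
        sim_counts_at(base, rep(0.5 * tf[j], size), config$plasma_depth,
                      plasma_ids[j], annotations = an))
    }
    sim$variants[[tum_id]] <- rbind(
      sim$variants[[tum_id]],
      sim_counts_at(base, rep(0.5 * config$tumour_cellularity, size),
                    config$tumour_depth, tum_id, annotations = an))
    sim$variants[[germ_id]] <- rbind(
      sim$variants[[germ_id]],
      sim_counts_at(base, rep(0, size), config$germline_depth, germ_id,
                    annotations = an))
    imd <- diff(pos)
    events[[e]] <- data.frame(chrom = chrom, start = min(pos),
                              end = max(pos), n = size,
                              mean_imd = mean(imd),
                              meets_definition = size >= 6 &&
                                mean(imd) <= 1000,
                              stringsAsFactors = FALSE)
  }
  sim$truth$kataegis <- do.call(rbind, events)
  sim
}

# ---- spectra and fragments ------------------------------------------------

#' Draw a 96-channel mutation spectrum from a signature mixture
#'
#' Counts are Multinomial(`n_mutations`, `M %*% exposures`).
#'
#' @param signature_matrix 96 x S column-stochastic matrix.
#' @param exposures non-negative weights summing to 1, length S.
#' @param n_mutations total mutation count.
#' @param seed optional integer seed.
#' @return named integer vector of length 96.
#' @export
simulate_spectrum <- function(signature_matrix, exposures, n_mutations,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(exposures) != ncol(signature_matrix)) {
    stop("exposure vector length must equal the number of signatures",
         call. = FALSE)
  }
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must be non-negative and sum to 1", call. = FALSE)
  }
  p <- as.vector(signature_matrix %*% exposures)
  if (n_mutations == 0) {
    out <- integer(96)
  } else {
    out <- as.integer(stats::rmultinom(1, n_mutations, p))
  }
  names(out) <- rownames(signature_matrix)
  out
}

#' Simulate cfDNA fragment lengths
#'
#' Mixture of a mononucleosomal component peaked at `modal_length` with
#' weight `1 - dinucleosome_weight` and a broad dinucleosomal
#' Normal(`2 * modal_length`, `2 * sd`) component, rounded to integers and
#' truncated at >= 50 bp. The mononucleosomal component is a Laplace
#' (double-exponential) with standard deviation `sd`: cfDNA length
#' profiles show a sharp cusp at the mononucleosomal mode rather than a
#' smooth dome, which also makes the 1-bp histogram mode well-defined.
#'
#' @param n number of fragments.
#' @param modal_length mononucleosomal mode (bp).
#' @param sd standard deviation of the mononucleosomal component.
#' @param dinucleosome_weight mixture weight `d` of the long component.
#' @param seed optional integer seed.
#' @return integer vector of lengths.
#' @export
simulate_fragments <- function(n, modal_length = 167, sd = 10,
                               dinucleosome_weight = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dinucleosome_weight < 0 || dinucleosome_weight > 1) {
    stop("dinucleosome_weight must be in [0,1]", call. = FALSE)
  }
  if (modal_length <= 0) stop("modal_length must be > 0", call. = FALSE)
  b <- sd / sqrt(2)  # Laplace scale with variance sd^2
  draw <- function(m) {
    di <- stats::runif(m) < dinucleosome_weight
    mono <- modal_length + stats::rexp(m, 1 / b) - stats::rexp(m, 1 / b)
    round(ifelse(di, stats::rnorm(m, 2 * modal_length, 2 * sd), mono))
  }
  out <- draw(n)
  while (any(out < 50)) out[out < 50] <- draw(sum(out < 50))
  as.integer(out)
}

# ---- copy-number profile simulation ---------------------------------------

#' Simulate a binned read-depth profile with known copy states
#'
#' Builds a 1 Mb bin grid over the requested chromosomes, assigns an integer
#' copy state per chromosome (2 unless listed in `aberrant`), and draws
#' sample/normal counts sharing a smooth GC bias so that the log2 ratio of
#' GC-corrected counts is Normal(`expected_logr(state, t)`, `sigma`).
#'
#' @param tumour_fraction simulated tumour fraction `t`.
#' @param aberrant named integer vector, chromosome -> copy state.
#' @param sigma per-bin log-ratio noise SD.
#' @param chroms chromosomes to profile.
#' @param mean_count expected normal read count per bin.
#' @param gc_bias_amplitude amplitude of the injected quadratic GC bias.
#' @param seed optional integer seed.
#' @return list with `sample`, `normal` (data.frames chrom,start,count,gc,
#'   mappability) and `truth` (list: tumour_fraction, per-bin state).
#' @export
simulate_bin_profile <- function(tumour_fraction, aberrant = c(chr18 = 1L),
                                 sigma = 0.05,
                                 chroms = paste0("chr", 1:6),
                                 mean_count = 5000,
                                 gc_bias_amplitude = 0.3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- autosome_lengths()[chroms]
  grid <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(0, lens[ch] - 1, by = 1e6)
    data.frame(chrom = ch, start = as.integer(starts))
  }))
  n <- nrow(grid)
  gc <- stats::runif(n, 0.35, 0.60)
  mapp <- ifelse(stats::runif(n) < 0.03, stats::runif(n, 0.3, 0.85), 1)
  state <- rep(2L, n)
  for (ch in names(aberrant)) state[grid$chrom == ch] <- aberrant[[ch]]
  bias <- 1 + gc_bias_amplitude * (1 - ((gc - 0.45) / 0.15)^2)
  normal_count <- mean_count * bias * exp(stats::rnorm(n, 0, sigma / 4 * log(2)))
  lr <- vapply(state, expected_logr, numeric(1), t = tumour_fraction)
  sample_count <- mean_count * bias * 2^(lr + stats::rnorm(n, 0, sigma))
  list(sample = data.frame(grid, count = round(sample_count), gc = gc,
                           mappability = mapp),
       normal = data.frame(grid, count = round(normal_count), gc = gc,
                           mappability = mapp),
       truth = list(tumour_fraction = tumour_fraction, state = state,
                    chrom = grid$chrom))
}

# ---- orchestration --------------------------------------------------------

#' Simulate a full synthetic patient
#'
#' Runs [simulate_clone_tree()], [simulate_reads()], [inject_artifacts()],
#' [inject_kataegis()] and [simulate_fragments()] under a single RNG seeded
#' from `config$seed`, and harmonizes per-locus annotations across samples.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (per-sample tables), `manifest`,
#'   `blacklist`, `fragments` and `truth` (clone tree, prevalence matrix,
#'   mutation assignments, artifact labels, kataegis events).
#' @export
simulate_patient <- function(config) {
  tree <- simulate_clone_tree(config)  # seeds the RNG
  sim <- simulate_reads(tree, config)
  sim$variants <- align_annotations(sim$variants, names(sim$variants)[1])
  sim <- inject_artifacts(sim, config)
  sim <- inject_kataegis(sim, config)
  sim$fragments <- simulate_fragments(config$fragment$n,
                                      config$fragment$modal_length,
                                      config$fragment$sd,
                                      config$fragment$dinucleosome_weight)
  sim
}

#' Write a simulated patient to disk
#'
#' Per-sample variant TSVs, manifest TSV, blacklist BED, fragment lengths
#' (one integer per line) and truth tables, all plain text.
#'
#' @param sim output of [simulate_patient()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$variants)) {
    write_variant_table(sim$variants[[nm]],
                        file.path(dir, paste0(nm, ".variants.tsv")))
  }
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bl <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sim$blacklist)),
    start = GenomicRanges::start(sim$blacklist) - 1L,
    end = GenomicRanges::end(sim$blacklist))
  utils::write.table(bl, file.path(dir, "blacklist.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(as.character(sim$fragments),
             file.path(dir, "fragment_lengths.txt"))
  utils::write.table(sim$truth$artifacts,
                     file.path(dir, "truth_artifacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- sim$truth$mutations
  utils::write.table(mt, file.path(dir, "truth_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth$prevalence),
                     file.path(dir, "truth_prevalence.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  if (!is.null(sim$truth$kataegis)) {
    utils::write.table(sim$truth$kataegis,
                       file.path(dir, "truth_kataegis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
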