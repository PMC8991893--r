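# Independent Fisher exact oracle: two-sided p by summing hypergeometric
# point probabilities no larger than the observed table's.
fisher_oracle <- function(rf, rr, af, ar) {
  m <- rf + rr
  n <- af + ar
  k <- rf + af
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(rf, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("plasma calling enforces strand-aware read support with tumour rescue", {
  cfg <- default_config()
  p <- rbind(vrow(pos = 1, alt_fwd = 2, alt_rev = 1),   # 3 reads, both strands
             vrow(pos = 2, alt_fwd = 3, alt_rev = 0),   # one-strand only
             vrow(pos = 3, alt_fwd = 1, alt_rev = 0))   # rescue candidate
  no_tum <- call_plasma_candidates(p, NULL, cfg)
  expect_equal(no_tum$pos, 1)
  tum <- vrow(pos = 3, sample_id = "T", alt_fwd = 3, alt_rev = 2)
  with_tum <- call_plasma_candidates(p, tum, cfg)
  expect_setequal(with_tum$pos, c(1, 3))
  # tumour support below 3 alt reads does not rescue
  weak_tum <- vrow(pos = 3, sample_id = "T", alt_fwd = 2, alt_rev = 0)
  expect_equal(call_plasma_candidates(p, weak_tum, cfg)$pos, 1)
})

test_that("dbSNP-only and exonic-function rules drop exactly as specified", {
  x <- rbind(vrow(pos = 1, cosmic_id = NA, dbsnp_id = "rs123"),
             vrow(pos = 2, cosmic_id = "COSV1", dbsnp_id = "rs123"),
             vrow(pos = 3, cosmic_id = NA, dbsnp_id = NA))
  expect_setequal(filter_dbsnp_only(x)$pos, c(2, 3))

  y <- rbind(vrow(pos = 1, exonic_function = "nonsynonymous"),
             vrow(pos = 2, exonic_function = "synonymous"),
             vrow(pos = 3, exonic_function = "stopgain"),
             vrow(pos = 4, exonic_function = "unknown"),
             vrow(pos = 5, exonic_function = NA))
  out <- filter_exonic_function(y)
  expect_setequal(out$pos, c(1, 3))
  expect_equal(attr(out, "n_missing_annotation"), 1)
})

test_that("base quality threshold is inclusive at 25", {
  x <- rbind(vrow(pos = 1, mean_alt_bq = 25.0),
             vrow(pos = 2, mean_alt_bq = 24.9),
             vrow(pos = 3, mean_alt_bq = 60))
  expect_setequal(filter_base_quality(x)$pos, c(1, 3))
})

test_that("germline exclusion requires 20x clean coverage", {
  cfg <- default_config()
  cand <- rbind(vrow(pos = 1), vrow(pos = 2), vrow(pos = 3), vrow(pos = 4))
  germ <- rbind(
    vrow(pos = 1, sample_id = "G", ref_fwd = 13, ref_rev = 12,
         alt_fwd = 0, alt_rev = 0),                       # 25x clean
    vrow(pos = 2, sample_id = "G", ref_fwd = 12, ref_rev = 12,
         alt_fwd = 1, alt_rev = 0),                       # 25x with alt
    vrow(pos = 3, sample_id = "G", ref_fwd = 10, ref_rev = 9,
         alt_fwd = 0, alt_rev = 0))                       # 19x undercovered
  out <- filter_germline(cand, germ, cfg)
  expect_equal(out$pos, 1)  # pos 4 absent -> depth 0 -> dropped
  expect_equal(attr(out, "n_undercovered"), 2)

  cfg$filtering$germline_undercovered <- "keep"
  out2 <- filter_germline(cand, germ, cfg)
  expect_setequal(out2$pos, c(1, 3, 4))
})

test_that("CP-control exclusion drops any locus with control alt reads", {
  cand <- rbind(vrow(pos = 1), vrow(pos = 2))
  cp <- rbind(vrow(pos = 1, sample_id = "CP1", ref_fwd = 250,
                   ref_rev = 250, alt_fwd = 1, alt_rev = 0),
              vrow(pos = 2, sample_id = "CP1", ref_fwd = 250,
                   ref_rev = 250, alt_fwd = 0, alt_rev = 0))
  expect_equal(filter_cp_controls(cand, list(cp))$pos, 2)
  expect_warning(out <- filter_cp_controls(cand, list()), "vacuous")
  expect_equal(nrow(out), 2)
})

test_that("multi-allelic loci are removed across serial plasma", {
  cand <- rbind(vrow(pos = 100, alt = "T", sample_id = "P1"),
                vrow(pos = 100, alt = "G", sample_id = "P3"),
                vrow(pos = 200, alt = "T", sample_id = "P1"),
                vrow(pos = 200, alt = "T", sample_id = "P2"),
                vrow(pos = 200, alt = "T", sample_id = "P4"))
  out <- filter_multiallelic(cand)
  expect_true(all(out$pos == 200))
  expect_equal(nrow(out), 3)
})

test_that("population-AF flag marks without removing by default", {
  cfg <- default_config()
  x <- rbind(vrow(pos = 1, af_gnomad = 0.001),
             vrow(pos = 2),
             vrow(pos = 3, af_gnomad = 0))
  out <- flag_population_af(x, cfg)
  expect_equal(nrow(out), 3)
  expect_true(grepl("pop_af", out$flags[1]))
  expect_false(any(grepl("pop_af", out$flags[2:3])))
  cfg$filtering$pop_af_action <- "drop"
  expect_setequal(flag_population_af(x, cfg)$pos, c(2, 3))
})

test_that("blacklist filter respects BED boundaries", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  bl <- read_blacklist(f)
  x <- rbind(vrow(pos = 150), vrow(pos = 100), vrow(pos = 200))
  expect_setequal(filter_blacklist(x, bl)$pos, 100)
})

test_that("strand-bias filter agrees with the Fisher oracle and spares low depth", {
  cases <- rbind(
    c(100, 100, 30, 0),   # extreme bias: drop
    c(100, 100, 15, 15),  # balanced: keep
    c(10, 10, 1, 0))      # low depth: keep (p above threshold)
  x <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i)
    vrow(pos = i, ref_fwd = cases[i, 1], ref_rev = cases[i, 2],
         alt_fwd = cases[i, 3], alt_rev = cases[i, 4])))
  out <- filter_strand_bias(x)
  expect_setequal(out$pos, c(2, 3))
  # oracle agreement on the decision inputs
  p1 <- fisher_oracle(100, 100, 30, 0)
  expect_lt(p1, 0.01)
  expect_equal(p1, stats::fisher.test(matrix(c(100, 100, 30, 0), 2,
                                             byrow = TRUE))$p.value,
               tolerance = 1e-9)
  p3 <- fisher_oracle(10, 10, 1, 0)
  expect_gt(p3, 0.01)
})

test_that("the cascade reproduces the hand-derived fixture truth", {
  fx <- read_fixture_tables()
  rep <- run_cascade(list(fx$p1, fx$p2), tumour = fx$tumour,
                     germline = fx$germline, cp_tables = list(fx$cp),
                     blacklist = fx$blacklist)
  survivors <- unique(variant_key(rep$candidates))
  truth <- fx$truth
  expect_setequal(survivors, truth$key[truth$class == "true_somatic"])
  stages <- drop_stage_table(rep)
  for (i in which(truth$class != "true_somatic")) {
    expect_equal(stages$stage[stages$key == truth$key[i]],
                 truth$designed_stage[i], label = truth$key[i])
  }
  # monotonicity of the report
  expect_true(all(rep$stages$n_out <= rep$stages$n_in))
  # rescue-eligible variant (1 plasma read, 5 tumour alt reads) survives
  rescue <- validate_variants(vrow(chrom = "chr13", pos = 500,
                                   sample_id = "FX01_P1",
                                   alt_fwd = 1, alt_rev = 0))
  tum2 <- rbind(fx$tumour,
                validate_variants(vrow(chrom = "chr13", pos = 500,
                                       sample_id = "FX01_T", alt_fwd = 3,
                                       alt_rev = 2)))
  germ2 <- rbind(fx$germline,
                 validate_variants(vrow(chrom = "chr13", pos = 500,
                                        sample_id = "FX01_G", ref_fwd = 50,
                                        ref_rev = 50, alt_fwd = 0,
                                        alt_rev = 0, mean_alt_bq = NA)))
  rep2 <- run_cascade(list(rbind(fx$p1, rescue), fx$p2), tumour = tum2,
                      germline = germ2, cp_tables = list(fx$cp),
                      blacklist = fx$blacklist)
  expect_true("chr13:500:C>T" %in% variant_key(rep2$candidates))
})

test_that("empty input yields an all-zero report", {
  expect_warning(rep <- run_cascade(list(), cp_tables = list()), "vacuous")
  expect_true(all(rep$stages$n_in == 0))
  expect_true(all(rep$stages$n_out == 0))
  expect_equal(nrow(rep$candidates), 0)
})

test_that("set filters commute: permuting stages 2-9 leaves the result fixed", {
  fx <- read_fixture_tables()
  cfg <- default_config()
  plasma <- rbind(fx$p1, fx$p2)
  called <- call_plasma_candidates(plasma, fx$tumour, cfg)
  filters <- list(
    dbsnp = function(x) filter_dbsnp_only(x),
    exonic = function(x) filter_exonic_function(x),
    bq = function(x) filter_base_quality(x, cfg),
    germ = function(x) filter_germline(x, fx$germline, cfg),
    cp = function(x) filter_cp_controls(x, list(fx$cp)),
    ma = function(x) filter_multiallelic(x, called = called),
    bl = function(x) filter_blacklist(x, fx$blacklist),
    sb = function(x) filter_strand_bias(x, cfg))
  run_perm <- function(ord) {
    cur <- called
    for (f in filters[ord]) cur <- f(cur)
    sort(unique(variant_key(cur)))
  }
  baseline <- run_perm(seq_along(filters))
  set.seed(1)
  for (i in 1:15) {
    expect_equal(run_perm(sample(seq_along(filters))), baseline)
  }
  expect_equal(run_perm(rev(seq_along(filters))), baseline)
})

test_that("on labelled simulations every artifact class is removed", {
  sim <- simulate_patient(sim_config(seed = 21))
  man <- sim$manifest
  plasma_ids <- man$sample_id[man$sample_class == "plasma"]
  cp_ids <- man$sample_id[man$sample_class == "cp_control"]
  rep <- run_cascade(sim$variants[plasma_ids],
                     tumour = sim$variants[["PT01_T"]],
                     germline = sim$variants[["PT01_G"]],
                     cp_tables = sim$variants[cp_ids],
                     blacklist = sim$blacklist)
  survivors <- unique(variant_key(rep$candidates))
  truth <- sim$truth$artifacts
  hard <- c("germline_leak", "cp_shared", "blacklist", "multiallelic",
            "synonymous", "low_bq", "dbsnp_only")
  expect_length(intersect(truth$key[truth$class %in% hard], survivors), 0)
  sb_keys <- truth$key[truth$class == "strand_bias"]
  expect_gte(mean(!sb_keys %in% survivors), 0.95)

  # true somatics with expected VAF >= 1% survive, barring alt < 3 draws
  muts <- sim$truth$mutations
  U <- sim$truth$prevalence
  ev <- 0.5 * sweep(U[muts$clone_id, , drop = FALSE], 2,
                    sim_config(seed = 21)$tumour_fraction, "*")
  detectable <- variant_key(muts)[apply(ev, 1, max) >= 0.01]
  lost <- setdiff(detectable, survivors)
  # exclude losses where no timepoint reached the 3-read strand-aware call
  called_keys <- unique(variant_key(rep$candidates))
  plasma_all <- do.call(rbind, sim$variants[plasma_ids])
  alt_by_key <- tapply(plasma_all$alt_fwd + plasma_all$alt_rev,
                       variant_key(plasma_all), max)
  genuine_lost <- lost[alt_by_key[lost] >= 3]
  expect_lte(length(genuine_lost) / max(length(detectable), 1), 0.05)
})
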