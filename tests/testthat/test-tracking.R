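man1 <- function(J = 3, patient = "PT01") {
  data.frame(patient_id = patient,
             sample_id = paste0(patient, "_P", seq_len(J)),
             sample_class = "plasma",
             timepoint_label = paste0("P", seq_len(J)),
             day = c(10, 100, 250, 400, 600)[seq_len(J)])
}

test_that("mean MAF is the arithmetic mean over the covered locus set", {
  man <- man1(1)
  cand <- rbind(
    vrow(pos = 1, sample_id = "PT01_P1", alt_fwd = 10, alt_rev = 10,
         ref_fwd = 490, ref_rev = 490),   # MAF 0.02
    vrow(pos = 2, sample_id = "PT01_P1", alt_fwd = 20, alt_rev = 20,
         ref_fwd = 480, ref_rev = 480),   # MAF 0.04
    vrow(pos = 3, sample_id = "PT01_P1", alt_fwd = 30, alt_rev = 30,
         ref_fwd = 470, ref_rev = 470))   # MAF 0.06
  out <- mean_maf_series(cand, man)
  expect_equal(out$mean_maf, 0.04)
  expect_equal(out$n_loci, 3)

  # undetected-but-covered loci count as zero
  tables <- list(PT01_P1 = rbind(cand[1, ],
                                 vrow(pos = 9, sample_id = "PT01_P1",
                                      alt_fwd = 0, alt_rev = 0,
                                      ref_fwd = 500, ref_rev = 500)))
  cand2 <- rbind(cand[1, ], vrow(pos = 9, sample_id = "PT01_PX",
                                 alt_fwd = 5, alt_rev = 5))
  out2 <- mean_maf_series(cand2, man, plasma_tables = tables)
  expect_equal(out2$mean_maf, 0.01)
  # all loci undetected at covered sites -> 0.0
  t3 <- list(PT01_P1 = vrow(pos = 1, sample_id = "PT01_P1", alt_fwd = 0,
                            alt_rev = 0, ref_fwd = 500, ref_rev = 500))
  out3 <- mean_maf_series(cand[1, ], man, plasma_tables = t3)
  expect_equal(out3$mean_maf, 0)
})

test_that("the MAF series is invariant to row order and duplication", {
  man <- man1(2)
  cand <- rbind(
    vrow(pos = 1, sample_id = "PT01_P1", alt_fwd = 10, alt_rev = 10),
    vrow(pos = 2, sample_id = "PT01_P1", alt_fwd = 30, alt_rev = 30),
    vrow(pos = 1, sample_id = "PT01_P2", alt_fwd = 5, alt_rev = 5))
  a <- mean_maf_series(cand, man)
  b <- mean_maf_series(cand[c(3, 1, 2), ], man)
  d <- mean_maf_series(rbind(cand, cand[1, ]), man)
  expect_equal(a, b)
  expect_equal(a, d)
})

test_that("the mean MAF series tracks the simulated tumour fraction", {
  tf <- c(0.3, 0.05, 0.2)
  cfg <- clean_sim_config(13, n_timepoints = 3, tumour_fraction = tf)
  sim <- simulate_patient(cfg)
  ids <- sim$manifest$sample_id[sim$manifest$sample_class == "plasma"]
  cand <- do.call(rbind, sim$variants[ids])
  out <- mean_maf_series(cand, sim$manifest,
                         plasma_tables = sim$variants[ids])
  expect_equal(stats::cor(out$mean_maf, tf, method = "spearman"), 1)
})

test_that("CA19-9 joins by nearest day within the window", {
  man <- man1(2)
  ca <- data.frame(day = c(12, 300), value = c(100, 55))
  cand <- vrow(pos = 1, sample_id = "PT01_P1", alt_fwd = 10, alt_rev = 10)
  out <- mean_maf_series(cand, man, ca199 = ca)
  expect_equal(out$ca199, c(100, NA))  # day 100 has no value within 14 d
})

test_that("concordance reports baseline and combined overlap fractions", {
  tum <- paste0("m", 1:4)
  cc <- concordance(tum, list(c("m1", "m2"), c("m3")))
  expect_equal(cc$baseline, 0.5)
  expect_equal(cc$combined, 0.75)
  expect_equal(cc$plasma_specific, 0)

  expect_equal(concordance(tum, list(c("x1")))$combined, 0)
  empty <- concordance(character(0), list("m1"))
  expect_true(empty$flagged)
  expect_true(is.na(empty$baseline))
})

test_that("combined overlap dominates baseline on random set pairs", {
  set.seed(9)
  for (i in 1:200) {
    tum <- sample(letters, sample(1:20, 1))
    sets <- lapply(1:3, function(j) sample(letters, sample(0:15, 1)))
    cc <- concordance(tum, sets)
    expect_gte(cc$combined, cc$baseline)
  }
})

test_that("mutation loads summarize per sample with group comparison", {
  man <- rbind(man1(2, "A"), man1(2, "B"))
  cands <- list(
    A = rbind(vrow(pos = 1, sample_id = "A_P1"),
              vrow(pos = 2, sample_id = "A_P1"),
              vrow(pos = 1, sample_id = "A_P2")),
    B = do.call(rbind, lapply(1:20, function(i)
      vrow(pos = i, sample_id = "B_P1"))))
  out <- mutation_load_table(cands, man,
                             groups = c(A = "resectable",
                                        B = "unresectable"))
  expect_equal(out$table$n_mutations[out$table$sample_id == "A_P1"], 2)
  expect_equal(out$table$n_mutations[out$table$sample_id == "B_P1"], 20)
  expect_gt(out$group_medians[["unresectable"]],
            out$group_medians[["resectable"]])
  expect_true(is.finite(out$p_value))

  single <- mutation_load_table(cands["A"], man)
  expect_equal(nrow(single$table), 2)
  expect_true(is.na(single$p_value))
})

test_that("modal fragment size takes the histogram argmax with tie flag", {
  expect_equal(modal_fragment_size(c(166, 167, 167, 168))$mode, 167)
  tie <- modal_fragment_size(c(100, 100, 200, 200))
  expect_equal(tie$mode, 100)
  expect_true(tie$tie)
  expect_error(modal_fragment_size(integer(0)), "no fragment")
  by_cls <- modal_fragment_size(c(167, 167, 320, 320, 320),
                                labels = c("wt", "wt", "mut", "mut", "mut"))
  expect_equal(by_cls$by_class[["mut"]], 320)
  expect_equal(by_cls$by_class[["wt"]], 167)
})

test_that("hypergeometric enrichment matches closed form and BH formula", {
  db <- data.frame(pathway = rep(c("PW1", "PW2"), c(10, 5)),
                   gene = c(paste0("g", 1:10), paste0("h", 1:5)))
  universe <- c(paste0("g", 1:10), paste0("h", 1:5),
                paste0("u", 1:85))  # N = 100
  res <- pathway_enrichment(c("g1", "g2", "g3"), db, universe)
  # N=100, K=10, n=3, k=3 -> C(10,3)/C(100,3)
  expect_equal(res$p[res$pathway == "PW1"], choose(10, 3) / choose(100, 3),
               tolerance = 1e-12)
  expect_equal(res$p[res$pathway == "PW2"], 1)  # k = 0 -> upper tail at 0

  # excluded genes are counted, not fatal
  res2 <- pathway_enrichment(c("g1", "NOT_THERE"), db, universe)
  expect_equal(attr(res2, "n_excluded_genes"), 1)

  expect_equal(stats::p.adjust(c(0.001, 0.02, 0.9), method = "BH"),
               c(0.003, 0.03, 0.9))
})

test_that("hypergeometric p equals a literal subset-enumeration oracle", {
  N <- 12; K <- 5; n <- 6
  universe <- paste0("x", 1:N)
  pw_genes <- universe[1:K]
  sel <- universe[c(1, 2, 6, 7, 8, 9)]  # k = 2
  db <- data.frame(pathway = "PW", gene = pw_genes)
  res <- pathway_enrichment(sel, db, universe)
  combos <- utils::combn(N, n)
  overlaps <- colSums(combos <= K)
  k_obs <- sum(sel %in% pw_genes)
  p_enum <- mean(overlaps >= k_obs)
  expect_equal(res$p, p_enum, tolerance = 1e-12)
})

test_that("actionability annotation classifies and tracks serial variants", {
  cat <- toy_gene_catalogue()
  cand <- rbind(
    vrow(pos = 1, sample_id = "P1", gene = "KRAS"),
    vrow(pos = 1, sample_id = "P3", gene = "KRAS"),
    vrow(pos = 2, sample_id = "P1", gene = "ZZZ9"),
    vrow(pos = 3, sample_id = "P2", gene = "BRCA2"))
  out <- annotate_actionability(list(PT01 = cand), cat)
  v <- out$variants
  expect_equal(v$class[v$gene == "KRAS"], "PDAC-driver")
  expect_equal(v$class[v$gene == "ZZZ9"], "none")
  expect_equal(v$class[v$gene == "BRCA2"], "DDR-biomarker")
  expect_equal(v$therapy[v$gene == "BRCA2"], "PARPi/platinum")
  expect_true(v$trackable[v$gene == "KRAS"])    # P1 and P3
  expect_false(v$trackable[v$gene == "BRCA2"])  # single sample
  expect_equal(out$matrix["PT01", "KRAS"], "PDAC-driver")
  expect_equal(out$matrix["PT01", "TP53"], "")
})
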