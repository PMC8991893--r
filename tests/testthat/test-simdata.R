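test_that("clone trees satisfy the sum condition at every node and timepoint", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed)
    tree <- simulate_clone_tree(cfg)
    U <- tree$prevalence
    parent <- tree$clones$parent_id
    # brute-force walk over all nodes and timepoints
    for (i in seq_len(nrow(U))) {
      kids <- which(parent == i)
      if (length(kids) == 0) next
      child_sum <- colSums(U[kids, , drop = FALSE])
      expect_true(all(child_sum <= U[i, ] + 1e-12))
    }
    expect_true(all(U[1, ] <= 1))
  }
})

test_that("clone tree generation is deterministic and validates config", {
  t1 <- simulate_clone_tree(sim_config(seed = 7))
  t2 <- simulate_clone_tree(sim_config(seed = 7))
  expect_identical(t1, t2)
  one <- simulate_clone_tree(sim_config(seed = 1, n_clones = 1))
  expect_equal(nrow(one$clones), 1)
  expect_true(is.na(one$clones$parent_id))
  expect_error(sim_config(muts_per_clone = 0), "muts_per_clone")
  expect_error(sim_config(n_clones = 0), "n_clones")
  expect_error(sim_config(tumour_fraction = 1.2), "tumour_fraction")
})

test_that("simulated alt counts follow the heterozygous VAF model", {
  # t = 0.5, P = 0.4, depth 1000 -> expected VAF 0.10, mean alt ~ 100
  cfg <- sim_config(seed = 3, n_clones = 1, muts_per_clone = 500,
                    n_timepoints = 1, tumour_fraction = 0.5,
                    plasma_depth = 1000)
  tree <- simulate_clone_tree(cfg)
  tree$prevalence[1, ] <- 0.4
  set.seed(42)
  sim <- simulate_reads(tree, cfg)
  p1 <- sim$variants$PT01_P1
  alt <- p1$alt_fwd + p1$alt_rev
  # sd of one draw ~ sqrt(1000*.1*.9 + .1^2*1000) ~ 10; 3 SE over 500 loci
  expect_lt(abs(mean(alt) - 100), 3 * 10 / sqrt(500))
  # strand split is balanced
  expect_lt(abs(mean(p1$alt_fwd / pmax(alt, 1)) - 0.5), 0.02)
  # germline carries no alt reads at somatic loci
  g <- sim$variants$PT01_G
  expect_true(all(g$alt_fwd + g$alt_rev == 0))
})

test_that("tumour fraction zero clears all plasma alt reads", {
  cfg <- sim_config(seed = 4, n_timepoints = 2, tumour_fraction = c(0, 0))
  tree <- simulate_clone_tree(cfg)
  sim <- simulate_reads(tree, cfg)
  for (id in c("PT01_P1", "PT01_P2")) {
    v <- sim$variants[[id]]
    expect_true(all(v$alt_fwd + v$alt_rev == 0))
  }
})

test_that("simulation tables are bitwise reproducible under a fixed seed", {
  s1 <- simulate_patient(sim_config(seed = 11))
  s2 <- simulate_patient(sim_config(seed = 11))
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$fragments, s2$fragments)
})

test_that("artifact injection matches each class definition", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_patient(cfg)
  truth <- sim$truth$artifacts
  expect_setequal(unique(truth$class),
                  c("germline_leak", "cp_shared", "strand_bias",
                    "blacklist", "dbsnp_only", "low_bq", "synonymous",
                    "multiallelic"))
  p1 <- sim$variants$PT01_P1
  g <- sim$variants$PT01_G
  key_p1 <- variant_key(p1)
  key_g <- variant_key(g)

  sb <- truth$key[truth$class == "strand_bias"]
  rows <- p1[key_p1 %in% sb, ]
  expect_true(all(rows$alt_rev == 0))
  expect_true(all(rows$alt_fwd > 0))

  gl <- truth$key[truth$class == "germline_leak"]
  grows <- g[key_g %in% gl, ]
  expect_true(all(grows$alt_fwd + grows$alt_rev >= 1))
  expect_true(all(variant_depth(grows) >= 20))

  bl <- truth$key[truth$class == "blacklist"]
  brows <- p1[key_p1 %in% bl, ]
  expect_true(all(in_blacklist(brows$chrom, brows$pos, sim$blacklist)))

  cp <- truth$key[truth$class == "cp_shared"]
  for (id in grep("^CP", names(sim$variants), value = TRUE)) {
    cpt <- sim$variants[[id]]
    hit <- cpt[variant_key(cpt) %in% cp, ]
    expect_true(all(hit$alt_fwd + hit$alt_rev >= 1))
  }

  lb <- p1[key_p1 %in% truth$key[truth$class == "low_bq"], ]
  expect_true(all(lb$mean_alt_bq < 25))

  ma <- truth$key[truth$class == "multiallelic"]
  ma_loci <- sub(":[ACGT]>[ACGT]$", "", ma)
  expect_true(all(table(ma_loci) == 2))
})

test_that("zero artifact rates leave the tables unchanged", {
  cfg <- clean_sim_config(1)
  tree <- simulate_clone_tree(cfg)
  sim <- simulate_reads(tree, cfg)
  before <- lapply(sim$variants, nrow)
  sim2 <- inject_artifacts(sim, cfg)
  for (nm in names(before)) {
    expect_equal(nrow(sim2$variants[[nm]]), before[[nm]])
  }
  expect_equal(nrow(sim2$truth$artifacts), 0)
  expect_error(sim_config(artifact_rates = list(cp_shared = 1.5)),
               "\\[0,1\\]")
})

test_that("kataegis injection writes truth meeting the stated definition", {
  cfg <- sim_config(seed = 6,
                    kataegis = list(n_clusters = 2, cluster_size = 6,
                                    spacing_max = 1000))
  sim <- simulate_patient(cfg)
  tr <- sim$truth$kataegis
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$n >= 6))
  expect_true(all(tr$mean_imd <= 1000))
  expect_true(all(tr$meets_definition))

  sub <- simulate_patient(sim_config(seed = 6,
    kataegis = list(n_clusters = 1, cluster_size = 5, spacing_max = 1000)))
  expect_false(any(sub$truth$kataegis$meets_definition))

  none <- simulate_patient(sim_config(seed = 6,
                                      kataegis = list(n_clusters = 0)))
  expect_equal(nrow(none$truth$kataegis), 0)
})

test_that("simulated spectra follow the multinomial signature mixture", {
  M <- random_signature_matrix(3, seed = 2)
  one_hot <- c(0, 1, 0)
  sp <- simulate_spectrum(M, one_hot, 10000, seed = 1)
  expect_equal(sum(sp), 10000)
  p_hat <- sp / 10000
  # within multinomial error of column 2 (99.9% envelope per channel)
  se <- sqrt(M[, 2] * (1 - M[, 2]) / 10000)
  expect_true(all(abs(p_hat - M[, 2]) <= 3.5 * se + 1e-9))

  expect_equal(sum(simulate_spectrum(M, one_hot, 0)), 0)

  M2 <- M[, 1:2]
  M2 <- sweep(M2, 2, colSums(M2), "/")
  expected <- 0.7 * M2[, 1] + 0.3 * M2[, 2]
  sp2 <- simulate_spectrum(M2, c(0.7, 0.3), 50000, seed = 3)
  expect_lt(max(abs(sp2 / 50000 - expected)), 0.01)

  expect_error(simulate_spectrum(M, c(0.5, 0.5), 10), "length")
  expect_error(simulate_spectrum(M, c(0.5, 0.4, 0.2), 10), "sum to 1")
})

test_that("fragment length simulation has the configured modal size", {
  fr <- simulate_fragments(1e5, modal_length = 167, sd = 10,
                           dinucleosome_weight = 0.15, seed = 9)
  tab <- table(fr)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 167)
  expect_true(all(fr >= 50))

  one <- simulate_fragments(1, seed = 1)
  expect_length(one, 1)
  expect_gte(one, 50)

  di <- simulate_fragments(5e4, dinucleosome_weight = 1, seed = 2)
  tab2 <- table(di)
  expect_lt(abs(as.integer(names(tab2)[which.max(tab2)]) - 334), 6)

  expect_error(simulate_fragments(10, dinucleosome_weight = 1.2),
               "dinucleosome_weight")
})

test_that("written simulations are plain text and reloadable", {
  dir <- withr::local_tempdir()
  sim <- simulate_patient(sim_config(seed = 2, muts_per_clone = 5))
  write_simulation(sim, dir)
  v <- read_variant_table(file.path(dir, "PT01_P1.variants.tsv"))
  expect_equal(nrow(v), nrow(sim$variants$PT01_P1))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), nrow(sim$manifest))
  bl <- read_blacklist(file.path(dir, "blacklist.bed"))
  expect_equal(length(bl), length(sim$blacklist))
  fr <- as.integer(readLines(file.path(dir, "fragment_lengths.txt")))
  expect_identical(fr, sim$fragments)
})
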