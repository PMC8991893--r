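# Shared helpers: fixture paths and small in-code builders.

fixture_path <- function(...) {
  system.file("extdata", ..., package = "ctlong")
}

read_fixture_tables <- function() {
  d <- fixture_path("filter_fixture")
  rd <- function(f) read_variant_table(file.path(d, f))
  list(p1 = rd("FX01_P1.variants.tsv"),
       p2 = rd("FX01_P2.variants.tsv"),
       germline = rd("FX01_G.variants.tsv"),
       tumour = rd("FX01_T.variants.tsv"),
       cp = rd("CPX1_P1.variants.tsv"),
       blacklist = read_blacklist(file.path(d, "blacklist.bed")),
       truth = utils::read.delim(file.path(d, "truth.tsv"),
                                 stringsAsFactors = FALSE))
}

# Minimal variant row builder for hand-constructed cases.
vrow <- function(chrom = "chr1", pos = 1000L, ref = "C", alt = "T",
                 sample_id = "S1", ref_fwd = 400L, ref_rev = 400L,
                 alt_fwd = 20L, alt_rev = 20L, mean_alt_bq = 35,
                 cosmic_id = NA_character_, dbsnp_id = NA_character_,
                 exonic_function = "nonsynonymous", af_1000g = NA_real_,
                 af_gnomad = NA_real_, af_hapmap = NA_real_,
                 gene = "GENE001", driver_class = NA_character_,
                 biomarker = NA_character_, context = NA_character_) {
  if (is.na(context)) context <- paste0("A", ref, "A")
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample_id = sample_id, ref_fwd = ref_fwd, ref_rev = ref_rev,
             alt_fwd = alt_fwd, alt_rev = alt_rev,
             mean_alt_bq = mean_alt_bq, cosmic_id = cosmic_id,
             dbsnp_id = dbsnp_id, exonic_function = exonic_function,
             af_1000g = af_1000g, af_gnomad = af_gnomad,
             af_hapmap = af_hapmap, gene = gene,
             driver_class = driver_class, biomarker = biomarker,
             context = context, stringsAsFactors = FALSE)
}

# A clean simulation config with no artifacts or kataegis, for clonal and
# filtering benchmarks that need pure tree-derived reads.
clean_sim_config <- function(seed, ...) {
  sim_config(seed = seed,
             artifact_rates = list(germline_leak = 0, cp_shared = 0,
                                   strand_bias = 0, blacklist = 0,
                                   multiallelic = 0, dbsnp_only = 0,
                                   low_bq = 0, synonymous = 0),
             kataegis = list(n_clusters = 0), ...)
}

# Map inferred clusters onto truth clones by majority vote and express the
# truth tree in cluster indices. Returns NULL when the mapping is not a
# bijection (cluster count wrong or clones merged).
truth_tree_in_cluster_space <- function(clusters, tree) {
  k_true <- nrow(tree$clones)
  if (clusters$k != k_true) return(NULL)
  truth_clone <- tree$mutations$clone_id[
    match(names(clusters$assignment), variant_key(tree$mutations))]
  mapping <- vapply(seq_len(k_true), function(g) {
    tc <- truth_clone[clusters$assignment == g]
    as.integer(names(sort(table(tc), decreasing = TRUE))[1])
  }, integer(1))
  if (length(unique(mapping)) != k_true) return(NULL)
  clone2cluster <- match(seq_len(k_true), mapping)
  true_parent <- ifelse(is.na(tree$clones$parent_id), 0L,
                        tree$clones$parent_id)
  parent_clusters <- vapply(seq_len(k_true), function(c) {
    p <- true_parent[mapping[c]]
    if (p == 0) 0L else clone2cluster[p]
  }, integer(1))
  list(parent = parent_clusters, mapping = mapping)
}
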