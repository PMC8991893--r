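#' Absence-aware binomial-mixture clustering of serial VAFs
#'
#' Variants are clustered across the joint timepoint space by a binomial
#' mixture model fitted with EM: cluster k has a per-timepoint mean VAF
#' `phi[k, j]` and a variant contributes `Binomial(depth[i, j], phi[k, j])`
#' likelihood at its observed alt count at every timepoint — zero alt reads
#' is evidence of absence, not missing data. The number of clusters is
#' selected by BIC over `k_range`; each k is fitted from 20 seeded
#' k-means++ initializations and the best likelihood kept, so the result is
#' deterministic given `seed`. Variants never detected at any timepoint are
#' excluded and reported.
#'
#' @param alt,depth integer matrices (variants x timepoints) of alt read
#'   counts and total depths, identical dimnames.
#' @param k_range candidate cluster counts (default from config).
#' @param seed integer seed.
#' @param config configuration list.
#' @return list of class `clone_clusters`: `assignment` (named integer
#'   vector), `phi` (k x J), `sizes`, `k`, `loglik`, `bic` (vector over
#'   `k_range`), `excluded` (keys of never-detected variants).
#' @export
cluster_vafs <- function(alt, depth, k_range = NULL, seed = 1L,
                         config = default_config()) {
  cl <- config$clonal
  if (is.null(k_range)) k_range <- cl$k_range
  stopifnot(all(dim(alt) == dim(depth)))
  detected <- rowSums(alt) > 0
  excluded <- rownames(alt)[!detected]
  alt <- alt[detected, , drop = FALSE]
  depth <- depth[detected, , drop = FALSE]
  n <- nrow(alt)
  J <- ncol(alt)
  if (n == 0) stop("no detected variants to cluster", call. = FALSE)
  set.seed(seed)
  k_range <- k_range[k_range <= n]
  fits <- list()
  for (k in k_range) {
    best <- NULL
    for (r in seq_len(cl$em_restarts)) {
      fit <- try(em_binmix(alt, depth, k, cl), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best$bic <- -2 * best$loglik + (k * J + (k - 1)) * log(n)
    fits[[as.character(k)]] <- best
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  pick <- fits[[which.min(bics)]]
  assignment <- stats::setNames(pick$z, rownames(alt))
  # standard error of the prevalence estimate U = 2*phi per cluster and
  # timepoint, from the pooled binomial depth of the member variants
  se <- pick$phi
  for (g in seq_len(pick$k)) {
    dsum <- colSums(depth[pick$z == g, , drop = FALSE])
    se[g, ] <- 2 * sqrt(pick$phi[g, ] * (1 - pick$phi[g, ]) /
                          pmax(dsum, 1))
  }
  structure(list(assignment = assignment,
                 phi = pick$phi,
                 se = se,
                 sizes = as.integer(table(factor(pick$z,
                                                 levels = seq_len(pick$k)))),
                 k = pick$k, loglik = pick$loglik,
                 bic = stats::setNames(bics, names(fits)),
                 excluded = excluded),
            class = "clone_clusters")
}

# One EM run for a k-component binomial mixture with k-means++ init.
# The per-iteration log-likelihood is asserted non-decreasing. The
# binomial coefficients are constant across clusters and cluster counts,
# so they are added to the log-likelihood once at the end.
em_binmix <- function(alt, depth, k, cl) {
  n <- nrow(alt)
  J <- ncol(alt)
  vaf <- ifelse(depth > 0, alt / depth, 0)
  lconst <- sum(lchoose(depth, alt))
  # k-means++ seeding on the VAF matrix
  centers <- matrix(0, nrow = k, ncol = J)
  centers[1, ] <- vaf[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((vaf - matrix(centers[1, ], n, J, byrow = TRUE))^2)
    for (i in 2:k) {
      pick <- if (sum(d2) <= 0) sample.int(n, 1)
              else sample.int(n, 1, prob = d2)
      centers[i, ] <- vaf[pick, ]
      d2 <- pmin(d2, rowSums((vaf - matrix(centers[i, ], n, J,
                                           byrow = TRUE))^2))
    }
  }
  phi <- pmin(pmax(centers, 1e-4), 1 - 1e-4)
  pi_k <- rep(1 / k, k)
  loglik <- -Inf
  lp <- NULL
  for (iter in seq_len(cl$em_max_iter)) {
    lp <- alt %*% t(log(phi)) + (depth - alt) %*% t(log1p(-phi))
    lp <- sweep(lp, 2, log(pi_k), "+")
    m <- lp[cbind(seq_len(n), max.col(lp))]
    ll <- sum(m + log(rowSums(exp(lp - m))))
    if (ll < loglik - 1e-6) {
      stop("EM log-likelihood decreased")  # invariant guard
    }
    converged <- is.finite(loglik) && (ll - loglik) < cl$em_tol
    loglik <- ll
    r <- exp(lp - m)
    r <- r / rowSums(r)
    if (converged) break
    pi_k <- pmax(colMeans(r), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    phi <- (t(r) %*% alt) / pmax(t(r) %*% depth, 1e-12)
    phi <- pmin(pmax(phi, 1e-9), 1 - 1e-9)
  }
  z <- max.col(lp)
  # relabel clusters by decreasing mean phi for stable reporting
  ord <- order(-rowMeans(phi))
  relabel <- match(seq_len(k), ord)
  list(phi = phi[ord, , drop = FALSE], z = relabel[z], k = k,
       loglik = loglik + lconst)
}

# All labelled trees on m nodes via Prufer sequences, decoded to parent
# vectors rooted at node `root`. Returns a list of integer parent vectors
# (parent[i] for node i; 0 for the root).
enumerate_rooted_trees <- function(m, root = 1L) {
  if (m == 1) return(list(c(0L)))
  decode <- function(seq) {
    degree <- rep(1L, m)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, nrow = m - 1, ncol = 2)
    used <- rep(FALSE, m)
    for (i in seq_along(seq)) {
      leaf <- which(degree == 1L & !used)[1]
      edges[i, ] <- c(leaf, seq[i])
      used[leaf] <- TRUE
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    rest <- which(!used & degree == 1L)
    edges[m - 1, ] <- rest
    # orient from root
    adj <- vector("list", m)
    for (i in seq_len(m - 1)) {
      adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
      adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
    }
    parent <- rep(0L, m)
    queue <- root
    seen <- rep(FALSE, m)
    seen[root] <- TRUE
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in adj[[u]]) if (!seen[v]) {
        seen[v] <- TRUE
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
    parent
  }
  if (m == 2) return(list(decode(integer(0))))
  seqs <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(m)), m - 2)))
  lapply(seq_len(nrow(seqs)), function(i) decode(seqs[i, ]))
}

sum_condition_violation <- function(parent, U, root_U = NULL, se = NULL) {
  # parent: length k, entries 0 (root) or cluster id. The root prevalence
  # defaults to the per-timepoint maximum cluster prevalence: ctDNA-scale
  # prevalences are bounded by the founding clone, not by 1 (purity
  # normalization), otherwise the root constraint never binds. When
  # standard errors are supplied, each constraint tolerates an excess of
  # 2 combined SEs before counting as violated.
  J <- ncol(U)
  if (is.null(root_U)) root_U <- apply(U, 2, max)
  viol <- 0
  for (p in unique(parent)) {
    kids <- which(parent == p)
    child_sum <- colSums(U[kids, , drop = FALSE])
    pu <- if (p == 0) root_U else U[p, ]
    tol <- 0
    if (!is.null(se)) {
      se_p <- if (p == 0) 0 else se[p, ]^2
      tol <- 2 * sqrt(se_p + colSums(se[kids, , drop = FALSE]^2))
    }
    viol <- viol + sum(pmax(0, child_sum - pu - tol))
  }
  viol
}

#' Infer the longitudinal clone tree by exhaustive constrained search
#'
#' Cluster cellular prevalences are `U = min(2 * phi, 1)` (heterozygous,
#' copy-neutral loci). All rooted trees over the clusters plus a germline
#' root (prevalence 1 at every timepoint) are enumerated via Prufer
#' sequences and scored by their total sum-condition violation
#' `sum over clones and timepoints of max(0, sum(children U) - parent U)`;
#' when the clustering supplies standard errors, each constraint tolerates
#' an excess of 2 combined SEs so that sampling noise does not flip
#' feasibility. The root (germline) prevalence is the per-timepoint maximum
#' cluster prevalence: on the ctDNA scale prevalences are bounded by the
#' founding clone, not by 1 (purity normalization), otherwise the root
#' constraint never binds. Among minimal-violation trees, ties are broken
#' by the attachment-density score `sum over clones and timepoints of
#' -log(parent prevalence)` — under a uniform-share generative model a
#' clone is more likely a child of the smallest clone that can contain it —
#' then by lexicographic parent vector. Per-timepoint clonal proportions
#' are the child-subtracted prevalences floored at zero. Exhaustive search
#' is exact, so whenever a zero-violation tree exists one is returned.
#'
#' @param clusters a `clone_clusters` object (or bare phi matrix).
#' @param config configuration list (`clonal$max_exhaustive_clones`).
#' @return list of class `clone_tree`: `parent` (0 = germline root),
#'   `U` (k x J prevalences), `proportions` (k x J), `violation`,
#'   `tied` (number of violation-tied trees).
#' @export
infer_longitudinal_tree <- function(clusters, config = default_config()) {
  is_cl <- inherits(clusters, "clone_clusters")
  phi <- if (is_cl) clusters$phi else clusters
  se <- if (is_cl) clusters$se else NULL
  k <- nrow(phi)
  if (k > config$clonal$max_exhaustive_clones) {
    stop("more than max_exhaustive_clones clusters (", k,
         "); raise config$clonal$max_exhaustive_clones for exhaustive ",
         "search at your own cost", call. = FALSE)
  }
  U <- pmin(pmax(2 * phi, 0), 1)
  rownames(U) <- paste0("clone", seq_len(k))
  trees <- enumerate_rooted_trees(k + 1L, root = 1L)
  # node 1 is the germline root; nodes 2..k+1 are clusters 1..k
  parents <- lapply(trees, function(p) {
    out <- p[-1]
    ifelse(out == 1L, 0L, out - 1L)
  })
  root_U <- apply(U, 2, max)
  viols <- vapply(parents, sum_condition_violation, numeric(1), U = U,
                  root_U = root_U, se = se)
  vmin <- min(viols)
  cand <- which(viols <= vmin + 1e-12)
  if (length(cand) > 1) {
    score <- vapply(cand, function(i) {
      p <- parents[[i]]
      s <- 0
      for (c in seq_len(k)) {
        pu <- if (p[c] == 0) root_U else U[p[c], ]
        s <- s - sum(log(pmax(pu, 1e-6)))
      }
      s
    }, numeric(1))
    cand <- cand[score >= max(score) - 1e-12]
    if (length(cand) > 1) {
      lex <- vapply(cand, function(i)
        paste(sprintf("%02d", parents[[i]]), collapse = ""), character(1))
      cand <- cand[order(lex)]
    }
  }
  parent <- parents[[cand[1]]]
  prop <- U
  for (i in seq_len(k)) {
    kids <- which(parent == i)
    if (length(kids)) {
      prop[i, ] <- pmax(0, U[i, ] - colSums(U[kids, , drop = FALSE]))
    }
  }
  structure(list(parent = parent, U = U, proportions = prop,
                 violation = vmin,
                 tied = sum(viols <= vmin + 1e-12)),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  k <- length(x$parent)
  cat(sprintf("Clone tree (%d clones, violation %.4g)\n", k, x$violation))
  for (i in seq_len(k)) {
    cat(sprintf("  clone%d <- %s   U: %s\n", i,
                if (x$parent[i] == 0) "root" else paste0("clone", x$parent[i]),
                paste(sprintf("%.2f", x$U[i, ]), collapse = " ")))
  }
  invisible(x)
}

#' Newick serialization of a clone tree
#'
#' @param tree a `clone_tree`.
#' @return single-element character, e.g. `"((clone2,clone3)clone1)root;"`.
#' @export
tree_newick <- function(tree) {
  build <- function(node) {
    kids <- which(tree$parent == node)
    label <- if (node == 0) "root" else paste0("clone", node)
    if (length(kids) == 0) return(label)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", label)
  }
  paste0(build(0L), ";")
}

#' Identify the stem clone
#'
#' The mutation cluster with the highest mean cellular prevalence across
#' timepoints; ties go to the earliest cluster id and are flagged.
#'
#' @param tree a `clone_tree` (or bare U matrix).
#' @return list: `clone` (integer id), `mean_prevalence`, `tie`.
#' @export
identify_stem_clone <- function(tree) {
  U <- if (inherits(tree, "clone_tree")) tree$U else tree
  m <- rowMeans(U)
  top <- which(m >= max(m) - 1e-12)
  list(clone = top[1], mean_prevalence = m[top[1]], tie = length(top) > 1)
}

#' Label per-clone longitudinal dynamics
#'
#' A clone is `emergent` when its prevalence is below the detection floor
#' at baseline and above it at a later timepoint; `declining` when its
#' prevalence drops by at least the configured relative fraction (default
#' 50%) between consecutive timepoints — restricted, when `treatment_days`
#' is supplied, to timepoint pairs spanning a treatment date; `stable`
#' otherwise.
#'
#' @param tree a `clone_tree`.
#' @param timepoint_days numeric vector of sampling days (one per
#'   timepoint); required for treatment-aware calls.
#' @param treatment_days numeric vector of treatment dates; NULL yields
#'   interval-agnostic labels.
#' @param config configuration list.
#' @return character vector of labels, one per clone.
#' @export
call_dynamics <- function(tree, timepoint_days = NULL,
                          treatment_days = NULL,
                          config = default_config()) {
  cl <- config$clonal
  U <- tree$U
  J <- ncol(U)
  spanning <- rep(TRUE, J - 1)
  if (!is.null(treatment_days) && !is.null(timepoint_days)) {
    spanning <- vapply(seq_len(J - 1), function(j)
      any(treatment_days > timepoint_days[j] &
            treatment_days <= timepoint_days[j + 1]), logical(1))
  }
  vapply(seq_len(nrow(U)), function(i) {
    u <- U[i, ]
    if (u[1] <= cl$detection_eps && any(u[-1] > cl$detection_eps)) {
      return("emergent")
    }
    drops <- which(u[-J] > 0 &
                     (u[-1] - u[-J]) / pmax(u[-J], 1e-12) <=
                     -cl$decline_fraction)
    if (any(spanning[drops])) return("declining")
    "stable"
  }, character(1))
}

#' Build alt/depth matrices from filtered candidates
#'
#' Pivots a candidate variant table (rows per variant per plasma sample)
#' into variants x timepoints alt and depth matrices, ordered by manifest
#' day. Loci inside non-neutral copy-number segments are excluded when
#' segments are supplied, keeping the heterozygous copy-neutral prevalence
#' transform valid.
#'
#' The candidate set defines which loci are clustered; per-timepoint counts
#' are taken from the full plasma pileup tables when supplied
#' (`plasma_tables`), so that a locus filtered out of one timepoint by the
#' calling threshold still contributes its covered zero-alt evidence there.
#' Timepoints with no pileup row at a locus get depth 0 (uninformative).
#'
#' @param candidates filtered variant data.frame.
#' @param manifest manifest data.frame (plasma rows define the timepoints).
#' @param plasma_tables optional named list of full per-sample plasma
#'   tables keyed by sample_id.
#' @param cn_segments optional segment data.frame from a `cn_fit`.
#' @return list: `alt`, `depth` matrices; `excluded_cn` keys.
#' @export
vaf_matrix <- function(candidates, manifest, plasma_tables = NULL,
                       cn_segments = NULL) {
  plasma <- manifest[manifest$sample_class == "plasma", , drop = FALSE]
  plasma <- plasma[order(plasma$day), , drop = FALSE]
  keys <- unique(variant_key(candidates))
  excluded <- character(0)
  if (!is.null(cn_segments)) {
    ab <- cn_segments[cn_segments$state != 2L, , drop = FALSE]
    if (nrow(ab) > 0) {
      first <- candidates[match(keys, variant_key(candidates)), ]
      bad <- vapply(seq_along(keys), function(i)
        any(ab$chrom == first$chrom[i] & ab$start <= first$pos[i] &
              ab$end >= first$pos[i]), logical(1))
      excluded <- keys[bad]
      keys <- keys[!bad]
    }
  }
  J <- nrow(plasma)
  alt <- matrix(0L, nrow = length(keys), ncol = J,
                dimnames = list(keys, plasma$timepoint_label))
  depth <- matrix(0L, nrow = length(keys), ncol = J,
                  dimnames = list(keys, plasma$timepoint_label))
  for (j in seq_len(J)) {
    sid <- plasma$sample_id[j]
    rows <- if (!is.null(plasma_tables) && !is.null(plasma_tables[[sid]])) {
      plasma_tables[[sid]]
    } else {
      candidates[candidates$sample_id == sid, , drop = FALSE]
    }
    idx <- match(variant_key(rows), keys)
    ok <- !is.na(idx)
    alt[idx[ok], j] <- rows$alt_fwd[ok] + rows$alt_rev[ok]
    depth[idx[ok], j] <- variant_depth(rows)[ok]
  }
  list(alt = alt, depth = depth, excluded_cn = excluded)
}
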