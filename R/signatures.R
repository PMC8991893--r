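#' Build a 96-channel trinucleotide mutation spectrum
#'
#' Each SNV is assigned to one of the 96 substitution-in-context channels
#' using its `context` column (the reference trinucleotide centred on the
#' variant, written on the same strand as `ref`). Purine-reference sites are
#' reverse-complemented, flanks included, so all channels are
#' pyrimidine-normalized. Records with ambiguous context bases or
#' indel-flagged alleles are skipped and counted.
#'
#' @param variants variant data.frame with `ref`, `alt` and `context`
#'   columns; duplicate loci (serial timepoints) are collapsed.
#' @return named integer 96-vector; attribute `n_skipped` counts records
#'   without a usable context.
#' @export
trinucleotide_spectrum <- function(variants) {
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  if (nrow(variants) == 0) return(structure(counts, n_skipped = 0L))
  v <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  if (!is.null(v$flags)) {
    v <- v[!has_flag(v$flags, "unsupported"), , drop = FALSE]
  }
  ctx <- if (is.null(v$context)) rep(NA_character_, nrow(v)) else v$context
  usable <- !is.na(ctx) & nchar(ctx) == 3 &
    !grepl("[^ACGT]", ctx) &
    substr(ctx, 2, 2) == v$ref &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!usable)
  v <- v[usable, , drop = FALSE]
  ctx <- ctx[usable]
  if (nrow(v) > 0) {
    purine <- v$ref %in% c("A", "G")
    ctx[purine] <- revcomp(ctx[purine])
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    alt <- ifelse(purine, comp[v$alt], v$alt)
    label <- paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">", alt,
                    "]", substr(ctx, 3, 3))
    tab <- table(label)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(counts, n_skipped = n_skipped)
}

# Non-negative least squares of s ~ M w subject to sum(w) <= 1.
# Unconstrained NNLS first; if the simplex bound is exceeded, re-solve with
# a heavily weighted sum-to-one penalty row (the optimum then lies on the
# boundary).
nnls_simplex <- function(M, s) {
  s <- as.numeric(s)
  fit <- pracma::lsqnonneg(M, s)
  w <- fit$x
  if (sum(w) > 1 + 1e-9) {
    lambda <- 1e4
    fit <- pracma::lsqnonneg(rbind(M, lambda), c(s, lambda))
    w <- fit$x
  }
  w
}

#' Refit signature exposures to a mutation spectrum
#'
#' Iterative forward selection in the style of deconstructSigs: starting
#' from the empty set, at each step the signature whose inclusion (weights
#' re-solved by non-negative least squares with total weight <= 1) most
#' reduces the sum of squared errors is added; selection stops when the
#' relative SSE improvement falls below `sse_rel_tol`. Weights below the
#' discard threshold are zeroed and the remaining support re-solved.
#'
#' @param spectrum numeric 96-vector of channel counts or proportions.
#' @param signature_matrix 96 x S column-stochastic matrix.
#' @param config configuration list (`signatures$discard_threshold`,
#'   `signatures$sse_rel_tol`).
#' @return list of class `exposure_fit`: `weights` (named, length S),
#'   `sse`, `n_mutations`, `fitted` (96-vector).
#' @export
fit_exposures <- function(spectrum, signature_matrix,
                          config = default_config()) {
  sc <- config$signatures
  n_mut <- sum(spectrum)
  if (n_mut <= 0) stop("empty spectrum", call. = FALSE)
  s <- spectrum / n_mut
  M <- signature_matrix
  S <- ncol(M)
  active <- integer(0)
  sse <- sum(s^2)  # SSE of the empty model (fit = 0)
  w_active <- numeric(0)
  repeat {
    cand <- setdiff(seq_len(S), active)
    if (length(cand) == 0) break
    best <- NULL
    for (k in cand) {
      idx <- c(active, k)
      w <- nnls_simplex(M[, idx, drop = FALSE], s)
      r <- s - M[, idx, drop = FALSE] %*% w
      sse_k <- sum(r^2)
      if (is.null(best) || sse_k < best$sse) {
        best <- list(idx = idx, w = w, sse = sse_k)
      }
    }
    if ((sse - best$sse) / sse < sc$sse_rel_tol) break
    active <- best$idx
    w_active <- best$w
    sse <- best$sse
    if (sse < 1e-12) break
  }
  weights <- stats::setNames(numeric(S), colnames(M))
  weights[active] <- w_active
  # discard trace weights and re-solve on the remaining support
  keep <- which(weights >= sc$discard_threshold)
  if (length(keep) < length(active)) {
    weights[] <- 0
    if (length(keep) > 0) {
      weights[keep] <- nnls_simplex(M[, keep, drop = FALSE], s)
      weights[weights < sc$discard_threshold] <- 0
    }
  }
  fitted <- as.vector(M %*% weights)
  structure(list(weights = weights, sse = sum((s - fitted)^2),
                 n_mutations = n_mut, fitted = fitted),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("Signature refit on %d mutations (SSE %.3g)\n",
              x$n_mutations, x$sse))
  w <- x$weights[x$weights > 0]
  for (nm in names(w)) cat(sprintf("  %-16s %.3f\n", nm, w[nm]))
  invisible(x)
}

#' Label genomic-instability mechanisms from fitted exposures
#'
#' Maps post-discard signature weights to instability labels: DSBR
#' (double-strand break repair, COSMIC signature 3), MMR (defective
#' mismatch repair, signatures 6/15/20/21/26) and POLN (polymerase
#' nu-associated hypermutation, signature 9). A label is assigned iff any
#' mapped signature has weight > 0; signatures named in the map but absent
#' from the fitted catalogue yield a warning and an undetermined label.
#'
#' @param fit an `exposure_fit` (or bare named weight vector).
#' @param config configuration list (`signatures$instability_map`).
#' @return named logical vector (NA where undetermined).
#' @export
classify_instability <- function(fit, config = default_config()) {
  weights <- if (inherits(fit, "exposure_fit")) fit$weights else fit
  map <- config$signatures$instability_map
  out <- stats::setNames(rep(NA, length(map)), names(map))
  for (lab in names(map)) {
    sigs <- map[[lab]]
    present <- sigs %in% names(weights)
    if (!any(present)) {
      warning("no signature for label ", lab, " in fitted catalogue",
              call. = FALSE)
      next
    }
    if (!all(present)) {
      warning("signature(s) missing for label ", lab, ": ",
              paste(sigs[!present], collapse = ", "), call. = FALSE)
    }
    out[lab] <- any(weights[sigs[present]] > 0)
  }
  out
}
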