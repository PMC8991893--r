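#' Inter-mutational distances
#'
#' Distances between consecutive sorted SNV positions, computed strictly
#' within chromosomes (a rainfall-plot construction). Duplicate positions on
#' one chromosome are an error: multi-allelic sites should have been removed
#' upstream.
#'
#' @param positions integer vector of 1-based positions (one chromosome), or
#'   a variant data.frame (`chrom`/`pos`), in which case a named list of
#'   per-chromosome IMD vectors is returned.
#' @return numeric vector of IMDs (or list thereof).
#' @export
intermutation_distances <- function(positions) {
  if (is.data.frame(positions)) {
    return(lapply(split(positions$pos, positions$chrom),
                  intermutation_distances))
  }
  pos <- sort(positions)
  if (anyDuplicated(pos)) {
    stop("duplicate position in inter-mutational distance input",
         call. = FALSE)
  }
  if (length(pos) < 2) return(numeric(0))
  diff(pos)
}

#' Detect kataegis events
#'
#' Greedy left-to-right grouping per chromosome: consecutive SNVs join the
#' open cluster while the gap to the previous SNV satisfies
#' log10(IMD) <= 4 (IMD <= 10,000 bp); a closed cluster is emitted as a
#' kataegis event iff it holds at least 6 mutations with mean
#' inter-mutational distance <= 1000 bp. Indel-flagged records are ignored.
#'
#' @param variants variant data.frame (typically the combined all-timepoint
#'   filtered plasma set of one patient; duplicate loci across timepoints
#'   are collapsed).
#' @param config configuration list.
#' @return data.frame of events: chrom, start, end, n_mutations, mean_imd,
#'   dominant_class, plus a `members` list-column of variant keys.
#' @export
detect_kataegis <- function(variants, config = default_config()) {
  kc <- config$kataegis
  if (!is.null(variants$flags)) {
    variants <- variants[!has_flag(variants$flags, "unsupported"), ,
                         drop = FALSE]
  }
  v <- variants[!duplicated(paste0(variants$chrom, ":", variants$pos)), ,
                drop = FALSE]
  events <- list()
  max_gap <- 10^kc$max_group_log10_imd
  for (ch in unique(v$chrom)) {
    cv <- v[v$chrom == ch, , drop = FALSE]
    cv <- cv[order(cv$pos), , drop = FALSE]
    if (nrow(cv) == 0) next
    gap <- c(Inf, diff(cv$pos))
    cluster_id <- cumsum(gap > max_gap)
    for (cl in split(seq_len(nrow(cv)), cluster_id)) {
      n <- length(cl)
      if (n < kc$min_mutations) next
      imd <- diff(cv$pos[cl])
      if (mean(imd) > kc$max_mean_imd) next
      spec <- substitution_spectrum(cv[cl, , drop = FALSE])
      events[[length(events) + 1]] <- data.frame(
        chrom = ch, start = min(cv$pos[cl]), end = max(cv$pos[cl]),
        n_mutations = n, mean_imd = mean(imd),
        dominant_class = spec$dominant,
        stringsAsFactors = FALSE)
      events[[length(events)]]$members <-
        list(variant_key(cv[cl, , drop = FALSE]))
    }
  }
  if (length(events) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_mutations = integer(0),
                      mean_imd = numeric(0), dominant_class = character(0),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  do.call(rbind, events)
}

#' Sliding-window hypermutation score
#'
#' `H = (count / window_bp) / background_rate`, with an upper-tail binomial
#' p-value for observing at least `count` mutations in `window_bp` bases at
#' the background per-base mutation rate. A window is flagged iff H >= 5 and
#' p < 0.05.
#'
#' @param count mutations observed in the window.
#' @param window_bp window width in bp.
#' @param background_rate genome-wide mutations per bp
#'   (total SNVs / covered bp).
#' @param config configuration list.
#' @return list: `score`, `p`, `flagged`.
#' @export
hypermutation_score <- function(count, window_bp, background_rate,
                                config = default_config()) {
  kc <- config$kataegis
  if (window_bp <= 0) stop("window_bp must be > 0", call. = FALSE)
  if (background_rate <= 0) {
    stop("background_rate must be > 0 for a defined hypermutation score",
         call. = FALSE)
  }
  H <- (count / window_bp) / background_rate
  p <- stats::pbinom(count - 1, size = round(window_bp),
                     prob = background_rate, lower.tail = FALSE)
  list(score = H, p = p,
       flagged = H >= kc$min_hypermutation_score & p < kc$hypermutation_p)
}

#' Pyrimidine-normalized substitution spectrum
#'
#' Maps each SNV to one of the six classes C>A, C>G, C>T, T>A, T>C, T>G
#' (purine-reference sites are complemented) and reports the class counts
#' and the dominant class (ties reported as a ";"-joined tie).
#'
#' @param variants variant data.frame with single-base `ref`/`alt`.
#' @return list: `counts` (named integer vector of 6), `dominant` (character
#'   or NA for an empty set), `tie` (logical).
#' @export
substitution_spectrum <- function(variants) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  counts <- stats::setNames(integer(6), classes)
  if (nrow(variants) > 0) {
    cls <- substitution_class(variants$ref, variants$alt)
    tab <- table(cls)
    counts[names(tab)] <- as.integer(tab)
  }
  if (sum(counts) == 0) {
    return(list(counts = counts, dominant = NA_character_, tie = FALSE))
  }
  top <- names(counts)[counts == max(counts)]
  list(counts = counts,
       dominant = paste(top, collapse = ";"),
       tie = length(top) > 1)
}

#' @rdname substitution_spectrum
#' @param ref,alt single-base allele vectors.
#' @return `substitution_class`: character vector of pyrimidine-normalized
#'   classes.
#' @export
substitution_class <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (any(!ok)) {
    stop("non-ACGT or degenerate allele in substitution input",
         call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  paste0(r, ">", a)
}

#' Rainfall table for plotting
#'
#' Per-chromosome sorted positions with the distance to the previous
#' mutation and the substitution class: the coordinates of a rainfall plot.
#'
#' @param variants variant data.frame.
#' @return data.frame chrom, pos, imd (NA for the first mutation of each
#'   chromosome), class.
#' @export
rainfall_table <- function(variants) {
  v <- variants[!duplicated(paste0(variants$chrom, ":", variants$pos)), ,
                drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  out <- do.call(rbind, lapply(split(v, v$chrom), function(cv) {
    data.frame(chrom = cv$chrom, pos = cv$pos,
               imd = c(NA, diff(cv$pos)),
               class = substitution_class(cv$ref, cv$alt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
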