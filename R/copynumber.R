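#' Copy-number state labels
#'
#' Integer states 0..5 mapped to HOMD (homozygous deletion), HETD
#' (heterozygous deletion), NEUT, GAIN, AMP, HLAMP (high-level
#' amplification).
#' @param state integer vector in 0..5.
#' @return character vector.
#' @export
cn_state_label <- function(state) {
  c("HOMD", "HETD", "NEUT", "GAIN", "AMP", "HLAMP")[state + 1L]
}

#' Expected log2 ratio for a copy state at tumour fraction t
#'
#' `log2((t*c + 2*(1-t)) / 2)` under a diploid normal background, floored at
#' -8 to guard the homozygous-deletion/pure-tumour singularity. Identically
#' 0 at c = 2 and strictly increasing in c for t > 0.
#'
#' @param state integer copy number c >= 0.
#' @param t tumour fraction in `[0,1]`.
#' @param floor lower bound on the returned log ratio.
#' @return numeric log2 ratio.
#' @export
expected_logr <- function(state, t, floor = -8) {
  x <- (t * state + 2 * (1 - t)) / 2
  out <- ifelse(x <= 0, -Inf, log2(x))
  pmax(out, floor)
}

#' GC/mappability normalization of binned read counts
#'
#' Counts from the sample and the matched normal are each divided by a
#' LOESS fit of count on GC fraction (the dominant coverage bias); when
#' mappability varies, a second LOESS of the ratio on mappability is
#' applied. The normalized signal is `r_b = log2(corrected_sample /
#' corrected_normal)`. Bins with mappability below the threshold or zero
#' normal count are masked and excluded downstream.
#'
#' @param sample,normal data.frames with columns chrom, start, count, gc,
#'   mappability, on an identical bin grid.
#' @param config configuration list.
#' @return data.frame chrom, start, raw_count, gc, mappability, logr,
#'   masked.
#' @export
normalize_bins <- function(sample, normal, config = default_config()) {
  cc <- config$copynumber
  if (nrow(sample) != nrow(normal) ||
      any(sample$chrom != normal$chrom) ||
      any(sample$start != normal$start)) {
    stop("sample and normal bin grids do not match", call. = FALSE)
  }
  masked <- sample$mappability < cc$min_mappability | normal$count <= 0
  correct <- function(count, gc, use) {
    fit <- stats::loess(count ~ gc, span = 0.5,
                        subset = use, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    pred <- stats::predict(fit, newdata = data.frame(gc = gc))
    pred[!is.finite(pred) | pred <= 0] <- stats::median(count[use])
    count / pred
  }
  use <- !masked
  s_corr <- correct(sample$count, sample$gc, use)
  n_corr <- correct(normal$count, normal$gc, use)
  ratio <- s_corr / pmax(n_corr, 1e-12)
  if (stats::sd(sample$mappability[use]) > 1e-6) {
    mfit <- stats::loess(ratio ~ m, span = 0.75,
                         data = data.frame(ratio = ratio[use],
                                           m = sample$mappability[use]))
    mpred <- stats::predict(mfit,
                            newdata = data.frame(m = sample$mappability))
    mpred[!is.finite(mpred) | mpred <= 0] <- 1
    ratio <- ratio / mpred
  }
  logr <- ifelse(ratio > 0, log2(ratio), NA_real_)
  logr[masked] <- NA_real_
  masked <- masked | !is.finite(logr)
  # centre on the genome-wide median: the majority of bins is assumed
  # copy-neutral, so the neutral state sits at log ratio 0
  logr <- logr - stats::median(logr[!masked])
  data.frame(chrom = sample$chrom, start = sample$start,
             raw_count = sample$count, gc = sample$gc,
             mappability = sample$mappability,
             logr = logr, masked = masked, stringsAsFactors = FALSE)
}

# Viterbi decoding of the 6-state copy-number HMM for one chromosome.
# Gaussian emissions N(expected_logr(c, t), sigma), self-transition p_self,
# off-diagonal transitions proportional to the state prior, initial
# distribution = state prior.
# Returns list(path = integer states, loglik = max path log-probability).
viterbi_chrom <- function(r, t, sigma, config) {
  cc <- config$copynumber
  states <- 0:cc$max_state
  K <- length(states)
  prior <- cc$state_prior / sum(cc$state_prior)
  mu <- expected_logr(states, t, cc$logr_floor)
  n <- length(r)
  emis <- sapply(mu, function(m) stats::dnorm(r, m, sigma, log = TRUE))
  if (n == 1) emis <- matrix(emis, nrow = 1)
  log_self <- log(cc$self_transition)
  # leaving a state distributes the remaining mass over the others by prior
  log_off <- sapply(seq_len(K), function(from) {
    w <- prior
    w[from] <- 0
    log((1 - cc$self_transition) * w / sum(w))
  })  # K x K: log_off[to, from]
  delta <- emis[1, ] + log(prior)
  psi <- matrix(0L, nrow = n, ncol = K)
  if (n > 1) {
    for (i in 2:n) {
      trans <- t(log_off)             # trans[from, to]
      trans <- trans + delta
      diag(trans) <- delta + log_self
      best_prev <- max.col(t(trans))
      delta <- trans[cbind(best_prev, seq_len(K))] + emis[i, ]
      psi[i, ] <- best_prev
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (i in (n - 1):1) path[i] <- psi[i + 1, path[i + 1]]
  list(path = states[path], loglik = max(delta))
}

cn_path_loglik <- function(profile, t, sigma, config) {
  tot <- 0
  paths <- list()
  for (ch in unique(profile$chrom)) {
    r <- profile$logr[profile$chrom == ch & !profile$masked]
    if (length(r) == 0) next
    vt <- viterbi_chrom(r, t, sigma, config)
    tot <- tot + vt$loglik
    paths[[ch]] <- vt$path
  }
  list(loglik = tot, paths = paths)
}

#' Segment a normalized profile and estimate tumour fraction
#'
#' For each candidate tumour fraction on the initialization grid (derived
#' from the normal-contamination values 0.2, 0.35, 0.5, 0.65, 0.8, 0.9,
#' 0.99), a 6-state Gaussian-emission HMM over bins is decoded by Viterbi
#' (self-transition 0.99); the tumour fraction maximizing the total path
#' likelihood is refined by golden-section search around the best grid
#' point. Clonal-only model: one aberrant cell population, no subclonal
#' fraction parameter. The emission SD is the Gaussian-scaled median
#' absolute deviation of the log ratios. A flat likelihood across the grid
#' (no aberrant evidence) is flagged and reported at the grid minimum with
#' an all-neutral segmentation.
#'
#' @param profile output of [normalize_bins()].
#' @param t_grid candidate tumour fractions; default `1 - grid` of the
#'   configured contamination values.
#' @param fixed_t optional known tumour fraction (e.g. pathology
#'   cellularity for tissue): skips estimation.
#' @param config configuration list.
#' @return list of class `cn_fit`: `segments` (data.frame chrom, start,
#'   end, state, label, mean_logr, n_bins), `tumour_fraction`, `loglik`,
#'   `no_evidence`, `sigma`.
#' @export
segment_and_estimate <- function(profile, t_grid = NULL, fixed_t = NULL,
                                 config = default_config()) {
  cc <- config$copynumber
  usable <- !profile$masked
  if (sum(usable) < 10) stop("insufficient bins", call. = FALSE)
  if (is.null(t_grid)) t_grid <- sort(1 - cc$normal_contamination_grid)
  r <- profile$logr[usable]
  sigma <- max(stats::mad(r), 0.01)
  no_evidence <- FALSE
  if (!is.null(fixed_t)) {
    t_hat <- fixed_t
  } else {
    ll <- vapply(t_grid, function(t)
      cn_path_loglik(profile, t, sigma, config)$loglik, numeric(1))
    best <- which.max(ll)
    lo <- if (best == 1) max(t_grid[1] / 2, 1e-3) else t_grid[best - 1]
    hi <- if (best == length(t_grid)) min(1, t_grid[best] * 1.1)
          else t_grid[best + 1]
    opt <- stats::optimize(function(t)
      cn_path_loglik(profile, t, sigma, config)$loglik,
      interval = c(lo, hi), maximum = TRUE, tol = 1e-3)
    t_hat <- if (opt$objective >= ll[best]) opt$maximum else t_grid[best]
  }
  fit <- cn_path_loglik(profile, t_hat, sigma, config)
  if (is.null(fixed_t) && all(unlist(fit$paths) == 2L)) {
    # an all-neutral decode carries no information about tumour fraction
    no_evidence <- TRUE
    t_hat <- min(t_grid)
    fit <- cn_path_loglik(profile, t_hat, sigma, config)
  }
  segs <- list()
  for (ch in unique(profile$chrom)) {
    sel <- profile$chrom == ch & !profile$masked
    if (!any(sel)) next
    path <- if (no_evidence) rep(2L, sum(sel)) else fit$paths[[ch]]
    starts <- profile$start[sel]
    lr <- profile$logr[sel]
    runs <- rle(path)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    segs[[ch]] <- data.frame(
      chrom = ch, start = starts[idx_start],
      end = starts[idx_end] + as.integer(cc$bin_size) - 1L,
      state = runs$values, label = cn_state_label(runs$values),
      mean_logr = vapply(seq_along(runs$values), function(i)
        mean(lr[idx_start[i]:idx_end[i]]), numeric(1)),
      n_bins = runs$lengths, stringsAsFactors = FALSE)
  }
  structure(list(segments = do.call(rbind, c(unname(segs),
                                             make.row.names = FALSE)),
                 tumour_fraction = t_hat,
                 loglik = fit$loglik, no_evidence = no_evidence,
                 sigma = sigma),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("Copy-number fit: t = %.3f%s, sigma = %.3f\n",
              x$tumour_fraction,
              if (x$no_evidence) " (no aberrant evidence)" else "",
              x$sigma))
  ab <- x$segments[x$segments$state != 2L, , drop = FALSE]
  if (nrow(ab)) print(ab, row.names = FALSE) else cat("all segments NEUT\n")
  invisible(x)
}

#' Cross-sample copy-state concordance
#'
#' Per chromosome (and per named locus when a gene map is supplied), the
#' bin-weighted dominant state of each sample and a shared/discordant call:
#' `concordant_neutral`, `shared_gain` / `shared_loss` (with
#' `amplitude-discordant` noted when the states differ in degree),
#' `<sample>-specific`, or `discordant` for opposite directions.
#'
#' @param fits named list of `cn_fit` objects (>= 2 samples of one
#'   patient).
#' @param gene_map optional data.frame gene, chrom, pos.
#' @return data.frame with one row per chromosome (and per gene), one state
#'   column per sample, and a `call` column.
#' @export
compare_sample_states <- function(fits, gene_map = NULL) {
  if (length(fits) < 2) stop("need >= 2 segmented samples", call. = FALSE)
  state_at <- function(fit, ch, pos = NULL) {
    s <- fit$segments[fit$segments$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) return(NA_integer_)
    if (!is.null(pos)) {
      hit <- s$start <= pos & s$end >= pos
      if (!any(hit)) return(NA_integer_)
      return(s$state[which(hit)[1]])
    }
    # bin-weighted dominant state of the chromosome
    agg <- tapply(s$n_bins, s$state, sum)
    as.integer(names(agg)[which.max(agg)])
  }
  classify <- function(states) {
    st <- states[!is.na(states)]
    if (length(st) == 0) return(NA_character_)
    if (all(st == 2)) return("concordant_neutral")
    if (all(st > 2)) {
      return(if (length(unique(st)) == 1) "shared_gain"
             else "shared_gain, amplitude-discordant")
    }
    if (all(st < 2)) {
      return(if (length(unique(st)) == 1) "shared_loss"
             else "shared_loss, amplitude-discordant")
    }
    nonneut <- names(states)[!is.na(states) & states != 2]
    if (length(nonneut) == 1) return(paste0(nonneut, "-specific"))
    "discordant"
  }
  chroms <- unique(unlist(lapply(fits, function(f) f$segments$chrom)))
  rows <- lapply(chroms, function(ch) {
    st <- vapply(fits, state_at, integer(1), ch = ch)
    c(list(unit = ch), as.list(st), list(call = classify(st)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(gene_map)) {
    grows <- lapply(seq_len(nrow(gene_map)), function(i) {
      st <- vapply(fits, state_at, integer(1),
                   ch = gene_map$chrom[i], pos = gene_map$pos[i])
      c(list(unit = gene_map$gene[i]), as.list(st),
        list(call = classify(st)))
    })
    out <- rbind(out, do.call(rbind, lapply(grows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE))))
  }
  rownames(out) <- NULL
  out
}
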