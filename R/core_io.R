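#' ctlong: longitudinal ctDNA analysis from serial plasma sequencing
#'
#' Variant tables are plain data.frames with one row per candidate variant
#' per sample. Required columns: `chrom`, `pos` (1-based), `ref`, `alt`,
#' `sample_id`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`, `mean_alt_bq`.
#' Optional annotation columns (`cosmic_id`, `dbsnp_id`, `exonic_function`,
#' `af_1000g`, `af_gnomad`, `af_hapmap`, `gene`, `driver_class`,
#' `biomarker`, `context`) use `NA` for absent values ("." on disk).
#' Chromosome names are normalized to the "chr"-prefixed dialect on read and
#' all internal comparisons use 1-based closed coordinates; BED input is
#' converted at the boundary.
#'
#' @keywords internal
"_PACKAGE"

VARIANT_REQUIRED_COLS <- c("chrom", "pos", "ref", "alt", "sample_id",
                           "ref_fwd", "ref_rev", "alt_fwd", "alt_rev",
                           "mean_alt_bq")

VARIANT_ANNOTATION_COLS <- c("cosmic_id", "dbsnp_id", "exonic_function",
                             "af_1000g", "af_gnomad", "af_hapmap",
                             "gene", "driver_class", "biomarker", "context")

EXONIC_FUNCTIONS <- c("nonsynonymous", "stopgain", "stoploss",
                      "synonymous", "unknown", "other")

SAMPLE_CLASSES <- c("tumour", "plasma", "germline", "cp_control")

#' Normalize chromosome names to the chr-prefixed dialect
#' @param chrom character vector of chromosome names.
#' @return character vector with a "chr" prefix.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Unique variant locus/allele key
#'
#' @param x variant data.frame.
#' @return character vector `chrom:pos:ref>alt`, the identity used for all
#'   set operations (concordance, filter reports, truth matching).
#' @export
variant_key <- function(x) {
  if (nrow(x) == 0) return(character(0))
  paste0(x$chrom, ":", x$pos, ":", x$ref, ">", x$alt)
}

#' Total read depth and variant allele fraction
#'
#' Depth is the sum of the four per-strand counts; VAF is alt/depth and `NA`
#' at zero depth.
#' @param x variant data.frame.
#' @return numeric vector.
#' @export
variant_depth <- function(x) {
  x$ref_fwd + x$ref_rev + x$alt_fwd + x$alt_rev
}

#' @rdname variant_depth
#' @export
variant_vaf <- function(x) {
  d <- variant_depth(x)
  ifelse(d > 0, (x$alt_fwd + x$alt_rev) / d, NA_real_)
}

#' Validate a variant table against the type invariants
#'
#' Checks required columns, non-negative counts, `pos >= 1`, `ref != alt`
#' and allele alphabet; normalizes chromosome names; flags indels (multi-base
#' alleles) as `unsupported` in the `flags` column rather than rejecting
#' them: downstream kataegis/signature analyses are SNV-defined.
#'
#' @param x data.frame to validate.
#' @return the validated (possibly column-augmented) data.frame.
#' @export
validate_variants <- function(x) {
  missing_cols <- setdiff(VARIANT_REQUIRED_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$chrom <- normalize_chrom(x$chrom)
  x$pos <- as.integer(x$pos)
  for (col in c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative or missing %s at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  bad <- which(is.na(x$pos) | x$pos < 1)
  if (length(bad) > 0) {
    stop(sprintf("invalid pos at row %d (must be >= 1)", bad[1]),
         call. = FALSE)
  }
  bad <- which(x$ref == x$alt)
  if (length(bad) > 0) {
    stop(sprintf("ref equals alt at row %d", bad[1]), call. = FALSE)
  }
  if (is.null(x$flags)) x$flags <- ""
  indel <- nchar(x$ref) != 1L | nchar(x$alt) != 1L |
    !(x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T"))
  x$flags[indel] <- add_flag(x$flags[indel], "unsupported")
  x
}

add_flag <- function(flags, flag) {
  ifelse(flags == "", flag,
         ifelse(grepl(flag, flags, fixed = TRUE), flags,
                paste(flags, flag, sep = ";")))
}

has_flag <- function(flags, flag) {
  grepl(flag, flags, fixed = TRUE)
}

#' Read / write a variant table (TSV)
#'
#' TSV with a header; "." encodes absent annotation values. Unknown columns
#' are preserved, so read -> write -> read is the identity on all fields.
#'
#' @param path file path.
#' @return validated variant data.frame.
#' @export
read_variant_table <- function(path) {
  char_cols <- c("chrom", "ref", "alt", "sample_id", "cosmic_id",
                 "dbsnp_id", "exonic_function", "gene", "driver_class",
                 "biomarker", "context", "flags")
  header <- utils::read.delim(path, sep = "\t", header = TRUE, nrows = 1,
                              check.names = FALSE)
  classes <- ifelse(names(header) %in% char_cols, "character", NA)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = ".",
                         check.names = FALSE, colClasses = classes)
  if (nrow(x) == 0 && ncol(x) == 0) {
    stop("variant table is missing required column(s): ",
         paste(VARIANT_REQUIRED_COLS, collapse = ", "), call. = FALSE)
  }
  x <- validate_variants(x)
  num_anno <- intersect(c("af_1000g", "af_gnomad", "af_hapmap"), names(x))
  for (col in num_anno) x[[col]] <- as.numeric(x[[col]])
  x
}

#' @rdname read_variant_table
#' @param x variant data.frame.
#' @export
write_variant_table <- function(x, path) {
  out <- x
  for (col in names(out)) {
    if (is.character(out[[col]])) out[[col]][is.na(out[[col]])] <- "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a BED blacklist into a GRanges interval set
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed
#' ranges so that a BED record `chr1 100 200` covers 1-based positions
#' 101..200. Intervals are sorted; membership queries use the interval tree
#' behind [GenomicRanges::findOverlaps()].
#'
#' @param path BED file (3+ columns, no header).
#' @return a sorted [GenomicRanges::GRanges] object.
#' @export
read_blacklist <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  bad <- which(x[[2]] >= x[[3]])
  if (length(bad) > 0) {
    stop(sprintf("invalid BED interval at line %d: start >= end", bad[1]),
         call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(x[[1]]),
    ranges = IRanges::IRanges(start = x[[2]] + 1L, end = x[[3]]))
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
}

#' Test 1-based positions for blacklist membership
#'
#' @param chrom,pos parallel vectors of chromosome and 1-based position.
#' @param blacklist GRanges from [read_blacklist()].
#' @return logical vector.
#' @export
in_blacklist <- function(chrom, pos, blacklist) {
  if (length(blacklist) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(seqnames = normalize_chrom(chrom),
                              ranges = IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, blacklist)
}

#' The 96 trinucleotide substitution channel labels
#'
#' Pyrimidine-normalized labels in COSMIC order: for each substitution class
#' C>A, C>G, C>T, T>A, T>C, T>G, the 16 flanking-base combinations, written
#' as e.g. `A[C>A]A`.
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", s, "]", three))
      }
    }
  }
  out
}

#' Read a 96-channel signature reference matrix
#'
#' TSV with 96 rows keyed by trinucleotide channel labels (first column) and
#' one column per signature. Columns are required to sum to 1 within 1e-3
#' (renormalized to machine precision), otherwise an error is raised; rows
#' are reordered into canonical channel order.
#'
#' @param path TSV file.
#' @return numeric matrix 96 x S with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  labels <- x[[1]]
  if (anyDuplicated(labels)) {
    stop("duplicate channel label in signature matrix: ",
         labels[duplicated(labels)][1], call. = FALSE)
  }
  channels <- sbs96_channels()
  if (nrow(x) != 96 || !setequal(labels, channels)) {
    stop("signature matrix must have exactly the 96 trinucleotide channels; ",
         "got ", nrow(x), " rows", call. = FALSE)
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  m <- m[channels, , drop = FALSE]
  sums <- colSums(m)
  off <- abs(sums - 1) > 1e-3
  if (any(off)) {
    stop("signature column(s) do not sum to 1 within 1e-3: ",
         paste(colnames(m)[off], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2, sums, "/")
}

#' Read and validate a sample manifest
#'
#' TSV with columns `patient_id`, `sample_id`, `sample_class` (one of
#' tumour/plasma/germline/cp_control), `timepoint_label`, `day`. Enforces at
#' most one germline sample per patient and strictly increasing plasma days
#' per patient (in manifest order).
#'
#' @param path TSV file.
#' @return data.frame of sample metadata.
#' @export
read_manifest <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = ".")
  validate_manifest(x)
}

#' @rdname read_manifest
#' @param x manifest data.frame.
#' @export
validate_manifest <- function(x) {
  required <- c("patient_id", "sample_id", "sample_class",
                "timepoint_label", "day")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) return(x)
  bad <- !x$sample_class %in% SAMPLE_CLASSES
  if (any(bad)) {
    stop("unknown sample_class: ", x$sample_class[bad][1], call. = FALSE)
  }
  for (p in unique(x$patient_id)) {
    px <- x[x$patient_id == p, ]
    if (sum(px$sample_class == "germline") > 1) {
      stop("patient ", p, " has more than one germline sample",
           call. = FALSE)
    }
    days <- px$day[px$sample_class == "plasma"]
    if (length(days) > 1 && any(diff(days) <= 0)) {
      stop("plasma days for patient ", p,
           " are not strictly increasing", call. = FALSE)
    }
  }
  x
}
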