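#' @importFrom stats cor rbinom rpois runif rbeta setNames aov anova sd TukeyHSD
#' @importFrom utils head tail
NULL

# Genotype call codes used throughout the package:
#   0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#   3 = missing.
CALL_HOM_REF <- 0L
CALL_HET <- 1L
CALL_HOM_ALT <- 2L
CALL_MISSING <- 3L

#' Construct a marker map
#'
#' A marker map records the physical coordinates and alleles of each
#' biallelic marker. Positions are 1-based base pairs; chromosome labels are
#' plain strings without a "chr" prefix.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based physical positions (bp).
#' @param id character vector of unique marker ids.
#' @param ref,alt reference and alternate allele symbols.
#' @return A `data.frame` with class `marker_map`, sorted by (chrom, pos).
#' @export
marker_map <- function(chrom, pos, id, ref = "A", alt = "G") {
  n <- length(pos)
  map <- data.frame(
    chrom = normalize_chrom(rep_len(as.character(chrom), n)),
    pos = as.integer(pos),
    id = rep_len(as.character(id), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$id)) stop("marker ids must be unique")
  ord <- order(chrom_order(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

# Numeric-aware chromosome ordering ("2" before "10"; non-numeric labels last).
chrom_order <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  ifelse(is.na(num), rank(x, ties.method = "min") + 1e6, num)
}

#' Construct a genotype dataset
#'
#' The central container: a samples x markers matrix of genotype calls coded
#' 0 (hom-ref), 1 (het), 2 (hom-alt), 3 (missing), together with a
#' [marker_map()], optional per-sample cohort labels, and optional
#' per-variant ANN annotation strings (SnpEff style).
#'
#' @param map a `marker_map`.
#' @param samples character vector of sample ids.
#' @param calls integer matrix, `length(samples)` rows x `nrow(map)` columns.
#' @param cohort optional character vector of cohort labels per sample.
#' @param ann optional character vector of ANN INFO strings per marker
#'   (`NA` where absent).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(map, samples, calls, cohort = NULL, ann = NULL) {
  samples <- as.character(samples)
  calls <- matrix(as.integer(calls), nrow = length(samples),
                  dimnames = list(samples, map$id))
  if (ncol(calls) != nrow(map)) {
    stop("call matrix has ", ncol(calls), " columns but map has ",
         nrow(map), " markers")
  }
  bad <- !(calls %in% c(0L, 1L, 2L, 3L))
  if (any(bad)) stop("genotype calls must be coded 0/1/2/3")
  if (!is.null(cohort)) {
    cohort <- rep_len(as.character(cohort), length(samples))
  }
  if (!is.null(ann)) {
    ann <- rep_len(as.character(ann), nrow(map))
  }
  structure(
    list(map = map, samples = samples, calls = calls,
         cohort = cohort, ann = ann),
    class = "genotype_dataset"
  )
}

#' @exportS3Method base::print
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$map), "markers on", length(unique(x$map$chrom)),
      "chromosome(s)\n")
  if (!is.null(x$cohort)) {
    cat("  cohorts:", paste(names(table(x$cohort)), table(x$cohort),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(length(x$samples), nrow(x$map))

#' Subset a genotype dataset by samples and/or markers
#'
#' @param ds a `genotype_dataset`.
#' @param samples sample ids or logical/integer index; `NULL` keeps all.
#' @param markers marker index (logical or integer into the map); `NULL`
#'   keeps all.
#' @return A `genotype_dataset`; sample and marker order are preserved.
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  si <- seq_along(ds$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, ds$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  mi <- seq_len(nrow(ds$map))
  if (!is.null(markers)) mi <- mi[markers]
  map <- ds$map[mi, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  genotype_dataset(
    map, ds$samples[si], ds$calls[si, mi, drop = FALSE],
    cohort = if (!is.null(ds$cohort)) ds$cohort[si],
    ann = if (!is.null(ds$ann)) ds$ann[mi]
  )
}

#' Marker-covered genome length
#'
#' Sum over chromosomes of (last marker position - first marker position),
#' in bp. This marker-covered span, rather than an assembly length, is the
#' denominator used for F_ROH and window coverage statistics.
#'
#' @param map a `marker_map`.
#' @return total covered length in bp.
#' @export
genome_length <- function(map) {
  if (nrow(map) == 0) stop("empty marker map")
  sum(tapply(map$pos, map$chrom, function(p) max(p) - min(p)))
}

#' Genotype dosage matrix
#'
#' Returns the alternate-allele dosage (0/1/2) with missing calls as `NA`.
#'
#' @param ds a `genotype_dataset`.
#' @return numeric matrix, samples x markers.
#' @export
dosage_matrix <- function(ds) {
  d <- ds$calls
  d[d == CALL_MISSING] <- NA_integer_
  storage.mode(d) <- "double"
  d
}
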