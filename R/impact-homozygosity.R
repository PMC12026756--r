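#' Impact categories from SnpEff-style ANN strings
#'
#' Parses pipe-delimited ANN annotations (impact in subfield 3 of each
#' comma-separated entry) into the category sets used for homozygosity
#' tallies: HIGH and MODERATE are kept as-is, while LOW and MODIFIER
#' collapse into a single NEUTRAL category. A variant belongs to every
#' distinct category among its annotations, so one variant can be tallied
#' in more than one category; a variant annotated both LOW and MODIFIER
#' appears once in NEUTRAL.
#'
#' @param ann character vector of ANN INFO strings (one per variant; `NA`
#'   allowed).
#' @return list with `categories` (list of character vectors, one per
#'   variant, subsets of HIGH/MODERATE/NEUTRAL) and `n_malformed` (variants
#'   skipped because no impact field could be read).
#' @export
categorize_variants <- function(ann) {
  n_malformed <- 0L
  categories <- lapply(ann, function(a) {
    if (is.na(a) || !nzchar(a)) return(character(0))
    entries <- strsplit(a, ",", fixed = TRUE)[[1]]
    imps <- vapply(entries, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(f) < 3) NA_character_ else toupper(trimws(f[3]))
    }, character(1), USE.NAMES = FALSE)
    known <- imps %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")
    if (!any(known)) {
      n_malformed <<- n_malformed + 1L
      return(character(0))
    }
    imps <- imps[known]
    imps[imps %in% c("LOW", "MODIFIER")] <- "NEUTRAL"
    sort(unique(imps))
  })
  list(categories = categories, n_malformed = n_malformed)
}

#' Genotype-class tallies per sample and impact category
#'
#' For each sample and each category (HIGH, MODERATE, NEUTRAL), counts
#' hom-ref, het, hom-alt and missing genotypes over the variants assigned
#' to that category, treating the alternate allele as the effect allele.
#' The percent homozygous alternate uses the non-missing denominator:
#' 100 x hom_alt / (hom_ref + het + hom_alt).
#'
#' @param ds a `genotype_dataset`.
#' @param categories per-variant category sets from
#'   [categorize_variants()]`$categories` (defaults to categorizing
#'   `ds$ann`).
#' @return data.frame per sample x category: `sample`, `category`,
#'   `hom_ref`, `het`, `hom_alt`, `missing`, `total`, `pct_hom_alt`.
#' @export
tally_impacts <- function(ds, categories = NULL) {
  if (is.null(categories)) {
    if (is.null(ds$ann)) stop("dataset has no ANN annotations")
    categories <- categorize_variants(ds$ann)$categories
  }
  stopifnot(length(categories) == nrow(ds$map))
  out <- list()
  for (cat in c("HIGH", "MODERATE", "NEUTRAL")) {
    in_cat <- vapply(categories, function(x) cat %in% x, logical(1))
    cc <- ds$calls[, in_cat, drop = FALSE]
    hr <- rowSums(cc == CALL_HOM_REF)
    ht <- rowSums(cc == CALL_HET)
    ha <- rowSums(cc == CALL_HOM_ALT)
    ms <- rowSums(cc == CALL_MISSING)
    nonmiss <- hr + ht + ha
    out[[cat]] <- data.frame(
      sample = ds$samples, category = cat, hom_ref = hr, het = ht,
      hom_alt = ha, missing = ms, total = ncol(cc),
      pct_hom_alt = ifelse(nonmiss > 0, 100 * ha / nonmiss, NA_real_),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation between F_ROH and percent homozygous impact variants
#'
#' Pearson correlation (and its square) between per-sample genomic
#' inbreeding and the percent of homozygous-alternate variants in one
#' impact category, matched by sample id.
#'
#' @param froh_tbl data.frame from [froh()] (columns `sample`, `froh`), or
#'   any data.frame with those columns.
#' @param tallies data.frame from [tally_impacts()].
#' @param category `"HIGH"`, `"MODERATE"` or `"NEUTRAL"`.
#' @return list with `r`, `r2` (rounded to 2 decimals) and `n`.
#' @export
correlate_froh_impact <- function(froh_tbl, tallies, category) {
  t1 <- tallies[tallies$category == category, , drop = FALSE]
  m <- match(froh_tbl$sample, t1$sample)
  ok <- !is.na(m)
  x <- froh_tbl$froh[ok]
  y <- t1$pct_hom_alt[m[ok]]
  if (length(x) < 3) stop("need at least 3 paired samples")
  r <- cor(x, y)
  list(r = r, r2 = round(r^2, 2), n = length(x))
}

#' Count variants falling inside ROH, by segment length class
#'
#' A variant is "in ROH" for a sample when its position lies within any of
#' that sample's segments (closed intervals, boundary positions included);
#' the containing segment's length class is recorded. Reports both
#' variant-sample pair counts and the number of distinct variants found in
#' ROH in any sample.
#'
#' @param positions data.frame with `chrom` and `pos` of the variants of
#'   interest (e.g. high-impact variants).
#' @param segments ROH table.
#' @param bounds_mb length-class lower bounds in Mb (last class open).
#' @return list with `pairs` (data.frame `sample`, `chrom`, `pos`,
#'   `class`), `class_counts` (pairs per class) and
#'   `n_distinct_variants`.
#' @export
variants_in_roh <- function(positions, segments,
                            bounds_mb = c(1, 2, 4, 8, 16)) {
  upper <- c(bounds_mb[-1], Inf)
  class_of <- function(len_mb) {
    k <- findInterval(len_mb, bounds_mb)
    ifelse(k == 0, NA_character_,
           ifelse(is.finite(upper[pmax(k, 1)]),
                  paste0(bounds_mb[pmax(k, 1)], "-", upper[pmax(k, 1)]),
                  paste0(">", bounds_mb[pmax(k, 1)])))
  }
  hits <- list()
  if (nrow(segments)) {
    for (i in seq_len(nrow(positions))) {
      sel <- segments$chrom == positions$chrom[i] &
        segments$start <= positions$pos[i] & segments$end >= positions$pos[i]
      if (any(sel)) {
        seg <- segments[sel, , drop = FALSE]
        hits[[length(hits) + 1L]] <- data.frame(
          sample = seg$sample, chrom = positions$chrom[i],
          pos = positions$pos[i],
          class = class_of(seg$length_kb / 1000),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(sample = character(), chrom = character(), pos = integer(),
               class = character(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  labels <- c(paste0(bounds_mb[-length(bounds_mb)], "-", bounds_mb[-1]),
              paste0(">", bounds_mb[length(bounds_mb)]))
  class_counts <- setNames(integer(length(labels)), labels)
  if (nrow(pairs)) {
    tab <- table(pairs$class)
    class_counts[names(tab)] <- as.integer(tab)
  }
  list(pairs = pairs, class_counts = class_counts,
       n_distinct_variants = nrow(unique(pairs[, c("chrom", "pos")])))
}
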