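#' Per-marker Weir-Cockerham F_ST between two cohorts
#'
#' The Weir & Cockerham (1984) theta estimator for r = 2 populations,
#' computed per marker from cohort sample sizes, alternate-allele
#' frequencies and observed heterozygote fractions. With cohort sizes n_i,
#' alt frequencies p_i and het fractions h_i:
#' n_bar = mean(n_i), n_c = (r n_bar - sum(n_i^2)/(r n_bar))/(r - 1),
#' p_bar = sum(n_i p_i)/(r n_bar), s2 = sum(n_i (p_i - p_bar)^2)/((r-1) n_bar),
#' h_bar = sum(n_i h_i)/(r n_bar), and the variance components
#' a = (n_bar/n_c) (s2 - (p_bar(1-p_bar) - ((r-1)/r) s2 - h_bar/4)/(n_bar-1)),
#' b = (n_bar/(n_bar-1)) (p_bar(1-p_bar) - ((r-1)/r) s2 - ((2 n_bar-1)/(4 n_bar)) h_bar),
#' c = h_bar/2, with F_ST = a/(a+b+c). Values may be negative and are
#' reported unclamped; markers with a + b + c = 0 (or fewer than two
#' genotyped samples in a cohort) are returned as `NA`.
#'
#' @param ds a `genotype_dataset` whose `$cohort` labels name exactly two
#'   cohorts.
#' @param exclude_samples optional ids dropped first (e.g. a precomputed
#'   first-degree-relative exclusion list).
#' @return data.frame per marker: `id`, `chrom`, `pos`, `n1`, `n2`, `p1`,
#'   `p2`, `fst`.
#' @export
fst_per_marker <- function(ds, exclude_samples = character()) {
  if (is.null(ds$cohort)) stop("dataset has no cohort labels")
  keep <- !(ds$samples %in% exclude_samples)
  calls <- ds$calls[keep, , drop = FALSE]
  cohort <- ds$cohort[keep]
  groups <- sort(unique(cohort))
  if (length(groups) != 2) {
    stop("exactly 2 cohorts required, found ", length(groups))
  }
  stats_for <- function(g) {
    cc <- calls[cohort == g, , drop = FALSE]
    nonmiss <- cc != CALL_MISSING
    n <- colSums(nonmiss)
    alt <- colSums((cc == CALL_HET) + 2L * (cc == CALL_HOM_ALT))
    het <- colSums(cc == CALL_HET)
    list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
         h = ifelse(n > 0, het / n, NA_real_))
  }
  s1 <- stats_for(groups[1])
  s2g <- stats_for(groups[2])
  r <- 2
  n1 <- s1$n; n2 <- s2g$n
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2g$p) / (r * nbar)
  s2 <- (n1 * (s1$p - pbar)^2 + n2 * (s2g$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2g$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cv <- hbar / 2
  denom <- a + b + cv
  ok <- n1 >= 2 & n2 >= 2 & !is.na(denom) & denom != 0
  fst <- ifelse(ok, a / denom, NA_real_)
  data.frame(id = ds$map$id, chrom = ds$map$chrom, pos = ds$map$pos,
             n1 = n1, n2 = n2, p1 = s1$p, p2 = s2g$p, fst = fst,
             wc_a = ifelse(ok, a, NA_real_),
             wc_denom = ifelse(ok, denom, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-wide Weir-Cockerham F_ST
#'
#' The ratio-of-sums ("weighted") estimate sum(a) / sum(a + b + c) over all
#' defined markers — the conventional genome-wide summary, and the one that
#' is consistent for the divergence parameter under the Balding-Nichols
#' model (the mean of per-marker ratios is biased downward by noisy
#' denominators).
#'
#' @param records data.frame from [fst_per_marker()].
#' @return a single F_ST value.
#' @export
fst_genome_wide <- function(records) {
  sum(records$wc_a, na.rm = TRUE) / sum(records$wc_denom, na.rm = TRUE)
}

#' Flag highly differentiated markers
#'
#' Markers with F_ST strictly above the threshold (default 0.75), the
#' convention for variants near fixation in one cohort.
#'
#' @param records data.frame from [fst_per_marker()].
#' @param threshold flagging threshold (strict inequality).
#' @return the flagged subset of `records`.
#' @export
flag_high_fst <- function(records, threshold = 0.75) {
  records[!is.na(records$fst) & records$fst > threshold, , drop = FALSE]
}
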