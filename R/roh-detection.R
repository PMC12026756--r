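#' ROH caller parameters
#'
#' Knobs of the window-based run-of-homozygosity caller, following the
#' common PLINK parameter dialect.
#'
#' @param window_snp scanning window size in SNPs (W).
#' @param window_het maximum heterozygous calls tolerated per window (H).
#' @param window_missing maximum missing calls tolerated per window (M).
#' @param threshold minimum fraction of accepting windows covering a SNP for
#'   it to be called in-run (T).
#' @param min_snp minimum SNPs per reported segment (L).
#' @param min_length_kb minimum segment length in kb.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a segment.
#' @param min_density_kb_per_snp maximum kb per SNP allowed within a segment
#'   (a density floor).
#' @return list of class `roh_params`.
#' @seealso [roh_preset()] for the array/WGS presets.
#' @export
roh_params <- function(window_snp = 50, window_het = 1, window_missing = 5,
                       threshold = 0.05, min_snp = 100,
                       min_length_kb = 1000, max_gap_kb = 1000,
                       min_density_kb_per_snp = 50) {
  stopifnot(window_snp >= 1, threshold > 0, threshold <= 1,
            min_snp >= 1, min_length_kb > 0, max_gap_kb > 0,
            min_density_kb_per_snp > 0)
  structure(list(window_snp = as.integer(window_snp),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 threshold = threshold, min_snp = as.integer(min_snp),
                 min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp),
            class = "roh_params")
}

#' ROH calling presets for array and sequence data
#'
#' `"array"`: minimum segment length 1000 kb, one het allowed per scanning
#' window — tuned to sparse common-allele panels where short ROH mostly
#' reflect LD. `"wgs"`: minimum length 70 kb with zero heterozygotes,
#' for dense sequence-derived genotypes. `min_snp` should normally be set
#' from [min_snp_threshold()] on the dataset at hand.
#'
#' @param preset `"array"` or `"wgs"`.
#' @param min_snp minimum SNPs per segment (L), e.g. from
#'   [min_snp_threshold()].
#' @param ... overrides passed to [roh_params()].
#' @return an `roh_params` object.
#' @export
roh_preset <- function(preset = c("array", "wgs"), min_snp = 100, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    array = list(window_het = 1, min_length_kb = 1000),
    wgs = list(window_het = 0, min_length_kb = 70)
  )
  args <- utils::modifyList(c(base, list(min_snp = min_snp)), list(...))
  do.call(roh_params, args)
}

#' Call runs of homozygosity
#'
#' Window-based caller. Per sample and chromosome: (1) every span of W
#' consecutive SNPs is "accepting" if it holds at most H het and M missing
#' calls; (2) a SNP is in-run if at least a fraction T of the scanning
#' windows covering it are accepting; (3) maximal stretches of in-run SNPs
#' become candidate segments, trimmed to the outermost homozygous
#' non-missing call; (4) candidates are split where the gap between
#' consecutive SNPs exceeds `max_gap_kb`; (5) surviving segments must have
#' at least `min_snp` SNPs, span at least `min_length_kb`, and satisfy the
#' density bound (kb per SNP).
#'
#' @param ds a `genotype_dataset`, markers sorted by (chrom, pos).
#' @param params an [roh_params()].
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `nsnp`, `length_kb`, `snp1`, `snp2`.
#' @export
call_roh <- function(ds, params = roh_params()) {
  map <- ds$map
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) stop("marker map is not sorted")
  }
  res <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    n <- length(sel)
    if (n < params$window_snp) {
      warning("chromosome ", ch, " has fewer SNPs (", n,
              ") than the scanning window; skipped")
      next
    }
    pos <- map$pos[sel]
    ids <- map$id[sel]
    gap_split <- which(diff(pos) / 1000 > params$max_gap_kb)
    for (s in seq_along(ds$samples)) {
      g <- ds$calls[s, sel]
      inrun <- in_run_snps(g, params)
      segs <- segments_from_inrun(inrun, g, pos, ids, gap_split, params)
      if (!is.null(segs) && nrow(segs)) {
        segs$sample <- ds$samples[s]
        segs$chrom <- ch
        res[[length(res) + 1L]] <- segs
      }
    }
  }
  if (!length(res)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), nsnp = integer(),
                      length_kb = numeric(), snp1 = character(),
                      snp2 = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("sample", "chrom", "start", "end", "nsnp", "length_kb",
          "snp1", "snp2")]
}

# In-run flags for one sample on one chromosome (steps 1-2 of call_roh).
in_run_snps <- function(g, params) {
  n <- length(g)
  W <- params$window_snp
  het <- as.integer(g == CALL_HET)
  mis <- as.integer(g == CALL_MISSING)
  nw <- n - W + 1L
  # rolling window sums
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  wh <- ch[(W + 1L):(n + 1L)] - ch[1:nw]
  wm <- cm[(W + 1L):(n + 1L)] - cm[1:nw]
  acc <- as.integer(wh <= params$window_het & wm <= params$window_missing)
  ca <- c(0L, cumsum(acc))
  j <- seq_len(n)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  covering <- hi - lo + 1L
  acc_cov <- ca[hi + 1L] - ca[lo]
  covering > 0L & acc_cov / covering >= params$threshold
}

# Steps 3-5: candidates from in-run flags, trimming, gap splitting, minima.
segments_from_inrun <- function(inrun, g, pos, ids, gap_split, params) {
  r <- rle(inrun)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- cbind(starts[r$values], ends[r$values])
  if (!nrow(cand)) return(NULL)
  pieces <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    cuts <- gap_split[gap_split >= a & gap_split < b]
    bounds <- cbind(c(a, cuts + 1L), c(cuts, b))
    for (q in seq_len(nrow(bounds))) {
      i0 <- bounds[q, 1]; i1 <- bounds[q, 2]
      hom <- which(g[i0:i1] == CALL_HOM_REF | g[i0:i1] == CALL_HOM_ALT)
      if (!length(hom)) next
      i0t <- i0 + hom[1] - 1L
      i1t <- i0 + hom[length(hom)] - 1L
      nsnp <- i1t - i0t + 1L
      len_kb <- (pos[i1t] - pos[i0t] + 1) / 1000
      if (nsnp < params$min_snp) next
      if (len_kb < params$min_length_kb) next
      if (len_kb / nsnp > params$min_density_kb_per_snp) next
      pieces[[length(pieces) + 1L]] <-
        data.frame(start = pos[i0t], end = pos[i1t], nsnp = nsnp,
                   length_kb = len_kb, snp1 = ids[i0t], snp2 = ids[i1t],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces)) return(NULL)
  do.call(rbind, pieces)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH is the summed ROH length divided by the marker-covered autosomal
#' genome length (sum over chromosomes of last minus first marker
#' position). Segment lengths enter the coefficient as `end - start` so
#' that a segment spanning a whole chromosome's markers contributes exactly
#' its share of the denominator (the reported `.hom` KB column keeps the
#' inclusive `end - start + 1` convention).
#'
#' @param segments ROH table from [call_roh()] (or [read_hom()]).
#' @param ds the `genotype_dataset` the segments were called on (supplies
#'   the genome denominator and the sample list).
#' @return data.frame per sample: `sample`, `froh`, `total_kb`,
#'   `n_segments`, `mean_length_kb`.
#' @export
froh <- function(segments, ds) {
  glen_bp <- genome_length(ds$map)
  per <- lapply(ds$samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    tot_bp <- sum(seg$end - seg$start)
    data.frame(sample = s,
               froh = tot_bp / glen_bp,
               total_kb = tot_bp / 1000,
               n_segments = nrow(seg),
               mean_length_kb = if (nrow(seg)) mean(seg$length_kb) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Observed homozygosity per sample
#'
#' Fraction of homozygous calls among non-missing calls at
#' cohort-polymorphic markers (markers monomorphic across the cohort's
#' non-missing calls are excluded from numerator and denominator), matching
#' the PLINK `--het` scan convention.
#'
#' @param ds a `genotype_dataset`.
#' @return data.frame per sample: `sample`, `o_hom` (count), `n_obs`
#'   (denominator), `pct_hom`.
#' @export
observed_homozygosity <- function(ds) {
  calls <- ds$calls
  nonmiss <- calls != CALL_MISSING
  # polymorphic: at least two distinct call values among non-missing calls
  poly <- vapply(seq_len(ncol(calls)), function(j) {
    v <- calls[nonmiss[, j], j]
    length(v) > 0 && (any(v == CALL_HET) || (any(v == CALL_HOM_REF) &&
                                             any(v == CALL_HOM_ALT)))
  }, logical(1))
  cp <- calls[, poly, drop = FALSE]
  nm <- nonmiss[, poly, drop = FALSE]
  hom <- (cp == CALL_HOM_REF | cp == CALL_HOM_ALT) & nm
  n_obs <- rowSums(nm)
  o_hom <- rowSums(hom)
  data.frame(sample = ds$samples, o_hom = o_hom, n_obs = n_obs,
             pct_hom = 100 * o_hom / n_obs, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' ROH length-class decomposition
#'
#' Splits segments into length classes (default 1-2, 2-4, 4-8, 8-16 and
#' >16 Mb; lower bound closed, upper bound open) and reports, per class:
#' the mean number of segments per sample, the mean percent of the genome
#' covered, the pooled mean segment length, and the class F_ROH under the
#' cumulative convention — the mean per-sample fraction of genome in
#' segments at least as long as the class lower bound. Under that
#' convention class_froh(c) - class_froh(next longer class) equals
#' coverage(c)/100, and the shortest class equals the overall F_ROH.
#'
#' @param segments ROH table.
#' @param ds the source `genotype_dataset` (genome denominator + samples).
#' @param bounds_mb increasing lower bounds of the classes in Mb; the last
#'   class is open-ended.
#' @return data.frame per class: `class`, `lower_mb`, `upper_mb`,
#'   `mean_n_per_sample`, `mean_length_mb`, `coverage_pct`, `class_froh`,
#'   `class_froh_sd`.
#' @export
length_class_table <- function(segments, ds,
                               bounds_mb = c(1, 2, 4, 8, 16)) {
  stopifnot(!is.unsorted(bounds_mb, strictly = TRUE))
  glen_bp <- genome_length(ds$map)
  len_mb <- segments$length_kb / 1000
  upper <- c(bounds_mb[-1], Inf)
  samples <- ds$samples
  rows <- lapply(seq_along(bounds_mb), function(k) {
    in_class <- len_mb >= bounds_mb[k] & len_mb < upper[k]
    at_least <- len_mb >= bounds_mb[k]
    per_sample <- function(mask) {
      vapply(samples, function(s) {
        sum(segments$length_kb[mask & segments$sample == s]) * 1000 / glen_bp
      }, numeric(1))
    }
    cf <- per_sample(at_least)
    cov <- per_sample(in_class)
    n_per <- vapply(samples, function(s) {
      sum(in_class & segments$sample == s)
    }, numeric(1))
    data.frame(
      class = if (is.finite(upper[k]))
        paste0(bounds_mb[k], "-", upper[k]) else paste0(">", bounds_mb[k]),
      lower_mb = bounds_mb[k], upper_mb = upper[k],
      mean_n_per_sample = mean(n_per),
      mean_length_mb = if (any(in_class)) mean(len_mb[in_class]) else NA_real_,
      coverage_pct = 100 * mean(cov),
      class_froh = mean(cf),
      class_froh_sd = sd(cf),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Minimum informative SNP count for ROH calling
#'
#' The false-positive guard of Lencz/Purfield: the smallest run length L
#' such that a chance run of homozygous calls is expected fewer than
#' `alpha` times across all samples and markers,
#' L = ceiling( ln(alpha / (n_markers * n_samples)) / ln(1 - het) ),
#' where `het` is the mean observed heterozygosity across individuals and
#' SNPs.
#'
#' @param ds a `genotype_dataset` (used for marker/sample counts and, when
#'   `mean_het` is `NULL`, the mean heterozygosity).
#' @param alpha expected count of false-positive runs (default 0.05).
#' @param mean_het optionally override the mean observed heterozygosity.
#' @return integer L.
#' @export
min_snp_threshold <- function(ds, alpha = 0.05, mean_het = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  n_markers <- nrow(ds$map)
  n_samples <- length(ds$samples)
  if (is.null(mean_het)) {
    nonmiss <- ds$calls != CALL_MISSING
    mean_het <- sum(ds$calls == CALL_HET) / sum(nonmiss)
  }
  if (mean_het <= 0) stop("mean heterozygosity is zero; threshold undefined")
  if (mean_het >= 1) stop("mean heterozygosity must be < 1")
  as.integer(ceiling(log(alpha / (n_markers * n_samples)) /
                       log(1 - mean_het)))
}

#' Validate called segments against caller constraints
#'
#' Post-hoc check that every reported segment respects the minimum SNP
#' count, minimum length, density and endpoint conventions.
#'
#' @param segments ROH table from [call_roh()].
#' @param params the `roh_params` used.
#' @return `TRUE` invisibly; stops on the first violated constraint.
#' @export
validate_segments <- function(segments, params) {
  stopifnot(all(segments$end >= segments$start),
            all(abs(segments$length_kb -
                    (segments$end - segments$start + 1) / 1000) < 1e-9),
            all(segments$nsnp >= params$min_snp),
            all(segments$length_kb >= params$min_length_kb),
            all(segments$length_kb / segments$nsnp <=
                  params$min_density_kb_per_snp))
  invisible(TRUE)
}
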