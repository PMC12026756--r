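#' Pairwise r-squared within a distance window
#'
#' Squared Pearson correlation of alternate-allele dosages (0/1/2) for all
#' same-chromosome marker pairs closer than `max_distance_kb`, using
#' pairwise-complete samples. Monomorphic markers (zero dosage variance
#' among informative samples) and pairs with fewer than two informative
#' samples are skipped and counted.
#'
#' @param ds a `genotype_dataset`, markers sorted by (chrom, pos).
#' @param max_distance_kb window limit in kb (default 1000 = 1 Mb).
#' @return list with `pairs` (data.frame `id1`, `id2`, `chrom`,
#'   `distance_bp`, `r2`) and `n_skipped` (monomorphic or uninformative
#'   pairs).
#' @export
pairwise_r2 <- function(ds, max_distance_kb = 1000) {
  dos <- dosage_matrix(ds)
  map <- ds$map
  max_bp <- max_distance_kb * 1000
  out <- list()
  n_skipped <- 0L
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    if (length(sel) < 2) next
    pos <- map$pos[sel]
    ids <- map$id[sel]
    d <- dos[, sel, drop = FALSE]
    i1 <- integer(0); i2 <- integer(0)
    for (i in seq_len(length(sel) - 1L)) {
      jmax <- findInterval(pos[i] + max_bp, pos)
      if (jmax > i) {
        i1 <- c(i1, rep.int(i, jmax - i))
        i2 <- c(i2, (i + 1L):jmax)
      }
    }
    if (!length(i1)) next
    cc <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
    r2 <- cc[cbind(i1, i2)]^2
    # drop pairs whose correlation is undefined (monomorphic / <2 samples)
    ok <- !is.na(r2)
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) {
      out[[length(out) + 1L]] <- data.frame(
        id1 = ids[i1[ok]], id2 = ids[i2[ok]], chrom = ch,
        distance_bp = pos[i2[ok]] - pos[i1[ok]], r2 = r2[ok],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(id1 = character(), id2 = character(), chrom = character(),
               distance_bp = integer(), r2 = numeric(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, n_skipped = n_skipped)
}

#' Equal-count distance bins of LD pairs
#'
#' Sorts pairs by distance (stable) and splits them into `n_bins` bins of
#' equal size (+/- 1 pair), the quantile-bin convention, reporting per-bin
#' mean distance and mean r-squared.
#'
#' @param pairs data.frame from [pairwise_r2()]`$pairs`.
#' @param n_bins number of bins (default 100).
#' @return data.frame per bin: `bin`, `n_pairs`, `min_bp`, `max_bp`,
#'   `mean_bp`, `mean_r2`.
#' @export
bin_ld <- function(pairs, n_bins = 100) {
  n <- nrow(pairs)
  if (n == 0) stop("no LD pairs to bin")
  if (n_bins > n) stop("more bins (", n_bins, ") than pairs (", n, ")")
  ord <- order(pairs$distance_bp)   # stable
  d <- pairs$distance_bp[ord]
  r2 <- pairs$r2[ord]
  # ntile: first (n mod n_bins) bins get one extra pair
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- data.frame(
    bin = seq_len(n_bins),
    n_pairs = as.vector(tapply(d, bin, length)),
    min_bp = as.vector(tapply(d, bin, min)),
    max_bp = as.vector(tapply(d, bin, max)),
    mean_bp = as.vector(tapply(d, bin, mean)),
    mean_r2 = as.vector(tapply(r2, bin, mean))
  )
  rownames(out) <- NULL
  out
}

#' Sved effective population size from binned LD
#'
#' Under a 1 cM/Mb genetic map, a bin at mean distance d bp corresponds to
#' recombination fraction c = d / 1e8 Morgans, reflecting the population
#' t = 1/(2c) generations ago. Sved's relation E[r2] = 1/(1 + 4 N_e c)
#' gives N_e = (1/r2 - 1) / (4c), and the per-generation inbreeding rate is
#' dF = 1/(2 N_e). An optional small-sample correction subtracts 1/n from
#' the mean r-squared before inversion.
#'
#' @param bins data.frame from [bin_ld()].
#' @param n_samples sample count, used only when `correct_sample_size` is
#'   `TRUE`.
#' @param correct_sample_size subtract the 1/n sampling inflation of
#'   r-squared (off by default).
#' @return `bins` with added columns `c_morgan`, `t_generations`, `ne`,
#'   `delta_f`.
#' @export
sved_ne <- function(bins, n_samples = NULL, correct_sample_size = FALSE) {
  r2 <- bins$mean_r2
  if (correct_sample_size) {
    if (is.null(n_samples)) stop("n_samples required for the 1/n correction")
    r2 <- pmax(r2 - 1 / n_samples, .Machine$double.eps)
  }
  if (any(r2 <= 0)) stop("mean r2 must be positive for the Sved inversion")
  if (any(r2 >= 1)) r2 <- pmin(r2, 1 - .Machine$double.eps)
  c_m <- bins$mean_bp / 1e8
  bins$c_morgan <- c_m
  bins$t_generations <- 1 / (2 * c_m)
  bins$ne <- (1 / r2 - 1) / (4 * c_m)
  bins$delta_f <- 1 / (2 * bins$ne)
  bins
}

#' Distance at which LD decays to half its maximum
#'
#' Linear interpolation between adjacent (mean distance, mean r2) bin
#' points; returns the first crossing of half the maximum bin mean, or `NA`
#' with a message if the curve never falls that low.
#'
#' @param bins data.frame from [bin_ld()].
#' @return distance in bp (`NA_real_` if not reached).
#' @export
decay_half_distance <- function(bins) {
  stopifnot(nrow(bins) >= 2)
  ord <- order(bins$mean_bp)
  d <- bins$mean_bp[ord]
  r2 <- bins$mean_r2[ord]
  half <- max(r2) / 2
  below <- which(r2 <= half)
  if (!length(below)) {
    message("LD never decays to half its maximum within the binned range")
    return(NA_real_)
  }
  j <- below[1]
  if (j == 1) return(d[1])
  d[j - 1] + (r2[j - 1] - half) / (r2[j - 1] - r2[j]) * (d[j] - d[j - 1])
}

#' Percent change of the inbreeding rate between intervals
#'
#' For a series of per-generation inbreeding rates (oldest to newest or any
#' declared order), the change from each value to the next is
#' (new - old)/old x 100.
#'
#' @param delta_f numeric vector of inbreeding rates (>= 2 values, ordered
#'   old to new).
#' @return numeric vector of length `length(delta_f) - 1` of percent
#'   changes.
#' @export
delta_f_percent_change <- function(delta_f) {
  stopifnot(length(delta_f) >= 2)
  old <- delta_f[-length(delta_f)]
  new <- delta_f[-1]
  if (any(old == 0)) stop("percent change undefined from a zero rate")
  (new - old) / old * 100
}
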