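#' Fixed-width genomic windows anchored at the first marker
#'
#' Tiles each chromosome with consecutive fixed-width windows starting at
#' the first marker position; the last window is truncated at the last
#' marker position. Coordinates are 1-based closed intervals; consecutive
#' windows abut (window k+1 starts 1 bp after window k ends).
#'
#' @param map a `marker_map`.
#' @param width_bp window width in bp (default 100000).
#' @return data.frame: `chrom`, `window` (1-based index per chromosome),
#'   `start`, `end`.
#' @export
make_windows <- function(map, width_bp = 100000) {
  stopifnot(width_bp > 0)
  out <- lapply(unique(map$chrom), function(ch) {
    p <- map$pos[map$chrom == ch]
    if (!length(p)) return(NULL)
    first <- min(p); last <- max(p)
    n_win <- max(1L, ceiling((last - first + 1) / width_bp))
    start <- first + (seq_len(n_win) - 1L) * width_bp
    end <- pmin(start + width_bp - 1L, last)
    keep <- start <= last
    data.frame(chrom = ch, window = seq_len(n_win)[keep],
               start = as.integer(start[keep]), end = as.integer(end[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count per-window ROH sharing by cohort
#'
#' For each window and cohort, the number (and percentage) of samples with
#' at least one ROH overlapping the window. Overlap is non-empty
#' intersection of closed intervals; a sample counts once per window no
#' matter how many of its segments touch it.
#'
#' @param windows data.frame from [make_windows()].
#' @param segments ROH table with a `sample` column.
#' @param cohorts named list mapping cohort name -> character vector of
#'   sample ids (cohort sizes are taken from these vectors, so samples
#'   without any ROH still count in the denominator).
#' @return `windows` with two added columns per cohort: `n_<cohort>` and
#'   `pct_<cohort>`.
#' @export
count_sharing <- function(windows, segments, cohorts) {
  stopifnot(is.list(cohorts), length(names(cohorts)) == length(cohorts))
  res <- windows
  for (cn in names(cohorts)) {
    ids <- as.character(cohorts[[cn]])
    seg <- segments[segments$sample %in% ids, , drop = FALSE]
    counts <- integer(nrow(windows))
    for (ch in unique(res$chrom)) {
      wi <- which(res$chrom == ch)
      sc <- seg[seg$chrom == ch, , drop = FALSE]
      if (!nrow(sc)) next
      # window index range touched by each segment
      first <- res$start[wi[1]]
      width <- res$end[wi[1]] - res$start[wi[1]] + 1L
      if (length(wi) > 1) width <- res$start[wi[2]] - res$start[wi[1]]
      w_lo <- pmax(1L, (sc$start - first) %/% width + 1L)
      w_hi <- pmin(length(wi), (sc$end - first) %/% width + 1L)
      ok <- sc$end >= first & w_lo <= length(wi)
      hits <- unique(do.call(rbind, lapply(which(ok), function(k) {
        cbind(w = w_lo[k]:w_hi[k], s = match(sc$sample[k], ids))
      })))
      if (!is.null(hits) && nrow(hits)) {
        tab <- table(hits[, "w"])
        counts[wi[as.integer(names(tab))]] <- as.integer(tab)
      }
    }
    res[[paste0("n_", cn)]] <- counts
    res[[paste0("pct_", cn)]] <- 100 * counts / length(ids)
  }
  res
}

#' Merge windows above a sharing threshold into regions
#'
#' Windows whose sharing percentage for `cohort` strictly exceeds
#' `threshold_pct` are merged with adjacent qualifying windows into maximal
#' regions.
#'
#' @param share data.frame from [count_sharing()].
#' @param cohort cohort name (its `pct_<cohort>` column is used).
#' @param threshold_pct percentage threshold (strict; default 90).
#' @return data.frame: `chrom`, `start`, `end`, `n_windows`, `max_pct`.
#' @export
high_sharing_regions <- function(share, cohort, threshold_pct = 90) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  col <- paste0("pct_", cohort)
  if (!col %in% names(share)) stop("no sharing column for cohort ", cohort)
  qual <- share[[col]] > threshold_pct
  out <- list()
  for (ch in unique(share$chrom)) {
    wi <- which(share$chrom == ch)
    q <- qual[wi]
    if (!any(q)) next
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rows <- wi[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = share$start[rows[1]],
        end = share$end[rows[length(rows)]],
        n_windows = length(rows),
        max_pct = max(share[[col]][rows]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_pct = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
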