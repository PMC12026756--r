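# Independent oracles used by the test suite. These deliberately use naive
# enumeration / direct formula transcription, not the package's code paths.

# ---- Wright path-counting inbreeding oracle --------------------------------
# F(focal) = sum over common ancestors A and pairs of ascending paths
# (sire -> A, dam -> A) sharing only A: (1/2)^(n1+n2+1) * (1 + F(A)).
oracle_fped <- function(ped, focal) {
  id <- ped$id
  sire <- match(ped$sire, id)
  dam <- match(ped$dam, id)
  paths_memo <- new.env(hash = TRUE, parent = emptyenv())
  # all ascending paths starting at i (each path a vector of indices, i first)
  paths_up <- function(i) {
    key <- as.character(i)
    v <- paths_memo[[key]]
    if (!is.null(v)) return(v)
    out <- list(i)
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) {
        out <- c(out, lapply(paths_up(p), function(pp) c(i, pp)))
      }
    }
    paths_memo[[key]] <- out
    out
  }
  f_memo <- new.env(hash = TRUE, parent = emptyenv())
  f_of <- function(i) {
    key <- as.character(i)
    v <- f_memo[[key]]
    if (!is.null(v)) return(v)
    s <- sire[i]; d <- dam[i]
    val <- 0
    if (!is.na(s) && !is.na(d)) {
      ps <- paths_up(s); pd <- paths_up(d)
      for (p1 in ps) for (p2 in pd) {
        a <- p1[length(p1)]
        if (p2[length(p2)] != a) next
        if (length(intersect(p1, p2)) != 1L) next
        val <- val + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + f_of(a))
      }
    }
    f_memo[[key]] <- val
    val
  }
  f_of(match(focal, id))
}

# Random pedigree: founders plus individuals whose parents are drawn from
# earlier individuals (possibly unknown), giving loops and varying depth.
random_pedigree <- function(n, n_founders = max(4, n %/% 5)) {
  id <- paste0("P", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1)
    pick <- function() if (runif(1) < 0.1) NA_character_ else
      id[sample(pool, 1)]
    sire[i] <- pick()
    dam[i] <- pick()
    # avoid sire == dam (selfing) for realism
    if (!is.na(sire[i]) && !is.na(dam[i]) && sire[i] == dam[i]) {
      dam[i] <- NA_character_
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam))
}

# ---- brute-force ROH enumeration (simplified regime) -----------------------
# Maximal stretches of homozygous calls (no het, no missing), split at gaps
# larger than max_gap_kb, filtered by the minima. Direct scan.
oracle_roh_simple <- function(g, pos, min_snp, min_length_kb, max_gap_kb,
                              min_density) {
  runs <- list()
  i <- 1
  n <- length(g)
  while (i <= n) {
    if (g[i] %in% c(0L, 2L)) {
      j <- i
      while (j < n && g[j + 1] %in% c(0L, 2L)) j <- j + 1
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  out <- list()
  for (r in runs) {
    # split at large gaps
    idx <- r[1]:r[2]
    cuts <- which(diff(pos[idx]) / 1000 > max_gap_kb)
    pieces <- split(idx, cumsum(c(0, seq_along(idx)[-1] %in% (cuts + 1))))
    for (p in pieces) {
      nsnp <- length(p)
      len_kb <- (pos[p[nsnp]] - pos[p[1]] + 1) / 1000
      if (nsnp >= min_snp && len_kb >= min_length_kb &&
          len_kb / nsnp <= min_density) {
        out[[length(out) + 1L]] <- c(start = pos[p[1]], end = pos[p[nsnp]],
                                     nsnp = nsnp)
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("start", "end", "nsnp"))))
  do.call(rbind, out)
}

# ---- independent Weir-Cockerham transcription ------------------------------
# Second implementation from genotype counts of the two cohorts (vectors of
# calls coded 0/1/2/3), scalar arithmetic throughout.
oracle_wc_fst <- function(calls1, calls2) {
  pop_stats <- function(v) {
    v <- v[v != 3L]
    n <- length(v)
    list(n = n, p = sum(v) / (2 * n), h = mean(v == 1L))
  }
  s1 <- pop_stats(calls1); s2 <- pop_stats(calls2)
  r <- 2
  nbar <- (s1$n + s2$n) / 2
  nc <- (r * nbar - (s1$n^2 + s2$n^2) / (r * nbar)) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / (r * nbar)
  ssq <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / (r * nbar)
  a <- (nbar / nc) *
    (ssq - (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * ssq - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# ---- brute-force window sharing --------------------------------------------
oracle_sharing <- function(windows, segments, ids) {
  counts <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    hit <- vapply(ids, function(s) {
      seg <- segments[segments$sample == s &
                        segments$chrom == windows$chrom[w], , drop = FALSE]
      any(seg$start <= windows$end[w] & seg$end >= windows$start[w])
    }, logical(1))
    counts[w] <- sum(hit)
  }
  counts
}

# small random genotype dataset for round-trip properties
random_dataset <- function(n_samples, n_markers, seed,
                           missing_rate = 0.1, n_chrom = 2) {
  set.seed(seed)
  chrom <- sort(rep_len(seq_len(n_chrom), n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(ix) {
    sort(sample.int(1e6, length(ix)))
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  map <- marker_map(chrom, pos, paste0("m", seq_len(n_markers)),
                    ref = ref, alt = alt)
  calls <- matrix(sample(0:2, n_samples * n_markers, replace = TRUE),
                  n_samples)
  calls[matrix(runif(length(calls)) < missing_rate, n_samples)] <- 3L
  genotype_dataset(map, paste0("s", seq_len(n_samples)), calls)
}
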