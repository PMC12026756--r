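# dataset with one sample and explicit calls at given positions
one_sample_ds <- function(calls, pos, chrom = "1") {
  map <- marker_map(chrom, pos, paste0("m", seq_along(pos)))
  genotype_dataset(map, "s1", matrix(as.integer(calls), 1))
}

test_that("a clean homozygous stretch yields exactly one segment", {
  pos <- seq(10000, by = 15000, length.out = 100)  # ~1.5 Mb span
  ds <- one_sample_ds(rep(0L, 100), pos)
  p <- roh_params(window_snp = 50, window_het = 0, window_missing = 0,
                  min_snp = 50, min_length_kb = 1000)
  segs <- call_roh(ds, p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$nsnp, 100L)
  expect_equal(segs$start, pos[1])
  expect_equal(segs$end, pos[100])
  validate_segments(segs, p)
})

test_that("one het with W=1, T=1, H=0 splits a run into two segments", {
  pos <- seq(1000, by = 10000, length.out = 41)
  calls <- rep(2L, 41); calls[21] <- 1L
  ds <- one_sample_ds(calls, pos)
  p <- roh_params(window_snp = 1, window_het = 0, window_missing = 0,
                  threshold = 1, min_snp = 5, min_length_kb = 100,
                  max_gap_kb = 1000, min_density_kb_per_snp = 50)
  segs <- call_roh(ds, p)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$nsnp, c(20L, 20L))
  # with a prohibitive minimum the same split yields none
  p2 <- roh_params(window_snp = 1, window_het = 0, window_missing = 0,
                   threshold = 1, min_snp = 30, min_length_kb = 100)
  expect_equal(nrow(call_roh(ds, p2)), 0L)
})

test_that("windowed caller equals brute-force run enumeration (simplified regime)", {
  set.seed(314)
  for (trial in 1:500) {
    n <- sample(10:60, 1)
    W <- sample(2:6, 1)
    pos <- sort(sample.int(3e6, n))
    calls <- sample(c(0L, 1L, 2L, 3L), n, replace = TRUE,
                    prob = c(0.45, 0.08, 0.45, 0.02))
    min_len <- sample(c(10, 50, 200), 1)
    gap <- sample(c(200, 500, 1e6), 1)
    dens <- sample(c(30, 100, 1e6), 1)
    p <- roh_params(window_snp = W, window_het = 0, window_missing = 0,
                    threshold = 1 / W, min_snp = W, min_length_kb = min_len,
                    max_gap_kb = gap, min_density_kb_per_snp = dens)
    ds <- one_sample_ds(calls, pos)
    got <- suppressWarnings(call_roh(ds, p))
    want <- oracle_roh_simple(calls, pos, min_snp = W,
                              min_length_kb = min_len, max_gap_kb = gap,
                              min_density = dens)
    expect_equal(nrow(got), nrow(want), info = paste("trial", trial))
    if (nrow(want)) {
      expect_equal(got$start, unname(want[, "start"]))
      expect_equal(got$end, unname(want[, "end"]))
      expect_equal(got$nsnp, unname(want[, "nsnp"]))
    }
  }
})

test_that("froh is total ROH length over marker-covered genome", {
  pos <- seq(1, by = 1000, length.out = 1001)  # span 1,000,000 bp
  ds <- one_sample_ds(rep(0L, 1001), pos)
  p <- roh_params(window_snp = 50, min_snp = 50, min_length_kb = 100,
                  min_density_kb_per_snp = 10)
  segs <- call_roh(ds, p)
  fr <- froh(segs, ds)
  # single segment covering the whole marker span
  expect_equal(fr$froh, 1)
  expect_equal(froh(segs[0, ], ds)$froh, 0)
  expect_equal(froh(segs[0, ], ds)$n_segments, 0L)
})

test_that("observed homozygosity excludes missing and monomorphic markers", {
  map <- marker_map("1", c(100, 200, 300, 400), paste0("m", 1:4))
  calls <- rbind(c(0L, 0L, 1L, 2L),
                 c(0L, 2L, 1L, 3L),
                 c(0L, 2L, 0L, 0L))
  ds <- genotype_dataset(map, c("a", "b", "c"), calls)
  oh <- observed_homozygosity(ds)
  # m1 is monomorphic (all hom-ref) -> excluded everywhere
  expect_equal(oh$n_obs, c(3, 2, 3))
  expect_equal(oh$o_hom, c(2, 1, 3))
  expect_equal(oh$pct_hom, 100 * c(2 / 3, 1 / 2, 1))
  # brute-force recount on a random dataset
  ds2 <- random_dataset(3, 40, seed = 17)
  oh2 <- observed_homozygosity(ds2)
  for (i in 1:3) {
    num <- den <- 0
    for (j in 1:40) {
      v <- ds2$calls[, j]
      obs <- v[v != 3L]
      poly <- any(obs == 1L) || (any(obs == 0L) && any(obs == 2L))
      if (poly && ds2$calls[i, j] != 3L) {
        den <- den + 1
        if (ds2$calls[i, j] %in% c(0L, 2L)) num <- num + 1
      }
    }
    expect_equal(oh2$o_hom[i], num)
    expect_equal(oh2$n_obs[i], den)
  }
})

test_that("length classes: coverage placement and the cumulative identity", {
  map <- marker_map("1", c(1, 100e6), c("a", "b"))
  ds <- genotype_dataset(map, "s1", matrix(c(0L, 0L), 1))
  segs <- data.frame(sample = "s1", chrom = "1", start = 1e6,
                     end = 4e6 - 1, nsnp = 100, length_kb = 3000,
                     snp1 = "a", snp2 = "b", stringsAsFactors = FALSE)
  tab <- length_class_table(segs, ds)
  expect_equal(tab$coverage_pct[tab$class == "2-4"], 3e6 / (100e6 - 1) * 100,
               tolerance = 1e-6)
  expect_equal(sum(tab$coverage_pct[tab$class != "2-4"]), 0)
  # identity class_froh(c) - class_froh(next) = coverage(c)/100 on random segments
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(5:40, 1)
    lens <- runif(n, 0.5e6, 30e6)
    starts <- sample.int(60e6, n)
    rs <- data.frame(sample = sample(c("s1", "s2"), n, replace = TRUE),
                     chrom = "1", start = starts,
                     end = starts + round(lens) - 1,
                     nsnp = 100, length_kb = round(lens) / 1000,
                     stringsAsFactors = FALSE)
    ds2 <- genotype_dataset(map, c("s1", "s2"), matrix(0L, 2, 2))
    tb <- length_class_table(rs, ds2)
    k <- nrow(tb)
    expect_equal(tb$class_froh[-k] - tb$class_froh[-1],
                 tb$coverage_pct[-k] / 100, tolerance = 1e-10)
    # total coverage equals overall froh restricted to >= smallest bound
    expect_equal(sum(tb$coverage_pct) / 100, tb$class_froh[1],
                 tolerance = 1e-10)
  }
})

test_that("minimum SNP threshold follows the false-positive formula", {
  map <- marker_map("1", seq(1000, by = 1000, length.out = 10), paste0("m", 1:10))
  ds <- genotype_dataset(map, "s1", matrix(0L, 1, 10))
  # worked example: alpha 0.05, 158,378 markers, 244 samples, het 0.31 -> 56
  big <- list(map = data.frame(id = seq_len(158378)),
              samples = seq_len(244))
  class(big) <- "genotype_dataset"
  expect_equal(min_snp_threshold(big, 0.05, mean_het = 0.31), 56L)
  # direct evaluation oracle on random inputs
  set.seed(5)
  for (trial in 1:20) {
    nm <- sample(1e3:2e5, 1); ns <- sample(10:500, 1)
    het <- runif(1, 0.05, 0.6); al <- runif(1, 0.01, 0.2)
    fake <- list(map = data.frame(id = seq_len(nm)), samples = seq_len(ns))
    class(fake) <- "genotype_dataset"
    expect_equal(min_snp_threshold(fake, al, mean_het = het),
                 as.integer(ceiling(log(al / (nm * ns)) / log(1 - het))))
  }
  # monotone decreasing in het
  f_at <- function(h) min_snp_threshold(big, 0.05, mean_het = h)
  expect_true(f_at(0.6) <= f_at(0.3))
  expect_true(f_at(0.99) <= f_at(0.6))
  expect_error(min_snp_threshold(big, 0.05, mean_het = 0), "zero")
  # computed from calls when not supplied
  calls <- matrix(c(0L, 1L, 1L, 3L, 0L, 1L, 0L, 0L, 2L, 2L), 1)
  dsx <- genotype_dataset(map, "s1", calls)
  expect_equal(min_snp_threshold(dsx, 0.05),
               as.integer(ceiling(log(0.05 / 10) / log(1 - 3 / 9))))
})

test_that("calling a het-free dataset returns segments covering inter-gap spans", {
  pos <- c(seq(1e4, by = 2e4, length.out = 60),
           seq(3e6, by = 2e4, length.out = 60))  # a 1.8 Mb gap
  ds <- one_sample_ds(rep(2L, 120), pos)
  p <- roh_params(window_snp = 20, min_snp = 20, min_length_kb = 500,
                  max_gap_kb = 1000, min_density_kb_per_snp = 50)
  segs <- call_roh(ds, p)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(pos[1], pos[61]))
  expect_equal(segs$end, c(pos[60], pos[120]))
})
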