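test_that("ANN parsing maps impacts to category sets with NEUTRAL merging", {
  ann <- c(
    "G|missense_variant|MODERATE|GENE1|x,G|synonymous_variant|LOW|GENE1|x",
    "A|5_prime_UTR_variant|MODIFIER|GENE2|x",
    "T|frameshift_variant|HIGH|GENE3|x",
    "C|synonymous_variant|LOW|G|x,C|intron_variant|MODIFIER|G|x",
    "bad_ann_without_pipes",
    NA
  )
  got <- categorize_variants(ann)
  expect_equal(got$categories[[1]], c("MODERATE", "NEUTRAL"))
  expect_equal(got$categories[[2]], "NEUTRAL")
  expect_equal(got$categories[[3]], "HIGH")
  # LOW + MODIFIER de-duplicates to a single NEUTRAL membership
  expect_equal(got$categories[[4]], "NEUTRAL")
  expect_equal(got$categories[[5]], character(0))
  expect_equal(got$n_malformed, 1L)
})

test_that("tallies count genotype classes with non-missing denominators", {
  map <- marker_map("1", c(100, 200, 300, 400), paste0("v", 1:4))
  calls <- matrix(c(0L, 1L, 2L, 3L), 1)  # one sample, one call of each kind
  ds <- genotype_dataset(map, "s1", calls,
                         ann = rep("A|missense_variant|MODERATE|G|x", 4))
  t1 <- tally_impacts(ds)
  mod <- t1[t1$category == "MODERATE", ]
  expect_equal(unlist(mod[, c("hom_ref", "het", "hom_alt", "missing")],
                      use.names = FALSE), c(1L, 1L, 1L, 1L))
  expect_equal(mod$pct_hom_alt, 100 / 3)
  expect_equal(t1$total[t1$category == "HIGH"], 0L)
  # a missense+synonymous variant is tallied in MODERATE and NEUTRAL
  ds2 <- genotype_dataset(map, "s1", calls, ann = c(
    "G|missense_variant|MODERATE|g|x,G|synonymous_variant|LOW|g|x",
    "G|synonymous_variant|LOW|g|x",
    "G|frameshift_variant|HIGH|g|x",
    "G|missense_variant|MODERATE|g|x"))
  t2 <- tally_impacts(ds2)
  expect_equal(t2$total[t2$category == "MODERATE"], 2L)
  expect_equal(t2$total[t2$category == "NEUTRAL"], 2L)
  expect_equal(t2$total[t2$category == "HIGH"], 1L)
  # multi-category totals exceed the distinct variant count
  expect_gt(sum(t2$total[1:3]), 4L)
})

test_that("tallies match a brute-force recount on synthetic annotations", {
  ds <- random_dataset(5, 200, seed = 41)
  ds <- annotate_synthetic_impacts(ds, proportions = c(
    HIGH = 0.1, MODERATE = 0.2, LOW = 0.3, MODIFIER = 0.4),
    multi_fraction = 0.2, seed = 42)
  cats <- categorize_variants(ds$ann)$categories
  tl <- tally_impacts(ds, cats)
  for (cat in c("HIGH", "MODERATE", "NEUTRAL")) {
    idx <- which(vapply(cats, function(x) cat %in% x, logical(1)))
    for (s in seq_along(ds$samples)) {
      v <- ds$calls[s, idx]
      row <- tl[tl$category == cat & tl$sample == ds$samples[s], ]
      expect_equal(row$hom_alt, sum(v == 2L))
      expect_equal(row$het, sum(v == 1L))
      expect_equal(row$missing, sum(v == 3L))
      expect_equal(row$pct_hom_alt, 100 * sum(v == 2L) / sum(v != 3L))
    }
  }
  # generator proportions are recovered (LOW+MODIFIER -> NEUTRAL ~ 0.7)
  frac_neutral <- mean(vapply(cats, function(x) "NEUTRAL" %in% x, logical(1)))
  expect_gt(frac_neutral, 0.6)
  # all-LOW proportions produce only NEUTRAL
  ds3 <- annotate_synthetic_impacts(random_dataset(2, 50, seed = 43),
    proportions = c(HIGH = 0, MODERATE = 0, LOW = 1, MODIFIER = 0),
    multi_fraction = 0, seed = 44)
  cats3 <- categorize_variants(ds3$ann)$categories
  expect_true(all(vapply(cats3, identical, logical(1), y = "NEUTRAL")))
})

test_that("F_ROH vs impact-homozygosity correlation is plain Pearson", {
  fr <- data.frame(sample = paste0("s", 1:5), froh = c(0.1, 0.2, 0.3, 0.4, 0.5))
  tl <- data.frame(sample = paste0("s", 1:5), category = "HIGH",
                   pct_hom_alt = c(1, 2, 3, 4, 5) * 2 + 7)
  got <- correlate_froh_impact(fr, tl, "HIGH")
  expect_equal(got$r2, 1)
  expect_equal(got$n, 5L)
  expect_error(correlate_froh_impact(fr[1:2, ], tl, "HIGH"), "3")
})

test_that("variants inside ROH are located per sample with closed boundaries", {
  segs <- data.frame(sample = c("d1", "d2"), chrom = "1",
                     start = c(1e6, 5e6), end = c(2.5e6, 22e6),
                     length_kb = c(1500, 17000), nsnp = 100,
                     stringsAsFactors = FALSE)
  posns <- data.frame(chrom = "1", pos = c(1e6, 2.5e6, 3e6, 6e6))
  got <- variants_in_roh(posns, segs)
  # boundary positions are inside (closed interval)
  d1 <- got$pairs[got$pairs$sample == "d1", ]
  expect_equal(sort(d1$pos), c(1e6, 2.5e6))
  expect_true(all(d1$class == "1-2"))
  d2 <- got$pairs[got$pairs$sample == "d2", ]
  expect_equal(d2$pos, 6e6)
  expect_equal(d2$class, ">16")
  expect_equal(unname(got$class_counts["1-2"]), 2L)
  expect_equal(got$n_distinct_variants, 3L)
  # no segments -> zero counts
  none <- variants_in_roh(posns, segs[0, ])
  expect_equal(sum(none$class_counts), 0L)
  expect_equal(none$n_distinct_variants, 0L)
})

test_that("planted high-impact variants inside short ROH are recovered there", {
  set.seed(45)
  segs <- data.frame(sample = rep(paste0("d", 1:10), each = 2), chrom = "1",
                     start = s <- sample.int(5e7, 20),
                     end = s + round(runif(20, 1.1e6, 1.9e6)),
                     stringsAsFactors = FALSE)
  segs$length_kb <- (segs$end - segs$start + 1) / 1000
  inside <- data.frame(chrom = "1",
                       pos = segs$start[1:5] + 1000)
  got <- variants_in_roh(inside, segs)
  expect_gte(got$n_distinct_variants, 5L)
  tab <- table(got$pairs$class)
  expect_equal(names(tab), "1-2")
})
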