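test_that("pedigree simulation schemes honor their construction rules", {
  # determinism
  cfg <- sim_config(n_founders = 8, n_generations = 3, seed = 51)
  expect_identical(as.data.frame(simulate_pedigree(cfg)),
                   as.data.frame(simulate_pedigree(cfg)))
  # 2 founders, full-sib loop: generation-2 offspring are full-sib matings
  cfg2 <- sim_config(n_founders = 2, n_generations = 3,
                     mating = "full_sib_loop", seed = 52)
  ped <- simulate_pedigree(cfg2)
  g2 <- ped[ped$year == 2, ]
  g1 <- ped[ped$year == 1, ]
  for (i in seq_len(nrow(g2))) {
    s <- g1[g1$id == g2$sire[i], ]
    d <- g1[g1$id == g2$dam[i], ]
    expect_equal(s$sire, d$sire)
    expect_equal(s$dam, d$dam)
  }
  expect_equal(f_ped(ped, ped$id[ped$year == 2][1])$fped, 0.25)
  # popular sire: at most ceil(0.1 * males) distinct sires per generation
  cfg3 <- sim_config(n_founders = 200, n_generations = 2,
                     mating = "popular_sire", sire_fraction = 0.1, seed = 53)
  ped3 <- simulate_pedigree(cfg3)
  for (g in 1:2) {
    gen <- ped3[ped3$year == g, ]
    expect_lte(length(unique(gen$sire)), 10)  # 100 males -> <= 10 sires
  }
  # acyclic by construction
  expect_silent(f_ped(ped3, ped3$id[nrow(ped3)]))
  # infeasible: founders all one sex is impossible by alternation, but a
  # single founder pair with no females in generation 1 cannot happen;
  # instead check the explicit guard via a degenerate config
  expect_error(sim_config(n_founders = 1, seed = 1), "n_founders")
})

test_that("founders and outbred offspring have zero true autozygosity", {
  cfg <- sim_config(n_founders = 6, n_generations = 1, n_chrom = 4,
                    chrom_length_bp = 5e7, seed = 54)
  ped <- simulate_pedigree(cfg)
  dh <- drop_haplotypes(ped, cfg)
  expect_true(all(dh$truth$true_autozygosity == 0))
})

test_that("selfing yields expected autozygosity 1/2 over replicates", {
  # an individual mated to itself: offspring autozygosity ~ Bin over genome
  autos <- vapply(1:200, function(r) {
    set.seed(6000 + r)
    cfg <- sim_config(n_founders = 2, n_generations = 1, n_chrom = 10,
                      chrom_length_bp = 8e7, seed = 6000 + r)
    ped <- as_pedigree(data.frame(id = c("F", "X"), sire = c(NA, "F"),
                                  dam = c(NA, "F")))
    drop_haplotypes(ped, cfg)$truth$true_autozygosity[2]
  }, numeric(1))
  se <- sd(autos) / sqrt(length(autos))
  expect_lt(abs(mean(autos) - 0.5), 3 * se + 1e-9)
})

test_that("full-sib offspring mean autozygosity matches F_PED = 1/4 (3 SE)", {
  autos <- vapply(1:200, function(r) {
    cfg <- sim_config(n_founders = 2, n_generations = 2,
                      mating = "full_sib_loop", n_chrom = 15,
                      chrom_length_bp = 1e8, seed = 7000 + r)
    ped <- simulate_pedigree(cfg)
    dh <- drop_haplotypes(ped, cfg)
    kid <- ped$id[ped$year == 2][1]
    dh$truth$true_autozygosity[dh$truth$id == kid]
  }, numeric(1))
  se <- sd(autos) / sqrt(length(autos))
  expect_lt(abs(mean(autos) - 0.25), 3 * se)
  # oracle cross-check: the pedigree F of a full-sib offspring is 0.25
  cfgx <- sim_config(n_founders = 2, n_generations = 2,
                     mating = "full_sib_loop", seed = 1)
  pedx <- simulate_pedigree(cfgx)
  expect_equal(f_ped(pedx, pedx$id[pedx$year == 2][1])$fped, 0.25)
})

test_that("gene-dropped genotypes are Mendelian-consistent before noise", {
  cfg <- sim_config(n_founders = 8, n_generations = 3, n_chrom = 2,
                    chrom_length_bp = 2e7, error_rate = 0, missing_rate = 0,
                    seed = 55)
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg, clean = TRUE)
  calls <- gd$dense$calls
  px <- as.data.frame(ped)
  for (i in which(!is.na(px$sire))) {
    kid <- calls[px$id[i], ]
    s <- calls[px$sire[i], ]
    d <- calls[px$dam[i], ]
    # impossible transmissions: parent hom x hom
    expect_equal(sum(kid == 1L & s == 0L & d == 0L), 0)
    expect_equal(sum(kid == 1L & s == 2L & d == 2L), 0)
    expect_equal(sum(kid == 0L & (s == 2L | d == 2L)), 0)
    expect_equal(sum(kid == 2L & (s == 0L | d == 0L)), 0)
  }
})

test_that("array panel is an ascertained, sparser subset of the dense panel", {
  cfg <- sim_config(n_founders = 10, n_generations = 2, n_chrom = 3,
                    chrom_length_bp = 3e7, error_rate = 0, missing_rate = 0,
                    seed = 56)
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg, clean = TRUE)
  expect_true(all(gd$array$map$id %in% gd$dense$map$id))
  expect_lt(nrow(gd$array$map), nrow(gd$dense$map))
  # MAF floor holds in the founder cohort by construction: check sample MAF
  founders <- ped$id[ped$year == 0]
  fa <- gd$array$calls[founders, , drop = FALSE]
  p <- colMeans(fa) / 2
  maf <- pmin(p, 1 - p)
  # founders' sample MAF approximates the ascertained haplotype MAF
  expect_gt(mean(maf >= 0.15), 0.95)
  # determinism of the full drop
  gd2 <- gene_drop(ped, cfg, clean = TRUE)
  expect_identical(gd$dense$calls, gd2$dense$calls)
})

test_that("noise injection respects configured rates", {
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_chrom = 2,
                    chrom_length_bp = 2e7, error_rate = 0.05,
                    missing_rate = 0.1, seed = 57)
  ped <- simulate_pedigree(cfg)
  clean <- gene_drop(ped, cfg, clean = TRUE)$dense$calls
  noisy <- gene_drop(ped, cfg)$dense$calls
  miss_rate <- mean(noisy == 3L)
  expect_lt(abs(miss_rate - 0.1), 0.01)
  chg <- mean(noisy != clean & noisy != 3L)
  expect_lt(abs(chg - 0.05 * (1 - 0.1)), 0.01)
})
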