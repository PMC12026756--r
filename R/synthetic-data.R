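#' Simulation configuration
#'
#' Parameters of the synthetic pedigree / gene-dropping generator. The
#' defaults emulate a closed dog-breed cohort genotyped on a sparse,
#' common-allele-ascertained array panel and a dense sequence-like panel:
#' founder alternate-allele frequencies are Beta(0.2, 2) (rare-variant
#' heavy) for the dense panel, and the array panel is an
#' ascertained subsample (minor allele frequency floor) of it;
#' recombination follows a 1 cM/Mb Haldane map (Poisson crossovers, no
#' interference); genotyping error and missingness default to plausible
#' array rates (0.002 and 0.02).
#'
#' @param n_founders number of unrelated founders (>= 2).
#' @param n_generations number of bred generations after the founders.
#' @param offspring_per_mating litter size (constant integer).
#' @param mating `"random"`, `"full_sib_loop"` or `"popular_sire"`.
#' @param sire_fraction fraction of available males used as sires under the
#'   popular-sire scheme.
#' @param n_chrom,chrom_length_bp genome shape (autosomes only). Marker
#'   spacings default to a realistic array density (15 kb per marker, the
#'   170k-SNP canine array scale) and a sequence-like panel six times
#'   denser; genome size is scaled per analysis to keep marker counts
#'   manageable.
#' @param cm_per_mb recombination rate.
#' @param dense_spacing_bp mean marker spacing of the dense
#'   (sequence-like) panel.
#' @param array_spacing_bp target spacing of the sparse (array-like) panel.
#' @param array_maf_floor minimum founder minor-allele frequency for an
#'   array marker (ascertainment).
#' @param beta_shape1,beta_shape2 founder alternate-allele frequency
#'   distribution of the dense panel.
#' @param error_rate per-call genotyping error (flip to a random different
#'   state).
#' @param missing_rate per-call missingness.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20, n_generations = 5,
                       offspring_per_mating = 2,
                       mating = c("random", "full_sib_loop", "popular_sire"),
                       sire_fraction = 0.25,
                       n_chrom = 10, chrom_length_bp = 2.5e7, cm_per_mb = 1,
                       dense_spacing_bp = 2500, array_spacing_bp = 15000,
                       array_maf_floor = 0.2,
                       beta_shape1 = 0.2, beta_shape2 = 2,
                       error_rate = 0.002, missing_rate = 0.02,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  mating <- match.arg(mating)
  stopifnot(n_founders >= 2, n_generations >= 1, offspring_per_mating >= 1,
            sire_fraction > 0, sire_fraction <= 1,
            n_chrom >= 1, chrom_length_bp > 0, cm_per_mb >= 0,
            dense_spacing_bp > 0, array_spacing_bp > 0,
            array_maf_floor >= 0, array_maf_floor <= 0.5,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pedigree
#'
#' Builds an acyclic multi-generation pedigree over `cfg$n_founders`
#' founders with alternating sexes. Under `"random"` mating, males and
#' females of the previous generation are paired at random; under
#' `"popular_sire"`, only a fraction of the males sire all litters
#' (concentrating ancestry the way popular sires do in dog breeds); under
#' `"full_sib_loop"`, matings are made within full-sib families whenever a
#' family has both sexes, producing consanguineous loops.
#'
#' @param cfg a [sim_config()].
#' @return a `pedigree` with `year` holding the generation index and an
#'   attribute `sex` (named character vector, `"M"`/`"F"`).
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  id <- paste0("G0_I", seq_len(cfg$n_founders))
  sex <- rep(c("M", "F"), length.out = cfg$n_founders)
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    year = 0L, stringsAsFactors = FALSE)
  sexes <- setNames(sex, id)
  prev <- data.frame(id = id, sex = sex, sire = NA_character_,
                     dam = NA_character_, stringsAsFactors = FALSE)
  for (g in seq_len(cfg$n_generations)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (!length(males) || !length(females)) {
      stop("mating scheme infeasible at generation ", g,
           ": need at least one male and one female")
    }
    matings <- switch(cfg$mating,
      random = {
        n_mat <- min(length(males), length(females))
        cbind(sample(males)[seq_len(n_mat)], sample(females)[seq_len(n_mat)])
      },
      popular_sire = {
        n_sires <- max(1L, ceiling(cfg$sire_fraction * length(males)))
        sires <- sample(males)[seq_len(n_sires)]
        cbind(sample(sires, length(females), replace = TRUE), females)
      },
      full_sib_loop = {
        fam <- paste(prev$sire, prev$dam)
        pairs <- list()
        for (f in unique(fam)) {
          fm <- prev$id[fam == f & prev$sex == "M"]
          ff <- prev$id[fam == f & prev$sex == "F"]
          for (k in seq_len(min(length(fm), length(ff)))) {
            pairs[[length(pairs) + 1L]] <- c(fm[k], ff[k])
          }
        }
        if (!length(pairs)) {  # founders or sexless families: random pairing
          n_mat <- min(length(males), length(females))
          pairs <- lapply(seq_len(n_mat), function(k) {
            c(sample(males)[k], sample(females)[k])
          })
        }
        do.call(rbind, pairs)
      })
    kids <- list()
    for (m in seq_len(nrow(matings))) {
      for (k in seq_len(cfg$offspring_per_mating)) {
        kid <- paste0("G", g, "_I", length(kids) + 1L)
        kids[[length(kids) + 1L]] <- data.frame(
          id = kid, sire = matings[m, 1], dam = matings[m, 2],
          year = g, stringsAsFactors = FALSE)
      }
    }
    kids <- do.call(rbind, kids)
    kid_sex <- rep(c("M", "F"), length.out = nrow(kids))
    sexes <- c(sexes, setNames(kid_sex, kids$id))
    ped <- rbind(ped, kids)
    prev <- data.frame(id = kids$id, sex = kid_sex, sire = kids$sire,
                       dam = kids$dam, stringsAsFactors = FALSE)
  }
  out <- as_pedigree(ped)
  attr(out, "sex") <- sexes
  out
}

# ---- haplotype machinery ---------------------------------------------------
# A haplotype on one chromosome is a list(brk, lab): segment start positions
# (brk[1] == 1) and integer founder-haplotype labels. Positions are
# continuous in [1, len].

founder_hap <- function(label) list(brk = 1, lab = label)

# Gamete from two parental haplotypes: crossovers as a Poisson process at
# `morgans` expected events (Haldane, no interference).
meiosis <- function(hA, hB, len, morgans) {
  nco <- rpois(1, morgans)
  xs <- if (nco > 0) sort(runif(nco, 1, len)) else numeric(0)
  use_a <- sample(c(TRUE, FALSE), 1)
  bounds <- c(1, xs, len + 1)
  brk <- numeric(0); lab <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    h <- if (use_a) hA else hB
    a <- bounds[i]; b <- bounds[i + 1L]
    j0 <- findInterval(a, h$brk)
    j1 <- findInterval(b - 1e-9, h$brk)
    piece_brk <- pmax(h$brk[j0:j1], a)
    piece_lab <- h$lab[j0:j1]
    # merge with previous segment when the label continues across the cut
    if (length(lab) && length(piece_lab) && piece_lab[1] == lab[length(lab)]) {
      piece_brk <- piece_brk[-1]; piece_lab <- piece_lab[-1]
    }
    brk <- c(brk, piece_brk); lab <- c(lab, piece_lab)
    use_a <- !use_a
  }
  list(brk = brk, lab = lab)
}

# Fraction of [1, len] where the two haplotypes carry the same founder label.
ibd_fraction <- function(h1, h2, len) {
  brk <- sort(unique(c(h1$brk, h2$brk)))
  ends <- c(brk[-1], len + 1)
  l1 <- h1$lab[findInterval(brk, h1$brk)]
  l2 <- h2$lab[findInterval(brk, h2$brk)]
  sum((ends - brk)[l1 == l2]) / len
}

# Labels of a haplotype at marker positions.
hap_labels_at <- function(h, pos) h$lab[findInterval(pos, h$brk)]

#' Drop founder haplotypes through a pedigree
#'
#' Runs gene dropping without marker panels: every founder carries two
#' uniquely labeled haplotypes per chromosome and each meiosis recombines
#' them under the Haldane model. Returns the haplotype mosaics and the true
#' autozygosity (fraction of genome identical by descent) per individual.
#'
#' @param ped a `pedigree` (acyclic).
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return list with `haplotypes` (per individual, per chromosome, a pair
#'   of label mosaics) and `truth` (data.frame `id`, `true_autozygosity`).
#' @export
drop_haplotypes <- function(ped, cfg, seed = cfg$seed + 1) {
  set.seed(seed)
  px <- ped_index(ped)
  topo <- ped_topo_order(px)
  n <- length(px$id)
  len <- cfg$chrom_length_bp
  morgans <- len / 1e6 * cfg$cm_per_mb / 100
  haps <- vector("list", n)
  founder_count <- 0L
  for (i in topo) {
    if (px$sire[i] == 0L && px$dam[i] == 0L) {
      founder_count <- founder_count + 1L
      labs <- c(2L * founder_count - 1L, 2L * founder_count)
      haps[[i]] <- lapply(seq_len(cfg$n_chrom), function(ch) {
        list(founder_hap(labs[1]), founder_hap(labs[2]))
      })
    } else {
      get_gamete <- function(p) {
        if (p == 0L) {
          # unknown single parent: treat as a fresh founder gamete
          founder_count <<- founder_count + 1L
          lapply(seq_len(cfg$n_chrom), function(ch) {
            founder_hap(2L * founder_count - 1L)
          })
        } else {
          lapply(seq_len(cfg$n_chrom), function(ch) {
            meiosis(haps[[p]][[ch]][[1]], haps[[p]][[ch]][[2]], len, morgans)
          })
        }
      }
      gs <- get_gamete(px$sire[i])
      gd <- get_gamete(px$dam[i])
      haps[[i]] <- lapply(seq_len(cfg$n_chrom), function(ch) {
        list(gs[[ch]], gd[[ch]])
      })
    }
  }
  auto <- vapply(seq_len(n), function(i) {
    mean(vapply(seq_len(cfg$n_chrom), function(ch) {
      ibd_fraction(haps[[i]][[ch]][[1]], haps[[i]][[ch]][[2]], len)
    }, numeric(1)))
  }, numeric(1))
  names(haps) <- px$id
  list(haplotypes = haps,
       truth = data.frame(id = px$id, true_autozygosity = auto,
                          stringsAsFactors = FALSE))
}

#' Gene-drop genotype data over a pedigree
#'
#' Full simulation: founder haplotypes are dropped through the pedigree
#' ([drop_haplotypes()]), a dense sequence-like marker panel is laid down
#' with Beta-distributed founder alternate-allele frequencies (rare-variant
#' heavy), and an array-like panel is ascertained from it (founder minor
#' allele frequency >= `array_maf_floor`, thinned to the target spacing).
#' Genotyping error flips a call to a random different non-missing state;
#' missingness masks calls to the missing code. The returned truth table
#' carries the true autozygosity (IBD fraction) and, optionally, the
#' pedigree inbreeding coefficient of every individual.
#'
#' @param ped a `pedigree`.
#' @param cfg a [sim_config()].
#' @param with_fped also compute F_PED (all generations) per individual.
#' @param clean skip error/missingness injection (useful for Mendelian
#'   checks).
#' @return list with `dense` and `array` (`genotype_dataset`s over all
#'   pedigree members) and `truth` (data.frame `id`, `true_autozygosity`,
#'   optionally `fped`).
#' @export
gene_drop <- function(ped, cfg, with_fped = FALSE, clean = FALSE) {
  dh <- drop_haplotypes(ped, cfg)
  haps <- dh$haplotypes
  n <- length(haps)
  len <- cfg$chrom_length_bp
  n_founder_haps <- max(vapply(haps, function(h) {
    max(vapply(h, function(p) max(p[[1]]$lab, p[[2]]$lab), numeric(1)))
  }, numeric(1)))
  # dense panel: uniform random positions at the target mean spacing
  m_per_chrom <- max(2L, round(len / cfg$dense_spacing_bp))
  panels <- lapply(seq_len(cfg$n_chrom), function(ch) {
    pos <- sort(sample.int(len - 1L, m_per_chrom))
    p_alt <- rbeta(m_per_chrom, cfg$beta_shape1, cfg$beta_shape2)
    hap_alleles <- matrix(
      rbinom(n_founder_haps * m_per_chrom, 1L, rep(p_alt, each = n_founder_haps)),
      nrow = n_founder_haps)
    list(pos = pos, hap_alleles = hap_alleles)
  })
  geno_chrom <- function(ch) {
    pan <- panels[[ch]]
    g <- matrix(0L, n, length(pan$pos))
    for (i in seq_len(n)) {
      l1 <- hap_labels_at(haps[[i]][[ch]][[1]], pan$pos)
      l2 <- hap_labels_at(haps[[i]][[ch]][[2]], pan$pos)
      g[i, ] <- pan$hap_alleles[cbind(l1, seq_along(pan$pos))] +
        pan$hap_alleles[cbind(l2, seq_along(pan$pos))]
    }
    g
  }
  calls <- do.call(cbind, lapply(seq_len(cfg$n_chrom), geno_chrom))
  chrom <- rep(seq_len(cfg$n_chrom),
               times = vapply(panels, function(p) length(p$pos), integer(1)))
  pos <- unlist(lapply(panels, `[[`, "pos"))
  ids <- paste0(chrom, "_", pos)
  map <- marker_map(chrom, pos, ids)
  samples <- names(haps)
  # array ascertainment on founder-haplotype allele frequencies
  f_alt <- unlist(lapply(panels, function(p) colMeans(p$hap_alleles)))
  maf <- pmin(f_alt, 1 - f_alt)
  eligible <- maf >= cfg$array_maf_floor
  target_per_chrom <- max(1L, round(len / cfg$array_spacing_bp))
  array_idx <- unlist(lapply(seq_len(cfg$n_chrom), function(ch) {
    cand <- which(chrom == ch & eligible)
    if (!length(cand)) return(integer(0))
    take <- min(length(cand), target_per_chrom)
    cand[unique(round(seq(1, length(cand), length.out = take)))]
  }))
  noisy <- function(g) if (clean) g else
    inject_noise(g, cfg$error_rate, cfg$missing_rate)
  dense <- genotype_dataset(map, samples, noisy(calls))
  amap <- ds_map_subset(map, sort(array_idx))
  array <- genotype_dataset(amap, samples,
                            noisy(calls[, sort(array_idx), drop = FALSE]))
  truth <- dh$truth
  if (with_fped) {
    px <- ped_index(ped)
    phi <- make_kinship(px)
    truth$fped <- vapply(seq_along(px$id), function(i) {
      phi(px$sire[i], px$dam[i])
    }, numeric(1))[match(truth$id, px$id)]
  }
  list(dense = dense, array = array, truth = truth)
}

ds_map_subset <- function(map, idx) {
  out <- map[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_map", "data.frame")
  out
}

inject_noise <- function(g, error_rate, missing_rate) {
  if (error_rate > 0) {
    flip <- which(runif(length(g)) < error_rate)
    if (length(flip)) {
      g[flip] <- (g[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
    }
  }
  if (missing_rate > 0) {
    g[runif(length(g)) < missing_rate] <- CALL_MISSING
  }
  g
}

#' Simulate two diverged cohorts (Balding-Nichols model)
#'
#' Draws per-marker ancestral frequencies p, then cohort frequencies from
#' Beta(p (1-F)/F, (1-p)(1-F)/F) with F = `fst_target`, and genotypes at
#' Hardy-Weinberg within each cohort — the standard model under which the
#' Weir-Cockerham estimator recovers F.
#'
#' @param n_per_cohort samples per cohort (length-2 vector or scalar).
#' @param n_markers number of markers.
#' @param fst_target divergence parameter in (0, 1).
#' @param seed RNG seed.
#' @param ancestral_range range of the uniform ancestral frequency draw.
#' @param spacing_bp marker spacing (markers are placed on chromosome 1).
#' @return a `genotype_dataset` with cohort labels `"A"` and `"B"`.
#' @export
simulate_two_cohorts <- function(n_per_cohort = 100, n_markers = 5000,
                                 fst_target = 0.2, seed,
                                 ancestral_range = c(0.1, 0.9),
                                 spacing_bp = 1e5) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(fst_target > 0, fst_target < 1)
  set.seed(seed)
  n_per_cohort <- rep_len(n_per_cohort, 2)
  p_anc <- runif(n_markers, ancestral_range[1], ancestral_range[2])
  shape <- (1 - fst_target) / fst_target
  p1 <- rbeta(n_markers, p_anc * shape, (1 - p_anc) * shape)
  p2 <- rbeta(n_markers, p_anc * shape, (1 - p_anc) * shape)
  draw <- function(nn, p) {
    matrix(rbinom(nn * n_markers, 2L, rep(p, each = nn)), nrow = nn)
  }
  calls <- rbind(draw(n_per_cohort[1], p1), draw(n_per_cohort[2], p2))
  map <- marker_map("1", spacing_bp * seq_len(n_markers),
                    paste0("snp", seq_len(n_markers)))
  samples <- c(paste0("A", seq_len(n_per_cohort[1])),
               paste0("B", seq_len(n_per_cohort[2])))
  genotype_dataset(map, samples, calls,
                   cohort = rep(c("A", "B"), n_per_cohort))
}

#' Attach synthetic SnpEff-style impact annotations
#'
#' Assigns each variant a primary impact category drawn from the given
#' proportions and, for a fraction of variants, a second distinct category
#' (so that tallies exercise multi-category counting). Emits ANN strings
#' with the impact in subfield 3.
#'
#' @param ds a `genotype_dataset`.
#' @param proportions named numeric vector over
#'   HIGH/MODERATE/LOW/MODIFIER, summing to 1.
#' @param multi_fraction fraction of variants given a second category.
#' @param seed RNG seed.
#' @return `ds` with `$ann` filled in.
#' @export
annotate_synthetic_impacts <- function(ds,
    proportions = c(HIGH = 0.001, MODERATE = 0.005, LOW = 0.01,
                    MODIFIER = 0.984),
    multi_fraction = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            setequal(names(proportions),
                     c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  set.seed(seed)
  effect_of <- c(HIGH = "frameshift_variant", MODERATE = "missense_variant",
                 LOW = "synonymous_variant",
                 MODIFIER = "5_prime_UTR_premature_start_codon_gain_variant")
  cats <- names(proportions)
  m <- nrow(ds$map)
  primary <- sample(cats, m, replace = TRUE, prob = proportions)
  ann <- vapply(seq_len(m), function(j) {
    chosen <- primary[j]
    if (runif(1) < multi_fraction) {
      chosen <- c(chosen, sample(setdiff(cats, chosen), 1))
    }
    paste(vapply(chosen, function(cc) {
      paste(ds$map$alt[j], effect_of[[cc]], cc,
            paste0("GENE", ds$map$chrom[j]), sep = "|")
    }, character(1)), collapse = ",")
  }, character(1))
  ds$ann <- ann
  ds
}

#' Forward Wright-Fisher simulation of a recombining chromosome
#'
#' Simulates 2N haplotypes of biallelic markers under random mating at
#' constant diploid size N with Haldane recombination (1 cM/Mb), starting
#' from intermediate allele frequencies. Used to check linkage
#' disequilibrium based estimates of effective population size against a
#' known truth.
#'
#' @param n_diploid constant population size N.
#' @param n_generations generations to evolve.
#' @param n_markers marker count.
#' @param chrom_length_bp chromosome length.
#' @param n_sample diploids sampled at the end.
#' @param seed RNG seed.
#' @return a `genotype_dataset` of the sampled diploids (markers that
#'   remain polymorphic).
#' @export
simulate_wright_fisher <- function(n_diploid = 50, n_generations = 150,
                                   n_markers = 300, chrom_length_bp = 1e7,
                                   n_sample = 30, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(seed)
  pos <- sort(sample.int(chrom_length_bp - 1L, n_markers))
  morgans <- chrom_length_bp / 1e8
  H <- matrix(rbinom(2L * n_diploid * n_markers, 1L, 0.5), nrow = 2L * n_diploid)
  gamete <- function(h1, h2) {
    nco <- rpois(1, morgans)
    if (nco == 0) return(if (runif(1) < 0.5) h1 else h2)
    xs <- sort(runif(nco, 1, chrom_length_bp))
    seg <- findInterval(pos, xs)
    use1 <- (seg + (runif(1) < 0.5)) %% 2 == 0
    ifelse(use1, h1, h2)
  }
  for (g in seq_len(n_generations)) {
    Hn <- matrix(0L, 2L * n_diploid, n_markers)
    for (i in seq_len(n_diploid)) {
      pa <- sample.int(n_diploid, 1); ma <- sample.int(n_diploid, 1)
      Hn[2L * i - 1L, ] <- gamete(H[2L * pa - 1L, ], H[2L * pa, ])
      Hn[2L * i, ] <- gamete(H[2L * ma - 1L, ], H[2L * ma, ])
    }
    H <- Hn
  }
  pick <- sample.int(n_diploid, n_sample)
  calls <- H[2L * pick - 1L, , drop = FALSE] + H[2L * pick, , drop = FALSE]
  freq <- colMeans(H)
  poly <- freq > 0 & freq < 1
  map <- marker_map("1", pos[poly], paste0("wf", which(poly)))
  genotype_dataset(map, paste0("S", seq_len(n_sample)),
                   calls[, poly, drop = FALSE])
}
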