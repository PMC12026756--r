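#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA across groups, via [stats::aov()].
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  tab <- suppressWarnings(anova(aov(y ~ g, data = df)))
  if (!is.finite(tab[["F value"]][1])) {
    stop("F statistic undefined (zero within-group variance)")
  }
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Tukey HSD compact letter display
#'
#' All-pairs Tukey honest significant difference tests
#' ([stats::TukeyHSD()]) followed by insert-and-absorb letter assignment:
#' groups sharing a letter do not differ at `alpha`.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level (default 0.01, the convention of
#'   means-with-superscripts cohort tables).
#' @return named character vector of letter codes per group.
#' @export
tukey_groups <- function(groups, alpha = 0.01) {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  gn <- names(groups)
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(gn, vapply(groups, length, integer(1))), levels = gn))
  hsd <- TukeyHSD(aov(y ~ g, data = df))$g
  k <- length(gn)
  sig <- matrix(FALSE, k, k, dimnames = list(gn, gn))
  for (r in rownames(hsd)) {
    pr <- strsplit(r, "-", fixed = TRUE)[[1]]
    s <- hsd[r, "p adj"] < alpha
    sig[pr[1], pr[2]] <- s
    sig[pr[2], pr[1]] <- s
  }
  # insert-and-absorb: start from one set; split every set containing a
  # significantly different pair, then drop sets that became subsets
  sets <- list(gn)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    offending <- vapply(sets, function(s) all(c(gn[i], gn[j]) %in% s),
                        logical(1))
    if (!any(offending)) next
    replacements <- unlist(lapply(sets[offending], function(s) {
      list(setdiff(s, gn[i]), setdiff(s, gn[j]))
    }), recursive = FALSE)
    sets <- c(sets[!offending], replacements)
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
          length(sets[[a]]) < length(sets[[b]])) keep[a] <- FALSE
    }
    # also drop exact duplicates
    sets <- unique(sets[keep])
  }
  # order sets by the smallest group mean they contain, then letter them
  means <- vapply(groups, mean, numeric(1))
  sets <- sets[order(vapply(sets, function(s) min(means[s]), numeric(1)))]
  out <- setNames(rep("", k), gn)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' End-to-end simulated-cohort pipeline
#'
#' Simulates a pedigree and gene-dropped genotype panels, applies QC, and
#' computes every measure in the package: pedigree inbreeding at the
#' requested depths, ROH and F_ROH on the dense and array panels, the ROH
#' length-class table, LD decay with the Sved effective-population-size
#' trajectory on the array panel, and observed homozygosity. All outputs
#' are returned and, when `outdir` is given, written as CSVs (with the seed
#' recorded in a run log).
#'
#' @param cfg a [sim_config()].
#' @param depths pedigree depths for the F_PED table.
#' @param outdir optional output directory.
#' @param n_bins LD distance bins.
#' @return list of result tables; see Details.
#' @export
run_pipeline <- function(cfg, depths = c(5, 10, Inf), outdir = NULL,
                         n_bins = 25) {
  ped <- simulate_pedigree(cfg)
  gd <- gene_drop(ped, cfg, with_fped = TRUE)
  qc <- apply_qc(gd$array, qc_thresholds())
  array_ds <- qc$dataset
  dense_ds <- apply_qc(gd$dense, qc_thresholds())$dataset
  last_gen <- ped$id[ped$year == max(ped$year)]
  fped_tbl <- cohort_fped_table(ped, last_gen, depths)
  call_on <- function(ds, preset) {
    p <- roh_preset(preset, min_snp = min(
      min_snp_threshold(ds, 0.05), 100L))
    segs <- call_roh(ds, p)
    list(params = p, segments = segs, froh = froh(segs, ds))
  }
  dense_roh <- call_on(dense_ds, "wgs")
  array_roh <- call_on(array_ds, "array")
  classes <- length_class_table(array_roh$segments, array_ds)
  lp <- pairwise_r2(array_ds)
  ld <- if (nrow(lp$pairs) >= n_bins) {
    sved_ne(bin_ld(lp$pairs, n_bins), n_samples = length(array_ds$samples))
  } else NULL
  ohom <- observed_homozygosity(array_ds)
  res <- list(pedigree = ped, fped = fped_tbl,
              dense = dense_roh, array = array_roh,
              length_classes = classes, ld = ld,
              observed_homozygosity = ohom,
              truth = gd$truth, seed = cfg$seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) data.table::fwrite(x, file.path(outdir, f))
    writeLines(c(paste("seed:", cfg$seed),
                 paste("generated:", format(Sys.time()))),
               file.path(outdir, "run_log.txt"))
    write_pedigree_csv(ped, file.path(outdir, "pedigree.csv"))
    wr(fped_tbl$individuals, "fped_individuals.csv")
    wr(fped_tbl$summary, "fped_summary.csv")
    write_hom(array_roh$segments, file.path(outdir, "array_roh.hom"))
    write_hom(dense_roh$segments, file.path(outdir, "dense_roh.hom"))
    wr(array_roh$froh, "array_froh.csv")
    wr(dense_roh$froh, "dense_froh.csv")
    wr(classes, "length_classes.csv")
    if (!is.null(ld)) wr(ld, "ld_ne.csv")
    wr(ohom, "observed_homozygosity.csv")
    wr(gd$truth, "truth.csv")
  }
  res
}
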