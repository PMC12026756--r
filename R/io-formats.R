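#' @importFrom data.table fread fwrite data.table as.data.table setorder
NULL

VALID_ALLELES <- c("A", "C", "G", "T", "0", "1", "2")

#' QC thresholds
#'
#' Call-rate and marker-type filters applied before analysis. Defaults
#' mirror common array practice: samples with call rate below 0.94
#' (PLINK `--mind 0.06`) and markers with call rate below 0.95
#' (`--geno 0.05`) are removed.
#'
#' @param min_sample_call_rate minimum fraction of non-missing calls per
#'   sample.
#' @param min_marker_call_rate minimum fraction of non-missing calls per
#'   marker.
#' @param biallelic_snv_only drop markers whose alleles are not two distinct
#'   single bases.
#' @param autosomes chromosome labels retained when `biallelic_snv_only` is
#'   set; default 1-38 (canine autosomes).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.94,
                          min_marker_call_rate = 0.95,
                          biallelic_snv_only = FALSE,
                          autosomes = as.character(1:38)) {
  stopifnot(min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_marker_call_rate >= 0, min_marker_call_rate <= 1)
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_marker_call_rate = min_marker_call_rate,
                 biallelic_snv_only = biallelic_snv_only,
                 autosomes = as.character(autosomes)),
            class = "qc_thresholds")
}

#' Apply sample and marker QC
#'
#' Samples are filtered before markers (the conventional duplicate ->
#' `--mind` -> `--geno` order); marker call rates are therefore computed on
#' the retained samples. An optional exclusion list stands in for external
#' duplicate/relatedness pruning.
#'
#' @param ds a `genotype_dataset`.
#' @param q a [qc_thresholds()].
#' @param exclude_samples sample ids to drop before any call-rate filter.
#' @return list with `dataset` (filtered) and `report` (removed sample ids,
#'   removed marker ids, counts).
#' @export
apply_qc <- function(ds, q = qc_thresholds(), exclude_samples = character()) {
  drop_pre <- intersect(as.character(exclude_samples), ds$samples)
  keep_s <- !(ds$samples %in% drop_pre)
  calls <- ds$calls[keep_s, , drop = FALSE]
  n_mark <- ncol(calls)
  s_rate <- 1 - rowSums(calls == CALL_MISSING) / n_mark
  low_s <- s_rate < q$min_sample_call_rate
  removed_samples <- rownames(calls)[low_s]
  calls2 <- calls[!low_s, , drop = FALSE]
  if (nrow(calls2) == 0) stop("QC removed every sample (empty cohort)")
  m_rate <- 1 - colSums(calls2 == CALL_MISSING) / nrow(calls2)
  low_m <- m_rate < q$min_marker_call_rate
  not_snv <- rep(FALSE, n_mark)
  if (q$biallelic_snv_only) {
    not_snv <- !(ds$map$ref %in% c("A", "C", "G", "T") &
                 ds$map$alt %in% c("A", "C", "G", "T") &
                 ds$map$ref != ds$map$alt &
                 ds$map$chrom %in% q$autosomes)
  }
  removed_markers <- ds$map$id[low_m | not_snv]
  keep_samples <- setdiff(ds$samples, c(drop_pre, removed_samples))
  out <- subset_dataset(ds, samples = keep_samples,
                        markers = !(ds$map$id %in% removed_markers))
  list(dataset = out,
       report = list(excluded_samples = drop_pre,
                     removed_samples = removed_samples,
                     removed_markers = removed_markers,
                     n_samples_kept = length(keep_samples),
                     n_markers_kept = nrow(out$map)))
}

# ---- PLINK text PED/MAP ----------------------------------------------------

#' Read PLINK text PED/MAP files
#'
#' The MAP file may have the standard 4 columns (chrom, id, cM, pos) or 6
#' columns with alleles appended (alt then ref, the orientation this package
#' writes). With 4 columns the alternate allele is inferred as the minor
#' allele among observed calls (ties broken alphabetically).
#'
#' @param ped_path,map_path file paths.
#' @return a `genotype_dataset`.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- fread(map_path, header = FALSE, data.table = FALSE,
                   colClasses = "character")
  if (!ncol(map_raw) %in% c(4L, 6L)) {
    stop("MAP file must have 4 (or 6, with alleles) columns, found ",
         ncol(map_raw))
  }
  n_mark <- nrow(map_raw)
  ped_raw <- fread(ped_path, header = FALSE, data.table = FALSE,
                   colClasses = "character")
  if (ncol(ped_raw) != 6L + 2L * n_mark) {
    stop("PED file has ", ncol(ped_raw), " columns; expected ",
         6L + 2L * n_mark, " for ", n_mark, " markers")
  }
  samples <- ped_raw[[2]]
  a1 <- as.matrix(ped_raw[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE])
  a2 <- as.matrix(ped_raw[, 6L + 2L * seq_len(n_mark), drop = FALSE])
  bad <- !(a1 %in% VALID_ALLELES) | !(a2 %in% VALID_ALLELES)
  if (any(bad)) {
    stop("invalid allele symbol(s) in PED file: ",
         paste(unique(c(a1[bad], a2[bad])), collapse = ", "))
  }
  if (ncol(map_raw) == 6L) {
    alt <- map_raw[[5]]; ref <- map_raw[[6]]
  } else {
    ref <- alt <- character(n_mark)
    for (j in seq_len(n_mark)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[obs != "0"]
      tab <- sort(table(obs))
      alleles <- names(tab)
      if (length(alleles) == 0) { ref[j] <- "A"; alt[j] <- "G" }
      else if (length(alleles) == 1) { ref[j] <- alleles; alt[j] <- "N" }
      else if (length(alleles) > 2) {
        stop("marker ", map_raw[[2]][j], " has >2 alleles")
      } else {
        # minor allele = alt; on a tie the alphabetically later allele
        if (tab[[1]] == tab[[2]]) alleles <- sort(alleles)
        alt[j] <- alleles[1]; ref[j] <- alleles[2]
      }
    }
  }
  calls <- matrix(CALL_MISSING, nrow = nrow(ped_raw), ncol = n_mark)
  for (j in seq_len(n_mark)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    calls[, j] <- (x1 == alt[j]) + (x2 == alt[j])
    calls[miss, j] <- CALL_MISSING
  }
  map <- marker_map(map_raw[[1]], as.integer(map_raw[[4]]), map_raw[[2]],
                    ref = ref, alt = alt)
  ord <- match(map$id, map_raw[[2]])
  genotype_dataset(map, samples, calls[, ord, drop = FALSE])
}

#' Write PLINK text PED/MAP files
#'
#' Writes a 6-column extended MAP (chrom, id, cM = 0, pos, alt, ref) so the
#' allele orientation survives a round trip; standard 4-column MAP readers
#' simply ignore the extra columns.
#'
#' @param ds a `genotype_dataset`.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(ds, prefix) {
  map <- ds$map
  fwrite(data.table(map$chrom, map$id, 0, map$pos, map$alt, map$ref),
         paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  n <- length(ds$samples)
  m <- nrow(map)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    g <- ds$calls[, j]
    a1[, j] <- ifelse(g == 3L, "0", ifelse(g >= 1L, map$alt[j], map$ref[j]))
    a2[, j] <- ifelse(g == 3L, "0", ifelse(g == 2L, map$alt[j], map$ref[j]))
  }
  geno <- matrix("", n, 2L * m)
  geno[, 2L * seq_len(m) - 1L] <- a1
  geno[, 2L * seq_len(m)] <- a2
  ped <- cbind(ds$samples, ds$samples, "0", "0", "0", "-9", geno)
  fwrite(as.data.table(ped), paste0(prefix, ".ped"), sep = " ",
         col.names = FALSE)
  invisible(prefix)
}

# ---- PLINK binary BED/BIM/FAM ---------------------------------------------

#' Read PLINK binary BED/BIM/FAM files
#'
#' SNP-major v1.00 format (magic bytes 0x6c 0x1b 0x01). Per-marker 2-bit
#' codes are mapped 00 -> homozygous A1, 10 -> het, 11 -> homozygous A2,
#' 01 -> missing. The BIM A1 column is treated as the alternate (effect)
#' allele, so code 00 becomes call 2 (hom-alt) and 11 becomes call 0
#' (hom-ref). Note that PLINK itself recodes A1 to the minor allele by
#' default, which need not be the alternate allele of the source VCF.
#'
#' @param prefix path prefix shared by `.bed`, `.bim`, `.fam`.
#' @return a `genotype_dataset`.
#' @export
read_bed_bim_fam <- function(prefix) {
  bim_path <- paste0(prefix, ".bim")
  bim <- if (file.size(bim_path) == 0) {
    data.frame(V1 = character(), V2 = character(), V3 = character(),
               V4 = character(), V5 = character(), V6 = character())
  } else {
    fread(bim_path, header = FALSE, data.table = FALSE,
          colClasses = "character")
  }
  fam <- fread(paste0(prefix, ".fam"), header = FALSE, data.table = FALSE,
               colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01)) {
    stop("not a SNP-major PLINK v1.00 .bed file (bad magic bytes)")
  }
  bpm <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpm * m) {
    stop(".bed payload is ", length(body), " bytes; expected ", bpm * m)
  }
  calls <- matrix(CALL_MISSING, n, max(m, 1L))
  if (m > 0 && n > 0) {
    ints <- as.integer(body)
    # unpack 2-bit fields, sample 1 in the lowest-order bits
    codes <- matrix(0L, 4L * bpm, m)
    block <- matrix(ints, bpm, m)
    for (k in 0:3) {
      codes[seq_len(bpm) * 4L - 3L + k, ] <- block %/% (4L^k) %% 4L
    }
    codes <- codes[seq_len(n), , drop = FALSE]
    # 00 -> hom A1 (alt) = 2; 01 -> missing; 10 -> het; 11 -> hom A2 (ref) = 0
    lookup <- c(`0` = CALL_HOM_ALT, `1` = CALL_MISSING,
                `2` = CALL_HET, `3` = CALL_HOM_REF)
    calls <- matrix(lookup[codes + 1L], n, m)
  }
  if (m == 0) calls <- matrix(integer(0), n, 0)
  map <- marker_map(bim[[1]], as.integer(bim[[4]]), bim[[2]],
                    ref = bim[[6]], alt = bim[[5]])
  ord <- match(map$id, bim[[2]])
  genotype_dataset(map, fam[[2]], calls[, ord, drop = FALSE])
}

#' Write PLINK binary BED/BIM/FAM files
#'
#' Inverse of [read_bed_bim_fam()]; BIM A1 = alternate allele.
#'
#' @param ds a `genotype_dataset`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bed_bim_fam <- function(ds, prefix) {
  map <- ds$map
  fwrite(data.table(map$chrom, map$id, 0, map$pos, map$alt, map$ref),
         paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  fwrite(data.table(ds$samples, ds$samples, 0, 0, 0, -9),
         paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  n <- length(ds$samples)
  m <- nrow(map)
  bpm <- ceiling(n / 4)
  # call -> 2-bit code: 2 -> 00, 3 -> 01, 1 -> 10, 0 -> 11
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L, `3` = 1L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0) {
    codes <- matrix(code_of[ds$calls + 1L], n, m)
    padded <- matrix(1L, 4L * bpm, m)   # pad with missing code 01
    padded[seq_len(n), ] <- codes
    bytes <- matrix(0L, bpm, m)
    for (k in 0:3) {
      bytes <- bytes + padded[seq_len(bpm) * 4L - 3L + k, , drop = FALSE] * 4L^k
    }
    writeBin(as.raw(as.vector(bytes)), con)
  }
  invisible(prefix)
}

# ---- VCF -------------------------------------------------------------------

#' Read genotypes (and ANN annotations) from a VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a `genotype_dataset`,
#' preserving SnpEff-style `ANN` INFO strings verbatim for downstream
#' impact tallies. With `biallelic_snv_only`, multiallelic records and
#' non-SNVs are silently dropped and counted, and records are restricted to
#' the given autosome set.
#'
#' @param path VCF file path.
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction.
#' @param biallelic_snv_only keep only biallelic single-nucleotide variants.
#' @param autosomes chromosome labels retained when filtering.
#' @return list with `dataset` (ANN strings attached as `$ann`) and
#'   `report` (`n_dropped_multiallelic`, `n_dropped_other`).
#' @export
read_vcf <- function(path, region = NULL, biallelic_snv_only = FALSE,
                     autosomes = as.character(1:38)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix   # includes INFO (getFIX drops it)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (!("FORMAT" %in% colnames(vcf@gt)) || ncol(vcf@gt) < 2) {
    stop("VCF has no genotype (GT) columns")
  }
  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("GT field missing from FORMAT")
  }
  chrom <- normalize_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    parts <- strsplit(region, "[:-]")[[1]]
    keep <- keep & chrom == normalize_chrom(parts[1])
    if (length(parts) == 3) {
      keep <- keep & pos >= as.integer(parts[2]) & pos <= as.integer(parts[3])
    }
  }
  n_multi <- 0L
  n_other <- 0L
  if (biallelic_snv_only) {
    multi <- grepl(",", alt)
    n_multi <- sum(multi & keep)
    snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
      alt %in% c("A", "C", "G", "T")
    auto <- chrom %in% as.character(autosomes)
    n_other <- sum(keep & !multi & !(snv & auto))
    keep <- keep & !multi & snv & auto
  }
  gt <- vcf@gt[, -1, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[keep, , drop = FALSE]
  info <- fix[keep, "INFO"]
  ann <- rep(NA_character_, sum(keep))
  has_ann <- grepl("(^|;)ANN=", info)
  ann[has_ann] <- sub(".*(^|;)ANN=([^;]*).*", "\\2", info[has_ann])
  # GT is the first colon-separated field
  gt_first <- sub(":.*", "", gt)
  gt_first <- gsub("\\|", "/", gt_first)
  to_call <- function(g) {
    out <- rep(CALL_MISSING, length(g))
    out[g == "0/0"] <- CALL_HOM_REF
    out[g %in% c("0/1", "1/0")] <- CALL_HET
    out[g == "1/1"] <- CALL_HOM_ALT
    out
  }
  calls <- t(apply(gt_first, 1, to_call))
  if (sum(keep) == 1L) calls <- matrix(as.integer(calls), ncol = ncol(gt))
  map <- marker_map(chrom[keep], pos[keep],
                    id = ifelse(fix[keep, "ID"] == "." | is.na(fix[keep, "ID"]),
                                paste0(chrom[keep], "_", pos[keep]),
                                fix[keep, "ID"]),
                    ref = ref[keep], alt = alt[keep])
  ord <- order(chrom_order(chrom[keep]), pos[keep])
  ds <- genotype_dataset(map, colnames(gt),
                         t(calls[ord, , drop = FALSE]),
                         ann = ann[ord])
  list(dataset = ds,
       report = list(n_dropped_multiallelic = n_multi,
                     n_dropped_other = n_other))
}

#' Write a genotype dataset as a VCF 4.2 file
#'
#' @param ds a `genotype_dataset`; `$ann` strings, when present, are emitted
#'   as `ANN=` INFO fields.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ds$samples), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1", "./.")
  info <- if (is.null(ds$ann)) rep(".", nrow(ds$map)) else
    ifelse(is.na(ds$ann), ".", paste0("ANN=", ds$ann))
  lines <- vapply(seq_len(nrow(ds$map)), function(j) {
    paste(c(ds$map$chrom[j], ds$map$pos[j], ds$map$id[j], ds$map$ref[j],
            ds$map$alt[j], ".", "PASS", info[j], "GT",
            gt_str[ds$calls[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

# ---- PLINK-style .hom segment tables --------------------------------------

#' Write ROH segments as a PLINK-style .hom table
#'
#' Columns: FID IID CHR SNP1 SNP2 POS1 POS2 KB NSNP.
#'
#' @param segments data.frame of ROH segments as returned by [call_roh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hom <- function(segments, path) {
  out <- data.table(FID = segments$sample, IID = segments$sample,
                    CHR = segments$chrom, SNP1 = segments$snp1,
                    SNP2 = segments$snp2, POS1 = segments$start,
                    POS2 = segments$end, KB = segments$length_kb,
                    NSNP = segments$nsnp)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a PLINK-style .hom segment table
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `nsnp`, `length_kb` (plus `snp1`/`snp2` marker ids when present).
#' @export
read_hom <- function(path) {
  x <- fread(path, header = TRUE, data.table = FALSE)
  data.frame(sample = as.character(x$IID),
             chrom = normalize_chrom(x$CHR),
             start = as.integer(x$POS1), end = as.integer(x$POS2),
             nsnp = as.integer(x$NSNP), length_kb = as.numeric(x$KB),
             snp1 = if ("SNP1" %in% names(x)) as.character(x$SNP1) else NA,
             snp2 = if ("SNP2" %in% names(x)) as.character(x$SNP2) else NA,
             stringsAsFactors = FALSE)
}

#' Read a pedigree CSV (id, sire, dam, year)
#'
#' @param path file path.
#' @return a `pedigree`.
#' @export
read_pedigree_csv <- function(path) {
  as_pedigree(fread(path, header = TRUE, data.table = FALSE,
                    colClasses = "character"))
}

#' Write a pedigree CSV
#'
#' @param ped a `pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  fwrite(out, path)
  invisible(path)
}
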