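gt_to_class <- function(gt) {
  # genotype string (possibly with :-separated FORMAT fields stripped
  # upstream) to class; any GT containing '.' is missing
  gt <- gsub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gt[known], "/", fixed = TRUE)
  cls <- vapply(alleles, function(a) {
    a <- suppressWarnings(as.integer(a))
    if (length(a) != 2 || any(is.na(a))) return("missing")
    if (all(a == 0)) return("hom_ref")
    if (all(a == a[1])) return("hom_alt")
    "het"
  }, character(1))
  out[known] <- cls
  out
}

class_to_gt <- function(cls) {
  unname(c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
           missing = "./.")[cls])
}

#' Read paired blood-tumor genotype calls from a VCF
#'
#' Reads a VCF 4.x file containing both samples of a patient pair and
#' returns one genotype-pair record per site and alternate allele.
#' Multi-allelic records are decomposed per alternate allele; a
#' heterozygote carrying two different alternate alleles is treated as
#' heterozygous for each. A `CTX` INFO field, when present, supplies the
#' trinucleotide context bin.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param blood,tumor Names of the blood and tumor sample columns.
#' @param sample Patient identifier stored in the output `sample` column;
#'   defaults to the file name without extension.
#' @return Tibble of genotype pairs: `sample`, `contig`, `pos` (1-based),
#'   `ref`, `alt`, `context`, `blood_gt`, `tumor_gt`, `blood_dp`,
#'   `tumor_dp`, `blood_gq`, `tumor_gq`. Malformed records are skipped with
#'   an informative message.
#' @export
read_paired_vcf <- function(path, blood = "BLOOD", tumor = "TUMOR",
                            sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  cols <- colnames(v@gt)
  for (nm in c(blood, tumor)) {
    if (!(nm %in% cols)) {
      abort(paste0("sample column '", nm, "' not found in ", path))
    }
  }
  sample <- sample %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(sample = character(), contig = character(),
                  pos = integer(), ref = character(), alt = character(),
                  context = character(), blood_gt = character(),
                  tumor_gt = character(), blood_dp = integer(),
                  tumor_dp = integer(), blood_gq = integer(),
                  tumor_gq = integer()))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ",
                                          as.numeric = TRUE))
  ctx <- vcfR::extract.info(v, element = "CTX")

  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- is.na(pos) | is.na(fix$REF) | is.na(fix$ALT)
  if (any(bad)) {
    inform(paste0(sum(bad), " malformed record(s) skipped in ",
                  basename(path)))
  }
  keep <- which(!bad)

  col_or_na <- function(m, col) {
    if (is.null(m) || !(col %in% colnames(m))) {
      return(rep(NA_integer_, nrow(fix)))
    }
    as.integer(m[, col])
  }
  blood_dp <- col_or_na(dp, blood); tumor_dp <- col_or_na(dp, tumor)
  blood_gq <- col_or_na(gq, blood); tumor_gq <- col_or_na(gq, tumor)
  if (length(ctx) == 0) ctx <- rep(NA_character_, nrow(fix))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  bi <- keep[!multi[keep]]
  out <- tibble(
    sample = sample, contig = fix$CHROM[bi], pos = pos[bi],
    ref = fix$REF[bi], alt = fix$ALT[bi], context = ctx[bi],
    blood_gt = gt_to_class(gt[bi, blood]),
    tumor_gt = gt_to_class(gt[bi, tumor]),
    blood_dp = blood_dp[bi], tumor_dp = tumor_dp[bi],
    blood_gq = blood_gq[bi], tumor_gq = tumor_gq[bi]
  )
  ma <- keep[multi[keep]]
  if (length(ma) > 0) {
    rows <- lapply(ma, function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      tibble(
        sample = sample, contig = fix$CHROM[i], pos = pos[i],
        ref = fix$REF[i], alt = alts, context = ctx[i],
        blood_gt = gt_for_alt(gt[i, blood], length(alts)),
        tumor_gt = gt_for_alt(gt[i, tumor], length(alts)),
        blood_dp = blood_dp[i], tumor_dp = tumor_dp[i],
        blood_gq = blood_gq[i], tumor_gq = tumor_gq[i]
      )
    })
    out <- arrange(bind_rows(out, bind_rows(rows)), .data$contig,
                   .data$pos)
  }
  out
}

# genotype class of one sample with respect to each alternate allele index
gt_for_alt <- function(gt, n_alt) {
  if (is.na(gt) || grepl("\\.", gt)) return(rep("missing", n_alt))
  a <- suppressWarnings(as.integer(strsplit(gsub("\\|", "/", gt), "/",
                                            fixed = TRUE)[[1]]))
  if (length(a) != 2 || any(is.na(a))) return(rep("missing", n_alt))
  vapply(seq_len(n_alt), function(k) {
    copies <- sum(a == k)
    if (copies == 2) "hom_alt" else if (copies == 1) "het" else "hom_ref"
  }, character(1))
}

#' Read a BED file into a sorted, merged region set
#'
#' @param path BED file (3+ columns, 0-based half-open, no header).
#' @param genome_length Total genome length in bp used to compute the
#'   covered fraction; when `NULL` the fraction attribute is `NA`.
#' @return Region tibble (`contig`, `start`, `end`), sorted with
#'   overlapping or adjacent intervals merged; attribute
#'   `"coverage_fraction"`.
#' @export
read_regions_bed <- function(path, genome_length = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  if (ncol(raw) < 3) abort("BED input needs at least 3 columns")
  bed <- tibble(contig = as.character(raw[[1]]),
                start = as.integer(raw[[2]]),
                end = as.integer(raw[[3]]))
  bad <- which(is.na(bed$start) | is.na(bed$end) | bed$start >= bed$end)
  if (length(bad) > 0) {
    abort(paste0("invalid interval (start >= end) at line ", bad[1],
                 " of ", basename(path)))
  }
  merge_regions(bed, genome_length)
}

merge_regions <- function(bed, genome_length = NULL) {
  out <- bed %>%
    group_by(.data$contig) %>%
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L,
                                            end = d$end))
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) %>%
    ungroup() %>%
    arrange(.data$contig, .data$start)
  attr(out, "coverage_fraction") <-
    if (is.null(genome_length)) NA_real_ else
      sum(out$end - out$start) / genome_length
  out
}

#' Write a region set as BED
#'
#' @param regions Region tibble (`contig`, `start`, `end`).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  readr::write_tsv(regions[, c("contig", "start", "end")], path,
                   col_names = FALSE, na = ".")
  invisible(path)
}

#' Read per-sample CNV window states from a BED-like file
#'
#' @param path 4-column file: contig, start, end (0-based half-open),
#'   state (gain/loss/neutral), no header.
#' @param sample Sample identifier; defaults to the file name.
#' @return Tibble: `sample`, `contig`, `start`, `end`, `state`.
#' @export
read_cnv_bed <- function(path, sample = NULL) {
  raw <- readr::read_tsv(path, col_names = c("contig", "start", "end",
                                             "state"),
                         col_types = "ciic", comment = "#")
  if (!all(raw$state %in% c("gain", "loss", "neutral"))) {
    abort("CNV state column must be gain/loss/neutral")
  }
  sample <- sample %||% sub("\\.(cnv\\.)?bed$", "", basename(path))
  mutate(raw, sample = sample, .before = 1)
}

#' Read a clinical/survival table
#'
#' @param path TSV with header: `sample`, `time_months`,
#'   `event_cancer_specific`, `event_total`, plus clinical covariates.
#'   `'.'` denotes an undefined value.
#' @return Tibble of survival records.
#' @export
read_clinical <- function(path) {
  readr::read_tsv(path, na = c("", "NA", "."), show_col_types = FALSE)
}

#' Serialize a synthetic cohort to standard formats
#'
#' Writes, under `directory`: one two-sample VCF (`BLOOD`, `TUMOR`
#' columns) and one CNV window BED per patient, the clinical table
#' (`clinical.tsv`), the ground-truth ledger (`ground_truth.tsv`), and a
#' `manifest.tsv` listing every file. The files round-trip losslessly
#' through [read_paired_vcf()], [read_cnv_bed()] and [read_clinical()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param directory Output directory (created if needed).
#' @return Tibble manifest: `patient`, `vcf`, `cnv_bed` (paths), invisibly
#'   also written as `manifest.tsv`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort(paste0("cannot create ", directory))
  genome <- cohort$config$toy_genome
  patients <- cohort$clinical$sample
  calls_by <- split(cohort$calls, cohort$calls$sample)
  cnv_by <- split(cohort$cnv, cohort$cnv$sample)
  manifest <- purrr::map_dfr(patients, function(p) {
    vcf_path <- file.path(directory, paste0(p, ".vcf"))
    write_pair_vcf(calls_by[[p]], vcf_path, genome)
    bed_path <- file.path(directory, paste0(p, ".cnv.bed"))
    readr::write_tsv(cnv_by[[p]][, c("contig", "start", "end", "state")],
                     bed_path, col_names = FALSE, na = ".")
    tibble(patient = p, vcf = vcf_path, cnv_bed = bed_path)
  })
  readr::write_tsv(cohort$clinical, file.path(directory, "clinical.tsv"), na = ".")
  readr::write_tsv(cohort$truth, file.path(directory, "ground_truth.tsv"), na = ".")
  readr::write_tsv(manifest, file.path(directory, "manifest.tsv"), na = ".")
  manifest
}

write_pair_vcf <- function(calls, path, genome) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", genome$contig, ",length=", genome$length, ">"),
    paste0("##INFO=<ID=CTX,Number=1,Type=String,",
           "Description=\"Trinucleotide context bin\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
           "Description=\"Genotype quality\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "BLOOD", "TUMOR", sep = "\t")
  )
  if (is.null(calls) || nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  calls <- arrange(calls, .data$contig, .data$pos)
  body <- paste(
    calls$contig, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
    paste0("CTX=", calls$context), "GT:DP:GQ",
    paste0(class_to_gt(calls$blood_gt), ":", calls$blood_dp, ":",
           calls$blood_gq),
    paste0(class_to_gt(calls$tumor_gt), ":", calls$tumor_dp, ":",
           calls$tumor_gq),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a cohort written by [write_cohort()]
#'
#' @param directory Directory holding `manifest.tsv` and the per-patient
#'   files.
#' @return List with `calls`, `cnv`, `clinical`, `truth`, `manifest`.
#' @export
read_cohort <- function(directory) {
  manifest <- readr::read_tsv(file.path(directory, "manifest.tsv"),
                              show_col_types = FALSE)
  calls <- purrr::map2_dfr(manifest$vcf, manifest$patient,
                           function(f, p) read_paired_vcf(f, sample = p))
  cnv <- purrr::map2_dfr(manifest$cnv_bed, manifest$patient,
                         function(f, p) read_cnv_bed(f, sample = p))
  truth_path <- file.path(directory, "ground_truth.tsv")
  list(
    calls = calls,
    cnv = cnv,
    clinical = read_clinical(file.path(directory, "clinical.tsv")),
    truth = if (file.exists(truth_path)) read_clinical(truth_path) else NULL,
    manifest = manifest
  )
}

#' Save / load a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a validated [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$toy_genome <- as.list(x$toy_genome)
  x$cnv_hotspots <- as.list(x$cnv_hotspots)
  x$true_signatures <- list(alpha = unname(x$true_signatures[1, ]),
                            beta = unname(x$true_signatures[2, ]))
  x$marker_coefs <- as.list(x$marker_coefs)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  sig <- rbind(alpha = unlist(x$true_signatures$alpha),
               beta = unlist(x$true_signatures$beta))
  colnames(sig) <- sbs_contexts()
  cohort_config(
    n_patients = x$n_patients,
    toy_genome = tibble(contig = unlist(x$toy_genome$contig),
                        length = unlist(x$toy_genome$length)),
    load_range = unlist(x$load_range),
    low_load_cutoff = x$low_load_cutoff,
    high_load_cutoff = x$high_load_cutoff,
    loh_dominance_slope = x$loh_dominance_slope,
    loh_noise_kappa = x$loh_noise_kappa,
    cn_neutral_loh_target = x$cn_neutral_loh_target,
    cn_neutral_kappa = x$cn_neutral_kappa,
    true_signatures = sig,
    alpha_mixing = unlist(x$alpha_mixing),
    loh_alpha_boost = x$loh_alpha_boost,
    cnv_hotspots = as_tibble(lapply(x$cnv_hotspots, unlist)),
    cnv_background_rate = x$cnv_background_rate,
    marker_coefs = unlist(x$marker_coefs),
    baseline_hazard = x$baseline_hazard,
    other_death_rate = x$other_death_rate,
    censoring_rate = x$censoring_rate,
    seed = x$seed
  )
}
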