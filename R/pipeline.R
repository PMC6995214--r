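#' Configuration for an end-to-end cohort analysis
#'
#' @param input_dir Directory with `manifest.tsv`, per-patient VCFs and CNV
#'   BEDs, and `clinical.tsv` (e.g. from [write_cohort()]).
#' @param output_dir Directory the stage outputs are written to.
#' @param blood_col,tumor_col VCF sample column names of the pair.
#' @param region_sets Optional named list of BED paths; each named subset
#'   is extracted, summarized and its genome-normalized loads reported.
#' @param genome_length Total genome length (bp) for subset coverage
#'   fractions; required when `region_sets` is non-empty.
#' @param min_depth,min_gq Genotype quality filters (see
#'   [classify_somatic()]).
#' @param event_type `"cancer_specific"` (default) or `"total"`.
#' @param min_prop Minimum per-side proportion of the optimal-cutpoint
#'   scan.
#' @param signature_iterations Bootstrap rounds for signature extraction;
#'   the default 100 keeps a desk-scale cohort fast, raise it for
#'   production use.
#' @param n_boot Bootstrap resamples for srCNV clustering (default 1000).
#' @param recurrence_alpha Poisson tail level for recurrent CNVs.
#' @param srcnv_p Log-rank cutoff defining srCNVs.
#' @param seed Seed used by every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            blood_col = "BLOOD", tumor_col = "TUMOR",
                            region_sets = list(), genome_length = NULL,
                            min_depth = 8, min_gq = 20,
                            event_type = "cancer_specific",
                            min_prop = 0.1,
                            signature_iterations = 100,
                            n_boot = 1000,
                            recurrence_alpha = 0.05, srcnv_p = 0.01,
                            seed = 1L) {
  if (!dir.exists(input_dir)) {
    abort(paste0("input directory does not exist: ", input_dir))
  }
  if (length(region_sets) > 0 && is.null(genome_length)) {
    abort("genome_length is required when region_sets are given")
  }
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         blood_col = blood_col, tumor_col = tumor_col,
         region_sets = region_sets, genome_length = genome_length,
         min_depth = min_depth, min_gq = min_gq, event_type = event_type,
         min_prop = min_prop,
         signature_iterations = signature_iterations, n_boot = n_boot,
         recurrence_alpha = recurrence_alpha, srcnv_p = srcnv_p,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name) {
  message(sprintf("[lohstrat] stage: %s", name))
}

#' Run the full genomic-subtyping pipeline
#'
#' Executes, in order: paired-VCF classification into GOH/LOH somatic
#' calls; per-sample mutational summaries (with copy-neutral LOH% from the
#' CNV windows); optional region-subset extraction with genome-normalized
#' loads; two-signature bootstrap-NMF resolution and per-sample alpha%;
#' Poisson recurrent-CNV detection and log-rank srCNV screening; srCNV
#' clustering into Groups H/L; optimal-cutpoint stratifications by SNV
#' load, LOH%, alpha% and copy-neutral LOH% (as a percentage of SNV load);
#' and the joint four-subgroup LOH% x srCNV stratification. Every stage's
#' table is written as TSV under the output directory together with a
#' `run_manifest.tsv` recording stage outputs and seeds; a stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results (`summaries`,
#'   `signature_fit`, `recurrent`, `srcnvs`, `cluster`, `stratifications`,
#'   `manifest`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  with_stage <- function(name, expr) {
    pipeline_stage(name)
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  cohort <- with_stage("read", read_cohort(config$input_dir))
  records <- cohort$clinical
  event_type <- config$event_type

  calls <- with_stage("classify", {
    cl <- classify_somatic(cohort$calls, min_depth = config$min_depth,
                           min_gq = config$min_gq)
    readr::write_tsv(cl, out("somatic_calls.tsv"), na = ".")
    cl
  })

  summaries <- with_stage("summarize", {
    s <- summarize_samples(calls, cohort$cnv)
    readr::write_tsv(s, out("sample_summaries.tsv"), na = ".")
    s
  })

  subset_summaries <- with_stage("subsets", {
    if (length(config$region_sets) == 0) {
      NULL
    } else {
      tabs <- purrr::imap_dfr(config$region_sets, function(bed, nm) {
        regions <- read_regions_bed(bed, config$genome_length)
        frac <- attr(regions, "coverage_fraction")
        sub <- extract_subset(calls, regions)
        summarize_samples(sub, cohort$cnv) %>%
          mutate(region_set = nm, coverage_fraction = frac,
                 normalized_load = normalize_load(.data$snv_load, frac))
      })
      readr::write_tsv(tabs, out("subset_summaries.tsv"), na = ".")
      tabs
    }
  })

  sig_fit <- with_stage("signatures", {
    catalog <- build_catalog(calls, samples = records$sample)
    fit <- extract_signatures(catalog,
                              iterations = config$signature_iterations,
                              seed = config$seed)
    readr::write_tsv(as_tibble(t(fit$signatures), rownames = "context"),
                     out("signatures.tsv"), na = ".")
    readr::write_tsv(tidy(fit), out("signature_exposures.tsv"), na = ".")
    fit
  })

  recurrent <- with_stage("cnv_recurrence", {
    r <- find_recurrent(cohort$cnv, alpha = config$recurrence_alpha)
    readr::write_tsv(r, out("recurrent_cnvs.tsv"), na = ".")
    r
  })

  srcnvs <- with_stage("srcnv", {
    s <- find_srcnvs(recurrent, cohort$cnv, records,
                     p_cut = config$srcnv_p, event_type = event_type)
    readr::write_tsv(s, out("srcnvs.tsv"), na = ".")
    s
  })

  cluster <- with_stage("srcnv_cluster", {
    if (nrow(srcnvs) == 0) {
      NULL
    } else {
      m <- presence_matrix(srcnvs, cohort$cnv, records$sample)
      cl <- cluster_srcnv(m, n_boot = config$n_boot, seed = config$seed)
      readr::write_tsv(tidy(cl), out("srcnv_groups.tsv"), na = ".")
      cl
    }
  })

  strats <- with_stage("stratify", {
    stats <- summaries[match(records$sample, summaries$sample), ]
    markers <- list(
      snv_load = stats$snv_load,
      loh_pct = stats$loh_pct,
      alpha_pct = sig_fit$alpha_pct$alpha_pct[
        match(records$sample, sig_fit$alpha_pct$sample)],
      # copy-neutral LOHs as a percentage of SNV load; 0 for LOH-free samples
      cn_neutral_loh_pct_of_load = ifelse(
        stats$loh_count == 0, 0,
        stats$loh_pct * stats$cn_neutral_loh_pct / 100)
    )
    res <- purrr::imap(markers, function(v, nm) {
      if (any(!is.finite(v))) return(NULL)
      optimal_cutpoint(records, v, min_prop = config$min_prop,
                       event_type = event_type, criterion = nm)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!is.null(cluster)) {
      grp <- cluster$groups$group[match(records$sample,
                                        cluster$groups$sample)]
      lr <- logrank_test(records, grp, event_type = event_type,
                         quiet = TRUE)
      res$srcnv <- new_stratification("srCNV (Group H vs L)", records, grp,
                                      NULL, event_type, lr)
      if (!is.null(res$loh_pct)) {
        res$joint <- joint_stratify(
          records,
          loh_high = res$loh_pct$groups$group == "high",
          srcnv_high = grp == "H",
          event_type = event_type)
      }
    }
    readr::write_tsv(purrr::map_dfr(res, glance), out("stratifications.tsv"),
                     na = ".")
    res
  })

  manifest <- with_stage("manifest", {
    files <- c("somatic_calls.tsv", "sample_summaries.tsv",
               if (!is.null(subset_summaries)) "subset_summaries.tsv",
               "signatures.tsv", "signature_exposures.tsv",
               "recurrent_cnvs.tsv", "srcnvs.tsv",
               if (!is.null(cluster)) "srcnv_groups.tsv",
               "stratifications.tsv")
    m <- tibble(
      stage = c("classify", "summarize",
                if (!is.null(subset_summaries)) "subsets",
                "signatures", "signatures", "cnv_recurrence", "srcnv",
                if (!is.null(cluster)) "srcnv_cluster", "stratify"),
      file = files,
      seed = config$seed
    )
    readr::write_tsv(m, out("run_manifest.tsv"), na = ".")
    m
  })

  invisible(list(
    calls = calls, summaries = summaries,
    subset_summaries = subset_summaries, signature_fit = sig_fit,
    recurrent = recurrent, srcnvs = srcnvs, cluster = cluster,
    stratifications = strats, manifest = manifest,
    output_dir = config$output_dir
  ))
}
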