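#' Classify a blood-tumor genotype pair as GOH, LOH, other or none
#'
#' A somatic SNV is a gain of heterozygosity (GOH) when the blood (germline)
#' genotype is homozygous (for either allele) and the tumor genotype is
#' heterozygous, and a loss of heterozygosity (LOH) when the blood genotype
#' is heterozygous and the tumor genotype is homozygous. Identical genotypes
#' carry no somatic change (`"none"`); a direct homozygote-to-homozygote
#' allele switch is classified `"other"` and excluded from both GOH and LOH
#' counts.
#'
#' @param blood,tumor Character vectors of genotype classes, each one of
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @return Character vector: `"GOH"`, `"LOH"`, `"other"`, `"none"`, or `NA`
#'   where either genotype is missing.
#' @export
#' @examples
#' classify_somatic_pair("het", "hom_alt") # LOH
#' classify_somatic_pair("hom_ref", "het") # GOH
classify_somatic_pair <- function(blood, tumor) {
  classes <- c("hom_ref", "het", "hom_alt", "missing")
  bad <- !(blood %in% classes) | !(tumor %in% classes)
  if (any(bad)) {
    abort("genotype classes must be one of hom_ref, het, hom_alt, missing")
  }
  hom <- c("hom_ref", "hom_alt")
  out <- rep(NA_character_, length(blood))
  known <- blood != "missing" & tumor != "missing"
  out[known & blood == tumor] <- "none"
  out[known & blood %in% hom & tumor == "het"] <- "GOH"
  out[known & blood == "het" & tumor %in% hom] <- "LOH"
  out[known & blood %in% hom & tumor %in% hom & blood != tumor] <- "other"
  out
}

#' Classify paired genotype calls and annotate substitution contexts
#'
#' Applies quality filters, classifies every call via
#' [classify_somatic_pair()], and annotates the pyrimidine-strand
#' substitution type, the 96-bin trinucleotide context, and the transition
#' flag. Calls with a missing genotype or failing a filter are dropped from
#' the classified output, with the per-reason counts reported as the
#' `"dropped"` attribute rather than an error.
#'
#' @param pairs Tibble of genotype pairs with columns `sample`, `contig`,
#'   `pos` (1-based), `ref`, `alt`, `blood_gt`, `tumor_gt`, and optionally
#'   `context` (96-bin label) or flanking bases `up`/`down`, plus quality
#'   columns `blood_dp`, `tumor_dp`, `blood_gq`, `tumor_gq`.
#' @param min_depth,min_gq Minimum per-sample read depth and genotype
#'   quality; calls lacking the quality columns are not depth/quality
#'   filtered.
#' @return Tibble of somatic calls (rows with `somatic_class` in GOH, LOH,
#'   other) with added columns `somatic_class`, `substitution`, `context`,
#'   `is_transition`; attribute `"dropped"` holds a tibble of exclusion
#'   reasons and counts.
#' @export
classify_somatic <- function(pairs, min_depth = 8, min_gq = 20) {
  pairs <- as_tibble(pairs)
  need <- c("sample", "contig", "pos", "ref", "alt", "blood_gt", "tumor_gt")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("pairs is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  drop_reason <- rep(NA_character_, nrow(pairs))
  miss <- pairs$blood_gt == "missing" | pairs$tumor_gt == "missing"
  drop_reason[miss] <- "missing_genotype"
  if (all(c("blood_dp", "tumor_dp") %in% names(pairs))) {
    low <- !miss & (pairs$blood_dp < min_depth | pairs$tumor_dp < min_depth)
    drop_reason[low & is.na(drop_reason)] <- "low_depth"
  }
  if (all(c("blood_gq", "tumor_gq") %in% names(pairs))) {
    lowq <- !miss & (pairs$blood_gq < min_gq | pairs$tumor_gq < min_gq)
    drop_reason[lowq & is.na(drop_reason)] <- "low_genotype_quality"
  }

  keep <- is.na(drop_reason)
  calls <- pairs[keep, , drop = FALSE]
  calls$somatic_class <- classify_somatic_pair(calls$blood_gt, calls$tumor_gt)
  no_change <- calls$somatic_class == "none"
  n_none <- sum(no_change)
  calls <- calls[!no_change, , drop = FALSE]

  if ("context" %in% names(calls)) {
    parts <- parse_context(calls$context)
    calls$substitution <- parts$substitution
    calls$is_transition <- calls$substitution %in% c("C>T", "T>C")
  } else if (all(c("up", "down") %in% names(calls))) {
    ann <- normalize_substitution(calls$ref, calls$alt, calls$up, calls$down)
    calls$substitution <- ann$substitution
    calls$context <- ann$context
    calls$is_transition <- ann$is_transition
  } else {
    ann <- normalize_substitution(calls$ref, calls$alt,
                                  rep("N", nrow(calls)), rep("N", nrow(calls)))
    calls$substitution <- ifelse(calls$ref %in% c("A", "G"),
                                 paste0(revcomp_base(calls$ref), ">",
                                        revcomp_base(calls$alt)),
                                 paste0(calls$ref, ">", calls$alt))
    calls$context <- NA_character_
    calls$is_transition <- calls$substitution %in% c("C>T", "T>C")
  }

  dropped <- tibble(reason = drop_reason[!keep]) %>%
    count(.data$reason, name = "n")
  if (n_none > 0) {
    dropped <- bind_rows(dropped, tibble(reason = "no_somatic_change",
                                         n = n_none))
  }
  attr(calls, "dropped") <- dropped
  calls
}

#' Per-sample mutational summaries
#'
#' Computes, for every sample, the SNV load and its GOH/LOH constituents,
#' LOH% (LOH count as a percentage of SNV load), the copy-neutral LOH%
#' (percentage of LOH calls falling in copy-number-neutral windows), and the
#' transition percentages among GOHs and LOHs separately. The SNV load is
#' `goh_count + loh_count + other_count`, so either load convention can be
#' recovered from the reported components.
#'
#' @param calls Tibble of classified somatic calls (from
#'   [classify_somatic()]): columns `sample`, `contig`, `pos`,
#'   `somatic_class`, `is_transition`.
#' @param cnv_windows Optional tibble of per-sample CNV window states
#'   (`sample`, `contig`, `start`, `end` 0-based half-open, `state` in
#'   gain/loss/neutral). When omitted, `cn_neutral_loh_pct` is `NA`. LOH
#'   calls in windows absent from a sample's grid count as neutral.
#' @return Tibble with one row per sample: `snv_load`, `goh_count`,
#'   `loh_count`, `other_count`, `loh_pct`, `cn_neutral_loh_pct`,
#'   `transition_pct_goh`, `transition_pct_loh`. Percentages are `NA` when
#'   their denominator is zero.
#' @export
summarize_samples <- function(calls, cnv_windows = NULL) {
  calls <- as_tibble(calls)
  base <- calls %>%
    group_by(sample = .data$sample) %>%
    summarise(
      snv_load = dplyr::n(),
      goh_count = sum(.data$somatic_class == "GOH"),
      loh_count = sum(.data$somatic_class == "LOH"),
      other_count = sum(.data$somatic_class == "other"),
      transition_pct_goh = pct(sum(.data$somatic_class == "GOH" &
                                     .data$is_transition),
                               sum(.data$somatic_class == "GOH")),
      transition_pct_loh = pct(sum(.data$somatic_class == "LOH" &
                                     .data$is_transition),
                               sum(.data$somatic_class == "LOH")),
      .groups = "drop"
    ) %>%
    mutate(loh_pct = pct(.data$loh_count, .data$snv_load))

  if (is.null(cnv_windows)) {
    base$cn_neutral_loh_pct <- NA_real_
  } else {
    loh <- calls %>% filter(.data$somatic_class == "LOH")
    neutral <- count_in_neutral(loh, as_tibble(cnv_windows))
    base <- left_join(base, neutral, by = "sample") %>%
      mutate(cn_neutral_loh_pct = pct(
        ifelse(is.na(.data$n_neutral), 0L, .data$n_neutral),
        .data$loh_count
      )) %>%
      select(-dplyr::any_of("n_neutral"))
  }
  base %>%
    select("sample", "snv_load", "goh_count", "loh_count", "other_count",
           "loh_pct", "cn_neutral_loh_pct",
           "transition_pct_goh", "transition_pct_loh")
}

pct <- function(num, den) {
  ifelse(den > 0, 100 * num / den, NA_real_)
}

# count LOH calls per sample that fall in a non-neutral (gain/loss) window;
# calls outside any listed window are treated as copy neutral
count_in_neutral <- function(loh, cnv_windows) {
  if (nrow(loh) == 0) {
    return(tibble(sample = character(), n_neutral = integer()))
  }
  altered <- cnv_windows %>% filter(.data$state != "neutral")
  loh$.in_altered <- FALSE
  if (nrow(altered) > 0) {
    key_l <- paste(loh$sample, loh$contig)
    key_a <- paste(altered$sample, altered$contig)
    for (k in intersect(unique(key_l), unique(key_a))) {
      li <- which(key_l == k)
      ai <- which(key_a == k)
      q <- IRanges::IRanges(start = loh$pos[li], width = 1L) # 1-based point
      s <- IRanges::IRanges(start = altered$start[ai] + 1L,
                            end = altered$end[ai])
      loh$.in_altered[li] <- IRanges::overlapsAny(q, s)
    }
  }
  loh %>%
    group_by(sample = .data$sample) %>%
    summarise(n_neutral = sum(!.data$.in_altered), .groups = "drop")
}

#' Restrict somatic calls to a region subset
#'
#' Keeps exactly the calls whose (1-based) position falls inside one of the
#' half-open, 0-based intervals of a region set, mirroring the extraction of
#' exome-like or inter-Alu-amplifiable subsets from whole-genome calls.
#' Calls on contigs absent from the region set are excluded.
#'
#' @param calls Tibble of calls with columns `contig`, `pos` (1-based).
#' @param regions Region tibble with columns `contig`, `start`, `end`
#'   (0-based half-open), e.g. from [read_regions_bed()] or
#'   [derive_subset_regions()].
#' @return The subset of `calls`, rows in their original order.
#' @export
extract_subset <- function(calls, regions) {
  calls <- as_tibble(calls)
  regions <- as_tibble(regions)
  if (nrow(calls) == 0 || nrow(regions) == 0) {
    return(calls[integer(0), , drop = FALSE])
  }
  keep <- logical(nrow(calls))
  for (ctg in intersect(unique(calls$contig), unique(regions$contig))) {
    ci <- which(calls$contig == ctg)
    ri <- which(regions$contig == ctg)
    q <- IRanges::IRanges(start = calls$pos[ci], width = 1L)
    s <- IRanges::IRanges(start = regions$start[ri] + 1L,
                          end = regions$end[ri])
    keep[ci] <- IRanges::overlapsAny(q, s)
  }
  calls[keep, , drop = FALSE]
}

#' Rescale a subset SNV count to a genome-equivalent load
#'
#' A count observed in a region subset covering a fraction of the genome is
#' scaled to a per-genome load by dividing by the covered fraction (e.g. 445
#' SNVs in a subset covering 2.14% of the genome scale to
#' `445 / 0.0214 = 20,794` per genome).
#'
#' @param subset_count Non-negative SNV count(s) observed in the subset.
#' @param coverage_fraction Fraction of the genome the subset covers, in
#'   (0, 1].
#' @return Genome-equivalent load, rounded to the nearest integer.
#' @export
#' @examples
#' normalize_load(445, 0.0214)
normalize_load <- function(subset_count, coverage_fraction) {
  if (any(!is.finite(coverage_fraction)) || any(coverage_fraction <= 0)) {
    abort("coverage_fraction must be > 0")
  }
  if (any(subset_count < 0)) {
    abort("subset_count must be non-negative")
  }
  round(subset_count / coverage_fraction)
}

#' Derive an empirically covered region subset from per-sample depth tracks
#'
#' Emulates the definition of an amplifiable subset: per sample, runs with
#' read depth at least `min_depth` are retained and runs separated by gaps
#' shorter than `max_gap` are merged; the subset is the intersection of the
#' merged regions across all samples.
#'
#' @param tracks Tibble of depth runs: columns `sample`, `contig`, `start`,
#'   `end` (0-based half-open), `depth`.
#' @param genome Tibble with columns `contig`, `length` (bp) defining the
#'   genome against which `coverage_fraction` is computed.
#' @param min_depth Minimum read depth of a retained run (default 4).
#' @param max_gap Gaps of this many bp or more are not bridged (default 80).
#' @return Region tibble (`contig`, `start`, `end`), sorted and
#'   non-overlapping, with attribute `"coverage_fraction"`.
#' @export
derive_subset_regions <- function(tracks, genome, min_depth = 4,
                                  max_gap = 80) {
  tracks <- as_tibble(tracks)
  genome <- as_tibble(genome)
  samples <- unique(tracks$sample)
  if (length(samples) == 0 || nrow(tracks) == 0) {
    warn("no coverage tracks supplied; returning an empty region set")
    return(empty_regions())
  }
  out <- list()
  for (ctg in genome$contig) {
    per_sample <- lapply(samples, function(s) {
      t <- tracks %>%
        filter(.data$sample == s, .data$contig == ctg,
               .data$depth >= min_depth)
      if (nrow(t) == 0) return(IRanges::IRanges())
      IRanges::reduce(IRanges::IRanges(start = t$start + 1L, end = t$end),
                      min.gapwidth = max_gap)
    })
    inter <- Reduce(IRanges::intersect, per_sample)
    if (length(inter) > 0) {
      out[[ctg]] <- tibble(contig = ctg,
                           start = IRanges::start(inter) - 1L,
                           end = IRanges::end(inter))
    }
  }
  regions <- if (length(out) > 0) bind_rows(out) else empty_regions()
  if (nrow(regions) == 0) {
    warn("depth/gap criteria left no shared regions")
  }
  attr(regions, "coverage_fraction") <-
    sum(regions$end - regions$start) / sum(genome$length)
  regions
}

empty_regions <- function() {
  r <- tibble(contig = character(), start = integer(), end = integer())
  attr(r, "coverage_fraction") <- 0
  r
}

#' Tally GOH/LOH calls by named region class
#'
#' Assigns every call to the first region class (in the order given) whose
#' intervals contain it, or to `"unclassified"`, and reports per-class GOH
#' and LOH counts and the LOH/GOH ratio. This supports comparisons across
#' genomic zone or replication-timing annotations.
#'
#' @param calls Classified somatic calls (columns `contig`, `pos`,
#'   `somatic_class`).
#' @param classes Named list of region tibbles (`contig`, `start`, `end`,
#'   0-based half-open); classes may overlap, earlier names take precedence.
#' @return Tibble with one row per class (plus `"unclassified"`):
#'   `region_class`, `goh_count`, `loh_count`, `loh_goh_ratio` (`NA` when
#'   the GOH count is zero).
#' @export
annotate_by_region_class <- function(calls, classes) {
  calls <- as_tibble(calls)
  label <- rep("unclassified", nrow(calls))
  for (nm in rev(names(classes))) {
    inside <- rep(FALSE, nrow(calls))
    sub <- extract_subset(mutate(calls, .row = dplyr::row_number()),
                          classes[[nm]])
    inside[sub$.row] <- TRUE
    label[inside] <- nm
  }
  lev <- c(names(classes), "unclassified")
  tibble(region_class = factor(label, levels = lev),
         somatic_class = calls$somatic_class) %>%
    group_by(.data$region_class, .drop = FALSE) %>%
    summarise(goh_count = sum(.data$somatic_class == "GOH"),
              loh_count = sum(.data$somatic_class == "LOH"),
              .groups = "drop") %>%
    mutate(region_class = as.character(.data$region_class),
           loh_goh_ratio = ifelse(.data$goh_count > 0,
                                  .data$loh_count / .data$goh_count,
                                  NA_real_))
}
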