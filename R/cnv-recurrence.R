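#' Partition a genome into fixed-size CNV windows
#'
#' @param genome Tibble with columns `contig`, `length` (bp).
#' @param window_size Window width in bp (default 350 kb); the final window
#'   of each contig keeps the remainder.
#' @return Tibble of windows: `contig`, `start`, `end` (0-based half-open),
#'   `window_id`.
#' @export
#' @examples
#' windowize(tibble::tibble(contig = "chr1", length = 1e6))
windowize <- function(genome, window_size = 350000) {
  genome <- as_tibble(genome)
  if (any(genome$length <= 0)) abort("contig lengths must be positive")
  purrr::pmap_dfr(genome, function(contig, length, ...) {
    starts <- seq(0, length - 1, by = window_size)
    tibble(contig = contig, start = starts,
           end = pmin(starts + window_size, length))
  }) %>%
    mutate(window_id = paste0(.data$contig, ":", .data$start, "-",
                              .data$end))
}

#' Poisson recurrence cutoff for CNV carrier counts
#'
#' Fits a Poisson null to the per-window carrier counts (lambda = mean
#' count over all windows) and returns the smallest integer count whose
#' upper-tail probability falls below `alpha`; windows carrying at least
#' that many samples are called recurrent.
#'
#' @param per_window_counts Non-negative integer vector of carrier counts,
#'   one per window (zero-count windows included).
#' @param n_samples Cohort size, used to express the cutoff as a frequency.
#' @param alpha Tail significance level (default 0.05).
#' @return List with `lambda`, `count_cutoff` (smallest c with
#'   `P(X >= c) < alpha`), and `freq_cutoff = count_cutoff / n_samples`
#'   (`NA` when `n_samples` is missing).
#' @export
#' @examples
#' recurrence_threshold(c(rep(0, 50), rep(2, 50)), n_samples = 100)
recurrence_threshold <- function(per_window_counts, n_samples = NULL,
                                 alpha = 0.05) {
  if (length(per_window_counts) == 0) abort("at least one window is required")
  if (any(per_window_counts < 0)) abort("carrier counts must be >= 0")
  lambda <- mean(per_window_counts)
  if (lambda == 0) {
    warn("all carrier counts are zero; count cutoff defaults to 1")
    cutoff <- 1L
  } else {
    # P(X >= c) = ppois(c - 1, lambda, lower.tail = FALSE)
    cutoff <- 1L
    while (ppois(cutoff - 1, lambda, lower.tail = FALSE) >= alpha) {
      cutoff <- cutoff + 1L
    }
  }
  list(lambda = lambda, count_cutoff = cutoff,
       freq_cutoff = if (is.null(n_samples)) NA_real_ else
         cutoff / n_samples)
}

check_shared_grid <- function(cnv_calls) {
  grids <- cnv_calls %>%
    group_by(.data$sample) %>%
    summarise(key = paste(sort(paste0(.data$contig, ":", .data$start, "-",
                                      .data$end)), collapse = ";"),
              .groups = "drop")
  if (length(unique(grids$key)) > 1) {
    abort("samples are on mismatched window grids")
  }
  invisible(TRUE)
}

#' Identify recurrent CNVs across a cohort
#'
#' Counts, for every window and direction, the samples carrying a gain
#' (resp. loss) in that window, and retains the windows whose carrier count
#' reaches the direction-specific Poisson cutoff from
#' [recurrence_threshold()]. Gains and losses get separate null rates, as
#' their genome-wide abundances differ.
#'
#' @param cnv_calls Tibble of per-sample window states: `sample`, `contig`,
#'   `start`, `end`, `state` (gain/loss/neutral), all samples on one grid.
#' @param alpha Poisson tail level (default 0.05).
#' @return Tibble of recurrent CNVs: window coordinates, `direction`,
#'   `carrier_count`, `frequency`, `recurrence_p` (the Poisson tail at the
#'   observed count); attribute `"thresholds"` holds the per-direction
#'   cutoffs.
#' @export
find_recurrent <- function(cnv_calls, alpha = 0.05) {
  cnv_calls <- as_tibble(cnv_calls)
  check_shared_grid(cnv_calls)
  n_samples <- length(unique(cnv_calls$sample))
  grid <- distinct(cnv_calls, .data$contig, .data$start, .data$end) %>%
    arrange(.data$contig, .data$start)

  out <- list()
  thresholds <- list()
  for (dir in c("gain", "loss")) {
    counts <- cnv_calls %>%
      filter(.data$state == dir) %>%
      count(.data$contig, .data$start, .data$end, name = "carrier_count")
    counts <- left_join(grid, counts,
                        by = c("contig", "start", "end")) %>%
      mutate(carrier_count = ifelse(is.na(.data$carrier_count), 0L,
                                    .data$carrier_count))
    thr <- recurrence_threshold(counts$carrier_count, n_samples, alpha)
    thresholds[[dir]] <- thr
    out[[dir]] <- counts %>%
      filter(.data$carrier_count >= thr$count_cutoff) %>%
      mutate(direction = dir,
             frequency = .data$carrier_count / n_samples,
             recurrence_p = ppois(.data$carrier_count - 1, thr$lambda,
                                  lower.tail = FALSE))
  }
  res <- bind_rows(out) %>%
    select("contig", "start", "end", "direction", "carrier_count",
           "frequency", "recurrence_p") %>%
    arrange(.data$contig, .data$start, .data$direction)
  attr(res, "thresholds") <- thresholds
  attr(res, "n_samples") <- n_samples
  res
}

#' Screen recurrent CNVs for survival association (srCNVs)
#'
#' For every recurrent CNV, splits the cohort into carriers (samples with
#' the same direction state in the same window) and non-carriers and
#' compares their survival by the two-group log-rank test; recurrent CNVs
#' with p below `p_cut` are survival-associated recurrent CNVs. CNVs
#' carried by every sample or by none are skipped and reported in the
#' `"skipped"` attribute.
#'
#' @param recurrent Output of [find_recurrent()].
#' @param cnv_calls The per-sample window states the recurrence was called
#'   from.
#' @param records Survival tibble with columns `sample`, `time_months`, and
#'   the event column selected by `event_type`.
#' @param p_cut Log-rank significance cutoff (default 0.01).
#' @param event_type `"cancer_specific"` (default) or `"total"` deaths.
#' @return Tibble of srCNVs: the recurrent-CNV columns plus `logrank_p`.
#' @export
find_srcnvs <- function(recurrent, cnv_calls, records, p_cut = 0.01,
                        event_type = c("cancer_specific", "total")) {
  event_type <- match.arg(event_type)
  recurrent <- as_tibble(recurrent)
  if (nrow(recurrent) == 0) {
    return(mutate(recurrent, logrank_p = numeric(0)))
  }
  records <- as_tibble(records)
  samples <- records$sample
  pres <- presence_matrix(recurrent, cnv_calls, samples)
  ps <- rep(NA_real_, nrow(recurrent))
  skipped <- integer(0)
  for (i in seq_len(nrow(recurrent))) {
    carrier <- pres[, i] == 1
    if (all(carrier) || !any(carrier)) {
      skipped <- c(skipped, i)
      next
    }
    lr <- logrank_test(records, ifelse(carrier, "carrier", "non-carrier"),
                       event_type = event_type, quiet = TRUE)
    ps[i] <- lr$p
  }
  if (length(skipped) > 0) {
    inform(paste0(length(skipped),
                  " recurrent CNV(s) skipped (carried by all or no samples)"))
  }
  res <- recurrent %>%
    mutate(logrank_p = ps) %>%
    filter(!is.na(.data$logrank_p), .data$logrank_p < p_cut)
  attr(res, "skipped") <- recurrent[skipped, , drop = FALSE]
  res
}

#' Binary sample-by-srCNV presence matrix
#'
#' @param srcnvs Tibble of (sr)CNVs with `contig`, `start`, `end`,
#'   `direction`.
#' @param cnv_calls Per-sample window states.
#' @param samples Character vector fixing row order.
#' @return Binary matrix, samples by srCNVs (columns named
#'   `contig:start-end:direction`); entry 1 iff the sample has the srCNV's
#'   direction state in its window.
#' @export
presence_matrix <- function(srcnvs, cnv_calls, samples = NULL) {
  srcnvs <- as_tibble(srcnvs)
  cnv_calls <- as_tibble(cnv_calls)
  if (is.null(samples)) samples <- sort(unique(cnv_calls$sample))
  key_cnv <- paste0(cnv_calls$contig, ":", cnv_calls$start, "-",
                    cnv_calls$end, ":", cnv_calls$state)
  key_sr <- paste0(srcnvs$contig, ":", srcnvs$start, "-", srcnvs$end, ":",
                   srcnvs$direction)
  m <- matrix(0L, nrow = length(samples), ncol = nrow(srcnvs),
              dimnames = list(samples, key_sr))
  carried <- cnv_calls[key_cnv %in% key_sr, , drop = FALSE]
  if (nrow(carried) > 0) {
    idx <- cbind(match(carried$sample, samples),
                 match(paste0(carried$contig, ":", carried$start, "-",
                              carried$end, ":", carried$state), key_sr))
    idx <- idx[!is.na(idx[, 1]) & !is.na(idx[, 2]), , drop = FALSE]
    m[idx] <- 1L
  }
  m
}

#' Merge adjacent recurrent windows of the same direction
#'
#' Recurrent CNVs are reported window by window; this utility collapses
#' runs of adjacent same-direction windows into single spans for display.
#'
#' @param recurrent Tibble from [find_recurrent()] or [find_srcnvs()].
#' @return Tibble with merged `contig`, `start`, `end`, `direction`,
#'   `n_windows`.
#' @export
merge_recurrent <- function(recurrent) {
  recurrent %>%
    arrange(.data$direction, .data$contig, .data$start) %>%
    group_by(.data$direction, .data$contig) %>%
    mutate(new_run = cumsum(
      dplyr::lag(.data$end, default = dplyr::first(.data$start)) !=
        .data$start)) %>%
    group_by(.data$direction, .data$contig, .data$new_run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = dplyr::n(), .groups = "drop") %>%
    select("contig", "start", "end", "direction", "n_windows")
}

#' Minimal log-ratio CNV caller for paired window read counts
#'
#' A convenience caller, not the canonical read-depth algorithm the window
#' states are normally produced with: the log2 ratio of tumor to blood
#' window read counts (each scaled to its sample total) is thresholded at
#' a fixed +/- 0.25 to call gains and losses.
#'
#' @param window_counts Tibble: `sample`, `contig`, `start`, `end`,
#'   `blood_reads`, `tumor_reads`.
#' @param threshold Absolute log2-ratio cutoff (default 0.25).
#' @return Tibble of window states (`sample`, `contig`, `start`, `end`,
#'   `state`); windows with zero reads in either sample are `neutral`.
#' @export
call_cnv_from_counts <- function(window_counts, threshold = 0.25) {
  wc <- as_tibble(window_counts)
  wc %>%
    group_by(.data$sample) %>%
    mutate(
      .bf = .data$blood_reads / sum(.data$blood_reads),
      .tf = .data$tumor_reads / sum(.data$tumor_reads),
      .lr = ifelse(.data$blood_reads > 0 & .data$tumor_reads > 0,
                   log2(.data$.tf / .data$.bf), 0),
      state = dplyr::case_when(
        .data$.lr >= threshold ~ "gain",
        .data$.lr <= -threshold ~ "loss",
        TRUE ~ "neutral"
      )
    ) %>%
    ungroup() %>%
    select("sample", "contig", "start", "end", "state")
}
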