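# small deterministic fixtures shared across test files

small_config <- function(n = 20, seed = 101, ...) {
  cohort_config(n_patients = n, load_range = c(300, 8000), seed = seed, ...)
}

# hand-sized survival table: times, events, and an id column
surv_fixture <- function(time, event_cs, event_total = event_cs) {
  tibble::tibble(
    sample = sprintf("S%02d", seq_along(time)),
    time_months = time,
    event_cancer_specific = event_cs,
    event_total = event_total
  )
}

# random classified somatic calls on a toy genome (for loop-oracle tests)
random_calls <- function(n, seed, contigs = c("chr1", "chr2"),
                         contig_len = 10000) {
  set.seed(seed)
  bins <- sbs_contexts()
  tibble::tibble(
    sample = sample(c("A", "B", "C"), n, replace = TRUE),
    contig = sample(contigs, n, replace = TRUE),
    pos = sample.int(contig_len, n, replace = TRUE),
    somatic_class = sample(c("GOH", "LOH", "other"), n, replace = TRUE,
                           prob = c(0.45, 0.45, 0.1)),
    context = sample(bins, n, replace = TRUE),
    is_transition = NA
  ) |>
    dplyr::mutate(is_transition = grepl("C>T|T>C", context))
}

# vectorized two-group log-rank chi-square computed from first principles,
# for permutation-null oracles: g01 is an n x P matrix of 0/1 labels
logrank_chisq_perm <- function(time, event, g01) {
  times <- sort(unique(time[event == 1]))
  P <- ncol(g01)
  o_minus_e <- numeric(P)
  v <- numeric(P)
  for (t in times) {
    at_risk <- time >= t
    dead <- time == t & event == 1
    n_t <- sum(at_risk)
    d_t <- sum(dead)
    n1 <- colSums(g01[at_risk, , drop = FALSE])
    d1 <- colSums(g01[dead, , drop = FALSE])
    o_minus_e <- o_minus_e + d1 - d_t * n1 / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  ifelse(v > 0, o_minus_e^2 / v, 0)
}
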