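event_column <- function(event_type = c("cancer_specific", "total")) {
  event_type <- match.arg(event_type)
  paste0("event_", event_type)
}

surv_from_records <- function(records,
                              event_type = c("cancer_specific", "total")) {
  records <- as_tibble(records)
  col <- event_column(event_type)
  if (!all(c("sample", "time_months", col) %in% names(records))) {
    abort(paste0("records must have columns sample, time_months, ", col))
  }
  if (any(!is.finite(records$time_months)) || any(records$time_months <= 0)) {
    abort("survival times must be positive and finite")
  }
  ev <- records[[col]]
  if (!all(ev %in% c(0, 1))) abort("event indicators must be 0/1")
  survival::Surv(records$time_months, ev)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function, optionally per group.
#'
#' @param records Survival tibble: `sample`, `time_months` (> 0), and 0/1
#'   event columns `event_cancer_specific` / `event_total`.
#' @param group Optional vector of group labels aligned with `records`.
#' @param event_type Which death indicator to use (default cancer-specific).
#' @return Tibble of class `km_curve`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`. `S(0) = 1` is implicit; rows appear at
#'   observed times.
#' @export
km_estimate <- function(records, group = NULL,
                        event_type = c("cancer_specific", "total")) {
  event_type <- match.arg(event_type)
  s <- surv_from_records(records, event_type)
  records <- as_tibble(records)
  if (is.null(group)) group <- rep("all", nrow(records))
  g <- factor(group)
  out <- purrr::map_dfr(levels(g), function(lv) {
    fit <- survival::survfit(s[g == lv, ] ~ 1)
    tibble(group = lv, time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, n_censor = fit$n.censor,
           surv = fit$surv)
  })
  class(out) <- c("km_curve", class(out))
  out
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square comparing the survival of two or more
#' groups, with hypergeometric variance under tied death times. With zero
#' events the test carries no information: the statistic is 0 and p = 1,
#' with a warning.
#'
#' @inheritParams km_estimate
#' @param group Vector of group labels (>= 2 non-empty groups).
#' @param quiet Suppress the zero-event warning (used by callers that
#'   screen many contrasts).
#' @return List with `statistic` (chi-square), `df` (groups - 1), `p`, and
#'   the per-group observed/expected table `table`.
#' @export
logrank_test <- function(records, group,
                         event_type = c("cancer_specific", "total"),
                         quiet = FALSE) {
  event_type <- match.arg(event_type)
  records <- as_tibble(records)
  g <- factor(group)
  if (nlevels(g) < 2) abort("at least two non-empty groups are required")
  if (length(group) != nrow(records)) {
    abort("group labels and records are misaligned")
  }
  s <- surv_from_records(records, event_type)
  ev <- records[[event_column(event_type)]]
  if (sum(ev) == 0) {
    if (!quiet) warn("no events observed; log-rank p set to 1")
    return(list(statistic = 0, df = nlevels(g) - 1L, p = 1,
                table = tibble(group = levels(g),
                               n = as.integer(table(g)),
                               observed = 0, expected = 0)))
  }
  sd <- survival::survdiff(s ~ g)
  df <- nlevels(g) - 1L
  list(
    statistic = unname(sd$chisq),
    df = df,
    p = pchisq(sd$chisq, df = df, lower.tail = FALSE),
    table = tibble(group = levels(g), n = as.integer(sd$n),
                   observed = unname(sd$obs), expected = unname(sd$exp))
  )
}

new_stratification <- function(criterion, records, group, cutpoint,
                               event_type, lr) {
  records <- as_tibble(records)
  ev <- records[[event_column(event_type)]]
  per_group <- tibble(group = as.character(group), event = ev) %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), deaths = sum(.data$event), .groups = "drop")
  structure(
    list(
      criterion = criterion,
      groups = tibble(sample = records$sample, group = as.character(group)),
      cutpoint = cutpoint,
      statistic = lr$statistic, df = lr$df, p = lr$p,
      per_group = per_group,
      km = km_estimate(records, group, event_type = event_type),
      event_type = event_type
    ),
    class = "stratification"
  )
}

#' @export
print.stratification <- function(x, ...) {
  cat("Survival stratification by ", x$criterion, sep = "")
  if (!is.null(x$cutpoint) && !is.na(x$cutpoint)) {
    cat(" (cutpoint = ", format(x$cutpoint), ")", sep = "")
  }
  cat("\n  log-rank chi-square = ", sprintf("%.3f", x$statistic),
      " on ", x$df, " df, p = ", format.pval(x$p, digits = 3), "\n",
      sep = "")
  info <- paste0(x$per_group$group, ": ", x$per_group$deaths, "/",
                 x$per_group$n)
  cat("  deaths/total -", paste(info, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.stratification <- function(x, ...) x$groups

#' @export
glance.stratification <- function(x, ...) {
  tibble(criterion = x$criterion,
         cutpoint = x$cutpoint %||% NA_real_,
         statistic = x$statistic, df = x$df, p = x$p,
         n_groups = nrow(x$per_group), event_type = x$event_type)
}

#' Optimal-cutpoint survival stratification of a continuous marker
#'
#' Dichotomizes a per-sample marker (SNV load, LOH%, signature-alpha %,
#' ...) at the cutpoint that minimizes the two-group log-rank p-value.
#' Candidate cutpoints are midpoints between consecutive distinct marker
#' values such that both resulting groups keep at least a `min_prop` share
#' of the cohort; the "low" group has marker values at or below the
#' cutpoint. Ties in p are broken toward the lower cutpoint. The reported
#' p is the naive minimum over the scan (no maximally-selected-statistic
#' correction), matching common optimal-cutpoint practice.
#'
#' @inheritParams km_estimate
#' @param values Numeric marker values aligned with `records`.
#' @param min_prop Minimum proportion of samples on each side (default
#'   0.1).
#' @param criterion Name recorded in the result (default the expression
#'   passed as `values`).
#' @return Object of class `stratification` with fields `groups`,
#'   `cutpoint`, `statistic`, `df`, `p`, `per_group`, and Kaplan-Meier
#'   curves; see [tidy()] / [glance()].
#' @export
optimal_cutpoint <- function(records, values, min_prop = 0.1,
                             event_type = c("cancer_specific", "total"),
                             criterion = NULL) {
  event_type <- match.arg(event_type)
  criterion <- criterion %||% deparse(substitute(values))
  records <- as_tibble(records)
  if (length(values) != nrow(records)) {
    abort("values and records are misaligned")
  }
  if (any(!is.finite(values))) abort("marker values must be finite")
  sv <- sort(unique(values))
  if (length(sv) < 2) abort("no admissible cutpoint: marker is constant")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  n <- length(values)
  n_low <- vapply(cand, function(cp) sum(values <= cp), numeric(1))
  ok <- n_low >= min_prop * n & (n - n_low) >= min_prop * n
  cand <- cand[ok]
  if (length(cand) == 0) {
    abort("no admissible cutpoint: min_prop constraint leaves no candidate")
  }
  ps <- vapply(cand, function(cp) {
    logrank_test(records, ifelse(values <= cp, "low", "high"),
                 event_type = event_type, quiet = TRUE)$p
  }, numeric(1))
  best <- cand[which.min(ps)]       # which.min takes the first (lowest) tie
  grp <- ifelse(values <= best, "low", "high")
  lr <- logrank_test(records, grp, event_type = event_type, quiet = TRUE)
  res <- new_stratification(criterion, records, grp, best, event_type, lr)
  res$scan <- tibble(cutpoint = cand, p = ps)
  res
}

#' Cluster samples into high- and low-srCNV groups
#'
#' Hierarchically clusters samples on their binary srCNV presence profiles
#' (Ward linkage on Euclidean distance) and cuts the tree at the root into
#' two clusters; the cluster with the higher mean srCNV burden is Group H,
#' the other Group L. Bootstrap support is the fraction of `n_boot`
#' feature-resampled clusterings (srCNV columns drawn with replacement)
#' that reproduce each cluster's exact membership.
#'
#' @param mat Binary samples x srCNV matrix from [presence_matrix()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `srcnv_cluster`: `groups` tibble (`sample`,
#'   `group` H/L, `burden`), `support` (named per-group bootstrap
#'   fraction), `hclust`, `n_boot`.
#' @export
cluster_srcnv <- function(mat, n_boot = 1000, seed = NULL) {
  if (nrow(mat) < 2 || ncol(mat) < 1) {
    abort("need >= 2 samples and >= 1 srCNV")
  }
  if (nrow(unique(as.data.frame(mat))) == 1) {
    abort("degenerate matrix: all samples have identical srCNV profiles")
  }
  if (!is.null(seed)) set.seed(seed)
  split2 <- function(m) {
    hc <- hclust(dist(m), method = "ward.D2")
    list(hc = hc, cl = cutree(hc, k = 2))
  }
  ref <- split2(mat)
  burden <- rowMeans(mat)
  mean_burden <- tapply(burden, ref$cl, mean)
  h_id <- as.integer(names(which.max(mean_burden)))
  group <- unname(ifelse(ref$cl == h_id, "H", "L"))
  members <- split(rownames(mat) %||% as.character(seq_len(nrow(mat))),
                   group)

  hits <- c(H = 0, L = 0)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    bm <- mat[, cols, drop = FALSE]
    if (nrow(unique(as.data.frame(bm))) == 1) next
    bcl <- split2(bm)$cl
    bsets <- split(rownames(mat) %||% as.character(seq_len(nrow(mat))), bcl)
    for (gname in c("H", "L")) {
      if (any(vapply(bsets, setequal, logical(1), y = members[[gname]]))) {
        hits[gname] <- hits[gname] + 1
      }
    }
  }
  structure(
    list(
      groups = tibble(sample = rownames(mat) %||%
                        as.character(seq_len(nrow(mat))),
                      group = group, burden = unname(burden)),
      support = hits / n_boot,
      hclust = ref$hc,
      n_boot = n_boot
    ),
    class = "srcnv_cluster"
  )
}

#' @export
print.srcnv_cluster <- function(x, ...) {
  tab <- table(x$groups$group)
  cat("srCNV clustering: Group H n = ", tab[["H"]], ", Group L n = ",
      tab[["L"]], "\n", sep = "")
  cat("  bootstrap support (", x$n_boot, " resamples): H = ",
      sprintf("%.2f", x$support[["H"]]), ", L = ",
      sprintf("%.2f", x$support[["L"]]), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.srcnv_cluster <- function(x, ...) x$groups

#' @export
glance.srcnv_cluster <- function(x, ...) {
  tab <- table(x$groups$group)
  tibble(n_h = tab[["H"]], n_l = tab[["L"]],
         support_h = x$support[["H"]], support_l = x$support[["L"]],
         n_boot = x$n_boot)
}

#' Joint four-subgroup stratification by LOH% and srCNV burden
#'
#' Crosses a binary LOH% labeling with a binary srCNV labeling into the
#' four subgroups ClLl, ClLh, ChLl, ChLh (low/high CNV x low/high LOH) and
#' tests their survival separation with an overall k-sample log-rank test
#' over the non-empty subgroups.
#'
#' @inheritParams km_estimate
#' @param loh_high,srcnv_high Logical vectors (TRUE = high) aligned with
#'   `records`.
#' @return `stratification` object; empty product groups are noted in the
#'   `empty_groups` field and excluded from the test (with a warning when
#'   fewer than two groups remain).
#' @export
joint_stratify <- function(records, loh_high, srcnv_high,
                           event_type = c("cancer_specific", "total")) {
  event_type <- match.arg(event_type)
  records <- as_tibble(records)
  stopifnot(length(loh_high) == nrow(records),
            length(srcnv_high) == nrow(records))
  lab <- paste0(ifelse(srcnv_high, "Ch", "Cl"),
                ifelse(loh_high, "Lh", "Ll"))
  all_levels <- c("ClLl", "ClLh", "ChLl", "ChLh")
  empty <- setdiff(all_levels, unique(lab))
  if (length(unique(lab)) < 2) {
    warn("fewer than two non-empty subgroups; no log-rank test performed")
    lr <- list(statistic = NA_real_, df = 0L, p = NA_real_, table = NULL)
  } else {
    lr <- logrank_test(records, lab, event_type = event_type)
  }
  res <- new_stratification("LOH% x srCNV (joint)", records, lab, NULL,
                            event_type, lr)
  res$empty_groups <- empty
  res
}

#' Single-covariate Cox proportional-hazards regression
#'
#' Fits a one-covariate Cox model (partial likelihood maximized by
#' Newton-Raphson, Breslow handling of tied deaths) and reports the hazard
#' ratio per a stated covariate increment, e.g. per 1 year of age or per
#' 1000 SNVs of load. With `percent = TRUE` the covariate is first
#' rescaled to the 0-100 range so the hazard ratio is per 1% increment.
#'
#' @inheritParams km_estimate
#' @param values Numeric covariate aligned with `records`.
#' @param increment Covariate increment the hazard ratio refers to
#'   (default 1).
#' @param percent Rescale the covariate to 0-100 before fitting.
#' @param term Covariate name recorded in the output.
#' @return One-row tibble: `term`, `increment`, `coef` (per unit), `hr`
#'   (per increment), `conf_low`, `conf_high` (95% CI per increment),
#'   `p` (Wald), `n`, `n_events`.
#' @export
cox_single <- function(records, values, increment = 1, percent = FALSE,
                       event_type = c("cancer_specific", "total"),
                       term = NULL) {
  event_type <- match.arg(event_type)
  term <- term %||% deparse(substitute(values))
  records <- as_tibble(records)
  if (length(values) != nrow(records)) {
    abort("values and records are misaligned")
  }
  if (any(!is.finite(values))) abort("covariate must be finite")
  if (sum(records[[event_column(event_type)]]) == 0) {
    abort("no events observed; Cox model is not estimable")
  }
  x <- values
  if (percent) {
    rng <- range(x)
    if (diff(rng) == 0) abort("constant covariate cannot be normalized")
    x <- 100 * (x - rng[1]) / diff(rng)
  }
  s <- surv_from_records(records, event_type)
  fit <- survival::coxph(s ~ x, ties = "breslow",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && isTRUE(fit$info$flag)) {
    warn("possible monotone likelihood (perfect separation)")
  }
  co <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(co) || !is.finite(se)) {
    abort("Cox fit did not converge to finite estimates")
  }
  z <- co / se
  tibble(
    term = term, increment = increment,
    coef = co,
    hr = exp(co * increment),
    conf_low = exp((co - 1.96 * se) * increment),
    conf_high = exp((co + 1.96 * se) * increment),
    p = 2 * stats::pnorm(-abs(z)),
    n = nrow(records),
    n_events = sum(records[[event_column(event_type)]])
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p sums the probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(8, 2, 6, 9), 2))
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  fisher.test(table)$p.value
}
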