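#' Build a 96-context mutation catalog
#'
#' Tabulates classified somatic calls into the samples-by-96-contexts count
#' matrix used for mutational-signature resolution. Calls carrying no
#' context (e.g. an ambiguous flanking base) are dropped and counted.
#'
#' @param calls Tibble of classified somatic calls with columns `sample`,
#'   `context` and `somatic_class`.
#' @param class_filter Restrict the catalog to `"GOH"` or `"LOH"` calls, or
#'   use `"all"` (default) for every classified SNV.
#' @param samples Optional character vector fixing the column set and order;
#'   defaults to the samples present, sorted.
#' @return Integer matrix, 96 rows (labelled by [sbs_contexts()]) by one
#'   column per sample; attribute `"n_dropped"` counts context-less calls.
#' @export
build_catalog <- function(calls, class_filter = c("all", "GOH", "LOH"),
                          samples = NULL) {
  class_filter <- match.arg(class_filter)
  calls <- as_tibble(calls)
  if (class_filter != "all") {
    calls <- calls %>% filter(.data$somatic_class == class_filter)
  }
  n_dropped <- sum(is.na(calls$context))
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " call(s) without a context bin dropped"))
    calls <- calls %>% filter(!is.na(.data$context))
  }
  bins <- sbs_contexts()
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  bad <- setdiff(unique(calls$context), bins)
  if (length(bad) > 0) {
    abort(paste0("unknown context bin(s): ", paste(head(bad, 5),
                                                   collapse = ", ")))
  }
  m <- table(factor(calls$context, levels = bins),
             factor(calls$sample, levels = samples))
  m <- matrix(as.integer(m), nrow = length(bins),
              dimnames = list(bins, samples))
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Cosine similarity between two mutation profiles
#'
#' @param a,b Numeric vectors of equal length (neither all-zero).
#' @return The cosine of the angle between `a` and `b`, in \[-1, 1\].
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

# one NMF fit by multiplicative updates minimizing generalized KL divergence
# D(V || WH); stops when the relative decrease in D falls below tol.
nmf_kl <- function(V, k, max_updates = 10000, tol = 1e-6,
                   track_divergence = FALSE) {
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  scale <- sqrt(mean(V) / k)
  W <- matrix(runif(n * k, 0.5, 1.5) * scale, n, k)
  H <- matrix(runif(k * m, 0.5, 1.5) * scale, k, m)
  kl <- function(A) {
    sum(ifelse(V > 0, V * log(V / pmax(A, eps)), 0) - V + A)
  }
  d_prev <- kl(W %*% H)
  trace <- if (track_divergence) d_prev else NULL
  for (i in seq_len(max_updates)) {
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / pmax(matrix(colSums(t(H)), n, k,
                                               byrow = TRUE), eps)
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH)) / pmax(matrix(colSums(W), k, m), eps)
    d <- kl(W %*% H)
    if (track_divergence) trace <- c(trace, d)
    if (is.finite(d_prev) && d_prev > 0 &&
        abs(d_prev - d) / d_prev < tol) {
      d_prev <- d
      break
    }
    d_prev <- d
  }
  # normalize signatures to probability vectors, folding scale into H
  s <- pmax(colSums(W), eps)
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 1, s, "*")
  list(W = W, H = H, divergence = d_prev, divergence_trace = trace)
}

#' Resolve a catalog into two mutational signatures by bootstrapped NMF
#'
#' Re-implements the bootstrap NMF scheme for signature deciphering at a
#' fixed number of signatures: in each of `iterations` rounds, every
#' sample's count vector is multinomially resampled with its own empirical
#' profile, NMF with Kullback-Leibler multiplicative updates is run from a
#' random non-negative initialization to convergence, and the resulting
#' signatures are pooled. The pool is partitioned into `k` clusters by
#' cosine similarity (spherical k-means, best of 10 restarts); the
#' normalized cluster centroids are the reported signatures and the mean
#' within-cluster cosine similarity their stability. Per-sample exposures
#' are then fitted on the original catalog by non-negative least squares,
#' and the *major* signature - the one with the largest summed exposure
#' across the cohort (ties broken toward the lower-entropy profile) - is
#' designated signature alpha; the percentage of each sample's mutations
#' assigned to it is its signature-alpha %.
#'
#' @param catalog 96 x samples count matrix from [build_catalog()].
#' @param k Number of signatures (fixed at 2 for the alpha/beta scheme).
#' @param iterations Bootstrap rounds (default 1000; fewer than 10 warns).
#' @param seed Optional integer seed making the whole extraction
#'   deterministic.
#' @param max_updates,tol NMF convergence controls (multiplicative update
#'   cap and relative KL-change tolerance).
#' @return Object of class `signature_fit`: `signatures` (k x 96 matrix,
#'   alpha first, rows summing to 1), `exposures` (k x samples), `alpha_pct`
#'   tibble (`sample`, `alpha_pct`), `stability` (per signature), and the
#'   iteration count. Supports [tidy()], [glance()] and [autoplot()].
#' @export
extract_signatures <- function(catalog, k = 2, iterations = 1000,
                               seed = NULL, max_updates = 10000,
                               tol = 1e-6) {
  if (!is.matrix(catalog) || nrow(catalog) != 96) {
    abort("catalog must be a 96 x samples matrix")
  }
  if (ncol(catalog) < 2) abort("at least two samples are required")
  if (sum(catalog) == 0) abort("catalog is all zero")
  if (iterations < 10) warn("fewer than 10 bootstrap iterations")
  if (!is.null(seed)) set.seed(seed)

  # canonical sample order makes the extraction invariant under column
  # permutation of the input catalog
  orig_cols <- colnames(catalog)
  if (!is.null(orig_cols)) {
    catalog <- catalog[, order(orig_cols), drop = FALSE]
  }
  n_s <- ncol(catalog)
  totals <- colSums(catalog)
  pool <- matrix(NA_real_, nrow = iterations * k, ncol = 96)
  for (it in seq_len(iterations)) {
    boot <- catalog
    for (j in seq_len(n_s)) {
      if (totals[j] > 0) {
        boot[, j] <- rmultinom(1, totals[j], catalog[, j])
      }
    }
    fit <- nmf_kl(boot, k, max_updates = max_updates, tol = tol)
    pool[(it - 1) * k + seq_len(k), ] <- t(fit$W)
  }

  cl <- cluster_signatures(pool, k)
  sigs <- cl$centroids            # k x 96, rows sum to 1
  expo <- fit_exposures_matrix(catalog, sigs)
  entropy <- vapply(seq_len(k), function(i) {
    p <- sigs[i, ][sigs[i, ] > 0]
    -sum(p * log(p))
  }, numeric(1))
  major <- order(-rowSums(expo), entropy)[1]  # ties -> lower entropy
  ord <- c(major, setdiff(seq_len(k), major))
  sigs <- sigs[ord, , drop = FALSE]
  expo <- expo[ord, , drop = FALSE]
  stability <- cl$stability[ord]
  colnames(sigs) <- rownames(catalog)
  rownames(sigs) <- paste0("signature_", c("alpha", "beta", letters)[
    seq_len(k)])
  dimnames(expo) <- list(rownames(sigs), colnames(catalog))

  if (!is.null(orig_cols)) {
    back <- match(orig_cols, colnames(catalog))
    expo <- expo[, back, drop = FALSE]
    catalog <- catalog[, back, drop = FALSE]
  }
  tot <- colSums(expo)
  alpha_pct <- tibble(
    sample = colnames(catalog) %||% as.character(seq_len(ncol(catalog))),
    alpha_pct = unname(ifelse(tot > 0, 100 * expo[1, ] / tot, NA_real_))
  )
  structure(
    list(signatures = sigs, exposures = expo, alpha_pct = alpha_pct,
         stability = stability, iterations = iterations, k = k),
    class = "signature_fit"
  )
}

# spherical k-means on L2-normalized profiles: Euclidean clustering on the
# unit sphere orders pairs identically to cosine distance
cluster_signatures <- function(pool, k) {
  unit <- pool / sqrt(rowSums(pool^2))
  km <- kmeans(unit, centers = k, nstart = 10, iter.max = 100)
  centroids <- matrix(NA_real_, k, ncol(pool))
  stability <- numeric(k)
  for (i in seq_len(k)) {
    members <- pool[km$cluster == i, , drop = FALSE]
    ctr <- colMeans(members)
    centroids[i, ] <- ctr / sum(ctr)
    stability[i] <- mean(apply(members, 1, cosine_sim, b = ctr))
  }
  list(centroids = centroids, stability = stability)
}

fit_exposures_matrix <- function(catalog, sigs) {
  A <- t(sigs)                    # 96 x k
  expo <- vapply(seq_len(ncol(catalog)), function(j) {
    v <- catalog[, j]
    if (sum(v) == 0) return(rep(0, nrow(sigs)))
    pracma::lsqnonneg(A, v)$x
  }, numeric(nrow(sigs)))
  matrix(expo, nrow = nrow(sigs), ncol = ncol(catalog))
}

#' Fit per-sample signature exposures by non-negative least squares
#'
#' Given fixed signature profiles, decomposes each sample's 96-context count
#' vector into non-negative signature loads and reports the percentage
#' attributed to the first (alpha) signature.
#'
#' @param catalog 96 x samples count matrix.
#' @param signatures k x 96 matrix of signature probability vectors (alpha
#'   first), e.g. `fit$signatures` from [extract_signatures()].
#' @return Tibble with one row per sample: `sample`, one `exposure_*` column
#'   per signature, and `alpha_pct` (`NA` for zero-count samples).
#' @export
compute_exposures <- function(catalog, signatures) {
  if (nrow(signatures) < 2) abort("at least two signatures are required")
  if (ncol(signatures) != nrow(catalog)) {
    abort("signatures and catalog disagree on the number of context bins")
  }
  expo <- fit_exposures_matrix(catalog, signatures)
  tot <- colSums(expo)
  nm <- rownames(signatures) %||% paste0("signature_", seq_len(nrow(signatures)))
  out <- as_tibble(setNames(as.data.frame(t(expo)), paste0("exposure_", nm)))
  out$sample <- colnames(catalog) %||% as.character(seq_len(ncol(catalog)))
  out$alpha_pct <- unname(ifelse(colSums(catalog) > 0 & tot > 0,
                                 100 * expo[1, ] / tot, NA_real_))
  select(out, "sample", dplyr::everything())
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Mutational signature fit (k = ", x$k, ", ", x$iterations,
      " bootstrap iterations)\n", sep = "")
  cat("  stability (mean within-cluster cosine): ",
      paste(sprintf("%.3f", x$stability), collapse = ", "), "\n", sep = "")
  cat("  cohort mean alpha%: ",
      sprintf("%.1f", mean(x$alpha_pct$alpha_pct, na.rm = TRUE)), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.signature_fit <- function(x, ...) {
  expo <- t(x$exposures)
  out <- as_tibble(expo)
  names(out) <- paste0("exposure_", rownames(x$exposures))
  out$sample <- colnames(x$exposures)
  left_join(select(out, "sample", dplyr::everything()), x$alpha_pct,
            by = "sample")
}

#' @export
glance.signature_fit <- function(x, ...) {
  tibble(
    k = x$k,
    iterations = x$iterations,
    stability_alpha = x$stability[1],
    stability_beta = x$stability[2],
    mean_alpha_pct = mean(x$alpha_pct$alpha_pct, na.rm = TRUE)
  )
}
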