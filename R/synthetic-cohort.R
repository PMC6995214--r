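#' Default pair of planted mutational signatures
#'
#' The first (alpha-like) signature concentrates its mass on C>T mutations
#' at NCG trinucleotides and T>C mutations at NTG trinucleotides - the
#' peaks characteristic of the LOH-resembling major signature in liver
#' cancers - with the remaining mass spread over the other pyrimidine
#' boxes. The second (beta-like) signature concentrates on C>A and C>G
#' mutations, where the alpha signature carries no mass. Each signature
#' thus has an anchor set of bins where the other is zero, which keeps the
#' pair identifiable for non-negative factorization (profiles sharing a
#' large common component are recovered only up to the data cone's extreme
#' rays).
#'
#' @return 2 x 96 matrix of probability vectors (rows sum to 1), columns
#'   named by [sbs_contexts()].
#' @export
default_signatures <- function() {
  bins <- sbs_contexts()
  ncg <- paste0(c("A", "C", "G", "T"), "[C>T]G")
  ntg <- paste0(c("A", "C", "G", "T"), "[T>C]G")
  alpha <- rep(0, 96)
  names(alpha) <- bins
  alpha[ncg] <- 0.10
  alpha[ntg] <- 0.06
  rest <- setdiff(bins[grepl("C>T|T>A|T>C|T>G", bins)], c(ncg, ntg))
  alpha[rest] <- 0.36 / length(rest)
  beta <- rep(0, 96)
  names(beta) <- bins
  heavy <- bins[grepl("C>A|C>G", bins)]
  beta[heavy] <- 0.75 / length(heavy)
  others <- setdiff(bins, c(heavy, ncg, ntg))
  beta[others] <- 0.25 / length(others)
  m <- rbind(alpha = alpha / sum(alpha), beta = beta / sum(beta))
  colnames(m) <- bins
  m
}

#' Default CNV hotspots of the toy genome
#'
#' Four recurrent hotspots mimic the chromosomal pattern seen in liver
#' cancers - clustered copy-number gains on one arm and sparser losses
#' elsewhere - two of which carry a survival hazard (the planted srCNVs).
#' Coordinates are 0-based half-open spans of whole 350-kb windows.
#'
#' @return Tibble: `contig`, `start`, `end`, `direction`, `frequency`
#'   (carrier fraction), `hazard_ratio` (1 = no survival effect).
#' @export
default_hotspots <- function() {
  tibble(
    contig = c("chr2", "chr3", "chr3", "chr1"),
    start = c(10150000, 3500000, 17500000, 1750000),
    end = c(11900000, 3850000, 20300000, 2100000),
    direction = c("loss", "loss", "gain", "gain"),
    frequency = c(0.30, 0.25, 0.35, 0.22),
    hazard_ratio = c(4, 1, 4, 1)
  )
}

#' Configuration of a synthetic blood-tumor cohort
#'
#' Bundles and validates the generative parameters of the synthetic cohort:
#' a toy genome, the SNV load distribution and its GOH/LOH composition, the
#' two planted mutational signatures and their per-sample mixing, CNV
#' hotspots with optional survival hazards, and the survival/censoring
#' model. Defaults emulate the published structure of a 110-patient
#' liver-cancer whole-genome cohort: loads spanning 735 to 126,965 SNVs,
#' GOH dominance below ~6000 and LOH dominance above ~20,000 SNVs, and
#' copy-neutral LOH averaging 69.5% of LOH calls.
#'
#' @param n_patients Cohort size (default 110).
#' @param toy_genome Tibble (`contig`, `length`); default three 30-Mb
#'   contigs (~257 windows of 350 kb).
#' @param load_range Min/max total SNVs per tumor, sampled log-uniformly
#'   (default `c(735, 126965)`).
#' @param low_load_cutoff,high_load_cutoff Loads below/above which GOH
#'   resp. LOH dominate in expectation (defaults 6000 / 20,000).
#' @param loh_dominance_slope Slope of the logistic (in log-load) giving
#'   the expected LOH fraction; its midpoint is the geometric mean of the
#'   two cutoffs.
#' @param loh_noise_kappa Beta concentration of per-sample noise around the
#'   expected LOH fraction.
#' @param cn_neutral_loh_target Mean percentage of LOH calls falling in
#'   copy-neutral windows (default 69.5).
#' @param cn_neutral_kappa Beta concentration around that target.
#' @param true_signatures 2 x 96 matrix of signature probability vectors
#'   (alpha first).
#' @param alpha_mixing Beta parameters `c(shape1, shape2)` of the
#'   per-sample alpha share. The default `c(0.9, 0.6)` has mean 0.6 with a
#'   U-shaped density, so cohorts contain tumors dominated by either
#'   mutational process; near-pure samples at both ends keep the
#'   signature pair identifiable for NMF recovery.
#' @param loh_alpha_boost Factor by which LOH calls are enriched for the
#'   alpha signature relative to the sample's overall alpha share, making
#'   the alpha signature resemble the LOH profile.
#' @param cnv_hotspots Hotspot tibble as in [default_hotspots()].
#' @param cnv_background_rate Per-window probability of a sporadic gain
#'   (and, independently, loss) outside hotspots.
#' @param marker_coefs Log-hazard coefficients of the planted markers:
#'   `log_load` (per log SNV), `loh_frac` and `alpha` (per unit fraction);
#'   hotspot hazards come from `cnv_hotspots$hazard_ratio`.
#' @param baseline_hazard Baseline cancer-death hazard, events/month.
#' @param other_death_rate Hazard of death from other causes, events/month
#'   (drives the total-death indicator).
#' @param censoring_rate Target fraction of patients censored (0-1).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 110,
                          toy_genome = tibble(
                            contig = c("chr1", "chr2", "chr3"),
                            length = rep(30000000, 3)),
                          load_range = c(735, 126965),
                          low_load_cutoff = 6000,
                          high_load_cutoff = 20000,
                          loh_dominance_slope = 2,
                          loh_noise_kappa = 60,
                          cn_neutral_loh_target = 69.5,
                          cn_neutral_kappa = 80,
                          true_signatures = default_signatures(),
                          alpha_mixing = c(0.9, 0.6),
                          loh_alpha_boost = 1.4,
                          cnv_hotspots = default_hotspots(),
                          cnv_background_rate = 0.02,
                          marker_coefs = c(log_load = 0.30,
                                           loh_frac = 0.8, alpha = 0.8),
                          baseline_hazard = 0.010,
                          other_death_rate = 0.003,
                          censoring_rate = 0.35,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, toy_genome = as_tibble(toy_genome),
    load_range = load_range, low_load_cutoff = low_load_cutoff,
    high_load_cutoff = high_load_cutoff,
    loh_dominance_slope = loh_dominance_slope,
    loh_noise_kappa = loh_noise_kappa,
    cn_neutral_loh_target = cn_neutral_loh_target,
    cn_neutral_kappa = cn_neutral_kappa,
    true_signatures = true_signatures,
    alpha_mixing = alpha_mixing, loh_alpha_boost = loh_alpha_boost,
    cnv_hotspots = as_tibble(cnv_hotspots),
    cnv_background_rate = cnv_background_rate,
    marker_coefs = marker_coefs,
    baseline_hazard = baseline_hazard,
    other_death_rate = other_death_rate,
    censoring_rate = censoring_rate, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 2) abort("n_patients must be >= 2")
  if (cfg$load_range[1] < 1 || cfg$load_range[2] < cfg$load_range[1]) {
    abort("load_range must satisfy 1 <= min <= max")
  }
  sig <- cfg$true_signatures
  if (!is.matrix(sig) || nrow(sig) != 2 || ncol(sig) != 96) {
    abort("true_signatures must be a 2 x 96 matrix")
  }
  if (any(abs(rowSums(sig) - 1) > 1e-9) || any(sig < 0)) {
    abort("each true signature must be a probability vector summing to 1")
  }
  if (any(cfg$cnv_hotspots$hazard_ratio <= 0)) {
    abort("hazard ratios must be > 0")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1) {
    abort("censoring_rate must lie in [0, 1]")
  }
  hs <- cfg$cnv_hotspots
  gl <- setNames(cfg$toy_genome$length, cfg$toy_genome$contig)
  if (!all(hs$contig %in% names(gl)) ||
      any(hs$start < 0) || any(hs$end > gl[hs$contig]) ||
      any(hs$start >= hs$end)) {
    abort("configuration error: hotspot coordinates fall outside the toy genome")
  }
  invisible(cfg)
}

#' Generate a synthetic paired blood-tumor cohort
#'
#' Draws a full cohort - paired genotype calls with trinucleotide contexts,
#' per-sample 350-kb CNV window states, and a survival table - whose
#' statistical structure matches the configuration: log-uniform SNV loads;
#' a LOH fraction that rises logistically with log-load (GOH-dominant below
#' the low-load cutoff, LOH-dominant above the high one); per-call
#' signature assignment mixing the two planted signatures at the sample's
#' alpha share, with LOH calls enriched for the alpha signature; hotspot
#' CNV carriage at the configured frequencies; and survival times from an
#' exponential proportional-hazards model whose log-hazard is linear in the
#' planted markers, censored by an independent uniform administrative time
#' calibrated to the target censoring rate.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `calls` (paired
#'   genotype records), `cnv` (per-sample window states), `clinical`
#'   (survival table with covariates), `truth` (per-sample planted values:
#'   load, LOH fraction, realized alpha%, copy-neutral LOH target, hotspot
#'   carrier flags, linear predictor) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  genome <- config$toy_genome

  # --- SNV loads and GOH/LOH composition -------------------------------
  loads <- round(exp(runif(n, log(config$load_range[1]),
                           log(config$load_range[2]))))
  loads <- pmin(pmax(loads, config$load_range[1]), config$load_range[2])
  midpoint <- sqrt(config$low_load_cutoff * config$high_load_cutoff)
  mu_loh <- plogis(config$loh_dominance_slope * (log(loads) - log(midpoint)))
  kap <- config$loh_noise_kappa
  loh_frac <- rbeta(n, mu_loh * kap, (1 - mu_loh) * kap)
  n_loh <- round(loads * loh_frac)
  n_goh <- loads - n_loh

  # --- CNV window states ----------------------------------------------
  grid <- windowize(genome)
  n_w <- nrow(grid)
  hs <- config$cnv_hotspots
  hs_windows <- lapply(seq_len(nrow(hs)), function(i) {
    which(grid$contig == hs$contig[i] & grid$start >= hs$start[i] &
            grid$end <= hs$end[i])
  })
  state <- matrix("neutral", nrow = n_w, ncol = n)
  in_hotspot <- rep(FALSE, n_w)
  for (i in seq_len(nrow(hs))) in_hotspot[hs_windows[[i]]] <- TRUE
  bg <- config$cnv_background_rate
  for (dir in c("gain", "loss")) {
    hit <- matrix(runif(n_w * n) < bg, n_w, n) & !in_hotspot &
      state == "neutral"
    state[hit] <- dir
  }
  carriers <- matrix(FALSE, nrow = nrow(hs), ncol = n)
  for (i in seq_len(nrow(hs))) {
    carriers[i, ] <- runif(n) < hs$frequency[i]
    state[hs_windows[[i]], carriers[i, ]] <- hs$direction[i]
  }
  cnv <- tibble(
    sample = rep(patients, each = n_w),
    contig = rep(grid$contig, n),
    start = rep(grid$start, n),
    end = rep(grid$end, n),
    state = as.vector(state)
  )

  # --- per-sample alpha share and class-conditional signature use ------
  alpha <- rbeta(n, config$alpha_mixing[1], config$alpha_mixing[2])
  a_loh <- pmin(1, alpha * config$loh_alpha_boost)
  a_goh <- ifelse(n_goh > 0,
                  (alpha * loads - a_loh * n_loh) / pmax(n_goh, 1), 0)
  a_goh <- pmin(pmax(a_goh, 0), 1)

  # --- per-patient calls ----------------------------------------------
  cn_target <- rbeta(n, config$cn_neutral_loh_target / 100 *
                       config$cn_neutral_kappa,
                     (1 - config$cn_neutral_loh_target / 100) *
                       config$cn_neutral_kappa)
  sig <- config$true_signatures
  bins <- sbs_contexts()
  parts <- parse_context(bins)
  call_list <- vector("list", n)
  alpha_realized <- numeric(n)
  for (i in seq_len(n)) {
    st <- state[, i]
    neutral_w <- which(st == "neutral")
    altered_w <- which(st != "neutral")
    # LOH sites: copy-neutral with per-sample target probability
    k_neutral <- rbinom(1, n_loh[i], cn_target[i])
    if (length(altered_w) == 0) k_neutral <- n_loh[i]
    if (length(neutral_w) == 0) k_neutral <- 0L
    w_loh <- c(
      if (k_neutral > 0)
        neutral_w[sample.int(length(neutral_w), k_neutral, replace = TRUE)],
      if (n_loh[i] - k_neutral > 0)
        altered_w[sample.int(length(altered_w), n_loh[i] - k_neutral,
                             replace = TRUE)]
    )
    w_goh <- sample.int(n_w, n_goh[i], replace = TRUE,
                        prob = grid$end - grid$start)
    w_all <- c(w_loh, w_goh)
    cls <- rep(c("LOH", "GOH"), c(n_loh[i], n_goh[i]))
    pos <- grid$start[w_all] +
      sample.int(350000, length(w_all), replace = TRUE)
    pos <- pmin(pos, grid$end[w_all])          # clamp inside short windows
    is_alpha <- runif(loads[i]) <
      ifelse(cls == "LOH", a_loh[i], a_goh[i])
    bin_idx <- integer(loads[i])
    if (any(is_alpha)) {
      bin_idx[is_alpha] <- sample.int(96, sum(is_alpha), replace = TRUE,
                                      prob = sig[1, ])
    }
    if (any(!is_alpha)) {
      bin_idx[!is_alpha] <- sample.int(96, sum(!is_alpha), replace = TRUE,
                                       prob = sig[2, ])
    }
    alpha_realized[i] <- mean(is_alpha)
    call_list[[i]] <- tibble(
      sample = patients[i],
      contig = grid$contig[w_all],
      pos = pos,
      ref = parts$ref[bin_idx],
      alt = parts$alt[bin_idx],
      context = bins[bin_idx],
      blood_gt = ifelse(cls == "LOH", "het", "hom_ref"),
      tumor_gt = ifelse(cls == "LOH", "hom_alt", "het"),
      blood_dp = 60L, tumor_dp = 60L, blood_gq = 99L, tumor_gq = 99L,
      true_class = cls,
      true_signature = ifelse(is_alpha, "alpha", "beta")
    )
  }
  calls <- bind_rows(call_list) %>%
    group_by(.data$sample) %>%
    arrange(.data$contig, .data$pos, .by_group = TRUE) %>%
    ungroup()

  # --- survival --------------------------------------------------------
  cf <- config$marker_coefs
  lp <- cf[["log_load"]] * (log(loads) - mean(log(config$load_range))) +
    cf[["loh_frac"]] * (loh_frac - 0.5) +
    cf[["alpha"]] * (alpha - config$alpha_mixing[1] /
                       sum(config$alpha_mixing))
  for (i in seq_len(nrow(hs))) {
    lp <- lp + log(hs$hazard_ratio[i]) * carriers[i, ]
  }
  rate_cancer <- config$baseline_hazard * exp(lp)
  t_cancer <- rexp(n, rate_cancer)
  t_other <- if (config$other_death_rate > 0) {
    rexp(n, config$other_death_rate)
  } else {
    rep(Inf, n)
  }
  t_death <- pmin(t_cancer, t_other)
  cens <- censoring_times(rate_cancer + config$other_death_rate,
                          config$censoring_rate, t_death, n)
  time <- pmax(pmin(t_death, cens), 1e-6)
  clinical <- tibble(
    sample = patients,
    time_months = time,
    event_cancer_specific = as.integer(t_cancer <= pmin(t_other, cens)),
    event_total = as.integer(t_death <= cens),
    age = pmin(pmax(round(rnorm(n, 63, 9)), 18), 90),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25)),
    viral_status = sample(c("HBV", "HCV", "none"), n, replace = TRUE,
                          prob = c(0.45, 0.25, 0.30)),
    tumor_size_cm = round(rlnorm(n, log(4), 0.4), 1),
    portal_vein_invasion = rbinom(n, 1, 0.20),
    hepatic_vein_invasion = rbinom(n, 1, 0.12)
  )

  truth <- tibble(
    sample = patients,
    load = loads,
    n_goh = n_goh,
    n_loh = n_loh,
    loh_frac = loh_frac,
    alpha_pct = 100 * alpha_realized,
    cn_neutral_target_pct = 100 * cn_target,
    linear_predictor = as.numeric(lp)
  )
  for (i in seq_len(nrow(hs))) {
    truth[[paste0("carrier_", hs$contig[i], "_", hs$direction[i], "_",
                  hs$start[i])]] <- as.integer(carriers[i, ])
  }

  structure(
    list(calls = calls, cnv = cnv, clinical = clinical, truth = truth,
         config = config),
    class = "synthetic_cohort"
  )
}

# administrative censoring C ~ U(0, a): a is calibrated so that the mean of
# P(censored_i) = (1 - exp(-mu_i a)) / (mu_i a) matches the target rate
censoring_times <- function(mu, rate, t_death, n) {
  if (rate <= 0) return(rep(Inf, n))
  if (rate >= 1) return(t_death * runif(n, 0.1, 0.9))  # censor everyone
  f <- function(log_a) {
    a <- exp(log_a)
    mean((1 - exp(-mu * a)) / (mu * a)) - rate
  }
  log_a <- uniroot(f, lower = log(1e-6), upper = log(1e8))$root
  runif(n, 0, exp(log_a))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic blood-tumor cohort: ", nrow(x$clinical), " patients, ",
      nrow(x$calls), " somatic calls, ",
      length(unique(paste(x$cnv$contig, x$cnv$start))), " CNV windows\n",
      sep = "")
  cat("  events (cancer-specific/total): ",
      sum(x$clinical$event_cancer_specific), "/",
      sum(x$clinical$event_total), "\n", sep = "")
  invisible(x)
}
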