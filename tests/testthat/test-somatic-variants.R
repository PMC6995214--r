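test_that("classification covers every blood x tumor genotype combination", {
  classes <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(blood = classes, tumor = classes,
                      stringsAsFactors = FALSE)
  got <- classify_somatic_pair(grid$blood, grid$tumor)
  expected <- function(b, t) {
    if (b == "missing" || t == "missing") return(NA_character_)
    if (b == t) return("none")
    hom <- c("hom_ref", "hom_alt")
    if (b %in% hom && t == "het") return("GOH")
    if (b == "het" && t %in% hom) return("LOH")
    "other"
  }
  want <- mapply(expected, grid$blood, grid$tumor)
  expect_identical(unname(got), unname(want))
  expect_error(classify_somatic_pair("bad", "het"), "genotype classes")
})

test_that("classify_somatic filters, annotates and logs drops", {
  pairs <- tibble::tibble(
    sample = "P1", contig = "chr1", pos = 1:6,
    ref = c("C", "G", "C", "T", "C", "C"),
    alt = c("A", "T", "T", "C", "G", "A"),
    context = c("A[C>A]A", "A[C>A]A", "T[C>T]G", "G[T>C]C", NA, "A[C>A]T"),
    blood_gt = c("hom_ref", "het", "het", "hom_ref", "missing", "hom_ref"),
    tumor_gt = c("het", "hom_alt", "hom_alt", "hom_ref", "het", "het"),
    blood_dp = c(60, 60, 60, 60, 60, 4),
    tumor_dp = 60, blood_gq = 99, tumor_gq = 99
  )
  out <- classify_somatic(pairs)
  # pos 4 identical genotypes (none), pos 5 missing, pos 6 low depth
  expect_equal(out$pos, 1:3)
  expect_equal(out$somatic_class, c("GOH", "LOH", "LOH"))
  expect_equal(out$is_transition, c(FALSE, FALSE, TRUE))
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$reason,
                  c("missing_genotype", "low_depth", "no_somatic_change"))
  expect_equal(sum(dropped$n), 3)
})

test_that("per-sample summaries match a per-call recount", {
  calls <- random_calls(500, seed = 42)
  # windows of 1000 bp with random states per sample
  set.seed(43)
  win <- expand.grid(sample = c("A", "B", "C"), contig = c("chr1", "chr2"),
                     start = seq(0, 9000, 1000), stringsAsFactors = FALSE)
  win$end <- win$start + 1000
  win$state <- sample(c("gain", "loss", "neutral"), nrow(win),
                      replace = TRUE, prob = c(.2, .2, .6))
  got <- summarize_samples(calls, win)

  for (s in c("A", "B", "C")) {
    cs <- calls[calls$sample == s, ]
    expect_equal(got$snv_load[got$sample == s], nrow(cs))
    expect_equal(got$goh_count[got$sample == s],
                 sum(cs$somatic_class == "GOH"))
    expect_equal(got$loh_pct[got$sample == s],
                 100 * sum(cs$somatic_class == "LOH") / nrow(cs))
    # brute-force copy-neutral recount
    loh <- cs[cs$somatic_class == "LOH", ]
    in_neutral <- vapply(seq_len(nrow(loh)), function(i) {
      w <- win[win$sample == s & win$contig == loh$contig[i] &
                 win$start < loh$pos[i] & win$end >= loh$pos[i], ]
      nrow(w) == 0 || all(w$state == "neutral")
    }, logical(1))
    expect_equal(got$cn_neutral_loh_pct[got$sample == s],
                 100 * sum(in_neutral) / nrow(loh))
    tr <- cs$somatic_class == "GOH" & cs$is_transition
    expect_equal(got$transition_pct_goh[got$sample == s],
                 100 * sum(tr) / sum(cs$somatic_class == "GOH"))
  }
})

test_that("summary arithmetic handles simple and degenerate inputs", {
  calls <- tibble::tibble(
    sample = "P1", contig = "chr1", pos = seq_len(100),
    somatic_class = rep(c("GOH", "LOH"), c(30, 70)),
    context = "A[C>A]A", is_transition = FALSE
  )
  s <- summarize_samples(calls)
  expect_equal(s$snv_load, 100)
  expect_equal(s$loh_pct, 70)
  # all LOH sites in neutral windows -> 100%
  win <- tibble::tibble(sample = "P1", contig = "chr1", start = 0,
                        end = 1000, state = "neutral")
  expect_equal(summarize_samples(calls, win)$cn_neutral_loh_pct, 100)
})

test_that("subset extraction respects the half-open coordinate convention", {
  calls <- tibble::tibble(sample = "P1", contig = "chr1", pos = c(99, 100, 101))
  regions <- tibble::tibble(contig = "chr1", start = 99, end = 100)
  # only the 1-based position 100 lies in 0-based [99, 100)
  expect_equal(extract_subset(calls, regions)$pos, 100)
  expect_equal(nrow(extract_subset(calls, empty <- tibble::tibble(
    contig = character(), start = integer(), end = integer()))), 0)
})

test_that("subset extraction agrees with per-base membership", {
  set.seed(7)
  for (rep in 1:5) {
    calls <- random_calls(200, seed = rep)
    regions <- tibble::tibble(
      contig = sample(c("chr1", "chr2"), 8, replace = TRUE),
      start = sample.int(9000, 8)
    )
    regions$end <- regions$start + sample.int(800, 8)
    got <- extract_subset(calls, regions)
    member <- vapply(seq_len(nrow(calls)), function(i) {
      any(regions$contig == calls$contig[i] &
            regions$start < calls$pos[i] & calls$pos[i] <= regions$end)
    }, logical(1))
    expect_equal(got, calls[member, ])
  }
})

test_that("subsetting commutes with summarizing", {
  calls <- random_calls(400, seed = 9)
  regions <- tibble::tibble(contig = "chr1", start = c(0, 5000),
                            end = c(2500, 8000))
  s1 <- summarize_samples(extract_subset(calls, regions))
  inside <- calls$contig == "chr1" &
    ((calls$pos > 0 & calls$pos <= 2500) |
       (calls$pos > 5000 & calls$pos <= 8000))
  s2 <- summarize_samples(calls[inside, ])
  expect_equal(s1, s2)
})

test_that("load normalization rescales subset counts to genome equivalents", {
  expect_equal(normalize_load(445, 0.0214), 20794)
  expect_equal(normalize_load(0, 0.5), 0)
  expect_equal(normalize_load(100, 1.0), 100)
  expect_error(normalize_load(10, 0), "coverage_fraction")
  # whole-genome region set is the identity
  calls <- random_calls(300, seed = 3)
  whole <- tibble::tibble(contig = c("chr1", "chr2"), start = 0, end = 10000)
  expect_equal(
    normalize_load(nrow(extract_subset(calls, whole)), 1.0),
    nrow(calls)
  )
})

test_that("subset-region derivation applies depth and gap rules", {
  genome <- tibble::tibble(contig = "chr1", length = 10000)
  # uniform depth 4 -> whole contig
  t1 <- tibble::tibble(sample = "s1", contig = "chr1", start = 0,
                       end = 10000, depth = 4)
  r1 <- derive_subset_regions(t1, genome)
  expect_equal(r1, tibble::tibble(contig = "chr1", start = 0, end = 10000),
               ignore_attr = TRUE)
  expect_equal(attr(r1, "coverage_fraction"), 1)
  # a 100-bp gap (>= 80) is not bridged; a 79-bp gap is
  t2 <- tibble::tibble(sample = "s1", contig = "chr1",
                       start = c(0, 1100), end = c(1000, 2000), depth = 4)
  expect_equal(nrow(derive_subset_regions(t2, genome)), 2)
  t3 <- tibble::tibble(sample = "s1", contig = "chr1",
                       start = c(0, 1079), end = c(1000, 2000), depth = 4)
  r3 <- derive_subset_regions(t3, genome)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$end - r3$start, 2000)
  # low-depth runs are ignored
  t4 <- dplyr::mutate(t1, depth = 3)
  expect_warning(r4 <- derive_subset_regions(t4, genome), "no shared")
  expect_equal(nrow(r4), 0)
})

test_that("multi-sample region intersection agrees with a per-base oracle", {
  genome <- tibble::tibble(contig = "chr1", length = 400)
  set.seed(13)
  for (rep in 1:5) {
    tracks <- purrr::map_dfr(c("s1", "s2", "s3"), function(s) {
      starts <- sort(sample(seq(0, 380, 20), 6))
      tibble::tibble(sample = s, contig = "chr1", start = starts,
                     end = starts + sample(c(10, 20), 6, replace = TRUE),
                     depth = sample(2:6, 6, replace = TRUE))
    })
    got <- suppressWarnings(
      derive_subset_regions(tracks, genome, min_depth = 4, max_gap = 15))
    # per-base oracle
    per_sample <- vapply(c("s1", "s2", "s3"), function(s) {
      cov <- rep(FALSE, 400)
      t <- tracks[tracks$sample == s & tracks$depth >= 4, ]
      for (i in seq_len(nrow(t))) cov[(t$start[i] + 1):t$end[i]] <- TRUE
      # bridge gaps < 15 between covered runs
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$values)) {
        if (!r$values[j] && r$lengths[j] < 15 && j > 1 &&
            j < length(r$values)) {
          cov[starts[j]:ends[j]] <- TRUE
        }
      }
      cov
    }, logical(400))
    want <- rowSums(per_sample) == 3
    got_base <- rep(FALSE, 400)
    for (i in seq_len(nrow(got))) got_base[(got$start[i] + 1):got$end[i]] <- TRUE
    expect_equal(got_base, unname(want))
  }
})

test_that("region-class annotation matches a brute-force tally", {
  calls <- random_calls(300, seed = 21)
  classes <- list(
    genic = tibble::tibble(contig = "chr1", start = 0, end = 4000),
    proximal = tibble::tibble(contig = c("chr1", "chr2"),
                              start = c(3000, 0), end = c(7000, 5000))
  )
  got <- annotate_by_region_class(calls, classes)
  # oracle: first matching class wins
  lab <- vapply(seq_len(nrow(calls)), function(i) {
    for (nm in names(classes)) {
      r <- classes[[nm]]
      if (any(r$contig == calls$contig[i] & r$start < calls$pos[i] &
                calls$pos[i] <= r$end)) return(nm)
    }
    "unclassified"
  }, character(1))
  for (nm in c(names(classes), "unclassified")) {
    expect_equal(got$goh_count[got$region_class == nm],
                 sum(lab == nm & calls$somatic_class == "GOH"))
    expect_equal(got$loh_count[got$region_class == nm],
                 sum(lab == nm & calls$somatic_class == "LOH"))
  }
  # empty class sets leave everything unclassified
  none <- annotate_by_region_class(calls, list(
    x = tibble::tibble(contig = character(), start = integer(),
                       end = integer())))
  expect_equal(none$goh_count[none$region_class == "x"], 0)
  expect_equal(sum(none$goh_count), sum(calls$somatic_class == "GOH"))
})
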