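toy_family <- function(years, seqs = NULL) {
  n <- length(years)
  if (is.null(seqs)) {
    set.seed(99)
    seqs <- apply(random_msa(n, 40), 1, paste, collapse = "")
  }
  data.frame(seq_id = sprintf("s%02d", seq_len(n)),
             residues = unname(seqs), year = years,
             stringsAsFactors = FALSE)
}

test_that("snapshot_at filters by publication date and preserves order", {
  fam <- toy_family(c(1995, 2001, 2013))
  s <- snapshot_at(fam, 2002)
  expect_equal(s$n_total_hits, 2)
  expect_identical(s$members$seq_id, c("s01", "s02"))
  expect_equal(snapshot_at(fam, 2014)$n_total_hits, 3)
  expect_equal(snapshot_at(fam, 1990)$n_total_hits, 0)
})

test_that("snapshots are nested across years", {
  set.seed(5)
  fam <- toy_family(sample(1994:2014, 30, replace = TRUE))
  yrs <- seq(1994, 2014, 2)
  members <- lapply(yrs, function(y) snapshot_at(fam, y)$members$seq_id)
  for (i in seq_along(yrs)[-1])
    expect_true(all(members[[i - 1]] %in% members[[i]]))
})

test_that("pairwise_identity follows the stated gap conventions", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("AC-E", "ACDE"), 0.75)
  expect_equal(pairwise_identity("A--C", "-AAC"), 0.25)
  expect_equal(pairwise_identity("A-C", "A-C"), 1.0)   # double gaps excluded
  expect_equal(pairwise_identity("--", "--"), 0)       # nothing informative
  expect_error(pairwise_identity("AC", "ACD"), "length")
  # symmetry and the identity criterion on random pairs
  set.seed(2)
  for (i in 1:20) {
    m <- random_msa(2, 30, gap_frac = 0.15)
    a <- paste(m[1, ], collapse = ""); b <- paste(m[2, ], collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("remove_redundancy keeps the greedy non-redundant subset", {
  base <- strsplit(paste(sample(AA, 100, replace = TRUE), collapse = ""), "")[[1]]
  mutate <- function(v, k) { v[seq_len(k)] <- rev(AA)[seq_len(k)]; v }
  set.seed(8)
  s1 <- base
  s2 <- mutate(base, 1)                       # 0.99 identical to s1
  s3 <- sample(AA, 100, replace = TRUE)
  s4 <- mutate(s3, 1)                         # 0.99 identical to s3
  s5 <- sample(AA, 100, replace = TRUE)
  fam <- toy_family(rep(2000, 5),
                    vapply(list(s1, s2, s3, s4, s5), paste, "", collapse = ""))
  filt <- remove_redundancy(snapshot_at(fam, 2005), 0.95)
  expect_identical(filt$members$seq_id, c("s01", "s03", "s05"))
  expect_equal(filt$n_after_redundancy, 3)
  expect_equal(filt$n_total_hits, 5)

  # two identical sequences collapse to one
  fam2 <- toy_family(c(2000, 2000), rep(paste(base, collapse = ""), 2))
  expect_equal(remove_redundancy(snapshot_at(fam2, 2001))$n_after_redundancy, 1)

  expect_error(remove_redundancy(snapshot_at(fam, 2005), 1.2), "threshold")
})

test_that("redundancy removal is sound and idempotent on random snapshots", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    m <- random_msa(n, 60)
    # plant some near-clones
    for (k in sample(n, 3)) {
      clone <- m[k, ]; clone[1] <- "W"
      m <- rbind(m, matrix(clone, 1))
    }
    rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
    fam <- data.frame(seq_id = rownames(m),
                      residues = apply(m, 1, paste, collapse = ""),
                      year = 2000)
    filt <- remove_redundancy(snapshot_at(fam, 2001), 0.95)
    kept <- sdpbench:::as_msa(filt$members)
    if (nrow(kept) > 1) {
      ids <- sdpbench:::identity_matrix(kept)
      expect_true(all(ids[upper.tri(ids)] <= 0.95))
    }
    again <- remove_redundancy(filt, 0.95)
    expect_identical(again$members, filt$members)
  }
})

test_that("workable applies the minimum-size gate at both thresholds", {
  fam <- toy_family(rep(2000, 15))
  s <- remove_redundancy(snapshot_at(fam, 2001))
  expect_true(workable(s, 15))
  expect_false(workable(remove_redundancy(snapshot_at(toy_family(rep(2000, 14)), 2001)), 15))
  expect_true(workable(remove_redundancy(snapshot_at(toy_family(rep(2000, 10)), 2001)), 10))
})

test_that("coverage_series counts workable families per year", {
  cfg <- benchmark_config(years = seq(1996, 2004, 2), min_sequences = 15,
                          reference_year = 2004)
  fam <- toy_family(rep(2000, 20))
  cov <- coverage_series(list(f1 = fam), cfg)
  expect_equal(cov$n_workable, c(0, 0, 1, 1, 1))
  expect_equal(coverage_series(list(), cfg)$n_workable, rep(0L, 5))
  # pre-redundancy workable counts are non-decreasing over years
  set.seed(12)
  fams <- lapply(1:6, function(i)
    toy_family(sample(1994:2014, 25, replace = TRUE)))
  pre_counts <- vapply(seq(1994, 2014, 2), function(y)
    sum(vapply(fams, function(f) snapshot_at(f, y)$n_total_hits >= 15,
               logical(1))), integer(1))
  expect_true(all(diff(pre_counts) >= 0))
})

test_that("redundancy_series reports the kept fraction per year", {
  base <- paste(sample(AA, 60, replace = TRUE), collapse = "")
  other <- paste(sample(AA, 60, replace = TRUE), collapse = "")
  mut <- function(s) { v <- strsplit(s, "")[[1]]; v[1] <- "W"; paste(v, collapse = "") }
  # 6 sequences with 2 clone pairs -> 4/6 kept
  fam <- toy_family(rep(2000, 6),
                    c(base, mut(base), other, mut(other),
                      paste(sample(AA, 60, replace = TRUE), collapse = ""),
                      paste(sample(AA, 60, replace = TRUE), collapse = "")))
  cfg <- benchmark_config(years = c(1996, 2000), reference_year = 2000)
  rs <- redundancy_series(fam, cfg)
  expect_true(is.na(rs$fraction[1]))
  expect_equal(rs$fraction[2], 4 / 6, tolerance = 1e-12)
})
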