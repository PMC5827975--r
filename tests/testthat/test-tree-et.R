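test_that("build_tree recovers well-separated clades at level 2", {
  fam <- study_family(seed = 33, n_subfamilies = 2, seqs_per_subfamily = 6,
                      n_columns = 120)
  tl <- build_tree(fam$msa)
  expect_equal(nrow(tl$membership), 12)
  expect_equal(length(level_partition(tl, 1)), 1)
  groups <- level_partition(tl, 2)
  expect_equal(length(groups), 2)
  sf <- fam$truth$subfamily_of
  for (g in groups)
    expect_equal(length(unique(sf[g])), 1L)
  # deepest level: one leaf per group
  expect_equal(length(level_partition(tl, 12)), 12)
  expect_error(build_tree(fam$msa[1:2, ]), "at least 3")
})

test_that("neighbor joining on identity distances matches a hand-computed topology", {
  # 4 sequences with identities chosen so that (a,b) and (c,d) pair up
  msa <- sdpbench:::as_msa(c(
    a = "AAAAAAAAAACCCCCCCCCC",
    b = "AAAAAAAAAWCCCCCCCCCC",   # 1 diff from a
    c = "RRRRRRRRRRDDDDDDDDDD",
    d = "RRRRRRRRRWDDDDDDDDDD")) # 1 diff from c
  tl <- build_tree(msa)
  groups <- lapply(level_partition(tl, 2), sort)
  expect_true(any(vapply(groups, identical, TRUE, y = c("a", "b"))) ||
              any(vapply(groups, identical, TRUE, y = c("c", "d"))))
  expect_setequal(unlist(groups), c("a", "b", "c", "d"))
})

test_that("et ranks: conserved columns are rank 1, two-clade SDPs rank 2", {
  fam <- study_family(seed = 51, n_subfamilies = 2, seqs_per_subfamily = 8,
                      n_columns = 150)
  tl <- build_tree(fam$msa)
  tab <- et_scores(fam$msa, tl)
  expect_true(all(tab$score[fam$conserved_cols] == 1))
  expect_true(all(tab$score[fam$sdp_cols] == 2))
  sel <- selected_columns(tab)
  expect_true(all(union(fam$conserved_cols, fam$sdp_cols) %in% sel))
  sdp_sel <- selected_columns(tab, sdp_only = TRUE)
  expect_true(all(fam$sdp_cols %in% sdp_sel))
  expect_length(intersect(sdp_sel, fam$conserved_cols), 0)
  # rank 1 implies conservation
  r1 <- which(tab$score == 1)
  expect_true(all(apply(fam$msa[, r1, drop = FALSE], 2,
                        function(v) length(unique(v[v != "-"]))) == 1))
})

test_that("et ranks equal the brute-force cut-enumeration oracle", {
  set.seed(23)
  for (case in 1:8) {
    n <- sample(5:12, 1)
    m <- random_msa(n, 15, gap_frac = if (case %% 4 == 0) 0.08 else 0)
    # mix in structured columns so low ranks occur too
    m[, 1] <- "A"
    m[, 2] <- c(rep("C", floor(n / 2)), rep("W", ceiling(n / 2)))
    tl <- build_tree(m)
    got <- et_scores(m, tl)$score
    want <- et_oracle(m, tl$tree)
    expect_equal(got, want)
  }
})

test_that("random columns almost never reach the selection rank", {
  m <- random_msa(20, 300, seed = 29)
  tab <- et_scores(m)
  expect_lt(mean(tab$score <= 2), 0.05)
  expect_true(all(tab$score >= 1))
  expect_true(all(tab$score <= 21))
})

test_that("selection is invariant under sequence permutation", {
  fam <- study_family(seed = 61)
  set.seed(5)
  perm <- sample(nrow(fam$msa))
  msa_p <- fam$msa[perm, ]
  cfg <- benchmark_config()
  expect_setequal(selected_columns(conserved_positions(fam$msa)),
                  selected_columns(conserved_positions(msa_p)))
  expect_setequal(selected_columns(xdet_scores(fam$msa)),
                  selected_columns(xdet_scores(msa_p)))
  expect_setequal(selected_columns(et_scores(fam$msa)),
                  selected_columns(et_scores(msa_p)))
  expect_setequal(selected_columns(teao_scores(fam$msa)),
                  selected_columns(teao_scores(msa_p)))
  expect_setequal(selected_columns(s3det_like(fam$msa, cfg)$scores),
                  selected_columns(s3det_like(msa_p, cfg)$scores))
})
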