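test_that("simulate_tree builds the requested clade structure deterministically", {
  tr <- simulate_tree(2, 3, 0.1, 1.0, seed = 1)
  expect_equal(ape::Ntip(tr), 6)
  sf <- attr(tr, "subfamily")
  expect_true(ape::is.monophyletic(tr, names(sf)[sf == 1]))
  expect_true(ape::is.monophyletic(tr, names(sf)[sf == 2]))

  tr4 <- simulate_tree(4, 10, 0.1, 1.0, seed = 7)
  expect_equal(ape::Ntip(tr4), 40)
  sf4 <- attr(tr4, "subfamily")
  for (k in 1:4)
    expect_true(ape::is.monophyletic(tr4, names(sf4)[sf4 == k]))
  expect_identical(ape::write.tree(tr4),
                   ape::write.tree(simulate_tree(4, 10, 0.1, 1.0, seed = 7)))
  # ultrametric: all leaves equally deep
  d <- ape::node.depth.edgelength(tr4)[seq_len(40)]
  expect_lt(diff(range(d)), 1e-9)

  expect_error(simulate_tree(1, 3, 0.1, 1), "counts")
  expect_error(simulate_tree(2, 3, -0.1, 1), "depths")
})

test_that("evolve_family honours the planted site classes", {
  tr <- simulate_tree(2, 4, 0.1, 2.0)
  # all columns conserved -> identical sequences
  prof <- site_class_profile(5, conserved_cols = 1:5)
  ev <- evolve_family(tr, prof, seed = 3)
  expect_equal(length(unique(ev$family$residues)), 1L)

  # one-residue-per-subfamily: zero within entropy, positive across entropy
  prof2 <- site_class_profile(10, sdp_cols = 1,
                              substitution_rate = 1)
  ev2 <- evolve_family(tr, prof2, seed = 5)
  msa <- sdpbench:::as_msa(ev2$family)
  sf <- ev2$truth$subfamily_of[rownames(msa)]
  for (k in unique(sf))
    expect_equal(length(unique(msa[sf == k, 1])), 1L)
  expect_gt(length(unique(msa[, 1])), 1L)
  expect_gt(column_entropy(msa[, 1]), 0)

  # conserved-in-one-subfamily: invariant in the designated subfamily
  prof3 <- site_class_profile(10, sdp_cols = 1,
                              sdp_mode = "conserved-in-one-subfamily")
  ev3 <- evolve_family(tr, prof3, seed = 11)
  msa3 <- sdpbench:::as_msa(ev3$family)
  sf3 <- ev3$truth$subfamily_of[rownames(msa3)]
  within_counts <- tapply(msa3[, 1], sf3, function(v) length(unique(v)))
  expect_true(any(within_counts == 1L))

  expect_error(site_class_profile(3, conserved_cols = 1:2, sdp_cols = 2:3),
               "disjoint")
  expect_error(site_class_profile(3, conserved_cols = 1:3, sdp_cols = 4:5))
})

test_that("per-subfamily SDP flavour gives each subfamily its own residue", {
  tr <- simulate_tree(4, 4, 0.1, 2.0)
  prof <- site_class_profile(6, sdp_cols = 1:3,
                             sdp_residue_groups = "per-subfamily")
  ev <- evolve_family(tr, prof, seed = 2)
  msa <- sdpbench:::as_msa(ev$family)
  sf <- ev$truth$subfamily_of[rownames(msa)]
  for (p in 1:3) {
    per_sf <- tapply(msa[, p], sf, unique)
    expect_true(all(lengths(per_sf) == 1L))
    expect_equal(length(unique(unlist(per_sf))), 4L)
  }
})

test_that("infinite-rate neutral columns are uniform over the 20 residues", {
  # star-like tree, huge rate: leaf states are i.i.d. uniform draws
  tr <- simulate_tree(2, 5, 1.0, 1.0)
  prof <- site_class_profile(1000, substitution_rate = 100)
  ev <- evolve_family(tr, prof, seed = 42)
  msa <- sdpbench:::as_msa(ev$family)
  counts <- table(factor(as.vector(msa), levels = AA))
  expect_equal(sum(counts), 10000)
  p <- stats::chisq.test(counts, p = rep(1 / 20, 20))$p.value
  expect_gt(p, 0.01)
})

test_that("evolve_family is byte-reproducible given the seed", {
  tr <- simulate_tree(3, 4, 0.2, 3.0)
  prof <- site_class_profile(50, conserved_cols = 1:5, sdp_cols = 6:10)
  e1 <- evolve_family(tr, prof, seed = 9)
  e2 <- evolve_family(tr, prof, seed = 9)
  expect_identical(e1, e2)
  e3 <- evolve_family(tr, prof, seed = 10)
  expect_false(identical(e1$family$residues, e3$family$residues))
})

test_that("assign_dates respects the accumulation model", {
  tr <- simulate_tree(2, 8, 0.25, 4)
  prof <- site_class_profile(60, substitution_rate = 1)
  fam <- evolve_family(tr, prof, seed = 1)$family
  mdl <- accumulation_model(1994, 2014, growth_rate = 1.3, n_final = 16)
  dated <- assign_dates(fam, mdl, seed = 5)
  expect_equal(nrow(dated), 16)
  expect_true(all(dated$year >= 1994 & dated$year <= 2014))
  cum <- cumsum(table(factor(dated$year, levels = 1994:2014)))
  expect_true(all(diff(cum) >= 0))
  expect_equal(unname(cum[["2014"]]), 16)

  # determinism and order invariance of the year marginal
  d2 <- assign_dates(fam, mdl, seed = 5)
  expect_identical(dated, d2)
  shuf <- fam[sample(nrow(fam)), ]
  d3 <- assign_dates(shuf, mdl, seed = 5)
  expect_identical(sort(d3$year), sort(dated$year))

  expect_error(assign_dates(fam[0, ], mdl, seed = 1), "empty")
  expect_error(assign_dates(fam[1:3, ], mdl, seed = 1), "n_final")
})

test_that("date counts double every two years when growth_rate is sqrt(2)", {
  tr <- simulate_tree(2, 8, 0.25, 4)
  prof <- site_class_profile(30, substitution_rate = 1)
  fam <- evolve_family(tr, prof, seed = 2)$family
  fam <- do.call(rbind, replicate(7, fam, simplify = FALSE))
  fam$seq_id <- sprintf("s%03d", seq_len(nrow(fam)))
  mdl <- accumulation_model(1994, 2014, growth_rate = sqrt(2), n_final = 100)
  set.seed(77)
  ratios <- replicate(50, {
    d <- assign_dates(fam, mdl, seed = sample.int(1e6, 1))
    cum <- cumsum(table(factor(d$year, levels = 1994:2014)))
    cum[["2010"]] / cum[["2012"]]
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})

test_that("synth_structure separates pocket, shell and remote residues", {
  st <- synth_structure(10, binding_cols = c(1, 2), near_cols = 3,
                        seed = 4, pocket_radius = 5)
  d <- vapply(1:10, residue_site_distance, 0, structure = st)
  expect_equal(d[1], 0)
  expect_equal(d[2], 0)
  far <- d[4:10]
  expect_true(all(d[3] < far))

  st2 <- synth_structure(200, binding_cols = 1:5, near_cols = 6:15, seed = 8)
  d2 <- vapply(1:200, residue_site_distance, 0, structure = st2)
  expect_gt(mean(d2[16:200]) / mean(d2[6:15]), 2)
  # remote residues never intrude into 3 pocket radii of the centroid
  cen <- sqrt(rowSums(st2$coords[16:200, ]^2))
  expect_true(all(cen >= 3 * st2$pocket_radius))

  expect_error(synth_structure(10, binding_cols = 1:2, near_cols = 2:3),
               "disjoint")
  # empty near set is fine
  expect_silent(synth_structure(10, binding_cols = 1:2, seed = 1))
})

test_that("simulate_benchmark_data is reproducible and carries coherent truth", {
  d1 <- simulate_benchmark_data(n_families = 2, seed = 3)
  d2 <- simulate_benchmark_data(n_families = 2, seed = 3)
  expect_identical(d1$families, d2$families)
  expect_identical(d1$structures, d2$structures)
  tr <- d1$truth$fam01
  expect_setequal(names(d1$families), c("fam01", "fam02"))
  expect_true(all(tr$binding_cols %in% which(d1$structures$fam01$binding)))
  # redundant clones are near-identical to their source and dated later or equal
  fam <- d1$families$fam01
  clones <- grep("_r$", fam$seq_id, value = TRUE)
  expect_gt(length(clones), 0)
  for (cl in clones) {
    src <- sub("_r$", "", cl)
    id <- pairwise_identity(fam$residues[fam$seq_id == src],
                            fam$residues[fam$seq_id == cl])
    expect_gt(id, 0.95)
    expect_gte(fam$year[fam$seq_id == cl], fam$year[fam$seq_id == src])
  }
})
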