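# Tanimoto scoring, hit rates, the Fisher-Pitman permutation test and
# pocket/ligand size statistics.

test_that("Tanimoto is 1 on identity, symmetric, and matches set arithmetic", {
  expect_identical(tanimoto("CCO", "OCC"), 1)
  for (pair in list(c("CCO", "c1ccccc1"), c("CC(=O)O", "CCN"),
                    c("c1ccsc1", "CC(=O)Oc1ccccc1C(=O)O"))) {
    t_ab <- tanimoto(pair[1], pair[2])
    t_ba <- tanimoto(pair[2], pair[1])
    expect_identical(t_ab, t_ba)
    # independent explicit bit-set enumeration
    fps <- pg$morgan_fingerprints(pair)
    a <- which(fps[1, ]); b <- which(fps[2, ])
    expect_equal(t_ab, length(intersect(a, b)) / length(union(a, b)))
    expect_gte(t_ab, 0); expect_lte(t_ab, 1)
  }
  # provably disjoint bit sets score 0
  fps <- pg$morgan_fingerprints(c("CCCC", "O"))
  if (!any(fps[1, ] & fps[2, ])) expect_identical(tanimoto("CCCC", "O"), 0)
  expect_error(tanimoto("C(", "CCO"))
})

test_that("max_tc_score finds the exhaustive maximum and honors tie order", {
  lib <- unname(fixture_ligand_library())
  label <- "CC(=O)Oc1ccccc1C(=O)O"
  sc <- max_tc_score(lib, label)
  expect_identical(sc$best_tc, 1)
  expect_identical(canonical_smiles(sc$best_molecule), canonical_smiles(label))
  one <- max_tc_score("CCO", label)
  expect_identical(one$best_tc, tanimoto("CCO", label))
  # brute-force max over a random subset
  set.seed(14)
  sub <- sample(lib, 10)
  sc2 <- max_tc_score(sub, "CCN(CC)CC")
  want <- max(vapply(sub, tanimoto, numeric(1), mol_b = "CCN(CC)CC"))
  expect_equal(sc2$best_tc, want, tolerance = 1e-12)
})

test_that("hit rates count thresholds and never increase with the cutoff", {
  hr <- hit_rates(c(1.0, 0.65, 0.8), thresholds = 0.7)
  expect_equal(hr$hit_rate_pct, 100 * 2 / 3, tolerance = 1e-9)
  hr2 <- hit_rates(rep(1, 5))
  expect_identical(hr2$hit_rate_pct, rep(100, 4))
  set.seed(15)
  tcs <- runif(40)
  hr3 <- hit_rates(tcs)
  for (k in seq_len(nrow(hr3)))
    expect_identical(hr3$hit_rate_pct[k], 100 * mean(tcs >= hr3$threshold[k]))
  expect_true(all(diff(hr3$hit_rate_pct) <= 0))
})

test_that("Fisher-Pitman enumerates exactly on small groups", {
  r <- fisher_pitman(c(0, 0), c(1, 1))
  expect_true(r$exhaustive)
  expect_identical(r$n_used, 6)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  # identical groups: every relabeling ties the observed statistic
  r2 <- fisher_pitman(c(2, 2, 2), c(2, 2, 2))
  expect_identical(r2$p_value, 1)
  expect_gt(fisher_pitman(rnorm(4), rnorm(4))$p_value, 0)
})

test_that("Monte-Carlo p-values converge to the exhaustive value", {
  set.seed(16)
  a <- rnorm(6); b <- rnorm(6) + 0.8
  exact <- fisher_pitman(a, b, n_perm = 10000)  # C(12,6) = 924: exhaustive
  expect_true(exact$exhaustive)
  mc <- fisher_pitman(a, b, n_perm = 800, seed = 2)  # forced Monte-Carlo
  expect_false(mc$exhaustive)
  p <- exact$p_value
  expect_lt(abs(mc$p_value - p), 3 * sqrt(p * (1 - p) / 800) + 2 / 800)
})

test_that("type-I error is calibrated at the 5% level", {
  # null simulations; the larger 1,000-replicate version runs in acceptance
  set.seed(17)
  rej <- mean(replicate(300, {
    fisher_pitman(rnorm(6), rnorm(6))$p_value <= 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("ligand sizes count heavy atoms", {
  expect_identical(ligand_size("CCO"), 3L)
  expect_identical(ligand_size("c1ccccc1"), 6L)
  expect_identical(ligand_size("CC(=O)Oc1ccccc1C(=O)O"), 13L)
})

test_that("size-group statistics bin pockets and match a sort-based oracle", {
  bins <- pg$pocket_size_bin(c(90, 150, 200, 250))
  expect_identical(as.character(bins), c("<100", "100-160", "161-220", ">220"))
  expect_identical(as.character(pg$pocket_size_bin(c(99, 100, 160, 161, 220, 221))),
                   c("<100", "100-160", "100-160", "161-220", "161-220", ">220"))
  set.seed(18)
  ps <- sample(50:300, 60, TRUE)
  ls <- sample(3:40, 60, TRUE)
  st <- size_group_stats(ps, ls)
  expect_true(all(st$q1 <= st$median & st$median <= st$q3))
  for (k in seq_len(nrow(st))) {
    x <- ls[as.character(pg$pocket_size_bin(ps)) == as.character(st$bin[k])]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    expect_equal(c(st$q1[k], st$median[k], st$q3[k]), q)
    expect_equal(st$iqr[k], q[3] - q[1])
  }
  expect_identical(sum(st$n), 60L)
})
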