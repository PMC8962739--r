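# Pocket parsing, SASA, contact edges, coordinate normalization and the
# composed graph representation.

toy_pdb <- function() {
  # 3 residues, 12 heavy atoms + 4 hydrogens
  make_pocket_pdb(12, seed = 2, n_hydrogens = 4)
}

test_that("parser keeps heavy atoms, drops hydrogens, renumbers residues", {
  atoms <- parse_pocket(toy_pdb())
  expect_identical(nrow(atoms), 12L)
  expect_false(any(atoms$element == "H"))
  expect_identical(atoms$atom_index, seq_len(12L))
  expect_identical(sort(unique(atoms$residue_index)),
                   seq_len(max(atoms$residue_index)))
})

test_that("hydrogen-only and malformed files raise parse errors", {
  hline <- "ATOM      1  H1  ALA A   1       0.000   0.000   0.000  1.00  0.00           H"
  expect_error(parse_pocket(hline), "no non-hydrogen atoms")
  expect_error(parse_pocket("REMARK nothing"), "no ATOM/HETATM")
  bad <- "ATOM      1  C1  ALA A   1       xx.000   0.000   0.000  1.00  0.00           C"
  expect_error(parse_pocket(bad), "line 1")
})

test_that("generated fixtures parse back to the requested atom count", {
  for (n in c(12, 57)) {
    atoms <- parse_pocket(make_pocket_pdb(n, seed = n))
    expect_identical(nrow(atoms), as.integer(n))
  }
})

test_that("SASA matches the closed form for one sphere and zero when buried", {
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  got <- compute_sasa(one)
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.02)
  # cage: central atom surrounded by a dense shell of 42 atoms at 2.2 A
  pts <- pg$sphere_points(42) * 2.2
  cage <- data.frame(element = c("C", rep("C", 42)),
                     x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]))
  expect_identical(compute_sasa(cage)[1], 0)
})

test_that("SASA agrees with a dense random-sampling reference on two atoms", {
  two <- data.frame(element = c("C", "O"), x = c(0, 2.4), y = 0, z = 0)
  got <- compute_sasa(two)
  ref <- oracle_sasa(as.matrix(two[, c("x", "y", "z")]), c(1.70, 1.52))
  expect_equal(got, ref, tolerance = 0.05)
})

test_that("contact edges equal brute-force distance thresholding", {
  two <- data.frame(element = c("C", "C"), x = c(0, 5), y = 0, z = 0,
                    residue_name = "ALA", residue_index = 1L)
  expect_identical(nrow(build_edges(two)$edges), 0L)
  two$x[2] <- 4
  e <- build_edges(two)
  expect_identical(nrow(e$edges), 2L)
  expect_identical(e$edge_attr, c(0, 0))
  # 200 random points in a 20 A box vs the O(N^2) oracle
  set.seed(9)
  cloud <- data.frame(element = "C", x = runif(200, 0, 20),
                      y = runif(200, 0, 20), z = runif(200, 0, 20))
  e <- build_edges(cloud)
  d <- as.matrix(dist(cloud[, c("x", "y", "z")]))
  want <- which(d <= 4.5 & upper.tri(d), arr.ind = TRUE)
  got <- unique(t(apply(e$edges, 1, sort)))
  expect_identical(nrow(got), nrow(want))
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_identical(key(got), key(want))
})

test_that("covalent-range pairs carry multiplicity, overridable by bond table", {
  at <- data.frame(element = c("C", "C", "S", "C"),
                   x = c(0, 1.5, 4, 6.05), y = 0, z = 0)
  e <- build_edges(at)
  key <- paste(e$edges[, 1], e$edges[, 2])
  expect_identical(e$edge_attr[key == "1 2"], 1)   # 1.5 A C-C: covalent
  expect_identical(e$edge_attr[key == "2 3"], 0)   # 2.5 A: contact
  expect_identical(e$edge_attr[key == "3 4"], 1)   # 2.05 A involving S: covalent
  e2 <- build_edges(at, bond_table = data.frame(i = 1, j = 2, order = 2))
  expect_identical(e2$edge_attr[key == "1 2"], 2)
  expect_identical(e2$edge_attr[key == "2 1"], 2)
})

test_that("coordinate normalization centers, diagonalizes and is rigid", {
  set.seed(4)
  x <- matrix(rnorm(150, sd = c(4, 2, 1)), ncol = 3, byrow = TRUE)
  out <- normalize_coordinates(x)
  expect_true(attr(out, "normalized"))
  expect_lt(max(abs(colMeans(out))), 1e-9)
  cv <- cov(out)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6 * max(diag(cv)))
  expect_true(all(diff(diag(cv)) <= 1e-9))
  expect_equal(as.matrix(dist(out)), as.matrix(dist(x)), tolerance = 1e-9)
  # axis-aligned input comes back unchanged up to sign
  expect_equal(abs(normalize_coordinates(out)), abs(out), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate input: centering only, flagged
  flat <- cbind(1:5, 1:5, 1:5)
  out2 <- normalize_coordinates(flat)
  expect_false(attr(out2, "normalized"))
  expect_lt(max(abs(colMeans(out2))), 1e-9)
})

test_that("featurization broadcasts residue scalars and defaults entropy to 0", {
  atoms <- parse_pocket(toy_pdb())
  tab <- residue_property_table()
  sasa <- compute_sasa(atoms)
  f <- featurize(atoms, tab, sasa)
  expect_identical(dim(f), c(12L, 8L))
  for (r in unique(atoms$residue_index)) {
    rows <- f[atoms$residue_index == r, 1:3, drop = FALSE]
    expect_true(all(apply(rows, 2, function(cc) length(unique(cc)) == 1)))
  }
  expect_identical(unname(f[, "entropy"]), rep(0, 12))
  ent <- seq_len(max(atoms$residue_index)) / 10
  f2 <- featurize(atoms, tab, sasa, entropy = ent)
  expect_identical(unname(f2[, "entropy"]), ent[atoms$residue_index])
  expect_error(featurize(atoms, tab, sasa, entropy = c(1, 2)), "entropy profile")
  # unknown residues resolve to the UNK row
  atoms$residue_name[1] <- "XXX"
  f3 <- featurize(atoms, tab, sasa)
  expect_identical(unname(f3[1, 1:3]), c(0, 0, 0))
})

test_that("to_graph composes deterministically and satisfies all invariants", {
  atoms <- parse_pocket(toy_pdb())
  g1 <- to_graph(atoms, pocket_id = "toy")
  g2 <- to_graph(atoms, pocket_id = "toy")
  expect_identical(g1, g2)
  expect_true(pg$validate_pocket_graph(g1))
  expect_identical(g1$n_atoms, 12L)
  g3 <- to_graph(parse_pocket(make_pocket_pdb(40, seed = 8)), pocket_id = "p40")
  expect_true(pg$validate_pocket_graph(g3))
})

test_that("graph JSON serialization round-trips", {
  g <- fixture_graph()
  f <- tempfile(fileext = ".json")
  write_pocket_graph(g, f)
  g2 <- read_pocket_graph(f)
  expect_equal(unname(g2$node_features), unname(g$node_features), tolerance = 1e-12)
  expect_identical(unname(g2$edges), unname(cbind(g$edges[, 1], g$edges[, 2])))
  expect_identical(g2$edge_attr, g$edge_attr)
  expect_identical(g2$label_smiles, g$label_smiles)
  expect_true(pg$validate_pocket_graph(g2))
  unlink(f)
})
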