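# Construction of the pocket graph: contact edges within a distance cutoff,
# principal-axis coordinate normalization, and the node feature matrix.

#' Contact edges of a pocket
#'
#' Connects every atom pair within `cutoff` Angstrom. Pairs classified as
#' covalently bonded carry their bond multiplicity as the edge attribute;
#' non-covalent contacts carry 0. Covalent classification is distance-based
#' (<= 1.9 Angstrom, or <= 2.1 Angstrom when sulfur is involved) with
#' multiplicity 1 unless a bond table states otherwise.
#'
#' @param atoms a `pocket_atoms` table (>= 2 atoms).
#' @param cutoff contact distance cutoff in Angstrom.
#' @param bond_table optional data.frame (`i`, `j`, `order`) overriding the
#'   multiplicity of specific covalent pairs (e.g. from CONECT records).
#' @return List with `edges` (E x 2 integer matrix holding both directions
#'   of every pair) and `edge_attr` (numeric, aligned with rows of `edges`).
#' @export
build_edges <- function(atoms, cutoff = 4.5, bond_table = NULL) {
  n <- nrow(atoms)
  pg_assert(n >= 2, "need at least two atoms to build edges")
  d <- as.matrix(stats::dist(pocket_coords(atoms)))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0)
    return(list(edges = matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("src", "dst"))),
                edge_attr = numeric()))
  i <- sel[, 1]; j <- sel[, 2]
  dd <- d[sel]
  has_s <- atoms$element[i] == "S" | atoms$element[j] == "S"
  covalent <- dd <= ifelse(has_s, 2.1, 1.9)
  attr1 <- ifelse(covalent, 1, 0)
  if (!is.null(bond_table) && nrow(bond_table)) {
    key <- paste(pmin(i, j), pmax(i, j))
    bkey <- paste(pmin(bond_table$i, bond_table$j), pmax(bond_table$i, bond_table$j))
    hit <- match(key, bkey)
    override <- !is.na(hit) & covalent
    attr1[override] <- bond_table$order[hit[override]]
  }
  edges <- cbind(src = c(i, j), dst = c(j, i))
  list(edges = edges, edge_attr = c(attr1, attr1))
}

#' Normalize pocket coordinates to principal axes
#'
#' Centers the cloud at the origin and rotates it so the principal axes of
#' the coordinate covariance align with the Cartesian axes (variances in
#' nonincreasing order). The axis-sign ambiguity is resolved by forcing the
#' largest-magnitude coordinate along each axis to be positive. Pairwise
#' distances are preserved. Degenerate input (< 3 points or rank-deficient
#' spread) falls back to centering only, flagged via attribute
#' `normalized = FALSE`.
#'
#' @param coords N x 3 numeric matrix (Angstrom).
#' @return N x 3 matrix with attribute `normalized`.
#' @export
normalize_coordinates <- function(coords) {
  coords <- as.matrix(coords)
  pg_assert(ncol(coords) == 3 && all(is.finite(coords)),
            "coords must be a finite N x 3 matrix")
  centered <- sweep(coords, 2, colMeans(coords), `-`)
  if (nrow(coords) < 3)
    return(structure(centered, normalized = FALSE))
  cv <- stats::cov(centered)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] <= 1e-12 * max(ev$values[1], 1e-300))
    return(structure(centered, normalized = FALSE))
  out <- centered %*% ev$vectors
  for (k in 1:3) {
    imax <- which.max(abs(out[, k]))
    if (out[imax, k] < 0) out[, k] <- -out[, k]
  }
  dimnames(out) <- NULL
  structure(out, normalized = TRUE)
}

#' Node feature matrix of a pocket
#'
#' Builds the per-atom feature rows `[hydrophobicity, charge,
#' binding_probability, sasa, entropy, x, y, z]`. The first three and the
#' entropy are residue-level values broadcast to every atom of the residue;
#' SASA and the (normalized) coordinates are per-atom. Residue types absent
#' from the property table resolve to its `UNK` row. A missing entropy
#' profile yields an all-zero entropy column.
#'
#' @param atoms a `pocket_atoms` table.
#' @param table residue property table ([residue_property_table()]).
#' @param sasa per-atom SASA vector.
#' @param entropy per-residue entropy vector (length = number of residues)
#'   or `NULL`.
#' @param coords N x 3 matrix of (typically normalized) coordinates.
#' @return N x 8 numeric matrix with fixed column names.
#' @export
featurize <- function(atoms, table, sasa, entropy = NULL, coords = pocket_coords(atoms)) {
  n <- nrow(atoms)
  pg_assert(length(sasa) == n, "sasa length must match atom count")
  n_res <- max(atoms$residue_index)
  if (is.null(entropy)) entropy <- numeric(n_res)
  pg_assert(length(entropy) == n_res,
            "entropy profile has length ", length(entropy),
            " but pocket has ", n_res, " residues")
  res <- atoms$residue_name
  res[!res %in% rownames(table)] <- "UNK"
  feat <- cbind(
    hydrophobicity = table[res, "hydrophobicity"],
    charge = table[res, "charge"],
    binding_probability = table[res, "binding_probability"],
    sasa = as.numeric(sasa),
    entropy = entropy[atoms$residue_index],
    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  rownames(feat) <- NULL
  feat
}

#' Build the full graph representation of a pocket
#'
#' Composes parsing, SASA, contact-edge construction, coordinate
#' normalization and featurization into a `pocket_graph`.
#'
#' @param atoms a `pocket_atoms` table (from [parse_pocket()]).
#' @param table residue property table; defaults to the bundled scales.
#' @param pocket_id identifier stored in the graph.
#' @param label_smiles optional binder molecule string (supervision label).
#' @param entropy optional per-residue entropy profile.
#' @param cutoff contact cutoff in Angstrom.
#' @param bond_table optional covalent-bond multiplicity table.
#' @param probe,n_points SASA parameters.
#' @return A `pocket_graph`: list with `pocket_id`, `node_features` (N x 8),
#'   `edges` (E x 2, symmetric), `edge_attr`, `coords` (N x 3, normalized),
#'   `label_smiles`, `n_atoms`.
#' @export
to_graph <- function(atoms, table = residue_property_table(), pocket_id = "pocket",
                     label_smiles = NULL, entropy = NULL, cutoff = 4.5,
                     bond_table = NULL, probe = 1.4, n_points = 960) {
  pg_assert(nrow(atoms) >= 2, "pocket must contain at least two atoms")
  sasa <- compute_sasa(atoms, probe = probe, n_points = n_points)
  eg <- build_edges(atoms, cutoff = cutoff, bond_table = bond_table)
  coords <- normalize_coordinates(pocket_coords(atoms))
  feat <- featurize(atoms, table, sasa, entropy = entropy, coords = coords)
  structure(list(
    pocket_id = pocket_id,
    node_features = feat,
    edges = eg$edges,
    edge_attr = eg$edge_attr,
    coords = coords,
    label_smiles = label_smiles,
    n_atoms = nrow(atoms)), class = "pocket_graph")
}

#' @export
print.pocket_graph <- function(x, ...) {
  cat("<pocket_graph> ", x$pocket_id, ": ", x$n_atoms, " atoms, ",
      nrow(x$edges) / 2, " contact pairs",
      if (!is.null(x$label_smiles)) paste0(", label ", x$label_smiles), "\n",
      sep = "")
  invisible(x)
}

# Invariant suite used by tests and by the JSON reader.
validate_pocket_graph <- function(g) {
  pg_assert(inherits(g, "pocket_graph"), "not a pocket_graph")
  n <- g$n_atoms
  pg_assert(nrow(g$node_features) == n && ncol(g$node_features) == 8,
            "node_features must be N x 8")
  if (nrow(g$edges)) {
    pg_assert(!any(g$edges[, 1] == g$edges[, 2]), "self edges present")
    key <- paste(g$edges[, 1], g$edges[, 2])
    rev <- paste(g$edges[, 2], g$edges[, 1])
    pg_assert(!anyDuplicated(key), "duplicate edges")
    hit <- match(rev, key)
    pg_assert(!anyNA(hit), "edge list not symmetric")
    pg_assert(all(g$edge_attr == g$edge_attr[hit]),
              "asymmetric edge attributes")
    d <- sqrt(rowSums((g$coords[g$edges[, 1], , drop = FALSE] -
                       g$coords[g$edges[, 2], , drop = FALSE])^2))
    pg_assert(all(d <= 4.5 + 1e-9), "edge exceeds distance cutoff")
  }
  pg_assert(all(abs(colMeans(g$coords)) < 1e-9), "coords not centered")
  invisible(TRUE)
}

#' Serialize / load a pocket graph as JSON
#'
#' @param graph a `pocket_graph`.
#' @param path output (input) file path.
#' @return `read_pocket_graph` returns the `pocket_graph`.
#' @export
write_pocket_graph <- function(graph, path) {
  obj <- list(pocket_id = graph$pocket_id,
              node_features = graph$node_features,
              edges = graph$edges,
              edge_attr = graph$edge_attr,
              coords = graph$coords,
              label_smiles = graph$label_smiles)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pocket_graph
#' @export
read_pocket_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- matrix(as.integer(obj$edges), ncol = 2,
                  dimnames = list(NULL, c("src", "dst")))
  structure(list(
    pocket_id = obj$pocket_id,
    node_features = as.matrix(obj$node_features),
    edges = edges,
    edge_attr = as.numeric(obj$edge_attr),
    coords = as.matrix(obj$coords),
    label_smiles = obj$label_smiles,
    n_atoms = nrow(as.matrix(obj$coords))), class = "pocket_graph")
}
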