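# Chemical-similarity evaluation protocol: Tanimoto scoring of generated
# molecules against label ligands, hit-rate tables over TC thresholds,
# Fisher-Pitman permutation comparisons and pocket-size/ligand-size
# statistics.

#' Default fingerprint configuration
#'
#' Circular (extended-connectivity, radius 2) substructure fingerprint as
#' produced by OpenBabel's ECFP4, folded to a fixed-width binary vector.
#' Any fingerprint name OpenBabel knows can be substituted.
#'
#' @param method OpenBabel fingerprint name.
#' @return List used as `fp_config` by the TC functions.
#' @export
fp_config <- function(method = "ECFP4") list(method = method)

#' Tanimoto coefficient between two molecules
#'
#' TC = |bits(a) & bits(b)| / |bits(a) | bits(b)| over the configured binary
#' fingerprint. Symmetric; 1 for identical fingerprints. If both
#' fingerprints are empty the molecules are indistinguishable to the
#' fingerprint and the TC is defined as 1.
#'
#' @param mol_a,mol_b SMILES strings.
#' @param config fingerprint configuration ([fp_config()]).
#' @return TC in [0, 1].
#' @export
tanimoto <- function(mol_a, mol_b, config = fp_config()) {
  fps <- morgan_fingerprints(c(mol_a, mol_b), config$method)
  inter <- sum(fps[1, ] & fps[2, ])
  uni <- sum(fps[1, ] | fps[2, ])
  if (uni == 0) return(1)
  inter / uni
}

#' Best Tanimoto score of a sample set against a label ligand
#'
#' Scores every sampled molecule against the label and keeps the maximum;
#' on ties the first molecule in canonical (lexicographic) order wins.
#'
#' @param samples character vector of sampled SMILES (nonempty).
#' @param label_smiles the label ligand.
#' @param config fingerprint configuration.
#' @param pocket_id identifier carried into the result.
#' @return List (`TcScore`) with `pocket_id`, `best_tc`, `best_molecule`.
#' @export
max_tc_score <- function(samples, label_smiles, config = fp_config(),
                         pocket_id = NA_character_) {
  pg_assert(length(samples) >= 1, "empty sample set")
  uniq <- sort(unique(samples), method = "radix")
  fps <- morgan_fingerprints(c(label_smiles, uniq), config$method)
  lab <- fps[1, ]
  rest <- fps[-1, , drop = FALSE]
  inter <- as.numeric(rest %*% lab)
  uni <- rowSums(rest) + sum(lab) - inter
  tc <- ifelse(uni == 0, 1, inter / uni)
  best <- which.max(tc)  # first index on ties = canonical order
  list(pocket_id = pocket_id, best_tc = unname(tc[best]),
       best_molecule = uniq[best])
}

#' Hit rates over TC thresholds
#'
#' Percentage of pockets whose best TC reaches each threshold.
#'
#' @param scores list of `TcScore` results (or numeric vector of best TCs).
#' @param thresholds TC thresholds.
#' @param sample_size,method annotation columns for the report.
#' @return data.frame (`HitRateReport`) with one row per threshold.
#' @export
hit_rates <- function(scores, thresholds = c(0.7, 0.8, 0.9, 1.0),
                      sample_size = NA_integer_, method = "pocketgen") {
  tcs <- if (is.numeric(scores)) scores
         else vapply(scores, function(s) s$best_tc, numeric(1))
  pg_assert(length(tcs) >= 1, "no scores")
  data.frame(method = method,
             sample_size = sample_size,
             threshold = thresholds,
             hit_rate_pct = vapply(thresholds,
                                   function(th) 100 * mean(tcs >= th), numeric(1)))
}

#' Fisher-Pitman permutation test for a difference of group means
#'
#' Two-sided test of the mean difference by re-randomizing group labels.
#' When the number of distinct assignments is at most `n_perm` the reference
#' distribution is enumerated exhaustively (the observed assignment
#' included); otherwise `n_perm` Monte-Carlo permutations are drawn and the
#' +1/+1-corrected estimator is used, guaranteeing p > 0.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @param n_perm permutation budget.
#' @param seed Monte-Carlo seed.
#' @return List with `p_value`, `statistic` (observed mean difference),
#'   `exhaustive` flag and `n_used`.
#' @export
fisher_pitman <- function(group_a, group_b, n_perm = 10000, seed = 1L) {
  pg_assert(length(group_a) >= 1 && length(group_b) >= 1, "both groups must be nonempty")
  v <- c(group_a, group_b)
  na <- length(group_a); nb <- length(group_b)
  n <- na + nb
  tot <- sum(v)
  stat <- function(sum_a) sum_a / na - (tot - sum_a) / nb
  obs <- stat(sum(group_a))
  n_comb <- choose(n, na)
  if (n_comb <= n_perm) {
    idx <- utils::combn(n, na)
    sums <- colSums(matrix(v[idx], nrow = na))
    ref <- abs(stat(sums))
    p <- mean(ref >= abs(obs) - 1e-12)
    return(list(p_value = p, statistic = obs, exhaustive = TRUE,
                n_used = n_comb))
  }
  hits <- with_seed(derive_seed(seed, "fp-perm"), {
    sum(vapply(seq_len(n_perm), function(k) {
      sa <- sum(v[sample.int(n, na)])
      abs(stat(sa)) >= abs(obs) - 1e-12
    }, logical(1)))
  })
  list(p_value = (hits + 1) / (n_perm + 1), statistic = obs,
       exhaustive = FALSE, n_used = n_perm)
}

#' Heavy-atom count of a molecule
#'
#' @param smiles a SMILES string.
#' @return Number of non-hydrogen atoms.
#' @export
ligand_size <- function(smiles) {
  kek <- kekulize_smiles(smiles)
  pg_assert(!is.na(kek), "cannot parse molecule: ", smiles)
  mol_n_atoms(parse_smiles(kek))
}

# Pocket size bins: <100, 100-160, 161-220, >220 heavy atoms.
pocket_size_bin <- function(n_atoms) {
  cut(n_atoms, breaks = c(0, 99.5, 160.5, 220.5, Inf),
      labels = c("<100", "100-160", "161-220", ">220"))
}

#' Ligand-size statistics by pocket-size group
#'
#' Assigns pockets to four size bins (<100, 100-160, 161-220, >220 heavy
#' atoms) and reports quartiles (linear interpolation) and the interquartile
#' range of the paired ligand heavy-atom counts per bin.
#'
#' @param pocket_sizes integer vector of pocket heavy-atom counts.
#' @param ligand_sizes integer vector of paired ligand heavy-atom counts.
#' @return data.frame with one row per (occupied) bin: `bin`, `n`, `q1`,
#'   `median`, `q3`, `iqr`.
#' @export
size_group_stats <- function(pocket_sizes, ligand_sizes) {
  pg_assert(length(pocket_sizes) == length(ligand_sizes),
            "pocket and ligand size vectors must align")
  pg_assert(all(pocket_sizes >= 1) && all(ligand_sizes >= 1), "sizes must be >= 1")
  bins <- pocket_size_bin(pocket_sizes)
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    x <- ligand_sizes[bins == b]
    if (!length(x)) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(bin = b, n = length(x), q1 = q[1], median = q[2], q3 = q[3],
               iqr = q[3] - q[1], stringsAsFactors = FALSE)
  }))
  out$bin <- factor(out$bin, levels = levels(bins))
  out
}

#' Score every pocket of a labeled sample table
#'
#' Convenience wrapper for the full evaluation protocol: joins a sample
#' table (pocket_id, smiles multisets) with a pairing table of labels and
#' computes per-pocket best-TC scores.
#'
#' @param samples_by_pocket named list: pocket_id -> character vector of
#'   sampled SMILES.
#' @param pairing data.frame (`pocket_id`, `smiles`) of label ligands.
#' @param config fingerprint configuration.
#' @return List of `TcScore` results.
#' @export
score_pockets <- function(samples_by_pocket, pairing, config = fp_config()) {
  lapply(names(samples_by_pocket), function(id) {
    hit <- match(id, pairing$pocket_id)
    pg_assert(!is.na(hit), "no label for pocket ", id)
    max_tc_score(samples_by_pocket[[id]], pairing$smiles[hit],
                 config = config, pocket_id = id)
  })
}
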