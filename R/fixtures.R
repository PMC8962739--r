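# Synthetic fixtures: deterministic pocket structure files, a built-in
# drug-like ligand library, and planted pocket-to-ligand datasets with known
# ground truth. The planted signal lives in the graph feature channels the
# encoder can see (residue composition), never in identifiers, so a model
# that recovers the mapping must have learned it through the encoder.

#' Built-in ligand library
#'
#' 23 neutral, drug-like molecules spanning 3-30 heavy atoms (solvent-sized
#' alcohols up to tamoxifen), embedded as literals so fixtures never require
#' a download. All are valid, stereochemistry-free and within the
#' tokenizer's element subset and sequence-length default.
#'
#' @return Named character vector of SMILES.
#' @export
fixture_ligand_library <- function() {
  c(ethanol = "CCO",
    acetic_acid = "CC(=O)O",
    fluoroform = "FC(F)F",
    thiophene = "c1ccsc1",
    benzene = "c1ccccc1",
    piperidine = "C1CCNCC1",
    alanine = "CC(N)C(=O)O",
    ethyl_acetate = "CCOC(=O)C",
    chlorobenzene = "Clc1ccccc1",
    triethylamine = "CCN(CC)CC",
    benzonitrile = "N#Cc1ccccc1",
    naphthalene = "c1ccc2ccccc2c1",
    salicylic_acid = "O=C(O)c1ccccc1O",
    isonicotinamide = "NC(=O)c1ccncc1",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    glucose = "OCC1OC(O)C(O)C(O)C1O",
    nicotine = "CN1CCCC1c1cccnc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    melatonin = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    tamoxifen = "CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1")
}

# Residue codes ordered so that consecutive planted pockets are maximally
# separated in the hydrophobicity/charge/binding-probability channels.
PLANT_RESIDUES <- c("ILE", "ARG", "ALA", "TRP", "GLY", "LYS", "PHE", "ASP",
                    "VAL", "HIS", "MET", "GLU", "CYS", "SER", "LEU", "TYR",
                    "THR", "PRO", "ASN", "GLN")

#' Generate a synthetic pocket structure file
#'
#' Emits syntactically valid PDB ATOM records forming a compact cluster:
#' atoms are placed sequentially 1.4-1.8 Angstrom from a random existing
#' atom, rejected below 1.2 Angstrom from any atom or beyond a 40 Angstrom
#' diameter. Residue names are drawn from `residue_pool`; elements cycle
#' through a protein-like C/N/O/S mixture. Fully deterministic under
#' `seed`.
#'
#' @param n_atoms number of heavy atoms (>= 4).
#' @param seed RNG seed.
#' @param residue_pool residue codes to draw from (default: all 20).
#' @param atoms_per_residue average atoms per residue.
#' @param n_hydrogens additionally interleave this many hydrogen records
#'   (parsers must drop them).
#' @return A single string of PDB-format text.
#' @export
make_pocket_pdb <- function(n_atoms, seed = 1L,
                            residue_pool = PLANT_RESIDUES,
                            atoms_per_residue = 4, n_hydrogens = 0) {
  pg_assert(n_atoms >= 4, "n_atoms must be >= 4")
  with_seed(seed, {
    xyz <- matrix(0, n_atoms, 3)
    for (i in 2:n_atoms) {
      repeat {
        anchor <- xyz[sample.int(i - 1, 1), ]
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- anchor + dir * stats::runif(1, 1.4, 1.8)
        d <- sqrt(colSums((t(xyz[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        if (min(d) >= 1.2 && max(abs(cand)) < 19) break
      }
      xyz[i, ] <- cand
    }
    n_res <- max(1L, round(n_atoms / atoms_per_residue))
    res_names <- sample(residue_pool, n_res, replace = TRUE)
    res_of_atom <- sort(rep_len(seq_len(n_res), n_atoms))
    elements <- sample(c("C", "C", "C", "N", "O", "S"), n_atoms, replace = TRUE)
    lines <- character()
    serial <- 0L
    counts <- integer(n_res)
    for (i in seq_len(n_atoms)) {
      serial <- serial + 1L
      r <- res_of_atom[i]
      counts[r] <- counts[r] + 1L
      name <- paste0(elements[i], counts[r])
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, name, res_names[r], r, xyz[i, 1], xyz[i, 2], xyz[i, 3],
        elements[i]))
      if (n_hydrogens > 0 && i <= n_hydrogens) {
        serial <- serial + 1L
        h <- xyz[i, ] + c(0.35, 0.35, 0.0)
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, paste0("H", counts[r]), res_names[r], r,
          h[1], h[2], h[3], "H"))
      }
    }
    paste(c(lines, "END"), collapse = "\n")
  })
}

#' Generate a planted pocket-to-ligand dataset
#'
#' Builds `k` synthetic pockets, each with a distinctive residue
#' composition, injectively paired with `k` distinct ligands from the
#' built-in library. With planted-signal strength `signal` every residue of
#' pocket i takes the pocket's planted residue type with probability
#' `signal` (uniform over all 20 types otherwise), so `signal = 1` gives
#' cleanly separable feature distributions and `signal = 0` makes the
#' pockets statistically indistinguishable (the null control).
#'
#' @param k number of pockets (<= library size and <= 20).
#' @param n_atoms_range inclusive range of heavy atoms per pocket.
#' @param signal planted-signal strength in [0, 1].
#' @param seed seed; fully determines the dataset.
#' @param library ligand library (named SMILES vector).
#' @param vocab optional vocabulary; defaults to one built over the whole
#'   library so datasets of any k share token indices.
#' @return A `pg_dataset` with extra fields `mapping` (data.frame
#'   `pocket_id`, `smiles`, `planted_residue`), `pdb_texts`, `signal`,
#'   `seed`.
#' @export
make_planted_dataset <- function(k = 8, n_atoms_range = c(50, 90), signal = 1,
                                 seed = 7L, library = fixture_ligand_library(),
                                 vocab = NULL) {
  pg_assert(k >= 1, "k must be >= 1")
  pg_assert(k <= length(library) && k <= length(PLANT_RESIDUES),
            "k exceeds the ligand library / planted residue inventory (max ",
            min(length(library), length(PLANT_RESIDUES)), ")")
  pg_assert(signal >= 0 && signal <= 1, "signal must be in [0, 1]")
  if (is.null(vocab)) vocab <- build_vocab(library)
  lig_idx <- with_seed(derive_seed(seed, "ligand-assign"),
                       sample.int(length(library), k))
  sizes <- with_seed(derive_seed(seed, "pocket-sizes"),
                     sample(n_atoms_range[1]:n_atoms_range[2], k, replace = TRUE))
  all20 <- sort(unique(c(PLANT_RESIDUES)))
  graphs <- vector("list", k)
  pdbs <- character(k)
  for (i in seq_len(k)) {
    # residue pool realizing the planted composition at the given strength
    pool_seed <- derive_seed(seed, paste0("pool-", i))
    n_draw <- 64
    pool <- with_seed(pool_seed, {
      planted <- stats::runif(n_draw) < signal
      ifelse(planted, PLANT_RESIDUES[i], sample(all20, n_draw, replace = TRUE))
    })
    pdbs[i] <- make_pocket_pdb(sizes[i], seed = derive_seed(seed, paste0("pdb-", i)),
                               residue_pool = pool)
    atoms <- parse_pocket(pdbs[i])
    graphs[[i]] <- to_graph(atoms, pocket_id = sprintf("pocket_%02d", i),
                            label_smiles = unname(library[lig_idx[i]]))
  }
  ds <- make_paired_dataset(graphs, vocab = vocab)
  ds$mapping <- data.frame(
    pocket_id = vapply(graphs, function(g) g$pocket_id, character(1)),
    smiles = unname(library[lig_idx]),
    planted_residue = if (signal > 0) PLANT_RESIDUES[seq_len(k)] else NA_character_,
    stringsAsFactors = FALSE)
  ds$pdb_texts <- pdbs
  ds$signal <- signal
  ds$seed <- seed
  ds
}

#' Write a fixture dataset to disk
#'
#' Writes one PDB per pocket plus a pairing TSV, directly consumable by the
#' featurize/train tooling.
#'
#' @param dataset output of [make_planted_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$pairs)) {
    id <- dataset$pairs[[i]]$graph$pocket_id
    writeLines(dataset$pdb_texts[i], file.path(dir, paste0(id, ".pdb")))
  }
  utils::write.table(dataset$mapping[, c("pocket_id", "smiles")],
                     file.path(dir, "pairing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
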