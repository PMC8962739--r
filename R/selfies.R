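# SELFIES-family token grammar. Every token sequence over the chemical
# alphabet derives a molecule that satisfies the standard valences, so the
# decoder is total: arbitrary (even random) sequences always yield valid
# molecules. Encoding walks a DFS spanning tree of the Kekule molecular
# graph; branches and rings store their size/target locally through
# overloaded index symbols, one base-16 digit per symbol.

# Fixed 16-symbol table used to read tokens as digits 0..15 after Branch/Ring
# identifiers (tokens not in the table read as 0).
SELFIES_INDEX_TOKENS <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[Branch2]", "[O]", "[N]",
  "[=N]", "[=C]", "[#C]", "[S]", "[P]", "[=O]", "[Cl]", "[F]", "[=S]")

#' The chemical token alphabet of the SELFIES grammar
#'
#' Atom tokens carry the bond order to the preceding atom as a prefix
#' (none/`=`/`#`), capped at the element's standard valence. Structural
#' tokens open branches (`[Branch1]`, `[Branch2]`) and close rings
#' (`[Ring1]`, `[=Ring1]`, `[Ring2]`, `[=Ring2]`); each is followed by one
#' (`1`) or two (`2`) index symbols encoding the branch length or ring
#' target distance in base 16.
#'
#' @return Character vector of all chemical tokens, in a fixed order.
#' @export
selfies_alphabet <- function() {
  toks <- character()
  for (el in names(PG_VALENCE)) {
    for (b in seq_len(min(3, PG_VALENCE[[el]])))
      toks <- c(toks, sprintf("[%s%s]", BOND_SYMBOL[b], el))
  }
  c(toks, "[Branch1]", "[Branch2]", "[Ring1]", "[=Ring1]", "[Ring2]", "[=Ring2]")
}

# Parse one token into its kind and parameters.
selfies_token_info <- function(tok) {
  m <- regmatches(tok, regexec("^\\[([=#]?)([A-Z][a-z]?)\\]$", tok))[[1]]
  if (length(m)) {
    el <- m[3]
    pg_assert(el %in% names(PG_VALENCE), "unknown element in SELFIES token: ", tok)
    return(list(kind = "atom", order = match(m[2], c("", "=", "#")), element = el))
  }
  m <- regmatches(tok, regexec("^\\[Branch([12])\\]$", tok))[[1]]
  if (length(m)) return(list(kind = "branch", ndigits = as.integer(m[2])))
  m <- regmatches(tok, regexec("^\\[(=?)Ring([12])\\]$", tok))[[1]]
  if (length(m)) return(list(kind = "ring", order = if (m[2] == "=") 2L else 1L,
                             ndigits = as.integer(m[3])))
  pg_stop("unknown SELFIES token: ", tok)
}

selfies_digit_value <- function(tok) {
  i <- match(tok, SELFIES_INDEX_TOKENS)
  if (is.na(i)) 0L else i - 1L
}

selfies_digit_tokens <- function(q, ndigits) {
  out <- character(ndigits)
  for (k in seq_len(ndigits)) {
    out[ndigits - k + 1] <- SELFIES_INDEX_TOKENS[(q %% 16L) + 1L]
    q <- q %/% 16L
  }
  out
}

# ---------------------------------------------------------------------------
# Derivation: tokens -> molgraph. Total on any token vector.
selfies_to_mol <- function(tokens) {
  G <- new.env(parent = emptyenv())
  G$element <- character()
  G$cap <- numeric()
  G$bonds <- matrix(integer(), ncol = 3)
  add_atom <- function(el) {
    G$element <- c(G$element, el)
    G$cap <- c(G$cap, PG_VALENCE[[el]])
    length(G$element)
  }
  add_bond <- function(a, b, order) {
    lo <- min(a, b); hi <- max(a, b)
    G$bonds <- rbind(G$bonds, c(lo, hi, order))
    G$cap[a] <- G$cap[a] - order
    G$cap[b] <- G$cap[b] - order
  }
  bond_exists <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    nrow(G$bonds) > 0 && any(G$bonds[, 1] == lo & G$bonds[, 2] == hi)
  }
  read_q <- function(toks, i, nd) {
    q <- 0L
    for (k in seq_len(nd)) {
      d <- if (i + k - 1L <= length(toks)) selfies_digit_value(toks[i + k - 1L]) else 0L
      q <- q * 16L + d
    }
    q
  }
  derive <- function(toks, attach) {
    cur <- attach
    i <- 1L
    n <- length(toks)
    while (i <= n) {
      info <- selfies_token_info(toks[i])
      i <- i + 1L
      if (info$kind == "atom") {
        if (is.na(cur)) {
          cur <- add_atom(info$element)
        } else {
          if (G$cap[cur] < 1) return(invisible(NULL))  # scope saturated: stop deriving
          m <- min(info$order, G$cap[cur], PG_VALENCE[[info$element]])
          new <- add_atom(info$element)
          add_bond(cur, new, m)
          cur <- new
        }
      } else if (info$kind == "branch") {
        q <- read_q(toks, i, info$ndigits)
        i <- i + info$ndigits
        len <- q + 1L
        # a branch needs one bond for its first atom and one for the chain
        if (!is.na(cur) && G$cap[cur] >= 2 && i <= n) {
          win <- toks[i:min(n, i + len - 1L)]
          derive(win, cur)
          i <- i + length(win)
        }
        # otherwise the construct is skipped and the body reads as main chain
      } else { # ring
        q <- read_q(toks, i, info$ndigits)
        i <- i + info$ndigits
        if (is.na(cur)) next
        tgt <- max(1L, length(G$element) - (q + 1L))
        if (tgt == cur || bond_exists(tgt, cur)) next
        m <- min(info$order, G$cap[cur], G$cap[tgt])
        if (m >= 1) add_bond(tgt, cur, m)
      }
    }
    invisible(NULL)
  }
  derive(tokens, NA_integer_)
  new_molgraph(G$element, G$bonds)
}

# ---------------------------------------------------------------------------
# Encoding: molgraph -> tokens, by DFS spanning tree from atom 1.
mol_to_selfies <- function(mol) {
  n <- mol_n_atoms(mol)
  if (n == 0) return(character())
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, "i"]; j <- mol$bonds[r, "j"]; o <- mol$bonds[r, "order"]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  visited <- logical(n)
  pos <- integer(n)        # discovery order = derivation order at decode time
  parent <- rep(NA_integer_, n)
  porder <- rep(NA_integer_, n)
  children <- vector("list", n)
  rings_at <- vector("list", n)  # attached at later endpoint: c(target, order)
  counter <- 0L
  dfs <- function(u) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    pos[u] <<- counter
    if (!is.null(adj[[u]])) {
      nb <- adj[[u]][order(adj[[u]][, 1]), , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; o <- nb[r, 2]
        if (!visited[v]) {
          parent[v] <<- u; porder[v] <<- o
          children[[u]] <<- c(children[[u]], v)
          dfs(v)
        }
      }
    }
  }
  dfs(1L)
  pg_assert(all(visited), "molecular graph is disconnected; cannot encode")
  # non-tree edges attach at the endpoint discovered later
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, "i"]; j <- mol$bonds[r, "j"]; o <- mol$bonds[r, "order"]
      tree <- (!is.na(parent[i]) && parent[i] == j) ||
              (!is.na(parent[j]) && parent[j] == i)
      if (!tree) {
        late <- if (pos[i] > pos[j]) i else j
        early <- if (late == i) j else i
        pg_assert(o <= 2, "ring-closure bonds of order ", o, " are not representable")
        rings_at[[late]] <- c(rings_at[[late]], list(c(early, o)))
      }
    }
  }
  atom_token <- function(el, order) {
    pg_assert(order <= min(3, PG_VALENCE[[el]]),
              "bond order ", order, " exceeds capacity of element ", el)
    sprintf("[%s%s]", BOND_SYMBOL[order], el)
  }
  sized_tokens <- function(q, kind, order = 1L) {
    if (kind == "branch") {
      pg_assert(q <= 255, "branch too long for the grammar (", q + 1, " tokens)")
      nd <- if (q <= 15) 1L else 2L
      c(sprintf("[Branch%d]", nd), selfies_digit_tokens(q, nd))
    } else {
      pg_assert(q <= 255, "ring span too long for the grammar")
      nd <- if (q <= 15) 1L else 2L
      c(sprintf("[%sRing%d]", if (order == 2) "=" else "", nd),
        selfies_digit_tokens(q, nd))
    }
  }
  emit <- function(u) {
    out <- atom_token(mol$element[u], if (is.na(parent[u])) 1L else porder[u])
    rg <- rings_at[[u]]
    if (length(rg)) {
      ord_idx <- order(vapply(rg, function(x) pos[x[1]], numeric(1)))
      for (b in rg[ord_idx])
        out <- c(out, sized_tokens(pos[u] - pos[b[1]] - 1L, "ring", b[2]))
    }
    ch <- children[[u]]
    if (length(ch)) {
      if (length(ch) > 1) {
        for (c_ in ch[-length(ch)]) {
          body <- emit(c_)
          out <- c(out, sized_tokens(length(body) - 1L, "branch"), body)
        }
      }
      out <- c(out, emit(ch[length(ch)]))
    }
    out
  }
  emit(1L)
}

#' Tokenize a molecule string
#'
#' Converts a SMILES string into a sequence of SELFIES tokens. The input is
#' syntax-checked, kekulized (aromatic rings rewritten with alternating
#' bonds) and parsed into a molecular graph before encoding, so decoding the
#' returned tokens yields a molecule canonically identical to the input.
#'
#' @param smiles a single SMILES string describing a valid, neutral molecule.
#' @return Character vector of SELFIES tokens.
#' @examples
#' \donttest{
#' smiles_to_tokens("CCO")
#' }
#' @export
smiles_to_tokens <- function(smiles) {
  check_smiles_syntax(smiles)
  kek <- kekulize_smiles(smiles)
  pg_assert(!is.na(kek), "OpenBabel could not interpret SMILES '", smiles, "'")
  mol_to_selfies(parse_smiles(kek))
}

#' Decode SELFIES tokens to a molecule string
#'
#' Total on any token vector over the chemical alphabet: branch/ring
#' constructs that cannot apply are skipped and bond orders are capped by
#' the remaining valence, so the result is always a valid molecule.
#'
#' @param tokens character vector of SELFIES tokens.
#' @return A Kekule SMILES string; `""` (with attribute `empty = TRUE`) when
#'   the sequence derives no atoms.
#' @export
tokens_to_smiles <- function(tokens) {
  mol <- selfies_to_mol(tokens)
  if (mol_n_atoms(mol) == 0) return(structure("", empty = TRUE))
  write_smiles(mol)
}
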