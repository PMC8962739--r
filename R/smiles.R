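# Minimal molecular-graph type plus a strict parser/writer for Kekule-form
# SMILES. The SELFIES grammar (R/selfies.R) interconverts with this graph
# type; aromatic input is kekulized through OpenBabel before parsing.
#
# Scope: neutral molecules over the drug-like element set with standard
# valences. Charges, isotopes, stereochemistry and multi-fragment strings
# are rejected with explicit errors.

# Standard (implicit-hydrogen) valences of the supported elements.
PG_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                F = 1, Cl = 1, Br = 1, I = 1)

BOND_SYMBOL <- c("", "=", "#")  # index = bond order

# Constructor: element is a character vector, bonds an integer matrix with
# columns i, j, order (i < j, no duplicates).
new_molgraph <- function(element, bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  structure(list(element = element, bonds = bonds), class = "molgraph")
}

mol_n_atoms <- function(mol) length(mol$element)

# Remaining implicit-hydrogen count per atom; negative values mean the graph
# violates the standard valences.
mol_free_valence <- function(mol) {
  used <- numeric(mol_n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      used[mol$bonds[r, "i"]] <- used[mol$bonds[r, "i"]] + mol$bonds[r, "order"]
      used[mol$bonds[r, "j"]] <- used[mol$bonds[r, "j"]] + mol$bonds[r, "order"]
    }
  }
  unname(PG_VALENCE[mol$element]) - used
}

# ---------------------------------------------------------------------------
# Syntax-level SMILES validation (accepts aromatic form). Catches malformed
# strings that permissive chemistry toolkits silently "repair", so that
# unparseable input raises an explicit error naming the offending string.
check_smiles_syntax <- function(smiles) {
  pg_assert(is.character(smiles) && length(smiles) == 1 && !is.na(smiles),
            "SMILES must be a single string")
  pg_assert(nzchar(smiles), "empty SMILES string")
  s <- smiles
  err <- function(what, pos) {
    pg_stop("invalid SMILES '", s, "': ", what, " at position ", pos)
  }
  n <- nchar(s)
  depth <- 0L
  open_rings <- integer()
  seen_atom <- FALSE
  pending_bond <- FALSE
  i <- 1L
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) err("unclosed bracket atom", i)
      seen_atom <- TRUE; pending_bond <- FALSE
      i <- i + j
    } else if (ch == "(") {
      if (!seen_atom) err("branch before any atom", i)
      if (pending_bond) err("bond symbol before '('", i)
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == ")") {
      if (depth == 0L) err("unmatched ')'", i)
      if (pending_bond) err("dangling bond before ')'", i)
      depth <- depth - 1L
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (pending_bond) err("two consecutive bond symbols", i)
      pending_bond <- TRUE
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (!seen_atom) err("ring closure before any atom", i)
      if (ch == "%") {
        num <- substr(s, i + 1, i + 2)
        if (!grepl("^[0-9]{2}$", num)) err("malformed %nn ring closure", i)
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      k <- as.integer(num)
      hit <- match(k, open_rings)
      if (is.na(hit)) open_rings <- c(open_rings, k) else open_rings <- open_rings[-hit]
      pending_bond <- FALSE
    } else if (grepl("^[A-Za-z*]$", ch)) {
      seen_atom <- TRUE; pending_bond <- FALSE
      # two-letter elements
      if (ch %in% c("C", "B") && i < n && substr(s, i + 1, i + 1) %in% c("l", "r")) {
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else if (ch == ".") {
      err("multi-fragment SMILES are not supported", i)
    } else {
      err(paste0("unexpected character '", ch, "'"), i)
    }
  }
  if (depth > 0L) pg_stop("invalid SMILES '", s, "': unclosed branch parenthesis")
  if (pending_bond) pg_stop("invalid SMILES '", s, "': trailing bond symbol")
  if (length(open_rings)) pg_stop("invalid SMILES '", s, "': unclosed ring bond ",
                                  paste(open_rings, collapse = ", "))
  if (!seen_atom) pg_stop("invalid SMILES '", s, "': contains no atoms")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Strict parser for Kekule-form SMILES -> molgraph.
parse_smiles <- function(smiles) {
  check_smiles_syntax(smiles)
  s <- smiles
  n <- nchar(s)
  err <- function(what, pos) {
    pg_stop("cannot parse SMILES '", s, "': ", what, " at position ", pos)
  }
  element <- character()
  h_explicit <- integer()   # NA = bare atom (implicit H)
  bonds <- matrix(integer(), ncol = 3)
  add_bond <- function(a, b, order, pos) {
    if (a == b) err("self bond", pos)
    lo <- min(a, b); hi <- max(a, b)
    if (nrow(bonds) && any(bonds[, 1] == lo & bonds[, 2] == hi))
      err("duplicate bond", pos)
    bonds <<- rbind(bonds, c(lo, hi, order))
  }
  prev <- NA_integer_
  pending <- NA_integer_
  stack <- integer()
  rings <- list()           # key: ring number -> c(atom, order or NA)
  new_atom <- function(el, h, pos) {
    if (!el %in% names(PG_VALENCE))
      err(paste0("unsupported element '", el, "'"), pos)
    element[length(element) + 1L] <<- el
    h_explicit[length(h_explicit) + 1L] <<- h
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- if (is.na(pending)) 1L else pending
      add_bond(prev, idx, ord, pos)
    } else if (!is.na(pending)) err("bond symbol before first atom", pos)
    pending <<- NA_integer_
    prev <<- idx
  }
  i <- 1L
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body, regexec("^([A-Z][a-z]?)(H([0-9]*))?$", body))[[1]]
      if (length(m) == 0)
        err(paste0("unsupported bracket atom '[", body,
                   "]' (charges/isotopes/stereo are out of scope)"), i)
      h <- if (m[3] == "") 0L else if (m[4] == "") 1L else as.integer(m[4])
      new_atom(m[2], h, i)
      i <- i + j
    } else if (ch %in% c("-", "=", "#")) {
      pending <- match(ch, c("-", "=", "#"))
      i <- i + 1L
    } else if (ch == ":") {
      err("aromatic bond in Kekule parser", i)
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        num <- as.integer(substr(s, i + 1L, i + 2L)); i <- i + 3L
      } else {
        num <- as.integer(ch); i <- i + 1L
      }
      key <- as.character(num)
      ord_here <- pending; pending <- NA_integer_
      if (is.null(rings[[key]])) {
        rings[[key]] <- c(prev, if (is.na(ord_here)) NA_integer_ else ord_here)
      } else {
        open <- rings[[key]]
        ord_open <- open[2]
        ord <- if (!is.na(ord_open) && !is.na(ord_here)) {
          if (ord_open != ord_here) err("conflicting ring bond orders", i - 1L)
          ord_open
        } else if (!is.na(ord_open)) ord_open
          else if (!is.na(ord_here)) ord_here else 1L
        add_bond(open[1], prev, ord, i - 1L)
        rings[[key]] <- NULL
      }
    } else {
      el <- ch
      if (ch %in% c("C", "B") && i < n && substr(s, i + 1L, i + 1L) %in% c("l", "r"))
        el <- substr(s, i, i + 1L)
      if (grepl("^[a-z]$", ch))
        err("aromatic (lowercase) atom; kekulize the SMILES first", i)
      new_atom(el, NA_integer_, i)
      i <- i + nchar(el)
    }
  }
  mol <- new_molgraph(element, bonds)
  # valence validation against the standard table
  free <- mol_free_valence(mol)
  for (a in seq_along(element)) {
    if (is.na(h_explicit[a])) {
      if (free[a] < 0)
        pg_stop("cannot parse SMILES '", s, "': atom ", a, " (", element[a],
                ") exceeds its standard valence")
    } else if (free[a] != h_explicit[a]) {
      pg_stop("cannot parse SMILES '", s, "': atom ", a, " (", element[a],
              ") has explicit H count ", h_explicit[a],
              " inconsistent with standard valence")
    }
  }
  mol
}

# ---------------------------------------------------------------------------
# molgraph -> Kekule SMILES. Atoms are emitted bare (implicit hydrogens fill
# the standard valence, which parse/derivation guarantee).
write_smiles <- function(mol) {
  n <- mol_n_atoms(mol)
  if (n == 0) return("")
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, "i"]; j <- mol$bonds[r, "j"]; o <- mol$bonds[r, "order"]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  porder <- rep(NA_integer_, n)
  children <- vector("list", n)
  back_at <- vector("list", n)  # per atom: list of c(partner, order)
  ring_no <- 0L
  ring_ids <- new.env(parent = emptyenv())
  dfs <- function(u) {
    visited[u] <<- TRUE
    if (!is.null(adj[[u]])) {
      nb <- adj[[u]][order(adj[[u]][, 1]), , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; o <- nb[r, 2]
        if (!visited[v]) {
          parent[v] <<- u; porder[v] <<- o
          children[[u]] <<- c(children[[u]], v)
          dfs(v)
        } else {
          is_parent_edge <- !is.na(parent[u]) && v == parent[u]
          key <- paste(min(u, v), max(u, v))
          if (!is_parent_edge && !exists(key, envir = ring_ids)) {
            ring_no <<- ring_no + 1L
            assign(key, ring_no, envir = ring_ids)
            back_at[[u]] <<- c(back_at[[u]], list(c(v, o, ring_no)))
            back_at[[v]] <<- c(back_at[[v]], list(c(u, o, ring_no)))
          }
        }
      }
    }
  }
  dfs(1L)
  pg_assert(all(visited), "molecular graph is disconnected; cannot write SMILES")
  ring_digit <- function(k) if (k < 10) as.character(k) else sprintf("%%%02d", k)
  emit <- function(u) {
    out <- if (is.na(parent[u])) mol$element[u]
           else paste0(BOND_SYMBOL[porder[u]], mol$element[u])
    for (b in back_at[[u]])
      out <- paste0(out, BOND_SYMBOL[b[2]], ring_digit(b[3]))
    ch <- children[[u]]
    if (length(ch)) {
      if (length(ch) > 1)
        for (c_ in ch[-length(ch)]) out <- paste0(out, "(", emit(c_), ")")
      out <- paste0(out, emit(ch[length(ch)]))
    }
    out
  }
  emit(1L)
}
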