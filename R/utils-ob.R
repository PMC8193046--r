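# Low-level OpenBabel helpers. All chemistry I/O funnels through these so the
# aromaticity / canonicalisation model is applied uniformly at parse time.

# Remove stereo descriptors at the string level. '@' occurs only inside
# bracket atoms (tetrahedral marks), '/' and '\' only as directional bonds,
# so deleting the characters preserves constitution.
.strip_stereo_text <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

# Canonical SMILES of a single structure via OpenBabel; "" signals a parse
# failure (OpenBabel warns on stderr and emits nothing).
.ob_canonical <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  sub("[ \t\n]+$", "", out)
}

# Persistent OBMol references for a vector of (valid) SMILES. Building these
# once and matching many SMARTS against them avoids re-parsing the molecule
# for every pattern.
.mol_refs <- function(smiles) {
  lapply(smiles, function(s) ChemmineOB::forEachMol("SMILES", s, identity)[[1]])
}

# Symmetry-deduplicated embedding counts of one SMARTS over OBMol refs.
.match_counts <- function(refs, smarts) {
  if (length(refs) == 0L) return(integer(0))
  as.integer(ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = TRUE))
}

# Parse a SMILES into an annotated graph using OpenBabel's mol2 writer, which
# exposes per-atom and per-bond aromaticity after perception. Returns
# list(atoms = data.frame(element, aromatic), bonds = data.frame(a1, a2,
# aromatic)) with hydrogens excluded.
.mol_graph <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "MOL2", smiles)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  tags <- grep("^@<TRIPOS>", lines)
  section <- function(name) {
    start <- which(lines == paste0("@<TRIPOS>", name))
    if (length(start) != 1L) return(character(0))
    nxt <- tags[tags > start]
    stop_at <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    if (stop_at < start + 1L) return(character(0))
    out <- lines[(start + 1L):stop_at]
    out[nzchar(trimws(out))]
  }
  atom_lines <- section("ATOM")
  bond_lines <- section("BOND")
  stopifnot(length(atom_lines) > 0L)

  af <- strsplit(trimws(atom_lines), "[ \t]+")
  types <- vapply(af, `[`, "", 6L)
  elements <- sub("\\..*$", "", types)
  aromatic <- grepl("\\.ar$", types)
  atoms <- data.frame(element = elements, aromatic = aromatic,
                      stringsAsFactors = FALSE)

  if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[ \t]+")
    bonds <- data.frame(
      a1 = as.integer(vapply(bf, `[`, "", 2L)),
      a2 = as.integer(vapply(bf, `[`, "", 3L)),
      aromatic = vapply(bf, `[`, "", 4L) == "ar",
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), aromatic = logical(0))
  }

  # mol2 atom types have no aromatic variant for O/S (no "O.ar"/"S.ar"),
  # so an atom is also aromatic when it lies on an aromatic bond
  if (nrow(bonds)) {
    ar <- bonds[bonds$aromatic, , drop = FALSE]
    atoms$aromatic[c(ar$a1, ar$a2)] <- TRUE
  }

  keep <- atoms$element != "H"
  if (!all(keep)) {
    idx <- cumsum(keep)
    bonds <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
    bonds$a1 <- idx[bonds$a1]
    bonds$a2 <- idx[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  list(atoms = atoms, bonds = bonds)
}

# Adjacency list from a bond table.
.adjacency <- function(n_atoms, bonds) {
  adj <- rep(list(integer(0)), n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Connected components over a subset of atoms using a subset of bonds.
# Returns a list of integer vectors (atom indices).
.components <- function(atoms_keep, bonds) {
  comp <- list()
  seen <- logical(max(c(atoms_keep, 0L)))
  adj <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- as.character(bonds$a1[k]); j <- as.character(bonds$a2[k])
    adj[[i]] <- c(adj[[i]], bonds$a2[k])
    adj[[j]] <- c(adj[[j]], bonds$a1[k])
  }
  for (a in atoms_keep) {
    if (seen[a]) next
    queue <- a; members <- integer(0)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      nb <- adj[[as.character(v)]]
      nb <- nb[nb %in% atoms_keep & !seen[nb]]
      queue <- c(queue, nb)
    }
    comp[[length(comp) + 1L]] <- sort(members)
  }
  comp
}

# Bridge (cut-edge) detection; an atom lies on a ring iff it has an incident
# non-bridge edge. Iterative Tarjan low-link to avoid recursion limits.
.ring_atoms <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L || n_atoms == 0L) return(logical(n_atoms))
  adj <- rep(list(integer(0)), n_atoms)   # store bond index alongside
  badj <- rep(list(integer(0)), n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); badj[[i]] <- c(badj[[i]], k)
    adj[[j]] <- c(adj[[j]], i); badj[[j]] <- c(badj[[j]], k)
  }
  disc <- rep(0L, n_atoms); low <- rep(0L, n_atoms)
  is_bridge <- rep(FALSE, nrow(bonds))
  timer <- 0L
  for (root in seq_len(n_atoms)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, parent_edge = 0L, i = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i == 1L) {
        timer <- timer + 1L
        disc[v] <- timer; low[v] <- timer
      }
      if (fr$i <= length(adj[[v]])) {
        u <- adj[[v]][fr$i]; e <- badj[[v]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (e == fr$parent_edge) next
        if (disc[u] != 0L) {
          low[v] <- min(low[v], disc[u])
        } else {
          stack[[length(stack) + 1L]] <- list(v = u, parent_edge = e, i = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pv <- stack[[length(stack)]]$v
          pe <- fr$parent_edge
          low[pv] <- min(low[pv], low[v])
          if (low[v] > disc[pv]) is_bridge[pe] <- TRUE
        }
      }
    }
  }
  on_ring <- rep(FALSE, n_atoms)
  ring_bonds <- which(!is_bridge)
  on_ring[bonds$a1[ring_bonds]] <- TRUE
  on_ring[bonds$a2[ring_bonds]] <- TRUE
  on_ring
}

# All chordless simple cycles of length 3..max_size, as ordered atom index
# vectors. Canonicalised so each cycle is reported once. Molecules handled
# here are small (pattern scaffolds, screening compounds), so a bounded DFS
# is adequate.
.find_rings <- function(n_atoms, bonds, max_size = 8L) {
  adj <- .adjacency(n_atoms, bonds)
  has_edge <- matrix(FALSE, n_atoms, n_atoms)
  for (k in seq_len(nrow(bonds))) {
    has_edge[bonds$a1[k], bonds$a2[k]] <- TRUE
    has_edge[bonds$a2[k], bonds$a1[k]] <- TRUE
  }
  found <- list(); seen_keys <- character(0)
  path <- integer(0)
  dfs <- function(start, v) {
    path <<- c(path, v)
    on.exit(path <<- path[-length(path)], add = TRUE)
    for (u in adj[[v]]) {
      if (u == start && length(path) >= 3L) {
        cyc <- path
        key <- paste(sort(cyc), collapse = ",")
        if (!(key %in% seen_keys)) {
          # chordless: no edge between non-consecutive cycle atoms
          n <- length(cyc); chord <- FALSE
          for (p in seq_len(n - 2L)) {
            qmax <- if (p == 1L) n - 1L else n
            for (q in (p + 2L):qmax) {
              if (has_edge[cyc[p], cyc[q]]) { chord <- TRUE; break }
            }
            if (chord) break
          }
          if (!chord) {
            seen_keys <<- c(seen_keys, key)
            found[[length(found) + 1L]] <<- cyc
          } else seen_keys <<- c(seen_keys, key)
        }
      } else if (u > start && !(u %in% path) && length(path) < max_size) {
        dfs(start, u)
      }
    }
  }
  for (s in seq_len(n_atoms)) dfs(s, s)
  found
}
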