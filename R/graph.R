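# Internal molecular graph machinery.
#
# A molgraph stores the heavy-atom skeleton only; hydrogens are folded into
# the per-atom nH count. Bond orders are kekulized (1/2/3) because the SDF
# produced by Open Babel carries no aromatic bond class.

new_molgraph <- function(elem, charge, nH, from, to, order) {
  g <- list(
    elem = as.character(elem),
    charge = as.integer(charge),
    nH = as.integer(nH),
    from = as.integer(from),
    to = as.integer(to),
    order = as.integer(order)
  )
  class(g) <- "molgraph"
  g
}

n_atoms <- function(g) length(g$elem)
n_bonds <- function(g) length(g$from)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d heavy atoms, %d bonds, formula %s>\n",
              n_atoms(x), n_bonds(x), hill_formula(x)))
  invisible(x)
}

# heavy-atom degree of every atom
atom_degree <- function(g) {
  tabulate(c(g$from, g$to), nbins = n_atoms(g))
}

# adjacency as two parallel lists: neighbour atom ids and bond ids
adjacency <- function(g) {
  n <- n_atoms(g)
  nbr <- vector("list", n)
  eid <- vector("list", n)
  for (b in seq_len(n_bonds(g))) {
    u <- g$from[b]; v <- g$to[b]
    nbr[[u]] <- c(nbr[[u]], v); eid[[u]] <- c(eid[[u]], b)
    nbr[[v]] <- c(nbr[[v]], u); eid[[v]] <- c(eid[[v]], b)
  }
  list(nbr = nbr, eid = eid)
}

# connected components; returns integer membership vector
graph_components <- function(g, adj = adjacency(g)) {
  n <- n_atoms(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj$nbr[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# BFS shortest path from u to v avoiding bond `skip`; returns atom path or NULL
bfs_path <- function(adj, n, u, v, skip) {
  parent <- integer(n)
  seen <- logical(n)
  seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    x <- queue[[1]]; queue <- queue[-1]
    nb <- adj$nbr[[x]]; eb <- adj$eid[[x]]
    for (i in seq_along(nb)) {
      if (eb[i] == skip) next
      w <- nb[i]
      if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- x
        if (w == v) {
          path <- w
          while (path[1] != u) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

edge_id_lookup <- function(g) {
  key <- paste(pmin(g$from, g$to), pmax(g$from, g$to))
  stats::setNames(seq_len(n_bonds(g)), key)
}

# Ring perception: bridges define cyclic atoms/bonds; SSSR is built from the
# shortest cycle through every cyclic bond, selected greedily by size under
# GF(2) independence until the circuit rank is reached.
ring_info <- function(g) {
  n <- n_atoms(g); nb <- n_bonds(g)
  adj <- adjacency(g)
  comp <- graph_components(g, adj)
  rank <- nb - n + length(unique(comp))
  cyclic_bond <- logical(nb)
  if (rank > 0L) {
    for (b in seq_len(nb)) {
      cyclic_bond[b] <- !is.null(bfs_path(adj, n, g$from[b], g$to[b], b))
    }
  }
  cyclic_atom <- logical(n)
  cyclic_atom[c(g$from[cyclic_bond], g$to[cyclic_bond])] <- TRUE

  rings <- list()
  if (rank > 0L) {
    elook <- edge_id_lookup(g)
    path_edges <- function(path) {
      m <- length(path)
      unname(elook[paste(pmin(path[-m], path[-1]), pmax(path[-m], path[-1]))])
    }
    cand <- list()
    for (b in which(cyclic_bond)) {
      p <- bfs_path(adj, n, g$from[b], g$to[b], b)
      cand[[length(cand) + 1L]] <- list(atoms = p, eids = sort(c(b, path_edges(p))))
    }
    key <- vapply(cand, function(r) paste(r$eids, collapse = ","), "")
    cand <- cand[!duplicated(key)]
    sizes <- vapply(cand, function(r) length(r$eids), 0L)
    ord <- order(sizes, vapply(cand, function(r) paste(sprintf("%04d", r$eids), collapse = ""), ""))
    cand <- cand[ord]

    basis <- list()   # reduced GF(2) vectors with pivot bookkeeping
    pivots <- integer(0)
    reduce <- function(vec) {
      for (i in seq_along(basis)) {
        if (vec[pivots[i]]) vec <- xor(vec, basis[[i]])
      }
      vec
    }
    for (r in cand) {
      if (length(rings) == rank) break
      vec <- logical(nb); vec[r$eids] <- TRUE
      red <- reduce(vec)
      if (any(red)) {
        basis[[length(basis) + 1L]] <- red
        pivots <- c(pivots, which(red)[1])
        rings[[length(rings) + 1L]] <- r
      }
    }
    # rare fused systems: augment with XOR combinations of candidates
    if (length(rings) < rank) {
      for (i in seq_along(cand)) {
        for (j in seq_along(cand)) {
          if (length(rings) == rank) break
          if (i >= j) next
          vi <- logical(nb); vi[cand[[i]]$eids] <- TRUE
          vj <- logical(nb); vj[cand[[j]]$eids] <- TRUE
          vv <- xor(vi, vj)
          if (!any(vv)) next
          red <- reduce(vv)
          if (any(red)) {
            eids <- which(vv)
            atoms <- sort(unique(c(g$from[eids], g$to[eids])))
            basis[[length(basis) + 1L]] <- red
            pivots <- c(pivots, which(red)[1])
            rings[[length(rings) + 1L]] <- list(atoms = atoms, eids = eids)
          }
        }
      }
    }
  }
  list(cyclic_atom = cyclic_atom, cyclic_bond = cyclic_bond,
       rings = rings, rank = rank)
}

# ---- SDF (V2000) parsing --------------------------------------------------

# Parse concatenated molblocks; explicit hydrogens are folded into nH.
# Returns list(graphs, titles, skipped).
parse_sdf_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  starts <- c(1L, head(ends, -1) + 1L)
  graphs <- list(); titles <- character(0); skipped <- 0L
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:(ends[k] - 1L)]
    g <- tryCatch(parse_molblock(block), error = function(e) NULL)
    if (is.null(g)) { skipped <- skipped + 1L; next }
    graphs[[length(graphs) + 1L]] <- g
    titles <- c(titles, trimws(block[1]))
  }
  list(graphs = graphs, titles = titles, skipped = skipped)
}

parse_molblock <- function(block) {
  counts <- block[4]
  na <- as.integer(substr(counts, 1, 3))
  nbnd <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nbnd)) stop("bad counts line")
  atom_lines <- block[seq.int(5L, length.out = na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(na)
  from <- to <- order <- integer(0)
  if (nbnd > 0) {
    bond_lines <- block[seq.int(5L + na, length.out = nbnd)]
    from <- as.integer(substr(bond_lines, 1, 3))
    to <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  }
  prop <- block[grepl("^M  CHG", block)]
  for (pl in prop) {
    f <- as.integer(strsplit(trimws(substr(pl, 7, nchar(pl))), "\\s+")[[1]])
    nentry <- f[1]
    for (i in seq_len(nentry)) charge[f[2 * i]] <- f[2 * i + 1]
  }
  if (any(is.na(from)) || any(is.na(to)) || any(is.na(order))) stop("bad bond block")
  if (any(order > 3L)) stop("un-kekulized aromatic bond (order 4)")

  heavy <- elem != "H"
  idx <- cumsum(heavy)
  nH <- integer(sum(heavy))
  keep <- logical(length(from))
  for (b in seq_along(from)) {
    hu <- heavy[from[b]]; hv <- heavy[to[b]]
    if (hu && hv) keep[b] <- TRUE
    else if (hu && !hv) nH[idx[from[b]]] <- nH[idx[from[b]]] + 1L
    else if (!hu && hv) nH[idx[to[b]]] <- nH[idx[to[b]]] + 1L
  }
  new_molgraph(elem[heavy], charge[heavy], nH,
               idx[from[keep]], idx[to[keep]], order[keep])
}

# Write a V2000 molblock (no coordinates, implicit hydrogens).
write_molblock <- function(g, title = "") {
  n <- n_atoms(g); nb <- n_bonds(g)
  head <- c(title, " flspace", "", sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$elem)
  bonds <- if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0", g$from, g$to, g$order) else character(0)
  chg <- which(g$charge != 0L)
  prop <- character(0)
  if (length(chg)) {
    prop <- sprintf("M  CHG%3d%s", length(chg),
                    paste(sprintf("%4d%4d", chg, g$charge[chg]), collapse = ""))
  }
  paste(c(head, atoms, bonds, prop, "M  END", "$$$$"), collapse = "\n")
}

# Hill-order molecular formula of a molgraph (implicit H included).
graph_formula <- function(g) {
  tab <- table(g$elem)
  nh <- sum(g$nH)
  els <- names(tab)
  out <- character(0)
  fmt <- function(sym, cnt) if (cnt == 1) sym else paste0(sym, cnt)
  if ("C" %in% els) {
    out <- c(out, fmt("C", tab[["C"]]))
    if (nh > 0) out <- c(out, fmt("H", nh))
    rest <- sort(setdiff(els, "C"))
    for (e in rest) out <- c(out, fmt(e, tab[[e]]))
  } else {
    rest <- sort(els)
    hdone <- FALSE
    for (e in rest) {
      if (!hdone && nh > 0 && e > "H") { out <- c(out, fmt("H", nh)); hdone <- TRUE }
      out <- c(out, fmt(e, tab[[e]]))
    }
    if (!hdone && nh > 0) out <- c(out, fmt("H", nh))
  }
  paste(out, collapse = "")
}
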