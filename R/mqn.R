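# The 42 Molecular Quantum Numbers and the city-block distance.

#' Canonical MQN descriptor names
#'
#' The 42 names in their fixed canonical order: element counts
#' (c, f, cl, br, i, s, p), acyclic/cyclic nitrogen and oxygen (an, cn,
#' ao, co), heavy atom count (hac), bond counts split acyclic/cyclic by
#' order (asb, adb, atb, csb, cdb, ctb), rotatable bonds (rbc), polarity
#' counts (hba, hbd, hbam, hbdm, pos, neg), node degree counts (asv, adv,
#' atv, aqv, cdv, ctv, cqv), ring-size counts over the smallest set of
#' smallest rings (r3..r9, rg10) and fused-ring atoms/bonds (afr, bfr).
#'
#' @return character vector of length 42.
#' @export
mqn_names <- function() {
  c("c", "f", "cl", "br", "i", "s", "p", "an", "cn", "ao", "co", "hac",
    "asb", "adb", "atb", "csb", "cdb", "ctb", "rbc",
    "hba", "hbd", "hbam", "hbdm", "pos", "neg",
    "asv", "adv", "atv", "aqv", "cdv", "ctv", "cqv",
    "r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10", "afr", "bfr")
}

# ---- ionization at pH 7.4 -------------------------------------------------

# Does atom `a` carry a double bond to O (or S for thio-acyl) in graph g?
has_double_to_O <- function(g, a, include_S = TRUE) {
  hit <- (g$from == a | g$to == a) & g$order == 2L
  if (!any(hit)) return(FALSE)
  other <- ifelse(g$from[hit] == a, g$to[hit], g$from[hit])
  any(g$elem[other] == "O" | (include_S & g$elem[other] == "S"))
}

neighbours_of <- function(g, a) {
  hit <- g$from == a | g$to == a
  list(atom = ifelse(g$from[hit] == a, g$to[hit], g$from[hit]),
       order = g$order[hit])
}

#' Apply the pH 7.4 ionization rule table
#'
#' Acidic O-H on carboxylic, sulfonic, sulfinic, phosphonic/phosphate
#' groups is deprotonated (one negative charge each); aliphatic amines
#' (primary/secondary/tertiary, non-amide, non-aromatic), amidines and
#' guanidines are protonated (one positive charge each). Alcohols, phenols,
#' thiols and amides are left unchanged. Heavy-atom composition is never
#' altered, and the rule table is idempotent: already-ionized groups do not
#' match again.
#'
#' @param g a molgraph (or a `molset`, ionized element-wise).
#' @return the ionized molgraph (or `molset`).
#' @export
ionize_ph74 <- function(g) {
  if (inherits(g, "molset")) {
    g$graph <- lapply(g$graph, ionize_ph74)
    return(g)
  }
  stopifnot(inherits(g, "molgraph"))
  n <- n_atoms(g)
  if (n == 0) return(g)
  depro <- integer(0)   # O atoms losing a proton
  proto <- integer(0)   # N atoms gaining a proton
  handled_n <- logical(n)

  # acidic O-H: X(=O)-O-H for X in {C, S, P}
  for (a in seq_len(n)) {
    if (!(g$elem[a] %in% c("C", "S", "P"))) next
    if (!has_double_to_O(g, a, include_S = FALSE)) next
    nb <- neighbours_of(g, a)
    oh <- nb$atom[nb$order == 1L & g$elem[nb$atom] == "O" &
                  g$nH[nb$atom] >= 1L & g$charge[nb$atom] == 0L]
    depro <- c(depro, oh)
  }

  ri <- NULL
  get_ri <- function() { if (is.null(ri)) ri <<- ring_info(g); ri }

  # amidines / guanidines: C(=N)(N...) -> protonate the imine N
  for (a in seq_len(n)) {
    if (g$elem[a] != "C") next
    nb <- neighbours_of(g, a)
    isN <- g$elem[nb$atom] == "N" & g$charge[nb$atom] == 0L
    dbN <- nb$atom[isN & nb$order == 2L]
    sbN <- nb$atom[isN & nb$order == 1L]
    if (length(dbN) >= 1 && length(sbN) >= 1) {
      proto <- c(proto, dbN[1])
      handled_n[c(dbN, sbN)] <- TRUE
    }
  }

  # aliphatic amines
  for (a in seq_len(n)) {
    if (g$elem[a] != "N" || g$charge[a] != 0L || handled_n[a]) next
    nb <- neighbours_of(g, a)
    if (length(nb$atom) == 0 || any(nb$order != 1L)) next
    # amide / sulfonamide: neighbour C/S/P with a double bond to O or S
    acyl <- vapply(nb$atom, function(x)
      g$elem[x] %in% c("C", "S", "P") && has_double_to_O(g, x), TRUE)
    if (any(acyl)) next
    # aromatic-like environments: N inside a ring that carries a double
    # bond, or attached to a ring atom that does (anilines, pyrroles)
    info <- get_ri()
    in_unsat_ring <- function(x) {
      if (!info$cyclic_atom[x]) return(FALSE)
      for (r in info$rings)
        if (x %in% r$atoms && any(g$order[r$eids] == 2L)) return(TRUE)
      FALSE
    }
    nbr_arom <- vapply(nb$atom, function(x)
      info$cyclic_atom[x] && in_unsat_ring(x), TRUE)
    if (in_unsat_ring(a) || any(nbr_arom)) next
    proto <- c(proto, a)
  }

  depro <- unique(depro); proto <- unique(proto)
  g$charge[depro] <- g$charge[depro] - 1L
  g$nH[depro] <- g$nH[depro] - 1L
  g$charge[proto] <- g$charge[proto] + 1L
  g$nH[proto] <- g$nH[proto] + 1L
  g
}

# ---- donor / acceptor conventions ----------------------------------------

# Acceptors: all O; N except amide/sulfonamide N and pyrrole-type ring N
# (cyclic, all-single-bonded, inside an unsaturated ring). S never.
acceptor_flags <- function(g, ri) {
  n <- n_atoms(g)
  acc <- g$elem == "O"
  for (a in which(g$elem == "N")) {
    nb <- neighbours_of(g, a)
    acyl <- any(vapply(nb$atom, function(x)
      g$elem[x] %in% c("C", "S", "P") && has_double_to_O(g, x), TRUE) & nb$order == 1L)
    if (acyl) next
    if (ri$cyclic_atom[a] && all(nb$order == 1L)) {
      unsat <- FALSE
      for (r in ri$rings)
        if (a %in% r$atoms && any(g$order[r$eids] == 2L)) unsat <- TRUE
      if (unsat) next   # pyrrole-type
    }
    acc[a] <- TRUE
  }
  acc
}

# Donors: N or O bearing at least one hydrogen (S-H is not a donor).
donor_flags <- function(g) g$elem %in% c("N", "O") & g$nH >= 1L

# ---- the 42 counts --------------------------------------------------------

compute_mqn_graph <- function(g) {
  nm <- mqn_names()
  v <- stats::setNames(integer(42), nm)
  n <- n_atoms(g)
  if (n == 0) return(v)
  deg <- atom_degree(g)
  if (any(deg > 4L))
    stop("heavy-atom degree > 4 at atom ", which(deg > 4L)[1],
         " (", g$elem[which(deg > 4L)[1]], ")")
  ri <- ring_info(g)

  v["c"] <- sum(g$elem == "C"); v["f"] <- sum(g$elem == "F")
  v["cl"] <- sum(g$elem == "Cl"); v["br"] <- sum(g$elem == "Br")
  v["i"] <- sum(g$elem == "I"); v["s"] <- sum(g$elem == "S")
  v["p"] <- sum(g$elem == "P")
  v["an"] <- sum(g$elem == "N" & !ri$cyclic_atom)
  v["cn"] <- sum(g$elem == "N" & ri$cyclic_atom)
  v["ao"] <- sum(g$elem == "O" & !ri$cyclic_atom)
  v["co"] <- sum(g$elem == "O" & ri$cyclic_atom)
  v["hac"] <- n

  cyc <- ri$cyclic_bond
  v["asb"] <- sum(!cyc & g$order == 1L); v["adb"] <- sum(!cyc & g$order == 2L)
  v["atb"] <- sum(!cyc & g$order == 3L)
  v["csb"] <- sum(cyc & g$order == 1L); v["cdb"] <- sum(cyc & g$order == 2L)
  v["ctb"] <- sum(cyc & g$order == 3L)

  # rotatable: acyclic single bond between two heavy atoms of degree >= 2,
  # neither end carrying a triple bond
  has_triple <- logical(n)
  has_triple[c(g$from[g$order == 3L], g$to[g$order == 3L])] <- TRUE
  rot <- !cyc & g$order == 1L & deg[g$from] >= 2L & deg[g$to] >= 2L &
    !has_triple[g$from] & !has_triple[g$to]
  v["rbc"] <- sum(rot)

  acc <- acceptor_flags(g, ri)
  don <- donor_flags(g)
  v["hba"] <- sum(acc)
  v["hbd"] <- sum(don)
  v["hbam"] <- sum(ifelse(g$elem[acc] == "O", ifelse(g$charge[acc] < 0L, 3L, 2L), 1L))
  v["hbdm"] <- sum(g$nH[don])
  v["pos"] <- sum(g$charge > 0L)
  v["neg"] <- sum(g$charge < 0L)

  ca <- ri$cyclic_atom
  v["asv"] <- sum(!ca & deg == 1L); v["adv"] <- sum(!ca & deg == 2L)
  v["atv"] <- sum(!ca & deg == 3L); v["aqv"] <- sum(!ca & deg == 4L)
  v["cdv"] <- sum(ca & deg == 2L); v["ctv"] <- sum(ca & deg == 3L)
  v["cqv"] <- sum(ca & deg == 4L)

  sizes <- vapply(ri$rings, function(r) length(r$eids), 0L)
  for (k in 3:9) v[paste0("r", k)] <- sum(sizes == k)
  v["rg10"] <- sum(sizes >= 10L)
  if (length(ri$rings) >= 2) {
    atom_mult <- table(unlist(lapply(ri$rings, `[[`, "atoms")))
    bond_mult <- table(unlist(lapply(ri$rings, `[[`, "eids")))
    v["afr"] <- sum(atom_mult >= 2)
    v["bfr"] <- sum(bond_mult >= 2)
  }
  v
}

#' Compute the 42 Molecular Quantum Numbers
#'
#' Counts are taken on the kekulized heavy-atom graph after ionization at
#' pH 7.4 (see [ionize_ph74()]; set `ionize = FALSE` if the input is
#' already ionized). Ring-size counts and fused-ring atoms/bonds are taken
#' over the smallest set of smallest rings; cyclic/acyclic classification
#' of atoms and bonds uses ring-bond (non-bridge) membership.
#'
#' @param x a `molset`, molgraph, or character vector of SMILES.
#' @param ionize apply the pH 7.4 rules first (default `TRUE`).
#' @return For a single molecule, a named integer vector of length 42; for
#'   a collection, an integer matrix (rows = molecules, named by id).
#' @examples
#' compute_mqn("CC")["asb"]    # ethane: one acyclic single bond
#' @export
compute_mqn <- function(x, ionize = TRUE) {
  if (inherits(x, "molgraph")) {
    if (ionize) x <- ionize_ph74(x)
    return(compute_mqn_graph(x))
  }
  ms <- as_molset(x)
  m <- mqn_table(ms, ionize = ionize)
  if (is.character(x) && length(x) == 1) return(m[1, ])
  m
}

#' MQN descriptor table for a collection
#'
#' @param ms a `molset`.
#' @param ionize apply the pH 7.4 rules first.
#' @return integer matrix, one row per molecule (rownames = ids), 42
#'   columns in canonical order. Molecules whose computation fails are
#'   dropped; their ids and messages are kept in attribute `"errors"`.
#' @export
mqn_table <- function(ms, ionize = TRUE) {
  stopifnot(inherits(ms, "molset"))
  out <- matrix(0L, nrow = length(ms), ncol = 42,
                dimnames = list(ms$id, mqn_names()))
  errs <- character(0)
  ok <- logical(length(ms))
  for (i in seq_len(length(ms))) {
    r <- tryCatch({
      g <- ms$graph[[i]]
      if (ionize) g <- ionize_ph74(g)
      compute_mqn_graph(g)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      errs <- c(errs, stats::setNames(conditionMessage(r), ms$id[i]))
    } else {
      out[i, ] <- r; ok[i] <- TRUE
    }
  }
  out <- out[ok, , drop = FALSE]
  attr(out, "errors") <- errs
  out
}

#' City-block (Manhattan) distance between MQN vectors
#'
#' @param a,b numeric vectors of equal length (typically 42 MQN counts).
#' @return the non-negative sum of absolute component differences.
#' @examples
#' cbd(compute_mqn("CC"), compute_mqn("c1ccccc1"))  # 24
#' @export
cbd <- function(a, b) {
  if (length(a) != length(b)) stop("vector length mismatch: ", length(a), " vs ", length(b))
  sum(abs(a - b))
}

# Row-wise CBD of a matrix against one vector (vectorized inner loop).
cbd_to <- function(m, v) {
  if (ncol(m) != length(v)) stop("vector length mismatch")
  as.vector(abs(m - rep(v, each = nrow(m))) %*% rep(1, length(v)))
}

#' Write / read an MQN table as TSV
#'
#' Header is `id` followed by the 42 canonical names; integer cells.
#' @param m matrix from [mqn_table()].
#' @param path TSV file.
#' @export
write_mqn <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mqn
#' @export
read_mqn <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c(id = "character"))
  m <- as.matrix(df[, mqn_names(), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}
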