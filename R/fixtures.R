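# Built-in molecules and synthetic libraries: a curated set of classic
# fragrance compounds (plus named non-fragrance-like exclusions), a
# fragment-grammar decoy generator emulating fragrance-like database
# backgrounds, and a structural-analog generator for planted-signal
# screening experiments.

#' Curated fragrance molecules
#'
#' The classic query compounds (furaneol, isoamyl acetate, caprylic acid,
#' vanillin, cinnamaldehyde, limonene, alpha-pinene, camphor, menthone,
#' rose oxide, menthol, citronellol, lauraldehyde), the carvone enantiomer
#' pair, and the named non-fragrance-like exclusions (pyrazine, ethyl
#' anthranilate, 3-ethylpyridine, cyclopentanethiol, dimethyl disulfide).
#'
#' @return a `molset`; attribute `"query_ids"` lists the 13 classic query
#'   compounds, attribute `"exclusion_ids"` the non-FL exclusions.
#' @export
curated_fragrances <- function() {
  path <- system.file("extdata", "curated_fragrances.smi", package = "flspace")
  ms <- read_molecules(path, format = "smiles")
  attr(ms, "query_ids") <- c("furaneol", "isoamyl_acetate", "caprylic_acid",
                             "vanillin", "cinnamaldehyde", "limonene",
                             "alpha_pinene", "camphor", "menthone",
                             "rose_oxide", "menthol", "citronellol",
                             "lauraldehyde")
  attr(ms, "exclusion_ids") <- c("pyrazine", "ethyl_anthranilate",
                                 "ethylpyridine_3", "cyclopentanethiol",
                                 "dimethyl_disulfide")
  ms
}

# random branched alkyl SMILES with n carbons
gen_alkyl <- function(n) {
  if (n <= 0) return("")
  if (n == 1) return("C")
  if (n >= 3 && stats::runif(1) < 0.3) {
    k <- sample.int(n - 2, 1)
    paste0("C(", gen_alkyl(k), ")", gen_alkyl(n - 1 - k))
  } else {
    paste0("C", gen_alkyl(n - 1))
  }
}

# heavy atoms in a SMILES assembled by the grammar (C/c/O/S/N tokens only)
grammar_hac <- function(s) nchar(gsub("[^CcOSN]", "", s))

# one random fragrance-like candidate around a target heavy atom count
gen_candidate <- function(target, fl_bias) {
  het <- 0L; don <- 0L
  rings <- list(c("C1CCCCC1", 6L, 0L), c("C1CCCC1", 5L, 0L),
                c("c1ccccc1", 6L, 0L), c("C1CCC(C)CC1", 7L, 0L),
                c("C1CCOC1", 5L, 1L), c("C1CCOCC1", 6L, 1L),
                c("C1CC1", 3L, 0L), c("C1CCCCCC1", 7L, 0L))
  mid_tokens <- list(c("C(=O)", 2L, 1L, 0L), c("C(=O)O", 3L, 2L, 0L),
                     c("O", 1L, 1L, 0L), c("S", 1L, 1L, 0L), c("", 0L, 0L, 0L))
  cap_tokens <- list(c("O", 1L, 1L, 1L), c("C=O", 2L, 1L, 0L),
                     c("C(=O)O", 3L, 2L, 1L), c("C(=O)OC", 4L, 2L, 0L),
                     c("", 0L, 0L, 0L))
  if (!fl_bias) {
    mid_tokens <- c(mid_tokens, list(c("N", 1L, 1L, 0L)))
    cap_tokens <- c(cap_tokens, list(c("N", 1L, 1L, 1L), c("C#N", 2L, 1L, 0L)))
  }
  ring <- if (stats::runif(1) < 0.45) rings[[sample.int(length(rings), 1)]] else NULL
  mid <- mid_tokens[[sample.int(length(mid_tokens), 1)]]
  cap <- cap_tokens[[sample.int(length(cap_tokens), 1)]]
  het <- as.integer(mid[3]) + as.integer(cap[3]) +
    if (is.null(ring)) 0L else as.integer(ring[3])
  if (fl_bias && het > 3L) cap <- c("", "0", "0", "0")
  budget <- target - as.integer(mid[2]) - as.integer(cap[2]) -
    if (is.null(ring)) 0L else as.integer(ring[2])
  if (budget < 1L) return(NA_character_)
  n1 <- sample.int(budget, 1)
  n2 <- budget - n1
  body <- if (is.null(ring)) gen_alkyl(n2) else
    paste0(ring[1], if (n2 > 0) gen_alkyl(n2) else "")
  s <- paste0(gen_alkyl(n1), mid[1], body, cap[1])
  if (!nzchar(s)) NA_character_ else s
}

#' Generate a synthetic decoy library
#'
#' Seed-deterministic assembly from a C/H/O/S fragment grammar (branched
#' alkyl chains, small carbocycles and oxygen heterocycles, carbonyl /
#' ester / ether / thioether / alcohol / aldehyde / acid caps). All
#' outputs parse and are valence-sane; duplicates are removed. With
#' `fl_bias = TRUE` (the default) the grammar keeps heteroatom and donor
#' budgets inside the fragrance-likeness rules so at least 90% of the
#' output passes the filter; with `fl_bias = FALSE` nitrogen-containing
#' fragments are also drawn.
#'
#' @param n number of molecules.
#' @param seed RNG seed (generation is reproducible given `n` and `seed`).
#' @param hac_range inclusive heavy-atom-count range (default 5..21).
#' @param fl_bias bias the grammar towards fragrance-like output.
#' @return a `molset` of `n` unique molecules with ids `D000001`-style.
#' @export
generate_decoys <- function(n, seed = 42L, hac_range = c(5L, 21L),
                            fl_bias = TRUE) {
  stopifnot(n >= 0)
  if (length(hac_range) != 2 || hac_range[1] > hac_range[2])
    stop("invalid hac_range")
  if (hac_range[2] < 3) stop("hac_range below grammar minimum (3 heavy atoms)")
  lo <- max(hac_range[1], 3L)
  if (n == 0) return(molset_from_smiles(character(0)))
  with_seed(seed, {
    seen <- character(0)
    graphs <- list()
    tries <- 0L
    while (length(seen) < n && tries < 60L) {
      tries <- tries + 1L
      batch <- max(500L, ceiling(1.6 * (n - length(seen))))
      targets <- sample(seq.int(lo, hac_range[2]), batch, replace = TRUE)
      cand <- vapply(targets, gen_candidate, "", fl_bias = fl_bias)
      cand <- cand[!is.na(cand)]
      h <- vapply(cand, grammar_hac, 0L, USE.NAMES = FALSE)
      cand <- cand[h >= hac_range[1] & h <= hac_range[2]]
      can <- canonical_smiles(cand)
      can <- can[!is.na(can)]
      fresh <- setdiff(unique(can), seen)
      seen <- c(seen, fresh)
    }
    if (length(seen) < n)
      stop("decoy grammar exhausted at ", length(seen), " of ", n,
           " unique molecules; widen hac_range")
    seen <- seen[seq_len(n)]
  })
  ms <- molset_from_smiles(seen, sprintf("D%06d", seq_len(n)))
  if (length(ms) != n) stop("internal: generated decoys failed to re-parse")
  ms
}

# ---- structural analogs ---------------------------------------------------

# edit moves on a molgraph; each returns the edited graph or NULL
move_homologate <- function(g) {
  cand <- which(g$elem == "C" & g$nH >= 1L)
  if (!length(cand)) return(NULL)
  a <- cand[sample.int(length(cand), 1)]
  g$elem <- c(g$elem, "C"); g$charge <- c(g$charge, 0L); g$nH <- c(g$nH, 3L)
  g$nH[a] <- g$nH[a] - 1L
  g$from <- c(g$from, a); g$to <- c(g$to, n_atoms(g)); g$order <- c(g$order, 1L)
  g
}

move_shorten <- function(g) {
  deg <- atom_degree(g)
  cand <- which(g$elem == "C" & deg == 1L)
  cand <- cand[vapply(cand, function(a) {
    b <- which(g$from == a | g$to == a)
    g$order[b] == 1L
  }, TRUE)]
  if (!length(cand) || n_atoms(g) <= 4L) return(NULL)
  a <- cand[sample.int(length(cand), 1)]
  drop_terminal_atom(g, a)
}

drop_terminal_atom <- function(g, a) {
  b <- which(g$from == a | g$to == a)
  other <- if (g$from[b] == a) g$to[b] else g$from[b]
  g$nH[other] <- g$nH[other] + 1L
  keep <- setdiff(seq_len(n_atoms(g)), a)
  remap <- match(seq_len(n_atoms(g)), keep)
  kb <- setdiff(seq_len(n_bonds(g)), b)
  new_molgraph(g$elem[keep], g$charge[keep], g$nH[keep],
               remap[g$from[kb]], remap[g$to[kb]], g$order[kb])
}

move_transpose_methyl <- function(g) {
  deg <- atom_degree(g)
  term <- which(g$elem == "C" & deg == 1L & g$nH == 3L)
  if (!length(term)) return(NULL)
  a <- term[sample.int(length(term), 1)]
  g2 <- drop_terminal_atom(g, a)
  dest <- which(g2$elem == "C" & g2$nH >= 1L)
  if (!length(dest)) return(NULL)
  d <- dest[sample.int(length(dest), 1)]
  g2$elem <- c(g2$elem, "C"); g2$charge <- c(g2$charge, 0L); g2$nH <- c(g2$nH, 3L)
  g2$nH[d] <- g2$nH[d] - 1L
  g2$from <- c(g2$from, d); g2$to <- c(g2$to, n_atoms(g2)); g2$order <- c(g2$order, 1L)
  g2
}

move_ring_resize <- function(g) {
  ri <- ring_info(g)
  if (!length(ri$rings)) return(NULL)
  r <- ri$rings[[sample.int(length(ri$rings), 1)]]
  if (stats::runif(1) < 0.5 && length(r$eids) < 8) {
    # grow: insert a CH2 into a single ring bond
    single <- r$eids[g$order[r$eids] == 1L]
    if (!length(single)) return(NULL)
    b <- single[sample.int(length(single), 1)]
    u <- g$from[b]; v <- g$to[b]
    g$elem <- c(g$elem, "C"); g$charge <- c(g$charge, 0L); g$nH <- c(g$nH, 2L)
    w <- n_atoms(g)
    g$to[b] <- w
    g$from <- c(g$from, w); g$to <- c(g$to, v); g$order <- c(g$order, 1L)
    g
  } else {
    if (length(r$eids) <= 3) return(NULL)
    deg <- atom_degree(g)
    cand <- r$atoms[g$elem[r$atoms] == "C" & deg[r$atoms] == 2L]
    cand <- cand[vapply(cand, function(a) {
      all(g$order[which(g$from == a | g$to == a)] == 1L)
    }, TRUE)]
    if (!length(cand)) return(NULL)
    a <- cand[sample.int(length(cand), 1)]
    bs <- which(g$from == a | g$to == a)
    nb <- ifelse(g$from[bs] == a, g$to[bs], g$from[bs])
    already <- any((g$from == nb[1] & g$to == nb[2]) | (g$from == nb[2] & g$to == nb[1]))
    if (already) return(NULL)
    keep <- setdiff(seq_len(n_atoms(g)), a)
    remap <- match(seq_len(n_atoms(g)), keep)
    kb <- setdiff(seq_len(n_bonds(g)), bs)
    new_molgraph(g$elem[keep], g$charge[keep], g$nH[keep],
                 c(remap[g$from[kb]], remap[nb[1]]),
                 c(remap[g$to[kb]], remap[nb[2]]),
                 c(g$order[kb], 1L))
  }
}

move_carbonyl_swap <- function(g) {
  dbl <- which(g$order == 2L)
  co <- dbl[vapply(dbl, function(b) {
    pair <- c(g$elem[g$from[b]], g$elem[g$to[b]])
    "O" %in% pair && "C" %in% pair
  }, TRUE)]
  oh <- which(g$elem == "O" & g$nH == 1L & atom_degree(g) == 1L)
  if (length(co) && (stats::runif(1) < 0.5 || !length(oh))) {
    # C=O -> C-OH (adds a donor: caller validates the donor budget)
    b <- co[sample.int(length(co), 1)]
    o <- if (g$elem[g$from[b]] == "O") g$from[b] else g$to[b]
    cc <- if (g$elem[g$from[b]] == "O") g$to[b] else g$from[b]
    g$order[b] <- 1L
    g$nH[o] <- g$nH[o] + 1L
    g$nH[cc] <- g$nH[cc] + 1L
    g
  } else if (length(oh)) {
    o <- oh[sample.int(length(oh), 1)]
    b <- which(g$from == o | g$to == o)
    cc <- if (g$from[b] == o) g$to[b] else g$from[b]
    if (g$elem[cc] != "C" || g$nH[cc] < 1L) return(NULL)
    if (any(g$order[which(g$from == cc | g$to == cc)] == 2L)) return(NULL)
    g$order[b] <- 2L
    g$nH[o] <- g$nH[o] - 1L
    g$nH[cc] <- g$nH[cc] - 1L
    g
  } else NULL
}

valence_sane <- function(g) {
  if (n_atoms(g) == 0) return(FALSE)
  vo <- numeric(n_atoms(g))
  for (b in seq_len(n_bonds(g))) {
    vo[g$from[b]] <- vo[g$from[b]] + g$order[b]
    vo[g$to[b]] <- vo[g$to[b]] + g$order[b]
  }
  tot <- vo + g$nH
  lim <- c(C = 4, O = 2, S = 2, N = 3)[g$elem]
  all(!is.na(lim)) && all(tot <= lim) && all(g$nH >= 0) &&
    length(unique(graph_components(g))) == 1
}

#' Generate a family of structural analogs
#'
#' Produces `n` fragrance-like structural analogs of a seed molecule by
#' seed-deterministic random edit moves (chain homologation and
#' shortening, methyl transposition, ring size changes, carbonyl/alcohol
#' swaps), each candidate validated for valence sanity and the
#' fragrance-likeness rules. The maximum MQN city-block distance of any
#' analog to the seed is reported.
#'
#' @param seed_smiles SMILES of the (fragrance-like) seed molecule.
#' @param n number of analogs.
#' @param seed RNG seed.
#' @param max_moves edit moves per candidate (1 to `max_moves`, default 3).
#' @return a `molset` of `n` analogs (ids `A001`-style), with attributes
#'   `"seed_smiles"` (canonical) and `"max_cbd"` (maximum MQN-CBD to the
#'   seed).
#' @export
generate_analog_family <- function(seed_smiles, n, seed = 1L, max_moves = 3L) {
  ms0 <- as_molset(seed_smiles)
  if (length(ms0) != 1) stop("need exactly one seed molecule")
  if (!is_fragrance_like(ms0)$passed)
    stop("seed molecule is not fragrance-like")
  g0 <- ms0$graph[[1]]
  if (n == 0) {
    out <- molset_from_smiles(character(0))
    attr(out, "seed_smiles") <- ms0$smiles
    attr(out, "max_cbd") <- NA_integer_
    return(out)
  }
  moves <- list(move_homologate, move_shorten, move_transpose_methyl,
                move_ring_resize, move_carbonyl_swap)
  analogs <- with_seed(seed, {
    seen <- character(0)
    tries <- 0L
    while (length(seen) < n && tries < 200L) {
      tries <- tries + 1L
      batch_graphs <- list()
      for (k in seq_len(max(50L, 4L * (n - length(seen))))) {
        g <- g0
        for (s in seq_len(sample.int(max_moves, 1))) {
          g2 <- moves[[sample.int(length(moves), 1)]](g)
          if (!is.null(g2) && valence_sane(g2)) g <- g2
        }
        batch_graphs[[k]] <- g
      }
      blocks <- vapply(seq_along(batch_graphs), function(i)
        write_molblock(batch_graphs[[i]], paste0("t", i)), "")
      can <- ob_convert("SDF", "CAN", paste(blocks, collapse = "\n"))
      lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
      smis <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
      smis <- setdiff(unique(smis[!is.na(smis) & nzchar(smis)]), c(seen, ms0$smiles))
      if (length(smis)) {
        ver <- tryCatch(is_fragrance_like(smis), error = function(e) NULL)
        if (!is.null(ver)) seen <- c(seen, smis[ver$passed])
      }
    }
    if (length(seen) < n)
      stop("analog generator produced only ", length(seen), " of ", n, " analogs")
    seen[seq_len(n)]
  })
  out <- molset_from_smiles(analogs, sprintf("A%03d", seq_len(n)))
  mq <- mqn_table(out)
  q <- compute_mqn(g0)
  attr(out, "seed_smiles") <- ms0$smiles
  attr(out, "max_cbd") <- as.integer(max(cbd_to(mq, q)))
  out
}
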