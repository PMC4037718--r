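#' @importFrom ChemmineOB convertFormat forEachMol prop_OB
NULL

# Open Babel conversion wrapper; always continues past unparsable records.
ob_convert <- function(from, to, source, extra = character(0)) {
  opts <- data.frame(names = c("e", names(extra)),
                     args = c("", unname(extra)),
                     stringsAsFactors = FALSE)
  ChemmineOB::convertFormat(from, to, source, options = opts)
}

# Canonicalize SMILES, returning NA for records Open Babel rejects.
# Internal ids t<i> keep the input/output association.
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  payload <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  out <- ob_convert("SMI", "CAN", payload)
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2) {
        i <- suppressWarnings(as.integer(sub("^t", "", p[2])))
        if (!is.na(i)) res[i] <- p[1]
      }
    }
  }
  res
}

# Convert SMILES to molgraphs (explicit H requested, then folded).
smiles_to_graphs <- function(smiles) {
  if (!length(smiles)) return(vector("list", 0))
  payload <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  sdf <- ob_convert("SMI", "SDF", payload, extra = c(h = ""))
  res <- vector("list", length(smiles))
  if (nzchar(sdf)) {
    parsed <- parse_sdf_blocks(sdf)
    for (k in seq_along(parsed$graphs)) {
      i <- suppressWarnings(as.integer(sub("^t", "", parsed$titles[k])))
      if (!is.na(i)) res[[i]] <- parsed$graphs[[k]]
    }
  }
  res
}

new_molset <- function(id, smiles, formula, hac, graph) {
  ms <- list(id = as.character(id), smiles = as.character(smiles),
             formula = as.character(formula), hac = as.integer(hac),
             graph = graph)
  class(ms) <- "molset"
  ms
}

#' Number of molecules in a collection
#' @param x a `molset`
#' @export
length.molset <- function(x) length(x$id)

#' Subset a molecule collection
#' @param x a `molset`
#' @param i index vector
#' @param ... ignored
#' @export
`[.molset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  new_molset(x$id[i], x$smiles[i], x$formula[i], x$hac[i], x$graph[i])
}

#' @export
print.molset <- function(x, ...) {
  cat(sprintf("<molset: %d molecules>\n", length(x)))
  n <- min(6L, length(x))
  if (n > 0)
    print(utils::head(as.data.frame(x), n))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.molset <- function(x, ...) {
  data.frame(id = x$id, smiles = x$smiles, formula = x$formula, hac = x$hac,
             stringsAsFactors = FALSE)
}

# Combine molsets (ids must stay unique).
molset_bind <- function(...) {
  parts <- list(...)
  ms <- new_molset(
    unlist(lapply(parts, `[[`, "id")),
    unlist(lapply(parts, `[[`, "smiles")),
    unlist(lapply(parts, `[[`, "formula")),
    unlist(lapply(parts, `[[`, "hac")),
    do.call(c, lapply(parts, `[[`, "graph"))
  )
  if (anyDuplicated(ms$id)) stop("duplicate ids when combining molsets")
  ms
}

# Build a molset from SMILES + ids: canonicalize, largest fragment, graphs.
molset_from_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("M%06d", seq_along(smiles))
  can <- canonical_smiles(smiles)
  multi <- !is.na(can) & grepl(".", can, fixed = TRUE)
  for (i in which(multi)) can[i] <- largest_fragment(can[i])
  keep <- which(!is.na(can))
  graphs <- smiles_to_graphs(can[keep])
  ok <- !vapply(graphs, is.null, TRUE)
  keep <- keep[ok]; graphs <- graphs[ok]
  ms <- new_molset(
    ids[keep], can[keep],
    vapply(graphs, graph_formula, ""),
    vapply(graphs, n_atoms, 0L),
    graphs
  )
  attr(ms, "parse_report") <- list(read = length(smiles), parsed = length(keep),
                                   skipped = length(smiles) - length(keep))
  ms
}

# Keep the largest organic fragment of a multi-fragment canonical SMILES:
# prefer carbon-containing fragments, then most heavy atoms, then first.
largest_fragment <- function(can) {
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  graphs <- smiles_to_graphs(frags)
  ok <- !vapply(graphs, is.null, TRUE)
  frags <- frags[ok]; graphs <- graphs[ok]
  if (!length(frags)) return(NA_character_)
  has_c <- vapply(graphs, function(g) "C" %in% g$elem, TRUE)
  hac <- vapply(graphs, n_atoms, 0L)
  ord <- order(-as.integer(has_c), -hac)
  canonical_smiles(frags[ord[1]])
}

#' Read a molecule collection
#'
#' Reads a SMILES file (whitespace-separated `SMILES [id]` per line, `#`
#' comments allowed) or an SDF (V2000), canonicalizes every record with
#' Open Babel (stereochemistry retained), keeps the largest organic fragment
#' of multi-fragment records, and assigns stable ids (`M000001`-style when
#' the input carries none). Unparsable records are skipped and counted in
#' the parse report attached as attribute `"parse_report"`.
#'
#' @param path file to read.
#' @param format `"smiles"` or `"sdf"`.
#' @return A `molset` with fields `id`, `smiles` (canonical), `formula`
#'   (Hill order), `hac` and the parsed molecular graphs.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), f)
#' ms <- read_molecules(f)
#' as.data.frame(ms)
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    toks <- strsplit(trimws(lines), "\\s+")
    smiles <- vapply(toks, `[`, "", 1)
    ids <- vapply(toks, function(t) if (length(t) > 1) t[2] else NA_character_, "")
    if (anyNA(ids)) ids[is.na(ids)] <- sprintf("M%06d", which(is.na(ids)))
    ms <- molset_from_smiles(smiles, ids)
  } else {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    n_rec <- length(gregexpr("\\$\\$\\$\\$", text)[[1]])
    can <- ob_convert("SDF", "CAN", text)
    lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smiles <- vapply(parts, `[`, "", 1)
    ids <- vapply(parts, function(p) if (length(p) > 1 && nzchar(p[2])) p[2] else NA_character_, "")
    if (anyNA(ids)) ids[is.na(ids)] <- sprintf("M%06d", which(is.na(ids)))
    ms <- molset_from_smiles(smiles, make.unique(ids, sep = "_"))
    rep0 <- attr(ms, "parse_report")
    rep0$read <- max(n_rec, rep0$read)
    rep0$skipped <- rep0$read - rep0$parsed
    attr(ms, "parse_report") <- rep0
  }
  if (length(ms) == 0)
    stop("no parsable records in ", path, " (read ",
         attr(ms, "parse_report")$read, ", all skipped)")
  if (anyDuplicated(ms$id)) stop("duplicate ids in input: ",
                                 paste(unique(ms$id[duplicated(ms$id)]), collapse = ", "))
  ms
}

#' Write a molecule collection as a SMILES file
#'
#' @param ms a `molset`.
#' @param path output file; one `SMILES id` line per molecule.
#' @export
write_molecules <- function(ms, path) {
  writeLines(paste(ms$smiles, ms$id), path)
  invisible(path)
}

#' Write a parse/dedup report as JSON
#'
#' @param ms a `molset` (uses its `"parse_report"` attribute, if present).
#' @param path output JSON file.
#' @param deduplicated optional count of records removed by [dedup()].
#' @export
write_parse_report <- function(ms, path, deduplicated = NA_integer_) {
  rep0 <- attr(ms, "parse_report")
  if (is.null(rep0)) rep0 <- list(read = length(ms), parsed = length(ms), skipped = 0L)
  rep0$deduplicated <- deduplicated
  jsonlite::write_json(rep0, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Remove duplicate molecules
#'
#' Molecules whose canonical stereo-aware SMILES are identical collapse to
#' the first occurrence; output preserves first-occurrence order. Enantiomer
#' pairs (for example the two carvones) are distinct unless
#' `ignore_stereo = TRUE`, which strips stereo annotations before comparing.
#'
#' @param ms a `molset`.
#' @param ignore_stereo collapse stereoisomers too?
#' @return the deduplicated `molset`; the number of removed records is in
#'   attribute `"removed"`.
#' @export
dedup <- function(ms, ignore_stereo = FALSE) {
  key <- ms$smiles
  if (ignore_stereo) key <- canonical_smiles(gsub("[@/\\\\]", "", key))
  keep <- !duplicated(key)
  out <- ms[which(keep)]
  attr(out, "removed") <- sum(!keep)
  attr(out, "parse_report") <- attr(ms, "parse_report")
  out
}

#' Hill-order molecular formula
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; implicit
#' hydrogens included. For carbon-free molecules all elements (including H)
#' are alphabetical.
#'
#' @param x a `molset`, a molgraph, or a character vector of SMILES.
#' @return character vector of formulas.
#' @examples
#' hill_formula("CC1CCC(C(C)C)C(=O)C1")  # menthone, "C10H18O"
#' @export
hill_formula <- function(x) {
  if (inherits(x, "molgraph")) return(graph_formula(x))
  if (inherits(x, "molset")) return(vapply(x$graph, graph_formula, ""))
  if (is.character(x)) {
    graphs <- smiles_to_graphs(x)
    return(vapply(graphs, function(g) if (is.null(g)) NA_character_ else graph_formula(g), ""))
  }
  stop("cannot compute a formula for ", class(x)[1])
}

# Resolve flexible molecule input (molset / molgraph / SMILES) to a molset.
as_molset <- function(x) {
  if (inherits(x, "molset")) return(x)
  if (inherits(x, "molgraph")) {
    return(new_molset("query", NA_character_, graph_formula(x), n_atoms(x), list(x)))
  }
  if (is.character(x)) {
    ms <- molset_from_smiles(x, if (is.null(names(x))) NULL else names(x))
    if (length(ms) != length(x)) stop("unparsable SMILES input")
    return(ms)
  }
  stop("cannot interpret ", class(x)[1], " as molecules")
}
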