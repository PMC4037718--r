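# Exact nearest-neighbour engine over MQN space. Entries are bucketed by
# the sum of their 42 MQN values; since |sum(a) - sum(b)| <= CBD(a, b),
# a query with distance bound d only needs the buckets whose sum lies
# within d of the query sum. Database membership is a bit mask (bits
# assigned per database; a search's "wanted" mask matches any shared bit).

#' Build an MQN similarity-search index
#'
#' @param ms a deduplicated `molset`.
#' @param db_assignments database membership: a named list mapping ids to
#'   character vectors of database names, or `NULL` to place everything in
#'   a single `"default"` database. At most 53 databases (mask bits must
#'   stay exactly representable in a double).
#' @param mqn optional precomputed [mqn_table()] for `ms`.
#' @return an object of class `mqn_index`.
#' @export
build_index <- function(ms, db_assignments = NULL, mqn = NULL) {
  stopifnot(inherits(ms, "molset"))
  if (anyDuplicated(ms$id)) stop("duplicate id: ",
                                 paste(unique(ms$id[duplicated(ms$id)]), collapse = ", "))
  if (is.null(db_assignments)) db_assignments <- stats::setNames(
    rep(list("default"), length(ms)), ms$id)
  bad <- setdiff(names(db_assignments), ms$id)
  if (length(bad)) stop("db assignment for unknown id: ", paste(bad, collapse = ", "))
  registry <- sort(unique(unlist(db_assignments)))
  if (length(registry) > 53) stop("at most 53 databases supported")
  if (is.null(mqn)) mqn <- mqn_table(ms)
  if (length(attr(mqn, "errors"))) {
    keep <- ms$id %in% rownames(mqn)
    ms <- ms[which(keep)]
  }
  mqn <- mqn[ms$id, , drop = FALSE]
  member <- matrix(FALSE, length(ms), length(registry),
                   dimnames = list(ms$id, registry))
  for (id in names(db_assignments)) {
    if (!id %in% ms$id) next
    member[id, db_assignments[[id]]] <- TRUE
  }
  if (any(rowSums(member) == 0))
    stop("entries without any database bit: ",
         paste(utils::head(ms$id[rowSums(member) == 0], 3), collapse = ", "))
  hba <- mqn[, "hba"]; hbd <- mqn[, "hbd"]
  sums <- as.integer(rowSums(mqn))
  idx <- list(ids = ms$id, mqn = mqn, sums = sums, member = member,
              formula = ms$formula, hba = unname(hba), hbd = unname(hbd),
              registry = registry,
              buckets = split(seq_along(sums), sums))
  class(idx) <- "mqn_index"
  idx
}

#' @export
print.mqn_index <- function(x, ...) {
  cat(sprintf("<mqn_index: %d molecules, %d buckets (MQN-sum %d..%d), databases: %s>\n",
              length(x$ids), length(x$buckets), min(x$sums), max(x$sums),
              paste(x$registry, collapse = ", ")))
  invisible(x)
}

#' Database bit mask
#'
#' @param index an `mqn_index`.
#' @param dbs database names (bitwise-OR of their bits); defaults to all.
#' @return the numeric mask value.
#' @export
db_mask <- function(index, dbs = index$registry) {
  bad <- setdiff(dbs, index$registry)
  if (length(bad)) stop("unknown database name: ", paste(bad, collapse = ", "))
  sum(2^(match(unique(dbs), index$registry) - 1))
}

# decode mask -> registry positions
mask_bits <- function(index, mask) {
  which(floor(mask / 2^(seq_along(index$registry) - 1)) %% 2 == 1)
}

#' Entry bit masks of an index
#'
#' @param index an `mqn_index`.
#' @return numeric vector, one mask per entry.
#' @export
entry_masks <- function(index) {
  as.vector(index$member %*% 2^(seq_along(index$registry) - 1))
}

# Resolve a query to list(mqn, formula, hba, hbd)
resolve_query <- function(query) {
  if (is.numeric(query) && length(query) == 42) {
    return(list(mqn = query, formula = NA_character_,
                hba = query[["hba"]], hbd = query[["hbd"]]))
  }
  ms <- as_molset(query)
  if (length(ms) != 1) stop("query must be a single molecule")
  m <- mqn_table(ms)
  list(mqn = m[1, ], formula = ms$formula[1], hba = m[1, "hba"], hbd = m[1, "hbd"])
}

#' Range search by city-block distance in MQN space
#'
#' Returns every indexed molecule within `d_max` of the query, restricted
#' to the wanted databases and the optional isomer/H-bond locks. Only the
#' MQN-sum buckets within `d_max` of the query sum are inspected; the
#' result is identical to a brute-force scan under the same constraints.
#'
#' @param index an `mqn_index`.
#' @param query a single molecule (`molset`, SMILES) or a 42-long MQN
#'   vector (structure-dependent constraints then require a structure).
#' @param d_max CBD distance boundary (default 12).
#' @param dbs database names to search (default: all registered).
#' @param wanted_mask alternative to `dbs`: explicit numeric bit mask;
#'   must be non-zero.
#' @param isomers_only restrict hits to molecules with the query's
#'   molecular formula.
#' @param lock_hbd,lock_hba restrict hits to molecules whose H-bond donor
#'   / acceptor atom counts equal the query's.
#' @return data.frame `(id, cbd)` sorted by distance, ties by id.
#' @export
range_search <- function(index, query, d_max = 12L, dbs = NULL,
                         wanted_mask = NULL, isomers_only = FALSE,
                         lock_hbd = FALSE, lock_hba = FALSE) {
  stopifnot(inherits(index, "mqn_index"), d_max >= 0)
  q <- resolve_query(query)
  if (is.null(wanted_mask)) {
    wanted_mask <- db_mask(index, if (is.null(dbs)) index$registry else dbs)
  }
  if (wanted_mask == 0) stop("wanted_mask must be non-zero")
  bits <- mask_bits(index, wanted_mask)
  if (length(index$ids) == 0)
    return(data.frame(id = character(0), cbd = integer(0)))
  if (isomers_only && is.na(q$formula))
    stop("isomer lock requires a structural query")
  qsum <- sum(q$mqn)
  bsums <- as.integer(names(index$buckets))
  cand <- unlist(index$buckets[bsums >= qsum - d_max & bsums <= qsum + d_max],
                 use.names = FALSE)
  if (!length(cand)) return(data.frame(id = character(0), cbd = integer(0)))
  d <- cbd_to(index$mqn[cand, , drop = FALSE], q$mqn)
  ok <- d <= d_max
  ok <- ok & rowSums(index$member[cand, bits, drop = FALSE]) > 0
  if (isomers_only) ok <- ok & index$formula[cand] == q$formula
  if (lock_hbd) ok <- ok & index$hbd[cand] == q$hbd
  if (lock_hba) ok <- ok & index$hba[cand] == q$hba
  cand <- cand[ok]; d <- d[ok]
  ord <- order(d, index$ids[cand])
  data.frame(id = index$ids[cand][ord], cbd = as.integer(d[ord]),
             stringsAsFactors = FALSE)
}

#' k-nearest-neighbour search in MQN space
#'
#' Expanding-ring wrapper over [range_search()]: the distance boundary is
#' doubled until at least `k` constrained hits are found (or the library
#' is exhausted), then the first `k` rows of the fully sorted result are
#' returned.
#'
#' @inheritParams range_search
#' @param k number of neighbours (>= 1).
#' @param ... constraints passed to [range_search()].
#' @return data.frame `(id, cbd)`, at most `k` rows.
#' @export
knn_search <- function(index, query, k, ...) {
  stopifnot(k >= 1)
  q <- resolve_query(query)
  d_limit <- sum(q$mqn) + max(index$sums, 0L) + 1L  # CBD <= sum(a) + sum(b)
  d <- 4L
  repeat {
    hits <- range_search(index, query, d_max = d, ...)
    if (nrow(hits) >= k || d >= d_limit) break
    d <- d * 2L
  }
  utils::head(hits, k)
}

#' Save / load an MQN index
#'
#' Writes `<stem>.tsv` (id, the 42 MQN columns, database mask, formula,
#' hba, hbd) and `<stem>.json` (database registry and format version).
#'
#' @param index an `mqn_index`.
#' @param stem file stem (without extension).
#' @export
save_index <- function(index, stem) {
  df <- data.frame(id = index$ids, index$mqn, mask = entry_masks(index),
                   formula = index$formula, hba = index$hba, hbd = index$hbd,
                   check.names = FALSE)
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(format = "flspace-mqn-index", version = 1L,
                            registry = index$registry),
                       paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(stem)
}

#' @rdname save_index
#' @export
load_index <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$format, "flspace-mqn-index"))
    stop("not an flspace index: ", stem)
  df <- utils::read.table(paste0(stem, ".tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = c(id = "character", formula = "character"))
  mqn <- as.matrix(df[, mqn_names(), drop = FALSE])
  storage.mode(mqn) <- "integer"
  rownames(mqn) <- df$id
  registry <- as.character(hdr$registry)
  member <- matrix(FALSE, nrow(df), length(registry),
                   dimnames = list(df$id, registry))
  for (j in seq_along(registry))
    member[, j] <- floor(df$mask / 2^(j - 1)) %% 2 == 1
  sums <- as.integer(rowSums(mqn))
  idx <- list(ids = df$id, mqn = mqn, sums = sums, member = member,
              formula = df$formula, hba = as.integer(df$hba),
              hbd = as.integer(df$hbd), registry = registry,
              buckets = split(seq_along(sums), sums))
  class(idx) <- "mqn_index"
  idx
}
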