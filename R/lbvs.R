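# Ligand-based virtual screening: curate fragrance families, pick a
# per-space medoid reference, dilute the family into a background library,
# rank by city-block distance and measure ROC/AUC and recovery at database
# fractions.

#' Curate fragrance families
#'
#' Applies the family curation rules: molecules listed in more than
#' `max_membership` raw families are removed from all of them; non
#' fragrance-like molecules are removed; an optional heavy-atom cap is
#' applied; families that end up below `min_size` are dropped. Output
#' order is deterministic (input order of families and members).
#'
#' @param raw named list: family name -> character vector of SMILES.
#' @param min_size minimum surviving family size (default 10).
#' @param max_membership maximum number of raw families a molecule may
#'   appear in (default 5).
#' @param hac_cap optional heavy-atom-count cap (e.g. 13 when screening
#'   against an enumerated database limited to 13 heavy atoms).
#' @return list of `fragrance_family` objects: name, member `molset`, and
#'   provenance counts (raw, removed_promiscuous, removed_non_fl,
#'   removed_hac_cap).
#' @export
curate_families <- function(raw, min_size = 10L, max_membership = 5L,
                            hac_cap = NULL) {
  stopifnot(is.list(raw), !is.null(names(raw)))
  sets <- lapply(seq_along(raw), function(k) {
    ms <- molset_from_smiles(raw[[k]],
                             sprintf("%s_%03d", names(raw)[k], seq_along(raw[[k]])))
    dedup(ms)
  })
  names(sets) <- names(raw)
  membership <- table(unlist(lapply(sets, function(ms) unique(ms$smiles))))
  promiscuous <- names(membership)[membership > max_membership]
  out <- list()
  for (k in seq_along(sets)) {
    ms <- sets[[k]]
    raw_n <- length(ms)
    keep <- !(ms$smiles %in% promiscuous)
    rem_prom <- sum(!keep)
    ms <- ms[which(keep)]
    v <- if (length(ms)) is_fragrance_like(ms)$passed else logical(0)
    rem_fl <- sum(!v)
    ms <- ms[which(v)]
    rem_cap <- 0L
    if (!is.null(hac_cap)) {
      ok <- ms$hac <= hac_cap
      rem_cap <- sum(!ok)
      ms <- ms[which(ok)]
    }
    if (length(ms) < min_size) next
    fam <- list(name = names(sets)[k], members = ms,
                provenance = c(raw = raw_n, removed_promiscuous = rem_prom,
                               removed_non_fl = rem_fl, removed_hac_cap = rem_cap))
    class(fam) <- "fragrance_family"
    out[[length(out) + 1L]] <- fam
  }
  out
}

#' @export
print.fragrance_family <- function(x, ...) {
  cat(sprintf("<fragrance_family '%s': %d members (raw %d; -%d promiscuous, -%d non-FL, -%d HAC cap)>\n",
              x$name, length(x$members), x$provenance["raw"],
              x$provenance["removed_promiscuous"], x$provenance["removed_non_fl"],
              x$provenance["removed_hac_cap"]))
  invisible(x)
}

#' Select the per-space reference compound of a family
#'
#' The medoid: the member minimizing the summed city-block distance to all
#' other members, computed in the given descriptor space. Ties are broken
#' by lowest id.
#'
#' @param family a `fragrance_family` (or a `molset`).
#' @param space descriptor space name (see [space_encode()]).
#' @param encoded optional precomputed encoding of the members.
#' @return the reference molecule id.
#' @export
select_reference <- function(family, space = "MQN", encoded = NULL) {
  ms <- if (inherits(family, "fragrance_family")) family$members else family
  if (length(ms) == 1) return(ms$id)
  if (is.null(encoded)) encoded <- space_encode(ms, space)
  n <- nrow(encoded)
  tot <- vapply(seq_len(n), function(i) sum(cbd_to(encoded, encoded[i, ])), 0)
  ord <- order(tot, rownames(encoded))
  rownames(encoded)[ord[1]]
}

# rank-averaged Mann-Whitney AUC (percent) for actives ranked by distance
auc_percent <- function(dist, is_active) {
  n_a <- sum(is_active); n_d <- sum(!is_active)
  if (n_a == 0 || n_d == 0) return(NA_real_)
  r <- rank(dist, ties.method = "average")
  # U counts (decoy farther than active) pairs, ties as 1/2
  u <- sum(r[!is_active]) - n_d * (n_d + 1) / 2
  100 * u / (n_a * n_d)
}

#' Run one enrichment experiment
#'
#' The family is diluted into the background library, every candidate is
#' ranked by ascending city-block distance to the reference in the chosen
#' descriptor space, and the ROC curve, its AUC (rank-averaged
#' Mann-Whitney, ties counted one half) and the recovery of actives at
#' database fractions are computed. Background molecules that duplicate a
#' family member (by canonical SMILES) are removed before dilution. The
#' reference itself is excluded from the actives and from the ranked list.
#'
#' @param family a `fragrance_family` (or `molset`) of actives.
#' @param background a `molset` of decoys.
#' @param space descriptor space name (see [space_encode()]).
#' @param reference optional reference id (default: the per-space medoid).
#' @param fractions database fractions for recovery (defaults 0.001, 0.01,
#'   0.1).
#' @return an object of class `enrichment_result`: family and space names,
#'   reference id, the ranked ids and distances, ROC points, `auc`
#'   (percent) and `recovery` (percent of actives found at each fraction).
#' @export
run_enrichment <- function(family, background, space = "MQN",
                           reference = NULL, fractions = c(0.001, 0.01, 0.1)) {
  fam_ms <- if (inherits(family, "fragrance_family")) family$members else family
  fam_name <- if (inherits(family, "fragrance_family")) family$name else "family"
  stopifnot(inherits(background, "molset"))
  bg <- background[which(!(background$smiles %in% fam_ms$smiles))]
  enc_fam <- space_encode(fam_ms, space)
  if (is.null(reference)) reference <- select_reference(fam_ms, space, encoded = enc_fam)
  actives <- fam_ms[which(fam_ms$id != reference)]
  if (length(actives) < 2)
    stop("family '", fam_name, "' has fewer than 2 actives after removing the reference")
  ref_vec <- enc_fam[reference, ]
  enc_act <- enc_fam[actives$id, , drop = FALSE]
  enc_bg <- space_encode(bg, space)
  dist <- c(cbd_to(enc_act, ref_vec), cbd_to(enc_bg, ref_vec))
  ids <- c(actives$id, bg$id)
  is_active <- c(rep(TRUE, length(actives)), rep(FALSE, length(bg)))
  ord <- order(dist, ids)
  dist <- dist[ord]; ids <- ids[ord]; is_active <- is_active[ord]
  n <- length(ids); n_a <- sum(is_active)
  roc <- data.frame(fpr = cumsum(!is_active) / max(1, n - n_a),
                    tpr = cumsum(is_active) / n_a)
  recovery <- vapply(fractions, function(f) {
    top <- max(1L, floor(f * n))
    100 * sum(is_active[seq_len(top)]) / n_a
  }, 0)
  names(recovery) <- paste0(100 * fractions, "%")
  res <- list(family = fam_name, space = space, reference = reference,
              ranked = data.frame(id = ids, dist = dist, active = is_active,
                                  stringsAsFactors = FALSE),
              roc = roc, auc = auc_percent(dist, is_active),
              recovery = recovery, n_actives = n_a, n_background = n - n_a)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment '%s' in %s space: AUC %.1f%%, %d actives in %d candidates>\n",
              x$family, x$space, x$auc, x$n_actives, x$n_actives + x$n_background))
  cat("  recovery:", paste(names(x$recovery), sprintf("%.1f%%", x$recovery),
                           sep = " -> ", collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("%s / %s (AUC %.1f%%)", x$family, x$space, x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Summarise enrichment results as a recovery table
#'
#' One row per family (size, mean heavy atom count, recovery per space at
#' the requested fraction, best space flagged) plus an `Average` row of
#' column means, and the mean AUC with SD per space.
#'
#' @param results list of `enrichment_result` objects (several spaces per
#'   family allowed).
#' @param fraction which recovery fraction to tabulate (default `"1%"`).
#' @return list with `table` (data.frame) and `auc` (data.frame of mean
#'   and SD per space).
#' @export
enrichment_table <- function(results, fraction = "1%") {
  if (!length(results)) {
    return(list(table = data.frame(family = character(0)),
                auc = data.frame(space = character(0), mean_auc = numeric(0),
                                 sd_auc = numeric(0))))
  }
  fams <- unique(vapply(results, `[[`, "", "family"))
  spaces <- unique(vapply(results, `[[`, "", "space"))
  tab <- data.frame(family = fams, stringsAsFactors = FALSE)
  tab$n <- NA_integer_
  for (sp in spaces) tab[[sp]] <- NA_real_
  for (r in results) {
    i <- match(r$family, fams)
    tab$n[i] <- r$n_actives + 1L
    tab[[r$space]][i] <- unname(r$recovery[fraction])
  }
  tab$best <- apply(tab[, spaces, drop = FALSE], 1, function(v)
    paste(spaces[!is.na(v) & v == max(v, na.rm = TRUE)], collapse = "/"))
  avg <- data.frame(family = "Average", n = round(mean(tab$n)),
                    stringsAsFactors = FALSE)
  for (sp in spaces) avg[[sp]] <- mean(tab[[sp]], na.rm = TRUE)
  avg$best <- ""
  auc_df <- do.call(rbind, lapply(spaces, function(sp) {
    aucs <- vapply(Filter(function(r) r$space == sp, results), `[[`, 0, "auc")
    data.frame(space = sp, mean_auc = mean(aucs),
               sd_auc = if (length(aucs) > 1) stats::sd(aucs) else 0,
               stringsAsFactors = FALSE)
  }))
  list(table = rbind(tab, avg), auc = auc_df)
}
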