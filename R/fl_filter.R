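# Fragrance-likeness: HAC <= 21, heavy elements within {C, O, S},
# O + S <= 3, at most one H-bond donor atom.

#' Fragrance-likeness verdicts
#'
#' Evaluates all four rules on every molecule (no short-circuiting, so the
#' set of failed rules is always complete). Molecules are ionized at
#' pH 7.4 first; the donor count uses the same convention as the MQN
#' `hbd` descriptor so the filter and the descriptors never disagree.
#'
#' @param x a `molset`, molgraph, or character vector of SMILES.
#' @param hac_max,os_max,hbd_max rule thresholds (defaults 21, 3, 1).
#' @param allowed_elements permitted heavy elements (default C, O, S).
#' @return a data.frame with one row per molecule: `id`, `passed`, one
#'   logical column per rule (`fail_hac`, `fail_elements`,
#'   `fail_heteroatoms`, `fail_hbd`), the measured values (`hac`, `os`,
#'   `hbd`, `elements`) and a `failed_rules` string column.
#' @examples
#' is_fragrance_like(c(vanillin = "COc1cc(C=O)ccc1O", pyrazine = "c1cnccn1"))
#' @export
is_fragrance_like <- function(x, hac_max = 21L, os_max = 3L, hbd_max = 1L,
                              allowed_elements = c("C", "O", "S")) {
  ms <- as_molset(x)
  n <- length(ms)
  hac <- integer(n); os <- integer(n); hbd <- integer(n)
  elements <- character(n); bad_el <- logical(n)
  for (i in seq_len(n)) {
    g <- ionize_ph74(ms$graph[[i]])
    hac[i] <- n_atoms(g)
    os[i] <- sum(g$elem %in% c("O", "S"))
    hbd[i] <- sum(donor_flags(g))
    els <- sort(unique(g$elem))
    elements[i] <- paste(els, collapse = "")
    bad_el[i] <- length(setdiff(els, allowed_elements)) > 0
  }
  fail_hac <- hac > hac_max
  fail_heteroatoms <- os > os_max
  fail_hbd <- hbd > hbd_max
  fails <- cbind(HAC = fail_hac, ELEMENTS = bad_el,
                 HETEROATOMS = fail_heteroatoms, HBD = fail_hbd)
  failed_rules <- apply(fails, 1, function(r) paste(colnames(fails)[r], collapse = ","))
  data.frame(id = ms$id, passed = !apply(fails, 1, any),
             fail_hac = fail_hac, fail_elements = bad_el,
             fail_heteroatoms = fail_heteroatoms, fail_hbd = fail_hbd,
             hac = hac, os = os, hbd = hbd, elements = elements,
             failed_rules = failed_rules, stringsAsFactors = FALSE)
}

#' Filter a collection to its fragrance-like subset
#'
#' @param ms a `molset`.
#' @inheritParams is_fragrance_like
#' @return an object of class `fl_filter_result`: list with the passing
#'   `subset` (input order preserved), the `retention` fraction (`NA` for
#'   empty input), per-rule `failure_counts`, and the full `verdicts`
#'   table.
#' @export
filter_database <- function(ms, hac_max = 21L, os_max = 3L, hbd_max = 1L,
                            allowed_elements = c("C", "O", "S")) {
  stopifnot(inherits(ms, "molset"))
  if (length(ms) == 0) {
    out <- list(subset = ms, retention = NA_real_,
                failure_counts = c(HAC = 0L, ELEMENTS = 0L, HETEROATOMS = 0L, HBD = 0L),
                verdicts = is_fragrance_like(ms))
    class(out) <- "fl_filter_result"
    return(out)
  }
  v <- is_fragrance_like(ms, hac_max, os_max, hbd_max, allowed_elements)
  out <- list(
    subset = ms[which(v$passed)],
    retention = mean(v$passed),
    failure_counts = c(HAC = sum(v$fail_hac), ELEMENTS = sum(v$fail_elements),
                       HETEROATOMS = sum(v$fail_heteroatoms), HBD = sum(v$fail_hbd)),
    verdicts = v
  )
  class(out) <- "fl_filter_result"
  out
}

#' @export
print.fl_filter_result <- function(x, ...) {
  cat(sprintf("Fragrance-likeness filter: %d / %d retained (%.1f%%)\n",
              length(x$subset), nrow(x$verdicts), 100 * x$retention))
  fc <- x$failure_counts
  cat("  rule failures:", paste(names(fc), fc, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Property profiles of a molecule collection
#'
#' The four histogram panels used to characterise fragrance databases:
#' heavy atom count, heteroatom count (all non-C heavy atoms), calculated
#' logP (Open Babel's atom-contribution estimator) and ring-count classes
#' (acyclic, monocyclic, bicyclic, polycyclic with >= 3 rings via the
#' smallest set of smallest rings). Histogram masses each sum to 1 for
#' non-empty input.
#'
#' @param ms a `molset`.
#' @param hac_breaks,het_breaks integer bin positions for the count
#'   histograms.
#' @param clogp_breaks numeric break points passed to [graphics::hist()]
#'   semantics for the clogP histogram.
#' @return an object of class `fl_profile`: list of four data.frames
#'   (`hac`, `heteroatoms`, `clogp`, `rings`), each with `bin` and
#'   `frequency` columns.
#' @export
property_profile <- function(ms, hac_breaks = 1:30, het_breaks = 0:10,
                             clogp_breaks = seq(-6, 12, by = 1)) {
  stopifnot(inherits(ms, "molset"))
  n <- length(ms)
  norm_hist <- function(values, bins) {
    cnt <- vapply(bins, function(b) sum(values == b), 0L)
    # open-ended top bin catches overflow so mass always sums to one
    cnt[length(cnt)] <- cnt[length(cnt)] + sum(values > bins[length(bins)])
    cnt[1] <- cnt[1] + sum(values < bins[1])
    data.frame(bin = bins, frequency = if (n == 0) rep(0, length(bins)) else cnt / n)
  }
  hac <- ms$hac
  het <- vapply(ms$graph, function(g) sum(g$elem != "C"), 0L)
  nring <- vapply(ms$graph, function(g) ring_info(g)$rank, 0L)
  ring_class <- cut(pmin(nring, 3L), breaks = c(-1, 0, 1, 2, 3),
                    labels = c("acyclic", "monocyclic", "bicyclic", "polycyclic"))
  rings <- data.frame(bin = c("acyclic", "monocyclic", "bicyclic", "polycyclic"),
                      frequency = if (n == 0) rep(0, 4) else
                        as.vector(table(ring_class)) / n)
  clogp <- if (n == 0) numeric(0) else clogp_values(ms)
  mids <- utils::head(clogp_breaks, -1) + diff(clogp_breaks) / 2
  cl_cut <- cut(pmin(pmax(clogp, min(clogp_breaks)), max(clogp_breaks)),
                breaks = clogp_breaks, include.lowest = TRUE)
  clogp_df <- data.frame(bin = mids,
                         frequency = if (n == 0) rep(0, length(mids)) else
                           as.vector(table(cl_cut)) / n)
  out <- list(hac = norm_hist(hac, hac_breaks),
              heteroatoms = norm_hist(het, het_breaks),
              clogp = clogp_df, rings = rings)
  class(out) <- "fl_profile"
  out
}

# calculated logP via Open Babel's atom-contribution model
clogp_values <- function(ms) {
  payload <- paste0(ms$smiles, "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", payload, identity)
  p <- ChemmineOB::prop_OB(mols)
  as.numeric(p$logP)
}

#' @export
print.fl_profile <- function(x, ...) {
  cat("<fl_profile: hac / heteroatoms / clogp / rings histograms>\n")
  cat("  ring classes:\n")
  print(x$rings, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fl_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$hac$frequency, names.arg = x$hac$bin, main = "Heavy atom count",
                    xlab = "HAC", ylab = "frequency", ...)
  graphics::barplot(x$heteroatoms$frequency, names.arg = x$heteroatoms$bin,
                    main = "Heteroatoms", xlab = "count", ylab = "frequency", ...)
  graphics::barplot(x$clogp$frequency, names.arg = x$clogp$bin, main = "clogP",
                    xlab = "clogP bin midpoint", ylab = "frequency", ...)
  graphics::barplot(x$rings$frequency, names.arg = x$rings$bin, main = "Ring classes",
                    ylab = "frequency", ...)
  invisible(x)
}
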