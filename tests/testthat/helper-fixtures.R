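# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

curated <- function() cached("curated", curated_fragrances())
curated_mqn <- function() cached("curated_mqn", mqn_table(curated()))

# small library for unit tests
unit_decoys <- function() cached("unit_decoys", generate_decoys(300, seed = 7))
unit_mqn <- function() cached("unit_mqn", mqn_table(unit_decoys()))

# full-scale library for the acceptance suite
acc_decoys <- function() cached("acc_decoys", generate_decoys(10000, seed = 42))
acc_mqn <- function() cached("acc_mqn", mqn_table(acc_decoys()))

# index over the unit decoys with two alternating databases
unit_index <- function() cached("unit_index", {
  d <- unit_decoys()
  dbs <- ifelse(seq_along(d$id) %% 2 == 0, "even", "odd")
  build_index(d, stats::setNames(as.list(dbs), d$id), mqn = unit_mqn())
})

# Brute-force search oracle: full linear scan with the same constraints.
brute_force_search <- function(mqn, meta, q, d_max, allowed_dbs = NULL,
                               isomers_only = FALSE, lock_hbd = FALSE,
                               lock_hba = FALSE) {
  d <- apply(mqn, 1, function(row) sum(abs(row - q$mqn)))
  ok <- d <= d_max
  if (!is.null(allowed_dbs))
    ok <- ok & vapply(meta$dbs, function(x) any(x %in% allowed_dbs), TRUE)
  if (isomers_only) ok <- ok & meta$formula == q$formula
  if (lock_hbd) ok <- ok & meta$hbd == q$hbd
  if (lock_hba) ok <- ok & meta$hba == q$hba
  ids <- rownames(mqn)[ok]
  dd <- d[ok]
  ord <- order(dd, ids)
  data.frame(id = ids[ord], cbd = as.integer(dd[ord]), stringsAsFactors = FALSE)
}

index_meta <- function(idx) {
  list(formula = idx$formula, hbd = idx$hbd, hba = idx$hba,
       dbs = lapply(seq_along(idx$ids), function(i)
         idx$registry[idx$member[i, ]]))
}

query_of <- function(ms, id) {
  m <- mqn_table(ms[id])
  list(mqn = m[1, ], formula = ms$formula[match(id, ms$id)],
       hbd = m[1, "hbd"], hba = m[1, "hba"])
}

# analogue families planted for screening tests
planted_families <- function(n_fam = 10, n_members = 15) {
  cached(sprintf("planted_%d_%d", n_fam, n_members), {
    seeds <- c("furaneol", "isoamyl_acetate", "caprylic_acid", "vanillin",
               "cinnamaldehyde", "limonene", "camphor", "menthone",
               "rose_oxide", "citronellol")[seq_len(n_fam)]
    cur <- curated()
    lapply(seq_along(seeds), function(k) {
      ms <- generate_analog_family(cur$smiles[match(seeds[k], cur$id)],
                                   n_members, seed = 100 + k)
      ms$id <- paste0(seeds[k], "_", ms$id)
      fam <- list(name = seeds[k], members = ms,
                  provenance = c(raw = n_members, removed_promiscuous = 0L,
                                 removed_non_fl = 0L, removed_hac_cap = 0L))
      class(fam) <- "fragrance_family"
      fam
    })
  })
}
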