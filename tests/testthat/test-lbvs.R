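# small FL ester/alcohol series used to build toy families
ester_series <- function(n, len0 = 2) {
  vapply(seq_len(n), function(k)
    paste0(paste(rep("C", len0 + k), collapse = ""), "OC(=O)C"), "")
}
alcohol_series <- function(n, len0 = 4) {
  vapply(seq_len(n), function(k)
    paste0(paste(rep("C", len0 + k), collapse = ""), "O"), "")
}

test_that("family curation applies promiscuity, FL and size rules", {
  shared <- "CCCCOC(=O)C"   # will sit in 6 of 8 families
  raw <- c(
    lapply(1:6, function(k) c(shared, ester_series(10, len0 = k + 2))),
    list(c(alcohol_series(11)), c(ester_series(4)))
  )
  names(raw) <- paste0("fam", 1:8)
  fams <- curate_families(raw, min_size = 10, max_membership = 5)
  shared_can <- flspace:::canonical_smiles(shared)
  for (f in fams) expect_false(shared_can %in% f$members$smiles)
  expect_false("fam8" %in% vapply(fams, `[[`, "", "name"))   # only 4 members

  # non-FL members are removed; a family dropping to 9 survivors is dropped
  raw2 <- list(ok = alcohol_series(10),
               short = c(alcohol_series(9), "c1cnccn1"))    # 9 FL + pyrazine
  fams2 <- curate_families(raw2, min_size = 10)
  expect_equal(vapply(fams2, `[[`, "", "name"), "ok")

  # constructed three-family case with known expected membership
  raw3 <- list(A = c(ester_series(12), "c1cnccn1"),
               B = alcohol_series(12),
               C = ester_series(5))
  fams3 <- curate_families(raw3, min_size = 10)
  expect_equal(vapply(fams3, `[[`, "", "name"), c("A", "B"))
  expect_equal(length(fams3[[1]]$members), 12)       # pyrazine removed
  expect_equal(unname(fams3[[1]]$provenance["removed_non_fl"]), 1L)
  expect_equal(length(fams3[[2]]$members), 12)

  # the heavy-atom cap trims large members
  fams4 <- curate_families(list(A = ester_series(12)), min_size = 5, hac_cap = 13)
  expect_true(all(fams4[[1]]$members$hac <= 13))
  expect_gt(unname(fams4[[1]]$provenance["removed_hac_cap"]), 0)
})

test_that("the reference compound is the per-space medoid with id ties low", {
  one <- flspace:::as_molset(c(only = "CCO"))
  expect_equal(select_reference(one), "only")

  # MW-collinear case: the middle value minimizes the distance sum
  alk <- flspace:::as_molset(c(
    heptane = "CCCCCCC",          # ~100 Da
    octane = "CCCCCCCC",          # ~114 Da
    tetradecane = "CCCCCCCCCCCCCC"))  # ~198 Da
  expect_equal(select_reference(alk, "MW"), "octane")

  # brute-force oracle on a 20-member generated family
  fam <- generate_analog_family("CC1CCC(C(C)C)C(=O)C1", 20, seed = 12)
  for (sp in c("MQN", "MW")) {
    enc <- space_encode(fam, sp)
    sums <- vapply(seq_len(nrow(enc)), function(i) {
      s <- 0
      for (j in seq_len(nrow(enc))) s <- s + sum(abs(enc[i, ] - enc[j, ]))
      s
    }, 0)
    best <- sort(rownames(enc)[sums == min(sums)])[1]
    expect_equal(select_reference(fam, sp), best)
  }
})

test_that("AUC matches a brute-force pairwise oracle, with ties as halves", {
  auc_oracle <- function(dist, act) {
    tot <- 0
    for (i in which(act)) for (j in which(!act)) {
      tot <- tot + (dist[j] > dist[i]) + 0.5 * (dist[j] == dist[i])
    }
    100 * tot / (sum(act) * sum(!act))
  }
  set.seed(31)
  for (k in 1:50) {
    n <- sample(20:60, 1)
    act <- seq_len(n) %in% sample(n, sample(3:8, 1))
    dist <- sample(0:12, n, replace = TRUE)     # heavy integer ties
    got <- flspace:::auc_percent(dist, act)
    expect_equal(got, auc_oracle(dist, act))
    # reversing the ranking mirrors the AUC
    expect_equal(flspace:::auc_percent(-dist, act), 100 - got)
  }
  # perfect and inverted rankings
  expect_equal(flspace:::auc_percent(c(1, 2, 10, 11), c(TRUE, TRUE, FALSE, FALSE)), 100)
  expect_equal(flspace:::auc_percent(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0)
})

test_that("enrichment runs rank candidates and report recovery correctly", {
  fam <- structure(list(name = "esters",
                        members = flspace:::as_molset(
                          stats::setNames(ester_series(6), paste0("e", 1:6))),
                        provenance = c(raw = 6, removed_promiscuous = 0,
                                       removed_non_fl = 0, removed_hac_cap = 0)),
                   class = "fragrance_family")
  bg <- unit_decoys()
  res <- run_enrichment(fam, bg, "MQN")
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$n_actives, 5)                     # reference excluded
  expect_false(res$reference %in% res$ranked$id)
  expect_false(is.unsorted(res$ranked$dist))
  expect_true(res$auc >= 0 && res$auc <= 100)
  # recovery is monotone in the fraction and hits 100% at fraction 1
  res2 <- run_enrichment(fam, bg, "MQN", fractions = c(0.001, 0.01, 0.1, 1))
  expect_true(all(diff(res2$recovery) >= 0))
  expect_equal(unname(res2$recovery["100%"]), 100)
  # ROC ends at (1, 1)
  expect_equal(unname(unlist(res$roc[nrow(res$roc), ])), c(1, 1))
  # background molecules equal to family members are removed before dilution
  bg2 <- flspace:::molset_bind(bg, flspace:::as_molset(
    stats::setNames(ester_series(2), c("dup1", "dup2"))))
  res3 <- run_enrichment(fam, bg2, "MQN")
  expect_equal(res3$n_background, sum(!(bg2$smiles %in% fam$members$smiles)))
  expect_lt(res3$n_background, length(bg2))
  # a family with fewer than 2 actives after reference removal errors
  tiny <- structure(list(name = "tiny",
                         members = flspace:::as_molset(
                           stats::setNames(ester_series(2), c("x", "y"))),
                         provenance = c(raw = 2, removed_promiscuous = 0,
                                        removed_non_fl = 0, removed_hac_cap = 0)),
                    class = "fragrance_family")
  expect_error(run_enrichment(tiny, bg, "MQN"), "fewer than 2")
})

test_that("enrichment tables average recoveries and AUCs per space", {
  fams <- planted_families(2, 12)
  bg <- unit_decoys()
  results <- list()
  for (f in fams) for (sp in c("MQN", "MW"))
    results[[length(results) + 1]] <- run_enrichment(f, bg, sp)
  tab <- enrichment_table(results, fraction = "1%")
  expect_equal(nrow(tab$table), 3)                   # 2 families + Average
  expect_equal(tab$table$family[3], "Average")
  expect_equal(tab$table$MQN[3], mean(tab$table$MQN[1:2]))
  expect_equal(nrow(tab$auc), 2)
  mqn_aucs <- vapply(Filter(function(r) r$space == "MQN", results), `[[`, 0, "auc")
  expect_equal(tab$auc$mean_auc[tab$auc$space == "MQN"], mean(mqn_aucs))
  expect_equal(tab$auc$sd_auc[tab$auc$space == "MQN"], stats::sd(mqn_aucs))

  # single result: the Average row equals the family row
  tab1 <- enrichment_table(results[1], fraction = "1%")
  expect_equal(tab1$table$MQN[2], tab1$table$MQN[1])
  # empty input: header only
  tab0 <- enrichment_table(list())
  expect_equal(nrow(tab0$table), 0)
})
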