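mqn_expected <- function(...) {
  v <- stats::setNames(integer(42), mqn_names())
  pairs <- list(...)
  for (nm in names(pairs)) v[nm] <- as.integer(pairs[[nm]])
  v
}

test_that("hand-counted MQN vectors are reproduced exactly", {
  expect_identical(compute_mqn("CC"),
                   mqn_expected(c = 2, hac = 2, asb = 1, asv = 2))
  expect_identical(compute_mqn("c1ccccc1"),
                   mqn_expected(c = 6, hac = 6, csb = 3, cdb = 3, cdv = 6, r6 = 1))
  expect_identical(compute_mqn("O=C1CCCCC1"),
                   mqn_expected(c = 6, ao = 1, hac = 7, csb = 6, adb = 1,
                                asv = 1, cdv = 5, ctv = 1, r6 = 1,
                                hba = 1, hbam = 2))
  expect_identical(compute_mqn("COc1cc(C=O)ccc1O"),
                   mqn_expected(c = 8, ao = 3, hac = 11, asb = 4, adb = 1,
                                csb = 3, cdb = 3, rbc = 2, hba = 3, hbd = 1,
                                hbam = 6, hbdm = 1, asv = 3, adv = 2,
                                cdv = 3, ctv = 3, r6 = 1))
})

test_that("the pH 7.4 ionization rule table fires on the right groups", {
  # acids deprotonate
  cap <- compute_mqn("CCCCCCCC(=O)O")
  expect_equal(unname(cap[c("neg", "pos", "hbd", "hbam")]), c(1, 0, 0, 5))
  sulf <- compute_mqn("CS(=O)(=O)O")
  expect_equal(unname(sulf["neg"]), 1)
  # amines, amidines, guanidines protonate
  expect_equal(unname(compute_mqn("CCN")["pos"]), 1)
  expect_equal(unname(compute_mqn("CCCN(C)C")["pos"]), 1)
  expect_equal(unname(compute_mqn("NC(N)=N")["pos"]), 1)     # guanidine
  # alcohols, phenols, thiols, amides, anilines unchanged
  for (smi in c("CCO", "Oc1ccccc1", "CCS", "CCC(N)=O", "Nc1ccccc1",
                "CC1CCC(C(C)C)C(=O)C1")) {
    v <- compute_mqn(smi)
    expect_equal(unname(v["pos"] + v["neg"]), 0, info = smi)
  }
  # heavy-atom composition is never altered
  g0 <- flspace:::as_molset("CCCCCCCC(=O)O")$graph[[1]]
  gi <- ionize_ph74(g0)
  expect_identical(gi$elem, g0$elem)
  expect_equal(sum(gi$nH), sum(g0$nH) - 1)
  # idempotence
  ms <- curated()
  g1 <- ionize_ph74(ms$graph[[3]])
  expect_identical(ionize_ph74(g1), g1)
})

test_that("cbd is the exact component-wise L1 sum and checks lengths", {
  v <- compute_mqn("CC")
  expect_equal(cbd(v, v), 0)
  a <- rep(0, 42); b <- rep(0, 42); b[5] <- 3; b[20] <- 2
  expect_equal(cbd(a, b), 5)
  expect_equal(cbd(compute_mqn("CC"), compute_mqn("c1ccccc1")), 24)
  expect_error(cbd(1:41, 1:42), "mismatch")
})

test_that("conservation invariants hold on curated and generated molecules", {
  sets <- list(curated(), unit_decoys())
  for (ms in sets) {
    m <- mqn_table(ms)
    expect_length(attr(m, "errors"), 0)
    for (i in seq_len(nrow(m))) {
      v <- m[i, ]
      g <- ms$graph[[match(rownames(m)[i], ms$id)]]
      expect_true(all(v >= 0))
      expect_equal(unname(v["an"] + v["cn"]), sum(g$elem == "N"))
      expect_equal(unname(v["ao"] + v["co"]), sum(g$elem == "O"))
      expect_equal(unname(sum(v[c("asb", "adb", "atb", "csb", "cdb", "ctb")])),
                   length(g$from))
      ncomp <- length(unique(flspace:::graph_components(g)))
      expect_equal(unname(sum(v[c("r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10")])),
                   length(g$from) - length(g$elem) + ncomp)
      deg0 <- sum(flspace:::atom_degree(g) == 0)
      expect_equal(unname(sum(v[c("asv", "adv", "atv", "aqv", "cdv", "ctv", "cqv")])),
                   unname(v["hac"]) - deg0)
    }
  }
})

test_that("CHOS-only molecules have zero N and halogen descriptors", {
  m <- unit_mqn()
  expect_true(all(m[, c("an", "cn", "f", "cl", "br", "i", "p")] == 0))
})

test_that("MQN values are invariant under input atom reordering", {
  variants <- list(
    c("CC1CCC(C(C)C)C(=O)C1", "O=C1CC(C)CCC1C(C)C"),
    c("COc1cc(C=O)ccc1O", "Oc1ccc(C=O)cc1OC"),
    c("CCO", "OCC"),
    c("CC1=CC[C@@H](CC1)C(=C)C", "C(=C)(C)[C@@H]1CC=C(C)CC1"))
  for (pair in variants) {
    expect_identical(compute_mqn(pair[1]), compute_mqn(pair[2]), info = pair[1])
  }
})

test_that("hypervalent atoms raise an error naming the atom", {
  g <- flspace:::new_molgraph(rep("C", 6), rep(0L, 6), c(0L, rep(3L, 5)),
                              rep(1L, 5), 2:6, rep(1L, 5))
  expect_error(compute_mqn(g), "degree > 4")
})

test_that("mqn_table round-trips through its TSV form", {
  m <- curated_mqn()
  f <- tempfile(fileext = ".tsv")
  write_mqn(m, f)
  back <- read_mqn(f)
  expect_identical(back, structure(m, errors = NULL))
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(header, c("id", mqn_names()))
})

test_that("formulas, heavy atoms and ring counts agree with an independent toolkit", {
  cur <- curated()
  py <- sprintf(paste0(
    "import json,sys\nfrom rdkit import Chem\n",
    "from rdkit.Chem import rdMolDescriptors as d\n",
    "smis=json.loads(sys.argv[1])\nout=[]\n",
    "for s in smis:\n",
    "    m=Chem.MolFromSmiles(s)\n",
    "    out.append([d.CalcMolFormula(m), m.GetNumHeavyAtoms(), len(Chem.GetSSSR(m))])\n",
    "print(json.dumps(out))\n"))
  script <- tempfile(fileext = ".py")
  writeLines(py, script)
  res <- system2("python", c(script, shQuote(jsonlite::toJSON(cur$smiles))),
                 stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(res[length(res)])
  m <- curated_mqn()
  nring <- rowSums(m[, c("r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10")])
  expect_equal(cur$formula, as.character(ref[, 1]))
  expect_equal(cur$hac, as.integer(ref[, 2]))
  expect_equal(unname(nring[cur$id]), as.integer(ref[, 3]))
})
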