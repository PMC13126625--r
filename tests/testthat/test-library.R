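# Active-ligand curation, fragment-environment pairs, scaffolds, analytics

test_that("pAct conversion and the activity threshold behave as documented", {
  recs <- data.frame(
    smiles = c("CCO", "CCN", "CCC", "CCCC"),
    protein_id = "P1",
    activity_type = c("IC50", "Ki", "qualitative", "IC50"),
    value_nM = c(10000, 100000, NA, 50),        # 10 uM, 100 uM, -, 50 nM
    qualifier = c(NA, NA, "active", NA),
    stringsAsFactors = FALSE)
  out <- curateActives(recs, keys = paste0("K", 1:4))
  expect_setequal(out$actives$key, c("K1", "K3", "K4"))   # 100 uM dropped
  expect_equal(out$actives$pAct[out$actives$key == "K1"], 5.0)
  expect_true(is.na(out$actives$pAct[out$actives$key == "K3"]))
})

test_that("curation is monotone in the threshold and deduplicates by max pAct", {
  recs <- data.frame(
    smiles = rep("CCO", 3), protein_id = c("P1", "P1", "P2"),
    activity_type = "IC50", value_nM = c(100, 10, 100),
    qualifier = NA, stringsAsFactors = FALSE)
  lo <- curateActives(recs, threshold = 5, keys = rep("K", 3))$actives
  hi <- curateActives(recs, threshold = 7.5, keys = rep("K", 3))$actives
  expect_true(all(interaction(hi$key, hi$protein_id) %in% interaction(lo$key, lo$protein_id)))
  expect_equal(nrow(lo), 2)                                  # (K,P1), (K,P2)
  expect_equal(lo$pAct[lo$protein_id == "P1"], 8)            # max kept
})

test_that("malformed records are logged, not fatal", {
  recs <- data.frame(smiles = c("CCO", "CCO"), protein_id = "P1",
                     activity_type = "IC50", value_nM = c("abc", "-5"),
                     qualifier = NA, stringsAsFactors = FALSE)
  out <- curateActives(recs, keys = c("K", "K"))
  expect_equal(nrow(out$actives), 0)
  expect_equal(length(out$rejected), 2)
})

test_that("pairs are unique by (fragment, protein) with merged provenance", {
  toy <- toy_complex()
  frag <- list(mol = toy$queries[[1]]@mol, key = "FRAGKEY", parent_key = "PARENT1",
               pose_id = "p1", cs = 0.7)
  frag2 <- frag; frag2$parent_key <- "PARENT2"; frag2$cs <- 0.9
  pairs <- buildPairs(list(frag, frag2), toy$pocket, "TOYPROT")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$n_provenance, 2)
  expect_equal(pairs$best_cs, 0.9)
  expect_true(grepl("PARENT1", pairs$parents) && grepl("PARENT2", pairs$parents))
})

test_that("far-away fragments are discarded with a warning", {
  toy <- toy_complex()
  far <- toy$queries[[1]]@mol
  atomCoords(far) <- sweep(atomCoords(far), 2, c(40, 0, 0), "+")
  frag <- list(mol = far, key = "FARKEY", parent_key = "P", pose_id = "p", cs = 0.7)
  expect_warning(pairs <- buildPairs(list(frag), toy$pocket, "TOYPROT"), "discard")
  expect_equal(nrow(pairs), 0)
})

test_that("contact residues follow the distance cutoff", {
  toy <- toy_complex()
  frag <- list(mol = toy$queries[[2]]@mol, key = "K", parent_key = "P",
               pose_id = "p", cs = 0.7)
  pairs <- buildPairs(list(frag), toy$pocket, "TOYPROT", contact_cutoff = 5)
  contacts <- strsplit(pairs$contacts, ",")[[1]]
  # brute-force recomputation
  X <- atomCoords(frag$mol, heavy = TRUE)
  P <- pocketCoords(toy$pocket)
  d <- sqrt(outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P))
  resk <- paste0(toy$pocket@atoms$chain, ":", toy$pocket@atoms$resid)
  expect_setequal(contacts, unique(resk[apply(d <= 5, 2, any)]))
})

test_that("Murcko scaffolds: side chains fall away, rings are fixed points", {
  expect_identical(inchikey(murckoScaffold(molFromSmiles("Cc1ccccc1"))),
                   inchikey(molFromSmiles("c1ccccc1")))
  expect_identical(inchikey(murckoScaffold(molFromSmiles("c1ccccc1"))),
                   inchikey(molFromSmiles("c1ccccc1")))
  expect_null(murckoScaffold(molFromSmiles("CCCCCC")))
  # linker between two rings is retained
  sc <- murckoScaffold(molFromSmiles("Cc1ccc(Cc2ccccc2)cc1"))
  expect_identical(inchikey(sc), inchikey(molFromSmiles("c1ccccc1Cc1ccccc1")))
})

test_that("frequency comparison joins, flags and counts correctly", {
  eq <- frequencyCompare(c("x", "y", "y"), c("x", "y", "y"))
  expect_true(all(eq$table$shared))
  expect_equal(eq$table$countA, eq$table$countB)
  dis <- frequencyCompare(c("a", "b"), c("c"))
  expect_equal(dis$n_shared, 0)
  ab <- frequencyCompare(c("x", "x", "x", "y"), c("y", "y"))
  expect_equal(ab$n_shared, 1)
  expect_identical(ab$table$key[ab$table$onlyA], "x")
  expect_equal(ab$frac_more_frequent_A, 0.5)
})

test_that("frequencyCompare(A,B) is the transpose of frequencyCompare(B,A)", {
  A <- c("x", "x", "y", "z"); B <- c("y", "w")
  ab <- frequencyCompare(A, B); ba <- frequencyCompare(B, A)
  expect_identical(ab$table$countA, ba$table$countB)
  expect_identical(ab$table$onlyA, ba$table$onlyB)
  expect_equal(ab$n_shared, ba$n_shared)
})

test_that("family enrichment counts and exclusivity flags match a hand table", {
  pairs <- data.frame(
    protein_id = c("P1", "P1", "P2", "P3", "P3", "P3"),
    scaffold_key = c("S1", "S2", "S1", "S3", "S3", "S2"),
    stringsAsFactors = FALSE)
  fams <- c(P1 = "kinase", P2 = "kinase", P3 = "gpcr")
  e <- familyEnrichment(pairs, fams)
  expect_equal(e$count[e$family == "kinase" & e$scaffold_key == "S1"], 2)
  expect_equal(e$count[e$family == "gpcr" & e$scaffold_key == "S3"], 2)
  expect_true(e$exclusive[e$scaffold_key == "S1"][1])       # only kinase
  expect_false(any(e$exclusive[e$scaffold_key == "S2"]))    # both families
  expect_true(all(diff(e$count) <= 0))
  # unmapped protein goes to "other"; single family -> everything exclusive
  solo <- familyEnrichment(pairs[1:2, ], c(P9 = "x"))
  expect_true(all(solo$family == "other"))
  expect_true(all(solo$exclusive))
})

test_that("the bundled activity CSV reads and curates end to end", {
  f <- system.file("extdata", "example_activities.csv", package = "posefrag")
  recs <- readActivityTable(f)
  out <- curateActives(recs)
  expect_true(all(out$actives$pAct >= 5 | is.na(out$actives$pAct)))
  # 250 uM hexane (pAct 3.6) is dropped; the qualitative active is kept
  expect_false(any(grepl("CCCCCC", out$actives$smiles)))
  expect_true("Nc1ccccc1" %in% out$actives$smiles)
  suppressWarnings(
    expect_error(readActivityTable(tempfile()), "cannot open|No such|does not exist"))
})
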