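# BRICS bond enumeration and exhaustive fragmentation

test_that("benzene has no cleavable bonds; returned bonds are always acyclic", {
  expect_equal(length(enumerateCleavableBonds(molFromSmiles("c1ccccc1"))), 0)
  for (smi in c("CCOC(=O)c1ccccc1", "CC(=O)Nc1ccccc1", "CN1CCC(CC1)Oc1ccccc1")) {
    mol <- molFromSmiles(smi)
    cl <- enumerateCleavableBonds(mol)
    expect_true(all(!mol@bonds$inRing[cl]))
  }
})

test_that("cleavable bonds and minimal fragments match an independent BRICS matcher", {
  ref <- rdkit_brics_reference(FRAG_TEST_SMILES)
  expect_false(is.null(ref))
  for (r in ref) {
    mol <- molFromSmiles(r$smiles)
    cl <- enumerateCleavableBonds(mol)
    expect_equal(length(cl), r$n_bonds, info = r$smiles)
    expect_identical(pkg_minimal_fragment_keys(mol), sort(unlist(r$frag_keys)),
                     info = r$smiles)
  }
})

test_that("the linear three-piece molecule yields exactly six substructures", {
  m <- posed_mol("c1ccccc1Cc1ccccc1")   # ring-CH2-ring, two cleavable bonds
  fr <- exhaustiveFragments(m)
  expect_equal(length(fr$fragments), 6)
  expect_false(fr$truncated)
})

test_that("a molecule with no cleavable bonds returns itself as the only fragment", {
  m <- posed_mol("c1ccccc1")
  fr <- exhaustiveFragments(m)
  expect_equal(length(fr$fragments), 1)
  expect_identical(fr$fragments[[1]]$key, inchikey(m))
})

test_that("fragment count equals the connected-induced-subgraph count", {
  for (smi in FRAG_TEST_SMILES[1:20]) {
    mol <- posed_mol(smi)
    fr <- exhaustiveFragments(mol)
    if (fr$truncated) next
    # rebuild the minimal-fragment adjacency graph independently
    cl <- enumerateCleavableBonds(mol)
    b <- mol@bonds
    keep <- setdiff(seq_len(nrow(b)), cl)
    g <- igraph::graph_from_data_frame(b[keep, c("a1", "a2"), drop = FALSE],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(natoms(mol))))
    comp <- igraph::components(g)$membership
    ids <- sort(unique(comp[heavyIdx(mol)]))
    relab <- match(comp, ids)
    adj <- lapply(seq_along(ids), function(i) integer())
    for (k in cl) {
      fi <- relab[b$a1[k]]; fj <- relab[b$a2[k]]
      adj[[fi]] <- union(adj[[fi]], fj); adj[[fj]] <- union(adj[[fj]], fi)
    }
    if (length(adj) > 8) next
    expect_equal(length(fr$fragments), count_connected_subgraphs(adj), info = smi)
  }
})

test_that("fragment heavy atoms inherit parent coordinates exactly", {
  m <- posed_mol("CCN(CC)C(=O)c1ccc(OC)cc1")
  fr <- exhaustiveFragments(m)
  X <- atomCoords(m)
  for (f in fr$fragments) {
    hvf <- heavyIdx(f$mol)
    sub <- atomCoords(f$mol)[hvf, , drop = FALSE]
    parent_heavy <- f$atoms
    expect_equal(nrow(sub), length(parent_heavy))
    expect_equal(max(abs(sub - X[parent_heavy, , drop = FALSE])), 0)
  }
})

test_that("the fragment key set is invariant to input atom ordering", {
  k1 <- sort(vapply(exhaustiveFragments(posed_mol("CC(=O)Nc1ccccc1"))$fragments,
                    `[[`, "", "key"))
  k2 <- sort(vapply(exhaustiveFragments(posed_mol("c1ccccc1NC(C)=O"))$fragments,
                    `[[`, "", "key"))
  expect_identical(unique(k1), unique(k2))
})

test_that("textbook fragment properties are reproduced", {
  bz <- fragmentProperties(molFromSmiles("c1ccccc1"))
  expect_equal(bz$MW, 78.1, tolerance = 0.05)
  expect_equal(unlist(bz[c("HBD", "HBA", "NR", "NRB")]),
               c(HBD = 0, HBA = 0, NR = 1, NRB = 0))
  ph <- fragmentProperties(molFromSmiles("Oc1ccccc1"))
  expect_equal(ph$HBD, 1); expect_equal(ph$HBA, 1)
  hx <- fragmentProperties(molFromSmiles("CCCCCC"))
  expect_equal(hx$NR, 0)
})

test_that("the five-criterion filter truth table behaves at the boundaries", {
  base <- data.frame(MW = 100, HBD = 0, HBA = 0, NR = 1, NRB = 0)
  expect_true(passesFilters(base))
  cases <- expand.grid(MW = c(300, 301), HBD = c(3, 4), HBA = c(6, 7),
                       NR = c(0, 1, 4, 5), NRB = c(5, 6))
  got <- passesFilters(cases)
  want <- cases$MW <= 300 & cases$HBD <= 3 & cases$HBA <= 6 &
    cases$NR >= 1 & cases$NR <= 4 & cases$NRB <= 5
  expect_identical(got, want)
  expect_gte(nrow(cases), 32)
})

test_that("filtering is monotone and idempotent", {
  m <- posed_mol("CCN(CC)C(=O)c1ccc(OC)cc1")
  fr <- exhaustiveFragments(m)
  props <- do.call(rbind, lapply(fr$fragments, fragmentProperties))
  keep <- passesFilters(props)
  expect_true(all(which(keep) %in% seq_along(fr$fragments)))
  expect_identical(passesFilters(props[keep, , drop = FALSE]),
                   rep(TRUE, sum(keep)))
})
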