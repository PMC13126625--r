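# Gaussian field similarity and rigid superposition

two_atom_mol <- function(d, elem = "C") {
  methods::new("Molecule",
    atoms = data.frame(elem = elem, x = c(0, d), y = 0, z = 0,
                       fcharge = 0L, pcharge = 0, aromatic = FALSE, inRing = FALSE),
    bonds = data.frame(a1 = 1L, a2 = 2L, order = 1L, aromatic = FALSE, inRing = FALSE))
}

one_atom_mol <- function(pos, elem = "C") {
  methods::new("Molecule",
    atoms = data.frame(elem = elem, x = pos[1], y = pos[2], z = pos[3],
                       fcharge = 0L, pcharge = 0, aromatic = FALSE, inRing = FALSE),
    bonds = data.frame(a1 = integer(), a2 = integer(), order = integer(),
                       aromatic = logical(), inRing = logical()))
}

test_that("field similarity is 1 for an exact copy in the same frame", {
  m <- posed_mol("Cc1ccccc1")
  expect_equal(fieldSimilarity(m, m), 1.0, tolerance = 1e-12)
})

test_that("two single atoms follow the closed-form Gaussian decay", {
  model <- fieldModel(useCharges = FALSE)
  alpha <- log(2) / 1.7^2   # carbon vdW radius
  for (d in c(0.5, 1, 2, 4)) {
    s <- fieldSimilarity(one_atom_mol(c(0, 0, 0)), one_atom_mol(c(d, 0, 0)), model)
    expect_equal(s, exp(-d^2 * alpha / 2), tolerance = 1e-10)
  }
  far <- fieldSimilarity(one_atom_mol(c(0, 0, 0)), one_atom_mol(c(50, 0, 0)), model)
  expect_lt(far, 1e-6)
})

test_that("field similarity is symmetric to 1e-9", {
  a <- posed_mol("Cc1ccccc1"); b <- posed_mol("Oc1ccccc1", seed = 3)
  expect_lt(abs(fieldSimilarity(a, b) - fieldSimilarity(b, a)), 1e-9)
})

test_that("similarity decays monotonically with rigid separation", {
  m <- posed_mol("c1ccccc1")
  sims <- vapply(seq(0, 6, by = 0.5), function(dx) {
    m2 <- m; atomCoords(m2) <- sweep(atomCoords(m), 2, c(dx, 0, 0), "+")
    fieldSimilarity(m, m2)
  }, 0)
  expect_true(all(diff(sims) <= 1e-12))
})

test_that("optimizer matches a dense grid search on the two-atom system", {
  model <- fieldModel(useCharges = FALSE)
  tmpl <- two_atom_mol(1.5)
  lig <- methods::new("StandardLigand", mol = two_atom_mol(1.5), key = "fixture-two-atom")
  lig@conformers <- list(atomCoords(tmpl) + 3)  # displaced start
  lig@energies <- 0
  poses <- alignToTemplate(lig, tmpl, model = model, n_poses = 1, n_random = 4, seed = 2)
  # dense grid: translations along x and rotations in the xy plane
  grid_best <- max(vapply(seq(-4, 4, by = 0.05), function(dx) {
    m2 <- tmpl
    atomCoords(m2) <- sweep(atomCoords(tmpl), 2, c(dx, 0, 0), "+")
    fieldSimilarity(tmpl, m2, model)
  }, 0))
  expect_gte(poses[[1]]$similarity3d + 1e-6, grid_best)
  expect_equal(poses[[1]]$similarity3d, 1.0, tolerance = 1e-4)
})

test_that("self-alignment recovers the template pose", {
  toy <- toy_complex()
  tmpl <- toy$template@mol
  lig <- toy$template
  lig@conformers <- list(sweep(atomCoords(tmpl), 2, c(8, -3, 2), "+"))
  lig@energies <- 0
  poses <- alignToTemplate(lig, tmpl, n_poses = 3, n_random = 4, seed = 5)
  expect_gte(poses[[1]]$similarity3d, 0.99)
  hv <- heavyIdx(tmpl)
  expect_lte(coordRmsd(poses[[1]]$coords[hv, ], atomCoords(tmpl)[hv, ]), 0.5)
})

test_that("returned poses are sorted, distinct and capped at n_poses", {
  toy <- toy_complex()
  q <- toy$queries[[1]]
  q <- generateConformers(q, 3, seed = 4)
  poses <- alignToTemplate(q, toy$template@mol, n_poses = 3, n_random = 4, seed = 4)
  expect_lte(length(poses), 3)
  sims <- vapply(poses, `[[`, 0, "similarity3d")
  expect_true(all(diff(sims) <= 1e-9))
  expect_true(all(vapply(poses, function(p) {
    r <- rotvec_to_matrix(c(0, 0, 0)) # no-op; keep structure
    det(p$R) > 0.999 && det(p$R) < 1.001
  }, TRUE)))
})

test_that("pre-translating the query conformers does not change similarities", {
  toy <- toy_complex()
  q <- generateConformers(toy$queries[[1]], 2, seed = 4)
  p1 <- alignToTemplate(q, toy$template@mol, n_poses = 2, n_random = 2, seed = 4)
  q2 <- q; q2@conformers <- lapply(q@conformers, function(X) sweep(X, 2, c(10, 0, 0), "+"))
  p2 <- alignToTemplate(q2, toy$template@mol, n_poses = 2, n_random = 2, seed = 4)
  expect_equal(p1[[1]]$similarity3d, p2[[1]]$similarity3d, tolerance = 1e-6)
})

test_that("alignment requires conformers", {
  toy <- toy_complex()
  bare <- methods::new("StandardLigand", mol = toy$queries[[1]]@mol,
                       key = toy$queries[[1]]@key)
  expect_error(alignToTemplate(bare, toy$template@mol), "no conformers")
})
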