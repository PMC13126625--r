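# Pose metrics, normalization, confidence score, weight optimization

single_atom_pocket <- function(pos, elem = "C", atomName = "CB", resname = "ALA") {
  methods::new("PocketModel",
    atoms = data.frame(elem = elem, atomName = atomName, resid = 1L,
                       resname = resname, chain = "A",
                       x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE),
    center = pos, radius = Inf, excluded = character())
}

carbon_probe <- function(pos = c(0, 0, 0)) {
  methods::new("Molecule",
    atoms = data.frame(elem = "C", x = pos[1], y = pos[2], z = pos[3],
                       fcharge = 0L, pcharge = 0, aromatic = FALSE, inRing = FALSE),
    bonds = data.frame(a1 = integer(), a2 = integer(), order = integer(),
                       aromatic = logical(), inRing = logical()))
}

test_that("no pocket atom within cutoff gives zero interaction terms and a flag", {
  res <- vinaTypeScore(carbon_probe(), single_atom_pocket(c(50, 0, 0)))
  expect_true(res$flag_no_contact)
  expect_equal(unname(res$terms), rep(0, 5))
  expect_equal(res$score, 0)
})

test_that("a C-C pair at the first Gaussian's optimum matches the closed form", {
  # surface distance 0 at center distance R_C + R_C = 3.8 A
  res <- vinaTypeScore(carbon_probe(), single_atom_pocket(c(3.8, 0, 0)))
  expect_equal(unname(res$terms["gauss1"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(res$terms["gauss2"]), exp(-((0 - 3) / 2)^2), tolerance = 1e-12)
  expect_equal(unname(res$terms["repulsion"]), 0)
  # both atoms hydrophobic carbons at surface distance 0 -> full ramp
  expect_equal(unname(res$terms["hydrophobic"]), 1.0)
  expect_equal(res$score,
               -0.035579 - 0.005156 * exp(-2.25) - 0.035069,
               tolerance = 1e-10)
})

test_that("overlapping atoms produce positive repulsion", {
  res <- vinaTypeScore(carbon_probe(), single_atom_pocket(c(1.0, 0, 0)))
  expect_gt(unname(res$terms["repulsion"]), 0)
})

test_that("ECIF features: empty pocket gives a zero vector", {
  m <- posed_mol("Cc1ccccc1")
  f <- ecifFeatures(m, empty_pocket())
  expect_equal(length(f), 0)
  fv <- ecifFeatures(m, empty_pocket(), vocabulary = c("a", "b"))
  expect_equal(unname(fv), c(0L, 0L))
})

test_that("ECIF features: one typed pair inside the cutoff fills exactly one bin", {
  pocket <- single_atom_pocket(c(5, 0, 0))
  probe <- carbon_probe()
  f <- ecifFeatures(probe, pocket, cutoff = 6)
  expect_equal(length(f), 1)
  expect_equal(unname(f[1]), 1L)
  # brute-force distance check: the single pair is at exactly 5 A
  expect_equal(sum(ecifFeatures(probe, pocket, cutoff = 4.9)), 0)
})

test_that("shrinking the ECIF cutoff never increases any bin", {
  toy <- toy_complex()
  m <- toy$queries[[1]]@mol
  f6 <- ecifFeatures(m, toy$pocket, cutoff = 6)
  f4 <- ecifFeatures(m, toy$pocket, cutoff = 4, vocabulary = names(f6))
  expect_true(all(f4 <= f6))
})

test_that("intSim is deterministic and supports trivial estimators", {
  toy <- toy_complex()
  m <- toy$queries[[1]]@mol
  sum_est <- function(f) sum(f)
  expect_equal(intSim(m, toy$pocket, sum_est),
               sum(ecifFeatures(m, toy$pocket)))
  expect_identical(intSim(m, toy$pocket, sum_est), intSim(m, toy$pocket, sum_est))
  expect_error(intSim(m, toy$pocket, NULL), "estimator")
  # linear estimator on a zero vector returns the intercept
  est <- list(vocabulary = c("X|Y"), coef = c("X|Y" = 2), intercept = 5.5)
  expect_equal(intSim(carbon_probe(c(100, 100, 100)), toy$pocket, est), 5.5)
})

test_that("fitted ECIF estimator reproduces a planted linear map", {
  toy <- toy_complex()
  mols <- lapply(c(list(toy$template), toy$queries), function(q) q@mol)
  feats <- lapply(mols, function(m) ecifFeatures(m, toy$pocket))
  vocab <- sort(unique(unlist(lapply(feats, names))))
  planted <- function(f) 3 + 0.05 * sum(f)
  y <- vapply(feats, planted, 0)
  est <- fitEcifEstimator(feats, y, lambda = 1e-8)
  pred <- vapply(mols, function(m) intSim(m, toy$pocket, est), 0)
  expect_equal(pred, y, tolerance = 0.05)
})

test_that("normalization maps endpoints and clamps outliers", {
  sc <- data.frame(sim2d = 0.5, sim3d = 0.5,
                   dock_raw = c(0, -12, -20, 5), affinity = c(2, 12, 20, 0))
  out <- normalizeMetrics(sc)
  expect_equal(out$dock_norm, c(0, 1, 1, 0))
  expect_equal(out$int_sim_norm, c(0, 1, 1, 0))
  expect_error(normalizeMetrics(sc, list(dock = c(worst = 1, best = 1),
                                         affinity = c(worst = 2, best = 12))),
               "degenerate")
})

test_that("confidence score arithmetic matches the published weights", {
  expect_equal(confidenceScore(c(0, 0, 0, 0)), 0)
  expect_equal(confidenceScore(c(1, 1, 1, 1)), 0.999)
  expect_equal(confidenceScore(c(0.37, 0.9, 0.1, 0.5), c(alpha = 1, beta = 0, gamma = 0, delta = 0)),
               0.37)
})

test_that("confidence score is linear in the metrics", {
  m <- c(0.4, 0.7, 0.2, 0.9)
  for (lam in c(0, 0.3, 1)) {
    expect_equal(confidenceScore(lam * m), lam * confidenceScore(m), tolerance = 1e-12)
  }
})

test_that("CS ranking is invariant to a common strictly increasing rescaling", {
  set.seed(1)
  cs <- runif(20)
  expect_identical(order(cs), order(2 * cs + 1))
  expect_identical(order(cs), order(cs^3))
})

test_that("weight optimization prefers the informative metric", {
  set.seed(42)
  n <- 120
  df <- data.frame(sim2d = runif(n), sim3d = runif(n),
                   dock_norm = runif(n), int_sim_norm = runif(n))
  success <- df$sim3d > 0.5
  res <- optimizeWeights(df, success, step = 0.1, sum_range = c(0.95, 1.05))
  expect_gt(res$weights["beta"], res$weights["alpha"])
  expect_gt(res$weights["beta"], res$weights["gamma"])
  expect_gt(res$weights["beta"], res$weights["delta"])
  expect_equal(res$f1, 1.0)
})

test_that("weight optimization is invariant to row permutation", {
  df <- makeScoredDataset(n = 80, seed = 3)
  sc <- df[, c("sim2d", "sim3d", "dock_norm", "int_sim_norm")]
  r1 <- optimizeWeights(sc, df$success, step = 0.1)
  perm <- sample(seq_len(nrow(sc)))
  r2 <- optimizeWeights(sc[perm, ], df$success[perm], step = 0.1)
  expect_identical(r1$weights, r2$weights)
  expect_equal(r1$f1, r2$f1)
})

test_that("single-class labels are rejected", {
  df <- makeScoredDataset(n = 60, seed = 4)
  sc <- df[, c("sim2d", "sim3d", "dock_norm", "int_sim_norm")]
  expect_error(optimizeWeights(sc, rep(TRUE, nrow(sc))), "both")
})

test_that("rotatable-bond counting follows the documented definition", {
  expect_equal(countRotatableBonds(molFromSmiles("c1ccccc1")), 0)
  expect_equal(countRotatableBonds(molFromSmiles("CCCC")), 1)
  expect_equal(countRotatableBonds(molFromSmiles("CC(=O)NC")), 0)   # amide excluded
  expect_equal(countRotatableBonds(molFromSmiles("CC(=O)NCC")), 1)  # N-CH2 rotatable
})
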