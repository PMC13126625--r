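# Backbone superposition, symmetry RMSD, site clustering, hotspot recovery

test_that("backbone superposition: identity, pure translation, jittered copy", {
  toy <- toy_complex()
  id <- backboneSuperpose(toy$pocket, toy$pocket)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  moved <- toy$pocket
  moved@atoms$x <- moved@atoms$x + 5
  tr <- backboneSuperpose(moved, toy$pocket)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)
  expect_equal(tr$t, c(-5, 0, 0), tolerance = 1e-9)
  set.seed(31)
  jit <- toy$pocket
  J <- matrix(rnorm(nrow(jit@atoms) * 3, 0, 0.1), ncol = 3)
  jit@atoms$x <- jit@atoms$x + J[, 1]
  jit@atoms$y <- jit@atoms$y + J[, 2]
  jit@atoms$z <- jit@atoms$z + J[, 3]
  fit <- backboneSuperpose(jit, toy$pocket)
  expect_lt(abs(fit$rmsd - 0.1 * sqrt(3)), 0.12)
  expect_error(backboneSuperpose(toy$pocket,
    methods::new("PocketModel",
                 atoms = toy$pocket@atoms[0, ], center = c(0, 0, 0),
                 radius = 1, excluded = character())), "at least 3")
})

test_that("symmetry RMSD absorbs a 60-degree benzene rotation", {
  bz <- posed_mol("c1ccccc1")
  hv <- heavyIdx(bz)
  X <- atomCoords(bz)
  ctr <- colMeans(X[hv, ])
  normal <- svd(sweep(X[hv, ], 2, ctr))$v[, 3]
  # rotation by 60 degrees about the ring normal through the centroid
  K <- matrix(c(0, -normal[3], normal[2], normal[3], 0, -normal[1],
                -normal[2], normal[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(pi / 3) * K + (1 - cos(pi / 3)) * K %*% K
  Xr <- sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr, "+")
  res <- symmetryRmsd(bz, coordsB = Xr)
  expect_lt(res$rmsd, 0.05)
  # naive index-matched RMSD is large
  expect_gt(coordRmsd(X[hv, ], Xr[hv, ]), 1)
})

test_that("a uniform 1 A translation gives symmetry RMSD exactly 1", {
  bz <- posed_mol("c1ccccc1")
  Xt <- sweep(atomCoords(bz), 2, c(1, 0, 0), "+")
  expect_equal(symmetryRmsd(bz, coordsB = Xt)$rmsd, 1, tolerance = 1e-9)
})

test_that("symmetry RMSD never exceeds the naive RMSD (100 random perturbations)", {
  mols <- list(posed_mol("c1ccccc1"), posed_mol("Cc1ccccc1"), posed_mol("CCO"))
  set.seed(99)
  for (i in seq_len(100)) {
    m <- mols[[(i %% length(mols)) + 1]]
    hv <- heavyIdx(m)
    X <- atomCoords(m)
    Xp <- X + matrix(rnorm(length(X), 0, 0.6), ncol = 3)
    naive <- coordRmsd(X[hv, ], Xp[hv, ])
    sym <- symmetryRmsd(m, coordsB = Xp)$rmsd
    expect_lte(sym, naive + 1e-9)
  }
})

test_that("asymmetric molecules give symmetry RMSD equal to the naive RMSD", {
  m <- posed_mol("CC(=O)NCC")   # no non-trivial automorphism of the heavy graph
  X <- atomCoords(m)
  set.seed(5)
  Xp <- X + matrix(rnorm(length(X), 0, 0.4), ncol = 3)
  hv <- heavyIdx(m)
  expect_equal(symmetryRmsd(m, coordsB = Xp)$rmsd, coordRmsd(X[hv, ], Xp[hv, ]),
               tolerance = 1e-12)
})

test_that("binding-site clustering separates distant pose groups", {
  toy <- toy_complex()
  m <- toy$template@mol
  shift <- function(v) { m2 <- m; atomCoords(m2) <- sweep(atomCoords(m), 2, v, "+"); m2 }
  near <- list(m, shift(c(2, 0, 0)), shift(c(0, 3, 0)))
  expect_equal(clusterBindingSites(near, cutoff = 8)$n_sites, 1)
  both <- c(near, list(shift(c(20, 0, 0)), shift(c(22, 0, 0))))
  cl <- clusterBindingSites(both, cutoff = 8)
  expect_equal(cl$n_sites, 2)
  expect_equal(cl$assignments[1:3], rep(1L, 3))
  expect_equal(clusterBindingSites(list())$n_sites, 0)
})

test_that("hotspot recovery matches an all-pairs brute force", {
  toy <- toy_complex()
  m <- toy$template@mol
  shift <- function(v) { m2 <- m; atomCoords(m2) <- sweep(atomCoords(m), 2, v, "+"); m2 }
  pred <- list(m, shift(c(1, 0, 0)), shift(c(5, 0, 0)), shift(c(0, 0, 3)))
  ref <- list(m, shift(c(0.5, 0, 0)), shift(c(10, 10, 0)))
  hr <- hotspotRecovery(pred, ref, cutoff = 2)
  predC <- t(vapply(pred, function(x) colMeans(atomCoords(x, heavy = TRUE)), numeric(3)))
  refC <- t(vapply(ref, function(x) colMeans(atomCoords(x, heavy = TRUE)), numeric(3)))
  brute <- apply(predC, 1, function(p) min(sqrt(rowSums(sweep(refC, 2, p)^2))))
  expect_equal(hr$per_fragment$min_dist, unname(brute), tolerance = 1e-9)
  expect_equal(hr$fraction_within, mean(brute <= 2))
  expect_equal(max(hr$per_fragment$max_sim), 1)   # identical molecule present
  expect_error(hotspotRecovery(pred, list()), "empty")
  ident <- hotspotRecovery(ref, ref, cutoff = 2)
  expect_equal(ident$fraction_within, 1)
  expect_equal(max(abs(ident$per_fragment$min_dist)), 0)
})

test_that("the cumulative curve is non-decreasing and reaches 100 percent", {
  r <- c(0.3, 0.8, 1.5, 2.5, 4)
  cc <- cumulativeCurve(r, thresholds = seq(0.25, 4, by = 0.25))
  expect_true(all(diff(cc$percent) >= 0))
  expect_equal(cc$percent[nrow(cc)], 100)
})
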