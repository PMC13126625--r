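# Interaction fingerprints, bioisostere search, attachment vectors,
# scaffold hopping

test_that("a ligand far from the protein has an empty fingerprint", {
  toy <- toy_complex()
  far <- toy$queries[[1]]@mol
  atomCoords(far) <- sweep(atomCoords(far), 2, c(100, 0, 0), "+")
  fp <- interactionFingerprint(far, toy$pocket)
  expect_equal(nrow(fp), 0)
})

test_that("parallel stacking over the phenylalanine ring is detected", {
  toy <- toy_complex()
  fp <- interactionFingerprint(toy$template@mol, toy$pocket)
  phe_res <- paste0("A:", toy$pocket@atoms$resid[toy$pocket@atoms$resname == "PHE"][1])
  expect_true(any(fp$residue == phe_res & fp$type == "pi-stacking"))
})

test_that("a near-linear hydroxyl donor to the serine oxygen is detected", {
  toy <- toy_complex()
  phenol <- toy$queries[[2]]@mol     # para-OH with H oriented at the serine
  fp <- interactionFingerprint(phenol, toy$pocket)
  ser_res <- paste0("A:", toy$pocket@atoms$resid[toy$pocket@atoms$resname == "SER"][1])
  expect_true(any(fp$residue == ser_res & fp$type == "HBond-donor"))
})

test_that("a halogen close to an acceptor is reported as a halogen bond", {
  toy <- toy_complex()
  chloro <- toy$queries[[1]]@mol     # para-Cl at 2.5 A from the serine OG
  fp <- interactionFingerprint(chloro, toy$pocket)
  expect_true(any(fp$type == "halogen"))
})

test_that("fingerprints are deterministic and atom-order invariant", {
  toy <- toy_complex()
  m <- toy$queries[[1]]@mol
  fp1 <- interactionFingerprint(m, toy$pocket)
  fp2 <- interactionFingerprint(m, toy$pocket)
  expect_identical(fp1, fp2)
  # reverse the atom order (bonds remapped accordingly)
  n <- natoms(m)
  perm <- rev(seq_len(n)); inv <- order(perm)
  m2 <- m
  m2@atoms <- m@atoms[perm, ]; rownames(m2@atoms) <- NULL
  b <- m@bonds; b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
  m2@bonds <- b
  expect_identical(interactionFingerprint(m2, toy$pocket), fp1)
})

make_fp_repo <- function(toy) {
  lapply(seq_along(toy$queries), function(i) {
    m <- toy$queries[[i]]@mol
    list(key = toy$queries[[i]]@key, protein_id = "TOYPROT", mol = m,
         fingerprint = interactionFingerprint(m, toy$pocket), cs = 0.6 + 0.1 * i)
  })
}

test_that("bioisostere search: self-match, strict vs superset, planted match", {
  toy <- toy_complex()
  repo <- make_fp_repo(toy)
  ref <- repo[[2]]$fingerprint       # phenol's fingerprint (has the H-bond)
  strict <- bioisostereSearch(repo, "TOYPROT", ref, mode = "strict")
  sup <- bioisostereSearch(repo, "TOYPROT", ref, mode = "superset")
  expect_true(repo[[2]]$key %in% vapply(strict, `[[`, "", "key"))
  expect_true(repo[[2]]$key %in% vapply(sup, `[[`, "", "key"))
  # strict results are a subset of superset results
  expect_true(all(vapply(strict, `[[`, "", "key") %in% vapply(sup, `[[`, "", "key")))
  # results sorted by cs descending
  if (length(sup) > 1)
    expect_true(all(diff(vapply(sup, `[[`, 0, "cs")) <= 0))
  # unknown protein: empty with warning
  expect_warning(none <- bioisostereSearch(repo, "NOPE", ref), "not present")
  expect_equal(length(none), 0)
  expect_equal(length(suppressWarnings(bioisostereSearch(list(), "NOPE", ref,
                                        mode = "strict"))), 0)
})

test_that("attachment vectors: counts and unit norms", {
  toy <- toy_complex()
  m <- toy$queries[[1]]@mol
  all_heavy <- heavyIdx(m)
  expect_equal(length(extractAttachmentVectors(m, all_heavy)), 0)  # whole molecule
  ring <- all_heavy[m@atoms$aromatic[all_heavy]]
  av <- extractAttachmentVectors(m, ring)
  expect_equal(length(av), 1)                    # one para substituent
  expect_equal(sqrt(sum(av[[1]]$dir^2)), 1, tolerance = 1e-6)
  # disconnected selection errors
  expect_error(extractAttachmentVectors(m, ring[c(1, 4)]), "connected")
})

test_that("scaffold hop: self-hop matches, translated copy is rejected", {
  toy <- toy_complex()
  ref <- toy$queries[[1]]@mol
  hv <- heavyIdx(ref)
  ring <- hv[ref@atoms$aromatic[hv]]
  core <- subMolecule(ref, ring, capH = TRUE)
  repo <- list(list(key = "self", protein_id = "TOYPROT", mol = core, cs = 0.9))
  res <- scaffoldHop(repo, "TOYPROT", ref, ring)
  expect_equal(nrow(res), 1)
  expect_equal(res$shape, 1, tolerance = 1e-6)
  expect_equal(res$n_matched, res$n_vectors)
  far <- core; atomCoords(far) <- sweep(atomCoords(core), 2, c(10, 0, 0), "+")
  repo2 <- list(list(key = "far", protein_id = "TOYPROT", mol = far, cs = 0.9))
  expect_equal(nrow(scaffoldHop(repo2, "TOYPROT", ref, ring)), 0)
})

test_that("scaffold hop: a 45-degree vector fails at 30 but passes at 50 degrees", {
  toy <- toy_complex()
  ref <- toy$queries[[1]]@mol
  hv <- heavyIdx(ref)
  ring <- hv[ref@atoms$aromatic[hv]]
  core <- subMolecule(ref, ring, capH = TRUE)
  # rotate only the capping hydrogens about the anchor: rebuild the core with
  # its attachment H rotated 45 degrees away from the reference direction
  av <- extractAttachmentVectors(ref, ring)[[1]]
  anchor_local <- which(apply(atomCoords(core), 1, function(p)
    sqrt(sum((p - av$anchor)^2))) < 1e-6)[1]
  hs <- which(core@atoms$elem == "H")
  X <- atomCoords(core)
  hi <- hs[which.min(apply(X[hs, , drop = FALSE], 1, function(p) {
    d <- p - av$anchor; 1 - sum(d * av$dir) / sqrt(sum(d^2))
  }))]
  d0 <- sqrt(sum((X[hi, ] - av$anchor)^2))
  rot45 <- av$dir %*% rot_z_mat(45 * pi / 180)
  X[hi, ] <- av$anchor + d0 * as.numeric(rot45)
  rotcore <- core; atomCoords(rotcore) <- X
  repo <- list(list(key = "rot", protein_id = "TOYPROT", mol = rotcore, cs = 0.9))
  expect_equal(nrow(scaffoldHop(repo, "TOYPROT", ref, ring, max_angle = 30)), 0)
  expect_equal(nrow(scaffoldHop(repo, "TOYPROT", ref, ring, max_angle = 50)), 1)
})

test_that("scaffold hop is invariant under a common rigid transform", {
  toy <- toy_complex()
  ref <- toy$queries[[1]]@mol
  hv <- heavyIdx(ref)
  ring <- hv[ref@atoms$aromatic[hv]]
  core <- subMolecule(ref, ring, capH = TRUE)
  repo <- list(list(key = "self", protein_id = "TOYPROT", mol = core, cs = 0.9))
  r0 <- scaffoldHop(repo, "TOYPROT", ref, ring)
  R <- rot_z_mat(0.7); t <- c(3, -2, 5)
  move <- function(m) { atomCoords(m) <- atomCoords(m) %*% R + matrix(t, natoms(m), 3, byrow = TRUE); m }
  repo2 <- list(list(key = "self", protein_id = "TOYPROT", mol = move(core), cs = 0.9))
  r1 <- scaffoldHop(repo2, "TOYPROT", move(ref), ring)
  expect_equal(r0$n_matched, r1$n_matched)
  expect_equal(r0$shape, r1$shape, tolerance = 1e-6)
})
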