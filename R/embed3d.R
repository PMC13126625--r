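# Seeded distance-geometry 3D embedding.
#
# Open Babel's conformer builder is stochastic without a controllable seed,
# so reproducible ensembles are generated here: distance bounds from the
# connection table (bond-length table, 1-3 distances from hybridization
# angles, van der Waals lower bounds, shortest-path upper bounds with
# triangle smoothing), seeded metrization, and classical metric MDS. The raw
# embedding is then cleaned up by a deterministic MMFF94s minimization.

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
VDW_RADII <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

elem_radius <- function(elem, table, default) {
  r <- table[elem]
  r[is.na(r)] <- default
  unname(r)
}

ideal_bond_length <- function(mol, k) {
  b <- mol@bonds[k, ]
  r <- elem_radius(mol@atoms$elem[c(b$a1, b$a2)], COVALENT_RADII, 1.1)
  len <- sum(r)
  if (b$aromatic) len * 0.93 else if (b$order == 2) len * 0.87
  else if (b$order == 3) len * 0.81 else len
}

# idealized bond angle at a center atom from its bonding pattern
ideal_angle <- function(mol, center) {
  b <- mol@bonds
  inc <- b[b$a1 == center | b$a2 == center, ]
  if (mol@atoms$aromatic[center]) return(120)
  if (any(inc$order == 3)) return(180)
  if (any(inc$order == 2)) return(120)
  109.47
}

# distance bounds matrices (lower, upper)
dg_bounds <- function(mol) {
  n <- natoms(mol)
  elem <- mol@atoms$elem
  BIG <- 999
  L <- matrix(0, n, n); U <- matrix(BIG, n, n)
  diag(U) <- 0
  vdw <- elem_radius(elem, VDW_RADII, 1.7)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    L[i, j] <- L[j, i] <- 0.85 * (vdw[i] + vdw[j]) * 0.7
  }
  blen <- vapply(seq_len(nrow(mol@bonds)), function(k) ideal_bond_length(mol, k), 0)
  for (k in seq_len(nrow(mol@bonds))) {
    i <- mol@bonds$a1[k]; j <- mol@bonds$a2[k]
    L[i, j] <- L[j, i] <- U[i, j] <- U[j, i] <- blen[k]
  }
  # 1-3 distances by the law of cosines at the idealized angle
  nb <- neighborList(mol)
  dbond <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(mol@bonds)))
    dbond[mol@bonds$a1[k], mol@bonds$a2[k]] <- dbond[mol@bonds$a2[k], mol@bonds$a1[k]] <- blen[k]
  for (c0 in seq_len(n)) {
    ns <- nb[[c0]]
    if (length(ns) < 2) next
    th <- ideal_angle(mol, c0) * pi / 180
    for (ii in seq_len(length(ns) - 1)) for (jj in (ii + 1):length(ns)) {
      i <- ns[ii]; j <- ns[jj]
      d <- sqrt(dbond[c0, i]^2 + dbond[c0, j]^2 - 2 * dbond[c0, i] * dbond[c0, j] * cos(th))
      L[i, j] <- L[j, i] <- U[i, j] <- U[j, i] <- d
    }
  }
  # triangle smoothing of upper bounds (Floyd), then lift lower bounds
  for (k in seq_len(n)) {
    Uk <- outer(U[, k], U[k, ], "+")
    U <- pmin(U, Uk)
  }
  L <- pmin(L, U)
  list(L = L, U = U)
}

# one seeded embedding: sample a distance matrix within bounds, embed by
# classical MDS on the double-centered squared-distance Gram matrix
dg_embed_once <- function(bounds, n) {
  L <- bounds$L; U <- bounds$U
  D <- matrix(0, n, n)
  iu <- upper.tri(D)
  D[iu] <- L[iu] + stats::runif(sum(iu)) * (U[iu] - L[iu])
  D <- D + t(D)
  D2 <- D^2
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% D2 %*% J
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values[1:3], 1e-6)
  X <- e$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3)
  X
}

#' Deterministic 3D embedding of molecules
#'
#' Generates \code{n_samples} seeded distance-geometry embeddings of a
#' molecule and relaxes each with MMFF94s. Deterministic for a fixed seed.
#'
#' @param mol a \linkS4class{Molecule}
#' @param n_samples number of embeddings
#' @param seed integer RNG seed
#' @param minimize run MMFF94s cleanup (default TRUE)
#' @return list with \code{coords} (list of n x 3 matrices) and
#'   \code{energy} (MMFF94s energies, kcal/mol; NA when not minimized)
#' @export
embedMolecule <- function(mol, n_samples = 1, seed = 1, minimize = TRUE) {
  n <- natoms(mol)
  if (n == 0) stop("cannot embed an empty molecule")
  bounds <- dg_bounds(mol)
  embeds <- with_local_seed(seed, lapply(seq_len(n_samples), function(i) dg_embed_once(bounds, n)))
  if (!minimize) return(list(coords = embeds, energy = rep(NA_real_, n_samples)))
  mols <- lapply(embeds, function(X) { m <- mol; atomCoords(m) <- X; m })
  sdf <- writeSDF(mols)
  msdf <- obMinimize(sdf)
  recs <- split_sdf_records(msdf)
  coords <- lapply(recs, function(lines) {
    p <- parse_molfile(lines)
    as.matrix(p$atoms[, c("x", "y", "z")])
  })
  energy <- obEnergy(msdf)
  list(coords = coords, energy = energy)
}

# evaluate expr under a given RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
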