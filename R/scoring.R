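# Pose metrics and the confidence score.
#
# Four metrics per pose: 2D fingerprint similarity to the template (2Dsim),
# Gaussian-field 3D similarity (3Dsim), an empirical docking score of the
# published AutoDock Vina functional form evaluated score-only (IntDock),
# and an interaction-feature affinity estimate built on typed
# protein-ligand atom-pair counts (IntSim). All four are min-max normalized
# to [0,1] and fused linearly: CS = alpha 2Dsim + beta 3Dsim +
# gamma IntDock + delta IntSim.

# Vina heavy-atom radii (Xs radii, Angstrom)
VINA_RADII <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5,
                Cl = 1.8, Br = 2.0, I = 2.2)
VINA_W <- c(gauss1 = -0.035579, gauss2 = -0.005156, repulsion = 0.840245,
            hydrophobic = -0.035069, hbond = -0.587439)
VINA_ROTOR_W <- 0.05846
VINA_CUTOFF <- 8

#' Published scoring weights of the confidence score
#'
#' alpha = 0.027 (2Dsim), beta = 0.324 (3Dsim), gamma = 0.378 (IntDock),
#' delta = 0.270 (IntSim).
#'
#' @return named numeric vector (alpha, beta, gamma, delta)
#' @export
defaultWeights <- function() c(alpha = 0.027, beta = 0.324, gamma = 0.378, delta = 0.270)

# atom typing helpers for the Vina terms -------------------------------------

vina_ligand_types <- function(mol) {
  hv <- heavyIdx(mol)
  elem <- mol@atoms$elem[hv]
  nbl <- neighborList(mol)
  hydrophobic <- vapply(seq_along(hv), function(k) {
    i <- hv[k]
    if (elem[k] %in% c("F", "Cl", "Br", "I")) return(TRUE)
    if (elem[k] != "C") return(FALSE)
    !any(mol@atoms$elem[nbl[[i]]] %in% c("N", "O"))
  }, TRUE)
  hc <- hydrogenCount(mol)[hv]
  donor <- elem %in% c("N", "O") & hc > 0
  acceptor <- elem %in% c("N", "O")
  list(idx = hv, elem = elem, hydrophobic = hydrophobic,
       donor = donor, acceptor = acceptor,
       radius = unname(ifelse(is.na(VINA_RADII[elem]), 1.9, VINA_RADII[elem])))
}

vina_pocket_types <- function(pocket) {
  a <- pocket@atoms
  hydrophobic <- a$elem == "C" & !(a$atomName %in% c("CA", "C"))  # backbone C/CA polarized
  donor <- (a$elem == "N") |
    (a$resname %in% c("SER", "THR", "TYR") & a$atomName %in% c("OG", "OG1", "OH"))
  acceptor <- a$elem == "O" | (a$resname == "HIS" & a$atomName %in% c("ND1", "NE2"))
  list(elem = a$elem, hydrophobic = hydrophobic, donor = donor, acceptor = acceptor,
       radius = unname(ifelse(is.na(VINA_RADII[a$elem]), 1.9, VINA_RADII[a$elem])))
}

#' Count rotatable bonds of a molecule
#'
#' Acyclic single bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds.
#'
#' @param mol a \linkS4class{Molecule}
#' @export
countRotatableBonds <- function(mol) {
  b <- mol@bonds
  hd <- heavyDegree(mol)
  elem <- mol@atoms$elem
  nbl <- neighborList(mol)
  is_amide_cn <- function(i, j) {
    # C(=O)-N in either direction
    ij <- c(i, j)
    ci <- ij[elem[ij] == "C"]; ni <- ij[elem[ij] == "N"]
    if (length(ci) != 1 || length(ni) != 1) return(FALSE)
    any(vapply(nbl[[ci]], function(k) {
      if (elem[k] != "O") return(FALSE)
      bb <- b[(b$a1 == ci & b$a2 == k) | (b$a2 == ci & b$a1 == k), ]
      nrow(bb) > 0 && bb$order[1] == 2
    }, TRUE))
  }
  n <- 0L
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    if (elem[i] == "H" || elem[j] == "H") next
    if (b$inRing[k] || b$order[k] != 1 || b$aromatic[k]) next
    if (hd[i] < 2 || hd[j] < 2) next
    if (is_amide_cn(i, j)) next
    n <- n + 1L
  }
  n
}

#' Empirical docking score (score-only)
#'
#' Evaluates the published Vina empirical terms -- two attractive Gaussians,
#' quadratic repulsion, hydrophobic and H-bond ramps on the surface distance
#' d' = d - R_i - R_j, with the published term weights and the rotor
#' penalty 1/(1 + w N_rot) -- for a pose inside a rigid pocket. No pose
#' search is performed.
#'
#' @param pose_mol posed \linkS4class{Molecule}
#' @param pocket a \linkS4class{PocketModel}
#' @param cutoff interaction cutoff in Angstrom (default 8)
#' @return list with \code{score} (weighted, rotor-scaled total),
#'   \code{terms} (named raw term sums) and \code{flag_no_contact}
#' @export
vinaTypeScore <- function(pose_mol, pocket, cutoff = VINA_CUTOFF) {
  lt <- vina_ligand_types(pose_mol)
  X <- atomCoords(pose_mol)[lt$idx, , drop = FALSE]
  pt <- vina_pocket_types(pocket)
  P <- pocketCoords(pocket)
  terms <- c(gauss1 = 0, gauss2 = 0, repulsion = 0, hydrophobic = 0, hbond = 0)
  any_contact <- FALSE
  if (nrow(P) > 0) {
    d <- sqrt(outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P))
    within <- d <= cutoff
    any_contact <- any(within)
    if (any_contact) {
      ij <- which(within, arr.ind = TRUE)
      dd <- d[within] - lt$radius[ij[, 1]] - pt$radius[ij[, 2]]
      terms["gauss1"] <- sum(exp(-(dd / 0.5)^2))
      terms["gauss2"] <- sum(exp(-((dd - 3) / 2)^2))
      terms["repulsion"] <- sum(ifelse(dd < 0, dd^2, 0))
      hpair <- lt$hydrophobic[ij[, 1]] & pt$hydrophobic[ij[, 2]]
      ramp_h <- pmin(1, pmax(0, (1.5 - dd) / 1.0))
      terms["hydrophobic"] <- sum(ramp_h[hpair])
      hb <- (lt$donor[ij[, 1]] & pt$acceptor[ij[, 2]]) |
            (lt$acceptor[ij[, 1]] & pt$donor[ij[, 2]])
      ramp_b <- pmin(1, pmax(0, -dd / 0.7))
      terms["hbond"] <- sum(ramp_b[hb])
    }
  }
  inter <- sum(VINA_W * terms)
  nrot <- countRotatableBonds(pose_mol)
  list(score = inter / (1 + VINA_ROTOR_W * nrot), terms = terms,
       flag_no_contact = !any_contact)
}

# ---- extended-connectivity interaction features ----------------------------

ecif_atom_code <- function(elem, valence, heavy_nb, n_h, aromatic, in_ring)
  sprintf("%s;%d;%d;%d;%d;%d", elem, valence, heavy_nb, n_h,
          as.integer(aromatic), as.integer(in_ring))

ecif_ligand_codes <- function(mol) {
  hv <- heavyIdx(mol)
  hd <- heavyDegree(mol)[hv]
  hc <- hydrogenCount(mol)[hv]
  b <- mol@bonds
  val <- integer(natoms(mol))
  for (k in seq_len(nrow(b))) {
    o <- if (b$aromatic[k]) 1L else b$order[k]
    val[b$a1[k]] <- val[b$a1[k]] + o
    val[b$a2[k]] <- val[b$a2[k]] + o
  }
  ecif_atom_code(mol@atoms$elem[hv], val[hv], hd, hc,
                 mol@atoms$aromatic[hv], mol@atoms$inRing[hv])
}

# protein heavy-atom codes from residue templates: element, heavy neighbors
# (distance-inferred within the residue), aromaticity/ring by residue table
AROMATIC_PROT <- list(HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
                      PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
RING_PROT <- c(AROMATIC_PROT, list(PRO = c("N", "CA", "CB", "CG", "CD")))

ecif_pocket_codes <- function(pocket) {
  a <- pocket@atoms
  X <- pocketCoords(pocket)
  n <- nrow(a)
  heavy_nb <- integer(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(X))
    heavy_nb <- rowSums(d > 0 & d < 1.8)
  }
  arom <- mapply(function(rn, an) an %in% (AROMATIC_PROT[[rn]] %||% character()),
                 a$resname, a$atomName)
  ring <- mapply(function(rn, an) an %in% (RING_PROT[[rn]] %||% character()),
                 a$resname, a$atomName)
  ecif_atom_code(a$elem, heavy_nb, heavy_nb, 0L, arom, ring)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extended-connectivity interaction features
#'
#' Counts of (protein atom type, ligand atom type) pairs within
#' \code{cutoff}. Atom types encode element, explicit valence, heavy
#' neighbors, attached hydrogens, aromaticity and ring membership.
#'
#' @param pose_mol posed \linkS4class{Molecule}
#' @param pocket a \linkS4class{PocketModel}
#' @param cutoff pair distance cutoff in Angstrom (default 6)
#' @param vocabulary optional fixed character vector of pair-type names; when
#'   given, the returned vector has exactly these bins (in order)
#' @return named non-negative integer vector of pair counts
#' @export
ecifFeatures <- function(pose_mol, pocket, cutoff = 6.0, vocabulary = NULL) {
  stopifnot(cutoff > 0)
  lc <- ecif_ligand_codes(pose_mol)
  X <- atomCoords(pose_mol, heavy = TRUE)
  pc <- ecif_pocket_codes(pocket)
  P <- pocketCoords(pocket)
  counts <- integer()
  if (nrow(P) > 0 && nrow(X) > 0) {
    d <- sqrt(outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P))
    ij <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(ij) > 0) {
      keys <- paste(pc[ij[, 2]], lc[ij[, 1]], sep = "|")
      tab <- table(keys)
      counts <- as.integer(tab); names(counts) <- names(tab)
    }
  }
  if (!is.null(vocabulary)) {
    out <- integer(length(vocabulary)); names(out) <- vocabulary
    common <- intersect(names(counts), vocabulary)
    out[common] <- counts[common]
    return(out)
  }
  if (length(counts) == 0) return(stats::setNames(integer(0), character(0)))
  counts[order(names(counts))]
}

#' Interaction-similarity affinity estimate
#'
#' Applies a fitted estimator to the ECIF vector of a pose. The estimator is
#' pluggable: a list with \code{vocabulary}, \code{coef} (named, same bins)
#' and \code{intercept}, or any function taking the named count vector.
#'
#' @param pose_mol posed \linkS4class{Molecule}
#' @param pocket a \linkS4class{PocketModel}
#' @param estimator fitted estimator (see Details)
#' @param cutoff ECIF cutoff in Angstrom
#' @return predicted affinity (pAct scale for the bundled estimators)
#' @export
intSim <- function(pose_mol, pocket, estimator, cutoff = 6.0) {
  if (missing(estimator) || is.null(estimator))
    stop("no affinity estimator supplied; fit one with fitEcifEstimator() or pass a function")
  if (is.function(estimator)) {
    feats <- ecifFeatures(pose_mol, pocket, cutoff)
    return(estimator(feats))
  }
  feats <- ecifFeatures(pose_mol, pocket, cutoff, vocabulary = estimator$vocabulary)
  as.numeric(estimator$intercept + sum(estimator$coef * feats))
}

#' Fit a linear ECIF affinity estimator
#'
#' Ridge-regularized least squares from ECIF vectors to affinities; intended
#' for small fixture-scale calibrations, not production affinity modeling.
#'
#' @param feature_list list of named count vectors (from
#'   \code{\link{ecifFeatures}})
#' @param affinities numeric response (pAct scale)
#' @param lambda ridge penalty
#' @return estimator list (\code{vocabulary}, \code{coef}, \code{intercept})
#' @export
fitEcifEstimator <- function(feature_list, affinities, lambda = 1e-3) {
  vocab <- sort(unique(unlist(lapply(feature_list, names))))
  M <- t(vapply(feature_list, function(f) {
    v <- numeric(length(vocab)); names(v) <- vocab
    v[names(f)] <- f; v
  }, numeric(length(vocab))))
  y <- affinities
  mu <- mean(y)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  A <- crossprod(Mc) + lambda * diag(ncol(Mc))
  beta <- solve(A, crossprod(Mc, y - mu))
  list(vocabulary = vocab, coef = stats::setNames(as.numeric(beta), vocab),
       intercept = mu - sum(colMeans(M) * beta))
}

# ---- normalization and fusion ----------------------------------------------

#' Default metric normalization ranges
#'
#' Docking score range [0, -12] (0 worst, -12 best) and affinity range
#' pAct in [2, 12]; both clamped.
#' @export
defaultNormalization <- function() list(dock = c(worst = 0, best = -12),
                                        affinity = c(worst = 2, best = 12))

#' Min-max normalize the four pose metrics
#'
#' Linear mapping with clamping to [0,1]; similarity metrics pass through.
#'
#' @param scores data.frame with columns \code{sim2d}, \code{sim3d},
#'   \code{dock_raw}, \code{affinity}
#' @param normalization list as in \code{\link{defaultNormalization}}
#' @return the data.frame with \code{dock_norm} and \code{int_sim_norm}
#'   columns added
#' @export
normalizeMetrics <- function(scores, normalization = defaultNormalization()) {
  lin <- function(x, rng) {
    if (abs(rng["best"] - rng["worst"]) < 1e-12)
      stop("degenerate normalization range (min == max)")
    pmin(1, pmax(0, (x - rng["worst"]) / (rng["best"] - rng["worst"])))
  }
  scores$dock_norm <- as.numeric(lin(scores$dock_raw, normalization$dock))
  scores$int_sim_norm <- as.numeric(lin(scores$affinity, normalization$affinity))
  scores
}

#' Confidence score of a pose
#'
#' CS = alpha 2Dsim + beta 3Dsim + gamma IntDock + delta IntSim on the
#' normalized metrics.
#'
#' @param scores data.frame with \code{sim2d}, \code{sim3d},
#'   \code{dock_norm}, \code{int_sim_norm} (or a numeric length-4 vector in
#'   that order)
#' @param weights named weights (alpha, beta, gamma, delta), each in [0,1]
#' @return numeric confidence score(s)
#' @export
confidenceScore <- function(scores, weights = defaultWeights()) {
  stopifnot(all(weights >= 0), all(weights <= 1))
  if (is.numeric(scores) && is.null(dim(scores))) {
    stopifnot(length(scores) == 4)
    return(sum(weights * scores))
  }
  as.numeric(weights["alpha"] * scores$sim2d + weights["beta"] * scores$sim3d +
             weights["gamma"] * scores$dock_norm + weights["delta"] * scores$int_sim_norm)
}

# best F1 over thresholds on a score vector; returns c(f1, threshold)
best_f1_threshold <- function(cs, labels) {
  ord <- order(-cs)
  lab <- labels[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  fn <- sum(lab) - tp
  f1 <- 2 * tp / (2 * tp + fp + fn)
  f1[!is.finite(f1)] <- 0
  k <- which.max(f1)
  c(f1 = f1[k], threshold = cs[ord][k])
}

#' Optimize confidence-score weights by exhaustive F1 grid search
#'
#' Scans (alpha, beta, gamma, delta) on a regular grid restricted to weight
#' sums in [0.95, 1.05]; for each combination the classification threshold on
#' CS is chosen to maximize F1 against the success labels (RMSD < 2 A).
#' Deterministic tie-break: the first combination in lexicographic grid
#' order is kept.
#'
#' @param scores normalized metric data.frame (see
#'   \code{\link{confidenceScore}})
#' @param success logical success labels
#' @param step grid step (default 0.027, the printed weight resolution)
#' @param sum_range allowed weight-sum interval
#' @return list with \code{weights}, \code{f1}, \code{threshold}
#' @export
optimizeWeights <- function(scores, success, step = 0.027, sum_range = c(0.95, 1.05)) {
  stopifnot(length(success) == nrow(scores))
  if (length(unique(success)) < 2)
    stop("weight optimization needs both successful and failed poses")
  vals <- seq(0, 1, by = step)
  M <- cbind(scores$sim2d, scores$sim3d, scores$dock_norm, scores$int_sim_norm)
  grid <- expand.grid(delta = vals, gamma = vals, beta = vals, alpha = vals)
  s <- grid$alpha + grid$beta + grid$gamma + grid$delta
  grid <- grid[s >= sum_range[1] & s <= sum_range[2], c("alpha", "beta", "gamma", "delta")]
  # lexicographic order in (alpha, beta, gamma, delta)
  grid <- grid[order(grid$alpha, grid$beta, grid$gamma, grid$delta), ]
  W <- as.matrix(grid)
  CS <- M %*% t(W)
  best <- c(-Inf, NA); best_i <- NA_integer_
  for (i in seq_len(ncol(CS))) {
    r <- best_f1_threshold(CS[, i], success)
    if (r[1] > best[1] + 1e-12) { best <- r; best_i <- i }
  }
  list(weights = stats::setNames(as.numeric(W[best_i, ]), c("alpha", "beta", "gamma", "delta")),
       f1 = unname(best[1]), threshold = unname(best[2]))
}
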