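# Rigid-pocket model, maximum common substructure tethers, and tethered
# local pose refinement.
#
# The refinement objective keeps the ligand's covalent geometry near its
# input conformation (pairwise-distance restraints over bonds and 1-3
# pairs), adds intramolecular and ligand-pocket Lennard-Jones terms, a
# Coulomb term with distance-dependent dielectric, and harmonic tethers on
# the MCS atoms. All terms depend only on pairwise distances, so gradients
# are analytic and minimization uses L-BFGS-B with the protein rigid.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' PocketModel: rigid protein environment around a binding site
#'
#' @slot atoms data.frame: \code{elem}, \code{atomName}, \code{resid}
#'   (residue number), \code{resname}, \code{chain}, \code{x,y,z}
#' @slot center pocket center (Angstrom)
#' @slot radius pocket radius used for extraction (Angstrom)
#' @slot excluded character log of removed components (waters, ions,
#'   cofactors)
#' @exportClass PocketModel
setClass("PocketModel",
  representation(atoms = "data.frame", center = "numeric", radius = "numeric",
                 excluded = "character"),
  prototype(excluded = character(), center = c(0, 0, 0), radius = Inf))

setValidity("PocketModel", function(object) {
  need <- c("elem", "atomName", "resid", "resname", "chain", "x", "y", "z")
  if (!all(need %in% names(object@atoms))) return("pocket atoms missing required columns")
  if (nrow(object@atoms) && !all(object@atoms$resname %in% STANDARD_AA))
    return("pocket atoms must belong to polymer (standard amino acid) residues")
  TRUE
})

setMethod("show", "PocketModel", function(object) {
  cat("PocketModel:", nrow(object@atoms), "protein atoms,",
      length(unique(paste(object@atoms$chain, object@atoms$resid))), "residues;",
      length(object@excluded), "component(s) excluded\n")
})

#' Pocket coordinates
#' @param pocket a \linkS4class{PocketModel}
#' @export
pocketCoords <- function(pocket) {
  m <- as.matrix(pocket@atoms[, c("x", "y", "z")]); rownames(m) <- NULL; m
}

#' Extract a rigid pocket model from a PDB file
#'
#' Reads the receptor with bio3d, drops crystallographic waters, metal ions
#' and non-polymeric cofactors (logged), and keeps polymer residues with any
#' heavy atom within \code{radius} of \code{center}.
#'
#' @param pdb_file path to a PDB file
#' @param center pocket center, typically the template ligand centroid; when
#'   NULL the full polymer is kept
#' @param radius residue-selection radius in Angstrom (default 8)
#' @return a \linkS4class{PocketModel}
#' @export
readPocket <- function(pdb_file, center = NULL, radius = 8) {
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  a <- pdb$atom
  excluded <- character()
  water <- a$resid %in% c("HOH", "WAT", "DOD")
  if (any(water)) excluded <- c(excluded, sprintf("water x%d", sum(water)))
  nonpoly <- !(a$resid %in% STANDARD_AA) & !water
  if (any(nonpoly))
    excluded <- c(excluded, sprintf("het %s x%d", unique(a$resid[nonpoly])[1], sum(nonpoly)))
  a <- a[a$resid %in% STANDARD_AA & a$elesy != "H", , drop = FALSE]
  atoms <- data.frame(elem = a$elesy, atomName = a$elety, resid = a$resno,
                      resname = a$resid, chain = a$chain,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  if (!is.null(center)) {
    X <- as.matrix(atoms[, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(X, 2, center)^2))
    atoms$d <- d
    keepres <- unique(atoms[atoms$d <= radius, c("chain", "resid")])
    keep <- interaction(atoms$chain, atoms$resid) %in% interaction(keepres$chain, keepres$resid)
    atoms <- atoms[keep, , drop = FALSE]
    atoms$d <- NULL
  } else center <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
  rownames(atoms) <- NULL
  methods::new("PocketModel", atoms = atoms, center = as.numeric(center),
               radius = radius, excluded = excluded)
}

# ---- maximum common substructure --------------------------------------------

#' Connected maximum common substructure between two molecules
#'
#' Element- and bond-order-matched connected MCS found as a maximum clique
#' of the modular product of the two heavy-atom graphs, restricted to
#' mappings whose query-side image is connected. Deterministic tie-break:
#' smallest sorted query index sequence.
#'
#' @param query,template \linkS4class{Molecule} or
#'   \linkS4class{StandardLigand}
#' @param min_atoms minimum MCS size to produce a tether (default 3)
#' @return list with \code{mapping} (two-column matrix: query atom index,
#'   template atom index) and \code{tethered} (FALSE when the MCS is below
#'   \code{min_atoms}; the mapping may still be returned for inspection)
#' @export
findMCS <- function(query, template, min_atoms = 3) {
  if (methods::is(query, "StandardLigand")) query <- query@mol
  if (methods::is(template, "StandardLigand")) template <- template@mol
  hq <- heavyIdx(query); ht <- heavyIdx(template)
  # vertex pairs with matching element + aromaticity
  pairs <- list()
  for (i in hq) for (j in ht) {
    if (query@atoms$elem[i] == template@atoms$elem[j] &&
        query@atoms$aromatic[i] == template@atoms$aromatic[j])
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (length(pairs) == 0) return(list(mapping = matrix(0L, 0, 2), tethered = FALSE))
  P <- do.call(rbind, pairs)
  bond_code <- function(mol) {
    b <- mol@bonds[mol@atoms$elem[mol@bonds$a1] != "H" & mol@atoms$elem[mol@bonds$a2] != "H", , drop = FALSE]
    m <- matrix(0L, natoms(mol), natoms(mol))
    code <- ifelse(b$aromatic, 4L, b$order)
    m[cbind(b$a1, b$a2)] <- code; m[cbind(b$a2, b$a1)] <- code
    m
  }
  bq <- bond_code(query); bt <- bond_code(template)
  np <- nrow(P)
  adj <- matrix(FALSE, np, np)
  for (u in seq_len(np - 1)) for (v in (u + 1):np) {
    i <- P[u, 1]; k <- P[v, 1]; j <- P[u, 2]; l <- P[v, 2]
    if (i == k || j == l) next
    if (bq[i, k] == bt[j, l]) adj[u, v] <- adj[v, u] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g, min = 1)
  # score each clique by the size of the largest connected piece of its
  # query-side image (bond-connected in the common mapping)
  best <- NULL; best_size <- 0; best_sig <- NULL
  for (clq in cl) {
    vs <- as.integer(clq)
    qi <- P[vs, 1]; ti <- P[vs, 2]
    sub <- matrix(FALSE, length(vs), length(vs))
    for (u in seq_along(vs)) for (v in seq_along(vs)) {
      if (u < v && bq[qi[u], qi[v]] > 0 && bq[qi[u], qi[v]] == bt[ti[u], ti[v]])
        sub[u, v] <- sub[v, u] <- TRUE
    }
    gg <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(gg)
    big <- which(comp$membership == which.max(comp$csize))
    size <- length(big)
    sig <- paste(sort(qi[big]), collapse = ",")
    if (size > best_size || (size == best_size && !is.null(best_sig) && sig < best_sig)) {
      best_size <- size; best_sig <- sig
      best <- cbind(query = qi[big], template = ti[big])
      best <- best[order(best[, 1]), , drop = FALSE]
    }
  }
  if (is.null(best)) return(list(mapping = matrix(0L, 0, 2), tethered = FALSE))
  list(mapping = best, tethered = best_size >= min_atoms)
}

#' Build a tether specification from an aligned pose
#'
#' @param mcs result of \code{\link{findMCS}}
#' @param aligned_coords all-atom coordinate matrix of the aligned query
#' @param k harmonic force constant (kcal/mol/A^2)
#' @param tol tether tolerance in Angstrom
#' @return list with \code{atoms} (query atom indices), \code{ref}
#'   (reference coordinates), \code{k}, \code{tol}, \code{tethered}
#' @export
tetherSpec <- function(mcs, aligned_coords, k = 10, tol = 0.5) {
  if (!mcs$tethered || nrow(mcs$mapping) == 0)
    return(list(atoms = integer(), ref = matrix(0, 0, 3), k = k, tol = tol, tethered = FALSE))
  idx <- mcs$mapping[, 1]
  list(atoms = idx, ref = aligned_coords[idx, , drop = FALSE], k = k, tol = tol,
       tethered = TRUE)
}

# ---- tethered minimization --------------------------------------------------

LJ_EPS <- 0.1          # kcal/mol, uniform well depth
COULOMB_K <- 332.06    # kcal mol^-1 A e^-2
DIELECTRIC <- 4        # distance-dependent dielectric: eps(r) = DIELECTRIC * r

# pairwise-distance restraint lists for the ligand internal model
internal_terms <- function(mol, X0) {
  n <- natoms(mol)
  b <- mol@bonds
  g <- molGraph(mol)
  sp <- igraph::distances(g)
  pairs12 <- cbind(b$a1, b$a2)
  idx13 <- which(sp == 2, arr.ind = TRUE); idx13 <- idx13[idx13[, 1] < idx13[, 2], , drop = FALSE]
  idx14p <- which(sp >= 3 & is.finite(sp), arr.ind = TRUE)
  idx14p <- idx14p[idx14p[, 1] < idx14p[, 2], , drop = FALSE]
  d0 <- function(p) sqrt(rowSums((X0[p[, 1], , drop = FALSE] - X0[p[, 2], , drop = FALSE])^2))
  vdw <- elem_radius(mol@atoms$elem, VDW_RADII, 1.7)
  list(p12 = pairs12, d12 = d0(pairs12),
       p13 = idx13, d13 = if (nrow(idx13)) d0(idx13) else numeric(),
       p14 = idx14p,
       sigma14 = if (nrow(idx14p)) 0.85 * (vdw[idx14p[, 1]] + vdw[idx14p[, 2]]) else numeric())
}

# energy + gradient of the tethered objective; pocket coordinates fixed
tether_objective <- function(mol, pocket_X, pocket_q, tether, terms, k_bond = 300, k_13 = 60) {
  hv_l <- heavyIdx(mol)
  vdw_l <- elem_radius(mol@atoms$elem, VDW_RADII, 1.7)
  q_l <- mol@atoms$pcharge
  function(par) {
    X <- matrix(par, ncol = 3)
    E <- 0
    G <- matrix(0, nrow(X), 3)
    add_pair <- function(p, fE, fdEdd) {
      if (nrow(p) == 0) return(invisible())
      dx <- X[p[, 1], , drop = FALSE] - X[p[, 2], , drop = FALSE]
      d <- sqrt(rowSums(dx^2)); d[d < 1e-8] <- 1e-8
      E <<- E + sum(fE(d))
      w <- fdEdd(d) / d
      gp <- dx * w
      for (c3 in 1:3) {
        G[, c3] <<- G[, c3] + tapply_add(gp[, c3], p[, 1], nrow(X))
        G[, c3] <<- G[, c3] - tapply_add(gp[, c3], p[, 2], nrow(X))
      }
      invisible()
    }
    # bonded + 1-3 distance restraints to the input geometry
    add_pair(terms$p12, function(d) k_bond * (d - terms$d12)^2,
             function(d) 2 * k_bond * (d - terms$d12))
    if (nrow(terms$p13))
      add_pair(terms$p13, function(d) k_13 * (d - terms$d13)^2,
               function(d) 2 * k_13 * (d - terms$d13))
    # intramolecular LJ (1-4 and beyond)
    if (nrow(terms$p14)) {
      s <- terms$sigma14
      add_pair(terms$p14,
               function(d) LJ_EPS * ((s / d)^12 - 2 * (s / d)^6),
               function(d) LJ_EPS * (-12 * s^12 / d^13 + 12 * s^6 / d^7))
    }
    # ligand-pocket LJ + Coulomb (heavy ligand atoms only for LJ)
    if (nrow(pocket_X) > 0) {
      for (i in hv_l) {
        dx <- sweep(pocket_X, 2, X[i, ], "-")
        d <- sqrt(rowSums(dx^2)); d[d < 1e-8] <- 1e-8
        s <- 0.9 * (vdw_l[i] + pocket_q$vdw)
        El <- LJ_EPS * ((s / d)^12 - 2 * (s / d)^6)
        dEl <- LJ_EPS * (-12 * s^12 / d^13 + 12 * s^6 / d^7)
        Ec <- COULOMB_K * q_l[i] * pocket_q$q / (DIELECTRIC * d^2)
        dEc <- -2 * COULOMB_K * q_l[i] * pocket_q$q / (DIELECTRIC * d^3)
        E <- E + sum(El + Ec)
        w <- (dEl + dEc) / d
        G[i, ] <- G[i, ] - colSums(dx * w)
      }
    }
    # harmonic tethers
    if (length(tether$atoms)) {
      dx <- X[tether$atoms, , drop = FALSE] - tether$ref
      E <- E + tether$k * sum(dx^2)
      G[tether$atoms, ] <- G[tether$atoms, ] + 2 * tether$k * dx
    }
    list(value = E, gradient = as.vector(G))
  }
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Tethered local minimization of a pose in a rigid pocket
#'
#' Minimizes ligand internal strain (distance restraints to the input
#' conformation plus intramolecular Lennard-Jones), ligand-pocket
#' Lennard-Jones and Coulomb energy, and harmonic tethers holding the MCS
#' atoms near their aligned positions. The protein never moves.
#'
#' @param pose_mol posed \linkS4class{Molecule} (coordinates = aligned pose)
#' @param pocket a \linkS4class{PocketModel}
#' @param tether result of \code{\link{tetherSpec}}
#' @param maxit L-BFGS-B iteration cap
#' @param clash_floor minimum acceptable ligand-protein heavy-atom distance
#' @return list with \code{mol} (refined molecule), \code{energy0},
#'   \code{energy}, \code{converged}, \code{clash} (TRUE when a
#'   ligand-protein contact below \code{clash_floor} remains),
#'   \code{tether_ok} (mapped atoms within tolerance)
#' @export
tetheredMinimize <- function(pose_mol, pocket, tether, maxit = 400, clash_floor = 2.0) {
  X0 <- atomCoords(pose_mol)
  terms <- internal_terms(pose_mol, X0)
  pX <- pocketCoords(pocket)
  pq <- list(vdw = elem_radius(pocket@atoms$elem, VDW_RADII, 1.7),
             q = protein_partial_charges(pocket))
  obj <- tether_objective(pose_mol, pX, pq, tether, terms)
  fn <- function(p) obj(p)$value
  gr <- function(p) obj(p)$gradient
  e0 <- fn(as.vector(X0))
  opt <- stats::optim(as.vector(X0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  if (!is.finite(opt$value)) stop("divergent tethered minimization for pose ", pose_mol@name)
  X <- matrix(opt$par, ncol = 3)
  out <- pose_mol; atomCoords(out) <- X
  hv <- heavyIdx(pose_mol)
  clash <- FALSE
  if (nrow(pX) > 0) {
    dmin <- min(apply(X[hv, , drop = FALSE], 1, function(p) min(sqrt(rowSums(sweep(pX, 2, p)^2)))))
    clash <- dmin < clash_floor
  }
  tether_ok <- TRUE
  if (length(tether$atoms)) {
    dev <- sqrt(rowSums((X[tether$atoms, , drop = FALSE] - tether$ref)^2))
    tether_ok <- all(dev <= tether$tol)
  }
  list(mol = out, energy0 = e0, energy = opt$value,
       converged = opt$convergence == 0, clash = clash, tether_ok = tether_ok)
}

# crude protein partial charges: charged side-chain termini only
protein_partial_charges <- function(pocket) {
  a <- pocket@atoms
  q <- numeric(nrow(a))
  q[a$resname == "ASP" & a$atomName %in% c("OD1", "OD2")] <- -0.5
  q[a$resname == "GLU" & a$atomName %in% c("OE1", "OE2")] <- -0.5
  q[a$resname == "LYS" & a$atomName == "NZ"] <- 1
  q[a$resname == "ARG" & a$atomName %in% c("NH1", "NH2")] <- 0.5
  q
}
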