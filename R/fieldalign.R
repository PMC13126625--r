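# Gaussian molecular-field similarity and rigid + conformational
# superposition of a query onto a template pose.
#
# Each heavy atom carries a spherical Gaussian. The steric channel uses unit
# amplitudes with exponents set so the Gaussian falls to half its maximum at
# the van der Waals radius; the electrostatic channel reuses the same
# centers with Gasteiger charges (hydrogen charges summed onto their heavy
# neighbor) as amplitudes. Similarity is the cosine-normalized overlap
# O(a,b)/sqrt(O(a,a) O(b,b)) per channel, channels mixed linearly.

#' FieldModel: parameters of the Gaussian molecular field
#'
#' @slot kappa Gaussian exponent scale; atom i gets exponent
#'   \code{kappa / r_vdw(i)^2} so kappa = log(2) puts the half-maximum at
#'   the van der Waals radius
#' @slot mix steric channel weight in [0, 1]; the electrostatic channel gets
#'   \code{1 - mix}
#' @slot useCharges evaluate the electrostatic channel (needs partial
#'   charges)
#' @exportClass FieldModel
setClass("FieldModel",
  representation(kappa = "numeric", mix = "numeric", useCharges = "logical"),
  prototype(kappa = log(2), mix = 0.5, useCharges = TRUE))

setValidity("FieldModel", function(object) {
  if (object@kappa <= 0) return("kappa must be positive")
  if (object@mix < 0 || object@mix > 1) return("mix must be in [0,1]")
  TRUE
})

#' Construct a field model
#' @param kappa exponent scale (default log 2)
#' @param mix steric channel weight (default 0.5)
#' @param useCharges include the electrostatic channel
#' @export
fieldModel <- function(kappa = log(2), mix = 0.5, useCharges = TRUE)
  methods::new("FieldModel", kappa = kappa, mix = mix, useCharges = useCharges)

# field descriptor of a posed molecule: heavy-atom centers, exponents, and
# effective charges (H charges folded onto the bonded heavy atom)
field_terms <- function(mol, model) {
  hv <- heavyIdx(mol)
  X <- atomCoords(mol)[hv, , drop = FALSE]
  alpha <- model@kappa / elem_radius(mol@atoms$elem[hv], VDW_RADII, 1.7)^2
  q <- mol@atoms$pcharge[hv]
  nbl <- neighborList(mol)
  pos <- integer(natoms(mol)); pos[hv] <- seq_along(hv)
  for (i in seq_len(natoms(mol))) {
    if (mol@atoms$elem[i] == "H") {
      hn <- nbl[[i]]
      hn <- hn[mol@atoms$elem[hn] != "H"]
      if (length(hn)) q[pos[hn[1]]] <- q[pos[hn[1]]] + mol@atoms$pcharge[i]
    }
  }
  list(X = X, alpha = alpha, q = q)
}

# Gaussian overlap sum_{ij} w_i w_j (pi/(ai+aj))^{3/2} exp(-ai aj/(ai+aj) d^2)
gaussian_overlap <- function(Xa, aa, wa, Xb, ab, wb) {
  d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * Xa %*% t(Xb)
  d2[d2 < 0] <- 0
  asum <- outer(aa, ab, "+")
  pref <- (pi / asum)^1.5
  expo <- exp(-outer(aa, ab) / asum * d2)
  sum((wa %o% wb) * pref * expo)
}

field_similarity_terms <- function(ta, tb, model) {
  o_ab <- gaussian_overlap(ta$X, ta$alpha, rep(1, nrow(ta$X)), tb$X, tb$alpha, rep(1, nrow(tb$X)))
  o_aa <- gaussian_overlap(ta$X, ta$alpha, rep(1, nrow(ta$X)), ta$X, ta$alpha, rep(1, nrow(ta$X)))
  o_bb <- gaussian_overlap(tb$X, tb$alpha, rep(1, nrow(tb$X)), tb$X, tb$alpha, rep(1, nrow(tb$X)))
  s_st <- o_ab / sqrt(o_aa * o_bb)
  if (!model@useCharges) return(s_st)
  qa <- ta$q; qb <- tb$q
  e_aa <- gaussian_overlap(ta$X, ta$alpha, qa, ta$X, ta$alpha, qa)
  e_bb <- gaussian_overlap(tb$X, tb$alpha, qb, tb$X, tb$alpha, qb)
  if (e_aa < 1e-12 || e_bb < 1e-12) return(s_st)  # apolar: steric only
  e_ab <- gaussian_overlap(ta$X, ta$alpha, qa, tb$X, tb$alpha, qb)
  s_el <- max(0, min(1, e_ab / sqrt(e_aa * e_bb)))
  model@mix * s_st + (1 - model@mix) * s_el
}

#' Field-based 3D molecular similarity
#'
#' Cosine-normalized Gaussian field overlap of two posed molecules in their
#' current frames (no optimization). Symmetric, in [0, 1], invariant under a
#' common rigid motion of both molecules.
#'
#' @param a,b posed \linkS4class{Molecule}s (3D coordinates)
#' @param model a \linkS4class{FieldModel}
#' @return similarity in [0, 1]
#' @export
fieldSimilarity <- function(a, b, model = fieldModel()) {
  if (methods::is(a, "StandardLigand")) a <- a@mol
  if (methods::is(b, "StandardLigand")) b <- b@mol
  if (length(heavyIdx(a)) == 0 || length(heavyIdx(b)) == 0)
    stop("field similarity needs at least one heavy atom per molecule")
  field_similarity_terms(field_terms(a, model), field_terms(b, model), model)
}

#' Superpose a query ligand onto a template pose
#'
#' For every conformer, maximizes the field similarity over rigid rotations
#' and translations by quasi-Newton refinement from 12 deterministic starts
#' (principal-axes alignments) plus seeded random starts, then returns the
#' best distinct poses across conformers (pairwise heavy-atom RMSD >= 0.5 A
#' after alignment), sorted by similarity descending.
#'
#' @param query a \linkS4class{StandardLigand} with conformers
#' @param template_pose a posed \linkS4class{Molecule}
#' @param model a \linkS4class{FieldModel}
#' @param n_poses number of poses to return (default 3)
#' @param n_random random starts per conformer (default 8)
#' @param seed RNG seed for the random starts
#' @return list of poses; each has \code{coords} (all-atom matrix),
#'   \code{conformer}, \code{similarity3d}, \code{R}, \code{t} (transform
#'   applied to the centered conformer)
#' @export
alignToTemplate <- function(query, template_pose, model = fieldModel(),
                            n_poses = 3, n_random = 8, seed = 1) {
  if (methods::is(template_pose, "StandardLigand")) template_pose <- template_pose@mol
  if (length(query@conformers) == 0) stop("query has no conformers; run generateConformers()")
  stopifnot(n_poses >= 1)
  tt <- field_terms(template_pose, model)
  hv <- heavyIdx(query@mol)
  mol <- query@mol
  qalpha <- model@kappa / elem_radius(mol@atoms$elem[hv], VDW_RADII, 1.7)^2
  cand <- list()
  rstarts <- with_local_seed(seed, lapply(seq_len(n_random), function(i) random_rotation(stats::runif(3))))
  for (ci in seq_along(query@conformers)) {
    Xfull <- query@conformers[[ci]]
    ctr <- colMeans(Xfull[hv, , drop = FALSE])
    Xc <- sweep(Xfull, 2, ctr)            # centered conformer, all atoms
    tmpl_ctr <- colMeans(tt$X)
    # starting rotations: principal-frame matches (4 proper sign choices x
    # query/template frame pairing) + seeded random rotations
    pq <- principal_frames(Xc[hv, , drop = FALSE])
    pt <- principal_frames(sweep(tt$X, 2, tmpl_ctr))
    starts <- c(lapply(seq_along(pq), function(i) pq[[i]] %*% t(pt[[1]])),
                lapply(seq_along(pt), function(i) pq[[1]] %*% t(pt[[i]])),
                lapply(seq_len(min(4, length(pq))), function(i) pq[[i]] %*% t(pt[[2]])),
                rstarts)
    molc <- mol; atomCoords(molc) <- Xc
    qf0 <- field_terms(molc, model)
    objective <- function(par) {
      R <- rotvec_to_matrix(par[1:3])
      qf <- qf0
      qf$X <- qf0$X %*% R + matrix(tmpl_ctr + par[4:6], nrow(qf0$X), 3, byrow = TRUE)
      -field_similarity_terms(qf, tt, model)
    }
    for (R0 in starts) {
      # convert start rotation to a rotation vector
      ang <- acos(max(-1, min(1, (sum(diag(R0)) - 1) / 2)))
      if (ang < 1e-8) v0 <- c(0, 0, 0)
      else {
        ax <- c(R0[3, 2] - R0[2, 3], R0[1, 3] - R0[3, 1], R0[2, 1] - R0[1, 2])
        nx <- sqrt(sum(ax^2))
        v0 <- if (nx < 1e-8) ang * c(1, 0, 0) else ang * ax / nx
      }
      opt <- stats::optim(c(v0, 0, 0, 0), objective, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-9))
      R <- rotvec_to_matrix(opt$par[1:3])
      shift <- tmpl_ctr + opt$par[4:6]
      coords <- Xc %*% R + matrix(shift, nrow(Xc), 3, byrow = TRUE)
      cand[[length(cand) + 1]] <- list(coords = coords, conformer = ci,
                                       similarity3d = -opt$value, R = R, t = shift)
    }
  }
  cand <- cand[order(-vapply(cand, `[[`, 0, "similarity3d"))]
  picked <- list()
  for (p in cand) {
    distinct <- all(vapply(picked, function(q)
      coordRmsd(p$coords[hv, , drop = FALSE], q$coords[hv, , drop = FALSE]) >= 0.5, TRUE))
    if (distinct) picked[[length(picked) + 1]] <- p
    if (length(picked) >= n_poses) break
  }
  picked
}
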