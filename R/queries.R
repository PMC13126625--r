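# Interaction fingerprints and fragment-library queries: bioisostere search
# by interaction replication, and scaffold hopping by spatial occupancy plus
# attachment-vector compatibility.
#
# Interaction types and geometric criteria (config-exposed defaults):
#   HBond:       donor-acceptor heavy distance <= 3.5 A and D-H...A >= 130
#                degrees (angle at the donor heavy atom when no explicit H)
#   pi-stacking: ring centroid distance <= 5.5 A, planes parallel (<= 30
#                degrees) or T-shaped (60-90 degrees)
#   hydrophobic: apolar-apolar <= 4.5 A
#   ionic:       opposite formal charges <= 4.5 A
#   halogen:     X...acceptor <= 3.5 A

#' Default interaction-geometry configuration
#' @export
interactionConfig <- function() {
  list(hbond_dist = 3.5, hbond_angle = 130,
       pistack_dist = 5.5, pistack_parallel = 30, pistack_tshape = c(60, 90),
       hydrophobic_dist = 4.5, ionic_dist = 4.5, halogen_dist = 3.5)
}

# protein donor/acceptor/apolar/charge/ring tables (heavy atoms, no H)
prot_hbond_donors <- function(a) {
  (a$atomName == "N" & a$resname != "PRO") |
    (a$resname %in% c("SER", "THR", "TYR") & a$atomName %in% c("OG", "OG1", "OH")) |
    (a$resname == "ASN" & a$atomName == "ND2") | (a$resname == "GLN" & a$atomName == "NE2") |
    (a$resname == "HIS" & a$atomName %in% c("ND1", "NE2")) |
    (a$resname == "LYS" & a$atomName == "NZ") |
    (a$resname == "ARG" & a$atomName %in% c("NE", "NH1", "NH2")) |
    (a$resname == "TRP" & a$atomName == "NE1") |
    (a$resname == "CYS" & a$atomName == "SG")
}

prot_hbond_acceptors <- function(a) {
  a$atomName %in% c("O", "OXT") |
    (a$resname %in% c("ASP") & a$atomName %in% c("OD1", "OD2")) |
    (a$resname %in% c("GLU") & a$atomName %in% c("OE1", "OE2")) |
    (a$resname == "ASN" & a$atomName == "OD1") | (a$resname == "GLN" & a$atomName == "OE1") |
    (a$resname %in% c("SER", "THR", "TYR") & a$atomName %in% c("OG", "OG1", "OH")) |
    (a$resname == "HIS" & a$atomName %in% c("ND1", "NE2")) |
    (a$resname == "MET" & a$atomName == "SD")
}

prot_charged <- function(a) {
  q <- numeric(nrow(a))
  q[a$resname == "ASP" & a$atomName %in% c("OD1", "OD2")] <- -1
  q[a$resname == "GLU" & a$atomName %in% c("OE1", "OE2")] <- -1
  q[a$resname == "LYS" & a$atomName == "NZ"] <- 1
  q[a$resname == "ARG" & a$atomName %in% c("NH1", "NH2", "NE")] <- 1
  q
}

prot_rings <- function(pocket) {
  a <- pocket@atoms
  out <- list()
  for (rk in unique(paste(a$chain, a$resid))) {
    sel <- paste(a$chain, a$resid) == rk
    rn <- a$resname[sel][1]
    ring_atoms <- AROMATIC_PROT[[rn]]
    if (is.null(ring_atoms)) next
    rsel <- sel & a$atomName %in% ring_atoms
    if (sum(rsel) >= 5) {
      X <- as.matrix(a[rsel, c("x", "y", "z")])
      out[[length(out) + 1]] <- list(res = rk, resname = rn, X = X)
    }
  }
  out
}

# ligand aromatic rings as coordinate sets: smallest cycle through each
# aromatic bond (unique cycles up to 7 atoms)
ligand_rings <- function(mol) {
  b <- mol@bonds[mol@bonds$aromatic, , drop = FALSE]
  if (nrow(b) == 0) return(list())
  g <- igraph::graph_from_data_frame(b[, c("a1", "a2")], directed = FALSE,
                                     vertices = data.frame(name = sort(unique(c(b$a1, b$a2)))))
  X <- atomCoords(mol)
  seen <- character()
  out <- list()
  for (k in seq_len(nrow(b))) {
    v1 <- as.character(b$a1[k]); v2 <- as.character(b$a2[k])
    eid <- igraph::get_edge_ids(g, c(v1, v2))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = v1, to = v2)$vpath[[1]])
    if (length(sp) == 0 || length(sp) > 7) next
    cyc <- sort(as.integer(names(sp)))
    sig <- paste(cyc, collapse = ",")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1]] <- list(atoms = cyc, X = X[cyc, , drop = FALSE])
  }
  out
}

ring_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc)$v[, 3]
}

angle_deg <- function(u, v) {
  c0 <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, c0))) * 180 / pi
}

#' Interaction fingerprint of a posed ligand
#'
#' Residue-level typed contacts: HBond-donor / HBond-acceptor (named from
#' the ligand's perspective), pi-stacking, hydrophobic, ionic and halogen
#' bonds, detected by the geometric criteria in
#' \code{\link{interactionConfig}}.
#'
#' @param pose_mol posed \linkS4class{Molecule}
#' @param pocket a \linkS4class{PocketModel}
#' @param config geometry thresholds
#' @return data.frame with columns \code{residue} ("chain:resid") and
#'   \code{type}; unique rows, sorted
#' @export
interactionFingerprint <- function(pose_mol, pocket, config = interactionConfig()) {
  a <- pocket@atoms
  P <- pocketCoords(pocket)
  resk <- paste0(a$chain, ":", a$resid)
  X <- atomCoords(pose_mol)
  elem <- pose_mol@atoms$elem
  hv <- heavyIdx(pose_mol)
  hits <- list()
  add <- function(res, type) hits[[length(hits) + 1]] <<- c(res, type)
  if (nrow(P) > 0 && length(hv) > 0) {
    hc <- hydrogenCount(pose_mol)
    nbl <- neighborList(pose_mol)
    ldon <- hv[elem[hv] %in% c("N", "O") & hc[hv] > 0]
    lacc <- hv[elem[hv] %in% c("N", "O")]
    lhal <- hv[elem[hv] %in% c("Cl", "Br", "I", "F")]
    lapol <- hv[vapply(hv, function(i) elem[i] %in% c("C", "Cl", "Br", "I") &&
                         !any(elem[nbl[[i]]] %in% c("N", "O")), TRUE)]
    pdon <- which(prot_hbond_donors(a)); pacc <- which(prot_hbond_acceptors(a))
    pq <- prot_charged(a); papol <- which(a$elem == "C")
    dAll <- sqrt(outer(rowSums(X[hv, , drop = FALSE]^2), rowSums(P^2), "+") -
                 2 * X[hv, , drop = FALSE] %*% t(P))
    rownames(dAll) <- as.character(hv)
    dist_lp <- function(i, j) dAll[as.character(i), j]
    # H-bonds, ligand donor -> protein acceptor, with D-H...A angle when an
    # explicit H exists (else the heavy-atom distance criterion decides)
    for (i in ldon) for (j in pacc) {
      if (dist_lp(i, j) > config$hbond_dist) next
      hs <- nbl[[i]][elem[nbl[[i]]] == "H"]
      ok <- if (length(hs)) any(vapply(hs, function(h) {
        v1 <- X[i, ] - X[h, ]; v2 <- unlist(P[j, ] - X[h, ])
        ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        ang >= config$hbond_angle
      }, TRUE)) else TRUE
      if (ok) add(resk[j], "HBond-donor")
    }
    for (i in lacc) for (j in pdon)
      if (dist_lp(i, j) <= config$hbond_dist) add(resk[j], "HBond-acceptor")
    # hydrophobic
    for (i in lapol) {
      close_ap <- papol[dAll[as.character(i), papol] <= config$hydrophobic_dist]
      for (j in close_ap) add(resk[j], "hydrophobic")
    }
    # ionic
    lq <- pose_mol@atoms$fcharge
    for (i in hv[lq[hv] != 0]) {
      opp <- which(pq * lq[i] < 0)
      for (j in opp[dAll[as.character(i), opp] <= config$ionic_dist]) add(resk[j], "ionic")
    }
    # halogen bonds
    for (i in lhal) for (j in pacc)
      if (dist_lp(i, j) <= config$halogen_dist) add(resk[j], "halogen")
  }
  # pi-stacking between ligand and protein aromatic rings
  lr <- ligand_rings(pose_mol)
  for (ring in lr) {
    cl <- colMeans(ring$X); nl <- ring_normal(ring$X)
    for (pr in prot_rings(pocket)) {
      cp <- colMeans(pr$X)
      if (sqrt(sum((cl - cp)^2)) > config$pistack_dist) next
      ang <- angle_deg(nl, ring_normal(pr$X))
      if (ang <= config$pistack_parallel ||
          (ang >= config$pistack_tshape[1] && ang <= config$pistack_tshape[2]))
        add(sub(" ", ":", pr$res), "pi-stacking")
    }
  }
  if (length(hits) == 0)
    return(data.frame(residue = character(), type = character()))
  m <- unique(do.call(rbind, hits))
  df <- data.frame(residue = m[, 1], type = m[, 2], stringsAsFactors = FALSE)
  df[order(df$residue, df$type), ]
}

fp_set <- function(fp) paste(fp$residue, fp$type)

#' Bioisostere search by interaction replication
#'
#' Finds library fragments on one protein whose interaction fingerprint,
#' restricted to the reference residues, equals the reference set (strict
#' mode) or contains it (superset mode). Results are sorted by parent pose
#' confidence score, descending.
#'
#' @param repo fragment repository: list of entries, each with \code{key},
#'   \code{protein_id}, \code{fingerprint} (data.frame residue/type),
#'   \code{cs}
#' @param protein_id protein accession to query
#' @param reference reference fingerprint (data.frame residue/type)
#' @param mode "strict" or "superset"
#' @return the matching repo entries (list), best cs first
#' @export
bioisostereSearch <- function(repo, protein_id, reference, mode = c("strict", "superset")) {
  mode <- match.arg(mode)
  on_prot <- Filter(function(e) identical(e$protein_id, protein_id), repo)
  if (length(on_prot) == 0) {
    warning("protein ", protein_id, " not present in the repository")
    return(list())
  }
  ref <- sort(fp_set(reference))
  ref_res <- unique(reference$residue)
  hits <- Filter(function(e) {
    fp <- e$fingerprint
    full <- sort(fp_set(fp))
    restricted <- sort(fp_set(fp[fp$residue %in% ref_res, , drop = FALSE]))
    if (mode == "strict") identical(restricted, ref) else all(ref %in% full)
  }, on_prot)
  hits[order(-vapply(hits, function(e) e$cs %||% 0, 0))]
}

#' Attachment vectors of a core selection
#'
#' One unit vector per bond crossing the core boundary, anchored at the
#' core-side atom and pointing toward the removed substituent.
#'
#' @param pose_mol posed reference \linkS4class{Molecule}
#' @param core_atoms atom indices of the (connected) core substructure
#' @return list of vectors; each has \code{anchor} (position), \code{dir}
#'   (unit vector), \code{anchor_atom}
#' @export
extractAttachmentVectors <- function(pose_mol, core_atoms) {
  hv <- heavyIdx(pose_mol)
  core_atoms <- intersect(core_atoms, hv)
  g <- igraph::induced_subgraph(molGraph(pose_mol), core_atoms)
  if (igraph::components(g)$no != 1) stop("core selection must be connected")
  X <- atomCoords(pose_mol)
  b <- pose_mol@bonds
  out <- list()
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    if (pose_mol@atoms$elem[i] == "H" || pose_mol@atoms$elem[j] == "H") next
    ini <- i %in% core_atoms; inj <- j %in% core_atoms
    if (ini == inj) next
    anchor <- if (ini) i else j
    outer_a <- if (ini) j else i
    v <- X[outer_a, ] - X[anchor, ]
    v <- v / sqrt(sum(v^2))
    out[[length(out) + 1]] <- list(anchor = X[anchor, ], dir = v, anchor_atom = anchor)
  }
  out
}

#' Gaussian shape-overlap Tanimoto between two posed molecules
#'
#' O_AB / (O_AA + O_BB - O_AB) on the steric channel in the current frames.
#'
#' @param a,b posed \linkS4class{Molecule}s
#' @param model a \linkS4class{FieldModel}
#' @return overlap Tanimoto in [0, 1]
#' @export
shapeTanimoto <- function(a, b, model = fieldModel()) {
  ta <- field_terms(a, model); tb <- field_terms(b, model)
  one_a <- rep(1, nrow(ta$X)); one_b <- rep(1, nrow(tb$X))
  oab <- gaussian_overlap(ta$X, ta$alpha, one_a, tb$X, tb$alpha, one_b)
  oaa <- gaussian_overlap(ta$X, ta$alpha, one_a, ta$X, ta$alpha, one_a)
  obb <- gaussian_overlap(tb$X, tb$alpha, one_b, tb$X, tb$alpha, one_b)
  oab / (oaa + obb - oab)
}

#' Scaffold hopping by occupancy and attachment-vector compatibility
#'
#' Ranks library fragments on the same protein that (a) overlap the
#' reference core region (shape Tanimoto above \code{min_shape}) and (b)
#' offer an attachment point within \code{max_anchor_dist} and
#' \code{max_angle} of every reference attachment vector. Ranking: vectors
#' matched desc, shape overlap desc, cs desc.
#'
#' @param repo list of fragment entries with \code{mol} (posed),
#'   \code{key}, \code{protein_id}, \code{cs}
#' @param protein_id protein accession
#' @param reference_pose posed reference \linkS4class{Molecule}
#' @param core_atoms core selection (atom indices into the reference)
#' @param max_anchor_dist anchor distance tolerance in Angstrom (default 1)
#' @param max_angle direction tolerance in degrees (default 30)
#' @param min_shape minimum core shape-overlap Tanimoto (default 0.5)
#' @return data.frame of candidates: \code{key}, \code{n_matched},
#'   \code{n_vectors}, \code{shape}, \code{cs}, ranked
#' @export
scaffoldHop <- function(repo, protein_id, reference_pose, core_atoms,
                        max_anchor_dist = 1.0, max_angle = 30, min_shape = 0.5) {
  vecs <- extractAttachmentVectors(reference_pose, core_atoms)
  if (length(vecs) == 0) stop("core selection has no attachment vectors")
  core_mol <- subMolecule(reference_pose, core_atoms, capH = FALSE)
  rows <- list()
  for (e in repo) {
    if (!identical(e$protein_id, protein_id)) next
    shp <- shapeTanimoto(core_mol, e$mol)
    if (shp < min_shape) next
    # candidate attachment points: heavy atoms bearing >= 1 hydrogen (a
    # substituent could be fused there) -- plus real attachment H caps
    hv <- heavyIdx(e$mol)
    hc <- hydrogenCount(e$mol)
    anchors <- hv[hc[hv] > 0]
    if (length(anchors) == 0) next
    Xf <- atomCoords(e$mol)
    nbl <- neighborList(e$mol)
    n_matched <- 0L
    for (v in vecs) {
      ok <- FALSE
      for (aatom in anchors) {
        if (sqrt(sum((Xf[aatom, ] - v$anchor)^2)) > max_anchor_dist) next
        hs <- nbl[[aatom]][e$mol@atoms$elem[nbl[[aatom]]] == "H"]
        for (h in hs) {
          d <- Xf[h, ] - Xf[aatom, ]; d <- d / sqrt(sum(d^2))
          ang <- acos(max(-1, min(1, sum(d * v$dir)))) * 180 / pi
          if (ang <= max_angle) { ok <- TRUE; break }
        }
        if (ok) break
      }
      if (ok) n_matched <- n_matched + 1L
    }
    if (n_matched < length(vecs)) next
    rows[[length(rows) + 1]] <- data.frame(
      key = e$key, n_matched = n_matched, n_vectors = length(vecs),
      shape = shp, cs = e$cs %||% NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(key = character(), n_matched = integer(),
                      n_vectors = integer(), shape = numeric(), cs = numeric()))
  df <- do.call(rbind, rows)
  df[order(-df$n_matched, -df$shape, -df$cs, df$key), ]
}
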