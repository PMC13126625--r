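# Exhaustive BRICS fragmentation with inherited coordinates.
#
# Cleavable bonds follow the published BRICS environment rules (L1-L16 link
# environments and their compatibility list), written here as predicate
# functions over the heavy-atom graph; ring bonds are never cleaved.
# "Every possible substructure" is realized as every connected union of
# minimal BRICS fragments, i.e. every connected induced subgraph of the
# minimal-fragment adjacency graph.

# per-atom context used by the environment predicates
brics_context <- function(mol) {
  nbl <- neighborList(mol)
  hd <- heavyDegree(mol)
  elem <- mol@atoms$elem
  arom <- mol@atoms$aromatic
  ring <- mol@atoms$inRing
  b <- mol@bonds
  bm <- matrix(0L, natoms(mol), natoms(mol))
  bm[cbind(b$a1, b$a2)] <- ifelse(b$aromatic, 4L, b$order)
  bm[cbind(b$a2, b$a1)] <- bm[cbind(b$a1, b$a2)]
  ringb <- matrix(FALSE, natoms(mol), natoms(mol))
  ringb[cbind(b$a1, b$a2)] <- b$inRing; ringb[cbind(b$a2, b$a1)] <- b$inRing
  hnb <- lapply(seq_len(natoms(mol)), function(i) nbl[[i]][elem[nbl[[i]]] != "H"])
  list(elem = elem, arom = arom, ring = ring, hd = hd, hnb = hnb,
       bm = bm, ringb = ringb, fch = mol@atoms$fcharge)
}

# TRUE when atom i has a double bond to some atom of element e
has_double_to <- function(ctx, i, e = NULL) {
  ns <- ctx$hnb[[i]]
  any(vapply(ns, function(j) ctx$bm[i, j] == 2 && (is.null(e) || ctx$elem[j] == e), TRUE))
}

# the 16 published link environments (predicates on the link atom)
brics_envs <- function(ctx) {
  n <- length(ctx$elem)
  ali <- function(e) ctx$elem == e & !ctx$arom
  L <- matrix(FALSE, n, 16)
  for (i in seq_len(n)) {
    e <- ctx$elem[i]; ar <- ctx$arom[i]; rg <- ctx$ring[i]; hd <- ctx$hd[i]
    ns <- ctx$hnb[[i]]
    nse <- ctx$elem[ns]
    # L1: acyl carbon C(=O) with a C/N/O neighbor, heavy degree 3
    if (e == "C" && !ar && hd == 3 && has_double_to(ctx, i, "O") &&
        any(nse %in% c("C", "N", "O"))) L[i, 1] <- TRUE
    # L3: ether/ester oxygen (two heavy neighbors), some acyclic single bond to C
    if (e == "O" && hd == 2 &&
        any(vapply(ns, function(j) ctx$elem[j] == "C" && ctx$bm[i, j] == 1 &&
                   !ctx$ringb[i, j], TRUE))) L[i, 3] <- TRUE
    # L4: aliphatic C, >=2 heavy neighbors, no double bond, acyclic single bond to a carbon
    if (e == "C" && !ar && hd >= 2 && !has_double_to(ctx, i) &&
        any(vapply(ns, function(j) ctx$elem[j] == "C" && ctx$bm[i, j] == 1 &&
                   !ctx$ringb[i, j], TRUE))) L[i, 4] <- TRUE
    # L5: amine N, >=2 heavy neighbors, no N=, all heavy neighbors C or S, not a lactam N
    if (e == "N" && !ar && hd >= 2 && !has_double_to(ctx, i) &&
        all(nse %in% c("C", "S"))) {
      lactam <- rg && any(vapply(ns, function(j)
        ctx$ringb[i, j] && ctx$elem[j] == "C" && has_double_to(ctx, j, "O"), TRUE))
      if (!lactam) L[i, 5] <- TRUE
    }
    # L6: acyclic acyl carbon with an acyclic single bond to C/N/O
    if (e == "C" && !ar && !rg && hd == 3 && has_double_to(ctx, i, "O") &&
        any(vapply(ns, function(j) ctx$elem[j] %in% c("C", "N", "O") &&
                   ctx$bm[i, j] == 1 && !ctx$ringb[i, j], TRUE))) L[i, 6] <- TRUE
    # L7: alkene carbon (2-3 heavy neighbors, bonded to a carbon)
    if (e == "C" && !ar && hd >= 2 && hd <= 3 && any(nse == "C")) L[i, 7] <- TRUE
    # L8: acyclic aliphatic C, >=2 heavy neighbors, all bonds single
    if (e == "C" && !ar && !rg && hd >= 2 &&
        all(vapply(ns, function(j) ctx$bm[i, j] == 1, TRUE))) L[i, 8] <- TRUE
    # L9: neutral aromatic nitrogen
    if (e == "N" && ar && ctx$fch[i] == 0) L[i, 9] <- TRUE
    # L10: cyclic amide nitrogen (ring N bonded in-ring to an acyl C and another ring atom)
    if (e == "N" && !ar && rg && any(vapply(ns, function(j)
        ctx$ringb[i, j] && ctx$elem[j] == "C" && has_double_to(ctx, j, "O"), TRUE)) &&
        sum(vapply(ns, function(j) ctx$ringb[i, j], TRUE)) >= 2) L[i, 10] <- TRUE
    # L11: thioether sulfur with an acyclic single bond to C
    if (e == "S" && hd == 2 && any(vapply(ns, function(j)
        ctx$elem[j] == "C" && ctx$bm[i, j] == 1 && !ctx$ringb[i, j], TRUE))) L[i, 11] <- TRUE
    # L12: sulfonyl sulfur S(=O)(=O) with a C neighbor
    if (e == "S" && hd == 4 &&
        sum(vapply(ns, function(j) ctx$elem[j] == "O" && ctx$bm[i, j] == 2, TRUE)) >= 2 &&
        any(nse == "C")) L[i, 12] <- TRUE
    # L13: ring aliphatic C with a ring bond to C/N/O/S and a ring bond to N/O/S
    if (e == "C" && !ar && rg) {
      rns <- ns[vapply(ns, function(j) ctx$ringb[i, j], TRUE)]
      if (any(ctx$elem[rns] %in% c("C", "N", "O", "S")) &&
          any(ctx$elem[rns] %in% c("N", "O", "S"))) L[i, 13] <- TRUE
    }
    # L14: aromatic carbon with an aromatic n/o/s neighbor
    if (e == "C" && ar) {
      ans <- ns[vapply(ns, function(j) ctx$bm[i, j] == 4, TRUE)]
      if (length(ans) >= 2 && any(ctx$elem[ans] %in% c("N", "O", "S") & ctx$arom[ans]))
        L[i, 14] <- TRUE
      # L16: aromatic carbon flanked by two aromatic carbons
      if (sum(ctx$elem[ans] == "C" & ctx$arom[ans]) >= 2) L[i, 16] <- TRUE
    }
    # L15: ring aliphatic C with two aliphatic ring-C neighbors
    if (e == "C" && !ar && rg) {
      rns <- ns[vapply(ns, function(j) ctx$ringb[i, j], TRUE)]
      if (sum(ctx$elem[rns] == "C" & !ctx$arom[rns]) >= 2) L[i, 15] <- TRUE
    }
  }
  L
}

# compatibility list: (envA, envB, bond order); 7-7 cuts a double bond
BRICS_COMPAT <- rbind(
  c(1, 3, 1), c(1, 5, 1), c(1, 10, 1),
  c(3, 4, 1), c(3, 13, 1), c(3, 14, 1), c(3, 15, 1), c(3, 16, 1),
  c(4, 5, 1), c(4, 11, 1),
  c(5, 12, 1), c(5, 13, 1), c(5, 14, 1), c(5, 15, 1), c(5, 16, 1),
  c(6, 13, 1), c(6, 14, 1), c(6, 15, 1), c(6, 16, 1),
  c(7, 7, 2),
  c(8, 9, 1), c(8, 10, 1), c(8, 13, 1), c(8, 14, 1), c(8, 15, 1), c(8, 16, 1),
  c(9, 13, 1), c(9, 14, 1), c(9, 15, 1), c(9, 16, 1),
  c(10, 13, 1), c(10, 14, 1), c(10, 15, 1), c(10, 16, 1),
  c(11, 13, 1), c(11, 14, 1), c(11, 15, 1), c(11, 16, 1),
  c(13, 14, 1), c(13, 15, 1), c(13, 16, 1),
  c(14, 14, 1), c(14, 15, 1), c(14, 16, 1),
  c(15, 16, 1),
  c(16, 16, 1))

#' Enumerate BRICS-cleavable bonds
#'
#' Bonds whose two ends match a compatible pair of the published link
#' environments with the required bond order; ring bonds are never
#' returned.
#'
#' @param mol a standardized \linkS4class{Molecule}
#' @return integer vector of row indices into \code{mol@bonds}
#' @export
enumerateCleavableBonds <- function(mol) {
  ctx <- brics_context(mol)
  L <- brics_envs(ctx)
  b <- mol@bonds
  out <- integer()
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    if (ctx$elem[i] == "H" || ctx$elem[j] == "H") next
    if (b$inRing[k] || b$aromatic[k]) next
    ok <- FALSE
    for (r in seq_len(nrow(BRICS_COMPAT))) {
      ea <- BRICS_COMPAT[r, 1]; eb <- BRICS_COMPAT[r, 2]; bo <- BRICS_COMPAT[r, 3]
      if (b$order[k] != bo) next
      if ((L[i, ea] && L[j, eb]) || (L[i, eb] && L[j, ea])) { ok <- TRUE; break }
    }
    if (ok) out <- c(out, k)
  }
  out
}

# all connected induced subgraphs of a small graph (adjacency list),
# optionally size-capped; deterministic enumeration order
connected_subgraphs <- function(adj, max_size = Inf) {
  n <- length(adj)
  res <- list()
  # standard enumeration: grow from each root, only adding vertices > root
  # or reachable, with an exclusion set to avoid duplicates
  grow <- function(sub, ext, forbidden) {
    res[[length(res) + 1]] <<- sub
    if (length(sub) >= max_size) return()
    while (length(ext) > 0) {
      v <- ext[1]; ext <- ext[-1]
      newext <- setdiff(union(ext, setdiff(adj[[v]], c(sub, forbidden, ext, v))), v)
      grow(c(sub, v), newext, forbidden)
      forbidden <- c(forbidden, v)
    }
  }
  forbidden <- integer()
  for (v in seq_len(n)) {
    grow(v, setdiff(adj[[v]], c(forbidden, v)), forbidden)
    forbidden <- c(forbidden, v)
  }
  res
}

#' Exhaustive BRICS fragments of a posed molecule
#'
#' Cuts all cleavable bonds to obtain minimal fragments, then returns one
#' fragment per connected union of minimal fragments (including the whole
#' molecule). Heavy-atom coordinates are inherited unchanged from the
#' parent pose; attachment points are hydrogen-capped.
#'
#' @param parent posed \linkS4class{Molecule}
#' @param parent_key identity key of the parent ligand (computed when NULL)
#' @param pose_id identifier of the parent pose
#' @param max_minimal cap on minimal fragments before the size-limited
#'   fallback engages
#' @param max_union subgraph size cap used beyond \code{max_minimal}
#' @return list with \code{fragments} (list; each has \code{mol} (capped,
#'   coordinates inherited), \code{atoms} (parent heavy-atom indices),
#'   \code{cut_bonds}, \code{key}, \code{parent_key}, \code{pose_id}) and
#'   \code{truncated} flag
#' @export
exhaustiveFragments <- function(parent, parent_key = NULL, pose_id = "pose1",
                                max_minimal = 14, max_union = 8) {
  if (is.null(parent_key)) parent_key <- inchikey(parent)
  cleav <- enumerateCleavableBonds(parent)
  hv <- heavyIdx(parent)
  # minimal fragments: connected components after deleting all cleavable bonds
  b <- parent@bonds
  keep <- setdiff(seq_len(nrow(b)), cleav)
  g <- igraph::graph_from_data_frame(b[keep, c("a1", "a2"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(natoms(parent))))
  comp <- igraph::components(g)$membership
  # restrict to heavy-atom components (H follows its heavy neighbor's component)
  frag_ids <- sort(unique(comp[hv]))
  nfrag <- length(frag_ids)
  relab <- match(comp, frag_ids)
  # adjacency between minimal fragments via the cleaved bonds
  adj <- lapply(seq_len(nfrag), function(i) integer())
  for (k in cleav) {
    fi <- relab[b$a1[k]]; fj <- relab[b$a2[k]]
    if (is.na(fi) || is.na(fj) || fi == fj) next
    adj[[fi]] <- union(adj[[fi]], fj)
    adj[[fj]] <- union(adj[[fj]], fi)
  }
  adj <- lapply(adj, sort)
  truncated <- nfrag > max_minimal
  subs <- connected_subgraphs(adj, max_size = if (truncated) max_union else Inf)
  frags <- lapply(subs, function(sset) {
    atoms <- which(relab %in% sset)          # includes attached hydrogens
    cut <- intersect(cleav, which(xor(b$a1 %in% atoms, b$a2 %in% atoms)))
    fm <- subMolecule(parent, atoms, capH = TRUE)
    list(mol = fm, atoms = intersect(atoms, hv), cut_bonds = cut,
         key = inchikey(fm), parent_key = parent_key, pose_id = pose_id)
  })
  list(fragments = frags, truncated = truncated)
}

#' Physicochemical fragment properties
#'
#' Computed on the hydrogen-capped fragment: molecular weight, H-bond
#' donors (N/O bearing hydrogen), H-bond acceptors (N/O count), ring count
#' (cycle-space rank), rotatable bonds.
#'
#' @param frag a capped fragment \linkS4class{Molecule} (or an entry from
#'   \code{\link{exhaustiveFragments}})
#' @return data.frame with \code{MW}, \code{HBD}, \code{HBA}, \code{NR},
#'   \code{NRB}
#' @export
fragmentProperties <- function(frag) {
  if (is.list(frag) && !methods::is(frag, "Molecule")) frag <- frag$mol
  ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, Si = 28.086, P = 30.974, S = 32.06,
                   Cl = 35.453, Br = 79.904, I = 126.904)
  m <- ATOMIC_MASS[frag@atoms$elem]; m[is.na(m)] <- 0
  hv <- heavyIdx(frag)
  hc <- hydrogenCount(frag)[hv]
  elem <- frag@atoms$elem[hv]
  nr <- nrow(frag@bonds) - natoms(frag) +
    igraph::components(molGraph(frag))$no
  data.frame(MW = sum(m),
             HBD = sum(elem %in% c("N", "O") & hc > 0),
             HBA = sum(elem %in% c("N", "O")),
             NR = nr,
             NRB = countRotatableBonds(frag))
}

#' Fragment-likeness filter
#'
#' TRUE iff MW <= 300, HBD <= 3, HBA <= 6, 1 <= NR <= 4 and NRB <= 5.
#'
#' @param props data.frame from \code{\link{fragmentProperties}} (vectorized
#'   over rows)
#' @return logical vector
#' @export
passesFilters <- function(props) {
  props$MW <= 300 & props$HBD <= 3 & props$HBA <= 6 &
    props$NR >= 1 & props$NR <= 4 & props$NRB <= 5
}
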