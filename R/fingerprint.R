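# Radius-2 circular (Morgan-type) fingerprints folded to a fixed length.
#
# Atom environments are hashed iteratively from initial invariants (element,
# heavy degree, hydrogen count, formal charge, ring membership, aromaticity)
# through neighbor updates, ECFP-style. The dialect (hash, folding) is this
# package's own; values are stable across platforms and atom orderings.

ELEMENT_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                     S = 16, Cl = 17, Br = 35, I = 53)

# deterministic 31-bit integer hash of a numeric vector
hash_vec <- function(v) {
  h <- 7
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Circular fingerprint bit set of a molecule
#'
#' @param mol a \linkS4class{Molecule}
#' @param radius neighborhood radius (default 2)
#' @param nbits folded length (default 2048)
#' @return sorted integer vector of set bit positions (0-based)
#' @export
circularFingerprint <- function(mol, radius = 2, nbits = 2048) {
  hv <- heavyIdx(mol)
  if (length(hv) == 0) stop("empty molecule has no fingerprint")
  hd <- heavyDegree(mol)[hv]
  hc <- hydrogenCount(mol)[hv]
  a <- mol@atoms[hv, ]
  zn <- ELEMENT_NUMBERS[a$elem]; zn[is.na(zn)] <- 0
  inv <- vapply(seq_along(hv), function(i)
    hash_vec(c(zn[i], hd[i], hc[i], a$fcharge[i], as.integer(a$inRing[i]),
               as.integer(a$aromatic[i]))), 0)
  # heavy-atom adjacency with bond codes (aromatic distinct from single/double)
  b <- mol@bonds
  bh <- b[b$a1 %in% hv & b$a2 %in% hv, , drop = FALSE]
  pos <- integer(natoms(mol)); pos[hv] <- seq_along(hv)
  nb <- vector("list", length(hv))
  for (k in seq_len(nrow(bh))) {
    i <- pos[bh$a1[k]]; j <- pos[bh$a2[k]]
    code <- if (bh$aromatic[k]) 4 else bh$order[k]
    nb[[i]] <- rbind(nb[[i]], c(j, code))
    nb[[j]] <- rbind(nb[[j]], c(i, code))
  }
  feats <- inv
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- vapply(seq_along(hv), function(i) {
      ns <- nb[[i]]
      if (is.null(ns)) return(hash_vec(c(r, cur[i])))
      pairs <- cbind(ns[, 2], cur[ns[, 1]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_vec(c(r, cur[i], t(pairs)))
    }, 0)
    feats <- c(feats, nxt)
    cur <- nxt
  }
  sort(unique(as.integer(feats %% nbits)))
}

#' 2D Tanimoto similarity on radius-2 circular fingerprints
#'
#' Symmetric; 1.0 for identical connection tables.
#'
#' @param a,b \linkS4class{Molecule} or \linkS4class{StandardLigand} objects
#' @param radius,nbits fingerprint parameters
#' @return similarity in [0, 1]
#' @export
tanimoto2d <- function(a, b, radius = 2, nbits = 2048) {
  if (methods::is(a, "StandardLigand")) a <- a@mol
  if (methods::is(b, "StandardLigand")) b <- b@mol
  fa <- circularFingerprint(a, radius, nbits)
  fb <- circularFingerprint(b, radius, nbits)
  length(intersect(fa, fb)) / length(union(fa, fb))
}
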