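# Pose-accuracy evaluation: symmetry-aware RMSD, success classification,
# leave-one-out benchmarking, binding-site clustering, hotspot recovery.

#' Superpose two protein backbones
#'
#' Pairs C-alpha atoms by (chain, residue number) and computes the
#' least-squares rigid transform (Kabsch) of A onto B.
#'
#' @param pocketA,pocketB \linkS4class{PocketModel}s (or data.frames with
#'   \code{atomName}, \code{chain}, \code{resid}, \code{x,y,z})
#' @return list with \code{R}, \code{t}, \code{rmsd}; apply to row vectors
#'   as \code{X \%*\% R + t}
#' @export
backboneSuperpose <- function(pocketA, pocketB) {
  getca <- function(p) {
    a <- if (methods::is(p, "PocketModel")) p@atoms else p
    ca <- a[a$atomName == "CA", , drop = FALSE]
    ca[order(ca$chain, ca$resid), , drop = FALSE]
  }
  ca <- getca(pocketA); cb <- getca(pocketB)
  ka <- paste(ca$chain, ca$resid); kb <- paste(cb$chain, cb$resid)
  common <- intersect(ka, kb)
  if (length(common) < 3)
    stop("backbone superposition needs at least 3 matched C-alpha atoms")
  A <- as.matrix(ca[match(common, ka), c("x", "y", "z")])
  B <- as.matrix(cb[match(common, kb), c("x", "y", "z")])
  kabsch(A, B)
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' Minimum heavy-atom RMSD over graph automorphisms (element- and
#' bond-order-colored), with coordinates compared in the common frame (no
#' re-fitting). Falls back to the identity matching with a flag when the
#' automorphism count exceeds \code{max_maps}.
#'
#' @param molA,molB the same molecule (identical graph) with two coordinate
#'   sets; either \linkS4class{Molecule}s or a molecule plus a coordinate
#'   matrix via \code{coordsB}
#' @param coordsB optional all-atom coordinates for B when \code{molB} is
#'   missing
#' @param max_maps automorphism cap (default 10000)
#' @return list with \code{rmsd}, \code{n_maps}, \code{capped}
#' @export
symmetryRmsd <- function(molA, molB = NULL, coordsB = NULL, max_maps = 1e4) {
  XA <- atomCoords(molA)
  if (is.null(molB)) {
    stopifnot(!is.null(coordsB))
    XB <- coordsB
    molB <- molA
  } else XB <- atomCoords(molB)
  hvA <- heavyIdx(molA); hvB <- heavyIdx(molB)
  if (length(hvA) != length(hvB)) stop("molecules differ in heavy-atom count")
  # heavy-atom colored graphs
  build <- function(mol, hv) {
    pos <- integer(natoms(mol)); pos[hv] <- seq_along(hv)
    b <- mol@bonds
    b <- b[mol@atoms$elem[b$a1] != "H" & mol@atoms$elem[b$a2] != "H", , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(a1 = pos[b$a1], a2 = pos[b$a2]), directed = FALSE,
      vertices = data.frame(name = seq_along(hv)))
    ecode <- ifelse(b$aromatic, 4L, b$order)
    list(g = g, vcol = match(paste(mol@atoms$elem[hv], mol@atoms$aromatic[hv]),
                             unique(paste(mol@atoms$elem[hv], mol@atoms$aromatic[hv]))),
         ecol = ecode)
  }
  ga <- build(molA, hvA); gb <- build(molB, hvB)
  maps <- tryCatch(
    igraph::graph.get.isomorphisms.vf2(ga$g, gb$g,
                                       vertex.color1 = ga$vcol, vertex.color2 = gb$vcol,
                                       edge.color1 = ga$ecol, edge.color2 = gb$ecol),
    error = function(e) NULL)
  if (is.null(maps) || length(maps) == 0) stop("molecular graphs do not match")
  capped <- length(maps) > max_maps
  if (capped) maps <- maps[1]
  A <- XA[hvA, , drop = FALSE]
  B <- XB[hvB, , drop = FALSE]
  best <- Inf
  for (m in maps) {
    perm <- as.integer(m)
    r <- sqrt(mean(rowSums((A - B[perm, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  list(rmsd = best, n_maps = length(maps), capped = capped)
}

#' Cluster ligand poses into discrete binding sites
#'
#' Single-linkage clustering of pose centroids cut at \code{cutoff}.
#'
#' @param poses list of posed \linkS4class{Molecule}s (aligned to one
#'   reference frame)
#' @param cutoff linkage cutoff in Angstrom (default 8)
#' @return list with \code{n_sites} and \code{assignments}
#' @export
clusterBindingSites <- function(poses, cutoff = 8) {
  if (length(poses) == 0) return(list(n_sites = 0L, assignments = integer()))
  C <- t(vapply(poses, function(m) colMeans(atomCoords(m, heavy = TRUE)), numeric(3)))
  if (nrow(C) == 1) return(list(n_sites = 1L, assignments = 1L))
  hc <- stats::hclust(stats::dist(C), method = "single")
  assign <- stats::cutree(hc, h = cutoff)
  # deterministic labels: renumber by first appearance
  lab <- match(assign, unique(assign))
  list(n_sites = length(unique(lab)), assignments = lab)
}

#' Hotspot recovery of predicted fragments
#'
#' For each predicted fragment: the minimum centroid distance to any
#' reference fragment and the maximum 2D Tanimoto to any reference
#' fragment; plus the fraction of predicted fragments within
#' \code{cutoff}.
#'
#' @param predicted,reference lists of posed fragment
#'   \linkS4class{Molecule}s
#' @param cutoff distance cutoff in Angstrom (default 2)
#' @return list with \code{fraction_within}, and \code{per_fragment}
#'   data.frame (\code{min_dist}, \code{max_sim})
#' @export
hotspotRecovery <- function(predicted, reference, cutoff = 2.0) {
  if (length(reference) == 0) stop("reference fragment set is empty")
  refC <- t(vapply(reference, function(m) colMeans(atomCoords(m, heavy = TRUE)), numeric(3)))
  per <- do.call(rbind, lapply(predicted, function(m) {
    cc <- colMeans(atomCoords(m, heavy = TRUE))
    dmin <- min(sqrt(rowSums(sweep(refC, 2, cc)^2)))
    smax <- max(vapply(reference, function(r) tanimoto2d(m, r), 0))
    data.frame(min_dist = dmin, max_sim = smax)
  }))
  list(fraction_within = mean(per$min_dist <= cutoff), per_fragment = per)
}

#' Cumulative success curve
#'
#' Fraction of entries with RMSD at or below each threshold.
#'
#' @param rmsd numeric vector of pose RMSDs
#' @param thresholds evaluation points (default 0.25 to max, 40 points)
#' @return data.frame with \code{threshold} and \code{percent}
#' @export
cumulativeCurve <- function(rmsd, thresholds = NULL) {
  rmsd <- rmsd[is.finite(rmsd)]
  if (is.null(thresholds))
    thresholds <- seq(0.25, max(rmsd, 2), length.out = 40)
  data.frame(threshold = thresholds,
             percent = vapply(thresholds, function(t) 100 * mean(rmsd <= t), 0))
}

#' Leave-one-out benchmark over a set of complexes
#'
#' For each entry the query's own template entry is excluded, the pose
#' pipeline (template selection, field alignment, tethered refinement,
#' scoring) is run, the best-CS pose is kept, and the symmetry-aware
#' heavy-atom RMSD to the crystal pose is measured after backbone
#' superposition. Success means RMSD below 2.0 A.
#'
#' @param entries list; each entry has \code{query}
#'   (\linkS4class{StandardLigand} with the crystal pose in its molecule
#'   coordinates), \code{entry_id}, \code{pocket}
#'   (\linkS4class{PocketModel}), \code{pool} (\linkS4class{TemplatePool})
#' @param config a \code{\link{pipelineConfig}} list
#' @return list with \code{results} (per-entry data.frame), \code{success_rate},
#'   \code{success_rate_highcs} (restricted to CS above the confidence
#'   threshold), \code{curve}
#' @export
runLeaveOneOut <- function(entries, config = pipelineConfig()) {
  rows <- list()
  poses <- list()
  for (e in entries) {
    pool <- e$pool
    if (config$exclude_by == "key") {
      pool <- excludeSelf(pool, e$query@key)
    } else {
      keep <- vapply(pool@entries, function(t) !identical(t$structureId, e$entry_id), TRUE)
      pool@entries <- pool@entries[keep]
    }
    pred <- if (poolSize(pool) == 0) NULL else
      tryCatch(predictPose(e$query, pool, e$pocket, config),
               error = function(err) NULL)
    if (is.null(pred) || is.null(pred$best)) {
      rows[[length(rows) + 1]] <- data.frame(
        entry_id = e$entry_id, rmsd = NA_real_, cs = NA_real_,
        success = FALSE, no_prediction = TRUE)
      poses[[e$entry_id]] <- NULL
      next
    }
    sym <- symmetryRmsd(e$query@mol, coordsB = atomCoords(pred$best$mol))
    rows[[length(rows) + 1]] <- data.frame(
      entry_id = e$entry_id, rmsd = sym$rmsd, cs = pred$best$cs,
      success = sym$rmsd < config$success_rmsd, no_prediction = FALSE)
    poses[[e$entry_id]] <- list(mol = pred$best$mol, cs = pred$best$cs,
                                cs_max_candidates = max(pred$candidates$cs))
  }
  res <- do.call(rbind, rows)
  evaluated <- if (config$empty_pool == "exclude") res[!res$no_prediction, , drop = FALSE] else res
  high <- evaluated[!is.na(evaluated$cs) & evaluated$cs > config$cs_threshold, , drop = FALSE]
  list(results = res,
       success_rate = 100 * mean(evaluated$success),
       success_rate_highcs = if (nrow(high)) 100 * mean(high$success) else NA_real_,
       curve = cumulativeCurve(res$rmsd),
       poses = poses)
}
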