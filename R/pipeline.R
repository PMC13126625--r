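# End-to-end pose prediction for one query against one protein's template
# pool, and the pipeline configuration object.

#' Pipeline configuration
#'
#' All thresholds and knobs of the pose-prediction pipeline with their
#' defaults: template similarity > 0.3 (strict), top 3 templates, 5 query
#' conformers, 3 alignment poses per template, confidence threshold 0.6,
#' success RMSD 2.0 A, pAct activity threshold 5.0, published fusion
#' weights.
#'
#' @param template_k templates kept per query
#' @param template_threshold strict 2D-similarity lower bound
#' @param n_conformers query conformers
#' @param n_poses alignment poses per template
#' @param n_random_starts random alignment starts per conformer
#' @param cs_threshold confidence-score gate for the fragment library
#' @param cs_comparator ">=" (default) or ">" for the gate
#' @param success_rmsd pose-success RMSD in Angstrom
#' @param pact_threshold activity threshold (pAct)
#' @param weights fusion weights (alpha, beta, gamma, delta)
#' @param normalization metric normalization ranges
#' @param tether_k,tether_tol tether force constant and tolerance
#' @param mcs_min_atoms minimum MCS size for tethering
#' @param pocket_radius pocket extraction radius in Angstrom
#' @param contact_cutoff fragment-environment contact cutoff in Angstrom
#' @param exclude_by leave-one-out exclusion convention: "entry" or "key"
#' @param empty_pool "exclude" entries without templates (default) or
#'   "fail" them
#' @param seed RNG seed used by conformer generation and alignment starts
#' @return named list of settings
#' @export
pipelineConfig <- function(template_k = 3, template_threshold = 0.3,
                           n_conformers = 5, n_poses = 3, n_random_starts = 4,
                           cs_threshold = 0.6, cs_comparator = ">=",
                           success_rmsd = 2.0, pact_threshold = 5.0,
                           weights = defaultWeights(),
                           normalization = defaultNormalization(),
                           tether_k = 10, tether_tol = 0.5, mcs_min_atoms = 3,
                           pocket_radius = 8, contact_cutoff = 5.0,
                           exclude_by = "entry", empty_pool = "exclude",
                           seed = 1) {
  list(template_k = template_k, template_threshold = template_threshold,
       n_conformers = n_conformers, n_poses = n_poses,
       n_random_starts = n_random_starts, cs_threshold = cs_threshold,
       cs_comparator = cs_comparator, success_rmsd = success_rmsd,
       pact_threshold = pact_threshold, weights = weights,
       normalization = normalization, tether_k = tether_k,
       tether_tol = tether_tol, mcs_min_atoms = mcs_min_atoms,
       pocket_radius = pocket_radius, contact_cutoff = contact_cutoff,
       exclude_by = exclude_by, empty_pool = empty_pool, seed = seed)
}

#' Predict the binding pose of one query ligand
#'
#' Template selection by 2D similarity, Gaussian-field superposition onto
#' each selected template pose, MCS-tethered refinement in the rigid
#' pocket, four-metric scoring and confidence-score fusion. The pose with
#' the highest CS is the prediction.
#'
#' @param query a \linkS4class{StandardLigand} (conformers generated here
#'   when absent)
#' @param pool a \linkS4class{TemplatePool}
#' @param pocket a \linkS4class{PocketModel}
#' @param config a \code{\link{pipelineConfig}} list
#' @param estimator optional ECIF affinity estimator; a neutral constant
#'   (mid-range affinity) is used when NULL
#' @return list with \code{best} (mol, cs, template, scores row; NULL when
#'   no template qualifies) and \code{candidates} (scores data.frame for
#'   all refined poses)
#' @export
predictPose <- function(query, pool, pocket, config = pipelineConfig(),
                        estimator = NULL) {
  matches <- selectTemplates(query, pool, k = config$template_k,
                             threshold = config$template_threshold)
  if (nrow(matches) == 0) return(list(best = NULL, candidates = NULL))
  if (length(query@conformers) == 0)
    query <- generateConformers(query, config$n_conformers, seed = config$seed)
  if (is.null(estimator))
    estimator <- function(feats) 2 + 10 * min(1, sum(feats) / 400)  # occupancy heuristic
  cand <- list()
  for (mi in seq_len(nrow(matches))) {
    tpl <- pool@entries[[matches$index[mi]]]
    tpl_mol <- tpl$ligand@mol
    poses <- alignToTemplate(query, tpl_mol, n_poses = config$n_poses,
                             n_random = config$n_random_starts, seed = config$seed)
    mcs <- findMCS(query@mol, tpl_mol, min_atoms = config$mcs_min_atoms)
    for (p in poses) {
      pm <- query@mol; atomCoords(pm) <- p$coords
      tether <- tetherSpec(mcs, p$coords, k = config$tether_k, tol = config$tether_tol)
      ref <- tetheredMinimize(pm, pocket, tether)
      dock <- vinaTypeScore(ref$mol, pocket)
      aff <- intSim(ref$mol, pocket, estimator)
      sim3 <- fieldSimilarity(ref$mol, tpl_mol)
      cand[[length(cand) + 1]] <- list(
        mol = ref$mol, template = matches$structureId[mi],
        row = data.frame(template = matches$structureId[mi],
                         conformer = p$conformer,
                         sim2d = matches$similarity2d[mi], sim3d = sim3,
                         dock_raw = dock$score, affinity = aff,
                         clash = ref$clash, tether_ok = ref$tether_ok))
    }
  }
  if (length(cand) == 0) return(list(best = NULL, candidates = NULL))
  scores <- do.call(rbind, lapply(cand, `[[`, "row"))
  scores <- normalizeMetrics(scores, config$normalization)
  scores$cs <- confidenceScore(scores, config$weights)
  best_i <- which.max(scores$cs)
  best <- list(mol = cand[[best_i]]$mol, cs = scores$cs[best_i],
               template = cand[[best_i]]$template, scores = scores[best_i, ])
  list(best = best, candidates = scores)
}

#' Gate poses for fragment deconstruction by confidence score
#'
#' @param cs numeric confidence scores
#' @param config a \code{\link{pipelineConfig}} list
#' @return logical vector (CS >= 0.6 by default; the comparator is
#'   config-exposed)
#' @export
passesConfidence <- function(cs, config = pipelineConfig()) {
  if (config$cs_comparator == ">") cs > config$cs_threshold else cs >= config$cs_threshold
}
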