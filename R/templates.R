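# Template pools: crystallographic ligands available per protein, selected
# for a query by 2D fingerprint similarity.

#' TemplatePool: crystallographic template ligands of one protein
#'
#' @slot proteinId protein accession (UniProt-style string)
#' @slot entries list; each entry is a list with \code{ligand} (a
#'   \linkS4class{StandardLigand} whose molecule carries the crystal pose
#'   coordinates), \code{structureId} (source structure code) and
#'   \code{pocketRef} (optional pocket identifier)
#' @exportClass TemplatePool
setClass("TemplatePool",
  representation(proteinId = "character", entries = "list"),
  prototype(entries = list()))

setValidity("TemplatePool", function(object) {
  for (e in object@entries) {
    if (!all(c("ligand", "structureId") %in% names(e)))
      return("every entry needs 'ligand' and 'structureId'")
    if (!methods::is(e$ligand, "StandardLigand"))
      return("entry ligands must be StandardLigand objects")
    X <- atomCoords(e$ligand@mol, heavy = TRUE)
    if (all(abs(X) < 1e-9))
      return("template entries must carry 3D coordinates")
  }
  keys <- vapply(object@entries, function(e) paste(e$ligand@key, e$structureId), "")
  if (anyDuplicated(keys)) return("entries must be unique by (ligand key, structure id)")
  TRUE
})

setMethod("show", "TemplatePool", function(object) {
  cat("TemplatePool for", object@proteinId, "with",
      length(object@entries), "template(s)\n")
})

#' Build a template pool
#' @param proteinId protein accession
#' @param ligands list of posed \linkS4class{StandardLigand}s
#' @param structureIds character vector of source structure ids
#' @param pocketRefs optional pocket identifiers
#' @return a \linkS4class{TemplatePool}
#' @export
templatePool <- function(proteinId, ligands, structureIds, pocketRefs = NULL) {
  stopifnot(length(ligands) == length(structureIds))
  entries <- lapply(seq_along(ligands), function(i)
    list(ligand = ligands[[i]], structureId = structureIds[[i]],
         pocketRef = if (is.null(pocketRefs)) NA_character_ else pocketRefs[[i]]))
  methods::new("TemplatePool", proteinId = proteinId, entries = entries)
}

#' Number of templates in a pool
#' @param pool a \linkS4class{TemplatePool}
#' @export
poolSize <- function(pool) length(pool@entries)

#' Select templates for a query by 2D similarity
#'
#' Ranks the pool by radius-2 circular-fingerprint Tanimoto similarity to
#' the query and returns at most \code{k} entries whose similarity strictly
#' exceeds \code{threshold}. Ties are broken by source structure id
#' (lexicographic ascending) so results do not depend on pool order.
#'
#' @param query a \linkS4class{StandardLigand}
#' @param pool a \linkS4class{TemplatePool}
#' @param k maximum number of templates (default 3)
#' @param threshold strict lower similarity bound (default 0.3)
#' @return data.frame with columns \code{index} (position in the pool),
#'   \code{structureId}, \code{ligandKey}, \code{similarity2d}, sorted by
#'   similarity descending; zero rows when nothing qualifies
#' @export
selectTemplates <- function(query, pool, k = 3, threshold = 0.3) {
  stopifnot(k >= 1, threshold >= 0, threshold <= 1)
  if (poolSize(pool) == 0)
    return(data.frame(index = integer(), structureId = character(),
                      ligandKey = character(), similarity2d = numeric()))
  sims <- vapply(pool@entries, function(e) tanimoto2d(query, e$ligand), 0)
  sid <- vapply(pool@entries, function(e) as.character(e$structureId), "")
  keys <- vapply(pool@entries, function(e) e$ligand@key, "")
  ord <- order(-sims, sid)
  res <- data.frame(index = ord, structureId = sid[ord], ligandKey = keys[ord],
                    similarity2d = sims[ord], stringsAsFactors = FALSE)
  res <- res[res$similarity2d > threshold, , drop = FALSE]
  head(res, k)
}

#' Remove a ligand from a template pool by identity key
#'
#' Used in leave-one-out validation so a query cannot serve as its own
#' template.
#'
#' @param pool a \linkS4class{TemplatePool}
#' @param query_key InChIKey to exclude
#' @return the pool without any entry whose ligand key equals
#'   \code{query_key}
#' @export
excludeSelf <- function(pool, query_key) {
  keep <- vapply(pool@entries, function(e) !identical(e$ligand@key, query_key), TRUE)
  pool@entries <- pool@entries[keep]
  pool
}
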