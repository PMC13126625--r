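# Fragment repository assembly and comparative analytics: active-ligand
# curation (pAct scale), fragment-protein environment pairs, Murcko
# scaffolds, frequency comparison and protein-family enrichment.

#' Read an activity table from CSV
#'
#' Expected columns: \code{smiles}, \code{protein_id}, \code{activity_type},
#' and \code{value_nM} and/or \code{qualifier}. Extra columns pass through.
#'
#' @param file path to a CSV file
#' @return data.frame suitable for \code{\link{curateActives}}
#' @export
readActivityTable <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("smiles", "protein_id", "activity_type")
  if (!all(need %in% names(df)))
    stop("activity CSV must have columns: ", paste(need, collapse = ", "))
  if (!"value_nM" %in% names(df) && !"qualifier" %in% names(df))
    stop("activity CSV needs a value_nM or qualifier column")
  df
}

#' Curate active ligands from an activity table
#'
#' Converts quantitative potencies to pAct = -log10(molar value), keeps
#' records with pAct >= \code{threshold} (default 5.0, i.e. 10 uM or
#' better) plus records explicitly labeled "active", and deduplicates by
#' (ligand key, protein id) keeping the maximum pAct. Malformed records are
#' rejected row-wise and logged, never fatal.
#'
#' @param records data.frame with columns \code{smiles}, \code{protein_id},
#'   \code{activity_type} (IC50/EC50/Ki/Kd or "qualitative"),
#'   \code{value_nM} (NA allowed) and optionally \code{qualifier} (e.g.
#'   "active")
#' @param threshold pAct activity threshold (default 5)
#' @param keys optional precomputed ligand identity keys (skips
#'   standardization; useful for large synthetic tables)
#' @return list with \code{actives} (curated data.frame incl. \code{pAct},
#'   \code{key}) and \code{rejected} (log of dropped records)
#' @export
curateActives <- function(records, threshold = 5.0, keys = NULL) {
  stopifnot(all(c("smiles", "protein_id", "activity_type") %in% names(records)))
  if (!"value_nM" %in% names(records)) records$value_nM <- NA_real_
  if (!"qualifier" %in% names(records)) records$qualifier <- NA_character_
  rejected <- character()
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    val <- suppressWarnings(as.numeric(r$value_nM))
    qual <- tolower(as.character(r$qualifier))
    pact <- if (!is.na(val) && val > 0) -log10(val * 1e-9) else NA_real_
    keep <- if (!is.na(pact)) pact >= threshold else identical(qual, "active")
    if (is.na(r$value_nM) && !identical(qual, "active") && is.na(pact)) {
      rejected <- c(rejected, sprintf("row %d: no usable value or qualifier", i))
      next
    }
    if (!is.na(r$value_nM) && (is.na(val) || val <= 0)) {
      rejected <- c(rejected, sprintf("row %d: malformed value '%s'", i, r$value_nM))
      next
    }
    if (!keep) next
    key <- if (!is.null(keys)) keys[i] else
      tryCatch(standardizeLigand(as.character(r$smiles))@key, error = function(e) NA_character_)
    if (is.na(key)) {
      rejected <- c(rejected, sprintf("row %d: unparsable smiles '%s'", i, r$smiles))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      smiles = as.character(r$smiles), protein_id = as.character(r$protein_id),
      activity_type = as.character(r$activity_type), pAct = pact, key = key,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(list(actives = data.frame(smiles = character(), protein_id = character(),
                                     activity_type = character(), pAct = numeric(),
                                     key = character()),
                rejected = rejected))
  df <- do.call(rbind, rows)
  # dedupe by (key, protein), keep max pAct (qualitative NA sorts last)
  ord <- order(df$key, df$protein_id, -ifelse(is.na(df$pAct), -Inf, df$pAct))
  df <- df[ord, ]
  df <- df[!duplicated(df[, c("key", "protein_id")]), ]
  rownames(df) <- NULL
  list(actives = df, rejected = rejected)
}

#' Build unique fragment-protein environment pairs
#'
#' One pair per (fragment key, protein id); contact residues are the pocket
#' residues with any heavy atom within \code{contact_cutoff} of any
#' fragment heavy atom. Pairs with no contacts are discarded; fragments
#' with no protein atom within 20 A are discarded with a warning.
#'
#' @param fragments list of fragment entries (from
#'   \code{\link{exhaustiveFragments}}; each needs \code{mol}, \code{key},
#'   \code{parent_key}, \code{pose_id}, and optionally \code{cs})
#' @param pocket a \linkS4class{PocketModel}
#' @param protein_id protein accession for the pairs
#' @param contact_cutoff heavy-atom contact cutoff in Angstrom (default 5)
#' @return data.frame with one row per unique pair: \code{frag_key},
#'   \code{protein_id}, \code{contacts} (comma-joined "chain:resid"),
#'   \code{n_provenance}, \code{parents}, \code{best_cs}
#' @export
buildPairs <- function(fragments, pocket, protein_id, contact_cutoff = 5.0) {
  P <- pocketCoords(pocket)
  resk <- paste0(pocket@atoms$chain, ":", pocket@atoms$resid)
  acc <- new.env(parent = emptyenv())
  for (fr in fragments) {
    X <- atomCoords(fr$mol, heavy = TRUE)
    if (nrow(P) == 0) next
    d <- sqrt(outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P))
    if (min(d) > 20) {
      warning("fragment ", fr$key, " is >20 A from the pocket; discarded (frame mismatch?)")
      next
    }
    contacts <- sort(unique(resk[apply(d <= contact_cutoff, 2, any)]))
    if (length(contacts) == 0) next
    id <- paste(fr$key, protein_id, sep = "|")
    prev <- if (!is.null(acc[[id]])) acc[[id]] else
      list(contacts = character(), n = 0L, parents = character(), best_cs = -Inf)
    acc[[id]] <- list(contacts = sort(union(prev$contacts, contacts)),
                      n = prev$n + 1L,
                      parents = union(prev$parents, fr$parent_key),
                      best_cs = max(prev$best_cs, fr$cs %||% NA_real_, na.rm = TRUE))
  }
  ids <- ls(acc)
  if (length(ids) == 0)
    return(data.frame(frag_key = character(), protein_id = character(),
                      contacts = character(), n_provenance = integer(),
                      parents = character(), best_cs = numeric()))
  out <- do.call(rbind, lapply(ids, function(id) {
    e <- acc[[id]]
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    data.frame(frag_key = parts[1], protein_id = parts[2],
               contacts = paste(e$contacts, collapse = ","),
               n_provenance = e$n, parents = paste(e$parents, collapse = ","),
               best_cs = ifelse(is.finite(e$best_cs), e$best_cs, NA_real_),
               stringsAsFactors = FALSE)
  }))
  out[order(out$frag_key), ]
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus connecting linkers; terminal side chains are pruned
#' iteratively. Returns NULL for acyclic molecules.
#'
#' @param mol a \linkS4class{Molecule}
#' @return scaffold \linkS4class{Molecule} or NULL
#' @export
murckoScaffold <- function(mol) {
  if (methods::is(mol, "StandardLigand")) mol <- mol@mol
  hv <- heavyIdx(mol)
  if (!any(mol@atoms$inRing[hv])) return(NULL)
  keep <- hv
  repeat {
    sub <- subMolecule(mol, keep, capH = FALSE)
    hd <- heavyDegree(sub)
    hvs <- heavyIdx(sub)
    term <- hvs[hd[hvs] <= 1 & !sub@atoms$inRing[hvs]]
    if (length(term) == 0) break
    keep <- keep[-term]  # heavy atoms of sub are in 'keep' order
  }
  subMolecule(mol, keep, capH = TRUE)
}

#' Scaffold identity key
#' @param mol a \linkS4class{Molecule}
#' @return InChIKey of the Murcko scaffold, or NA for acyclic input
#' @export
scaffoldKey <- function(mol) {
  s <- murckoScaffold(mol)
  if (is.null(s)) NA_character_ else inchikey(s)
}

#' Compare fragment frequency between two multisets
#'
#' Full outer join on the key; reports per-key counts, exclusivity flags,
#' the shared-key count, and the fraction of keys more frequent in A.
#'
#' @param setA,setB character vectors of keys (multisets)
#' @return list with \code{table} (key, countA, countB, onlyA, onlyB,
#'   shared), \code{n_shared}, \code{frac_more_frequent_A} (among all
#'   distinct keys, the fraction with countA > countB)
#' @export
frequencyCompare <- function(setA, setB) {
  ta <- table(setA); tb <- table(setB)
  keys <- sort(union(names(ta), names(tb)))
  ca <- as.integer(ta[keys]); ca[is.na(ca)] <- 0L
  cb <- as.integer(tb[keys]); cb[is.na(cb)] <- 0L
  tab <- data.frame(key = keys, countA = ca, countB = cb,
                    onlyA = ca > 0 & cb == 0, onlyB = cb > 0 & ca == 0,
                    shared = ca > 0 & cb > 0, stringsAsFactors = FALSE)
  list(table = tab, n_shared = sum(tab$shared),
       frac_more_frequent_A = if (length(keys)) mean(ca > cb) else NA_real_)
}

#' Per-family scaffold frequency and exclusivity
#'
#' Maps each pair's protein to a family (unmapped proteins go to "other"),
#' counts scaffold occurrences per family, and flags scaffolds seen in
#' exactly one family as family-exclusive. Sorted by count descending with
#' a deterministic (family, scaffold) tie-break.
#'
#' @param pairs data.frame with \code{protein_id} and \code{scaffold_key}
#'   columns (NA scaffolds are dropped)
#' @param families named character vector: protein id -> family
#' @return data.frame with \code{family}, \code{scaffold_key}, \code{count},
#'   \code{exclusive}
#' @export
familyEnrichment <- function(pairs, families) {
  df <- pairs[!is.na(pairs$scaffold_key), , drop = FALSE]
  fam <- families[df$protein_id]
  fam[is.na(fam)] <- "other"
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = list(family = fam, scaffold_key = df$scaffold_key), FUN = sum)
  nfam <- tapply(agg$family, agg$scaffold_key, function(x) length(unique(x)))
  agg$exclusive <- nfam[agg$scaffold_key] == 1
  agg <- agg[order(-agg$count, agg$family, agg$scaffold_key), ]
  rownames(agg) <- NULL
  agg
}
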