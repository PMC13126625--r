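# Ligand standardization and conformer ensembles.
#
# Standardization strips salts/solvents to the largest organic component and
# assigns pH-7.0 protonation states through Open Babel's pH-transform rule
# table, so carboxylic acids come out anionic and aliphatic amines cationic.
# Conformers come from the seeded distance-geometry embedder with MMFF94s
# relaxation, pruned at 0.5 A heavy-atom RMSD.

#' StandardLigand: a standardized molecule with a conformer ensemble
#'
#' @slot mol the standardized \linkS4class{Molecule} (explicit hydrogens,
#'   pH-7 formal charges)
#' @slot key InChIKey identity key (atom-order and conformer invariant)
#' @slot conformers list of n x 3 coordinate matrices (all atoms, Angstrom)
#' @slot energies per-conformer MMFF94s strain energy (kcal/mol)
#' @exportClass StandardLigand
setClass("StandardLigand",
  representation(mol = "Molecule", key = "character",
                 conformers = "list", energies = "numeric"),
  prototype(conformers = list(), energies = numeric()))

setValidity("StandardLigand", function(object) {
  if (length(object@conformers) != length(object@energies))
    return("conformers and energies differ in length")
  n <- natoms(object@mol)
  ok <- vapply(object@conformers, function(X) is.matrix(X) && nrow(X) == n && ncol(X) == 3, TRUE)
  if (!all(ok)) return("conformer dimensions do not match the molecule")
  TRUE
})

setMethod("show", "StandardLigand", function(object) {
  cat("StandardLigand ", object@key, ": ",
      length(heavyIdx(object@mol)), " heavy atoms, ",
      length(object@conformers), " conformer(s)\n", sep = "")
})

#' Identity key of a standardized ligand
#' @param lig a \linkS4class{StandardLigand}
#' @export
ligandKey <- function(lig) lig@key

#' Standardize a ligand to physiological conditions
#'
#' Strips salts and solvents down to the largest organic component, assigns
#' formal charges by the pH-7.0 protonation rule set, adds explicit
#' hydrogens, and computes the InChIKey identity key.
#'
#' @param input a SMILES string, SDF text, or a \linkS4class{Molecule}
#' @param format "SMI" or "SDF" when \code{input} is text
#' @param name optional ligand title
#' @return a \linkS4class{StandardLigand} (conformers not yet populated)
#' @export
standardizeLigand <- function(input, format = c("SMI", "SDF"), name = "") {
  format <- match.arg(format)
  if (methods::is(input, "Molecule")) {
    input <- writeSDF(input)
    format <- "SDF"
    if (!nzchar(name)) name <- ""
  }
  smi <- tryCatch(obConvert(input, format, "CAN"),
                  error = function(e) stop("unparsable ligand input: ", conditionMessage(e)))
  smi <- strsplit(trimws(strsplit(smi, "\n")[[1]][1]), "\t")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("unparsable ligand input")
  # salt/solvent stripping: keep the largest organic (carbon-containing)
  # component, largest = most heavy atoms, ties by SMILES string
  parts <- strsplit(smi, ".", fixed = TRUE)[[1]]
  if (length(parts) > 1) {
    info <- lapply(parts, function(p) {
      m <- tryCatch(molFromSmiles(p), error = function(e) NULL)
      if (is.null(m)) return(c(-1, 0))
      c(sum(m@atoms$elem != "H"), as.integer(any(m@atoms$elem == "C")))
    })
    nh <- vapply(info, `[`, 0, 1); org <- vapply(info, `[`, 0, 2)
    cand <- if (any(org == 1)) which(org == 1) else seq_along(parts)
    pick <- cand[order(-nh[cand], parts[cand])][1]
    smi <- parts[pick]
  }
  mol <- tryCatch({
    sdf <- obConvert(paste0(smi, "\t", name), "SMI", "SDF", options = c(p = "7"))
    readMolecules(sdf, "SDF", addH = FALSE)[[1]]
  }, error = function(e) stop("protonation/standardization failed: ", conditionMessage(e)))
  if (sum(mol@atoms$elem != "H") == 0) stop("empty molecule after salt stripping")
  mol@name <- if (nzchar(name)) name else mol@name
  methods::new("StandardLigand", mol = mol, key = inchikey(mol))
}

# aligned heavy-atom RMSD between two conformers of one molecule
conformer_rmsd <- function(Xa, Xb, hv) {
  kabsch(Xa[hv, , drop = FALSE], Xb[hv, , drop = FALSE])$rmsd
}

#' Generate a pruned, minimized conformer ensemble
#'
#' Over-generates seeded distance-geometry embeddings, relaxes each with
#' MMFF94s, prunes so that every retained pair differs by heavy-atom RMSD of
#' at least \code{prune_rmsd}, and keeps at most \code{n_requested}
#' conformers selected for diversity (lowest-energy first, then greedy
#' max-min RMSD). Deterministic for a fixed seed.
#'
#' @param lig a \linkS4class{StandardLigand}
#' @param n_requested maximum ensemble size (default 5)
#' @param seed integer RNG seed
#' @param prune_rmsd heavy-atom RMSD pruning threshold in Angstrom
#' @param oversample embeddings generated per requested conformer
#' @param retries extra attempts (with offset seeds) if embedding fails
#' @return the ligand with \code{conformers} and \code{energies} populated
#' @export
generateConformers <- function(lig, n_requested = 5, seed = 1,
                               prune_rmsd = 0.5, oversample = 4, retries = 3) {
  stopifnot(n_requested >= 1)
  n_gen <- max(n_requested * oversample, 8)
  emb <- NULL
  for (att in 0:retries) {
    emb <- tryCatch(embedMolecule(lig@mol, n_samples = n_gen, seed = seed + att),
                    error = function(e) NULL)
    if (!is.null(emb)) break
  }
  if (is.null(emb))
    stop("conformer generation failed for ligand ", lig@key)
  hv <- heavyIdx(lig@mol)
  ord <- order(emb$energy)
  coords <- emb$coords[ord]; energy <- emb$energy[ord]
  # prune: energy-ascending greedy, drop anything within prune_rmsd of a keeper
  keep <- integer()
  for (i in seq_along(coords)) {
    if (all(vapply(keep, function(j) conformer_rmsd(coords[[i]], coords[[j]], hv), 0) >= prune_rmsd))
      keep <- c(keep, i)
  }
  coords <- coords[keep]; energy <- energy[keep]
  # diversity selection down to n_requested: lowest energy first, then the
  # conformer with the largest minimum RMSD to those already chosen
  if (length(coords) > n_requested) {
    sel <- 1L
    while (length(sel) < n_requested) {
      rest <- setdiff(seq_along(coords), sel)
      dmin <- vapply(rest, function(i)
        min(vapply(sel, function(j) conformer_rmsd(coords[[i]], coords[[j]], hv), 0)), 0)
      sel <- c(sel, rest[which.max(dmin)])
    }
    sel <- sort(sel)
    coords <- coords[sel]; energy <- energy[sel]
  }
  lig@conformers <- coords
  lig@energies <- energy
  methods::validObject(lig)
  lig
}

#' Write a conformer ensemble as multi-record SDF
#'
#' Each record carries the identity key and MMFF94s energy as SD tags.
#'
#' @param lig a \linkS4class{StandardLigand} with conformers
#' @param file optional path; when NULL the SDF text is returned
#' @export
writeConformersSDF <- function(lig, file = NULL) {
  if (length(lig@conformers) == 0) stop("ligand has no conformers")
  mols <- lapply(lig@conformers, function(X) { m <- lig@mol; atomCoords(m) <- X; m })
  tags <- lapply(seq_along(mols), function(i)
    c(inchikey = lig@key, mmff94s_energy = format(lig@energies[i])))
  txt <- writeSDF(mols, tags)
  if (is.null(file)) txt else writeLines(txt, file)
}
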