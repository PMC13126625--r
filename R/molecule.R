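# Small-molecule container and chemical text I/O.
#
# A Molecule holds an explicit-hydrogen connection table with 3D (or
# placeholder) coordinates, formal charges, Gasteiger partial charges and
# aromaticity/ring perception. Parsing and writing go through Open Babel;
# graph work goes through igraph.

#' Molecule: an explicit-hydrogen small molecule with coordinates
#'
#' @slot atoms data.frame with columns \code{elem}, \code{x}, \code{y},
#'   \code{z}, \code{fcharge} (formal charge), \code{pcharge} (Gasteiger
#'   partial charge), \code{aromatic}, \code{inRing}
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order},
#'   \code{aromatic}, \code{inRing}
#' @slot name molecule title
#' @exportClass Molecule
setClass("Molecule",
  representation(atoms = "data.frame", bonds = "data.frame", name = "character"),
  prototype(name = ""))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  need_a <- c("elem", "x", "y", "z", "fcharge", "pcharge", "aromatic", "inRing")
  need_b <- c("a1", "a2", "order", "aromatic", "inRing")
  if (!all(need_a %in% names(a))) return("atoms is missing required columns")
  if (!all(need_b %in% names(b))) return("bonds is missing required columns")
  if (nrow(b) > 0 && (max(b$a1, b$a2) > nrow(a) || min(b$a1, b$a2) < 1))
    return("bond indices out of range")
  TRUE
})

setMethod("show", "Molecule", function(object) {
  nh <- sum(object@atoms$elem != "H")
  cat("Molecule", if (nzchar(object@name)) sQuote(object@name) else "",
      ": ", nrow(object@atoms), " atoms (", nh, " heavy), ",
      nrow(object@bonds), " bonds\n", sep = "")
})

#' Number of atoms
#' @param mol a \linkS4class{Molecule}
#' @export
natoms <- function(mol) nrow(mol@atoms)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a \linkS4class{Molecule}
#' @export
heavyIdx <- function(mol) which(mol@atoms$elem != "H")

#' Atom coordinate matrix (n x 3)
#' @param mol a \linkS4class{Molecule}
#' @param heavy return only heavy-atom rows
#' @export
atomCoords <- function(mol, heavy = FALSE) {
  m <- as.matrix(mol@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  if (heavy) m[heavyIdx(mol), , drop = FALSE] else m
}

#' Replace atom coordinates
#' @param mol a \linkS4class{Molecule}
#' @param value n x 3 matrix
#' @export
`atomCoords<-` <- function(mol, value) {
  stopifnot(nrow(value) == natoms(mol), ncol(value) == 3)
  mol@atoms$x <- value[, 1]; mol@atoms$y <- value[, 2]; mol@atoms$z <- value[, 3]
  mol
}

#' Molecular graph as an igraph object (all atoms)
#' @param mol a \linkS4class{Molecule}
#' @keywords internal
molGraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol@bonds)) mol@bonds[, c("a1", "a2")] else data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(natoms(mol))))
}

# neighbor index list, one entry per atom
neighborList <- function(mol) {
  nb <- vector("list", natoms(mol))
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- c(nb[[b$a1[k]]], b$a2[k])
    nb[[b$a2[k]]] <- c(nb[[b$a2[k]]], b$a1[k])
  }
  nb
}

# counts of heavy neighbors and attached hydrogens, per atom
heavyDegree <- function(mol) {
  hvy <- mol@atoms$elem != "H"
  d <- integer(natoms(mol))
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    if (hvy[b$a2[k]]) d[b$a1[k]] <- d[b$a1[k]] + 1L
    if (hvy[b$a1[k]]) d[b$a2[k]] <- d[b$a2[k]] + 1L
  }
  d
}

hydrogenCount <- function(mol) {
  hh <- mol@atoms$elem == "H"
  d <- integer(natoms(mol))
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    if (hh[b$a2[k]]) d[b$a1[k]] <- d[b$a1[k]] + 1L
    if (hh[b$a1[k]]) d[b$a2[k]] <- d[b$a2[k]] + 1L
  }
  d
}

# ---- parsing ----------------------------------------------------------------

# parse a single V2000 molfile (vector of lines) into atoms/bonds (no
# aromaticity yet); returns list(atoms=, bonds=, name=)
parse_molfile <- function(lines) {
  name <- trimws(lines[1])
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop("unparsable molfile counts line")
  at <- lines[5:(4 + na)]
  atoms <- data.frame(
    elem = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    fcharge = 0L, pcharge = 0, aromatic = FALSE, inRing = FALSE,
    stringsAsFactors = FALSE)
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)),
      aromatic = FALSE, inRing = FALSE)
  } else data.frame(a1 = integer(), a2 = integer(), order = integer(),
                    aromatic = logical(), inRing = logical())
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    flds <- strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]]
    flds <- as.integer(flds)
    for (i in seq(1, length(flds), by = 2))
      atoms$fcharge[flds[i]] <- flds[i + 1]
  }
  list(atoms = atoms, bonds = bonds, name = name)
}

split_sdf_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) return(list(lines))
  starts <- c(1, head(ends, -1) + 1)
  mapply(function(s, e) lines[s:(e - 1)], starts, ends, SIMPLIFY = FALSE)
}

# annotate aromaticity and Gasteiger charges using a mol2 conversion of the
# same record (Open Babel preserves atom order)
annotate_mol2 <- function(mol, sdf_text) {
  m2 <- obConvert(sdf_text, "SDF", "MOL2", options = c(partialcharge = "gasteiger"))
  lines <- strsplit(m2, "\n", fixed = TRUE)[[1]]
  ai <- grep("^@<TRIPOS>ATOM", lines)[1]
  bi <- grep("^@<TRIPOS>BOND", lines)[1]
  na <- natoms(mol)
  at <- lines[(ai + 1):(ai + na)]
  flds <- strsplit(trimws(at), "\\s+")
  types <- vapply(flds, `[`, "", 6)
  pch <- suppressWarnings(as.numeric(vapply(flds, function(f) f[length(f)], "")))
  mol@atoms$aromatic <- grepl("\\.ar$", types)
  if (!any(is.na(pch))) mol@atoms$pcharge <- pch
  if (!is.na(bi) && nrow(mol@bonds) > 0) {
    bl <- lines[(bi + 1):(bi + nrow(mol@bonds))]
    bf <- strsplit(trimws(bl), "\\s+")
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    arom <- vapply(bf, function(f) identical(f[4], "ar"), TRUE)
    b1 <- as.integer(vapply(bf, `[`, "", 2)); b2 <- as.integer(vapply(bf, `[`, "", 3))
    m <- match(key(mol@bonds$a1, mol@bonds$a2), key(b1, b2))
    mol@bonds$aromatic <- !is.na(m) & arom[ifelse(is.na(m), 1L, m)]
    # heteroatoms in aromatic rings are not always typed .ar (e.g. furan O):
    # any atom on an aromatic bond counts as aromatic
    ab <- mol@bonds[mol@bonds$aromatic, , drop = FALSE]
    mol@atoms$aromatic[unique(c(ab$a1, ab$a2))] <- TRUE
  }
  mol
}

annotate_rings <- function(mol) {
  if (nrow(mol@bonds) == 0) return(mol)
  g <- molGraph(mol)
  br <- igraph::bridges(g)
  ring_edge <- rep(TRUE, nrow(mol@bonds))
  ring_edge[as.integer(br)] <- FALSE
  # terminal edges are bridges; mark ring bonds = non-bridge edges
  mol@bonds$inRing <- ring_edge
  inring <- rep(FALSE, natoms(mol))
  inring[unique(c(mol@bonds$a1[ring_edge], mol@bonds$a2[ring_edge]))] <- TRUE
  mol@atoms$inRing <- inring
  mol
}

#' Parse molecules from chemical text
#'
#' Reads one or more molecules from SMILES or SDF text, adds explicit
#' hydrogens, and perceives aromaticity (via a mol2 round trip), ring
#' membership and Gasteiger partial charges.
#'
#' @param text SMILES lines (optionally tab-separated titles) or SDF text
#' @param format "SMI" or "SDF"
#' @param addH add explicit hydrogens (default TRUE)
#' @return list of \linkS4class{Molecule}
#' @export
readMolecules <- function(text, format = c("SMI", "SDF"), addH = TRUE) {
  format <- match.arg(format)
  # SDF input goes through the CLI (or untouched) so 3D coordinates survive;
  # the in-process converter regenerates depiction coordinates
  sdf <- tryCatch({
    if (format == "SDF" && !addH) text
    else if (format == "SDF") obConvertCLI(text, "SDF", "SDF", "-h")
    else {
      opts <- if (addH) c(h = "") else NULL
      obConvert(text, format, "SDF", options = opts)
    }
  }, error = function(e) stop("unparsable molecule input: ", conditionMessage(e)))
  recs <- split_sdf_records(sdf)
  lapply(recs, function(lines) {
    p <- parse_molfile(lines)
    mol <- methods::new("Molecule", atoms = p$atoms, bonds = p$bonds, name = p$name)
    rec_text <- paste(c(lines, "$$$$"), collapse = "\n")
    mol <- annotate_mol2(mol, rec_text)
    annotate_rings(mol)
  })
}

#' Parse a single molecule from SMILES
#' @param smiles SMILES string
#' @param name optional title
#' @inheritParams readMolecules
#' @return a \linkS4class{Molecule}
#' @export
molFromSmiles <- function(smiles, name = "", addH = TRUE) {
  mols <- readMolecules(paste0(smiles, "\t", name), "SMI", addH = addH)
  mols[[1]]
}

# ---- writing ----------------------------------------------------------------

#' Write molecules as SDF text
#'
#' Produces V2000 molfile records with formal charges (M CHG) and optional
#' SD data tags.
#'
#' @param mols a Molecule or list of Molecules
#' @param tags optional list (one per molecule) of named character vectors
#'   written as SD tags
#' @return SDF text
#' @export
writeSDF <- function(mols, tags = NULL) {
  if (methods::is(mols, "Molecule")) mols <- list(mols)
  blocks <- vapply(seq_along(mols), function(i) {
    mol <- mols[[i]]
    a <- mol@atoms; b <- mol@bonds
    # line 2 carries the dimension code in columns 21-22; without "3D" some
    # Open Babel conversion paths regenerate depiction coordinates
    hdr <- c(mol@name, "  posefrag          3D", "")
    cnt <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
    at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  a$x, a$y, a$z, a$elem)
    bl <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order) else character()
    chg_idx <- which(a$fcharge != 0)
    chg <- if (length(chg_idx)) {
      sprintf("M  CHG%3d%s", length(chg_idx),
              paste0(sprintf("%4d%4d", chg_idx, a$fcharge[chg_idx]), collapse = ""))
    } else character()
    tg <- character()
    if (!is.null(tags) && length(tags) >= i && length(tags[[i]])) {
      tv <- tags[[i]]
      tg <- unlist(lapply(names(tv), function(nm) c(sprintf(">  <%s>", nm), tv[[nm]], "")))
    }
    paste(c(hdr, cnt, at, bl, chg, "M  END", tg, "$$$$"), collapse = "\n")
  }, "")
  paste(blocks, collapse = "\n")
}

#' InChIKey identity key of a molecule
#'
#' Invariant to atom order and to the conformer set; computed through Open
#' Babel's InChI implementation.
#'
#' @param mol a \linkS4class{Molecule}
#' @return character InChIKey
#' @export
inchikey <- function(mol) {
  if (natoms(mol) == 0) stop("empty molecule has no identity key")
  out <- obConvert(writeSDF(mol), "SDF", "INCHIKEY")
  trimws(strsplit(out, "\n")[[1]][1])
}

#' Canonical SMILES of a molecule
#' @param mol a \linkS4class{Molecule}
#' @return character SMILES
#' @export
toSmiles <- function(mol) {
  out <- obConvert(writeSDF(mol), "SDF", "CAN")
  strsplit(trimws(strsplit(out, "\n")[[1]][1]), "\t")[[1]][1]
}

#' Induced submolecule on an atom index set
#'
#' Extracts the induced subgraph with its coordinates; bonds cut at the
#' selection boundary can be capped with hydrogens placed along the former
#' bond direction.
#'
#' @param mol a \linkS4class{Molecule}
#' @param atom_idx atom indices to keep
#' @param capH cap cut bonds with hydrogens (default FALSE)
#' @return a \linkS4class{Molecule}
#' @export
subMolecule <- function(mol, atom_idx, capH = FALSE) {
  atom_idx <- sort(unique(atom_idx))
  map <- integer(natoms(mol)); map[atom_idx] <- seq_along(atom_idx)
  a <- mol@atoms[atom_idx, , drop = FALSE]
  keep <- mol@bonds$a1 %in% atom_idx & mol@bonds$a2 %in% atom_idx
  b <- mol@bonds[keep, , drop = FALSE]
  cut <- mol@bonds[xor(mol@bonds$a1 %in% atom_idx, mol@bonds$a2 %in% atom_idx), , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  rownames(a) <- rownames(b) <- NULL
  if (capH && nrow(cut)) {
    for (k in seq_len(nrow(cut))) {
      inner <- if (cut$a1[k] %in% atom_idx) cut$a1[k] else cut$a2[k]
      outer <- if (cut$a1[k] %in% atom_idx) cut$a2[k] else cut$a1[k]
      p1 <- unlist(mol@atoms[inner, c("x", "y", "z")])
      p2 <- unlist(mol@atoms[outer, c("x", "y", "z")])
      v <- p2 - p1; nv <- sqrt(sum(v^2))
      if (nv < 1e-9) v <- c(1, 0, 0) else v <- v / nv
      hp <- p1 + 1.09 * v
      a <- rbind(a, data.frame(elem = "H", x = hp[1], y = hp[2], z = hp[3],
                               fcharge = 0L, pcharge = 0, aromatic = FALSE,
                               inRing = FALSE))
      b <- rbind(b, data.frame(a1 = map[inner], a2 = nrow(a), order = 1L,
                               aromatic = FALSE, inRing = FALSE))
    }
  }
  m <- methods::new("Molecule", atoms = a, bonds = b, name = mol@name)
  annotate_rings(m)
}
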