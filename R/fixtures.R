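# Deterministic synthetic test systems: a rigid toy pocket with a bound
# aromatic template ligand, congeneric query ligands whose true poses are
# known by construction, and scored-pose tables with planted
# metric-success relationships.
#
# The receptor is a synthetic but format-valid PDB shell: a ring of glycine
# residues caging a central cavity, one phenylalanine whose ring stacks
# over the ligand plane, and one serine whose hydroxyl faces the ligand's
# para substituent. Queries are derived from the template by substituent
# swaps that keep the aromatic core coordinates fixed, so the true core
# RMSD is zero by construction.

hexagon <- function(r = 1.394, z = 0) {
  th <- seq(0, 300, by = 60) * pi / 180
  cbind(r * cos(th), r * sin(th), z)
}

# build a posed para-substituted benzene as a Molecule; subst is one of
# "H","CH3","Cl","F","Br","OH","NH2","CH2CH3","CH2OH"
build_phenyl_ligand <- function(subst, name) {
  ring <- hexagon()
  atoms <- data.frame(elem = rep("C", 6), x = ring[, 1], y = ring[, 2], z = ring[, 3],
                      fcharge = 0L, pcharge = 0, aromatic = TRUE, inRing = TRUE,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L),
                      aromatic = TRUE, inRing = TRUE)
  add_atom <- function(df, elem, pos) rbind(df, data.frame(
    elem = elem, x = pos[1], y = pos[2], z = pos[3], fcharge = 0L, pcharge = 0,
    aromatic = FALSE, inRing = FALSE))
  add_bond <- function(df, i, j, o = 1L) rbind(df, data.frame(
    a1 = i, a2 = j, order = o, aromatic = FALSE, inRing = FALSE))
  # ring hydrogens on atoms 2..6 (atom 1 carries the substituent)
  for (i in 2:6) {
    u <- ring[i, ] / sqrt(sum(ring[i, ]^2))
    atoms <- add_atom(atoms, "H", ring[i, ] + 1.08 * u)
    bonds <- add_bond(bonds, i, nrow(atoms))
  }
  dirx <- c(1, 0, 0)
  base <- ring[1, ]
  grow <- function(elem, dist, from = base, dir = dirx) from + dist * dir
  if (subst == "H") {
    atoms <- add_atom(atoms, "H", grow("H", 1.08)); bonds <- add_bond(bonds, 1, nrow(atoms))
  } else if (subst == "CH3") {
    atoms <- add_atom(atoms, "C", grow("C", 1.50)); c1 <- nrow(atoms)
    bonds <- add_bond(bonds, 1, c1)
    for (d in list(c(0.52, 0.95, 0.52), c(0.52, -0.95, 0.52), c(0.52, 0, -1.04)))
      { atoms <- add_atom(atoms, "H", atoms[c1, c("x", "y", "z")] + d); bonds <- add_bond(bonds, c1, nrow(atoms)) }
  } else if (subst %in% c("Cl", "F", "Br")) {
    dist <- c(Cl = 1.73, F = 1.35, Br = 1.88)[subst]
    atoms <- add_atom(atoms, subst, grow(subst, dist)); bonds <- add_bond(bonds, 1, nrow(atoms))
  } else if (subst == "OH") {
    atoms <- add_atom(atoms, "O", grow("O", 1.36)); o1 <- nrow(atoms)
    bonds <- add_bond(bonds, 1, o1)
    # hydroxyl H oriented along +x (toward the toy pocket's serine OG) so a
    # near-linear donor geometry exists in the truth pose
    atoms <- add_atom(atoms, "H", unlist(atoms[o1, c("x", "y", "z")]) + c(0.86, 0.40, 0))
    bonds <- add_bond(bonds, o1, nrow(atoms))
  } else if (subst == "NH2") {
    atoms <- add_atom(atoms, "N", grow("N", 1.40)); n1 <- nrow(atoms)
    bonds <- add_bond(bonds, 1, n1)
    for (d in list(c(0.47, 0.88, 0), c(0.47, -0.88, 0)))
      { atoms <- add_atom(atoms, "H", unlist(atoms[n1, c("x", "y", "z")]) + d); bonds <- add_bond(bonds, n1, nrow(atoms)) }
  } else if (subst == "CH2CH3") {
    atoms <- add_atom(atoms, "C", grow("C", 1.50)); c1 <- nrow(atoms)
    bonds <- add_bond(bonds, 1, c1)
    atoms <- add_atom(atoms, "C", unlist(atoms[c1, c("x", "y", "z")]) + c(0.72, 1.33, 0)); c2 <- nrow(atoms)
    bonds <- add_bond(bonds, c1, c2)
    for (d in list(c(0.5, -0.55, 0.75), c(0.5, -0.55, -0.75)))
      { atoms <- add_atom(atoms, "H", unlist(atoms[c1, c("x", "y", "z")]) + d); bonds <- add_bond(bonds, c1, nrow(atoms)) }
    for (d in list(c(1.0, 0.3, 0), c(-0.3, 1.0, 0.3), c(0.3, 0.6, -0.9)))
      { atoms <- add_atom(atoms, "H", unlist(atoms[c2, c("x", "y", "z")]) + d); bonds <- add_bond(bonds, c2, nrow(atoms)) }
  } else if (subst == "CH2OH") {
    atoms <- add_atom(atoms, "C", grow("C", 1.50)); c1 <- nrow(atoms)
    bonds <- add_bond(bonds, 1, c1)
    atoms <- add_atom(atoms, "O", unlist(atoms[c1, c("x", "y", "z")]) + c(0.65, 1.25, 0)); o1 <- nrow(atoms)
    bonds <- add_bond(bonds, c1, o1)
    for (d in list(c(0.5, -0.55, 0.75), c(0.5, -0.55, -0.75)))
      { atoms <- add_atom(atoms, "H", unlist(atoms[c1, c("x", "y", "z")]) + d); bonds <- add_bond(bonds, c1, nrow(atoms)) }
    atoms <- add_atom(atoms, "H", unlist(atoms[o1, c("x", "y", "z")]) + c(0.95, 0.2, 0))
    bonds <- add_bond(bonds, o1, nrow(atoms))
  } else stop("unknown substituent ", subst)
  rownames(atoms) <- rownames(bonds) <- NULL
  mol <- methods::new("Molecule", atoms = atoms, bonds = bonds, name = name)
  # refresh Gasteiger charges/aromatic perception through an SDF round trip
  m2 <- readMolecules(writeSDF(mol), "SDF", addH = FALSE)[[1]]
  m2@name <- name
  m2
}

TOY_SUBSTITUENTS <- c("Cl", "OH", "F", "CH2CH3", "NH2", "Br", "CH2OH", "H")

gly_template_atoms <- function() {
  # local backbone geometry (N, CA, C, O), CA at origin
  rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(1.52, 0, 0), O = c(2.15, 1.05, 0))
}

rot_z <- function(th) matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)

#' Build the deterministic toy complex
#'
#' A rigid synthetic pocket (glycine shell, a stacking phenylalanine, a
#' hydrogen-bonding serine) with a bound toluene template and congeneric
#' para-substituted query ligands whose true poses share the template's
#' aromatic core coordinates exactly. Regeneration with the same seed is
#' bit-identical; files (PDB receptor, SDF poses) are written under
#' \code{dir}.
#'
#' @param seed integer seed (jitters the glycine shell reproducibly)
#' @param n_queries number of query ligands (1 to 8)
#' @param dir output directory (default a fresh tempdir subdirectory)
#' @return list with \code{receptor_file}, \code{pocket}
#'   (\linkS4class{PocketModel}), \code{template}
#'   (posed \linkS4class{StandardLigand}), \code{queries} (list of posed
#'   StandardLigands = ground truth), \code{pool}
#'   (\linkS4class{TemplatePool} of template + query truth poses),
#'   \code{seed}
#' @export
makeToyComplex <- function(seed = 1, n_queries = 5, dir = NULL) {
  stopifnot(n_queries >= 1, n_queries <= length(TOY_SUBSTITUENTS))
  if (is.null(dir)) dir <- file.path(tempdir(), sprintf("toy_%d_%d", seed, n_queries))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jit <- with_local_seed(seed, matrix(stats::runif(12 * 3, -0.25, 0.25), 12, 3))
  # receptor: 10 glycines on a 9.5 A ring (z = -1.5 / +1.5 alternating),
  # one phenylalanine stacking at z ~ 3.8, one serine along +x
  rows <- list(); resno <- 0
  add_res <- function(resname, coords) {
    resno <<- resno + 1
    for (an in rownames(coords)) {
      rows[[length(rows) + 1]] <<- data.frame(
        elem = substr(an, 1, 1), atomName = an, resid = resno, resname = resname,
        chain = "A", x = coords[an, 1], y = coords[an, 2], z = coords[an, 3],
        stringsAsFactors = FALSE)
    }
  }
  tmpl <- gly_template_atoms()
  for (k in 1:10) {
    th <- 2 * pi * (k - 1) / 10
    ctr <- c(9.5 * cos(th), 9.5 * sin(th), ifelse(k %% 2 == 0, 1.5, -1.5)) + jit[k, ]
    Xr <- tmpl %*% t(rot_z(th + pi / 2))
    Xr <- sweep(Xr, 2, ctr, "+"); rownames(Xr) <- rownames(tmpl)
    add_res("GLY", Xr)
  }
  # phenylalanine: ring parallel to the ligand plane, centroid (0,0,3.8)
  ring <- hexagon(z = 3.8)
  phe <- rbind(N = c(5.6, 1.2, 5.8), CA = c(4.9, 0, 5.9), C = c(5.8, -1.2, 6.3),
               O = c(6.9, -1.0, 6.8), CB = c(3.6, 0.2, 5.3),
               CG = ring[1, ] + c(0, 0, 0), CD1 = ring[2, ], CD2 = ring[6, ],
               CE1 = ring[3, ], CE2 = ring[5, ], CZ = ring[4, ])
  phe["CG", ] <- ring[1, ]
  add_res("PHE", phe)
  # serine: OG 2.9 A beyond the para-oxygen truth position along +x
  ser <- rbind(N = c(8.9, 1.2, 0.4), CA = c(8.2, 0, 0.2), C = c(8.9, -1.25, 0.6),
               O = c(9.9, -1.3, 1.3), CB = c(6.9, 0, 0.9), OG = c(5.65, 0, 0))
  add_res("SER", ser)
  atoms <- do.call(rbind, rows)
  pocket <- methods::new("PocketModel", atoms = atoms, center = c(0, 0, 0),
                         radius = 12, excluded = character())
  receptor_file <- file.path(dir, "receptor.pdb")
  writePocketPDB(pocket, receptor_file)
  # ligands
  template_mol <- build_phenyl_ligand("CH3", "template_toluene")
  template <- methods::new("StandardLigand", mol = template_mol, key = inchikey(template_mol))
  queries <- lapply(seq_len(n_queries), function(i) {
    m <- build_phenyl_ligand(TOY_SUBSTITUENTS[i], sprintf("query_%02d", i))
    methods::new("StandardLigand", mol = m, key = inchikey(m))
  })
  writeLines(writeSDF(template_mol), file.path(dir, "template.sdf"))
  writeLines(writeSDF(lapply(queries, function(q) q@mol)), file.path(dir, "queries.sdf"))
  pool <- templatePool("TOYPROT",
                       c(list(template), queries),
                       c("TPL001", sprintf("QRY%03d", seq_len(n_queries))))
  list(receptor_file = receptor_file, pocket = pocket, template = template,
       queries = queries, pool = pool, seed = seed, dir = dir)
}

#' Write a pocket model as a PDB file
#' @param pocket a \linkS4class{PocketModel}
#' @param file output path
#' @export
writePocketPDB <- function(pocket, file) {
  a <- pocket@atoms
  lines <- sprintf("ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   seq_len(nrow(a)), a$atomName, a$resname, a$chain, a$resid,
                   a$x, a$y, a$z, a$elem)
  writeLines(c(lines, "END"), file)
}

#' Leave-one-out benchmark entries for a toy complex
#'
#' One entry per query ligand; the pool holds the template plus every query
#' truth pose. With \code{with_copies = TRUE} each query's truth pose is
#' additionally present under a distinct structure id, so entry-based
#' exclusion leaves an exact-copy template available (self-recovery
#' scenario).
#'
#' @param toy result of \code{\link{makeToyComplex}}
#' @param with_copies add exact-copy templates under separate structure ids
#' @return list of entries for \code{\link{runLeaveOneOut}}
#' @export
toyBenchmarkEntries <- function(toy, with_copies = FALSE) {
  pool <- toy$pool
  if (with_copies) {
    n <- poolSize(pool)
    copies <- lapply(seq_along(toy$queries), function(i)
      list(ligand = toy$queries[[i]], structureId = sprintf("CPY%03d", i),
           pocketRef = NA_character_))
    pool@entries <- c(pool@entries, copies)
  }
  lapply(seq_along(toy$queries), function(i)
    list(query = toy$queries[[i]], entry_id = sprintf("QRY%03d", i),
         pocket = toy$pocket, pool = pool))
}

#' Pipeline configuration matched to the toy complex
#'
#' The toy pocket is a small open shell, so docking energies and
#' interaction-feature affinities span a narrower range than in real
#' pockets; the normalization ranges are set accordingly (dock [0, -4],
#' affinity pAct [2, 6]), with fewer conformers and random starts because
#' the ligands are rigid.
#'
#' @param ... overrides passed to \code{\link{pipelineConfig}}
#' @export
toyPipelineConfig <- function(...) {
  defaults <- list(n_conformers = 3, n_random_starts = 2,
                   normalization = list(dock = c(worst = 0, best = -4),
                                        affinity = c(worst = 2, best = 6)))
  args <- utils::modifyList(defaults, list(...))
  do.call(pipelineConfig, args)
}

#' Synthetic scored-pose table with planted weights
#'
#' Draws the four normalized metrics uniformly in [0,1], computes the
#' planted confidence score, and labels success as (cs + noise) above the
#' median cs. Deterministic for a fixed seed; labels are balanced by
#' construction.
#'
#' @param weights planted weights (alpha, beta, gamma, delta)
#' @param n rows (>= 50)
#' @param noise_sd label noise standard deviation (0 = separable)
#' @param seed integer seed
#' @return data.frame with the metric columns, \code{cs_true},
#'   \code{success}
#' @export
makeScoredDataset <- function(weights = defaultWeights(), n = 200,
                              noise_sd = 0, seed = 1) {
  stopifnot(n >= 50)
  with_local_seed(seed, {
    df <- data.frame(sim2d = stats::runif(n), sim3d = stats::runif(n),
                     dock_norm = stats::runif(n), int_sim_norm = stats::runif(n))
    df$cs_true <- as.numeric(as.matrix(df) %*% weights)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    df$success <- as.vector(df$cs_true + noise > stats::median(df$cs_true))
    df
  })
}
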