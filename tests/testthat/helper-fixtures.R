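# Shared fixtures, memoized so expensive objects are built once per run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

toy_complex <- function() memo("toy", function() makeToyComplex(seed = 7, n_queries = 3))

toy_loo <- function() memo("loo", function() {
  toy <- toy_complex()
  runLeaveOneOut(toyBenchmarkEntries(toy, with_copies = TRUE), toyPipelineConfig())
})

empty_pocket <- function() methods::new("PocketModel",
  atoms = data.frame(elem = character(), atomName = character(), resid = integer(),
                     resname = character(), chain = character(),
                     x = numeric(), y = numeric(), z = numeric()),
  center = c(0, 0, 0), radius = Inf, excluded = character())

# a posed molecule from SMILES: first generated conformer as coordinates
posed_mol <- function(smiles, seed = 1) {
  lig <- standardizeLigand(smiles)
  lig <- generateConformers(lig, 1, seed = seed)
  m <- lig@mol; atomCoords(m) <- lig@conformers[[1]]
  m
}

# drug-like test SMILES for fragmentation oracles
FRAG_TEST_SMILES <- c(
  "CCOC(=O)c1ccccc1", "CC(=O)Nc1ccccc1", "c1ccccc1Cc1ccccc1",
  "CCN(CC)C(=O)c1ccc(OC)cc1", "c1ccc(cc1)CCNC(=O)C",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CCS(=O)(=O)N1CCCC1",
  "c1ccc2c(c1)cccn2", "COc1ccc(CN2CCN(C)CC2)cc1", "CC(=O)OCC(=O)Nc1ccccn1",
  "O=C(Oc1ccccc1C(=O)O)C", "c1cnc2[nH]ccc2c1", "CN1CCC(CC1)Oc1ccccc1",
  "CC(C)NCC(O)COc1ccccc1", "O=C(NCc1ccco1)c1cccnc1", "CCOc1ccc(NC(C)=O)cc1",
  "Clc1ccc(CN2CCOCC2)cc1", "CC(=O)N1CCN(c2ccccc2)CC1",
  "O=S(=O)(N)c1ccc(Cl)cc1", "CCCCn1ccc(=O)[nH]c1=O",
  "CSc1ccccc1C(=O)NC", "COC(=O)C1CCCN1C(C)=O", "Cc1ccccc1OCC(=O)O",
  "CCOC(=O)N1CCC(NC(C)=O)CC1")

# independent connected-induced-subgraph counter: brute force over all
# vertex subsets, connectivity checked with igraph
count_connected_subgraphs <- function(adj) {
  n <- length(adj)
  if (n == 0) return(0L)
  el <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- adj[[i]][adj[[i]] > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  cnt <- 0L
  for (mask in seq_len(2^n - 1)) {
    vs <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(vs) == 1) { cnt <- cnt + 1L; next }
    sub <- el[el[, 1] %in% vs & el[, 2] %in% vs, , drop = FALSE]
    g <- igraph::graph_from_data_frame(as.data.frame(sub), directed = FALSE,
                                       vertices = data.frame(name = vs))
    if (igraph::components(g)$no == 1) cnt <- cnt + 1L
  }
  cnt
}

# rdkit BRICS oracle (python, pre-installed): returns per-smiles list with
# n_bonds and sorted minimal-fragment InChIKeys
rdkit_brics_reference <- function(smiles) {
  script <- '
import sys, json
from rdkit import Chem
from rdkit.Chem import BRICS
from rdkit.Chem.inchi import MolToInchiKey
smis = json.load(open(sys.argv[1]))
out = []
for smi in smis:
    m = Chem.MolFromSmiles(smi)
    bonds = list(BRICS.FindBRICSBonds(m))
    if bonds:
        pieces = Chem.GetMolFrags(BRICS.BreakBRICSBonds(m), asMols=True)
    else:
        pieces = [m]
    keys = []
    for p in pieces:
        pe = Chem.RWMol(p)
        for a in pe.GetAtoms():
            if a.GetAtomicNum() == 0:
                a.SetAtomicNum(1); a.SetIsotope(0)
        keys.append(MolToInchiKey(Chem.RemoveHs(pe.GetMol())))
    out.append({"smiles": smi, "n_bonds": len(bonds), "frag_keys": sorted(keys)})
json.dump(out, open(sys.argv[2], "w"))
'
  pyf <- tempfile(fileext = ".py"); writeLines(script, pyf)
  inf <- tempfile(fileext = ".json"); outf <- tempfile(fileext = ".json")
  jsonlite::write_json(smiles, inf)
  status <- system2("python", c(pyf, inf, outf), stdout = FALSE, stderr = FALSE)
  on.exit(unlink(c(pyf, inf, outf)))
  if (status != 0) return(NULL)
  jsonlite::fromJSON(outf, simplifyVector = FALSE)
}

# minimal-fragment InChIKeys from this package's cleavable-bond set
pkg_minimal_fragment_keys <- function(mol) {
  cl <- enumerateCleavableBonds(mol)
  b <- mol@bonds
  keep <- setdiff(seq_len(nrow(b)), cl)
  g <- igraph::graph_from_data_frame(b[keep, c("a1", "a2"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(natoms(mol))))
  comp <- igraph::components(g)$membership
  hv <- heavyIdx(mol)
  sort(vapply(unique(comp[hv]), function(ci)
    inchikey(subMolecule(mol, which(comp == ci), capH = TRUE)), ""))
}

rot_z_mat <- function(th) matrix(c(cos(th), -sin(th), 0,
                                   sin(th),  cos(th), 0,
                                   0, 0, 1), 3, 3, byrow = TRUE)
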