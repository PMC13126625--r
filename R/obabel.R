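# Bridge to Open Babel: in-process format conversion through ChemmineOB and
# the obabel/obenergy command-line tools for force-field work.

ob_options <- function(...) {
  v <- c(...)
  if (length(v) == 0) return(NULL)
  data.frame(names = names(v), args = unname(v), stringsAsFactors = FALSE)
}

#' Convert chemical text between formats via Open Babel
#'
#' Thin wrapper around \code{ChemmineOB::convertFormat}. Formats are Open
#' Babel format codes ("SMI", "SDF", "MOL2", "INCHIKEY", "PDB", ...).
#'
#' @param text input text in the source format
#' @param from,to Open Babel format codes
#' @param options named character vector of Open Babel options,
#'   e.g. \code{c(p = "7")} for pH-7 protonation or \code{c(h = "")} to add
#'   explicit hydrogens
#' @return character scalar in the target format
#' @keywords internal
obConvert <- function(text, from, to, options = NULL) {
  out <- if (is.null(options)) {
    ChemmineOB::convertFormat(from, to, text)
  } else {
    ChemmineOB::convertFormat(from, to, text, options = ob_options(options))
  }
  if (!nzchar(out)) stop("Open Babel conversion ", from, " -> ", to, " produced no output")
  out
}

ob_cli <- function(args, stdin_text = NULL) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) stop("obabel executable not found on PATH")
  infile <- NULL
  if (!is.null(stdin_text)) {
    infile <- tempfile(fileext = ".txt")
    writeLines(stdin_text, infile)
    on.exit(unlink(infile), add = TRUE)
    args <- c(infile, args)
  }
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = FALSE))
  out
}

#' Convert chemical text through the obabel command line
#'
#' Used where 3D coordinates must be preserved exactly; the in-process
#' conversion path regenerates depiction coordinates for some output
#' formats.
#'
#' @inheritParams obConvert
#' @param extra_args additional obabel arguments (e.g. "-h")
#' @return character scalar in the target format
#' @keywords internal
obConvertCLI <- function(text, from, to, extra_args = character()) {
  fin <- tempfile(fileext = paste0(".", tolower(from)))
  fout <- tempfile(fileext = paste0(".", tolower(to)))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(text, fin)
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) stop("obabel executable not found on PATH")
  suppressWarnings(system2(exe, c(paste0("-i", tolower(from)), fin,
                                  paste0("-o", tolower(to)), "-O", fout, extra_args),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout) || file.size(fout) == 0)
    stop("Open Babel CLI conversion ", from, " -> ", to, " produced no output")
  paste(readLines(fout), collapse = "\n")
}

#' Minimize structures with an Open Babel force field
#'
#' Runs \code{obabel --minimize} on a (possibly multi-record) SDF text and
#' returns the minimized SDF text. Deterministic for identical input.
#'
#' @param sdf_text SDF text, one or more records
#' @param ff force-field name ("MMFF94s" default)
#' @param steps maximum minimization steps
#' @param crit convergence criterion on the energy change
#' @return minimized SDF text
#' @keywords internal
obMinimize <- function(sdf_text, ff = "MMFF94s", steps = 2500, crit = 1e-6) {
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf_text, fin)
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) stop("obabel executable not found on PATH")
  suppressWarnings(system2(exe, c(fin, "-osdf", "-O", fout, "--minimize",
                                  "--ff", ff, "--steps", as.character(steps),
                                  "--crit", format(crit)),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout) || file.size(fout) == 0)
    stop("force-field minimization failed (", ff, ")")
  paste(readLines(fout), collapse = "\n")
}

#' Evaluate force-field energies
#'
#' Runs \code{obenergy} on SDF text and returns the total energy of each
#' record in kcal/mol.
#'
#' @inheritParams obMinimize
#' @return numeric vector, one energy per SDF record
#' @keywords internal
obEnergy <- function(sdf_text, ff = "MMFF94s") {
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin), add = TRUE)
  writeLines(sdf_text, fin)
  exe <- Sys.which("obenergy")
  if (!nzchar(exe)) stop("obenergy executable not found on PATH")
  out <- suppressWarnings(system2(exe, c("-ff", ff, fin), stdout = TRUE, stderr = FALSE))
  en <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (length(en) == 0) stop("obenergy returned no energies")
  as.numeric(sub("^TOTAL ENERGY\\s*=\\s*([-0-9.eE+]+).*", "\\1", en))
}
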