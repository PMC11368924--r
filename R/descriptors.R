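# Descriptor scoring goes through RDKit via a batch python bridge: QED,
# Ertl SA score and NP-likeness have no native R implementation, and these
# contrib scorers are the field's reference code. One subprocess scores a
# whole SMILES batch; a per-session cache avoids rescoring during search.

the <- new.env(parent = emptyenv())
the$descriptor_cache <- new.env(parent = emptyenv())
the$rdkit_version <- NULL

descriptor_script <- function() {
  path <- system.file("python", "descriptors.py", package = "paretomcts")
  if (!nzchar(path)) stop("descriptor bridge script not found", call. = FALSE)
  path
}

#' Score drug-likeness descriptors for SMILES strings
#'
#' Computes Crippen LogP, QED, the Ertl synthetic-accessibility score
#' (1 easy – 10 hard) and NP-likeness (about -5 to 5) with RDKit's
#' reference implementations, plus the canonical SMILES. Scoring is batch
#' (one interpreter launch per call) and deterministic; results are cached
#' per session, and the RDKit version used is recorded in the
#' `rdkit_version` attribute of the result.
#'
#' @param smiles Character vector of SMILES strings.
#' @param python Python interpreter to use (must have RDKit importable).
#' @return A tibble with columns `smiles`, `canonical`, `valid` (logical),
#'   `logp`, `qed`, `sa`, `np`; invalid strings get `valid = FALSE` and
#'   `NA` metrics.
#' @export
score_properties <- function(smiles, python = getOption("paretomcts.python", "python")) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(tibble::tibble(smiles = character(0), canonical = character(0),
                          valid = logical(0), logp = numeric(0),
                          qed = numeric(0), sa = numeric(0), np = numeric(0)))
  }
  if (any(!nzchar(smiles))) {
    invalid_molecule("", "empty SMILES string")
  }
  todo <- unique(smiles[!vapply(smiles, function(s)
    exists(s, envir = the$descriptor_cache), logical(1))])
  if (length(todo) > 0L) {
    scored <- run_descriptor_bridge(todo, python)
    for (i in seq_len(nrow(scored))) {
      assign(scored$smiles[i], scored[i, ], envir = the$descriptor_cache)
    }
  }
  out <- dplyr::bind_rows(lapply(smiles, get, envir = the$descriptor_cache))
  out$smiles <- smiles
  attr(out, "rdkit_version") <- the$rdkit_version
  out
}

run_descriptor_bridge <- function(smiles, python) {
  if (!nzchar(Sys.which(python))) {
    stop("python interpreter '", python, "' not found; ",
         "descriptor scoring requires RDKit via python", call. = FALSE)
  }
  infile <- tempfile("smiles_")
  writeLines(smiles, infile)
  on.exit(unlink(infile))
  lines <- suppressWarnings(
    system2(python, descriptor_script(), stdin = infile,
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(lines, "status")
  if (!is.null(status) && status != 0L) {
    stop("descriptor bridge exited with status ", status, call. = FALSE)
  }
  header <- lines[startsWith(lines, "#")]
  if (length(header) > 0L) {
    the$rdkit_version <- sub("^#rdkit=", "", header[1])
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = c("character", "character", "integer",
                                          "numeric", "numeric", "numeric",
                                          "numeric"))
  tab$valid <- tab$valid == 1L
  tibble::as_tibble(tab)
}

#' Version of the descriptor backend
#' @return The RDKit version string recorded by the last scoring call, or
#'   `NA` if nothing has been scored yet.
#' @export
descriptor_versions <- function() {
  c(rdkit = the$rdkit_version %||% NA_character_)
}

chem_scorer <- function(metric) {
  force(metric)
  function(tokens) {
    smi <- strip_terminal(tokens)
    if (!nzchar(smi)) invalid_molecule(tokens, "empty molecule")
    row <- score_properties(smi)
    if (!row$valid[1]) invalid_molecule(tokens)
    row[[metric]][1]
  }
}

strip_terminal <- function(tokens) sub("\\$$", "", tokens)

#' Standard chemistry objective set
#'
#' The default multi-objective profile for molecule generation: QED
#' (maximise), SA score (minimise), NP-likeness (maximise) and the
#' druggable-LogP range indicator (`[-0.4, 5.6]`, see
#' [logp_range_metric()]). Additional objectives — typically a
#' [docking_objective()] or a surrogate — can be appended. SMILES are
#' canonicalized with RDKit.
#'
#' @param ... Extra [objective()]s appended after the standard four.
#' @param python Python interpreter with RDKit.
#' @return An [objective_set()].
#' @export
chem_objective_set <- function(..., python = getOption("paretomcts.python", "python")) {
  canonicalize <- function(tokens) {
    smi <- strip_terminal(tokens)
    if (!nzchar(smi)) invalid_molecule(tokens, "empty molecule")
    row <- score_properties(smi, python = python)
    if (!row$valid[1]) invalid_molecule(tokens)
    paste0(row$canonical[1], terminal_token())
  }
  objective_set(
    c(list(
      objective("qed", chem_scorer("qed"), "maximize"),
      objective("sa", chem_scorer("sa"), "minimize"),
      objective("np", chem_scorer("np"), "maximize"),
      objective("logp", chem_scorer("logp"), "range", lo = -0.4, hi = 5.6)
    ), list(...)),
    canonicalize = canonicalize
  )
}

#' Docking objective via an external docking executable
#'
#' Wraps a command-line docking program (smina-compatible interface) as a
#' maximise-type objective. The raw docking score is the *negated* best
#' binding energy reported by the program, so higher is better
#' (kcal/mol). The executable and receptor are checked at setup time;
#' a docking failure during scoring is routed through the
#' invalid-molecule path. All configured parameters are recorded on the
#' returned objective for logging.
#'
#' @param receptor Path to the receptor structure file (PDB/PDBQT, passed
#'   through to the executable).
#' @param executable Docking program path or name on `PATH`.
#' @param args Extra command-line arguments (character vector), e.g. box
#'   definition or exhaustiveness.
#' @param name Metric name.
#' @return An [objective()] with attributes `receptor`, `executable`,
#'   `args`.
#' @export
docking_objective <- function(receptor, executable = "smina",
                              args = character(0), name = "docking") {
  exe <- Sys.which(executable)
  if (!nzchar(exe)) {
    if (file.exists(executable)) exe <- normalizePath(executable)
    else stop("docking executable not found: ", executable, call. = FALSE)
  }
  if (!file.exists(receptor)) {
    stop("receptor file not found: ", receptor, call. = FALSE)
  }
  scorer <- function(tokens) {
    smi <- strip_terminal(tokens)
    out <- tryCatch(
      suppressWarnings(
        system2(exe, c("-r", shQuote(receptor), args,
                       "--ligand_smiles", shQuote(smi)),
                stdout = TRUE, stderr = FALSE)
      ),
      error = function(e) NULL
    )
    status <- attr(out, "status")
    if (is.null(out) || (!is.null(status) && status != 0L)) {
      invalid_molecule(tokens, "docking run failed")
    }
    energy <- parse_docking_energy(out)
    if (is.na(energy)) invalid_molecule(tokens, "no affinity in docking output")
    -energy
  }
  obj <- objective(name, scorer, "maximize")
  obj$receptor <- receptor
  obj$executable <- unname(exe)
  obj$args <- args
  obj
}

# First pose affinity from smina-style output: either an "Affinity: x"
# line or the first row of the mode table ("   1    -9.8   ...").
parse_docking_energy <- function(lines) {
  aff <- grep("^Affinity:", lines, value = TRUE)
  if (length(aff) > 0L) {
    return(as.numeric(strsplit(trimws(sub("^Affinity:", "", aff[1])),
                               "\\s+")[[1]][1]))
  }
  mode <- grep("^\\s*1\\s+-?[0-9.]+", lines, value = TRUE)
  if (length(mode) > 0L) {
    return(as.numeric(strsplit(trimws(mode[1]), "\\s+")[[1]][2]))
  }
  NA_real_
}
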