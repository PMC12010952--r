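# Reading and writing docked structures, score tables and the docking
# configuration. Residue identity throughout the package is
# (chain, author residue number, insertion code); no renumbering is ever
# performed, so HDX peptide ranges given in antigen author numbering map
# directly onto parsed structures.

#' Construct a docked-pose structure model
#'
#' A \code{structure_model} holds the atoms of one docked antibody-antigen
#' pose together with the chain partition into the two binding partners.
#' Atoms are stored as a data frame in PDB column conventions
#' (\code{chain}, \code{resno}, \code{insert}, \code{resid}, \code{elety},
#' \code{x}, \code{y}, \code{z}, \code{elesy}) plus an \code{is_h} flag;
#' distance computations elsewhere in the package use heavy atoms only.
#'
#' @param model_id character scalar identifying the pose.
#' @param atoms data frame of atom records (see Details).
#' @param ab_chains character vector of antibody chain ids.
#' @param ag_chains character vector of antigen chain ids.
#' @return An object of class \code{structure_model}.
#' @export
structure_model <- function(model_id, atoms, ab_chains, ag_chains) {
  ab_chains <- as.character(ab_chains)
  ag_chains <- as.character(ag_chains)
  if (length(ab_chains) == 0L || length(ag_chains) == 0L)
    stop("both antibody and antigen chain sets must be non-empty")
  if (length(intersect(ab_chains, ag_chains)) > 0L)
    stop("antibody and antigen chain sets overlap: ",
         paste(intersect(ab_chains, ag_chains), collapse = ", "))
  required <- c("chain", "resno", "insert", "resid", "elety",
                "x", "y", "z", "elesy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("model ", model_id, ": non-finite coordinates")
  stray <- setdiff(unique(atoms$chain), c(ab_chains, ag_chains))
  if (length(stray) > 0L)
    stop("model ", model_id, ": chain(s) ", paste(stray, collapse = ", "),
         " belong to neither partner")
  if (!any(atoms$chain %in% ab_chains) || !any(atoms$chain %in% ag_chains))
    stop("model ", model_id, ": a binding partner has no atoms")
  if (is.null(atoms$is_h))
    atoms$is_h <- toupper(atoms$elesy) == "H"
  ca <- atoms[atoms$elety == "CA" & !atoms$is_h, , drop = FALSE]
  keys <- res_key(ca$chain, ca$resno, ca$insert)
  if (anyDuplicated(keys))
    stop("model ", model_id, ": duplicate C-alpha for residue(s) ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  structure(
    list(model_id = as.character(model_id), atoms = atoms,
         ab_chains = ab_chains, ag_chains = ag_chains),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$model_id, "-", nrow(x$atoms), "atoms; Ab chains:",
      paste(x$ab_chains, collapse = ","), "Ag chains:",
      paste(x$ag_chains, collapse = ","), "\n")
  invisible(x)
}

# Convert one bio3d pdb object into a structure_model, applying the
# package conventions: ATOM records only (waters/heteroatoms excluded),
# first alternate conformer only, hydrogens kept but flagged.
#' @noRd
pdb_to_model <- function(pdb, model_id, ab_chains, ag_chains) {
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elesy <- at$elesy
  # infer element from the atom name when the element column is blank
  blank <- is.na(elesy) | elesy == ""
  elesy[blank] <- substr(gsub("[^A-Za-z].*$", "", at$elety[blank]), 1, 1)
  atoms <- data.frame(
    chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    elesy = elesy, is_h = toupper(elesy) == "H",
    stringsAsFactors = FALSE)
  structure_model(model_id, atoms, ab_chains, ag_chains)
}

#' Read docked models from a (multi-MODEL) PDB file
#'
#' Each \code{MODEL ... ENDMDL} block becomes one \code{structure_model};
#' files without MODEL records yield a single model. Models containing a
#' chain assigned to neither partner, or lacking one partner entirely, are
#' rejected with a diagnostic rather than silently dropped.
#'
#' @param path PDB file.
#' @param ab_chains,ag_chains chain ids of the antibody and antigen.
#' @param quiet suppress rejection diagnostics.
#' @return List of \code{structure_model}; rejected blocks are reported via
#'   \code{warning} and recorded in the \code{"diagnostics"} attribute.
#' @export
read_pdb_models <- function(path, ab_chains, ag_chains, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts) == 0L) {
    list(list(id = "1", lines = lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    mapply(function(s, e) {
      id <- trimws(sub("^MODEL", "", lines[s]))
      if (id == "") id <- as.character(s)
      list(id = id, lines = lines[(s + 1):(e - 1)])
    }, starts, ends, SIMPLIFY = FALSE)
  }
  models <- list()
  diagnostics <- character(0)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (b in blocks) {
    writeLines(c(b$lines, "END"), tmp)
    res <- tryCatch({
      pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
      pdb_to_model(pdb, b$id, ab_chains, ag_chains)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "structure_model")) {
      models[[length(models) + 1L]] <- res
    } else {
      msg <- sprintf("%s MODEL %s rejected: %s", path, b$id, res)
      diagnostics <- c(diagnostics, msg)
      if (!quiet) warning(msg, call. = FALSE)
    }
  }
  attr(models, "diagnostics") <- diagnostics
  models
}

#' Write models to a multi-MODEL PDB file
#'
#' @param models list of \code{structure_model} (or a single one).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb_models <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  out <- character(0)
  for (i in seq_along(models)) {
    at <- models[[i]]$atoms
    bio3d::write.pdb(pdb = NULL, file = tmp,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, chain = at$chain,
                     insert = ifelse(at$insert == "", NA, at$insert),
                     resid = at$resid, elety = at$elety,
                     eleno = seq_len(nrow(at)), elesy = at$elesy)
    body <- grep("^(ATOM|HETATM|TER)", readLines(tmp, warn = FALSE),
                 value = TRUE)
    out <- c(out, sprintf("MODEL     %4d", i), body, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Load a docking configuration (JSON or YAML)
#'
#' Required keys: \code{ab_chains}, \code{ag_chains}, \code{cdrs} (list of
#' \code{chain}/\code{start}/\code{end} segments on antibody chains) and
#' \code{hdx_peptides} (list of \code{label}/\code{chain}/\code{start}/
#' \code{end} spans on antigen chains; may be empty, in which case scoring
#' degrades to the base interface score). Omitted optional keys take the
#' defaults: restraint threshold \code{d = 10} Angstrom with \code{k = 1}
#' required residue and proline excluded, \code{hdx_weight = 4.5},
#' \code{allostery_threshold = 0.75}, \code{top_n = 10}.
#'
#' @param path config file; format chosen by extension (\code{.json} vs
#'   \code{.yml}/\code{.yaml}).
#' @return A \code{docking_config} list with all defaults materialized.
#' @export
load_docking_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  docking_config(
    ab_chains = raw$ab_chains, ag_chains = raw$ag_chains,
    cdrs = raw$cdrs, hdx_peptides = raw$hdx_peptides,
    restraint = raw$restraint,
    hdx_weight = raw$hdx_weight,
    allostery_threshold = raw$allostery_threshold,
    top_n = raw$top_n)
}

#' Build and validate a docking configuration in code
#'
#' @param ab_chains,ag_chains chain id vectors for antibody and antigen.
#' @param cdrs list of CDR segments, each \code{list(chain=, start=, end=)}.
#' @param hdx_peptides list of HDX-interacting peptides, each
#'   \code{list(label=, chain=, start=, end=)}; may be empty.
#' @param restraint optional list overriding \code{restraint_spec} fields.
#' @param hdx_weight weight on the normalized HDX score in the combined
#'   score (default 4.5).
#' @param allostery_threshold top-10 mean weighted HDX score above which a
#'   dataset is flagged as containing an allosteric peptide (default 0.75).
#' @param top_n number of final models selected (default 10).
#' @return A validated \code{docking_config}.
#' @export
docking_config <- function(ab_chains, ag_chains, cdrs, hdx_peptides = list(),
                           restraint = NULL, hdx_weight = NULL,
                           allostery_threshold = NULL, top_n = NULL) {
  ab_chains <- as.character(unlist(ab_chains))
  ag_chains <- as.character(unlist(ag_chains))
  if (length(ab_chains) == 0L || length(ag_chains) == 0L)
    stop("ab_chains and ag_chains must be non-empty")
  if (length(intersect(ab_chains, ag_chains)) > 0L)
    stop("ab_chains and ag_chains overlap")
  if (length(cdrs) == 0L) stop("at least one CDR segment is required")
  cdrs <- lapply(cdrs, function(s) {
    s <- as.list(s)
    if (!all(c("chain", "start", "end") %in% names(s)))
      stop("CDR segment needs chain/start/end")
    if (!(s$chain %in% ab_chains))
      stop("CDR segment on chain ", s$chain, " which is not an antibody chain")
    if (s$start > s$end) stop("CDR segment start > end on chain ", s$chain)
    list(chain = as.character(s$chain),
         start = as.integer(s$start), end = as.integer(s$end))
  })
  hdx_peptides <- lapply(seq_along(hdx_peptides), function(i) {
    p <- as.list(hdx_peptides[[i]])
    if (!all(c("chain", "start", "end") %in% names(p)))
      stop("HDX peptide needs chain/start/end")
    if (!(p$chain %in% ag_chains))
      stop("HDX peptide on chain ", p$chain, " which is not an antigen chain")
    if (p$start > p$end) stop("HDX peptide start > end on chain ", p$chain)
    list(label = as.character(p$label %||%
                                sprintf("%s:%d-%d", p$chain, p$start, p$end)),
         chain = as.character(p$chain),
         start = as.integer(p$start), end = as.integer(p$end))
  })
  labels <- vapply(hdx_peptides, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate HDX peptide label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  restraint <- as.list(restraint)
  spec <- restraint_spec(
    d = restraint$d %||% 10,
    k = restraint$k %||% 1L,
    exclude_proline = restraint$exclude_proline %||% TRUE)
  cfg <- list(
    ab_chains = ab_chains, ag_chains = ag_chains,
    cdrs = cdrs, hdx_peptides = hdx_peptides, restraint = spec,
    hdx_weight = hdx_weight %||% 4.5,
    allostery_threshold = allostery_threshold %||% 0.75,
    top_n = as.integer(top_n %||% 10L))
  if (cfg$hdx_weight < 0) stop("hdx_weight must be non-negative")
  if (cfg$top_n < 1L) stop("top_n must be at least 1")
  class(cfg) <- "docking_config"
  cfg
}

#' Write a docking configuration to YAML
#'
#' @param config a \code{docking_config}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_docking_config <- function(config, path) {
  out <- unclass(config)
  out$restraint <- unclass(out$restraint)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a base interface-score table
#'
#' Delimited table (TSV/CSV, header row) with a \code{model_id} column and
#' an \code{interface_score} column in Rosetta energy units (lower =
#' better). Extra columns are ignored.
#'
#' @param path file path.
#' @return Named numeric vector of scores, names = model ids.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  id_col <- intersect(c("model_id", "model", "id"), names(df))[1]
  sc_col <- intersect(c("interface_score", "score"), names(df))[1]
  if (is.na(id_col) || is.na(sc_col))
    stop("score table must have model_id and interface_score columns")
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate model_id in score table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sc <- suppressWarnings(as.numeric(df[[sc_col]]))
  bad <- ids[!is.finite(sc)]
  if (length(bad) > 0L)
    stop("non-numeric or non-finite score for model(s): ",
         paste(bad, collapse = ", "))
  stats::setNames(sc, ids)
}

#' Write a full score-row table
#'
#' Columns: \code{model_id}, \code{interface_score}, \code{hdx_raw},
#' \code{hdx_normalized}, \code{hdx_weighted}, \code{combined}, \code{rank}.
#'
#' @param rows score-row data frame (see \code{\link{score_rows}}).
#' @param path output file; TSV unless the extension is \code{.csv}.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(rows, path) {
  cols <- c("model_id", "interface_score", "hdx_raw", "hdx_normalized",
            "hdx_weighted", "combined", "rank")
  for (cl in setdiff(cols, names(rows))) rows[[cl]] <- numeric(nrow(rows))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows[, cols, drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a full score-row table written by \code{write_score_table}
#'
#' @param path file path.
#' @return Score-row data frame.
#' @export
read_full_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  df$model_id <- as.character(df$model_id)
  if (anyDuplicated(df$model_id)) stop("duplicate model_id")
  df
}
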