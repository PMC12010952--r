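# HDX-interacting peptides as distance restraints. Each peptide demands
# that at least k of its residues place a C-alpha within d Angstrom of any
# C-alpha in the antibody CDRs; violation is penalized by a flat-harmonic
# on the k-th smallest per-residue minimum distance. Proline carries no
# exchangeable backbone amide and is excluded from the peptide side by
# default.

#' Restraint stringency specification
#'
#' @param d C-alpha--C-alpha threshold distance in Angstrom (default 10,
#'   the most lenient of the supported stringency grid d in \{5, 8, 10\}).
#' @param k minimum number of peptide residues required within the
#'   threshold (grid 1..3; default 1).
#' @param exclude_proline drop proline residues from the peptide side
#'   (default TRUE).
#' @return A \code{restraint_spec}.
#' @export
restraint_spec <- function(d = 10, k = 1L, exclude_proline = TRUE) {
  d <- as.numeric(d); k <- as.integer(k)
  if (!is.finite(d) || d <= 0) stop("threshold distance d must be > 0")
  if (is.na(k) || k < 1L) stop("minimum residue count k must be >= 1")
  structure(list(d = d, k = k, exclude_proline = isTRUE(exclude_proline)),
            class = "restraint_spec")
}

#' Flat-harmonic restraint penalty
#'
#' Zero inside the threshold, squared excess outside:
#' \code{0} for \code{x <= d}, \code{(x - d)^2} for \code{x > d}.
#' Vectorized over \code{x}.
#'
#' @param x distance(s) in Angstrom.
#' @param d threshold distance in Angstrom.
#' @return Penalty in squared Angstrom.
#' @export
flat_harmonic <- function(x, d) {
  if (any(d <= 0)) stop("threshold distance d must be > 0")
  if (any(x < 0)) stop("distance x must be non-negative")
  pmax(x - d, 0)^2
}

# C-alpha table of a model: one row per residue with a C-alpha (heavy
# atoms only; calcium ions arrive as HETATM and are excluded at parse).
#' @noRd
ca_table <- function(model) {
  at <- model$atoms
  at[at$elety == "CA" & !at$is_h, , drop = FALSE]
}

# Coordinates of CDR C-alphas as a matrix; NULL row names.
#' @noRd
cdr_ca_coords <- function(model, cdrs) {
  ca <- ca_table(model)
  # insertion-coded residues inside a segment's numeric range also belong
  keep <- rep(FALSE, nrow(ca))
  for (s in cdrs)
    keep <- keep | (ca$chain == s$chain & ca$resno >= s$start &
                      ca$resno <= s$end)
  as.matrix(ca[keep, c("x", "y", "z"), drop = FALSE])
}

# Eligible peptide C-alpha coordinates (non-proline when excluded).
#' @noRd
peptide_ca_coords <- function(model, peptide, spec) {
  ca <- ca_table(model)
  keep <- ca$chain == peptide$chain & ca$resno >= peptide$start &
    ca$resno <= peptide$end
  if (spec$exclude_proline) keep <- keep & ca$resid != "PRO"
  as.matrix(ca[keep, c("x", "y", "z"), drop = FALSE])
}

#' Effective shortest distance of an HDX peptide to the CDRs
#'
#' For each eligible peptide residue the shortest C-alpha--C-alpha distance
#' to any CDR C-alpha is taken; the k-th smallest of these per-residue
#' minima is the effective distance (for \code{k = 1}, the global shortest
#' distance). Peptide residues absent from the model contribute nothing; if
#' fewer than \code{k} eligible residues are present the largest available
#' order statistic is used with a message.
#'
#' @param model a \code{structure_model}.
#' @param peptide HDX peptide (list with \code{chain}, \code{start},
#'   \code{end}, \code{label}).
#' @param cdrs list of CDR segments.
#' @param spec a \code{restraint_spec}.
#' @return Distance in Angstrom.
#' @export
peptide_effective_distance <- function(model, peptide, cdrs,
                                       spec = restraint_spec()) {
  pep <- peptide_ca_coords(model, peptide, spec)
  label <- peptide$label %||%
    sprintf("%s:%d-%d", peptide$chain, peptide$start, peptide$end)
  if (nrow(pep) == 0L)
    stop("peptide ", label, ": no eligible residues with a C-alpha ",
         "(all-proline span or residues absent from model ",
         model$model_id, ")")
  cdr <- cdr_ca_coords(model, cdrs)
  if (nrow(cdr) == 0L)
    stop("peptide ", label, ": no CDR C-alpha atoms parsed in model ",
         model$model_id)
  per_res_min <- unname(apply(cross_dist(pep, cdr), 1, min))
  k <- spec$k
  if (k > length(per_res_min)) {
    message("peptide ", label, ": only ", length(per_res_min),
            " eligible residue(s) for k = ", k, "; using the largest")
    k <- length(per_res_min)
  }
  sort(per_res_min)[k]
}

#' Total HDX restraint penalty of one docked model
#'
#' The per-peptide flat-harmonic penalties on the effective distances are
#' summed; a model satisfying every restraint scores exactly zero.
#'
#' @inheritParams peptide_effective_distance
#' @param peptides list of HDX peptides.
#' @return A \code{model_penalty}: list with \code{model_id},
#'   \code{peptides} (data frame: label, distance, penalty) and
#'   \code{total}.
#' @export
model_hdx_penalty <- function(model, peptides, cdrs,
                              spec = restraint_spec()) {
  if (length(peptides) == 0L) {
    tab <- data.frame(label = character(0), distance = numeric(0),
                      penalty = numeric(0))
  } else {
    dist <- vapply(peptides, peptide_effective_distance, numeric(1),
                   model = model, cdrs = cdrs, spec = spec)
    tab <- data.frame(
      label = vapply(seq_along(peptides), function(i)
        peptides[[i]]$label %||% as.character(i), ""),
      distance = dist, penalty = flat_harmonic(dist, spec$d),
      stringsAsFactors = FALSE)
  }
  structure(list(model_id = model$model_id, peptides = tab,
                 total = sum(tab$penalty)),
            class = "model_penalty")
}

#' Per-model, per-peptide penalty matrix for an ensemble
#'
#' @param models list of \code{structure_model}.
#' @param peptides list of HDX peptides.
#' @param cdrs list of CDR segments.
#' @param spec a \code{restraint_spec}.
#' @return Numeric matrix, rows = model ids, columns = peptide labels;
#'   the per-model effective distances are attached as the
#'   \code{"distances"} attribute (same shape).
#' @export
hdx_penalty_matrix <- function(models, peptides, cdrs,
                               spec = restraint_spec()) {
  labels <- vapply(seq_along(peptides), function(i)
    peptides[[i]]$label %||% as.character(i), "")
  pen <- matrix(0, length(models), length(peptides),
                dimnames = list(vapply(models, `[[`, "", "model_id"), labels))
  dst <- pen
  for (i in seq_along(models)) {
    mp <- model_hdx_penalty(models[[i]], peptides, cdrs, spec)
    pen[i, ] <- mp$peptides$penalty
    dst[i, ] <- mp$peptides$distance
  }
  attr(pen, "distances") <- dst
  pen
}

#' Normalize penalty totals to a percentage of the ensemble maximum
#'
#' Each total is divided by the maximum observed among all models and
#' expressed as a percentage, enabling comparison across restraint
#' stringencies. An all-zero list maps to all zeros.
#'
#' @param penalties numeric vector of per-model penalty totals.
#' @return Percentages in [0, 100].
#' @export
percent_normalize <- function(penalties) {
  if (length(penalties) == 0L) stop("empty penalty list")
  if (any(penalties < 0)) stop("penalties must be non-negative")
  m <- max(penalties)
  if (m == 0) return(rep(0, length(penalties)))
  100 * penalties / m
}
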