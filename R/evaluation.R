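# Model accuracy against a reference complex (fnat, L-RMSD, iRMSD, CAPRI
# class) and ensemble-level scoring performance (enrichment, two-sample
# KS). Conventions: antigen = receptor (superposition frame), antibody =
# ligand; all distance tests use heavy atoms; interface residues are
# defined on the reference complex only.

# Heavy atoms of one partner as a coordinate matrix plus residue keys.
#' @noRd
partner_heavy <- function(model, chains) {
  at <- model$atoms
  at <- at[at$chain %in% chains & !at$is_h, , drop = FALSE]
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       key = res_key(at$chain, at$resno, at$insert))
}

#' Interface residues of a complex
#'
#' A residue belongs to the interface iff any of its heavy atoms lies
#' within \code{cutoff} of any heavy atom of the other binding partner.
#'
#' @param reference a \code{structure_model}.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return Character vector of residue keys (\code{chain|resno|icode}) on
#'   both partners, sorted.
#' @export
interface_residues <- function(reference, cutoff = 10) {
  ab <- partner_heavy(reference, reference$ab_chains)
  ag <- partner_heavy(reference, reference$ag_chains)
  if (nrow(ab$xyz) == 0L || nrow(ag$xyz) == 0L)
    stop("a binding partner has no heavy atoms")
  d <- cross_dist(ab$xyz, ag$xyz)
  hit <- d <= cutoff
  sort(unique(c(ab$key[rowSums(hit) > 0], ag$key[colSums(hit) > 0])))
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Finds the proper rotation (no reflection) and translation minimizing
#' the RMSD between paired coordinate lists.
#'
#' @param mobile,target n x 3 coordinate matrices, rows paired by residue
#'   identity, n >= 3.
#' @return List with \code{rotation} (3 x 3), \code{translation} (length
#'   3; the fit is \code{mobile \%*\% t(rotation) + translation}),
#'   \code{rmsd} (Angstrom) and \code{fitted} coordinates.
#' @export
superpose_rmsd <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("mobile and target must be equal-size n x 3 matrices")
  if (nrow(mobile) < 3L) stop("need at least 3 paired points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  mc <- sweep(mobile, 2, cm); tc <- sweep(target, 2, ct)
  s <- svd(crossprod(mc, tc))              # 3x3 covariance t(mc) %*% tc
  sign_fix <- sign(det(s$v %*% t(s$u)))
  if (sign_fix == 0) sign_fix <- 1
  R <- s$v %*% diag(c(1, 1, sign_fix)) %*% t(s$u)
  fitted <- mc %*% t(R) + matrix(ct, nrow(mobile), 3, byrow = TRUE)
  list(rotation = R, translation = ct - as.numeric(R %*% cm),
       rmsd = sqrt(mean(rowSums((fitted - target)^2))), fitted = fitted)
}

# C-alpha coordinates keyed by residue, restricted to given chains.
#' @noRd
ca_by_key <- function(model, chains = NULL) {
  ca <- ca_table(model)
  if (!is.null(chains)) ca <- ca[ca$chain %in% chains, , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- res_key(ca$chain, ca$resno, ca$insert)
  xyz
}

# Inter-partner residue contact pairs (any heavy-atom pair < cutoff).
#' @noRd
contact_pairs <- function(model, cutoff = 5) {
  ab <- partner_heavy(model, model$ab_chains)
  ag <- partner_heavy(model, model$ag_chains)
  hit <- which(cross_dist(ab$xyz, ag$xyz) < cutoff, arr.ind = TRUE)
  unique(paste(ab$key[hit[, 1]], ag$key[hit[, 2]], sep = "::"))
}

# CAPRI class from the three metrics. Cumulative upper-bound windows
# checked best-first, so a model meeting a higher class's criteria takes
# the higher class.
#' @noRd
capri_class <- function(fnat, lrmsd, irmsd) {
  if (fnat >= 0.5 && (lrmsd <= 1 || irmsd <= 1)) return("high")
  if (fnat >= 0.3 && (lrmsd <= 5 || irmsd <= 2)) return("medium")
  if (fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

#' CAPRI-style quality metrics of a docked model
#'
#' \code{fnat} is the fraction of reference inter-partner residue contacts
#' (any heavy-atom pair < \code{fnat_cutoff}) reproduced by the model.
#' \code{lrmsd} is the antibody C-alpha RMSD after superposing the model
#' on the reference antigen C-alphas. \code{irmsd} is the C-alpha RMSD
#' over the reference-defined interface residues after superposing on
#' exactly those C-alphas. The CAPRI class follows the standard
#' fnat/L-RMSD/iRMSD thresholds (high: fnat >= 0.5 and L-RMSD <= 1 or
#' iRMSD <= 1; medium: fnat >= 0.3 and L-RMSD <= 5 or iRMSD <= 2;
#' acceptable: fnat >= 0.1 and L-RMSD <= 10 or iRMSD <= 4; else
#' incorrect).
#'
#' @param model,reference \code{structure_model}s sharing residue
#'   identities over the scored residues.
#' @param fnat_cutoff native-contact heavy-atom cutoff (default 5).
#' @param interface_cutoff interface-definition cutoff (default 10).
#' @return List (class \code{quality_metrics}): \code{fnat}, \code{lrmsd},
#'   \code{irmsd}, \code{capri_class}.
#' @export
compute_quality <- function(model, reference, fnat_cutoff = 5,
                            interface_cutoff = 10) {
  ref_contacts <- contact_pairs(reference, fnat_cutoff)
  if (length(ref_contacts) == 0L)
    stop("reference complex has no inter-partner contacts")
  fnat <- mean(ref_contacts %in% contact_pairs(model, fnat_cutoff))

  # L-RMSD: fit on shared antigen C-alphas, measure over antibody
  ref_ag <- ca_by_key(reference, reference$ag_chains)
  mod_ag <- ca_by_key(model, model$ag_chains)
  shared_ag <- intersect(rownames(ref_ag), rownames(mod_ag))
  if (length(shared_ag) < 3L) stop("fewer than 3 shared antigen C-alphas")
  fit <- superpose_rmsd(mod_ag[shared_ag, , drop = FALSE],
                        ref_ag[shared_ag, , drop = FALSE])
  ref_ab <- ca_by_key(reference, reference$ab_chains)
  mod_ab <- ca_by_key(model, model$ab_chains)
  shared_ab <- intersect(rownames(ref_ab), rownames(mod_ab))
  if (length(shared_ab) == 0L) stop("no shared antibody C-alphas")
  mob <- mod_ab[shared_ab, , drop = FALSE] %*% t(fit$rotation) +
    matrix(fit$translation, length(shared_ab), 3, byrow = TRUE)
  lrmsd <- sqrt(mean(rowSums((mob - ref_ab[shared_ab, , drop = FALSE])^2)))

  # iRMSD: fit and measure over the reference interface C-alphas
  iface <- interface_residues(reference, interface_cutoff)
  ref_all <- ca_by_key(reference)
  mod_all <- ca_by_key(model)
  shared_iface <- intersect(intersect(iface, rownames(ref_all)),
                            rownames(mod_all))
  if (length(shared_iface) < 3L)
    stop("fewer than 3 shared interface residues with C-alpha")
  ifit <- superpose_rmsd(mod_all[shared_iface, , drop = FALSE],
                         ref_all[shared_iface, , drop = FALSE])
  irmsd <- ifit$rmsd

  structure(list(fnat = fnat, lrmsd = lrmsd, irmsd = irmsd,
                 capri_class = capri_class(fnat, lrmsd, irmsd)),
            class = "quality_metrics")
}

#' Whether quality metrics count as near-native
#'
#' Near-native = CAPRI acceptable quality or better.
#'
#' @param quality a \code{quality_metrics} or a character class vector.
#' @return Logical.
#' @export
is_near_native <- function(quality) {
  cls <- if (inherits(quality, "quality_metrics")) quality$capri_class
  else as.character(quality)
  cls %in% c("acceptable", "medium", "high")
}

#' Enrichment of a scored, quality-annotated ensemble
#'
#' Models in the top \code{fraction} (default 10\%) by selection score are
#' positives (P); those positives also in the ensemble-wide top
#' \code{fraction} by iRMSD are true positives. Enrichment is
#' \code{(TP / (TP + FP)) * ((P + N) / P)}; with a 10\% fraction the
#' maximum possible value is 10.
#'
#' @param score numeric selection scores (lower = better).
#' @param irmsd numeric iRMSD values, same length (lower = better).
#' @param fraction tail fraction (default 0.10).
#' @return List (class \code{enrichment_result}): \code{P}, \code{N},
#'   \code{TP}, \code{FP}, \code{enrichment}.
#' @export
enrichment <- function(score, irmsd, fraction = 0.10) {
  n <- length(score)
  if (length(irmsd) != n) stop("score and irmsd length mismatch")
  if (n < 10L) stop("need at least 10 models")
  p <- as.integer(ceiling(fraction * n))
  pos <- order(score)[seq_len(p)]
  best <- order(irmsd)[seq_len(p)]
  tp <- sum(pos %in% best)
  structure(list(P = p, N = n - p, TP = tp, FP = p - tp,
                 enrichment = (tp / p) * (n / p)),
            class = "enrichment_result")
}

#' Two-sample Kolmogorov-Smirnov comparison of iRMSD distributions
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the p-value uses the asymptotic two-sample formula.
#'
#' @param a,b numeric samples (e.g. iRMSD of two docking ensembles).
#' @return List with \code{D} and \code{p_value}.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Evaluate an ensemble against a reference complex
#'
#' @param models list of \code{structure_model}.
#' @param reference the reference \code{structure_model}.
#' @param ... passed to \code{\link{compute_quality}}.
#' @return Data frame: model_id, fnat, lrmsd, irmsd, capri_class,
#'   near_native.
#' @export
evaluate_ensemble <- function(models, reference, ...) {
  rows <- lapply(models, function(m) {
    q <- compute_quality(m, reference, ...)
    data.frame(model_id = m$model_id, fnat = q$fnat, lrmsd = q$lrmsd,
               irmsd = q$irmsd, capri_class = q$capri_class,
               near_native = is_near_native(q), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Docking success of a ranked, evaluated ensemble
#'
#' A run is successful iff at least one near-native model appears in the
#' top \code{n} by rank.
#'
#' @param quality data frame from \code{\link{evaluate_ensemble}}.
#' @param rows ranked score-row data frame.
#' @param n top-n size (default 10).
#' @return Logical scalar.
#' @export
docking_success <- function(quality, rows, n = 10L) {
  top <- select_top_n(rows, n)
  any(quality$near_native[match(top$model_id, quality$model_id)],
      na.rm = TRUE)
}
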