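# Deterministic synthetic fixtures: idealized C-alpha-trace antibody-
# antigen complexes with planted HDX structure, rigid-body decoy
# ensembles with tunable score-quality correlation, and deuterium-uptake
# tables with known truth labels. Everything a module test needs is
# generated here; no external data is ever read.
#
# Geometry: both chains run along the x axis at 3.8 Angstrom C-alpha
# spacing on parallel lines 6 Angstrom apart; each residue carries a
# C-beta pseudo-atom reaching 1.6 Angstrom toward the partner (bridging
# to 2.8 Angstrom across the interface so native contacts exist) plus a
# backbone O. CDR segments sit directly above the planted interacting
# peptides (effective C-alpha distance ~6 Angstrom < 10); planted
# allosteric peptides are offset along the chain so their reference
# effective distance is at least the requested gap.

CA_SPACING <- 3.8
Z_GAP <- 6.0
AB_OFFSET <- 14 * CA_SPACING

# Atom rows for one idealized residue.
#' @noRd
toy_residue <- function(chain, resno, resid, x, z, toward) {
  data.frame(
    chain = chain, resno = resno, insert = "", resid = resid,
    elety = c("CA", "CB", "O"),
    x = c(x, x, x + 0.6), y = c(0, 0.3, -1.1),
    z = c(z, z + toward * 1.6, z),
    elesy = c("C", "C", "O"), is_h = FALSE,
    stringsAsFactors = FALSE)
}

#' Generate a toy antibody-antigen reference complex
#'
#' Antigen chain \code{A} (residues 1..\code{n_ag}, z = 0) and antibody
#' chain \code{H} (residues 1..\code{n_ab}, z = 6, shifted along x). Two
#' CDR segments (H 5-10 and H 18-23) lie directly above the planted
#' interacting peptides \code{I1} (A 19-24) and \code{I2} (A 32-37).
#' Allosteric peptides (labels \code{X1}, \code{X2}) are placed so their
#' reference effective distance to the CDRs is at least the requested
#' gap: the first beyond the last CDR, the second before the first. One
#' proline is planted at A 20 to exercise the exclusion rule.
#'
#' @param seed RNG seed (coordinate jitter).
#' @param n_ab,n_ag chain lengths (residues).
#' @param n_interacting number of planted interacting peptides (1 or 2).
#' @param allosteric_gaps numeric vector (length 0-2) of minimum
#'   reference effective distances, Angstrom, each > 10.
#' @param jitter_sd isotropic Gaussian coordinate jitter, Angstrom.
#' @return List: \code{reference} (\code{structure_model} "native"),
#'   \code{config} (\code{docking_config} whose \code{hdx_peptides} are
#'   the planted interacting plus allosteric peptides), \code{truth}
#'   (list of interacting / allosteric labels).
#' @export
make_toy_complex <- function(seed = 1L, n_ab = 30L, n_ag = 52L,
                             n_interacting = 2L,
                             allosteric_gaps = numeric(0),
                             jitter_sd = 0.2) {
  if (n_ab < 23L || n_ag < 50L)
    stop("chains too short for the fixed CDR/peptide layout")
  if (!n_interacting %in% 1:2) stop("n_interacting must be 1 or 2")
  if (length(allosteric_gaps) > 2L)
    stop("at most 2 allosteric peptides supported")
  if (any(allosteric_gaps <= 10))
    stop("allosteric gaps must exceed the 10 Angstrom threshold")
  set.seed(seed)

  ag_res <- lapply(seq_len(n_ag), function(r)
    toy_residue("A", r, if (r == 20L) "PRO" else "ALA",
                CA_SPACING * (r - 1), 0, toward = +1))
  ab_res <- lapply(seq_len(n_ab), function(r)
    toy_residue("H", r, "ALA", CA_SPACING * (r - 1) + AB_OFFSET, Z_GAP,
                toward = -1))
  atoms <- do.call(rbind, c(ag_res, ab_res))
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(atoms), 0, jitter_sd), ncol = 3)

  cdrs <- list(list(chain = "H", start = 5L, end = 10L),
               list(chain = "H", start = 18L, end = 23L))
  interacting <- list(
    list(label = "I1", chain = "A", start = 19L, end = 24L),
    list(label = "I2", chain = "A", start = 32L, end = 37L)
  )[seq_len(n_interacting)]

  cdr_x <- CA_SPACING * (c(5, 23) - 1) + AB_OFFSET  # first/last CDR x
  allosteric <- list()
  for (i in seq_along(allosteric_gaps)) {
    dx <- sqrt(allosteric_gaps[i]^2 - Z_GAP^2)
    if (i == 1L) {
      s <- ceiling((cdr_x[2] + dx) / CA_SPACING) + 1L
      if (s + 5L > n_ag) stop("antigen too short for requested gap")
      span <- c(s, s + 5L)
    } else {
      e <- floor((cdr_x[1] - dx) / CA_SPACING) + 1L
      if (e < 6L) stop("antigen too short for requested left-side gap")
      span <- c(e - 5L, e)
    }
    allosteric[[i]] <- list(label = paste0("X", i), chain = "A",
                            start = span[1], end = span[2])
  }

  config <- docking_config(
    ab_chains = "H", ag_chains = "A", cdrs = cdrs,
    hdx_peptides = c(interacting, allosteric))
  list(reference = structure_model("native", atoms, "H", "A"),
       config = config,
       truth = list(interacting = vapply(interacting, `[[`, "", "label"),
                    allosteric = vapply(allosteric, `[[`, "", "label")))
}

#' Generate a rigid-body decoy ensemble with a base-score table
#'
#' Each decoy is the reference with its antibody rigidly perturbed; the
#' interface RMSD of every decoy is then measured with the evaluation
#' machinery and the base interface score is a monotone linear function
#' of that iRMSD plus Gaussian noise, so the score-ranking quality is
#' tunable (noise 0 = perfect ranking). An optional biased
#' sub-population is displaced along a fixed direction with a score
#' bonus, emulating an energy funnel centered away from the epitope.
#'
#' @param reference reference \code{structure_model}.
#' @param n_decoys ensemble size.
#' @param max_disp maximum displacement magnitude, Angstrom.
#' @param score_slope,score_intercept base score = intercept + slope *
#'   iRMSD (+ noise), REU.
#' @param score_noise_sd Gaussian score noise SD, REU.
#' @param bias_fraction fraction of decoys in the biased sub-population.
#' @param bias_direction unit displacement direction of that population.
#' @param bias_range displacement magnitude range of that population.
#' @param bias_bonus score bonus (subtracted) for biased decoys, REU.
#' @param seed RNG seed.
#' @return List: \code{models}, \code{scores} (named vector),
#'   \code{truth} data frame (model_id, displacement, irmsd, biased).
#' @export
make_decoy_ensemble <- function(reference, n_decoys = 200L, max_disp = 20,
                                score_slope = 0.8, score_intercept = -30,
                                score_noise_sd = 0.5, bias_fraction = 0,
                                bias_direction = c(1, 0, 0),
                                bias_range = c(3.5, 5.5), bias_bonus = 8,
                                seed = 1L) {
  set.seed(seed)
  n_bias <- round(bias_fraction * n_decoys)
  iface <- interface_residues(reference)
  ref_all <- ca_by_key(reference)
  iface <- intersect(iface, rownames(ref_all))
  bias_direction <- bias_direction / sqrt(sum(bias_direction^2))

  models <- vector("list", n_decoys)
  disp <- irmsd <- numeric(n_decoys)
  for (i in seq_len(n_decoys)) {
    biased <- i <= n_bias
    if (biased) {
      m <- stats::runif(1, bias_range[1], bias_range[2])
      t <- m * bias_direction
      R <- random_small_rotation(1)
    } else {
      m <- max_disp * stats::runif(1)^1.5
      t <- m * random_unit_vector()
      R <- random_small_rotation(4)
    }
    pose <- structure(list(rotation = R, translation = t,
                           provenance = list(seed = seed, index = i)),
                      class = "pose")
    mod <- apply_pose(reference, pose)
    mod$model_id <- sprintf("m%04d", i)
    models[[i]] <- mod
    disp[i] <- m
    mob <- ca_by_key(mod)[iface, , drop = FALSE]
    irmsd[i] <- superpose_rmsd(mob, ref_all[iface, , drop = FALSE])$rmsd
  }
  ids <- vapply(models, `[[`, "", "model_id")
  scores <- score_intercept + score_slope * irmsd +
    stats::rnorm(n_decoys, 0, score_noise_sd) -
    bias_bonus * (seq_len(n_decoys) <= n_bias)
  list(models = models, scores = stats::setNames(scores, ids),
       truth = data.frame(model_id = ids, displacement = disp,
                          irmsd = irmsd,
                          biased = seq_len(n_decoys) <= n_bias,
                          stringsAsFactors = FALSE))
}

#' One-call allosteric-detection scenario
#'
#' \code{masked = FALSE}: planted allosteric peptide(s) far from the
#' CDRs (gaps 30 and, for a second, 36 Angstrom), unbiased decoys - the
#' dataset should be flagged and the planted labels recovered.
#' \code{masked = TRUE}: one allosteric peptide just beyond the
#' threshold (~13 Angstrom) plus a biased decoy population whose
#' favorable base scores satisfy it - the known failure mode in which
#' the metric stays silent.
#'
#' @param seed RNG seed.
#' @param n_allosteric planted allosteric peptides (1 or 2; masked mode
#'   forces 1).
#' @param masked build the failure-mode scenario.
#' @param n_decoys ensemble size.
#' @return List: \code{penalties} (model x peptide matrix),
#'   \code{scores}, \code{truth}, \code{config}, \code{reference},
#'   \code{models}, \code{ensemble_truth}.
#' @export
make_allostery_case <- function(seed = 1L, n_allosteric = 1L,
                                masked = FALSE, n_decoys = 200L) {
  gaps <- if (masked) 13 else c(30, 36)[seq_len(n_allosteric)]
  toy <- make_toy_complex(seed = seed, allosteric_gaps = gaps)
  ens <- make_decoy_ensemble(
    toy$reference, n_decoys = n_decoys, seed = seed + 1000L,
    bias_fraction = if (masked) 0.15 else 0,
    bias_direction = c(1, 0, 0),
    bias_range = c(8, 12))
  pen <- hdx_penalty_matrix(ens$models, toy$config$hdx_peptides,
                            toy$config$cdrs, toy$config$restraint)
  list(penalties = pen, scores = ens$scores, truth = toy$truth,
       config = toy$config, reference = toy$reference,
       models = ens$models, ensemble_truth = ens$truth)
}

#' Generate a deuterium-uptake table with known truth labels
#'
#' Two exposure timepoints (100 s and 1000 s) by default. Protected
#' (interacting) peptides receive per-timepoint protection clearing
#' every significance gate (0.8 and 1.0 Da against SDs of 0.05 Da);
#' non-interacting peptides receive sub-threshold differences. Optional
#' Gaussian noise perturbs the means.
#'
#' @param seed RNG seed.
#' @param n_peptides number of peptides.
#' @param interacting_idx indices of planted interacting peptides.
#' @param time_s exposure times, seconds.
#' @param protected_diff per-timepoint protection of planted peptides, Da.
#' @param null_diff per-timepoint difference of non-interacting
#'   peptides, Da (below every gate).
#' @param sd per-timepoint, per-state SD, Da.
#' @param noise_sd extra Gaussian noise on the means, Da.
#' @return List: \code{records} (list of \code{uptake_record}),
#'   \code{truth} (character labels of planted interacting peptides).
#' @export
make_uptake_table <- function(seed = 1L, n_peptides = 8L,
                              interacting_idx = c(1L, 3L),
                              time_s = c(100, 1000),
                              protected_diff = c(0.8, 1.0),
                              null_diff = c(0.1, 0.15),
                              sd = 0.05, noise_sd = 0) {
  set.seed(seed)
  records <- lapply(seq_len(n_peptides), function(i) {
    span <- c(1 + 6 * (i - 1), 6 * i)
    base <- 1.5 + 0.4 * i + 0.8 * log10(time_s / time_s[1])
    diff <- if (i %in% interacting_idx) protected_diff else null_diff
    uptake_record(
      label = sprintf("pep%02d", i), chain = "A",
      start = span[1], end = span[2], time_s = time_s,
      unbound_mean = base + stats::rnorm(length(time_s), 0, noise_sd),
      bound_mean = base - diff + stats::rnorm(length(time_s), 0, noise_sd),
      unbound_sd = sd, bound_sd = sd)
  })
  list(records = records,
       truth = sprintf("pep%02d", intersect(seq_len(n_peptides),
                                            interacting_idx)))
}
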