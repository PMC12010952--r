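# Toy rigid-body Metropolis docking. The antibody moves as a rigid body
# about its own C-alpha centroid; the antigen never moves. A deliberately
# non-physical coarse contact/clash score stands in for a molecular
# energy function; its only job is to exercise the Metropolis-with-HDX-
# penalty acceptance contract. With HDX guidance the total is
# coarse + hdx_ratio * penalty (default ratio 1:1).

#' Sampler configuration
#'
#' Defaults mirror a standard rigid-body scramble-then-perturb protocol:
#' 10 Angstrom initial displacement with a 60 degree scramble rotation
#' before full orientation randomization, Gaussian perturbations of
#' 3 Angstrom / 8 degrees per move, and an HDX:coarse score ratio of 1.
#'
#' @param steps Metropolis steps (required, > 0 unless exactly 0 for a
#'   scramble-only run).
#' @param displacement initial displacement magnitude in Angstrom.
#' @param rotation_deg scramble rotation in degrees.
#' @param perturb_trans_sd per-axis translation SD of a move, Angstrom.
#' @param perturb_rot_sd rotation-angle SD of a move, degrees.
#' @param temperature Metropolis temperature in coarse-score units.
#' @param hdx_ratio weight of the HDX penalty relative to the coarse
#'   score.
#' @param seed integer RNG seed.
#' @return A \code{sampler_config}.
#' @export
sampler_config <- function(steps = 500L, displacement = 10,
                           rotation_deg = 60, perturb_trans_sd = 3,
                           perturb_rot_sd = 8, temperature = 1,
                           hdx_ratio = 1, seed = 1L) {
  vals <- c(displacement = displacement, rotation_deg = rotation_deg,
            perturb_trans_sd = perturb_trans_sd,
            perturb_rot_sd = perturb_rot_sd, temperature = temperature,
            hdx_ratio = hdx_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all sampler parameters must be positive")
  if (steps < 0) stop("steps must be >= 0")
  structure(list(steps = as.integer(steps), displacement = displacement,
                 rotation_deg = rotation_deg,
                 perturb_trans_sd = perturb_trans_sd,
                 perturb_rot_sd = perturb_rot_sd,
                 temperature = temperature, hdx_ratio = hdx_ratio,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Identity pose
#'
#' A pose is a proper rotation plus translation applied to the antibody
#' about its C-alpha centroid in the input complex.
#'
#' @return A \code{pose} with identity rotation and zero translation.
#' @export
pose_identity <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 provenance = list()), class = "pose")
}

#' Apply a pose to a complex
#'
#' Antibody atoms are transformed as
#' \code{x' = R (x - c) + c + t} with \code{c} the antibody C-alpha
#' centroid of \code{complex}; antigen atoms are untouched.
#'
#' @param complex a \code{structure_model}.
#' @param pose a \code{pose}.
#' @return A transformed \code{structure_model}.
#' @export
apply_pose <- function(complex, pose) {
  at <- complex$atoms
  ab <- at$chain %in% complex$ab_chains
  ca <- ca_table(complex)
  ctr <- colMeans(as.matrix(
    ca[ca$chain %in% complex$ab_chains, c("x", "y", "z")]))
  xyz <- as.matrix(at[ab, c("x", "y", "z")])
  moved <- sweep(xyz, 2, ctr) %*% t(pose$rotation)
  moved <- sweep(moved, 2, ctr + pose$translation, "+")
  at[ab, c("x", "y", "z")] <- moved
  out <- complex
  out$atoms <- at
  out
}

#' Scrambled starting pose
#'
#' Displaces the antibody by exactly \code{displacement} Angstrom along a
#' uniformly random direction with a \code{rotation_deg} scramble
#' rotation, assigns a uniformly random orientation, then applies one
#' Gaussian perturbation (\code{perturb_trans_sd}, \code{perturb_rot_sd}).
#' Deterministic given the RNG state.
#'
#' @param config a \code{sampler_config}.
#' @return A \code{pose}; the exact pre-randomization displacement vector
#'   is recorded in \code{provenance$initial_displacement}.
#' @export
scramble_start <- function(config = sampler_config()) {
  disp <- config$displacement * random_unit_vector()
  R <- random_small_rotation(config$perturb_rot_sd) %*%
    random_rotation() %*%
    rotation_about_axis(random_unit_vector(),
                        config$rotation_deg * pi / 180)
  t <- disp + stats::rnorm(3, 0, config$perturb_trans_sd)
  structure(list(rotation = R, translation = t,
                 provenance = list(initial_displacement = disp)),
            class = "pose")
}

#' Coarse contact/clash score of a docked pose
#'
#' Counts inter-partner C-alpha pairs: each pair closer than 3.5 Angstrom
#' adds +10 (clash), each pair in [3.5, 8) Angstrom adds -1 (contact).
#' Lower is better. Non-physical by construction.
#'
#' @param model a (pose-applied) \code{structure_model}.
#' @return Numeric score.
#' @export
surrogate_score <- function(model) {
  ca <- ca_table(model)
  ab <- as.matrix(ca[ca$chain %in% model$ab_chains, c("x", "y", "z")])
  ag <- as.matrix(ca[ca$chain %in% model$ag_chains, c("x", "y", "z")])
  surrogate_from_dists(cross_dist(ab, ag))
}

#' @noRd
surrogate_from_dists <- function(d) {
  10 * sum(d < 3.5) - sum(d >= 3.5 & d < 8)
}

# Precompute the geometry needed per Metropolis step: antibody/antigen
# C-alpha coordinates, the CDR subset of the antibody C-alphas, and for
# each HDX peptide the column indices of its eligible antigen residues.
#' @noRd
sampler_geometry <- function(complex, peptides, cdrs, spec) {
  ca <- ca_table(complex)
  ab_ca <- ca[ca$chain %in% complex$ab_chains, , drop = FALSE]
  ag_ca <- ca[ca$chain %in% complex$ag_chains, , drop = FALSE]
  cdr_idx <- rep(FALSE, nrow(ab_ca))
  for (s in cdrs %||% list())
    cdr_idx <- cdr_idx | (ab_ca$chain == s$chain & ab_ca$resno >= s$start &
                            ab_ca$resno <= s$end)
  pep_cols <- lapply(peptides %||% list(), function(p) {
    keep <- ag_ca$chain == p$chain & ag_ca$resno >= p$start &
      ag_ca$resno <= p$end
    if (spec$exclude_proline) keep <- keep & ag_ca$resid != "PRO"
    which(keep)
  })
  list(ab_xyz = as.matrix(ab_ca[, c("x", "y", "z")]),
       ag_xyz = as.matrix(ag_ca[, c("x", "y", "z")]),
       centroid = colMeans(as.matrix(ab_ca[, c("x", "y", "z")])),
       cdr_idx = which(cdr_idx), pep_cols = pep_cols)
}

# Total HDX penalty from a cross-distance matrix (CDR rows, antigen
# C-alpha columns).
#' @noRd
penalty_from_dists <- function(d_cdr_ag, pep_cols, spec) {
  total <- 0
  for (cols in pep_cols) {
    if (length(cols) == 0L)
      stop("an HDX peptide has no eligible residues in the complex")
    per_res <- apply(d_cdr_ag[, cols, drop = FALSE], 2, min)
    k <- min(spec$k, length(per_res))
    total <- total + flat_harmonic(unname(sort(per_res)[[k]]), spec$d)
  }
  total
}

#' Restraint-guided rigid-body Metropolis run
#'
#' Starts from a scrambled pose and proposes Gaussian rigid-body
#' perturbations; a move is accepted when the total score (coarse score
#' plus, when \code{use_hdx}, \code{hdx_ratio} times the HDX penalty)
#' decreases, or with probability \code{exp(-delta / temperature)}
#' otherwise. The full trajectory is reproducible from the seed.
#'
#' @param complex reference \code{structure_model} to scramble and dock.
#' @param config a \code{sampler_config} (its \code{seed} seeds the run).
#' @param use_hdx include the HDX penalty in the acceptance total.
#' @param peptides,cdrs,spec restraint inputs (required when
#'   \code{use_hdx}; the penalty is still tracked, unweighted, when not).
#' @param keep_poses record the pose at every step (heavier; default
#'   FALSE keeps only the final pose).
#' @return List: \code{trajectory} data frame (step, surrogate,
#'   hdx_penalty, total, accepted), \code{final_pose},
#'   \code{final_model}, and \code{poses} when requested.
#' @export
metropolis_run <- function(complex, config, use_hdx = TRUE,
                           peptides = NULL, cdrs = NULL,
                           spec = restraint_spec(), keep_poses = FALSE) {
  if (use_hdx && (length(peptides) == 0L || length(cdrs) == 0L))
    stop("use_hdx = TRUE requires peptides and cdrs")
  set.seed(config$seed)
  geom <- sampler_geometry(complex, peptides, cdrs, spec)
  track_hdx <- length(geom$pep_cols) > 0L && length(geom$cdr_idx) > 0L

  eval_pose <- function(R, t) {
    ab <- sweep(sweep(geom$ab_xyz, 2, geom$centroid) %*% t(R), 2,
                geom$centroid + t, "+")
    d <- cross_dist(ab, geom$ag_xyz)
    sur <- surrogate_from_dists(d)
    hdx <- if (track_hdx)
      penalty_from_dists(d[geom$cdr_idx, , drop = FALSE],
                         geom$pep_cols, spec) else 0
    c(sur = sur, hdx = hdx,
      total = sur + if (use_hdx) config$hdx_ratio * hdx else 0)
  }

  start <- scramble_start(config)
  R <- start$rotation; t <- start$translation
  cur <- eval_pose(R, t)
  n <- config$steps
  sur_v <- hdx_v <- tot_v <- numeric(n + 1L)
  acc_v <- logical(n + 1L)
  sur_v[1] <- cur[["sur"]]; hdx_v[1] <- cur[["hdx"]]
  tot_v[1] <- cur[["total"]]; acc_v[1] <- TRUE
  poses <- if (keep_poses) vector("list", n + 1L)
  if (keep_poses) poses[[1]] <- list(rotation = R, translation = t)
  if (n > 0) for (i in seq_len(n)) {
    Rp <- random_small_rotation(config$perturb_rot_sd) %*% R
    tp <- t + stats::rnorm(3, 0, config$perturb_trans_sd)
    prop <- eval_pose(Rp, tp)
    delta <- prop[["total"]] - cur[["total"]]
    accept <- delta <= 0 ||
      stats::runif(1) < exp(-delta / config$temperature)
    if (accept) { R <- Rp; t <- tp; cur <- prop }
    sur_v[i + 1L] <- cur[["sur"]]; hdx_v[i + 1L] <- cur[["hdx"]]
    tot_v[i + 1L] <- cur[["total"]]; acc_v[i + 1L] <- accept
    if (keep_poses) poses[[i + 1L]] <- list(rotation = R, translation = t)
  }
  traj <- data.frame(step = 0:n, surrogate = sur_v, hdx_penalty = hdx_v,
                     total = tot_v, accepted = acc_v)
  final_pose <- structure(
    list(rotation = R, translation = t,
         provenance = list(seed = config$seed, step = n,
                           initial_displacement =
                             start$provenance$initial_displacement)),
    class = "pose")
  out <- list(trajectory = traj, final_pose = final_pose,
              final_model = apply_pose(complex, final_pose))
  if (keep_poses) out$poses <- poses
  out
}
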