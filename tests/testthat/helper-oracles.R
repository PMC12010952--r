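# Independent brute-force oracles and small model builders. Everything
# here deliberately uses plain double loops and naive arithmetic so the
# vectorized implementation is checked against a structurally different
# computation.

# Build a structure_model from per-residue C-alpha rows
# (data frames with chain, resno, resid, x, y, z).
ca_only_model <- function(id, ab, ag) {
  mk <- function(df) data.frame(
    chain = df$chain, resno = df$resno, insert = "",
    resid = if (is.null(df$resid)) "ALA" else df$resid,
    elety = "CA", x = df$x, y = df$y, z = df$z, elesy = "C",
    is_h = FALSE, stringsAsFactors = FALSE)
  structure_model(id, rbind(mk(ab), mk(ag)),
                  unique(ab$chain), unique(ag$chain))
}

ca_row <- function(chain, resno, x, y, z, resid = "ALA") {
  data.frame(chain = chain, resno = resno, resid = resid,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

# k-th smallest per-residue minimum distance, exhaustive double loop.
oracle_kth_min_dist <- function(pep_xyz, cdr_xyz, k) {
  per_res <- numeric(nrow(pep_xyz))
  for (i in seq_len(nrow(pep_xyz))) {
    best <- Inf
    for (j in seq_len(nrow(cdr_xyz)))
      best <- min(best, euclid(pep_xyz[i, ], cdr_xyz[j, ]))
    per_res[i] <- best
  }
  sort(per_res)[min(k, length(per_res))]
}

# Interface residue keys by exhaustive atom-pair scan.
oracle_interface <- function(model, cutoff = 10) {
  at <- model$atoms[!model$atoms$is_h, , drop = FALSE]
  ab <- at[at$chain %in% model$ab_chains, , drop = FALSE]
  ag <- at[at$chain %in% model$ag_chains, , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(ab))) for (j in seq_len(nrow(ag))) {
    if (euclid(as.numeric(ab[i, c("x", "y", "z")]),
               as.numeric(ag[j, c("x", "y", "z")])) <= cutoff)
      hits <- c(hits,
                paste(ab$chain[i], ab$resno[i], ab$insert[i], sep = "|"),
                paste(ag$chain[j], ag$resno[j], ag$insert[j], sep = "|"))
  }
  sort(unique(hits))
}

# Inter-partner residue contact pairs (< cutoff), exhaustive.
oracle_contacts <- function(model, cutoff = 5) {
  at <- model$atoms[!model$atoms$is_h, , drop = FALSE]
  ab <- at[at$chain %in% model$ab_chains, , drop = FALSE]
  ag <- at[at$chain %in% model$ag_chains, , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(ab))) for (j in seq_len(nrow(ag))) {
    if (euclid(as.numeric(ab[i, c("x", "y", "z")]),
               as.numeric(ag[j, c("x", "y", "z")])) < cutoff)
      hits <- c(hits, paste(
        paste(ab$chain[i], ab$resno[i], ab$insert[i], sep = "|"),
        paste(ag$chain[j], ag$resno[j], ag$insert[j], sep = "|"),
        sep = "::"))
  }
  unique(hits)
}

oracle_fnat <- function(model, reference, cutoff = 5) {
  ref <- oracle_contacts(reference, cutoff)
  mod <- oracle_contacts(model, cutoff)
  sum(ref %in% mod) / length(ref)
}

# Two-sample KS D by scanning the pooled support.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  d <- 0
  for (g in grid)
    d <- max(d, abs(mean(a <= g) - mean(b <= g)))
  d
}

# Coarse clash/contact score by exhaustive pair counting.
oracle_surrogate <- function(model) {
  at <- model$atoms
  ca <- at[at$elety == "CA" & !at$is_h, , drop = FALSE]
  ab <- ca[ca$chain %in% model$ab_chains, , drop = FALSE]
  ag <- ca[ca$chain %in% model$ag_chains, , drop = FALSE]
  s <- 0
  for (i in seq_len(nrow(ab))) for (j in seq_len(nrow(ag))) {
    d <- euclid(as.numeric(ab[i, c("x", "y", "z")]),
                as.numeric(ag[j, c("x", "y", "z")]))
    if (d < 3.5) s <- s + 10 else if (d < 8) s <- s - 1
  }
  s
}

# CAPRI class by an independent formulation: the final class is the
# worse of the fnat-implied class and the better of the two RMSD-implied
# classes.
oracle_capri <- function(fnat, lrmsd, irmsd) {
  lev <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  fnat_cls <- if (fnat >= 0.5) 3 else if (fnat >= 0.3) 2 else
    if (fnat >= 0.1) 1 else 0
  l_cls <- if (lrmsd <= 1) 3 else if (lrmsd <= 5) 2 else
    if (lrmsd <= 10) 1 else 0
  i_cls <- if (irmsd <= 1) 3 else if (irmsd <= 2) 2 else
    if (irmsd <= 4) 1 else 0
  names(lev)[lev == min(fnat_cls, max(l_cls, i_cls))]
}

# Best rigid-fit RMSD by direct numerical minimization over a rotation
# vector (translation profiled out by centering); several starts.
oracle_min_rmsd <- function(mobile, target, n_starts = 8) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  tc <- sweep(target, 2, colMeans(target))
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    u <- v / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) sqrt(mean(rowSums((mc %*% t(rot(v)) - tc)^2)))
  best <- Inf
  starts <- c(list(c(0, 0, 0)),
              lapply(seq_len(n_starts), function(i) stats::runif(3, -pi, pi)))
  for (s in starts) {
    o <- stats::optim(s, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
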