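# CAPRI-style quality metrics, superposition, enrichment and the KS
# comparison.

test_that("interface membership follows the 10 Angstrom heavy-atom rule", {
  near <- ca_only_model("1", ca_row("H", 1, 0, 0, 9),
                        ca_row("A", 1, 0, 0, 0))
  expect_setequal(interface_residues(near), c("A|1|", "H|1|"))
  far <- ca_only_model("1", ca_row("H", 1, 0, 0, 11),
                       ca_row("A", 1, 0, 0, 0))
  expect_length(interface_residues(far), 0)
})

test_that("interface residues match the exhaustive all-pairs oracle", {
  toy <- make_toy_complex(seed = 61)
  expect_identical(interface_residues(toy$reference),
                   oracle_interface(toy$reference))
})

test_that("superposition removes rigid motion and matches a numerical minimizer", {
  set.seed(23)
  pts <- matrix(rnorm(30, 0, 5), ncol = 3)
  expect_equal(superpose_rmsd(pts, pts)$rmsd, 0, tolerance = 1e-9)
  shifted <- sweep(pts, 2, c(5, 5, 5), "+")
  expect_equal(superpose_rmsd(pts, shifted)$rmsd, 0, tolerance = 1e-9)

  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  noisy <- pts %*% t(Rz) + matrix(rnorm(30, 0, 0.5), ncol = 3)
  fit <- superpose_rmsd(pts, noisy)
  expect_equal(fit$rmsd, oracle_min_rmsd(pts, noisy), tolerance = 1e-4)
  # returned transform reproduces the reported RMSD and is proper
  applied <- pts %*% t(fit$rotation) +
    matrix(fit$translation, nrow(pts), 3, byrow = TRUE)
  expect_equal(sqrt(mean(rowSums((applied - noisy)^2))), fit$rmsd)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # cross-check against bio3d's least-squares fitting
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(noisy)),
                   mobile = as.numeric(t(pts))))
  expect_equal(fit$rmsd,
               sqrt(mean(colSums(matrix(fitted - as.numeric(t(noisy)),
                                        nrow = 3)^2))),
               tolerance = 1e-6)
  expect_error(superpose_rmsd(pts, pts[1:5, ]), "equal-size")
})

test_that("a model identical to the reference is high quality by construction", {
  toy <- make_toy_complex(seed = 41)
  q <- compute_quality(toy$reference, toy$reference)
  expect_equal(q$fnat, 1)
  expect_equal(q$lrmsd, 0, tolerance = 1e-9)
  expect_equal(q$irmsd, 0, tolerance = 1e-9)
  expect_equal(q$capri_class, "high")
})

test_that("fnat matches the exhaustive contact oracle on perturbed decoys", {
  toy <- make_toy_complex(seed = 43)
  ens <- make_decoy_ensemble(toy$reference, n_decoys = 6, seed = 44,
                             max_disp = 8)
  for (m in ens$models) {
    q <- compute_quality(m, toy$reference)
    expect_equal(q$fnat, oracle_fnat(m, toy$reference))
  }
})

test_that("CAPRI classification reproduces the published threshold table", {
  expect_equal(compute_quality(
    make_toy_complex(seed = 2)$reference,
    make_toy_complex(seed = 2)$reference)$capri_class, "high")
  cases <- list(
    list(0.35, 6.0, 1.5, "medium"),
    list(0.05, 0.5, 0.5, "incorrect"),
    list(0.6, 0.5, 0.5, "high"),
    list(0.6, 8, 3, "acceptable"),
    list(0.3, 1.0, 5.0, "medium"),
    list(0.1, 10, 12, "acceptable"),
    list(0.5, 1.0, 9, "high"),
    list(0.12, 12, 4.0, "acceptable"),
    list(0.12, 12, 4.01, "incorrect"))
  for (cs in cases)
    expect_equal(hdxdock:::capri_class(cs[[1]], cs[[2]], cs[[3]]),
                 cs[[4]])
  # dense boundary grid against the independent formulation
  grid <- expand.grid(fnat = c(0.05, 0.1, 0.3, 0.5, 0.8),
                      lrmsd = c(0.5, 1, 2, 4, 5, 10, 11),
                      irmsd = c(0.5, 1, 2, 4, 5, 10))
  for (i in seq_len(nrow(grid)))
    expect_equal(
      hdxdock:::capri_class(grid$fnat[i], grid$lrmsd[i], grid$irmsd[i]),
      oracle_capri(grid$fnat[i], grid$lrmsd[i], grid$irmsd[i]))
})

test_that("iRMSD and L-RMSD are invariant under rigid motion of the model", {
  toy <- make_toy_complex(seed = 45)
  ens <- make_decoy_ensemble(toy$reference, n_decoys = 3, seed = 46)
  m <- ens$models[[2]]
  q1 <- compute_quality(m, toy$reference)
  R <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  moved <- m
  moved$atoms[, c("x", "y", "z")] <- sweep(
    as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R), 2, c(3, -9, 17), "+")
  q2 <- compute_quality(moved, toy$reference)
  expect_equal(q2$irmsd, q1$irmsd, tolerance = 1e-6)
  expect_equal(q2$lrmsd, q1$lrmsd, tolerance = 1e-6)
  expect_equal(q2$fnat, q1$fnat)
})

test_that("enrichment spans its analytic extremes and bounds", {
  irmsd <- runif(200, 0, 25)
  perfect <- enrichment(irmsd, irmsd)
  expect_equal(perfect$enrichment, 10)
  reversed <- enrichment(-irmsd, irmsd)
  expect_equal(reversed$enrichment, 0)
  expect_equal(perfect$P + perfect$N, 200L)
  expect_equal(perfect$TP + perfect$FP, perfect$P)
  expect_error(enrichment(1:5, 1:5), "at least 10")
})

test_that("KS statistic equals the exhaustive ECDF scan", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$D, 1)
  set.seed(33)
  a <- rnorm(500, 5, 2)
  b <- rnorm(500, 6.5, 2)
  ks <- ks_two_sample(a, b)
  expect_equal(ks$D, oracle_ks_D(a, b), tolerance = 1e-12)
  expect_lt(ks$p_value, 0.001)
})

test_that("near-native calls and docking success follow the top-10 rule", {
  expect_true(is_near_native("acceptable"))
  expect_true(is_near_native("high"))
  expect_false(is_near_native("incorrect"))
  toy <- make_toy_complex(seed = 47)
  ens <- make_decoy_ensemble(toy$reference, n_decoys = 30, seed = 48,
                             score_noise_sd = 0)
  quality <- evaluate_ensemble(ens$models, toy$reference)
  rows <- rescore_ensemble(score_rows(names(ens$scores), ens$scores,
                                      0))
  # perfect score-quality correlation: the top 10 hold the best decoys
  expect_true(docking_success(quality, rows))
})
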