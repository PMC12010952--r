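# Flat-harmonic restraint penalties from peptide-CDR C-alpha geometry.

test_that("flat harmonic is zero inside the threshold and squared outside", {
  expect_equal(flat_harmonic(7.2, 10), 0)
  expect_equal(flat_harmonic(10, 10), 0)
  expect_equal(flat_harmonic(12, 10), 4)
  expect_equal(flat_harmonic(c(0, 5, 10, 11, 15), 10),
               c(0, 0, 0, 1, 25))
  expect_error(flat_harmonic(5, 0), "d must be")
  expect_error(flat_harmonic(-1, 10), "non-negative")
})

test_that("single-pair geometry gives the plain Euclidean distance", {
  m <- ca_only_model("1",
                     ca_row("H", 1, 0, 0, 6),
                     ca_row("A", 1, 0, 0, 0))
  pep <- list(label = "p", chain = "A", start = 1, end = 1)
  cdrs <- list(list(chain = "H", start = 1, end = 1))
  expect_equal(peptide_effective_distance(m, pep, cdrs), 6)
})

test_that("an all-proline peptide has no eligible residues", {
  m <- ca_only_model("1",
                     ca_row("H", 1, 0, 0, 6),
                     ca_row("A", 1, 0, 0, 0, resid = "PRO"))
  pep <- list(label = "pro-pep", chain = "A", start = 1, end = 1)
  cdrs <- list(list(chain = "H", start = 1, end = 1))
  expect_error(peptide_effective_distance(m, pep, cdrs), "pro-pep")
  # with exclusion off the proline counts
  expect_equal(
    peptide_effective_distance(m, pep, cdrs,
                               restraint_spec(exclude_proline = FALSE)),
    6)
})

test_that("k-th smallest per-residue minimum matches the brute-force oracle", {
  set.seed(71)
  for (rep in 1:5) {
    pep_xyz <- matrix(runif(20 * 3, 0, 40), ncol = 3)
    cdr_xyz <- matrix(runif(30 * 3, 0, 40), ncol = 3)
    ab <- do.call(rbind, lapply(1:30, function(i)
      ca_row("H", i, cdr_xyz[i, 1], cdr_xyz[i, 2], cdr_xyz[i, 3])))
    ag <- do.call(rbind, lapply(1:20, function(i)
      ca_row("A", i, pep_xyz[i, 1], pep_xyz[i, 2], pep_xyz[i, 3])))
    m <- ca_only_model("r", ab, ag)
    pep <- list(label = "p", chain = "A", start = 1, end = 20)
    cdrs <- list(list(chain = "H", start = 1, end = 30))
    for (k in 1:3)
      expect_equal(
        peptide_effective_distance(m, pep, cdrs, restraint_spec(k = k)),
        oracle_kth_min_dist(pep_xyz, cdr_xyz, k))
  }
})

test_that("model penalty is the sum of per-peptide flat harmonics", {
  # two single-residue peptides at controlled distances 12 and 13
  ab <- ca_row("H", 1, 0, 0, 0)
  ag <- rbind(ca_row("A", 1, 12, 0, 0), ca_row("A", 5, 0, 13, 0))
  m <- ca_only_model("1", ab, ag)
  cdrs <- list(list(chain = "H", start = 1, end = 1))
  peps <- list(list(label = "a", chain = "A", start = 1, end = 1),
               list(label = "b", chain = "A", start = 5, end = 5))
  mp <- model_hdx_penalty(m, peps, cdrs)
  expect_equal(mp$total, 13)  # 4 + 9
  expect_equal(mp$peptides$penalty, c(4, 9))
  expect_equal(mp$total, sum(mp$peptides$penalty))
})

test_that("ensemble penalties match brute-force recomputation from coordinates", {
  toy <- make_toy_complex(seed = 11, allosteric_gaps = 30)
  ens <- make_decoy_ensemble(toy$reference, n_decoys = 25, seed = 12)
  cfg <- toy$config
  pen <- hdx_penalty_matrix(ens$models, cfg$hdx_peptides, cfg$cdrs,
                            cfg$restraint)
  for (i in seq_along(ens$models)) {
    at <- ens$models[[i]]$atoms
    ca <- at[at$elety == "CA", , drop = FALSE]
    for (p in cfg$hdx_peptides) {
      sel <- ca$chain == p$chain & ca$resno >= p$start &
        ca$resno <= p$end & ca$resid != "PRO"
      cdr_sel <- rep(FALSE, nrow(ca))
      for (s in cfg$cdrs)
        cdr_sel <- cdr_sel | (ca$chain == s$chain & ca$resno >= s$start &
                                ca$resno <= s$end)
      d <- oracle_kth_min_dist(as.matrix(ca[sel, c("x", "y", "z")]),
                               as.matrix(ca[cdr_sel, c("x", "y", "z")]),
                               cfg$restraint$k)
      expect_equal(pen[i, p$label],
                   max(d - cfg$restraint$d, 0)^2,
                   ignore_attr = TRUE)
    }
  }
})

test_that("satisfied restraints give exactly zero total penalty", {
  toy <- make_toy_complex(seed = 3)   # interacting peptides only
  mp <- model_hdx_penalty(toy$reference, toy$config$hdx_peptides,
                          toy$config$cdrs, toy$config$restraint)
  expect_identical(mp$total, 0)
})

test_that("stringency grid orders penalties monotonically", {
  toy <- make_toy_complex(seed = 21, allosteric_gaps = 30)
  ens <- make_decoy_ensemble(toy$reference, n_decoys = 15, seed = 22)
  cfg <- toy$config
  total_under <- function(d, k) {
    sum(hdx_penalty_matrix(ens$models, cfg$hdx_peptides, cfg$cdrs,
                           restraint_spec(d = d, k = k)))
  }
  by_d <- vapply(c(5, 8, 10), total_under, numeric(1), k = 1)
  expect_true(by_d[1] >= by_d[2] && by_d[2] >= by_d[3])
  by_k <- vapply(1:3, function(k) total_under(10, k), numeric(1))
  expect_true(by_k[3] >= by_k[2] && by_k[2] >= by_k[1])
})

test_that("penalties are invariant under rigid motion of the whole complex", {
  toy <- make_toy_complex(seed = 31, allosteric_gaps = 30)
  cfg <- toy$config
  before <- model_hdx_penalty(toy$reference, cfg$hdx_peptides, cfg$cdrs,
                              cfg$restraint)
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 degrees about z
  moved <- toy$reference
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <-
    sweep(xyz %*% t(R), 2, c(11, -7, 3), "+")
  after <- model_hdx_penalty(moved, cfg$hdx_peptides, cfg$cdrs,
                             cfg$restraint)
  expect_equal(after$total, before$total, tolerance = 1e-6)
  expect_equal(after$peptides$penalty, before$peptides$penalty,
               tolerance = 1e-6)
})

test_that("percent normalization scales to the observed maximum", {
  expect_equal(percent_normalize(c(0, 5, 10)), c(0, 50, 100))
  expect_equal(percent_normalize(c(0, 0, 0)), c(0, 0, 0))
  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(2:50, 1), 0, 100)
    out <- percent_normalize(v)
    expect_equal(max(out), 100)
    expect_equal(out, 100 * v / max(v))
  }
})
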