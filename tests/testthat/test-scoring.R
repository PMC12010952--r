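# HDX normalization against the interface-score range and combined
# ranking.

test_that("trimmed extremes average the outer ceil(10%) of values", {
  expect_equal(trimmed_extremes(1:10), c(low = 1, high = 10))
  expect_equal(trimmed_extremes(1:20), c(low = 1.5, high = 19.5))
  set.seed(9)
  v <- rnorm(137, 0, 30)
  s <- sort(v)
  m <- ceiling(0.1 * 137)
  expect_equal(trimmed_extremes(v),
               c(low = mean(s[1:m]), high = mean(rev(s)[1:m])))
})

test_that("normalization reproduces the scale formula on a 20-model table", {
  set.seed(17)
  iface <- runif(20, -30, -5)
  raw <- runif(20, 0, 50)
  rows <- normalize_hdx_scores(score_rows(sprintf("m%02d", 1:20),
                                          iface, raw))
  ie <- trimmed_extremes(iface)
  he <- trimmed_extremes(raw)
  scale <- (ie[["high"]] - ie[["low"]]) / (he[["high"]] - he[["low"]])
  expect_equal(rows$hdx_normalized, scale * raw)
  expect_equal(attr(rows, "hdx_scale"), scale)
  # linearity: scaling all interface scores by c > 0 scales the output
  rows2 <- normalize_hdx_scores(score_rows(sprintf("m%02d", 1:20),
                                           3 * iface, raw))
  expect_equal(rows2$hdx_normalized, 3 * rows$hdx_normalized)
})

test_that("a degenerate HDX range normalizes to zero with a log note", {
  rows <- score_rows(c("a", "b", "c"), c(-10, -20, -30), c(7, 7, 7))
  expect_message(out <- normalize_hdx_scores(rows), "degenerate")
  expect_equal(out$hdx_normalized, c(0, 0, 0))
  expect_true(is.na(attr(out, "hdx_scale")))
  zero <- score_rows(c("a", "b", "c"), c(-10, -20, -30), 0)
  expect_equal(suppressMessages(
    normalize_hdx_scores(zero))$hdx_normalized, c(0, 0, 0))
})

test_that("combined score arithmetic and limits follow the formula", {
  rows <- score_rows("m1", -20)
  rows$hdx_normalized <- 2
  out <- combine_scores(rows, weight = 4.5)
  expect_equal(out$combined, -11)
  expect_equal(out$hdx_weighted, 9)
  # weight 0 collapses to the base score; zero HDX keeps base ranking
  set.seed(2)
  tab <- score_rows(sprintf("m%02d", 1:15), rnorm(15, -20, 5),
                    runif(15, 0, 30))
  tab <- normalize_hdx_scores(tab)
  w0 <- combine_scores(tab, weight = 0)
  expect_equal(w0$combined, w0$interface_score)
  tab0 <- tab; tab0$hdx_normalized <- 0
  expect_equal(combine_scores(tab0)$rank,
               rank(tab0$interface_score, ties.method = "first"))
})

test_that("ranking is deterministic under ties and stable under shifts", {
  rows <- score_rows(c("zeta", "alpha"), c(-5, -5), c(0, 0))
  rows$hdx_normalized <- 0
  out <- combine_scores(rows)
  expect_equal(out$rank[out$model_id == "alpha"], 1L)
  # adding a constant to all interface scores leaves ranks unchanged
  set.seed(4)
  tab <- score_rows(sprintf("m%02d", 1:25), rnorm(25, -20, 4),
                    runif(25, 0, 40))
  r1 <- rescore_ensemble(tab)
  tab2 <- tab; tab2$interface_score <- tab2$interface_score + 100
  r2 <- suppressMessages(rescore_ensemble(tab2))
  expect_equal(r1$rank, r2$rank)
})

test_that("extreme weights converge to HDX-only or base-only selection", {
  set.seed(8)
  tab <- score_rows(sprintf("m%03d", 1:60), rnorm(60, -20, 4),
                    runif(60, 0, 40))
  tab <- normalize_hdx_scores(tab)
  huge <- select_top_n(combine_scores(tab, weight = 1e9), 10)
  expect_setequal(huge$model_id,
                  tab$model_id[order(tab$hdx_raw)][1:10])
  none <- select_top_n(combine_scores(tab, weight = 0), 10)
  expect_setequal(none$model_id,
                  tab$model_id[order(tab$interface_score)][1:10])
})

test_that("combine_scores is idempotent and select_top_n handles short tables", {
  set.seed(12)
  tab <- rescore_ensemble(score_rows(sprintf("m%02d", 1:12),
                                     rnorm(12, -20, 4), runif(12, 0, 9)))
  again <- combine_scores(tab, weight = 4.5)
  expect_equal(again$combined, tab$combined)
  top <- select_top_n(tab, 10)
  expect_equal(nrow(top), 10)
  expect_true(all(diff(top$combined) >= 0))
  expect_message(short <- select_top_n(tab[1:7, ], 10), "only 7")
  expect_equal(nrow(short), 7)
})

test_that("the weight sweep tracks selection quality on a decoy ensemble", {
  toy <- make_toy_complex(seed = 51, allosteric_gaps = 30)
  ens <- make_decoy_ensemble(toy$reference, n_decoys = 60, seed = 52)
  pen <- hdx_penalty_matrix(ens$models, toy$config$hdx_peptides,
                            toy$config$cdrs, toy$config$restraint)
  rows <- score_rows(rownames(pen), ens$scores[rownames(pen)],
                     rowSums(pen))
  quality <- setNames(ens$truth$irmsd, ens$truth$model_id)
  sweep <- sweep_hdx_weight(rows, weights = c(0.5, 4.5, 15), n = 10,
                            quality = quality)
  expect_equal(nrow(sweep), 3)
  expect_true(all(is.finite(sweep$mean_quality)))
})
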