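# Detection of allosteric peptides: antigen peptides with a genuine HDX
# protection signal that lie away from the actual epitope. A restraint set
# containing one misguides scoring; the tell-tale is a top-10 mean
# weighted HDX score that stays high. The offending peptide is the one
# whose leave-one-out exclusion (with full renormalization and
# re-selection) drops that mean the most.

# Rescore an ensemble from a per-peptide penalty matrix restricted to a
# peptide subset; returns the ranked score rows.
#' @noRd
rescore_subset <- function(penalties, interface_score, include, weight,
                           fraction = 0.10) {
  raw <- if (length(include) == 0L) rep(0, nrow(penalties))
  else rowSums(penalties[, include, drop = FALSE])
  rows <- score_rows(rownames(penalties), interface_score, raw)
  suppressMessages(rescore_ensemble(rows, weight, fraction))
}

#' Mean weighted HDX score of the current top-n models
#'
#' @param rows ranked score-row data frame.
#' @param n top-n size (default 10).
#' @return Arithmetic mean of \code{hdx_weighted} over the top n.
#' @export
mean_weighted_hdx <- function(rows, n = 10L) {
  if (nrow(rows) == 0L) stop("empty ensemble")
  mean(select_top_n(rows, n)$hdx_weighted)
}

#' Leave-one-out exclusion scan over the HDX peptide set
#'
#' For each peptide, its penalty column is dropped, the raw totals are
#' recomputed, the normalization is redone on the reduced totals, models
#' are re-ranked by the new combined score and the mean weighted HDX
#' score of the new top-n is reported. The peptide minimizing this value
#' is the allosteric candidate.
#'
#' @param penalties per-model, per-peptide penalty matrix
#'   (\code{\link{hdx_penalty_matrix}}); row names = model ids, column
#'   names = peptide labels.
#' @param interface_score named or positional numeric vector of base
#'   scores aligned with the matrix rows.
#' @param weight HDX weight (default 4.5).
#' @param n top-n size (default 10).
#' @param include peptide labels forming the active set (default: all
#'   columns).
#' @return Data frame: \code{excluded}, \code{mean_weighted_hdx}, ordered
#'   as the active set.
#' @export
loo_exclusion_scan <- function(penalties, interface_score, weight = 4.5,
                               n = 10L, include = colnames(penalties)) {
  if (length(include) < 2L)
    stop("need at least 2 peptides to run an exclusion scan")
  vals <- vapply(include, function(p) {
    rows <- rescore_subset(penalties, interface_score,
                           setdiff(include, p), weight)
    mean_weighted_hdx(rows, n)
  }, numeric(1))
  data.frame(excluded = include, mean_weighted_hdx = unname(vals),
             stringsAsFactors = FALSE)
}

#' Iterative allosteric-peptide detection
#'
#' The ensemble is scored with the full peptide set; if the top-n mean
#' weighted HDX score exceeds \code{threshold} the dataset is flagged and
#' leave-one-out scans peel off the argmin peptide one at a time until
#' the mean falls to the threshold or fewer than 2 peptides remain.
#'
#' @inheritParams loo_exclusion_scan
#' @param threshold flag threshold on the top-n mean weighted HDX score
#'   (default 0.75).
#' @return An \code{allostery_report}: list with
#'   \code{mean_weighted_hdx} (initial), \code{flagged},
#'   \code{predicted_allosteric} (labels in detection order),
#'   \code{final_mean} (after all exclusions), \code{iterations} and
#'   \code{scan} (list of per-iteration scan tables).
#' @export
detect_allosteric_iterative <- function(penalties, interface_score,
                                        weight = 4.5, threshold = 0.75,
                                        n = 10L) {
  if (ncol(penalties) < 2L)
    stop("need at least 2 peptides; with 1, exclusion would empty ",
         "the restraint set")
  active <- colnames(penalties)
  initial <- mean_weighted_hdx(
    rescore_subset(penalties, interface_score, active, weight), n)
  flagged <- initial > threshold
  predicted <- character(0)
  scans <- list()
  current <- initial
  while (current > threshold && length(active) >= 2L) {
    scan <- loo_exclusion_scan(penalties, interface_score, weight, n,
                               include = active)
    pick <- scan$excluded[which.min(scan$mean_weighted_hdx)]
    predicted <- c(predicted, pick)
    scans[[length(scans) + 1L]] <- scan
    active <- setdiff(active, pick)
    current <- min(scan$mean_weighted_hdx)
  }
  structure(list(mean_weighted_hdx = initial, flagged = flagged,
                 predicted_allosteric = predicted, final_mean = current,
                 iterations = length(predicted), scan = scans,
                 threshold = threshold),
            class = "allostery_report")
}

#' @export
print.allostery_report <- function(x, ...) {
  cat("allostery_report: top-n mean weighted HDX =",
      format(x$mean_weighted_hdx, digits = 4),
      if (x$flagged) "(flagged)" else "(not flagged)", "\n")
  if (length(x$predicted_allosteric))
    cat("predicted allosteric peptide(s):",
        paste(x$predicted_allosteric, collapse = ", "),
        "| final mean =", format(x$final_mean, digits = 4), "\n")
  invisible(x)
}
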