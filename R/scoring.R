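# Combined HDX + interface-energy model selection. The raw HDX penalty is
# rescaled so its trimmed range matches the trimmed range of the base
# interface score, weighted (default 4.5) and added to the interface
# score; models are then ranked ascending (lower = better, interface
# scores being negative-favorable).

#' Assemble a score-row table
#'
#' @param model_id character vector of model ids (unique).
#' @param interface_score base interface energies (REU, lower = better).
#' @param hdx_raw raw HDX penalty totals (squared Angstrom,
#'   non-negative); default all zero.
#' @return Data frame with the full score-row columns, unfilled derived
#'   columns set to \code{NA}.
#' @export
score_rows <- function(model_id, interface_score, hdx_raw = 0) {
  model_id <- as.character(model_id)
  if (anyDuplicated(model_id)) stop("duplicate model_id")
  n <- length(model_id)
  if (length(interface_score) != n) stop("length mismatch")
  if (!all(is.finite(interface_score))) stop("non-finite interface score")
  hdx_raw <- rep_len(hdx_raw, n)
  if (any(hdx_raw < 0)) stop("hdx_raw must be non-negative")
  data.frame(model_id = model_id, interface_score = interface_score,
             hdx_raw = hdx_raw, hdx_normalized = NA_real_,
             hdx_weighted = NA_real_, combined = NA_real_,
             rank = NA_integer_, stringsAsFactors = FALSE)
}

#' Trimmed extremes of a numeric vector
#'
#' Means of the lowest and highest \code{ceiling(fraction * N)} values
#' (at least one each), the quantities entering the HDX normalization.
#'
#' @param values numeric vector.
#' @param fraction tail fraction (default 0.10).
#' @return Named numeric vector \code{c(low = , high = )}.
#' @export
trimmed_extremes <- function(values, fraction = 0.10) {
  if (length(values) == 0L) stop("empty value list")
  s <- sort(values)
  m <- max(1L, ceiling(fraction * length(values)))
  c(low = mean(s[seq_len(m)]), high = mean(s[length(s) - m + seq_len(m)]))
}

#' Normalize raw HDX penalties against the interface-score range
#'
#' The scale factor is the ratio of trimmed ranges,
#' \code{(interface_high - interface_low) / (hdx_high - hdx_low)}, and
#' each normalized value is \code{scale * hdx_raw}. When every raw penalty
#' is (trimmed-)identical the scale is undefined and all normalized values
#' are set to zero, so the combined score reduces to the base score.
#'
#' @param rows score-row data frame (\code{\link{score_rows}}).
#' @param fraction tail fraction for \code{\link{trimmed_extremes}}.
#' @return \code{rows} with \code{hdx_normalized} filled; the scale is
#'   attached as attribute \code{"hdx_scale"} (\code{NA} when degenerate).
#' @export
normalize_hdx_scores <- function(rows, fraction = 0.10) {
  if (nrow(rows) < 2L) stop("need at least 2 rows to normalize")
  iface <- trimmed_extremes(rows$interface_score, fraction)
  hdx <- trimmed_extremes(rows$hdx_raw, fraction)
  if (hdx["high"] == hdx["low"]) {
    message("degenerate HDX range (all penalties equal); ",
            "normalized scores set to 0, scale undefined")
    rows$hdx_normalized <- 0
    attr(rows, "hdx_scale") <- NA_real_
    return(rows)
  }
  scale <- (iface[["high"]] - iface[["low"]]) / (hdx[["high"]] - hdx[["low"]])
  rows$hdx_normalized <- scale * rows$hdx_raw
  attr(rows, "hdx_scale") <- scale
  rows
}

#' Combine HDX and interface scores and rank the ensemble
#'
#' \code{combined = weight * hdx_normalized + interface_score}; ranks are
#' ascending by combined score with ties broken lexicographically by
#' model id for cross-platform reproducibility.
#'
#' @param rows score-row data frame with \code{hdx_normalized} filled.
#' @param weight HDX weight (default 4.5).
#' @return \code{rows} with \code{hdx_weighted}, \code{combined} and
#'   \code{rank} filled.
#' @export
combine_scores <- function(rows, weight = 4.5) {
  if (any(is.na(rows$hdx_normalized)))
    stop("hdx_normalized not filled; run normalize_hdx_scores() first")
  rows$hdx_weighted <- weight * rows$hdx_normalized
  rows$combined <- rows$hdx_weighted + rows$interface_score
  rows$rank <- NA_integer_
  rows$rank[order(rows$combined, rows$model_id)] <- seq_len(nrow(rows))
  rows
}

#' Select the top-n models by rank
#'
#' @param rows ranked score-row data frame.
#' @param n number of models to keep (default 10).
#' @return The first \code{min(n, N)} rows ordered by rank.
#' @export
select_top_n <- function(rows, n = 10L) {
  if (any(is.na(rows$rank))) stop("rows are not ranked; run combine_scores()")
  if (nrow(rows) < n)
    message("ensemble has only ", nrow(rows), " models (< n = ", n, ")")
  rows[order(rows$rank), , drop = FALSE][seq_len(min(n, nrow(rows))), ,
                                         drop = FALSE]
}

#' One-call rescoring pipeline
#'
#' Normalizes, combines and ranks in one step.
#'
#' @inheritParams normalize_hdx_scores
#' @inheritParams combine_scores
#' @return Ranked score-row data frame.
#' @export
rescore_ensemble <- function(rows, weight = 4.5, fraction = 0.10) {
  combine_scores(normalize_hdx_scores(rows, fraction), weight)
}

#' Sweep the HDX weight over a grid
#'
#' Re-runs the combination at each weight and summarizes the top-n
#' selection, the harness used to examine weight sensitivity on synthetic
#' ensembles (grid default 0.5 to 15 in 0.5 steps).
#'
#' @param rows score-row data frame (normalization is done once).
#' @param weights numeric grid of weights.
#' @param n top-n size.
#' @param quality optional named numeric vector (e.g. iRMSD per model id)
#'   averaged over the selected models at each weight.
#' @return Data frame: weight, mean combined score, mean hdx_raw of the
#'   top n, and mean quality when supplied.
#' @export
sweep_hdx_weight <- function(rows, weights = seq(0.5, 15, by = 0.5),
                             n = 10L, quality = NULL) {
  rows <- normalize_hdx_scores(rows)
  out <- lapply(weights, function(w) {
    top <- select_top_n(combine_scores(rows, w), n)
    data.frame(weight = w,
               mean_combined = mean(top$combined),
               mean_hdx_raw = mean(top$hdx_raw),
               mean_quality = if (is.null(quality)) NA_real_
               else mean(quality[top$model_id]))
  })
  do.call(rbind, out)
}
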