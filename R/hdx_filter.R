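# Significance filter for differential deuterium-uptake time courses:
# classify antigen peptides as HDX-interacting when bound-state protection
# passes both a per-timepoint gate (>= 0.5 Da and >= 3 pooled SDs) and a
# cumulative gate (> 1.1 Da summed over all exposure times).

#' Build a per-peptide uptake record
#'
#' @param label peptide label.
#' @param chain antigen chain id.
#' @param start,end residue span (inclusive, author numbering).
#' @param time_s exposure times in seconds, strictly increasing.
#' @param unbound_mean,bound_mean mean uptake (Da) per timepoint.
#' @param unbound_sd,bound_sd per-state SDs (Da), non-negative.
#' @return An \code{uptake_record}.
#' @export
uptake_record <- function(label, chain, start, end, time_s,
                          unbound_mean, bound_mean,
                          unbound_sd = 0, bound_sd = 0) {
  nt <- length(time_s)
  unbound_sd <- rep_len(unbound_sd, nt); bound_sd <- rep_len(bound_sd, nt)
  if (length(unbound_mean) != nt || length(bound_mean) != nt)
    stop("peptide ", label, ": per-timepoint arrays have unequal length")
  if (nt > 1 && any(diff(time_s) <= 0))
    stop("peptide ", label, ": times must be strictly increasing")
  if (any(unbound_sd < 0) || any(bound_sd < 0))
    stop("peptide ", label, ": negative SD")
  structure(list(label = as.character(label), chain = as.character(chain),
                 start = as.integer(start), end = as.integer(end),
                 time_s = as.numeric(time_s),
                 unbound_mean = as.numeric(unbound_mean),
                 bound_mean = as.numeric(bound_mean),
                 unbound_sd = unbound_sd, bound_sd = bound_sd),
            class = "uptake_record")
}

#' Read a long-format uptake table
#'
#' One row per peptide-timepoint with columns \code{label}, \code{chain},
#' \code{start}, \code{end}, \code{time_s}, \code{unbound_mean},
#' \code{unbound_sd}, \code{bound_mean}, \code{bound_sd}.
#'
#' @param path TSV/CSV file.
#' @return List of \code{uptake_record}.
#' @export
read_uptake_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("label", "chain", "start", "end", "time_s",
            "unbound_mean", "unbound_sd", "bound_mean", "bound_sd")
  if (!all(need %in% names(df)))
    stop("uptake table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$label)[unique(df$label)], function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    uptake_record(g$label[1], g$chain[1], g$start[1], g$end[1], g$time_s,
                  g$unbound_mean, g$bound_mean, g$unbound_sd, g$bound_sd)
  })
}

#' Write uptake records to a long-format TSV
#'
#' @param records list of \code{uptake_record}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_uptake_table <- function(records, path) {
  rows <- lapply(records, function(r)
    data.frame(label = r$label, chain = r$chain, start = r$start,
               end = r$end, time_s = r$time_s,
               unbound_mean = r$unbound_mean, unbound_sd = r$unbound_sd,
               bound_mean = r$bound_mean, bound_sd = r$bound_sd))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag HDX-interacting peptides from bound/unbound uptake
#'
#' Protection is \code{diff_t = unbound_mean_t - bound_mean_t} (positive
#' when binding protects). A peptide is interacting iff some timepoint has
#' \code{diff_t >= diff_min} and \code{diff_t >= sd_mult * pooled_sd_t}
#' (pooled SD = quadrature sum of the two state SDs), and the signed
#' cumulative difference over all timepoints exceeds \code{cum_min}.
#' Deprotection (negative diffs) never contributes to flagging.
#'
#' @param records list of \code{uptake_record}.
#' @param diff_min per-timepoint difference gate in Da (default 0.5).
#' @param sd_mult SD multiplier (default 3.0).
#' @param cum_min cumulative difference gate in Da (default 1.1, strict).
#' @return Data frame: label, chain, start, end, interacting, max_diff,
#'   cumulative_diff, n_significant_timepoints.
#' @export
flag_interacting_peptides <- function(records, diff_min = 0.5,
                                      sd_mult = 3.0, cum_min = 1.1) {
  rows <- lapply(records, function(r) {
    diffs <- r$unbound_mean - r$bound_mean
    pooled <- sqrt(r$unbound_sd^2 + r$bound_sd^2)
    sig <- diffs >= diff_min & diffs >= sd_mult * pooled
    cum <- sum(diffs)
    data.frame(label = r$label, chain = r$chain, start = r$start,
               end = r$end, interacting = any(sig) && cum > cum_min,
               max_diff = max(diffs), cumulative_diff = cum,
               n_significant_timepoints = sum(sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert flagged peptides to HDX peptide entries
#'
#' @param flags data frame from \code{\link{flag_interacting_peptides}}.
#' @return List of peptides (\code{label}/\code{chain}/\code{start}/
#'   \code{end}) for the interacting subset, consumable by
#'   \code{\link{docking_config}}.
#' @export
flagged_to_peptides <- function(flags) {
  keep <- flags[flags$interacting, , drop = FALSE]
  lapply(seq_len(nrow(keep)), function(i)
    list(label = keep$label[i], chain = keep$chain[i],
         start = keep$start[i], end = keep$end[i]))
}
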