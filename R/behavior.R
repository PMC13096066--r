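#' Per-participant reaction-time condition difference
#'
#' Removes trials with reaction times above `cutoffMs` (and trials without
#' a response) and returns, per participant, the mean RT of the
#' non-predictive (50\%) condition minus the mean RT of the predictive
#' (80\%) condition. Participants missing either condition after exclusion
#' are dropped with a warning.
#'
#' @param behavior a trial table with `participant_id`, `condition` and
#'   `rt_ms` columns (see [generateRtTable()]).
#' @param cutoffMs RT exclusion cutoff in ms (default 1000).
#' @param earlyOnly restrict to early-target trials (default TRUE, matching
#'   the conditions compared in the connectivity analysis).
#' @return named numeric vector of delta RT (ms) per participant.
#' @export
rtConditionDifference <- function(behavior, cutoffMs = 1000,
                                  earlyOnly = TRUE) {
  assertPositive(cutoffMs, "cutoffMs")
  b <- behavior[!is.na(behavior$rt_ms) & behavior$rt_ms <= cutoffMs, ]
  if (earlyOnly && "target_latency" %in% names(b))
    b <- b[b$target_latency == "early", ]
  out <- vapply(split(b, b$participant_id), function(bp) {
    m50 <- bp$rt_ms[bp$condition == "nonpredictive_50"]
    m80 <- bp$rt_ms[bp$condition == "predictive_80"]
    if (!length(m50) || !length(m80)) return(NA_real_)
    mean(m50) - mean(m80)
  }, numeric(1L))
  if (anyNA(out)) {
    warning("participant(s) missing a condition excluded: ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Strongest inflow connections of a masked NDTE matrix
#'
#' Sorts the significant pairs by standardized flow (descending) and
#' returns the first k, with a deterministic tie-break by target then
#' source label.
#'
#' @param M an [NDTEMatrix-class] (or a plain matrix with NAs outside the
#'   mask).
#' @param k number of connections.
#' @return data.frame with columns `target`, `source`, `Z`, ordered.
#' @export
topKConnections <- function(M, k) {
  Z <- if (is(M, "NDTEMatrix")) flows(M) else as.matrix(M)
  if (is.null(rownames(Z)))
    dimnames(Z) <- list(paste0("R", seq_len(nrow(Z))),
                        paste0("R", seq_len(ncol(Z))))
  idx <- which(!is.na(Z) & row(Z) != col(Z), arr.ind = TRUE)
  if (k > nrow(idx))
    stop("k = ", k, " exceeds the ", nrow(idx), " available masked pairs")
  df <- data.frame(target = rownames(Z)[idx[, 1L]],
                   source = colnames(Z)[idx[, 2L]],
                   Z = Z[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$Z, df$target, df$source), ]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Correlate reaction-time differences with connection strengths
#'
#' Pearson correlation, across participants, between the per-participant
#' RT condition difference and the per-participant standardized flow of
#' each selected connection, with two-sided p-values from the t transform
#' and Benjamini-Hochberg correction across the connections. Connections
#' with zero variance (or a constant RT difference) get `r = NA`.
#'
#' @param deltas named numeric vector of per-participant RT differences.
#' @param connections participants x k matrix of per-participant connection
#'   strengths (columns = connections, e.g. from
#'   `participantFlows(ndteMatrix)` at the [topKConnections()] pairs).
#' @param q FDR level for the correction (default 0.05).
#' @return data.frame with `connection`, `r`, `p_raw`, `p_corrected`,
#'   `significant`.
#' @export
correlateRtFc <- function(deltas, connections, q = 0.05) {
  connections <- as.matrix(connections)
  n <- length(deltas)
  if (n < 3L) stop("need at least 3 participants")
  if (nrow(connections) != n)
    stop("connections must have one row per participant")
  res <- lapply(seq_len(ncol(connections)), function(j) {
    x <- connections[, j]
    if (stats::sd(deltas) == 0 || is.na(stats::sd(x)) || stats::sd(x) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(deltas, x, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  r <- vapply(res, `[[`, numeric(1L), "r")
  p <- vapply(res, `[[`, numeric(1L), "p")
  pc <- stats::p.adjust(p, method = "BH")
  data.frame(
    connection = if (!is.null(colnames(connections))) colnames(connections)
                 else paste0("conn", seq_along(r)),
    r = r, p_raw = p, p_corrected = pc,
    significant = !is.na(pc) & pc <= q,
    stringsAsFactors = FALSE)
}
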