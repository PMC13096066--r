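#' Circular-shift surrogate of a time series
#'
#' Rotates the series by a random offset drawn uniformly from
#' `[L/4, 3L/4]`, preserving the multiset of values (hence the amplitude
#' spectrum) while destroying cross-signal alignment. Offsets are kept away
#' from 0 and L so surrogates are never near-identical to the input.
#'
#' @param x numeric vector of length >= 4.
#' @param seed RNG seed.
#' @param offset force a specific offset (mainly for testing); 0 returns
#'   the input unchanged.
#' @return the rotated series.
#' @export
circularShift <- function(x, seed = NULL, offset = NULL) {
  L <- length(x)
  if (L < 4L) stop("series must have length >= 4")
  if (is.null(offset))
    offset <- withSeed(seed,
      sample(seq.int(floor(L / 4), ceiling(3 * L / 4)), 1L))
  offset <- offset %% L
  if (offset == 0L) return(x)
  c(x[(L - offset + 1L):L], x[seq_len(L - offset)])
}

#' Surrogate-based p-values for the NDTE flows of one epoch
#'
#' For every ordered region pair the observed NDTE flow is compared with
#' `nSurrogates` flows recomputed after circularly shifting the *source*
#' series (the target's past and future are left intact). The per-trial
#' p-value follows the add-one permutation rule,
#' `p = (1 + #\{surrogate >= observed\}) / (nSurrogates + 1)`, so it can
#' never be exactly zero. The surrogate mean and standard deviation per
#' pair are retained for later standardization.
#'
#' @param epoch an [EpochSet-class] (with `trial`) or regions x samples
#'   matrix.
#' @param lag a [ModelOrder-class] or integer embedding length.
#' @param nSurrogates number of circular-shift surrogates (>= 19).
#' @param trial trial index when `epoch` is an `EpochSet`.
#' @param seed RNG seed.
#' @return a list with `flow` (the observed [FlowMatrix-class]), `pTrial`,
#'   `surrogateMean`, `surrogateSd` (regions x regions matrices) and
#'   `nSurrogates`.
#' @export
surrogatePvalues <- function(epoch, lag, nSurrogates = 100L, trial = 1L,
                             seed = NULL) {
  nSurrogates <- assertCount(nSurrogates, "nSurrogates", min = 19L)
  m <- epochTraceMatrix(epoch, trial)
  if (is(lag, "ModelOrder")) lagS <- lag@lagSamples else lagS <- as.integer(lag)
  R <- nrow(m); L <- ncol(m)
  obs <- ndteMatrix(m, lag)
  F <- flows(obs)
  pTrial <- matrix(NA_real_, R, R, dimnames = dimnames(F))
  sMean <- sSd <- matrix(NA_real_, R, R, dimnames = dimnames(F))
  offsets <- withSeed(seed,
    sample(seq.int(floor(L / 4), ceiling(3 * L / 4)), nSurrogates,
           replace = TRUE))
  for (j in seq_len(R)) {
    shifted <- vapply(offsets, function(o) circularShift(m[j, ], offset = o),
                      numeric(L))
    for (i in seq_len(R)) {
      if (i == j) next
      surr <- vapply(seq_len(nSurrogates), function(s)
        ndtePair(shifted[, s], m[i, ], lagS), numeric(1L))
      pTrial[i, j] <- (1 + sum(surr >= F[i, j])) / (nSurrogates + 1)
      sMean[i, j] <- mean(surr)
      sSd[i, j] <- stats::sd(surr)
    }
  }
  list(flow = obs, pTrial = pTrial, surrogateMean = sMean, surrogateSd = sSd,
       nSurrogates = nSurrogates)
}

#' Combine p-values with Stouffer's method
#'
#' One-sided combination: each p is mapped to `z = qnorm(1 - p)`, the z sum
#' is scaled by `sqrt(n)` and mapped back, `1 - pnorm(sum(z)/sqrt(n))`.
#' Inputs of exactly 0 or 1 are clipped to `[1e-15, 1 - 1e-15]` with a
#' warning.
#'
#' @param pvals numeric vector of p-values in (0, 1).
#' @return the combined p-value.
#' @examples
#' stoufferCombine(c(0.05, 0.05))  # 0.0100
#' @export
stoufferCombine <- function(pvals) {
  if (!length(pvals)) stop("no p-values to combine")
  if (any(pvals <= 0 | pvals >= 1)) {
    warning("p-values of exactly 0/1 clipped to [1e-15, 1 - 1e-15]")
    pvals <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  }
  z <- stats::qnorm(1 - pvals)
  stats::pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR mask
#'
#' Standard step-up rule: reject all p at or below the largest order
#' statistic `p_(k)` with `p_(k) <= k q / m` (computed via
#' `stats::p.adjust(method = "BH") <= q`, which is equivalent).
#'
#' @param pvals numeric vector of p-values (NAs are never rejected).
#' @param q FDR level in (0, 1).
#' @return logical vector, TRUE where rejected.
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (!length(pvals)) return(logical(0L))
  out <- stats::p.adjust(pvals, method = "BH") <= q
  out[is.na(out)] <- FALSE
  out
}

#' Standardize NDTE flows and build the shared significance mask
#'
#' Aggregates the per-trial surrogate p-values with Stouffer's method,
#' first across trials within each participant and then across
#' participants, applies one Benjamini-Hochberg mask over all ordered
#' off-diagonal pairs of the group p matrix, and standardizes each trial's
#' observed flow against its own surrogate distribution,
#' `z = (F - mean_surr) / sd_surr`. Standardized flows are retained only on
#' masked pairs, averaged over trials per participant and over participants
#' for the group matrix. Pairs with zero surrogate sd in a trial are
#' dropped from that trial's average with a warning.
#'
#' @param participants a list (one element per participant) of lists of
#'   per-trial results from [surrogatePvalues()].
#' @param q FDR level for the shared mask (default 0.05).
#' @return an [NDTEMatrix-class].
#' @export
standardizeAndMask <- function(participants, q = 0.05) {
  stopifnot(length(participants) >= 1L)
  R <- nrow(participants[[1L]][[1L]]$pTrial)
  labs <- rownames(participants[[1L]][[1L]]$pTrial)
  dn <- list(labs, labs)
  off <- which(diag(R) == 0)
  pPart <- lapply(participants, function(trials) {
    P <- matrix(NA_real_, R, R, dimnames = dn)
    for (ij in off) {
      ps <- vapply(trials, function(tr) tr$pTrial[ij], numeric(1L))
      P[ij] <- stoufferCombine(ps)
    }
    P
  })
  pGroup <- matrix(NA_real_, R, R, dimnames = dn)
  for (ij in off)
    pGroup[ij] <- stoufferCombine(vapply(pPart, `[`, numeric(1L), ij))
  mask <- matrix(FALSE, R, R, dimnames = dn)
  mask[off] <- bhFdr(pGroup[off], q)
  zPart <- array(NA_real_, c(length(participants), R, R))
  droppedAny <- FALSE
  for (pi in seq_along(participants)) {
    trials <- participants[[pi]]
    zs <- vapply(trials, function(tr) {
      z <- (flows(tr$flow) - tr$surrogateMean) / tr$surrogateSd
      bad <- !is.na(tr$surrogateSd) & tr$surrogateSd == 0
      if (any(bad)) { droppedAny <<- TRUE; z[bad] <- NA_real_ }
      z
    }, matrix(0, R, R))
    zm <- apply(zs, c(1L, 2L), mean, na.rm = TRUE)
    zm[!mask] <- NA_real_
    zPart[pi, , ] <- zm
  }
  if (droppedAny)
    warning("pairs with zero surrogate sd dropped from trial averages")
  Z <- apply(zPart, c(2L, 3L), mean, na.rm = TRUE)
  Z[!mask] <- NA_real_
  dimnames(Z) <- dn
  new("NDTEMatrix", Z = Z, ZParticipant = zPart, mask = mask,
      pGroup = pGroup, q = q)
}

#' Write an NDTEMatrix as three TSVs plus a JSON provenance sidecar
#'
#' @param x an [NDTEMatrix-class].
#' @param path base path; `<path>_Z.tsv`, `<path>_p.tsv`, `<path>_mask.tsv`
#'   and `<path>.json` are written.
#' @param extra named list merged into the JSON sidecar (e.g. lag,
#'   nSurrogates).
#' @export
writeNDTEMatrix <- function(x, path, extra = list()) {
  wt <- function(M, f) utils::write.table(M, f, sep = "\t", quote = FALSE,
                                          col.names = NA)
  wt(flows(x), paste0(path, "_Z.tsv"))
  wt(groupPvalues(x), paste0(path, "_p.tsv"))
  wt(significanceMask(x) * 1L, paste0(path, "_mask.tsv"))
  jsonlite::write_json(c(list(q = x@q), extra), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
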