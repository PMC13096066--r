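#' Total inflow and outflow per region
#'
#' Under the package orientation (entry `[i, j]` = flow from source j into
#' target i) the total inflow of region i is its row sum and the total
#' outflow of region j its column sum. The orientation is isolated here so
#' it can be flipped in one place via `orientation = "columns"` should a
#' matrix with the transposed convention be supplied.
#'
#' @param M square numeric matrix with zero diagonal (an [NDTEMatrix-class]
#'   group matrix, a [FlowMatrix-class], or a plain matrix; NAs off the
#'   significance mask are treated as zero flow).
#' @param orientation "rows" (default: inflow = row sums) or "columns".
#' @return named numeric vector of per-region flow sums.
#' @export
totalInflow <- function(M, orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  M <- flowMatrixOf(M)
  if (orientation == "rows") rowSums(M) else colSums(M)
}

#' @rdname totalInflow
#' @export
totalOutflow <- function(M, orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  M <- flowMatrixOf(M)
  if (orientation == "rows") colSums(M) else rowSums(M)
}

flowMatrixOf <- function(M) {
  if (is(M, "NDTEMatrix")) M <- flows(M)
  else if (is(M, "FlowMatrix")) M <- flows(M)
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("flow matrix must be square")
  if (is.null(rownames(M)))
    dimnames(M) <- list(paste0("R", seq_len(nrow(M))),
                        paste0("R", seq_len(ncol(M))))
  M[is.na(M)] <- 0
  M
}

#' FRIC value of a candidate club
#'
#' The functional rich-club value of a set of regions: the sum of
#' connections among club members, plus all inflow from non-members into
#' the club, minus all outflow from the club to non-members.
#'
#' @param M flow matrix (orientation `[i, j]` = flow j -> i).
#' @param club region labels or 1-based indices.
#' @return the FRIC value (flow units).
#' @examples
#' M <- rbind(c(0, 2, 1), c(3, 0, 1), c(1, 1, 0))
#' fricValue(M, club = 1:2)  # 5
#' @export
fricValue <- function(M, club) {
  M <- flowMatrixOf(M)
  club <- resolveRegions(M, club)
  if (!length(club)) stop("club must be non-empty")
  out <- setdiff(seq_len(nrow(M)), club)
  sum(M[club, club]) + sum(M[club, out]) - sum(M[out, club])
}

resolveRegions <- function(M, club) {
  if (is.character(club)) {
    idx <- match(club, rownames(M))
    if (anyNA(idx)) stop("unknown region(s): ",
                         paste(club[is.na(idx)], collapse = ", "))
    idx
  } else {
    club <- as.integer(club)
    if (!all(club %in% seq_len(nrow(M)))) stop("club indices out of range")
    club
  }
}

#' Monte-Carlo p-value of a club of size k
#'
#' Surrogate clubs keep the first k - 1 members of `club` and replace the
#' k-th by a uniformly random non-member; the p-value is the add-one
#' fraction of surrogate FRIC values at or above the observed one,
#' `p = (1 + #\{surrogate >= observed\}) / (nMc + 1)`. Because the surrogate
#' value depends only on which member is drawn, the candidate values are
#' precomputed and the Monte-Carlo loop reduces to seeded sampling.
#'
#' @param M flow matrix.
#' @param club ordered region set of size >= 2 (labels or indices).
#' @param nMc number of Monte-Carlo surrogate clubs (>= 1).
#' @param seed RNG seed.
#' @return the Monte-Carlo p-value.
#' @export
clubPvalue <- function(M, club, nMc = 100000L, seed = NULL) {
  nMc <- assertCount(nMc, "nMc")
  M <- flowMatrixOf(M)
  club <- resolveRegions(M, club)
  k <- length(club)
  if (k < 2L) stop("club must have at least 2 members")
  candidates <- setdiff(seq_len(nrow(M)), club)
  if (!length(candidates))
    stop("no eligible replacement member outside the club")
  obs <- fricValue(M, club)
  base <- club[-k]
  candVals <- vapply(candidates, function(y) fricValue(M, c(base, y)),
                     numeric(1L))
  draws <- withSeed(seed,
    sample.int(length(candidates), nMc, replace = TRUE))
  (1 + sum(candVals[draws] >= obs)) / (nMc + 1)
}

#' Detect the functional rich club by inflow-ranked Monte-Carlo growth
#'
#' Regions are ranked by total inflow (descending, ties broken by label
#' order) and nested candidate clubs are formed from the ranking prefixes.
#' Every size k from 2 upward is tested with [clubPvalue()]; the detected
#' club is the largest prefix whose FRIC value is significantly larger than
#' that of its surrogate clubs (p < alpha). When no size is significant the
#' top-inflow singleton is returned with `significant = FALSE`.
#'
#' All tested sizes and their p-values are reported in the result, so the
#' growth path can be audited.
#'
#' @param M flow matrix (an [NDTEMatrix-class] group matrix or plain
#'   matrix), at least 3 regions.
#' @param alpha significance level (default 0.05).
#' @param nMc Monte-Carlo surrogates per tested size (default 100000;
#'   reduce for desk-scale runs).
#' @param seed RNG seed.
#' @param maxSize largest club size tested (default all of
#'   2..(regions - 1)).
#' @return a [FRICResult-class].
#' @export
findFric <- function(M, alpha = 0.05, nMc = 100000L, seed = NULL,
                     maxSize = NULL) {
  M <- flowMatrixOf(M)
  R <- nrow(M)
  if (R < 3L) stop("need at least 3 regions")
  inflow <- totalInflow(M)
  ranking <- rownames(M)[order(-inflow, rownames(M))]
  kMax <- min(if (is.null(maxSize)) R - 1L else maxSize, R - 1L)
  ks <- 2:kMax
  withSeed(seed, {
    pv <- fv <- stats::setNames(numeric(length(ks)), ks)
    for (m in seq_along(ks)) {
      club <- ranking[seq_len(ks[m])]
      fv[m] <- fricValue(M, club)
      pv[m] <- clubPvalue(M, club, nMc = nMc)
    }
    sig <- pv < alpha
    if (any(sig)) {
      kStar <- ks[max(which(sig))]
      new("FRICResult", ranking = ranking, club = ranking[seq_len(kStar)],
          fricValues = fv, pValues = pv, nMc = as.integer(nMc),
          alpha = alpha, significant = TRUE)
    } else {
      new("FRICResult", ranking = ranking, club = ranking[1L],
          fricValues = fv, pValues = pv, nMc = as.integer(nMc),
          alpha = alpha, significant = FALSE)
    }
  })
}

#' Serialize a FRICResult to JSON (plus optional top-edge TSV)
#'
#' @param x a [FRICResult-class].
#' @param file JSON output path.
#' @param M optional flow matrix from which the strongest `topN` edges are
#'   written alongside as `<file>_edges.tsv` (columns source, target, Z).
#' @param topN number of edges to export (default 20).
#' @export
writeFricResult <- function(x, file, M = NULL, topN = 20L) {
  jsonlite::write_json(
    list(ranking = x@ranking, club = x@club,
         tested_sizes = as.integer(names(x@pValues)),
         fric_values = unname(x@fricValues),
         p_values = unname(x@pValues),
         n_mc = x@nMc, alpha = x@alpha, significant = x@significant),
    file, auto_unbox = TRUE, digits = NA)
  if (!is.null(M)) {
    M <- flowMatrixOf(M)
    ord <- order(-M)
    ord <- ord[!(((ord - 1L) %% nrow(M)) + 1L == ((ord - 1L) %/% nrow(M)) + 1L)]
    ord <- utils::head(ord, topN)
    i <- ((ord - 1L) %% nrow(M)) + 1L
    j <- ((ord - 1L) %/% nrow(M)) + 1L
    utils::write.table(
      data.frame(source = rownames(M)[j], target = rownames(M)[i],
                 Z = M[ord]),
      paste0(sub("\\.json$", "", file), "_edges.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
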