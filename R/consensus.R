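# Consensus pose-ranking baselines. Every scheme first aligns each term so
# that larger = better (via the per-term direction annotation), then ranks
# within groups. Final ranks are always a permutation of 1..m per group:
# ties in the scheme's aggregate are resolved by the scheme's stated
# secondary keys and ultimately by the candidate key.

.alignScores <- function(df, terms, directions) {
  if (is.null(directions)) directions <- rep("higher", length(terms))
  if (length(directions) == 1L) directions <- rep(directions, length(terms))
  if (!is.null(names(directions))) directions <- directions[terms]
  if (!all(directions %in% c("higher", "lower")))
    .stopf("directions must be 'higher' or 'lower'")
  S <- as.matrix(df[, terms, drop = FALSE])
  S[, directions == "lower"] <- -S[, directions == "lower", drop = FALSE]
  S
}

.checkTerms <- function(poseTable, terms) {
  miss <- setdiff(terms, featureNames(poseTable))
  if (length(miss)) .stopf("unknown scoring term(s): %s", paste(miss, collapse = ", "))
}

# assemble a RankingResult: order by (aggregate desc is handled by caller
# passing "ordering keys"), final rank 1..m per group
.rankWithin <- function(df, grp, orderKeys, method) {
  rank <- integer(nrow(df))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ord <- do.call(order, lapply(orderKeys, function(k) k[idx]))
    rank[idx[ord]] <- seq_along(idx)
  }
  out <- df[, .keyCols]
  out$rank <- rank
  attr(out, "method") <- method
  class(out) <- c("RankingResult", "data.frame")
  out
}

#' Rank poses by a single scoring term
#'
#' Baseline scheme: within each group, candidates are ordered by one scoring
#' term (direction-aligned); rank 1 is best. Ties break by candidate key.
#'
#' @param poseTable a [PoseTable-class].
#' @param term scoring-term (feature) name.
#' @param direction "higher" (higher score is better) or "lower".
#' @param groupBy grouping column(s), default `"ligand_id"`.
#' @return data.frame of class `"RankingResult"`: key columns + `rank`
#'   (1 = best per group).
#' @export
singleFunctionRanking <- function(poseTable, term,
                                  direction = c("higher", "lower"),
                                  groupBy = "ligand_id") {
  direction <- match.arg(direction)
  stopifnot(is(poseTable, "PoseTable"))
  .checkTerms(poseTable, term)
  df <- as.data.frame(poseTable)
  s <- .alignScores(df, term, direction)[, 1L]
  grp <- interaction(df[groupBy], drop = TRUE)
  .rankWithin(df, grp, list(-s, .keyString(df)), "single")
}

#' Rank-by-number consensus
#'
#' Candidates are re-ranked by the mean of their (direction-aligned,
#' optionally z-standardized) scores over a panel of terms. Standardization
#' uses the pooled per-term mean/sd and is on by default because raw scoring
#' functions live on incomparable numeric spans.
#'
#' @param poseTable a [PoseTable-class].
#' @param terms panel of scoring-term names (>= 2).
#' @param directions per-term direction annotation ("higher"/"lower"),
#'   recycled or matched by name.
#' @param standardize z-standardize each term before averaging.
#' @param groupBy grouping column(s).
#' @return `"RankingResult"` data.frame.
#' @export
rankByNumber <- function(poseTable, terms, directions = "higher",
                         standardize = TRUE, groupBy = "ligand_id") {
  stopifnot(is(poseTable, "PoseTable"))
  if (length(terms) < 2) .stopf("consensus requires >= 2 terms")
  .checkTerms(poseTable, terms)
  df <- as.data.frame(poseTable)
  S <- .alignScores(df, terms, directions)
  if (standardize) {
    sds <- apply(S, 2, stats::sd)
    if (any(sds == 0))
      .stopf("zero-variance term(s) cannot be standardized: %s",
             paste(terms[sds == 0], collapse = ", "))
    S <- scale(S)
  }
  m <- rowMeans(S)
  grp <- interaction(df[groupBy], drop = TRUE)
  .rankWithin(df, grp, list(-m, .keyString(df)), "number")
}

#' Rank-by-rank consensus
#'
#' Candidates are re-ranked by the mean of their per-term within-group ranks
#' (average ranks on per-term ties), making the scheme invariant to any
#' strictly increasing transform of individual terms.
#'
#' @inheritParams rankByNumber
#' @return `"RankingResult"` data.frame.
#' @export
rankByRank <- function(poseTable, terms, directions = "higher",
                       groupBy = "ligand_id") {
  stopifnot(is(poseTable, "PoseTable"))
  if (length(terms) < 2) .stopf("consensus requires >= 2 terms")
  .checkTerms(poseTable, terms)
  df <- as.data.frame(poseTable)
  S <- .alignScores(df, terms, directions)
  grp <- interaction(df[groupBy], drop = TRUE)
  meanRank <- numeric(nrow(df))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    R <- apply(-S[idx, , drop = FALSE], 2, rank, ties.method = "average")
    if (is.null(dim(R))) R <- matrix(R, nrow = 1L)
    meanRank[idx] <- rowMeans(R)
  }
  .rankWithin(df, grp, list(meanRank, .keyString(df)), "rank")
}

#' Rank-by-vote consensus
#'
#' Each term votes for its top `ceiling(topFraction * m)` candidates within a
#' group (per-term ordering with key tie-break); candidates are ordered by
#' vote count, then mean per-term rank, then candidate key. With the default
#' `topFraction = 1/3` each term endorses the best third of a group.
#'
#' @inheritParams rankByNumber
#' @param topFraction fraction of each group receiving a vote, in (0, 1].
#' @return `"RankingResult"` data.frame (with a `votes` column).
#' @export
rankByVote <- function(poseTable, terms, directions = "higher",
                       topFraction = 1/3, groupBy = "ligand_id") {
  stopifnot(is(poseTable, "PoseTable"))
  if (length(terms) < 2) .stopf("consensus requires >= 2 terms")
  if (!is.numeric(topFraction) || topFraction <= 0 || topFraction > 1)
    .stopf("topFraction must be in (0, 1]")
  .checkTerms(poseTable, terms)
  df <- as.data.frame(poseTable)
  S <- .alignScores(df, terms, directions)
  grp <- interaction(df[groupBy], drop = TRUE)
  ks <- .keyString(df)
  votes <- integer(nrow(df))
  meanRank <- numeric(nrow(df))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    m <- length(idx)
    nVote <- ceiling(topFraction * m)
    R <- apply(-S[idx, , drop = FALSE], 2, rank, ties.method = "average")
    if (is.null(dim(R))) R <- matrix(R, nrow = 1L)
    meanRank[idx] <- rowMeans(R)
    for (t in seq_along(terms)) {
      ord <- idx[order(-S[idx, t], ks[idx])]
      votes[ord[seq_len(nVote)]] <- votes[ord[seq_len(nVote)]] + 1L
    }
  }
  out <- .rankWithin(df, grp, list(-votes, meanRank, ks), "vote")
  out$votes <- votes
  out
}
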