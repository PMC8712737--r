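# Pathway scoring against disease-feature risk sets: mean-cosine correlation
# scores, database-size-corrected ranking scores, seeded permutation
# p-values, and the classical hypergeometric overlap baseline.

#' Correlation score of a risk set against one pathway
#'
#' Aggregates, over the risk molecules, the cosine similarity between each
#' molecule's source vector and the pathway's target vector (the walk runs
#' from molecule toward pathway). Risk molecules absent from the embedding
#' are dropped with a message; an empty effective risk set is an error.
#'
#' @param emb An `embedding_space` from [svd_embed()].
#' @param risk_set Character vector of risk molecule ids.
#' @param pathway_id Pathway node id.
#' @param agg Aggregation over the risk set: `"mean"` (default), `"max"` or
#'   `"sum"`.
#' @return A single numeric score.
#' @export
correlation_score <- function(emb, risk_set, pathway_id,
                              agg = c("mean", "max", "sum")) {
  agg <- match.arg(agg)
  risk_set <- unique(risk_set)
  present <- risk_set %in% rownames(emb$source)
  if (any(!present)) {
    message(sum(!present), " risk molecule(s) absent from embedding, dropped")
  }
  risk_set <- risk_set[present]
  if (length(risk_set) == 0L) stop("no risk molecule present in embedding")
  if (!pathway_id %in% rownames(emb$target)) {
    stop("pathway not in embedding: ", pathway_id)
  }
  pv <- emb$target[pathway_id, ]
  cosines <- molecule_pathway_cosines(emb, risk_set, pv)
  switch(agg, mean = mean(cosines), max = max(cosines), sum = sum(cosines))
}

# cosines of a set of molecule source vectors against one pathway target
# vector, vectorized over molecules; zero-norm vectors give 0
molecule_pathway_cosines <- function(emb, ids, pathway_vec) {
  S <- emb$source[ids, , drop = FALSE]
  num <- as.numeric(S %*% pathway_vec)
  ns <- sqrt(rowSums(S * S))
  np <- sqrt(sum(pathway_vec^2))
  den <- ns * np
  out <- ifelse(den > 0, num / den, 0)
  names(out) <- ids
  out
}

#' Score every pathway against a risk set
#'
#' Computes the correlation score and risk-gene overlap count for each
#' pathway record, then fills per-database ranks and ranking scores via
#' [rank_and_score()]. Empirical p-values are added when `n_perm > 0`
#' (see [empirical_pvalue()]).
#'
#' @param emb An `embedding_space` covering molecules and pathway nodes.
#' @param pathways Pathway records ([read_gmt()]).
#' @param risk_set Character vector of risk molecule ids (mRNAs and miRNAs).
#' @param feature Feature label stored with each score row.
#' @param node_type Named character vector node id -> type, used to
#'   type-match permutation null sets; required when `n_perm > 0`.
#' @param n_perm Number of permutations for the empirical p-value
#'   (0 disables).
#' @param perm_seed Integer seed for the permutation draws.
#' @param agg Aggregation passed to [correlation_score()].
#' @return Data frame with one row per pathway: feature, pathway_id,
#'   source_db, correlation_score, overlap_count, rank_in_db, ranking_score,
#'   empirical_p.
#' @export
score_pathways <- function(emb, pathways, risk_set, feature = "feature",
                           node_type = NULL, n_perm = 0L, perm_seed = 1L,
                           agg = "mean") {
  risk_set <- unique(risk_set)
  risk_in <- risk_set[risk_set %in% rownames(emb$source)]
  scores <- data.frame(
    feature = feature,
    pathway_id = pathways$pathway_id,
    source_db = pathways$source_db,
    correlation_score = vapply(pathways$pathway_id, function(p) {
      correlation_score(emb, risk_in, p, agg = agg)
    }, numeric(1L)),
    overlap_count = vapply(pathways$members, function(m) {
      length(intersect(m, risk_set))
    }, integer(1L)),
    stringsAsFactors = FALSE)
  scores <- rank_and_score(scores)
  scores$empirical_p <- NA_real_
  if (n_perm > 0L) {
    if (is.null(node_type)) {
      stop("node_type is required to draw type-matched null sets")
    }
    for (i in seq_len(nrow(scores))) {
      scores$empirical_p[i] <- empirical_pvalue(
        emb, risk_in, scores$pathway_id[i], node_type,
        n_perm = n_perm, seed = perm_seed, agg = agg)
    }
  }
  rownames(scores) <- NULL
  scores
}

#' Per-database ranks and size-corrected ranking scores
#'
#' Within each source database, pathways are ranked by correlation score in
#' descending order with competition ("min") ranks for ties, and the rank is
#' transformed to `ranking_score = -log2(rank / (N_db + 1))` where `N_db` is
#' the number of pathways from that database. The transform removes the
#' database-size bias of raw ranks: rank 1 in a 63-pathway database scores
#' exactly 6, and a score of 6 always marks the top 1/64 quantile of its
#' database whatever its size.
#'
#' @param scores Data frame with columns `source_db` and `correlation_score`.
#' @return The input with `rank_in_db` and `ranking_score` filled.
#' @export
rank_and_score <- function(scores) {
  scores$rank_in_db <- NA_integer_
  scores$ranking_score <- NA_real_
  for (db in unique(scores$source_db)) {
    sel <- scores$source_db == db
    r <- rank(-scores$correlation_score[sel], ties.method = "min")
    n_db <- sum(sel)
    scores$rank_in_db[sel] <- as.integer(r)
    scores$ranking_score[sel] <- -log2(r / (n_db + 1))
  }
  scores
}

#' Empirical p-value from permutation of the risk set
#'
#' Draws `n_perm` random molecule sets from the network's molecule nodes,
#' each matching the observed risk set's mRNA and miRNA counts, rescores the
#' pathway against each, and returns the add-one-corrected empirical
#' p-value `(1 + b) / (1 + N)` where `b` counts null scores at least as
#' large as the observed score. The correction keeps p strictly positive,
#' with a floor of `1 / (1 + N)`.
#'
#' @inheritParams score_pathways
#' @param pathway_id Pathway node id.
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param n_perm Number of permutations (>= 1).
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(emb, risk_set, pathway_id, node_type,
                             n_perm = 199L, seed = 1L, agg = "mean") {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  risk_set <- unique(risk_set)
  risk_set <- risk_set[risk_set %in% rownames(emb$source)]
  if (length(risk_set) == 0L) stop("empty effective risk set")
  types <- node_type[risk_set]
  if (anyNA(types)) {
    stop("risk set larger than available molecule pool: ",
         sum(is.na(types)), " risk molecule(s) missing from the typed pool")
  }
  n_m <- sum(types == "mRNA")
  n_mi <- sum(types == "miRNA")
  pool_m <- names(node_type)[node_type == "mRNA"]
  pool_mi <- names(node_type)[node_type == "miRNA"]
  pool_m <- pool_m[pool_m %in% rownames(emb$source)]
  pool_mi <- pool_mi[pool_mi %in% rownames(emb$source)]
  if (n_m > length(pool_m) || n_mi > length(pool_mi)) {
    stop("risk set larger than available molecule pool")
  }
  pv <- emb$target[pathway_id, ]
  # one cosine per pool molecule, reused across permutations
  cos_m <- molecule_pathway_cosines(emb, pool_m, pv)
  cos_mi <- if (length(pool_mi) > 0L) {
    molecule_pathway_cosines(emb, pool_mi, pv)
  } else numeric(0L)
  all_cos <- c(cos_m, cos_mi)
  observed <- aggregate_cosines(all_cos[risk_set], agg)
  null_scores <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      draw <- c(if (n_m > 0L) sample(cos_m, n_m),
                if (n_mi > 0L) sample(cos_mi, n_mi))
      aggregate_cosines(draw, agg)
    }, numeric(1L))
  })
  empirical_p_from_null(observed, null_scores)
}

aggregate_cosines <- function(x, agg) {
  switch(agg, mean = mean(x), max = max(x), sum = sum(x),
         stop("unknown aggregation: ", agg))
}

#' Add-one empirical p-value from observed and null scores
#'
#' @param observed Observed score.
#' @param null_scores Numeric vector of null scores.
#' @return `(1 + #\{null >= observed\}) / (1 + N)`.
#' @export
empirical_p_from_null <- function(observed, null_scores) {
  (1 + sum(null_scores >= observed)) / (1 + length(null_scores))
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Filter pathway scores to the significant set
#'
#' Keeps pathways passing both thresholds (ranking score at or above
#' `ranking_threshold` and empirical p at or below `p_threshold`), sorted by
#' feature, then empirical p ascending, then ranking score descending.
#' The default ranking threshold of 6 selects, within each source database,
#' approximately the top 1/64 of pathways.
#'
#' @param scores Score data frame carrying `ranking_score` and
#'   `empirical_p`.
#' @param ranking_threshold Minimum ranking score (inclusive).
#' @param p_threshold Maximum empirical p (inclusive).
#' @return The filtered, sorted data frame.
#' @export
select_significant <- function(scores, ranking_threshold = 6,
                               p_threshold = 0.05) {
  keep <- scores$ranking_score >= ranking_threshold &
    scores$empirical_p <= p_threshold
  keep[is.na(keep)] <- FALSE
  out <- scores[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    out <- out[order(out$feature, out$empirical_p, -out$ranking_score), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap enrichment (classical baseline)
#'
#' One-sided hypergeometric tail probability `P(X >= overlap)` of seeing at
#' least the observed number of risk genes among the pathway members, with
#' the universe as population. Members or risk genes outside the universe
#' are trimmed with a warning.
#'
#' @param risk_genes Character vector of risk gene ids.
#' @param members Character vector of pathway member gene ids.
#' @param universe Character vector, the gene population.
#' @return The enrichment p-value.
#' @export
overlap_enrichment <- function(risk_genes, members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  members <- unique(members)
  risk_genes <- unique(risk_genes)
  if (any(!members %in% universe)) {
    warning(sum(!members %in% universe),
            " pathway member(s) outside universe trimmed")
    members <- intersect(members, universe)
  }
  if (any(!risk_genes %in% universe)) {
    warning(sum(!risk_genes %in% universe),
            " risk gene(s) outside universe trimmed")
    risk_genes <- intersect(risk_genes, universe)
  }
  overlap <- length(intersect(risk_genes, members))
  stats::phyper(overlap - 1L, length(members),
                length(universe) - length(members),
                length(risk_genes), lower.tail = FALSE)
}
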