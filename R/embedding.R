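# Random walk with restart from every node, truncated SVD of the proximity
# matrix, and cosine similarity in the shared low-dimensional space.

#' Random walk with restart
#'
#' Computes the stationary distribution of the iteration
#' `p <- (1 - r) * T %*% p + r * seed` on the commixture matrix `T`.
#' Small systems (`n <= dense_cutoff`) are solved directly as
#' `(I - (1 - r) T) p = r seed`; larger ones by power iteration with an L1
#' stopping rule. Non-convergence raises an error rather than returning a
#' truncated result.
#'
#' @param cm A `commixture` object, or a column-stochastic matrix.
#' @param seed Probability vector over nodes (must sum to 1), or a character
#'   vector of node ids given equal seed mass.
#' @param r Restart probability in (0, 1).
#' @param tol L1 convergence tolerance for the iterative path.
#' @param max_iter Maximum number of power iterations.
#' @param method `"auto"`, `"iterative"` or `"direct"`.
#' @param dense_cutoff Problem size up to which `"auto"` uses the direct
#'   linear solve.
#' @return Stationary probability vector (named when node ids are known),
#'   with attribute `iterations` for the iterative path.
#' @export
rwr <- function(cm, seed, r = 0.7, tol = 1e-10, max_iter = 10000L,
                method = c("auto", "iterative", "direct"),
                dense_cutoff = 2000L) {
  method <- match.arg(method)
  Tm <- if (inherits(cm, "commixture")) cm$matrix else cm
  n <- nrow(Tm)
  if (r <= 0 || r >= 1) stop("restart probability must be in (0, 1)")
  if (is.character(seed)) {
    ids <- seed
    seed <- numeric(n)
    names(seed) <- rownames(Tm)
    pos <- match(ids, rownames(Tm))
    if (anyNA(pos)) stop("seed node not in network: ", ids[is.na(pos)][1L])
    seed[pos] <- 1 / length(pos)
  }
  if (length(seed) != n) stop("seed length ", length(seed), " != n ", n)
  if (any(seed < 0) || abs(sum(seed) - 1) > 1e-8) {
    stop("seed must be a probability vector summing to 1")
  }
  if (method == "auto") {
    method <- if (n <= dense_cutoff) "direct" else "iterative"
  }
  if (method == "direct") {
    M <- diag(n) - (1 - r) * as.matrix(Tm)
    p <- as.numeric(solve(M, r * seed))
    attr(p, "iterations") <- NA_integer_
  } else {
    p <- seed
    it <- 0L
    repeat {
      p_new <- as.numeric((1 - r) * (Tm %*% p)) + r * seed
      delta <- sum(abs(p_new - p))
      p <- p_new
      it <- it + 1L
      if (delta < tol) break
      if (it >= max_iter) {
        stop("random walk did not converge within ", max_iter,
             " iterations (last L1 change ", signif(delta, 3), ")")
      }
    }
    attr(p, "iterations") <- it
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("internal error: stationary vector sums to ", sum(p))
  }
  names(p) <- rownames(Tm)
  p
}

#' Proximity matrix: RWR from every node
#'
#' Row i holds the stationary distribution of a walk restarted at node i.
#' For systems up to `dense_cutoff` nodes all rows are obtained from one
#' dense factorization of `I - (1 - r) T`; larger systems fall back to
#' per-seed power iteration.
#'
#' @inheritParams rwr
#' @return An object of class `proximity_matrix` with fields `matrix`
#'   (dense n x n, rows = seeds) and `node_index`.
#' @export
rwr_all <- function(cm, r = 0.7, tol = 1e-10, max_iter = 10000L,
                    dense_cutoff = 2000L) {
  Tm <- if (inherits(cm, "commixture")) cm$matrix else cm
  n <- nrow(Tm)
  if (r <= 0 || r >= 1) stop("restart probability must be in (0, 1)")
  if (n <= dense_cutoff) {
    M <- diag(n) - (1 - r) * as.matrix(Tm)
    # column j of solve(M) scaled by r is the walk seeded at node j
    P <- r * t(solve(M))
  } else {
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- numeric(n); s[i] <- 1
      P[i, ] <- rwr(Tm, s, r = r, tol = tol, max_iter = max_iter,
                    method = "iterative")
    }
  }
  rs <- rowSums(P)
  if (max(abs(rs - 1)) > 1e-8) {
    stop("internal error: proximity rows sum off by ", max(abs(rs - 1)))
  }
  dimnames(P) <- dimnames(Tm)
  structure(list(matrix = P,
                 node_index = if (inherits(cm, "commixture")) cm$node_index
                              else stats::setNames(seq_len(n), rownames(Tm)),
                 restart = r),
            class = "proximity_matrix")
}

#' Truncated SVD embedding of a proximity matrix
#'
#' Factorizes `P ~ U_d S_d V_d'` and places each node in a shared
#' d-dimensional space twice: its source vector (row of `U_d sqrt(S_d)`,
#' the node as walk origin) and its target vector (row of `V_d sqrt(S_d)`,
#' the node as walk destination). The square-root split of the singular
#' values balances the norms of the two roles. A deterministic sign
#' convention (largest-magnitude component of each left singular vector made
#' positive) makes the embedding reproducible across platforms.
#'
#' @param P A `proximity_matrix`, or a plain numeric matrix with dimnames.
#' @param d Embedding dimension, 1 <= d <= n. Default `min(128, n - 1)`.
#' @param symmetrize Average P with its transpose before factorizing, for
#'   role-free vectors.
#' @param log_transform Apply `log1p` to P before factorizing.
#' @return An object of class `embedding_space` with fields `d`, `source`
#'   (n x d), `target` (n x d) and `singular_values`.
#' @export
svd_embed <- function(P, d = NULL, symmetrize = FALSE,
                      log_transform = FALSE) {
  M <- if (inherits(P, "proximity_matrix")) P$matrix else as.matrix(P)
  n <- nrow(M)
  if (is.null(d)) d <- min(128L, n - 1L)
  d <- as.integer(d)
  if (d < 1L || d > n) stop("embedding dimension d must satisfy 1 <= d <= n")
  if (isTRUE(log_transform)) M <- log1p(M)
  if (isTRUE(symmetrize)) M <- (M + t(M)) / 2
  sv <- svd(M, nu = d, nv = d)
  U <- sv$u; V <- sv$v
  for (k in seq_len(d)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  scale_ <- sqrt(sv$d[seq_len(d)])
  src <- U * rep(scale_, each = n)
  tgt <- V * rep(scale_, each = n)
  rownames(src) <- rownames(tgt) <- rownames(M)
  structure(list(d = d, source = src, target = tgt,
                 singular_values = sv$d[seq_len(d)]),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("embedding space:", nrow(x$source), "nodes, d =", x$d,
      "| leading singular value", signif(x$singular_values[1L], 4), "\n")
  invisible(x)
}

#' Write an embedding space to TSV (node, role, v1..vd)
#'
#' @param emb An `embedding_space`.
#' @param path Output path.
#' @export
write_embedding <- function(emb, path) {
  mk <- function(m, role) {
    df <- as.data.frame(m)
    names(df) <- paste0("v", seq_len(ncol(m)))
    cbind(data.frame(node = rownames(m), role = role), df)
  }
  out <- rbind(mk(emb$source, "source"), mk(emb$target, "target"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Cosine similarity between two vectors
#'
#' Returns `u . v / (|u| |v|)`; if either vector has zero norm the
#' similarity is defined as 0 with a warning.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vector length mismatch: ", length(u), " vs ", length(v))
  }
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    warning("zero-norm vector in cosine similarity; returning 0")
    return(0)
  }
  sum(u * v) / (nu * nv)
}
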