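# Assembly of the multiplex-heterogeneous network (gene layer, miRNA layer,
# bipartite miRNA-mRNA couplings, pathway membership links) and its
# transformation into the column-stochastic commixture (supra-transition)
# matrix that drives the random walk.

#' Random-walk parameters
#'
#' @param restart Restart probability r in (0, 1). At each step the walker
#'   returns to the seed distribution with probability r.
#' @param delta Probability mass a molecule node sends across the bipartite
#'   miRNA-mRNA coupling, in \[0, 1).
#' @param lambda Probability mass a molecule node sends to its pathway
#'   neighbors, in \[0, 1). `delta + lambda` must be < 1; the remainder goes
#'   to intra-layer neighbors.
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(restart = 0.7, delta = 0.3, lambda = 0.2) {
  if (!is.numeric(restart) || restart <= 0 || restart >= 1) {
    stop("restart must be in (0, 1)")
  }
  if (!is.numeric(delta) || delta < 0 || delta >= 1) {
    stop("delta must be in [0, 1)")
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda >= 1) {
    stop("lambda must be in [0, 1)")
  }
  if (delta + lambda >= 1) {
    stop("delta + lambda must be < 1 (got ", delta + lambda, ")")
  }
  structure(list(restart = restart, delta = delta, lambda = lambda),
            class = "walk_params")
}

#' Build the multiplex-heterogeneous network
#'
#' Registers nodes in deterministic order (sorted mRNAs from the gene layer,
#' then sorted miRNAs from the miRNA layer, then sorted pathway ids) and
#' validates every edge set against the registered node set. Coupling edges
#' with an unregistered endpoint are dropped and counted; pathway members
#' absent from the gene layer are dropped from the membership links while the
#' pathway record itself is kept for overlap statistics.
#'
#' Pathway nodes link to member mRNAs. Optionally (`link_mirna_pathways`),
#' a pathway is also linked to every miRNA that targets at least
#' `mirna_link_min_targets` of its members, which routes miRNA walkers to
#' pathways directly rather than only through their targets.
#'
#' @param gene_edges Undirected weighted mRNA-mRNA edges ([read_edge_list()]).
#' @param mirna_edges Undirected weighted miRNA-miRNA edges.
#' @param target_edges miRNA-mRNA interactions ([read_interactions()]),
#'   treated as undirected couplings.
#' @param pathways Pathway records ([read_gmt()]).
#' @param link_mirna_pathways Also link pathways to strongly targeting
#'   miRNAs (default off).
#' @param mirna_link_min_targets Minimum member targets for such a link.
#' @return An object of class `mh_network`.
#' @export
build_network <- function(gene_edges, mirna_edges, target_edges, pathways,
                          link_mirna_pathways = FALSE,
                          mirna_link_min_targets = 3L) {
  genes <- sort(unique(c(gene_edges$source, gene_edges$target)))
  if (length(genes) == 0L) stop("gene layer is empty")
  mirnas <- sort(unique(c(mirna_edges$source, mirna_edges$target)))
  pw_ids <- sort(unique(pathways$pathway_id))

  overlap <- intersect(genes, mirnas)
  if (length(overlap) > 0L) {
    stop("identifier(s) present in both layers: ", overlap[1L])
  }

  nodes <- data.frame(
    id = c(genes, mirnas, pw_ids),
    type = c(rep("mRNA", length(genes)), rep("miRNA", length(mirnas)),
             rep("pathway", length(pw_ids))),
    stringsAsFactors = FALSE)
  node_index <- stats::setNames(seq_len(nrow(nodes)), nodes$id)

  # couplings: keep only edges whose miRNA and mRNA endpoints are registered
  cp <- data.frame(mirna = target_edges$regulator,
                   gene = target_edges$target,
                   weight = 1, stringsAsFactors = FALSE)
  keep <- cp$mirna %in% mirnas & cp$gene %in% genes
  dropped_coupling <- sum(!keep)
  if (dropped_coupling > 0L) {
    message(dropped_coupling,
            " coupling edge(s) dropped (unregistered endpoint)")
  }
  cp <- cp[keep, , drop = FALSE]
  cp <- cp[!duplicated(cp[c("mirna", "gene")]), , drop = FALSE]

  # pathway membership links, unit weights, mRNA members only
  pl <- data.frame(
    pathway_id = rep(pathways$pathway_id, lengths(pathways$members)),
    member = unlist(pathways$members, use.names = FALSE),
    stringsAsFactors = FALSE)
  linkable <- pl$member %in% genes
  dropped_members <- sum(!linkable)
  pl <- pl[linkable, , drop = FALSE]

  if (isTRUE(link_mirna_pathways) && nrow(cp) > 0L) {
    member_sets <- split(pl$member, pl$pathway_id)
    extra <- do.call(rbind, lapply(names(member_sets), function(p) {
      hits <- cp[cp$gene %in% member_sets[[p]], , drop = FALSE]
      cnt <- table(hits$mirna)
      mi <- names(cnt)[cnt >= mirna_link_min_targets]
      if (length(mi) == 0L) return(NULL)
      data.frame(pathway_id = p, member = mi, stringsAsFactors = FALSE)
    }))
    if (!is.null(extra)) pl <- rbind(pl, extra)
  }

  empty_pw <- setdiff(pw_ids, unique(pl$pathway_id))
  if (length(empty_pw) > 0L) {
    warning(length(empty_pw),
            " pathway(s) have no linkable members; kept with self-loop: ",
            paste(utils::head(empty_pw, 3L), collapse = ", "))
  }
  rownames(cp) <- rownames(pl) <- NULL

  structure(list(
    nodes = nodes,
    node_index = node_index,
    gene_edges = gene_edges[c("source", "target", "weight")],
    mirna_edges = mirna_edges[c("source", "target", "weight")],
    coupling = cp,
    pathway_links = pl,
    pathways = pathways,
    dropped = list(coupling = dropped_coupling, members = dropped_members)
  ), class = "mh_network")
}

#' @export
print.mh_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat("multiplex-heterogeneous network:",
      sum(tt), "nodes (", paste(names(tt), tt, collapse = ", "), ")\n")
  cat("  gene edges:", nrow(x$gene_edges),
      "| miRNA edges:", nrow(x$mirna_edges),
      "| couplings:", nrow(x$coupling),
      "| pathway links:", nrow(x$pathway_links), "\n")
  invisible(x)
}

#' Transform a network into the column-stochastic commixture matrix
#'
#' Column v of the matrix holds the transition probabilities out of node v.
#' From a molecule node the mass splits by edge class: `lambda` to pathway
#' neighbors, `delta` to bipartite coupling neighbors, the remainder
#' (`1 - delta - lambda`) to intra-layer neighbors, each share distributed
#' proportionally to edge weight. When an edge class is absent at v its
#' share is renormalized over the classes present. From a pathway node all
#' mass goes to member molecules, weight-proportionally. Nodes with no edges
#' at all receive a unit self-loop, so every column sums to exactly 1.
#'
#' @param net An `mh_network` from [build_network()].
#' @param params A `walk_params` object.
#' @return An object of class `commixture` holding the sparse matrix, the
#'   node index and the parameters used.
#' @export
to_commixture <- function(net, params = walk_params()) {
  stopifnot(inherits(net, "mh_network"))
  if (!inherits(params, "walk_params")) {
    params <- do.call(walk_params, as.list(params))
  }
  idx <- net$node_index
  n <- length(idx)
  is_pathway <- net$nodes$type == "pathway"

  # per-column neighbor lists split by edge class
  intra <- rbind(
    data.frame(from = c(net$gene_edges$source, net$gene_edges$target),
               to = c(net$gene_edges$target, net$gene_edges$source),
               w = rep(net$gene_edges$weight, 2L)),
    data.frame(from = c(net$mirna_edges$source, net$mirna_edges$target),
               to = c(net$mirna_edges$target, net$mirna_edges$source),
               w = rep(net$mirna_edges$weight, 2L)))
  coup <- data.frame(from = c(net$coupling$mirna, net$coupling$gene),
                     to = c(net$coupling$gene, net$coupling$mirna),
                     w = rep(net$coupling$weight, 2L))
  # molecule -> pathway direction uses the lambda share; pathway -> member
  # mass is handled separately below
  pthw <- data.frame(from = net$pathway_links$member,
                     to = net$pathway_links$pathway_id,
                     w = rep(1, nrow(net$pathway_links)))

  class_shares <- c(intra = 1 - params$delta - params$lambda,
                    coup = params$delta, pthw = params$lambda)
  by_col <- list(intra = split(intra, intra$from),
                 coup = split(coup, coup$from),
                 pthw = split(pthw, pthw$from))

  ti <- vector("list", n)
  for (v in seq_len(n)) {
    id <- net$nodes$id[v]
    if (is_pathway[v]) {
      members <- net$pathway_links[net$pathway_links$pathway_id == id, ,
                                   drop = FALSE]
      if (nrow(members) == 0L) {
        ti[[v]] <- data.frame(i = v, j = v, x = 1)
      } else {
        w <- rep(1, nrow(members))
        ti[[v]] <- data.frame(i = unname(idx[members$member]), j = v,
                              x = w / sum(w))
      }
      next
    }
    present <- list(intra = by_col$intra[[id]], coup = by_col$coup[[id]],
                    pthw = by_col$pthw[[id]])
    have <- !vapply(present, is.null, logical(1L))
    if (!any(have)) {
      ti[[v]] <- data.frame(i = v, j = v, x = 1)
      next
    }
    shares <- class_shares[have]
    if (sum(shares) <= 0) shares[] <- 1  # only zero-share classes present
    shares <- shares / sum(shares)
    parts <- Map(function(df, s) {
      data.frame(i = unname(idx[df$to]), j = v, x = s * df$w / sum(df$w))
    }, present[have], shares)
    ti[[v]] <- do.call(rbind, parts)
  }
  trip <- do.call(rbind, ti)
  mat <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(n, n),
                              dimnames = list(names(idx), names(idx)))
  cs <- Matrix::colSums(mat)
  if (max(abs(cs - 1)) > 1e-12) {
    stop("internal error: commixture column sums deviate by ",
         max(abs(cs - 1)))
  }
  structure(list(matrix = mat, node_index = idx, params = params,
                 node_type = net$nodes$type),
            class = "commixture")
}

#' Serialize a commixture matrix to sparse-triplet and node-index TSV files
#'
#' @param cm A `commixture` object.
#' @param triplet_path Output path for the (row, col, value) triplets.
#' @param index_path Output path for the node index (node, position, type).
#' @export
write_commixture <- function(cm, triplet_path, index_path) {
  tm <- methods::as(cm$matrix, "TsparseMatrix")
  trip <- data.frame(row = tm@i + 1L, col = tm@j + 1L, value = tm@x)
  trip <- trip[order(trip$col, trip$row), , drop = FALSE]
  utils::write.table(trip, triplet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nidx <- data.frame(node = names(cm$node_index),
                     position = unname(cm$node_index),
                     type = cm$node_type)
  utils::write.table(nidx, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
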