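# ceRNA-mediated SNP switching pathway networks: enumerate
# lncRNA -> miRNA -> mRNA regulations inside significant pathways, attach
# classified SNPs, compute per-network SNP density/ratio statistics, and
# filter the regulations whose both edges carry regulatory SNPs.

#' Enumerate ceRNA regulations of a pathway
#'
#' A ceRNA regulation is a triple lncRNA -> miRNA -> mRNA such that both
#' interaction edges are evidenced, the mRNA belongs to the pathway, and all
#' three molecules appear in the admitted risk catalog. With
#' `feature_strict = TRUE` (default) the catalog is filtered to the given
#' feature before admission; the permissive setting admits risk molecules of
#' any feature.
#'
#' @param pathway One pathway record: a single-row data frame from
#'   [read_gmt()], or a list with `pathway_id` and `members`.
#' @param feature Feature label of the network being built.
#' @param catalog Risk catalog ([read_risk_catalog()]).
#' @param lnc_mi lncRNA-miRNA interactions ([read_interactions()]).
#' @param mi_m miRNA-mRNA interactions.
#' @param feature_strict Restrict the catalog to `feature`.
#' @return Data frame of regulations with columns `lncrna`, `mirna`, `mrna`,
#'   `pathway_id`, `feature` and empty SNP list columns, ordered
#'   deterministically.
#' @export
build_cerna_network <- function(pathway, feature, catalog, lnc_mi, mi_m,
                                feature_strict = TRUE) {
  if (is.data.frame(pathway)) {
    stopifnot(nrow(pathway) == 1L)
    members <- pathway$members[[1L]]
    pathway_id <- pathway$pathway_id
  } else {
    members <- pathway$members
    pathway_id <- pathway$pathway_id
  }
  cat_f <- if (isTRUE(feature_strict)) {
    catalog[catalog$feature == feature, , drop = FALSE]
  } else catalog
  adm <- split(cat_f$molecule_id, cat_f$molecule_type)
  lncs <- unique(adm$lncRNA); mis <- unique(adm$miRNA)
  ms <- intersect(unique(adm$mRNA), members)

  e1 <- lnc_mi[lnc_mi$regulator %in% lncs & lnc_mi$target %in% mis, ,
               drop = FALSE]
  e2 <- mi_m[mi_m$regulator %in% mis & mi_m$target %in% ms, , drop = FALSE]
  if (nrow(e1) == 0L || nrow(e2) == 0L) {
    return(empty_regulations(pathway_id, feature))
  }
  regs <- merge(
    data.frame(lncrna = e1$regulator, mirna = e1$target,
               stringsAsFactors = FALSE),
    data.frame(mirna = e2$regulator, mrna = e2$target,
               stringsAsFactors = FALSE),
    by = "mirna")
  if (nrow(regs) == 0L) return(empty_regulations(pathway_id, feature))
  regs <- unique(regs[c("lncrna", "mirna", "mrna")])
  regs <- regs[order(regs$lncrna, regs$mirna, regs$mrna), , drop = FALSE]
  regs$pathway_id <- pathway_id
  regs$feature <- feature
  n <- nrow(regs)
  regs$lnc_mi_snps <- replicate(n, character(0L), simplify = FALSE)
  regs$mi_m_snps <- replicate(n, character(0L), simplify = FALSE)
  regs$host_snps <- replicate(n, character(0L), simplify = FALSE)
  rownames(regs) <- NULL
  class(regs) <- c("cerna_regulations", "data.frame")
  regs
}

empty_regulations <- function(pathway_id = character(0L),
                              feature = character(0L)) {
  regs <- data.frame(lncrna = character(0L), mirna = character(0L),
                     mrna = character(0L), pathway_id = character(0L),
                     feature = character(0L), stringsAsFactors = FALSE)
  regs$lnc_mi_snps <- list()
  regs$mi_m_snps <- list()
  regs$host_snps <- list()
  class(regs) <- c("cerna_regulations", "data.frame")
  regs
}

#' Attach classified SNPs to ceRNA regulations
#'
#' Attachment rules per location class:
#' * `lnc_binding_site` on lncRNA L with partner miRNA M attaches to the
#'   lncRNA-miRNA edge of every regulation with that (L, M) pair;
#' * `mirna_seed` on miRNA M attaches to the miRNA-mRNA edge of every
#'   regulation through M;
#' * `utr3` on mRNA G attaches to the miRNA-mRNA edge of regulations
#'   targeting G; when the record names a partner miRNA, only regulations
#'   through that miRNA qualify (a partnerless record attaches to all of
#'   them, a conservative superset);
#' * `lnc_gene_body` (on the regulation's lncRNA) and `pri_pre_mirna` (on
#'   its miRNA) go to the host-SNP slot, which never counts as regulatory.
#'
#' Annotation recomputes all three slots from scratch, so applying it twice
#' equals applying it once.
#'
#' @param regs Regulations from [build_cerna_network()].
#' @param snps SNP records ([read_snp_table()]).
#' @return The regulations with `lnc_mi_snps`, `mi_m_snps`, `host_snps`
#'   filled with sorted rsid vectors.
#' @export
annotate_snps <- function(regs, snps) {
  if (nrow(regs) == 0L) return(regs)
  bs <- snps[snps$location_class == "lnc_binding_site", , drop = FALSE]
  seed_ <- snps[snps$location_class == "mirna_seed", , drop = FALSE]
  utr <- snps[snps$location_class == "utr3", , drop = FALSE]
  body_ <- snps[snps$location_class == "lnc_gene_body", , drop = FALSE]
  pri <- snps[snps$location_class == "pri_pre_mirna", , drop = FALSE]
  no_partner <- function(x) is.na(x) | x == ""
  for (i in seq_len(nrow(regs))) {
    l <- regs$lncrna[i]; mi <- regs$mirna[i]; m <- regs$mrna[i]
    regs$lnc_mi_snps[[i]] <- sort(unique(
      bs$rsid[bs$host_molecule == l & bs$partner_molecule == mi]))
    regs$mi_m_snps[[i]] <- sort(unique(c(
      seed_$rsid[seed_$host_molecule == mi],
      utr$rsid[utr$host_molecule == m &
                 (no_partner(utr$partner_molecule) |
                    utr$partner_molecule == mi)])))
    regs$host_snps[[i]] <- sort(unique(c(
      body_$rsid[body_$host_molecule == l],
      pri$rsid[pri$host_molecule == mi])))
  }
  regs
}

#' Per-network SNP statistics of a ceRNA regulatory network
#'
#' For one pathway's annotated regulation set, counts the regulations, the
#' regulations carrying at least one regulatory SNP (on either edge), and
#' the regulatory SNPs themselves, then derives:
#' * `snp_density` — regulatory SNPs per SNP-carrying regulation (undefined,
#'   reported `NA` with a warning, when no regulation carries one);
#' * `snp_ratio` — the proportion of regulations carrying a regulatory SNP.
#'
#' With `distinct_snps = TRUE` (default) an rsID shared by several
#' regulations counts once in the density numerator; the alternative counts
#' every attachment.
#'
#' @param regs Annotated regulations for one pathway network.
#' @param distinct_snps Count distinct rsIDs rather than attachments.
#' @return One-row data frame: pathway_id, feature, n_regulations,
#'   n_regulations_with_snp, n_regulatory_snps, snp_density, snp_ratio.
#' @export
compute_stats <- function(regs, distinct_snps = TRUE) {
  if (nrow(regs) == 0L) stop("no regulations: statistics undefined")
  reg_snps <- Map(c, regs$lnc_mi_snps, regs$mi_m_snps)
  with_snp <- lengths(reg_snps) > 0L
  n_with <- sum(with_snp)
  n_snps <- if (isTRUE(distinct_snps)) {
    length(unique(unlist(reg_snps, use.names = FALSE)))
  } else {
    sum(lengths(reg_snps))
  }
  if (n_with == 0L) {
    warning("no regulation carries a regulatory SNP; density undefined")
    density <- NA_real_
  } else {
    density <- n_snps / n_with
  }
  data.frame(pathway_id = regs$pathway_id[1L], feature = regs$feature[1L],
             n_regulations = nrow(regs), n_regulations_with_snp = n_with,
             n_regulatory_snps = n_snps, snp_density = density,
             snp_ratio = n_with / nrow(regs), stringsAsFactors = FALSE)
}

#' Switch-candidate regulations
#'
#' Keeps the regulations carrying regulatory SNPs on both edges — the
#' lncRNA-miRNA binding site and the miRNA-mRNA interaction (seed region or
#' 3'UTR) — the configuration in which a variant on either side can toggle
#' the ceRNA balance. An optional list of upstream genes (e.g. receptors at
#' the head of the pathway, curated by the user) restricts candidates to
#' those target mRNAs.
#'
#' @param regs Annotated regulations.
#' @param upstream_genes Optional character vector of mRNA ids.
#' @return The qualifying subset of `regs`.
#' @export
find_switch_candidates <- function(regs, upstream_genes = NULL) {
  keep <- lengths(regs$lnc_mi_snps) > 0L & lengths(regs$mi_m_snps) > 0L
  if (!is.null(upstream_genes)) keep <- keep & regs$mrna %in% upstream_genes
  out <- regs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a ceRNA-SNP network to node/edge tables and GraphML
#'
#' Writes (a) a node table (id, type, has_host_snp, has_regulatory_snp),
#' (b) an edge table with one row per regulation edge (regulation index,
#' source, target, edge class, attached rsIDs) from which the regulation set
#' is fully recoverable, and (c) a GraphML file with the same attributes
#' (edges deduplicated) loadable by standard graph viewers.
#'
#' @param regs Annotated regulations.
#' @param nodes_path,edges_path,graphml_path Output paths; pass `NULL` to
#'   skip a file.
#' @return Invisibly, a list with the node and edge data frames.
#' @export
export_csspn <- function(regs, nodes_path = NULL, edges_path = NULL,
                         graphml_path = NULL) {
  n <- nrow(regs)
  edge_rows <- function(i) {
    rbind(
      data.frame(regulation = i, source = regs$lncrna[i],
                 target = regs$mirna[i], edge_class = "lnc_mi",
                 rsids = paste(regs$lnc_mi_snps[[i]], collapse = ","),
                 stringsAsFactors = FALSE),
      data.frame(regulation = i, source = regs$mirna[i],
                 target = regs$mrna[i], edge_class = "mi_m",
                 rsids = paste(regs$mi_m_snps[[i]], collapse = ","),
                 stringsAsFactors = FALSE))
  }
  edges <- if (n > 0L) do.call(rbind, lapply(seq_len(n), edge_rows)) else
    data.frame(regulation = integer(0L), source = character(0L),
               target = character(0L), edge_class = character(0L),
               rsids = character(0L), stringsAsFactors = FALSE)

  ids <- c(regs$lncrna, regs$mirna, regs$mrna)
  types <- c(rep("lncRNA", n), rep("miRNA", n), rep("mRNA", n))
  host_by_mol <- list()
  reg_by_mol <- list()
  for (i in seq_len(n)) {
    for (mol in c(regs$lncrna[i], regs$mirna[i])) {
      host_by_mol[[mol]] <- c(host_by_mol[[mol]], regs$host_snps[[i]])
    }
    touched <- c(regs$lncrna[i], regs$mirna[i], regs$mrna[i])
    has_reg <- length(regs$lnc_mi_snps[[i]]) + length(regs$mi_m_snps[[i]]) > 0L
    if (has_reg) for (mol in touched) reg_by_mol[[mol]] <- TRUE
  }
  keep <- !duplicated(ids)
  nodes <- data.frame(id = ids[keep], type = types[keep],
                      stringsAsFactors = FALSE)
  nodes$has_host_snp <- vapply(nodes$id, function(m) {
    length(host_by_mol[[m]]) > 0L
  }, logical(1L))
  nodes$has_regulatory_snp <- vapply(nodes$id, function(m) {
    isTRUE(reg_by_mol[[m]])
  }, logical(1L))

  if (!is.null(nodes_path)) {
    utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(edges_path)) {
    utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml_path) && nrow(nodes) > 0L) {
    gedges <- edges[!duplicated(edges[c("source", "target", "edge_class")]),
                    c("source", "target", "edge_class", "rsids"),
                    drop = FALSE]
    g <- igraph::graph_from_data_frame(gedges, directed = TRUE,
                                       vertices = nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(list(nodes = nodes, edges = edges))
}

#' Rebuild a regulation set from exported node/edge tables
#'
#' Inverse of the tabular part of [export_csspn()].
#'
#' @param edges_path Path to the edge table.
#' @return A `cerna_regulations` data frame (without pathway/feature labels).
#' @export
read_csspn_edges <- function(edges_path) {
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE,
                             colClasses = c(regulation = "integer"))
  edges$rsids[is.na(edges$rsids)] <- ""
  regs <- empty_regulations()
  for (k in sort(unique(edges$regulation))) {
    e <- edges[edges$regulation == k, , drop = FALSE]
    e1 <- e[e$edge_class == "lnc_mi", , drop = FALSE]
    e2 <- e[e$edge_class == "mi_m", , drop = FALSE]
    row <- data.frame(lncrna = e1$source, mirna = e1$target,
                      mrna = e2$target, pathway_id = NA_character_,
                      feature = NA_character_, stringsAsFactors = FALSE)
    split_rs <- function(x) {
      if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1L]] else character(0L)
    }
    row$lnc_mi_snps <- list(split_rs(e1$rsids))
    row$mi_m_snps <- list(split_rs(e2$rsids))
    row$host_snps <- list(character(0L))
    regs <- rbind(regs, row)
  }
  rownames(regs) <- NULL
  class(regs) <- c("cerna_regulations", "data.frame")
  regs
}
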