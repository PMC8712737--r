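# Seeded generator of complete, self-consistent input bundles with a
# planted pathway signal, so the whole pipeline is testable without any
# external download. All randomness flows through one seed per bundle
# (R's default Mersenne-Twister generator); the caller's RNG state is left
# untouched.

#' Simulation configuration
#'
#' The planted signal works by topology, not by weights: the planted
#' pathway's members are densified into a module in the gene layer
#' (edge probability `planted_edge_prob` instead of the background
#' probability) and a set of module miRNAs each target several members.
#' The risk catalog then draws a fraction `planted_fraction` of its mRNAs
#' from the module and of its miRNAs from the module miRNAs, the remainder
#' uniformly, so recovery tests whether the walk finds the module rather
#' than reading planted weights.
#'
#' @param n_mrna,n_mirna,n_lncrna Number of molecules per type.
#' @param n_pathways Number of pathway gene sets, split across two synthetic
#'   source databases.
#' @param pathway_size_range Integer pair, members drawn per pathway.
#' @param planted_fraction Fraction of the risk set drawn from the planted
#'   module (mRNAs) and its targeting miRNAs, in (0, 1].
#' @param background_edge_prob Erdos-Renyi edge probability of both
#'   intra-layer networks.
#' @param planted_edge_prob Edge probability inside the planted module.
#' @param intra_weight_range Range of uniform intra-layer edge weights.
#' @param target_prob Probability that a given miRNA targets a given mRNA.
#' @param snp_rate_per_edge Probability that an eligible interaction edge
#'   carries a regulatory SNP, in \[0, 1\]; host-class SNP rates scale with
#'   it.
#' @param risk_n_mrna,risk_n_mirna,risk_n_lncrna Risk catalog sizes.
#' @param feature Feature label of the generated catalog.
#' @param seed Integer seed; bundles are byte-identical given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 200L, n_mirna = 50L, n_lncrna = 10L,
                       n_pathways = 20L, pathway_size_range = c(10L, 25L),
                       planted_fraction = 0.7,
                       background_edge_prob = 0.02,
                       planted_edge_prob = 0.8,
                       intra_weight_range = c(0.3, 1),
                       target_prob = 0.02,
                       snp_rate_per_edge = 0.25,
                       risk_n_mrna = 25L, risk_n_mirna = 8L,
                       risk_n_lncrna = 4L,
                       feature = "inflammation", seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              planted_fraction = planted_fraction,
              background_edge_prob = background_edge_prob,
              planted_edge_prob = planted_edge_prob,
              intra_weight_range = as.numeric(intra_weight_range),
              target_prob = target_prob,
              snp_rate_per_edge = snp_rate_per_edge,
              risk_n_mrna = as.integer(risk_n_mrna),
              risk_n_mirna = as.integer(risk_n_mirna),
              risk_n_lncrna = as.integer(risk_n_lncrna),
              feature = feature, seed = as.integer(seed))
  counts <- c(cfg$n_mrna, cfg$n_mirna, cfg$n_lncrna, cfg$n_pathways,
              cfg$risk_n_mrna, cfg$risk_n_mirna, cfg$risk_n_lncrna)
  if (any(counts <= 0L)) stop("all counts must be positive")
  probs <- c(cfg$background_edge_prob, cfg$planted_edge_prob,
             cfg$target_prob, cfg$snp_rate_per_edge)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$planted_fraction <= 0 || cfg$planted_fraction > 1) {
    stop("planted_fraction must be in (0, 1]")
  }
  if (cfg$pathway_size_range[2L] > cfg$n_mrna) {
    stop("pathway_size_range exceeds the mRNA layer size")
  }
  if (cfg$risk_n_mrna > cfg$n_mrna || cfg$risk_n_mirna > cfg$n_mirna ||
      cfg$risk_n_lncrna > cfg$n_lncrna) {
    stop("risk set larger than the corresponding molecule pool")
  }
  structure(cfg, class = "sim_config")
}

# undirected random edges over `ids`: background probability everywhere,
# plus densification over `module` members; isolated nodes are given one
# low-degree anchor edge so every molecule is registered in its layer
random_layer <- function(ids, p_bg, wrange, module = NULL, p_module = 0) {
  n <- length(ids)
  pairs <- utils::combn(n, 2L)
  p <- rep(p_bg, ncol(pairs))
  if (!is.null(module) && length(module) >= 2L) {
    in_mod <- matrix(ids[pairs] %in% module, nrow = 2L)
    p[in_mod[1L, ] & in_mod[2L, ]] <- p_module
  }
  sel <- stats::runif(ncol(pairs)) < p
  src <- ids[pairs[1L, sel]]
  tgt <- ids[pairs[2L, sel]]
  isolated <- setdiff(ids, c(src, tgt))
  for (v in isolated) {
    u <- sample(setdiff(ids, v), 1L)
    src <- c(src, min(u, v)); tgt <- c(tgt, max(u, v))
  }
  w <- stats::runif(length(src), wrange[1L], wrange[2L])
  edges <- data.frame(source = pmin(src, tgt), target = pmax(src, tgt),
                      weight = round(w, 6L), stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Generate a complete synthetic input bundle
#'
#' Produces, from one seed, every table the pipeline consumes — gene and
#' miRNA layers, miRNA-mRNA and lncRNA-miRNA interactions, pathway sets
#' over two synthetic source databases, a one-feature risk catalog with
#' planted signal, and a classified SNP table — together with a truth record
#' (planted pathway id, module miRNAs, risk ids, emitted counts).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_bundle` with elements `gene_edges`,
#'   `mirna_edges`, `target_edges`, `lnc_mi_edges`, `pathways`, `catalog`,
#'   `snps`, `truth`, `config`.
#' @export
generate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    mrna_ids <- sprintf("G%03d", seq_len(cfg$n_mrna))
    mirna_ids <- sprintf("MIR%03d", seq_len(cfg$n_mirna))
    lnc_ids <- sprintf("LNC%02d", seq_len(cfg$n_lncrna))
    pw_ids <- sprintf("PW%02d", seq_len(cfg$n_pathways))

    sizes <- sample(seq(cfg$pathway_size_range[1L],
                        cfg$pathway_size_range[2L]),
                    cfg$n_pathways, replace = TRUE)
    members <- lapply(sizes, function(s) sort(sample(mrna_ids, s)))
    pathways <- data.frame(
      pathway_id = pw_ids, name = pw_ids,
      source_db = rep(c("SYNDB_A", "SYNDB_B"),
                      length.out = cfg$n_pathways),
      stringsAsFactors = FALSE)
    pathways$members <- members
    planted <- pw_ids[1L]
    planted_members <- members[[1L]]

    gene_edges <- random_layer(mrna_ids, cfg$background_edge_prob,
                               cfg$intra_weight_range,
                               module = planted_members,
                               p_module = cfg$planted_edge_prob)
    mirna_edges <- random_layer(mirna_ids, cfg$background_edge_prob,
                                cfg$intra_weight_range)

    # miRNA -> mRNA targets: uniform background, plus module miRNAs that
    # each target several planted members
    tg <- expand.grid(regulator = mirna_ids, target = mrna_ids,
                      stringsAsFactors = FALSE)
    tg <- tg[stats::runif(nrow(tg)) < cfg$target_prob, , drop = FALSE]
    n_module_mirnas <- max(4L, cfg$risk_n_mirna)
    mod_mi <- sample(mirna_ids, n_module_mirnas)
    extra <- do.call(rbind, lapply(mod_mi, function(mi) {
      data.frame(regulator = mi,
                 target = sample(planted_members,
                                 min(3L, length(planted_members))),
                 stringsAsFactors = FALSE)
    }))
    target_edges <- rbind(tg, extra)
    target_edges <- target_edges[!duplicated(target_edges), , drop = FALSE]
    target_edges <- target_edges[order(target_edges$regulator,
                                       target_edges$target), , drop = FALSE]
    target_edges$regulator_type <- "miRNA"
    target_edges$target_type <- "mRNA"
    target_edges$evidence <- "synthetic"
    rownames(target_edges) <- NULL

    # module miRNAs as emitted: >= 2 planted-member targets
    hit_counts <- table(target_edges$regulator[
      target_edges$target %in% planted_members])
    module_mirnas <- sort(names(hit_counts)[hit_counts >= 2L])

    # lncRNA -> miRNA: each lncRNA gets a couple of module partners plus
    # random ones, so ceRNA triples through the risk set exist
    lnc_mi <- do.call(rbind, lapply(lnc_ids, function(l) {
      partners <- unique(c(
        sample(module_mirnas, min(2L, length(module_mirnas))),
        sample(mirna_ids, sample(2:4, 1L))))
      data.frame(regulator = l, target = sort(partners),
                 stringsAsFactors = FALSE)
    }))
    lnc_mi$regulator_type <- "lncRNA"
    lnc_mi$target_type <- "miRNA"
    lnc_mi$evidence <- "synthetic"
    lnc_mi <- lnc_mi[order(lnc_mi$regulator, lnc_mi$target), , drop = FALSE]
    rownames(lnc_mi) <- NULL

    # risk catalog with planted fraction f
    f <- cfg$planted_fraction
    n_pm <- min(round(f * cfg$risk_n_mrna), length(planted_members))
    risk_m <- c(sample(planted_members, n_pm),
                sample(setdiff(mrna_ids, planted_members),
                       cfg$risk_n_mrna - n_pm))
    n_mm <- min(round(f * cfg$risk_n_mirna), length(module_mirnas))
    risk_mi <- c(sample(module_mirnas, n_mm),
                 sample(setdiff(mirna_ids, module_mirnas),
                        cfg$risk_n_mirna - n_mm))
    # prefer lncRNAs wired to the risk miRNAs
    lnc_hits <- vapply(lnc_ids, function(l) {
      sum(lnc_mi$target[lnc_mi$regulator == l] %in% risk_mi)
    }, numeric(1L))
    risk_lnc <- lnc_ids[order(-lnc_hits, lnc_ids)][seq_len(cfg$risk_n_lncrna)]
    catalog <- data.frame(
      molecule_id = c(sort(risk_m), sort(risk_mi), sort(risk_lnc)),
      molecule_type = c(rep("mRNA", length(risk_m)),
                        rep("miRNA", length(risk_mi)),
                        rep("lncRNA", length(risk_lnc))),
      feature = cfg$feature, stringsAsFactors = FALSE)

    # SNP table: regulatory classes on eligible edges, host classes on
    # molecules at half the edge rate
    rate <- cfg$snp_rate_per_edge
    snp_rows <- list()
    rs_counter <- 0L
    new_rs <- function() {
      rs_counter <<- rs_counter + 1L
      sprintf("rs%06d", rs_counter)
    }
    for (i in seq_len(nrow(lnc_mi))) {
      if (stats::runif(1L) < rate) {
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          rsid = new_rs(), host_molecule = lnc_mi$regulator[i],
          host_type = "lncRNA", location_class = "lnc_binding_site",
          partner_molecule = lnc_mi$target[i], stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(target_edges))) {
      if (stats::runif(1L) < rate) {
        if (stats::runif(1L) < 0.5) {
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            rsid = new_rs(), host_molecule = target_edges$regulator[i],
            host_type = "miRNA", location_class = "mirna_seed",
            partner_molecule = NA_character_, stringsAsFactors = FALSE)
        } else {
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            rsid = new_rs(), host_molecule = target_edges$target[i],
            host_type = "mRNA", location_class = "utr3",
            partner_molecule = target_edges$regulator[i],
            stringsAsFactors = FALSE)
        }
      }
    }
    for (l in lnc_ids) {
      if (stats::runif(1L) < rate / 2) {
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          rsid = new_rs(), host_molecule = l, host_type = "lncRNA",
          location_class = "lnc_gene_body",
          partner_molecule = NA_character_, stringsAsFactors = FALSE)
      }
    }
    for (mi in mirna_ids) {
      if (stats::runif(1L) < rate / 2) {
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          rsid = new_rs(), host_molecule = mi, host_type = "miRNA",
          location_class = "pri_pre_mirna",
          partner_molecule = NA_character_, stringsAsFactors = FALSE)
      }
    }
    snps <- if (length(snp_rows) > 0L) do.call(rbind, snp_rows) else
      data.frame(rsid = character(0L), host_molecule = character(0L),
                 host_type = character(0L), location_class = character(0L),
                 partner_molecule = character(0L), stringsAsFactors = FALSE)

    truth <- list(
      planted_pathway = planted,
      feature = cfg$feature,
      module_mirnas = module_mirnas,
      risk_mrna = sort(risk_m), risk_mirna = sort(risk_mi),
      risk_lncrna = sort(risk_lnc),
      n_gene_edges = nrow(gene_edges),
      n_mirna_edges = nrow(mirna_edges),
      n_target_edges = nrow(target_edges),
      n_lnc_mi_edges = nrow(lnc_mi),
      n_snps = nrow(snps),
      n_snps_by_class = as.list(table(snps$location_class)))

    structure(list(gene_edges = gene_edges, mirna_edges = mirna_edges,
                   target_edges = target_edges, lnc_mi_edges = lnc_mi,
                   pathways = pathways, catalog = catalog, snps = snps,
                   truth = truth, config = cfg),
              class = "sim_bundle")
  })
}

#' Write a bundle to a directory in the pipeline's input dialects
#'
#' Emits `gene_edges.tsv`, `mirna_edges.tsv`, `target_edges.tsv`,
#' `lnc_mi_edges.tsv`, `pathways.gmt`, `risk_catalog.tsv`, `snps.tsv` and
#' `truth.yaml`, exactly the formats the readers in this package consume.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wt(bundle$gene_edges, "gene_edges.tsv")
  wt(bundle$mirna_edges, "mirna_edges.tsv")
  wt(bundle$target_edges[c("regulator", "target", "evidence")],
     "target_edges.tsv")
  wt(bundle$lnc_mi_edges[c("regulator", "target", "evidence")],
     "lnc_mi_edges.tsv")
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  wt(bundle$catalog, "risk_catalog.tsv")
  wt(bundle$snps, "snps.tsv")
  yaml::write_yaml(bundle$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a bundle directory back through the package readers
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `sim_bundle`-shaped list (without `config`).
#' @export
read_bundle <- function(dir) {
  structure(list(
    gene_edges = read_edge_list(file.path(dir, "gene_edges.tsv")),
    mirna_edges = read_edge_list(file.path(dir, "mirna_edges.tsv")),
    target_edges = read_interactions(file.path(dir, "target_edges.tsv"),
                                     "mi_m"),
    lnc_mi_edges = read_interactions(file.path(dir, "lnc_mi_edges.tsv"),
                                     "lnc_mi"),
    pathways = read_gmt(file.path(dir, "pathways.gmt")),
    catalog = read_risk_catalog(file.path(dir, "risk_catalog.tsv")),
    snps = read_snp_table(file.path(dir, "snps.tsv")),
    truth = yaml::read_yaml(file.path(dir, "truth.yaml"))),
    class = "sim_bundle")
}

#' Expected ceRNA-SNP statistics by brute-force recount
#'
#' Recomputes, by plain nested loops over the emitted tables (never through
#' the network builders), the ceRNA regulation triples of a pathway and
#' their SNP statistics. Serves as an independent oracle for
#' [build_cerna_network()], [annotate_snps()] and [compute_stats()].
#'
#' @param bundle A `sim_bundle`.
#' @param pathway_id Pathway to recount (default: the planted pathway).
#' @param feature Feature label (default: the bundle's).
#' @return One-row data frame shaped like [compute_stats()] output, or
#'   `NULL` when the pathway has no regulation.
#' @export
expected_stats <- function(bundle, pathway_id = NULL, feature = NULL) {
  if (is.null(pathway_id)) pathway_id <- bundle$truth$planted_pathway
  if (is.null(feature)) feature <- bundle$truth$feature
  cat_f <- bundle$catalog[bundle$catalog$feature == feature, , drop = FALSE]
  members <- bundle$pathways$members[[
    which(bundle$pathways$pathway_id == pathway_id)]]
  lncs <- cat_f$molecule_id[cat_f$molecule_type == "lncRNA"]
  mis <- cat_f$molecule_id[cat_f$molecule_type == "miRNA"]
  ms <- cat_f$molecule_id[cat_f$molecule_type == "mRNA"]
  lm_key <- paste(bundle$lnc_mi_edges$regulator, bundle$lnc_mi_edges$target)
  mm_key <- paste(bundle$target_edges$regulator, bundle$target_edges$target)
  snps <- bundle$snps
  n_reg <- 0L; n_with <- 0L; rs_seen <- character(0L)
  for (l in lncs) for (mi in mis) for (m in ms) {
    if (!(m %in% members)) next
    if (!(paste(l, mi) %in% lm_key)) next
    if (!(paste(mi, m) %in% mm_key)) next
    n_reg <- n_reg + 1L
    rs <- character(0L)
    for (k in seq_len(nrow(snps))) {
      cls <- snps$location_class[k]
      host <- snps$host_molecule[k]
      partner <- snps$partner_molecule[k]
      hit <- (cls == "lnc_binding_site" && host == l &&
                !is.na(partner) && partner == mi) ||
        (cls == "mirna_seed" && host == mi) ||
        (cls == "utr3" && host == m &&
           (is.na(partner) || partner == "" || partner == mi))
      if (hit) rs <- c(rs, snps$rsid[k])
    }
    if (length(rs) > 0L) n_with <- n_with + 1L
    rs_seen <- union(rs_seen, rs)
  }
  if (n_reg == 0L) return(NULL)
  data.frame(pathway_id = pathway_id, feature = feature,
             n_regulations = n_reg, n_regulations_with_snp = n_with,
             n_regulatory_snps = length(rs_seen),
             snp_density = if (n_with > 0L) length(rs_seen) / n_with
                           else NA_real_,
             snp_ratio = n_with / n_reg, stringsAsFactors = FALSE)
}
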