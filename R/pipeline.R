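# End-to-end orchestration: declarative run configuration, validation
# before any compute, and the per-feature chain
# network build -> commixture -> walk -> embedding -> scores -> significant
# set -> ceRNA-SNP networks. The command-line wrapper in inst/cli is a thin
# shell over run_pipeline().

PIPELINE_DEFAULTS <- list(
  gene_edges = NULL, mirna_edges = NULL, target_edges = NULL,
  lnc_mi_edges = NULL, gmt = NULL, catalog = NULL, snps = NULL,
  out_dir = "mhnpath_out",
  restart = 0.7, delta = 0.3, lambda = 0.2,
  dim = 128L, tol = 1e-10, max_iter = 10000L,
  symmetrize = FALSE, log_transform = FALSE,
  link_mirna_pathways = FALSE, mirna_link_min_targets = 3L,
  agg = "mean", n_perm = 199L, seed = 1L,
  ranking_threshold = 6, p_threshold = 0.05,
  feature_strict = TRUE, switch_only = FALSE, top_k = 0L)

#' Resolve and validate a run configuration
#'
#' A configuration is a flat key-value document (an R list, or a path to a
#' YAML file). Every key has a default; unknown keys are rejected.
#' Validation — parameter ranges and existence of every input file — happens
#' before any computation starts.
#'
#' @param config A named list, or a YAML file path.
#' @return The fully resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  walk_params(cfg$restart, cfg$delta, cfg$lambda)  # range validation
  if (cfg$n_perm < 0L) stop("n_perm must be >= 0")
  inputs <- c("gene_edges", "mirna_edges", "target_edges", "lnc_mi_edges",
              "gmt", "catalog", "snps")
  for (key in inputs) {
    p <- cfg[[key]]
    if (is.null(p)) stop("missing required input path: ", key)
    if (!file.exists(p)) stop("input file for '", key, "' not found: ", p)
  }
  cfg
}

#' Run the full prioritization and ceRNA-SNP pipeline
#'
#' For each feature in the risk catalog: builds the multiplex-heterogeneous
#' network, the commixture matrix and the proximity embedding, scores every
#' pathway with per-database ranking scores and permutation p-values, writes
#' the score table, then builds the annotated ceRNA regulation network of
#' every significant pathway and writes node/edge/GraphML exports, the
#' per-network SNP statistics table and the switch-candidate table. The
#' resolved configuration is echoed to `resolved_config.yaml` and its MD5
#' checksum recorded in `run_manifest.tsv` next to every output file name,
#' so each run is attributable to the exact configuration that produced it.
#'
#' @param config A named list or YAML path, see [resolve_config()].
#' @return Invisibly, a list with the resolved config, per-feature score
#'   tables, significant sets, ceRNA statistics and output paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- resolve_config(config)

  gene_edges <- read_edge_list(cfg$gene_edges)
  mirna_edges <- read_edge_list(cfg$mirna_edges)
  target_edges <- read_interactions(cfg$target_edges, "mi_m")
  lnc_mi <- read_interactions(cfg$lnc_mi_edges, "lnc_mi")
  pathways <- read_gmt(cfg$gmt)
  catalog <- read_risk_catalog(cfg$catalog)
  snps <- read_snp_table(cfg$snps)

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "resolved_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  config_md5 <- unname(tools::md5sum(cfg_path))

  features <- sort(unique(catalog$feature))
  params <- walk_params(cfg$restart, cfg$delta, cfg$lambda)
  manifest <- list()
  all_scores <- list(); all_sig <- list(); all_stats <- list()
  all_switch <- list()

  for (feat in features) {
    pipeline_log("building network for feature '%s'", feat)
    net <- build_network(gene_edges, mirna_edges, target_edges, pathways,
                         link_mirna_pathways = cfg$link_mirna_pathways,
                         mirna_link_min_targets = cfg$mirna_link_min_targets)
    cm <- to_commixture(net, params)
    P <- rwr_all(cm, r = cfg$restart, tol = cfg$tol,
                 max_iter = cfg$max_iter)
    d <- min(cfg$dim, nrow(P$matrix) - 1L)
    emb <- svd_embed(P, d = d, symmetrize = cfg$symmetrize,
                     log_transform = cfg$log_transform)
    node_type <- stats::setNames(net$nodes$type, net$nodes$id)

    cat_f <- catalog[catalog$feature == feat, , drop = FALSE]
    risk <- cat_f$molecule_id[cat_f$molecule_type %in% c("mRNA", "miRNA")]
    scores <- score_pathways(emb, pathways, risk, feature = feat,
                             node_type = node_type, n_perm = cfg$n_perm,
                             perm_seed = cfg$seed, agg = cfg$agg)
    score_path <- file.path(cfg$out_dir,
                            sprintf("scores_%s.tsv", safe_name(feat)))
    write_scores(scores, score_path)
    manifest[[length(manifest) + 1L]] <- score_path
    if (cfg$top_k > 0L) {
      topk <- do.call(rbind, lapply(split(scores, scores$source_db),
                                    function(g) {
        g[order(-g$ranking_score), , drop = FALSE][
          seq_len(min(cfg$top_k, nrow(g))), , drop = FALSE]
      }))
      topk_path <- file.path(cfg$out_dir,
                             sprintf("top%d_%s.tsv", cfg$top_k,
                                     safe_name(feat)))
      write_scores(topk, topk_path)
      manifest[[length(manifest) + 1L]] <- topk_path
    }
    sig <- select_significant(scores, cfg$ranking_threshold,
                              cfg$p_threshold)
    pipeline_log("feature '%s': %d/%d pathways significant", feat,
                 nrow(sig), nrow(scores))

    stats_rows <- list(); switch_rows <- list()
    for (pid in sig$pathway_id) {
      pw <- pathways[pathways$pathway_id == pid, , drop = FALSE]
      regs <- build_cerna_network(pw, feat, catalog, lnc_mi, target_edges,
                                  feature_strict = cfg$feature_strict)
      if (nrow(regs) == 0L) next
      regs <- annotate_snps(regs, snps)
      stats_rows[[pid]] <- compute_stats(regs)
      sw <- find_switch_candidates(regs)
      if (nrow(sw) > 0L) switch_rows[[pid]] <- sw
      base <- sprintf("csspn_%s_%s", safe_name(feat), safe_name(pid))
      to_export <- if (isTRUE(cfg$switch_only)) sw else regs
      if (nrow(to_export) > 0L) {
        export_csspn(to_export,
                     nodes_path = file.path(cfg$out_dir,
                                            paste0(base, "_nodes.tsv")),
                     edges_path = file.path(cfg$out_dir,
                                            paste0(base, "_edges.tsv")),
                     graphml_path = file.path(cfg$out_dir,
                                              paste0(base, ".graphml")))
        manifest[[length(manifest) + 1L]] <-
          file.path(cfg$out_dir, paste0(base, "_edges.tsv"))
      }
    }
    if (length(stats_rows) > 0L) {
      stats_df <- do.call(rbind, stats_rows)
      rownames(stats_df) <- NULL
      stats_path <- file.path(cfg$out_dir,
                              sprintf("csspn_stats_%s.tsv", safe_name(feat)))
      utils::write.table(stats_df, stats_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest[[length(manifest) + 1L]] <- stats_path
      all_stats[[feat]] <- stats_df
    }
    if (length(switch_rows) > 0L) {
      sw_df <- do.call(rbind, lapply(switch_rows, flatten_regulations))
      rownames(sw_df) <- NULL
      sw_path <- file.path(cfg$out_dir,
                           sprintf("switch_candidates_%s.tsv",
                                   safe_name(feat)))
      utils::write.table(sw_df, sw_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest[[length(manifest) + 1L]] <- sw_path
      all_switch[[feat]] <- sw_df
    }
    all_scores[[feat]] <- scores
    all_sig[[feat]] <- sig
  }

  man <- data.frame(file = basename(unlist(manifest)),
                    config_md5 = config_md5, stringsAsFactors = FALSE)
  utils::write.table(man, file.path(cfg$out_dir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(config = cfg, config_md5 = config_md5,
                 scores = all_scores, significant = all_sig,
                 csspn_stats = all_stats, switch_candidates = all_switch,
                 out_dir = cfg$out_dir))
}

# regulations with list columns flattened to comma-joined strings for TSV
flatten_regulations <- function(regs) {
  out <- regs[c("lncrna", "mirna", "mrna", "pathway_id", "feature")]
  out$lnc_mi_snps <- vapply(regs$lnc_mi_snps, paste, character(1L),
                            collapse = ",")
  out$mi_m_snps <- vapply(regs$mi_m_snps, paste, character(1L),
                          collapse = ",")
  out$host_snps <- vapply(regs$host_snps, paste, character(1L),
                          collapse = ",")
  out
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

pipeline_log <- function(fmt, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [INFO] ",
          sprintf(fmt, ...))
}
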