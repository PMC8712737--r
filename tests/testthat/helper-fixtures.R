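# Shared fixtures and independent oracles. Everything is generated in code;
# no fixture files are stored.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent RWR oracle: exact solve of (I - (1-r)T) p = r * seed
rwr_solve_oracle <- function(Tm, seed_vec, r) {
  Tm <- as.matrix(Tm)
  as.numeric(solve(diag(nrow(Tm)) - (1 - r) * Tm, r * seed_vec))
}

# independent hypergeometric tail oracle: direct summation of
# C(m, x) C(n_univ - m, k - x) / C(n_univ, k) for x = q..min(m, k)
hyper_tail_oracle <- function(q, m, n_univ, k) {
  xs <- q:min(m, k)
  xs <- xs[xs >= max(0L, k - (n_univ - m))]
  if (length(xs) == 0L) return(0)
  sum(choose(m, xs) * choose(n_univ - m, k - xs)) / choose(n_univ, k)
}

# a random multiplex-heterogeneous instance (raw tables + built network),
# sized for exactness tests; includes miRNAs without couplings and, with
# some seeds, pathways with no linkable members
random_mh_instance <- function(seed, n_genes = 12L, n_mirnas = 6L,
                               n_pathways = 3L) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  mirnas <- sprintf("mi%02d", seq_len(n_mirnas))
  rand_edges <- function(ids, n_edges) {
    pick <- t(replicate(n_edges, sort(sample(ids, 2L))))
    df <- data.frame(source = pick[, 1L], target = pick[, 2L],
                     weight = round(stats::runif(n_edges, 0.1, 1), 4L),
                     stringsAsFactors = FALSE)
    df[!duplicated(df[1:2]), , drop = FALSE]
  }
  gene_edges <- rand_edges(genes, n_genes * 2L)
  mirna_edges <- rand_edges(mirnas, n_mirnas)
  n_cp <- max(1L, rpois(1L, n_mirnas))
  target_edges <- data.frame(
    regulator = sample(mirnas, n_cp, replace = TRUE),
    target = sample(genes, n_cp, replace = TRUE),
    regulator_type = "miRNA", target_type = "mRNA",
    evidence = "syn", stringsAsFactors = FALSE)
  target_edges <- target_edges[!duplicated(target_edges[1:2]), ,
                               drop = FALSE]
  members <- lapply(seq_len(n_pathways), function(i) {
    if (i == n_pathways && seed %% 3L == 0L) {
      "unregistered_gene"  # pathway with no linkable members (dangling)
    } else {
      sample(genes, sample(2:5, 1L))
    }
  })
  pathways <- data.frame(pathway_id = sprintf("pw%02d", seq_len(n_pathways)),
                         name = sprintf("pw%02d", seq_len(n_pathways)),
                         source_db = "DB", stringsAsFactors = FALSE)
  pathways$members <- members
  net <- suppressWarnings(suppressMessages(
    build_network(gene_edges, mirna_edges, target_edges, pathways)))
  list(gene_edges = gene_edges, mirna_edges = mirna_edges,
       target_edges = target_edges, pathways = pathways, net = net)
}

# hand-built embedding space for scoring tests
toy_embedding <- function(source, target) {
  structure(list(d = ncol(source), source = source, target = target,
                 singular_values = rep(1, ncol(source))),
            class = "embedding_space")
}

# annotated regulations encoding the MALAT1 -> hsa-miR-155 -> IL13 switch
# pattern: binding-site SNP on the lncRNA-miRNA edge, 3'UTR SNP on the
# miRNA-mRNA edge
malat1_fixture <- function() {
  regs <- build_cerna_network(
    list(pathway_id = "IL4_IL13_SIGNALING", members = c("IL13", "STAT6")),
    feature = "inflammation",
    catalog = data.frame(
      molecule_id = c("MALAT1", "hsa-miR-155", "IL13", "NEAT1"),
      molecule_type = c("lncRNA", "miRNA", "mRNA", "lncRNA"),
      feature = "inflammation", stringsAsFactors = FALSE),
    lnc_mi = data.frame(regulator = c("MALAT1", "NEAT1"),
                        target = c("hsa-miR-155", "hsa-miR-155"),
                        regulator_type = "lncRNA", target_type = "miRNA",
                        evidence = "curated", stringsAsFactors = FALSE),
    mi_m = data.frame(regulator = "hsa-miR-155", target = "IL13",
                      regulator_type = "miRNA", target_type = "mRNA",
                      evidence = "curated", stringsAsFactors = FALSE))
  snps <- data.frame(
    rsid = c("rs765499057", "rs764699354", "rs189435941",
             "rs201185816", "rs1000978586", "rs202101165"),
    host_molecule = c("MALAT1", "MALAT1", "MALAT1",
                      "IL13", "IL13", "IL13"),
    host_type = c(rep("lncRNA", 3L), rep("mRNA", 3L)),
    location_class = c(rep("lnc_binding_site", 3L), rep("utr3", 3L)),
    partner_molecule = rep("hsa-miR-155", 6L),
    stringsAsFactors = FALSE)
  annotate_snps(regs, snps)
}
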