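micro_catalog <- function() {
  data.frame(
    molecule_id = c("L1", "L2", "M1", "M2", "G1", "G2", "G3"),
    molecule_type = c("lncRNA", "lncRNA", "miRNA", "miRNA",
                      "mRNA", "mRNA", "mRNA"),
    feature = "inflammation", stringsAsFactors = FALSE)
}

inter <- function(reg, tgt, kind) {
  types <- if (kind == "lnc_mi") c("lncRNA", "miRNA") else c("miRNA", "mRNA")
  data.frame(regulator = reg, target = tgt, regulator_type = types[1L],
             target_type = types[2L], evidence = "e",
             stringsAsFactors = FALSE)
}

test_that("triples require both edges, pathway membership and catalog admission", {
  cat_ <- micro_catalog()
  lnc_mi <- inter("L1", "M1", "lnc_mi")
  mi_m <- inter("M1", "G1", "mi_m")
  pw <- list(pathway_id = "P1", members = "G1")
  regs <- build_cerna_network(pw, "inflammation", cat_, lnc_mi, mi_m)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$lncrna, "L1")
  expect_equal(regs$mirna, "M1")
  expect_equal(regs$mrna, "G1")

  # mRNA outside the pathway
  regs <- build_cerna_network(list(pathway_id = "P1", members = "G2"),
                              "inflammation", cat_, lnc_mi, mi_m)
  expect_equal(nrow(regs), 0L)
  # molecule missing from the feature catalog
  regs <- build_cerna_network(pw, "remodeling", cat_, lnc_mi, mi_m)
  expect_equal(nrow(regs), 0L)
  regs <- build_cerna_network(pw, "remodeling", cat_, lnc_mi, mi_m,
                              feature_strict = FALSE)
  expect_equal(nrow(regs), 1L)
})

test_that("shared miRNAs expand combinatorially: 2 lncRNAs x 2 targets = 4 triples", {
  cat_ <- micro_catalog()
  lnc_mi <- inter(c("L1", "L2"), c("M1", "M1"), "lnc_mi")
  mi_m <- inter(c("M1", "M1"), c("G1", "G2"), "mi_m")
  regs <- build_cerna_network(list(pathway_id = "P1",
                                   members = c("G1", "G2")),
                              "inflammation", cat_, lnc_mi, mi_m)
  expect_equal(nrow(regs), 4L)
  expect_equal(regs[order(regs$lncrna, regs$mrna), ]$mrna,
               c("G1", "G2", "G1", "G2"))
})

test_that("triple enumeration matches a brute-force cross join", {
  set.seed(23)
  for (k in 1:20) {
    cat_ <- micro_catalog()
    lnc_mi <- unique(inter(sample(c("L1", "L2"), 6L, TRUE),
                           sample(c("M1", "M2"), 6L, TRUE), "lnc_mi"))
    mi_m <- unique(inter(sample(c("M1", "M2"), 6L, TRUE),
                         sample(c("G1", "G2", "G3"), 6L, TRUE), "mi_m"))
    members <- sample(c("G1", "G2", "G3"), sample(1:3, 1L))
    regs <- build_cerna_network(list(pathway_id = "P", members = members),
                                "inflammation", cat_, lnc_mi, mi_m)
    brute <- 0L
    for (l in c("L1", "L2")) for (mi in c("M1", "M2")) {
      for (m in members) {
        if (any(lnc_mi$regulator == l & lnc_mi$target == mi) &&
            any(mi_m$regulator == mi & mi_m$target == m)) {
          brute <- brute + 1L
        }
      }
    }
    expect_equal(nrow(regs), brute)
  }
})

test_that("SNPs attach by host, class and partner; annotation is idempotent", {
  cat_ <- micro_catalog()
  regs <- build_cerna_network(
    list(pathway_id = "P1", members = c("G1", "G2")), "inflammation",
    cat_, inter(c("L1", "L1"), c("M1", "M2"), "lnc_mi"),
    inter(c("M1", "M2"), c("G1", "G1"), "mi_m"))
  expect_equal(nrow(regs), 2L)  # (L1,M1,G1), (L1,M2,G1)
  snps <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    host_molecule = c("L1", "G1", "M1", "L1", "M1"),
    host_type = c("lncRNA", "mRNA", "miRNA", "lncRNA", "miRNA"),
    location_class = c("lnc_binding_site", "utr3", "mirna_seed",
                       "lnc_gene_body", "pri_pre_mirna"),
    partner_molecule = c("M1", "M2", NA, NA, NA),
    stringsAsFactors = FALSE)
  ann <- annotate_snps(regs, snps)
  i1 <- which(ann$mirna == "M1"); i2 <- which(ann$mirna == "M2")
  # binding-site SNP only on the (L1, M1) edge
  expect_equal(ann$lnc_mi_snps[[i1]], "rs1")
  expect_equal(ann$lnc_mi_snps[[i2]], character(0L))
  # 3'UTR SNP with partner M2 attaches only to the M2 regulation;
  # seed SNP on M1 only to the M1 regulation
  expect_equal(ann$mi_m_snps[[i1]], "rs3")
  expect_equal(ann$mi_m_snps[[i2]], "rs2")
  # host classes are never regulatory
  expect_equal(ann$host_snps[[i1]], c("rs4", "rs5"))
  expect_equal(ann$host_snps[[i2]], "rs4")
  expect_identical(annotate_snps(ann, snps), ann)

  # a partnerless 3'UTR SNP attaches to all regulations through the mRNA
  snps2 <- snps
  snps2$partner_molecule[2L] <- NA
  ann2 <- annotate_snps(regs, snps2)
  expect_true("rs2" %in% ann2$mi_m_snps[[i1]])
  expect_true("rs2" %in% ann2$mi_m_snps[[i2]])
})

test_that("a seed-region SNP is shared by every regulation through its miRNA", {
  cat_ <- micro_catalog()
  regs <- build_cerna_network(
    list(pathway_id = "P1", members = c("G1", "G2")), "inflammation",
    cat_, inter(c("L1", "L2"), c("M1", "M1"), "lnc_mi"),
    inter(c("M1", "M1"), c("G1", "G2"), "mi_m"))
  snps <- data.frame(rsid = "rs9", host_molecule = "M1",
                     host_type = "miRNA", location_class = "mirna_seed",
                     partner_molecule = NA, stringsAsFactors = FALSE)
  ann <- annotate_snps(regs, snps)
  expect_true(all(vapply(ann$mi_m_snps, function(s) "rs9" %in% s,
                         logical(1L))))
})

test_that("network statistics follow the density and ratio definitions", {
  # 4 regulations, 2 carrying SNPs, 5 distinct regulatory SNPs
  regs <- empty_regs <- build_cerna_network(
    list(pathway_id = "P1", members = c("G1", "G2")), "inflammation",
    micro_catalog(),
    inter(c("L1", "L2"), c("M1", "M1"), "lnc_mi"),
    inter(c("M1", "M1"), c("G1", "G2"), "mi_m"))
  expect_equal(nrow(regs), 4L)
  regs$lnc_mi_snps <- list(c("rs1", "rs2"), character(0L),
                           c("rs3"), character(0L))
  regs$mi_m_snps <- list(c("rs4"), character(0L), c("rs5"), character(0L))
  st <- compute_stats(regs)
  expect_equal(st$n_regulations, 4L)
  expect_equal(st$n_regulations_with_snp, 2L)
  expect_equal(st$n_regulatory_snps, 5L)
  expect_equal(st$snp_density, 2.5)
  expect_equal(st$snp_ratio, 0.5)
  # identity: density * regulations-with-snp = distinct regulatory SNPs
  expect_equal(st$snp_density * st$n_regulations_with_snp,
               st$n_regulatory_snps)

  # no SNP anywhere: ratio 0, density undefined
  expect_warning(st0 <- compute_stats(empty_regs), "undefined")
  expect_equal(st0$snp_ratio, 0)
  expect_true(is.na(st0$snp_density))

  # one SNP shared by two regulations counts once distinct, twice by
  # attachment
  regs$lnc_mi_snps <- list("rs1", "rs1", character(0L), character(0L))
  regs$mi_m_snps <- replicate(4L, character(0L), simplify = FALSE)
  st1 <- compute_stats(regs)
  expect_equal(st1$n_regulatory_snps, 1L)
  expect_equal(st1$snp_density, 0.5)
  st2 <- compute_stats(regs, distinct_snps = FALSE)
  expect_equal(st2$n_regulatory_snps, 2L)
  expect_equal(st2$snp_density, 1)

  expect_error(compute_stats(empty_regs[0L, ]), "no regulations")
})

test_that("switch candidates need regulatory SNPs on both edges", {
  regs <- build_cerna_network(
    list(pathway_id = "P1", members = c("G1", "G2")), "inflammation",
    micro_catalog(),
    inter(c("L1", "L2"), c("M1", "M1"), "lnc_mi"),
    inter(c("M1", "M1"), c("G1", "G2"), "mi_m"))
  regs$lnc_mi_snps <- list("rs1", "rs2", character(0L), character(0L))
  regs$mi_m_snps <- list("rs3", character(0L), "rs4", character(0L))
  sw <- find_switch_candidates(regs)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$lncrna, regs$lncrna[1L])
  # upstream-gene restriction
  expect_equal(nrow(find_switch_candidates(regs, upstream_genes = "G9")),
               0L)
  expect_equal(nrow(find_switch_candidates(regs[0L, ])), 0L)
})

test_that("the MALAT1 / miR-155 / IL13 switch pattern is kept", {
  ann <- malat1_fixture()
  # MALAT1 and NEAT1 both reach IL13 through hsa-miR-155; only MALAT1
  # carries binding-site SNPs
  expect_equal(nrow(ann), 2L)
  sw <- find_switch_candidates(ann)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$lncrna, "MALAT1")
  expect_equal(sw$mrna, "IL13")
  expect_true("rs765499057" %in% sw$lnc_mi_snps[[1L]])
  expect_true("rs201185816" %in% sw$mi_m_snps[[1L]])
})

test_that("network export writes recoverable node and edge tables", {
  ann <- malat1_fixture()
  np <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  out <- export_csspn(ann, np, ep, gp)
  # 2 regulations over 4 molecules, 2 edges each
  expect_equal(nrow(out$nodes), 4L)
  expect_equal(nrow(out$edges), 4L)
  expect_true(out$nodes$has_regulatory_snp[out$nodes$id == "MALAT1"])
  back <- read_csspn_edges(ep)
  expect_equal(back$lncrna, ann$lncrna)
  expect_equal(back$mirna, ann$mirna)
  expect_equal(back$mrna, ann$mrna)
  expect_identical(back$lnc_mi_snps, ann$lnc_mi_snps)
  expect_identical(back$mi_m_snps, ann$mi_m_snps)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)  # shared miRNA->mRNA edge deduplicated

  # single regulation: 3 nodes, 2 edges
  one <- export_csspn(ann[1L, ], NULL, NULL, NULL)
  expect_equal(nrow(one$nodes), 3L)
  expect_equal(nrow(one$edges), 2L)
})

test_that("switch marking scales to many regulations in the export", {
  cat_ <- data.frame(
    molecule_id = c(sprintf("L%d", 1:11), "MX", sprintf("G%d", 1:11)),
    molecule_type = c(rep("lncRNA", 11L), "miRNA", rep("mRNA", 11L)),
    feature = "remodeling", stringsAsFactors = FALSE)
  lnc_mi <- inter(sprintf("L%d", 1:11), rep("MX", 11L), "lnc_mi")
  mi_m <- inter(rep("MX", 11L), sprintf("G%d", 1:11), "mi_m")
  # 11 disjoint switch triples: pair L_i with G_i only
  regs <- build_cerna_network(
    list(pathway_id = "P", members = sprintf("G%d", 1:11)),
    "remodeling", cat_, lnc_mi, mi_m)
  regs <- regs[regs$mrna == sub("L", "G", regs$lncrna), ]
  rownames(regs) <- NULL
  expect_equal(nrow(regs), 11L)
  regs$lnc_mi_snps <- as.list(sprintf("rsA%d", 1:11))
  regs$mi_m_snps <- as.list(sprintf("rsB%d", 1:11))
  sw <- find_switch_candidates(regs)
  expect_equal(nrow(sw), 11L)
  gp <- withr::local_tempfile(fileext = ".graphml")
  export_csspn(sw, NULL, NULL, gp)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(sum(igraph::E(g)$edge_class == "lnc_mi"), 11L)
  expect_equal(sum(igraph::E(g)$edge_class == "mi_m"), 11L)
})
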