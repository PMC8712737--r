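mini_instance <- function() {
  gene_edges <- data.frame(source = "GA", target = "GB", weight = 1)
  mirna_edges <- data.frame(source = "M1", target = "M2", weight = 0.5)
  target_edges <- data.frame(regulator = "M1", target = "GA",
                             regulator_type = "miRNA",
                             target_type = "mRNA", evidence = "e")
  pathways <- data.frame(pathway_id = "P1", name = "P1", source_db = "DB")
  pathways$members <- list(c("GA", "GB"))
  list(gene_edges = gene_edges, mirna_edges = mirna_edges,
       target_edges = target_edges, pathways = pathways)
}

test_that("node registration is deterministic and typed", {
  x <- mini_instance()
  net <- build_network(x$gene_edges, x$mirna_edges, x$target_edges,
                       x$pathways)
  # sorted mRNAs, then sorted miRNAs, then pathway ids
  expect_equal(names(net$node_index), c("GA", "GB", "M1", "M2", "P1"))
  expect_equal(unname(net$node_index), 1:5)
  expect_equal(net$nodes$type, c("mRNA", "mRNA", "miRNA", "miRNA",
                                 "pathway"))
})

test_that("coupling edges with unregistered endpoints are dropped and counted", {
  x <- mini_instance()
  x$target_edges <- rbind(x$target_edges,
                          data.frame(regulator = "M9", target = "GX",
                                     regulator_type = "miRNA",
                                     target_type = "mRNA", evidence = "e"))
  expect_message(
    net <- build_network(x$gene_edges, x$mirna_edges, x$target_edges,
                         x$pathways),
    "dropped")
  expect_equal(net$dropped$coupling, 1L)
  expect_equal(nrow(net$coupling), 1L)
})

test_that("empty gene layer errors; memberless pathway kept with warning", {
  x <- mini_instance()
  expect_error(build_network(x$gene_edges[0L, ], x$mirna_edges,
                             x$target_edges, x$pathways), "empty")
  x$pathways$members <- list("NOT_A_GENE")
  expect_warning(
    net <- build_network(x$gene_edges, x$mirna_edges, x$target_edges,
                         x$pathways),
    "no linkable members")
  expect_true("P1" %in% names(net$node_index))
  cm <- to_commixture(net)
  expect_equal(cm$matrix["P1", "P1"], 1)  # self-loop keeps it stochastic
})

test_that("build is invariant to input row order", {
  x <- random_mh_instance(11L)
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  set.seed(99)
  net2 <- suppressWarnings(suppressMessages(build_network(
    shuf(x$gene_edges), shuf(x$mirna_edges), shuf(x$target_edges),
    x$pathways[sample(nrow(x$pathways)), , drop = FALSE])))
  expect_identical(net2$node_index, x$net$node_index)
  expect_equal(as.matrix(to_commixture(net2)$matrix),
               as.matrix(to_commixture(x$net)$matrix))
})

test_that("column mass splits by edge class and renormalizes absent classes", {
  # intra-layer only, weights {2, 3}: lambda/delta shares renormalize away
  ge <- data.frame(source = c("GA", "GA"), target = c("GB", "GC"),
                   weight = c(2, 3))
  me <- data.frame(source = "M1", target = "M2", weight = 1)
  te <- data.frame(regulator = "M1", target = "GA",
                   regulator_type = "miRNA", target_type = "mRNA",
                   evidence = "e")
  pw <- data.frame(pathway_id = "P1", name = "P1", source_db = "DB")
  pw$members <- list("GA")
  net <- build_network(ge, me, te, pw)
  cm <- to_commixture(net, walk_params(0.7, 0.3, 0.2))
  expect_equal(cm$matrix["GA", "GC"], 1)  # GC: single intra neighbor
  # GB has one intra edge (to GA) only
  expect_equal(cm$matrix["GA", "GB"], 1)
  # GA has intra {2 to GB, 3 to GC}, coupling to M1, pathway link to P1:
  # shares 0.5 / 0.3 / 0.2
  expect_equal(cm$matrix["GB", "GA"], 0.5 * 2 / 5)
  expect_equal(cm$matrix["GC", "GA"], 0.5 * 3 / 5)
  expect_equal(cm$matrix["M1", "GA"], 0.3)
  expect_equal(cm$matrix["P1", "GA"], 0.2)
  # pathway node sends all mass to members
  expect_equal(cm$matrix["GA", "P1"], 1)
})

test_that("three-class split example: one neighbor per class gives {0.5, 0.3, 0.2}", {
  ge <- data.frame(source = "GA", target = "GB", weight = 1)
  me <- data.frame(source = "M1", target = "M2", weight = 1)
  te <- data.frame(regulator = "M1", target = "GA",
                   regulator_type = "miRNA", target_type = "mRNA",
                   evidence = "e")
  pw <- data.frame(pathway_id = "P1", name = "P1", source_db = "DB")
  pw$members <- list("GA")
  cm <- to_commixture(build_network(ge, me, te, pw),
                      walk_params(0.7, 0.3, 0.2))
  col <- as.numeric(cm$matrix[, "GA"])
  names(col) <- rownames(cm$matrix)
  expect_equal(unname(col[c("GB", "M1", "P1")]), c(0.5, 0.3, 0.2))
})

test_that("parameter validation rejects delta + lambda >= 1", {
  expect_error(walk_params(0.7, 0.6, 0.4), "delta \\+ lambda")
  expect_error(walk_params(1.2, 0.3, 0.2), "restart")
})

test_that("columns are stochastic over many random instances", {
  for (s in 1:100) {
    x <- random_mh_instance(s, n_genes = sample(5:20, 1L),
                            n_mirnas = sample(2:10, 1L),
                            n_pathways = sample(1:4, 1L))
    cm <- to_commixture(x$net)
    expect_lt(max(abs(Matrix::colSums(cm$matrix) - 1)), 1e-12)
    expect_true(all(cm$matrix@x >= 0))
  }
})

test_that("relabeling node ids permutes the commixture matrix", {
  x <- random_mh_instance(5L)
  # string reversal changes the sort order, so the permutation is nontrivial
  relabel <- function(v) {
    out <- vapply(strsplit(v, ""), function(s) {
      paste(rev(s), collapse = "")
    }, character(1L))
    ifelse(v %in% x$pathways$pathway_id, v, out)
  }
  net2 <- suppressWarnings(suppressMessages(build_network(
    transform(x$gene_edges, source = relabel(source),
              target = relabel(target)),
    transform(x$mirna_edges, source = relabel(source),
              target = relabel(target)),
    transform(x$target_edges, regulator = relabel(regulator),
              target = relabel(target)),
    {
      pw <- x$pathways
      pw$members <- lapply(pw$members, relabel)
      pw
    })))
  m1 <- as.matrix(to_commixture(x$net)$matrix)
  m2 <- as.matrix(to_commixture(net2)$matrix)
  perm <- match(relabel(rownames(m1)), rownames(m2))
  expect_lt(max(abs(m2[perm, perm] - m1)), 1e-15)
})

test_that("adding one intra-layer edge changes only the two affected columns", {
  x <- random_mh_instance(7L)
  genes <- x$net$nodes$id[x$net$nodes$type == "mRNA"]
  existing <- paste(x$gene_edges$source, x$gene_edges$target)
  pick <- NULL
  for (a in genes) for (b in genes) {
    if (a < b && !(paste(a, b) %in% existing)) { pick <- c(a, b); break }
  }
  ge2 <- rbind(x$gene_edges,
               data.frame(source = pick[1L], target = pick[2L],
                          weight = 0.9))
  net2 <- suppressWarnings(suppressMessages(build_network(
    ge2, x$mirna_edges, x$target_edges, x$pathways)))
  m1 <- as.matrix(to_commixture(x$net)$matrix)
  m2 <- as.matrix(to_commixture(net2)$matrix)
  untouched <- setdiff(colnames(m1), pick)
  expect_equal(m2[, untouched], m1[, untouched])
  expect_gt(max(abs(m2[, pick] - m1[, pick])), 0)
})

test_that("commixture serialization writes triplets and node index", {
  x <- mini_instance()
  cm <- to_commixture(build_network(x$gene_edges, x$mirna_edges,
                                    x$target_edges, x$pathways))
  tp <- withr::local_tempfile(fileext = ".tsv")
  ip <- withr::local_tempfile(fileext = ".tsv")
  write_commixture(cm, tp, ip)
  trip <- read.delim(tp)
  nidx <- read.delim(ip)
  m <- matrix(0, nrow(nidx), nrow(nidx))
  m[cbind(trip$row, trip$col)] <- trip$value
  expect_equal(m, unname(as.matrix(cm$matrix)))
  expect_equal(nidx$node, names(cm$node_index))
})
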