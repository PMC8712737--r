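# Readers and writers for the tabular inputs and outputs of the pipeline.
# Every downstream module consumes the validated data frames produced here;
# identifiers are opaque strings and are never remapped.

MOLECULE_TYPES <- c("mRNA", "miRNA", "lncRNA")
SNP_CLASSES <- c("utr3", "mirna_seed", "lnc_binding_site",
                 "lnc_gene_body", "pri_pre_mirna")
# classes that directly perturb ceRNA binding (3'UTR of the mRNA, seed region
# of the mature miRNA, miRNA binding site on the lncRNA)
REGULATORY_SNP_CLASSES <- c("utr3", "mirna_seed", "lnc_binding_site")

#' Read a weighted edge list
#'
#' Parses a tab-separated edge list with columns source, target, weight.
#' A header row is auto-detected (non-numeric third field). Self-edges are
#' dropped with a warning; for undirected lists, edges are stored once in
#' canonical (lexicographically sorted) endpoint order and duplicates are
#' merged keeping the maximum weight, matching confidence-score semantics of
#' interaction databases.
#'
#' @param path Path to a TSV file with at least three columns.
#' @param directed Treat the list as directed (no canonicalization).
#' @return A data frame with columns `source`, `target`, `weight` and
#'   attributes `rows_in` (raw data rows parsed) and `self_edges_dropped`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty edge list file: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("edge list line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  }
  first_line <- 1L
  w1 <- suppressWarnings(as.numeric(fields[[1L]][3L]))
  if (is.na(w1)) first_line <- 2L  # header detected
  if (first_line > length(lines)) {
    stop("edge list file contains only a header: ", path)
  }
  rows <- fields[seq(first_line, length(fields))]
  src <- vapply(rows, `[[`, character(1L), 1L)
  tgt <- vapply(rows, `[[`, character(1L), 2L)
  wchr <- vapply(rows, `[[`, character(1L), 3L)
  weight <- suppressWarnings(as.numeric(wchr))
  bad <- which(is.na(weight))
  if (length(bad) > 0L) {
    stop("malformed weight '", wchr[bad[1L]], "' on line ",
         bad[1L] + first_line - 1L, " of ", path)
  }
  if (any(weight < 0)) {
    bad <- which(weight < 0)[1L]
    stop("negative weight on line ", bad + first_line - 1L, " of ", path)
  }
  rows_in <- length(src)
  self <- src == tgt
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped from ", basename(path))
    src <- src[!self]; tgt <- tgt[!self]; weight <- weight[!self]
  }
  if (!directed && length(src) > 0L) {
    swap <- src > tgt
    tmp <- src[swap]; src[swap] <- tgt[swap]; tgt[swap] <- tmp
  }
  edges <- data.frame(source = src, target = tgt, weight = weight,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      wmax <- tapply(edges$weight, key, max)
      keep <- !duplicated(key)
      edges <- edges[keep, , drop = FALSE]
      edges$weight <- as.numeric(wmax[paste(edges$source, edges$target,
                                            sep = "\r")])
    }
  }
  rownames(edges) <- NULL
  attr(edges, "rows_in") <- rows_in
  attr(edges, "self_edges_dropped") <- sum(self)
  edges
}

#' Read an interaction table (regulator -> target)
#'
#' Reads a headered TSV with columns `regulator`, `target` and optionally
#' `evidence`. The admissible regulator/target type pair is fixed by `kind`:
#' `"mi_m"` for miRNA-to-mRNA target interactions, `"lnc_mi"` for
#' lncRNA-to-miRNA interactions.
#'
#' @param path Path to the TSV file.
#' @param kind `"mi_m"` or `"lnc_mi"`.
#' @return Data frame with columns `regulator`, `target`, `regulator_type`,
#'   `target_type`, `evidence`.
#' @export
read_interactions <- function(path, kind = c("mi_m", "lnc_mi")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("regulator", "target")
  if (!all(need %in% names(df))) {
    stop("interaction table must have columns 'regulator' and 'target': ",
         path)
  }
  types <- switch(kind,
                  mi_m = c("miRNA", "mRNA"),
                  lnc_mi = c("lncRNA", "miRNA"))
  out <- data.frame(regulator = df$regulator, target = df$target,
                    regulator_type = types[1L], target_type = types[2L],
                    evidence = if ("evidence" %in% names(df)) df$evidence
                               else NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("regulator", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rows_in") <- nrow(df)
  out
}

#' Read pathway gene sets from a GMT file
#'
#' One pathway per line: `id<TAB>description<TAB>member1<TAB>member2...`.
#' The description field carries the source-database label unless a
#' `source_db` named vector (pathway id -> database label) is supplied, in
#' which case the description is kept as the pathway name.
#'
#' @param path Path to the GMT file.
#' @param source_db Optional named character vector mapping pathway ids to
#'   source-database labels.
#' @return Data frame with columns `pathway_id`, `name`, `source_db` and a
#'   list column `members`.
#' @export
read_gmt <- function(path, source_db = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id in GMT: ",
         ids[duplicated(ids)][1L])
  }
  desc <- vapply(fields, `[[`, character(1L), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(members) == 0L)) {
    stop("GMT line ", which(lengths(members) == 0L)[1L],
         " has an empty member list")
  }
  if (is.null(source_db)) {
    db <- desc
    nm <- ids
  } else {
    missing_db <- setdiff(ids, names(source_db))
    if (length(missing_db) > 0L) {
      stop("no source_db mapping for pathway ", missing_db[1L])
    }
    db <- unname(source_db[ids])
    nm <- desc
  }
  out <- data.frame(pathway_id = ids, name = nm, source_db = db,
                    stringsAsFactors = FALSE)
  out$members <- members
  attr(out, "rows_in") <- length(lines)
  out
}

#' Write pathway records to a GMT file
#'
#' @param pathways Data frame as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$source_db[i],
            pathways$members[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a disease-feature risk-molecule catalog
#'
#' Headered TSV with columns `molecule_id`, `molecule_type`, `feature`.
#' Duplicate (molecule, feature) pairs are collapsed; unknown molecule types
#' are rejected with per-row diagnostics.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three columns; attribute `rejected` holds a
#'   data frame of rejected rows with reasons.
#' @export
read_risk_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("molecule_id", "molecule_type", "feature")
  if (!all(need %in% names(df))) {
    stop("risk catalog must have columns ", paste(need, collapse = ", "))
  }
  rows_in <- nrow(df)
  ok <- df$molecule_type %in% MOLECULE_TYPES
  rejected <- data.frame(row = which(!ok),
                         reason = rep("unknown molecule_type", sum(!ok)),
                         stringsAsFactors = FALSE)
  df <- df[ok, need, drop = FALSE]
  df <- df[!duplicated(df[c("molecule_id", "feature")]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rows_in") <- rows_in
  attr(df, "rejected") <- rejected
  df
}

#' Read and validate a SNP annotation table
#'
#' Headered TSV with columns `rsid`, `host_molecule`, `host_type`,
#' `location_class`, `partner_molecule` (last may be empty). Rows violating
#' the host-type/location-class consistency rules, or binding-site rows
#' lacking the partner miRNA, are rejected with per-row diagnostics.
#'
#' Location classes: `utr3` (3'UTR of an mRNA), `mirna_seed` (seed region of
#' a mature miRNA), `lnc_binding_site` (miRNA binding site on a lncRNA;
#' `partner_molecule` names the miRNA), `lnc_gene_body`, `pri_pre_mirna`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of valid records; attribute `rejected` is a data frame
#'   (`row`, `reason`) of diagnostics, `rows_in` the raw row count.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("rsid", "host_molecule", "host_type", "location_class")
  if (!all(need %in% names(df))) {
    stop("SNP table must have columns ", paste(need, collapse = ", "))
  }
  if (!"partner_molecule" %in% names(df)) df$partner_molecule <- NA_character_
  validated <- validate_snp_records(df)
  attr(validated$records, "rows_in") <- nrow(df)
  attr(validated$records, "rejected") <- validated$rejected
  validated$records
}

# shared row-level validation for SNP records (used by the reader and by the
# synthetic generator's self-check)
validate_snp_records <- function(df) {
  expected_host <- c(utr3 = "mRNA", mirna_seed = "miRNA",
                     pri_pre_mirna = "miRNA", lnc_binding_site = "lncRNA",
                     lnc_gene_body = "lncRNA")
  reason <- rep(NA_character_, nrow(df))
  unknown <- !(df$location_class %in% SNP_CLASSES)
  reason[unknown] <- "unknown location_class"
  mismatch <- !unknown &
    df$host_type != unname(expected_host[df$location_class])
  reason[mismatch] <- "class/type mismatch"
  no_partner <- is.na(reason) & df$location_class == "lnc_binding_site" &
    (is.na(df$partner_molecule) | df$partner_molecule == "")
  reason[no_partner] <- "lnc_binding_site requires partner_molecule"
  ok <- is.na(reason)
  records <- df[ok, c("rsid", "host_molecule", "host_type",
                      "location_class", "partner_molecule"), drop = FALSE]
  rownames(records) <- NULL
  rejected <- data.frame(row = which(!ok), reason = reason[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " SNP row(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  list(records = records, rejected = rejected)
}

SCORE_COLUMNS <- c("feature", "pathway_id", "source_db", "correlation_score",
                   "rank_in_db", "ranking_score", "empirical_p")

#' Write a pathway score table
#'
#' Writes a TSV with stable column order (feature, pathway_id, source_db,
#' correlation_score, rank_in_db, ranking_score, empirical_p, plus
#' overlap_count when present), rows sorted by feature then ranking score
#' descending, floating point values rendered with six significant digits.
#'
#' @param scores Data frame of pathway scores (see [score_pathways()]).
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  cols <- SCORE_COLUMNS
  if ("overlap_count" %in% names(scores)) cols <- c(cols, "overlap_count")
  missing_cols <- setdiff(cols, names(scores))
  for (m in missing_cols) scores[[m]] <- NA
  out <- scores[cols]
  if (nrow(out) > 0L) {
    out <- out[order(out$feature, -out$ranking_score,
                     out$pathway_id), , drop = FALSE]
  }
  fmt <- out
  for (cc in c("correlation_score", "ranking_score", "empirical_p")) {
    fmt[[cc]] <- formatC(out[[cc]], digits = 6L, format = "g")
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read a pathway score table written by [write_scores()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with typed score columns.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in c("correlation_score", "ranking_score", "empirical_p")) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if ("rank_in_db" %in% names(df)) df$rank_in_db <- as.integer(df$rank_in_db)
  df
}
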