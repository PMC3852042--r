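#' Define a group of genomes under comparison
#'
#' A genome group fixes the ordered list of genomes an analysis refers to,
#' and optionally names clades (disjoint subsets of the genomes) used when
#' selecting homology sets that lost genes in two different clades, e.g. one
#' Panicoideae genome and one BEP-clade genome among four grasses.
#'
#' @param genomes Character vector of genome identifiers (non-empty, unique).
#' @param name Label for the group (e.g. `"rosids"`).
#' @param clades Optional named list of character vectors; each element is a
#'   clade, the vectors must be disjoint subsets of `genomes`.
#' @return An object of class `genome_group`.
#' @examples
#' genome_group(c("rice", "setaria", "sorghum", "brachypodium"),
#'              name = "monocots",
#'              clades = list(Panicoideae = c("sorghum", "setaria"),
#'                            BEP = c("rice", "brachypodium")))
#' @export
genome_group <- function(genomes, name = "group", clades = NULL) {
  genomes <- as.character(genomes)
  if (length(genomes) == 0L) stopf("a genome group needs at least one genome")
  if (anyDuplicated(genomes)) stopf("duplicated genome_id in group")
  if (!is.null(clades)) {
    if (is.null(names(clades)) || any(!nzchar(names(clades))))
      stopf("clades must be a named list")
    all_members <- unlist(clades, use.names = FALSE)
    if (anyDuplicated(all_members)) stopf("clades must be disjoint")
    unknown <- setdiff(all_members, genomes)
    if (length(unknown) > 0L)
      stopf("clade members not in group: %s", paste(unknown, collapse = ", "))
  }
  structure(list(name = name, genomes = genomes, clades = clades),
            class = "genome_group")
}

#' @export
print.genome_group <- function(x, ...) {
  cat(sprintf("Genome group '%s': %s\n", x$name,
              paste(x$genomes, collapse = ", ")))
  for (cl in names(x$clades))
    cat(sprintf("  clade %s: %s\n", cl, paste(x$clades[[cl]], collapse = ", ")))
  invisible(x)
}

#' Read a gene table
#'
#' @param path TSV file with header and columns `gene_id`, `genome_id`.
#' @return Data frame with character columns `gene_id`, `genome_id`.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_id", "genome_id"))
  df$gene_id <- as.character(df$gene_id)
  df$genome_id <- as.character(df$genome_id)
  if (anyDuplicated(df$gene_id))
    stopf("duplicated gene_id in gene table: %s",
          df$gene_id[duplicated(df$gene_id)][1L])
  df[, c("gene_id", "genome_id")]
}

#' Read a syntenic homology edge list
#'
#' Accepts the TSV shape produced by exporting SynMap/DAGChainer-style pair
#' lists: header plus columns `gene_a`, `gene_b`, `relation` (`ortholog` or
#' `paralog`) and optionally `block_id` (`"."` for missing).
#'
#' @param path TSV file.
#' @return Data frame with columns `gene_a`, `gene_b`, `relation`, `block_id`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_a", "gene_b", "relation"))
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$relation <- as.character(df$relation)
  df$block_id <- if ("block_id" %in% names(df)) as.character(df$block_id) else "."
  df[, c("gene_a", "gene_b", "relation", "block_id")]
}

validate_edges <- function(edges, genes) {
  stopifnot(is.data.frame(edges), is.data.frame(genes))
  need <- c("gene_a", "gene_b", "relation")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0L)
    stopf("edge table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(edges) == 0L) return(invisible(TRUE))
  bad <- edges$gene_a == edges$gene_b
  if (any(bad))
    stopf("self-edge not allowed: %s -- %s", edges$gene_a[which(bad)[1L]],
          edges$gene_b[which(bad)[1L]])
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  for (col in c("gene_a", "gene_b")) {
    unknown <- !(edges[[col]] %in% genes$gene_id)
    if (any(unknown)) {
      i <- which(unknown)[1L]
      stopf("edge %s -- %s references unknown gene_id '%s'",
            edges$gene_a[i], edges$gene_b[i], edges[[col]][i])
    }
  }
  same <- genome_of[edges$gene_a] == genome_of[edges$gene_b]
  bad_rel <- !(edges$relation %in% c("ortholog", "paralog"))
  if (any(bad_rel))
    stopf("unknown relation '%s'", edges$relation[which(bad_rel)[1L]])
  wrong <- (edges$relation == "ortholog" & same) |
           (edges$relation == "paralog" & !same)
  if (any(wrong)) {
    i <- which(wrong)[1L]
    stopf("edge %s -- %s: relation '%s' inconsistent with genome assignment",
          edges$gene_a[i], edges$gene_b[i], edges$relation[i])
  }
  invisible(TRUE)
}

#' Build homology sets from syntenic homology edges
#'
#' Genes are vertices and ortholog/paralog edges are undirected edges; each
#' connected component is one homology set, interpreted as the surviving
#' descendants of a single pre-polyploidy ancestral gene. Genes with no
#' incident edge carry no homology evidence and are excluded from the sets
#' (they are reported in the `unplaced` element rather than silently
#' dropped). Components are ordered by their lexicographically smallest
#' member `gene_id`, so the output is deterministic.
#'
#' @param edges Data frame of edges (`gene_a`, `gene_b`, `relation`, optional
#'   `block_id`); see [read_edge_list()].
#' @param genes Data frame with `gene_id`, `genome_id`; see [read_gene_table()].
#' @param group Optional [genome_group()]; defaults to all genomes present in
#'   `genes`, in order of first appearance.
#' @param max_copies Optional cap on per-genome copy number: sets in which any
#'   genome holds more than `max_copies` members are marked `reject`
#'   (a coarse guard against tandem-array contamination; default no cap).
#' @return An object of class `homology_sets` with elements
#'   \describe{
#'     \item{membership}{data frame `set_id`, `gene_id`, `genome_id`;}
#'     \item{copy_counts}{integer matrix, one row per set, one column per
#'       genome of the group;}
#'     \item{summary}{data frame `set_id`, `n_genes`, `score`,
#'       `completeness` (one of `full`, `missing_one`, `missing_two`,
#'       `reject`) and `absent` (comma-joined absent genomes);}
#'     \item{group}{the genome group;}
#'     \item{unplaced}{gene_ids present in `genes` but in no edge.}
#'   }
#' @seealso [fractionation_score()], [classify_completeness()]
#' @examples
#' genes <- data.frame(gene_id = c("a1", "b1"), genome_id = c("A", "B"))
#' edges <- data.frame(gene_a = "a1", gene_b = "b1", relation = "ortholog")
#' build_homology_sets(edges, genes)
#' @export
build_homology_sets <- function(edges, genes, group = NULL, max_copies = NULL) {
  validate_edges(edges, genes)
  if (is.null(group)) group <- genome_group(unique(genes$genome_id))
  unknown_genome <- setdiff(genes$genome_id, group$genomes)
  if (length(unknown_genome) > 0L)
    stopf("gene table contains genome(s) outside the group: %s",
          paste(unknown_genome, collapse = ", "))

  if (nrow(edges) == 0L) {
    empty <- data.frame(set_id = character(), gene_id = character(),
                        genome_id = character(), stringsAsFactors = FALSE)
    cc <- matrix(integer(), nrow = 0L, ncol = length(group$genomes),
                 dimnames = list(NULL, group$genomes))
    smry <- data.frame(set_id = character(), n_genes = integer(),
                       score = integer(), completeness = character(),
                       absent = character(), stringsAsFactors = FALSE)
    return(structure(list(membership = empty, copy_counts = cc,
                          summary = smry, group = group,
                          unplaced = genes$gene_id),
                     class = "homology_sets"))
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  members <- split(vnames, comp$membership)
  # deterministic order: by smallest gene_id in the component
  members <- members[order(vapply(members, min, character(1L)))]
  members <- lapply(members, function(v) sort(v))
  set_ids <- sprintf("HS%06d", seq_along(members))

  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  membership <- data.frame(
    set_id = rep(set_ids, lengths(members)),
    gene_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
  membership$genome_id <- unname(genome_of[membership$gene_id])

  tab <- table(factor(membership$set_id, levels = set_ids),
               factor(membership$genome_id, levels = group$genomes))
  cc <- matrix(as.integer(tab), nrow = length(set_ids),
               dimnames = list(set_ids, group$genomes))

  cls <- classify_completeness(cc, group)
  if (!is.null(max_copies)) {
    over <- apply(cc, 1L, max) > max_copies
    cls$completeness[over] <- "reject"
    cls$absent[over] <- ""
  }
  smry <- data.frame(
    set_id = set_ids,
    n_genes = as.integer(lengths(members)),
    score = fractionation_score(cc),
    completeness = cls$completeness,
    absent = cls$absent,
    stringsAsFactors = FALSE)

  structure(list(membership = membership, copy_counts = cc, summary = smry,
                 group = group,
                 unplaced = setdiff(genes$gene_id, vnames)),
            class = "homology_sets")
}

#' @export
print.homology_sets <- function(x, ...) {
  cat(sprintf("%d homology sets over %d genomes (%s)\n",
              nrow(x$summary), length(x$group$genomes), x$group$name))
  if (nrow(x$summary) > 0L)
    print(table(completeness = x$summary$completeness))
  if (length(x$unplaced) > 0L)
    cat(sprintf("%d gene(s) with no homology evidence (unplaced)\n",
                length(x$unplaced)))
  invisible(x)
}

#' Subset a homology_sets object by set id or logical/integer index
#' @param x A `homology_sets` object.
#' @param i Set ids, or an index into the summary rows.
#' @param ... Unused.
#' @export
`[.homology_sets` <- function(x, i, ...) {
  ids <- if (is.character(i)) i else x$summary$set_id[i]
  keep <- x$summary$set_id %in% ids
  x$summary <- x$summary[keep, , drop = FALSE]
  x$copy_counts <- x$copy_counts[x$summary$set_id, , drop = FALSE]
  x$membership <- x$membership[x$membership$set_id %in% ids, , drop = FALSE]
  x
}

#' Fractionation score: genomes retaining more than one copy
#'
#' The score of a homology set is the number of genomes in the group with
#' strictly more than one member copy (2, 3 or more copies all qualify), so
#' it runs from 0 (every genome single-copy) to the number of genomes.
#'
#' @param copy_counts Named integer vector (one set) or matrix with one
#'   column per genome (many sets).
#' @return Integer vector of scores.
#' @examples
#' fractionation_score(c(A = 3, B = 2, C = 1))  # 2
#' @export
fractionation_score <- function(copy_counts) {
  if (is.matrix(copy_counts)) {
    as.integer(rowSums(copy_counts > 1L))
  } else {
    as.integer(sum(copy_counts > 1L))
  }
}

#' Classify homology-set completeness across the genome group
#'
#' A set is `full` when every genome of the group retains at least one copy,
#' `missing_one`/`missing_two` when exactly one or two genomes have none, and
#' `reject` otherwise (three or more absent genomes; such sets -- including
#' single-genome paralog-only components -- are excluded from all analyses).
#'
#' @inheritParams fractionation_score
#' @param group A [genome_group()]. For matrix input the columns must match
#'   the group's genomes.
#' @return For a vector: a list with `completeness` and `absent` (character
#'   vector of absent genomes). For a matrix: a list of two equal-length
#'   vectors, `completeness` and comma-joined `absent`.
#' @examples
#' classify_completeness(c(A = 2, B = 1, C = 0), genome_group(c("A", "B", "C")))
#' @export
classify_completeness <- function(copy_counts, group) {
  lab <- function(n_absent) {
    if (n_absent == 0L) "full"
    else if (n_absent == 1L) "missing_one"
    else if (n_absent == 2L) "missing_two"
    else "reject"
  }
  if (is.matrix(copy_counts)) {
    stopifnot(identical(colnames(copy_counts), group$genomes))
    absent_mat <- copy_counts == 0L
    n_absent <- rowSums(absent_mat)
    absent <- apply(absent_mat, 1L, function(z)
      paste(group$genomes[z], collapse = ","))
    list(completeness = vapply(n_absent, lab, character(1L)),
         absent = unname(absent))
  } else {
    counts <- copy_counts[group$genomes]
    counts[is.na(counts)] <- 0L
    absent <- group$genomes[counts == 0L]
    list(completeness = lab(length(absent)), absent = absent)
  }
}

#' Keep missing-two sets whose losses straddle the two clades
#'
#' For groups with two named clades (e.g. Panicoideae vs the BEP clade among
#' grasses), restricts `missing_two` homology sets to those whose two absent
#' genomes fall in *different* clades, the configuration informative about
#' independent post-speciation loss rather than a clade-specific deletion.
#'
#' @param sets A `homology_sets` object.
#' @param group A [genome_group()] whose `clades` names exactly two clades.
#' @return The filtered `homology_sets` object.
#' @export
filter_missing_two_clade <- function(sets, group = sets$group) {
  if (is.null(group$clades) || length(group$clades) != 2L)
    stopf("group must define exactly two clades")
  smry <- sets$summary
  keep <- character(0L)
  m2 <- smry[smry$completeness == "missing_two", , drop = FALSE]
  if (nrow(m2) > 0L) {
    clade_of <- stats::setNames(
      rep(names(group$clades), lengths(group$clades)),
      unlist(group$clades, use.names = FALSE))
    absent <- strsplit(m2$absent, ",", fixed = TRUE)
    cross <- vapply(absent, function(a) {
      cl <- clade_of[a]
      length(a) == 2L && !anyNA(cl) && cl[1L] != cl[2L]
    }, logical(1L))
    keep <- m2$set_id[cross]
  }
  sets[keep]
}

#' Write homology sets to TSV files
#'
#' @param sets A `homology_sets` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`membership.tsv`, `summary.tsv`).
#' @export
write_homology_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "membership.tsv")
  write_tsv(sets$membership, p1)
  smry <- cbind(sets$summary["set_id"],
                as.data.frame(sets$copy_counts),
                sets$summary[, c("n_genes", "score", "completeness", "absent")])
  p2 <- file.path(dir, "summary.tsv")
  write_tsv(smry, p2)
  invisible(c(p1, p2))
}
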