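# Independent brute-force oracles and small fixture builders.

# Transitive-closure grouping by repeated pairwise merging until fixpoint;
# deliberately ignorant of igraph.
oracle_components <- function(edges) {
  groups <- lapply(unique(c(edges$gene_a, edges$gene_b)), identity)
  repeat {
    merged <- FALSE
    for (k in seq_len(nrow(edges))) {
      ia <- which(vapply(groups, function(g) edges$gene_a[k] %in% g,
                         logical(1L)))
      ib <- which(vapply(groups, function(g) edges$gene_b[k] %in% g,
                         logical(1L)))
      if (ia != ib) {
        groups[[ia]] <- union(groups[[ia]], groups[[ib]])
        groups <- groups[-ib]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, character(1L)))]
}

# Random valid edge instance over n genes in the given genomes.
random_instance <- function(n_genes, genomes, n_edges, seed) {
  set.seed(seed)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    genome_id = sample(genomes, n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  a <- sample(genes$gene_id, n_edges, replace = TRUE)
  b <- sample(genes$gene_id, n_edges, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  gm <- stats::setNames(genes$genome_id, genes$gene_id)
  edges <- data.frame(
    gene_a = a, gene_b = b,
    relation = ifelse(gm[a] == gm[b], "paralog", "ortholog"),
    block_id = ".", stringsAsFactors = FALSE)
  list(genes = genes, edges = edges)
}

# Minimal homology_sets container with prescribed per-set scores, for
# feeding the trends machinery directly.
make_sets <- function(scores, genomes = c("A", "B", "C")) {
  ids <- sprintf("HS%06d", seq_along(scores))
  structure(list(
    membership = data.frame(set_id = ids,
                            gene_id = paste0("gene_", ids),
                            genome_id = genomes[1L],
                            stringsAsFactors = FALSE),
    copy_counts = matrix(1L, nrow = length(ids), ncol = length(genomes),
                         dimnames = list(ids, genomes)),
    summary = data.frame(set_id = ids, n_genes = 1L,
                         score = as.integer(scores),
                         completeness = "full", absent = "",
                         stringsAsFactors = FALSE),
    group = genome_group(genomes),
    unplaced = character(0L)), class = "homology_sets")
}

# Ancestor-closed set annotation: each set in `hit_sets` carries `term`
# (plus its ancestors); each set in `pop_sets` carries the namespace root
# of `term` so it belongs to the regression population.
make_set_ann <- function(dag, term, hit_sets, pop_sets) {
  root <- namespace_roots(dag)[[dag$namespace[[term]]]]
  closure <- c(term, ancestors(dag, term))
  df <- rbind(
    if (length(hit_sets) > 0L)
      data.frame(set_id = rep(hit_sets, each = length(closure)),
                 term_id = closure, stringsAsFactors = FALSE),
    if (length(pop_sets) > 0L)
      data.frame(set_id = pop_sets, term_id = root,
                 stringsAsFactors = FALSE))
  df <- unique(df)
  class(df) <- c("set_annotation", "data.frame")
  df
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
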