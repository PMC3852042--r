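GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

#' Load a Gene Ontology file (OBO 1.2)
#'
#' Line-oriented reader for the `[Term]` stanzas of an OBO 1.2 file. Keeps
#' `is_a` parents (and, optionally, `relationship: part_of`), records each
#' term's namespace, and drops obsolete terms together with any edges that
#' point at them. The parent relation is checked to be acyclic.
#'
#' @param path Path to an OBO 1.2 file.
#' @param use_part_of Also treat `part_of` relationships as parent edges
#'   (default `FALSE`: `is_a` only, the conservative standard for
#'   propagating annotations).
#' @return An object of class `ontology_dag`: list with `terms` (character),
#'   `parents` (named list of character vectors), `namespace` (named
#'   character), `name` (named character, term labels), `obsolete`
#'   (character vector of dropped ids) and `roots` (terms with no parents,
#'   one per namespace in a full GO release).
#' @export
load_ontology <- function(path, use_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stopf("no stanzas found in OBO file '%s'", path)
  bounds <- c(starts, length(lines) + 1L)

  ids <- character(0L); nms <- character(0L); nsp <- character(0L)
  parents <- list(); obsolete <- character(0L)
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    chunk <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    field <- function(tag) sub(paste0("^", tag, ": *"), "",
                               grep(paste0("^", tag, ": "), chunk, value = TRUE))
    id <- field("id")[1L]
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", chunk))) {
      obsolete <- c(obsolete, id)
      next
    }
    ns <- field("namespace")[1L]
    if (is.na(ns)) stopf("term %s has no namespace", id)
    if (!ns %in% GO_NAMESPACES)
      stopf("term %s has unknown namespace '%s'", id, ns)
    isa <- sub(" *!.*$", "", field("is_a"))
    if (use_part_of) {
      rel <- field("relationship")
      po <- sub(" *!.*$", "", sub("^part_of +", "", grep("^part_of ", rel,
                                                         value = TRUE)))
      isa <- c(isa, po)
    }
    ids <- c(ids, id)
    nms <- c(nms, field("name")[1L] %||% NA_character_)
    nsp <- c(nsp, ns)
    parents[[id]] <- isa
  }
  names(nms) <- ids
  names(nsp) <- ids
  # drop edges to obsolete or unknown terms
  parents <- lapply(parents, function(p) intersect(p, ids))

  dag <- structure(list(terms = ids, parents = parents, namespace = nsp,
                        name = nms, obsolete = obsolete,
                        roots = ids[lengths(parents) == 0L],
                        cache = new.env(parent = emptyenv())),
                   class = "ontology_dag")
  check_acyclic(dag)
  dag
}

check_acyclic <- function(dag) {
  indeg <- lengths(dag$parents)        # edges point child -> parent
  # Kahn's algorithm on the child->parent graph
  children <- split(rep(names(dag$parents), lengths(dag$parents)),
                    unlist(dag$parents, use.names = FALSE))
  queue <- dag$terms[indeg == 0L]
  seen <- 0L
  indeg_work <- stats::setNames(indeg, dag$terms)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]] %||% character(0L)) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(dag$terms))
    stopf("ontology parent relation contains a cycle")
  invisible(TRUE)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d roots, %d obsolete dropped\n",
              length(x$terms), length(x$roots), length(x$obsolete)))
  invisible(x)
}

#' All ancestor terms of a term
#'
#' Terms reachable from `term` by repeatedly following parent edges,
#' excluding the term itself. Results are memoized inside the DAG object.
#'
#' @param dag An `ontology_dag`.
#' @param term A term id present in the DAG.
#' @return Sorted character vector of ancestor term ids.
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stopf("unknown term '%s'", term)
  cached <- dag$cache[[term]]
  if (!is.null(cached)) return(cached)
  out <- character(0L)
  frontier <- dag$parents[[term]]
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier],
                                      use.names = FALSE)), out)
  }
  out <- sort(out)
  assign(term, out, envir = dag$cache)
  out
}

#' High-level terms: direct children of the namespace roots
#'
#' The three GO namespaces each have a single root; the terms one level
#' below those roots ("high-level terms") are the categories usually plotted
#' in fractionation-trend figures. How many there are depends on the GO
#' release.
#'
#' @param dag An `ontology_dag`.
#' @return Sorted character vector of term ids.
#' @export
high_level_terms <- function(dag) {
  roots <- dag$roots
  hits <- vapply(dag$terms, function(t)
    length(intersect(dag$parents[[t]], roots)) > 0L, logical(1L))
  sort(setdiff(dag$terms[hits], roots))
}

#' Namespace root of each namespace present in a DAG
#' @param dag An `ontology_dag`.
#' @return Named character vector, names are namespaces.
#' @export
namespace_roots <- function(dag) {
  r <- dag$roots
  stats::setNames(r, dag$namespace[r])
}

#' Read gene-to-GO annotations
#'
#' Understands GAF 2.x (17-column, `!` comments; gene id from column 2,
#' term from column 5) and plain two-column TSV (`gene_id`, `term_id`, with
#' or without a header line).
#'
#' @param path Annotation file.
#' @param format `"auto"` (default), `"gaf"` or `"tsv"`.
#' @return Data frame with columns `gene_id`, `term_id` (deduplicated).
#' @export
read_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    body <- grep("^!", lines, invert = TRUE, value = TRUE)
    ncol1 <- length(strsplit(body[1L] %||% "", "\t", fixed = TRUE)[[1L]])
    format <- if (any(grepl("^!", lines)) || ncol1 >= 15L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    body <- grep("^!", lines, invert = TRUE, value = TRUE)
    body <- body[nzchar(body)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    short <- lengths(parts) < 5L
    if (any(short)) stopf("GAF line with fewer than 5 columns")
    df <- data.frame(gene_id = vapply(parts, `[[`, "", 2L),
                     term_id = vapply(parts, `[[`, "", 5L),
                     stringsAsFactors = FALSE)
  } else {
    body <- lines[nzchar(lines)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) stopf("annotation TSV line with < 2 columns")
    df <- data.frame(gene_id = vapply(parts, `[[`, "", 1L),
                     term_id = vapply(parts, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
    if (nrow(df) > 0L && !grepl("^GO:", df$term_id[1L]))
      df <- df[-1L, , drop = FALSE]  # header line
  }
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Close a gene/term annotation table under the ancestor relation
#'
#' @param ann Data frame with `gene_id`, `term_id`.
#' @param dag An `ontology_dag`; annotations to terms not in the DAG
#'   (obsolete or unknown) are dropped, their count reported as the
#'   `n_dropped_terms` attribute.
#' @return Data frame `gene_id`, `term_id`, ancestor-closed and deduplicated.
#' @export
close_annotations <- function(ann, dag) {
  known <- ann$term_id %in% dag$terms
  dropped <- sum(!known)
  ann <- ann[known, , drop = FALSE]
  if (nrow(ann) > 0L) {
    anc <- lapply(unique(ann$term_id), function(t) c(t, ancestors(dag, t)))
    names(anc) <- unique(ann$term_id)
    expanded <- data.frame(
      gene_id = rep(ann$gene_id, lengths(anc[ann$term_id])),
      term_id = unlist(anc[ann$term_id], use.names = FALSE),
      stringsAsFactors = FALSE)
    ann <- unique(expanded)
  }
  attr(ann, "n_dropped_terms") <- dropped
  ann
}

#' Annotate homology sets with the union of their genes' GO terms
#'
#' Every term carried by any member gene -- plus all of that term's
#' ancestors -- becomes an annotation of the set. Presence/absence only: the
#' multiplicity of a term within the set is deliberately ignored.
#' Annotations on genes that belong to no set are skipped (their count is
#' attached as the `n_genes_outside_sets` attribute), and annotations to
#' terms missing from the DAG are dropped (`n_dropped_terms` attribute).
#'
#' @param sets A `homology_sets` object.
#' @param ann Data frame `gene_id`, `term_id` of direct annotations.
#' @param dag An `ontology_dag`.
#' @return Object of class `set_annotation`: a data frame `set_id`,
#'   `term_id`, closed under the ancestor relation.
#' @export
annotate_sets <- function(sets, ann, dag) {
  in_sets <- ann$gene_id %in% sets$membership$gene_id
  outside <- length(unique(ann$gene_id[!in_sets]))
  ann <- ann[in_sets, , drop = FALSE]
  closed <- close_annotations(ann, dag)
  set_of <- stats::setNames(sets$membership$set_id, sets$membership$gene_id)
  out <- unique(data.frame(set_id = unname(set_of[closed$gene_id]),
                           term_id = closed$term_id,
                           stringsAsFactors = FALSE))
  out <- out[order(out$set_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genes_outside_sets") <- outside
  attr(out, "n_dropped_terms") <- attr(closed, "n_dropped_terms")
  class(out) <- c("set_annotation", "data.frame")
  out
}

#' Write a toy or derived ontology back to OBO 1.2
#'
#' @param dag An `ontology_dag`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines("[Term]", con)
    writeLines(sprintf("id: %s", t), con)
    nm <- dag$name[[t]]
    if (!is.na(nm)) writeLines(sprintf("name: %s", nm), con)
    writeLines(sprintf("namespace: %s", dag$namespace[[t]]), con)
    for (p in dag$parents[[t]]) writeLines(sprintf("is_a: %s", p), con)
    writeLines("", con)
  }
  invisible(path)
}
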