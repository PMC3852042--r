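#' Run the full fractionation analysis pipeline
#'
#' Orchestrates the stages on file inputs: read genes/edges, build homology
#' sets, read and propagate GO annotations, fit per-term trends, derive
#' pair/triple counts from full homology sets and (optionally) fit the
#' two-class retention model. Every stage's output is also written to
#' `out_dir` (when given) in the same TSV formats its standalone reader
#' accepts, so stages can be re-run independently.
#'
#' @param genes_file,edges_file Gene table and edge list TSVs.
#' @param obo_file OBO 1.2 ontology; `annotations_file` GAF 2.x or
#'   two-column TSV (may be `NULL` to skip annotation stages).
#' @param annotations_file Optional annotation file.
#' @param group Optional [genome_group()]; defaults to the genomes present.
#' @param alpha_level Significance level for trend calls.
#' @param fit_model Fit the retention model on counts derived from full
#'   homology sets (default `TRUE`).
#' @param N Ancestral gene number for the model fit; default
#'   `round(1.25 * number of homology sets)`, i.e. assuming roughly 80% of
#'   ancestral genes left a detectable set.
#' @param seed Seed for the model multistart.
#' @param out_dir Optional output directory.
#' @return Object of class `pipeline_report`: list with `sets_by_completeness`,
#'   `n_sets`, `pct_sets_with_go`, `trends`, `counts`, `fit` (or `NULL`),
#'   and `files` (paths written).
#' @export
run_pipeline <- function(genes_file, edges_file, obo_file = NULL,
                         annotations_file = NULL, group = NULL,
                         alpha_level = 0.05, fit_model = TRUE, N = NULL,
                         seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  genes <- stage("read-genes", read_gene_table(genes_file))
  edges <- stage("read-edges", read_edge_list(edges_file))
  sets <- stage("build-sets", build_homology_sets(edges, genes, group = group))

  report <- list(
    n_sets = nrow(sets$summary),
    sets_by_completeness = table(sets$summary$completeness),
    pct_sets_with_go = NA_real_,
    trends = NULL, counts = NULL, fit = NULL, files = character(0L))

  set_ann <- NULL; dag <- NULL
  if (!is.null(obo_file) && !is.null(annotations_file)) {
    dag <- stage("load-ontology", load_ontology(obo_file))
    ann <- stage("read-annotations", read_annotations(annotations_file))
    set_ann <- stage("annotate", annotate_sets(sets, ann, dag))
    report$pct_sets_with_go <-
      100 * length(unique(set_ann$set_id)) / max(1L, nrow(sets$summary))
    report$trends <- stage("trends",
      trend_table(set_ann, sets, dag, alpha_level = alpha_level))
  }

  full <- sets[sets$summary$completeness == "full"]
  cc <- full$copy_counts
  counts <- data.frame(
    species = sets$group$genomes,
    n2 = vapply(sets$group$genomes, function(g)
      sum(cc[, g] == 2L), integer(1L)),
    n3 = vapply(sets$group$genomes, function(g)
      sum(cc[, g] == 3L), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  report$counts <- counts

  if (fit_model && nrow(counts) > 0L && sum(counts$n2 + counts$n3) > 0L) {
    if (is.null(N)) N <- max(round(1.25 * nrow(sets$summary)),
                             max(counts$n2 + counts$n3))
    report$fit <- stage("fit-model",
      fit_retention_model(counts, N = N, seed = seed))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_homology_sets(sets, out_dir)
    f <- file.path(out_dir, "derived_counts.tsv")
    write_tsv(counts, f); files <- c(files, f)
    if (!is.null(set_ann)) {
      f <- file.path(out_dir, "set_annotations.tsv")
      write_tsv(as.data.frame(set_ann), f); files <- c(files, f)
    }
    if (!is.null(report$trends)) {
      f <- file.path(out_dir, "trends.tsv")
      write_tsv(as.data.frame(report$trends), f); files <- c(files, f)
    }
    if (!is.null(report$fit)) {
      pr <- report$fit$params
      f <- file.path(out_dir, "model_fit.tsv")
      write_tsv(data.frame(parameter = c("p", paste0("q_", counts$species),
                                         "theta", "alpha", "N", "loglik"),
                           value = c(pr$p, pr$q, pr$theta, pr$alpha, pr$N,
                                     report$fit$loglik)), f)
      files <- c(files, f)
    }
    report$files <- files
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d homology sets\n", x$n_sets))
  print(x$sets_by_completeness)
  if (!is.na(x$pct_sets_with_go))
    cat(sprintf("%.1f%% of sets hit at least one GO term\n",
                x$pct_sets_with_go))
  if (!is.null(x$trends))
    cat(sprintf("trend table: %d terms (%d significant)\n",
                nrow(x$trends),
                sum(x$trends$call %in% c("prone", "resistant"))))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
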