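set_scores <- function(sets) {
  stats::setNames(sets$summary$score, sets$summary$set_id)
}

# sets (ids) whose closed annotation contains >= 1 term of the namespace,
# i.e. contains that namespace's root term
namespace_hitters <- function(set_ann, dag, ns) {
  root <- namespace_roots(dag)[[ns]]
  if (is.null(root)) stopf("namespace '%s' absent from DAG", ns)
  unique(set_ann$set_id[set_ann$term_id == root])
}

#' Namespace-normalized term proportions by fractionation score
#'
#' Sets with many surviving copies carry more genes and hence more raw
#' annotations, which would make almost every category look enriched at
#' high scores. The normalization used here divides, at each score, the
#' number of sets hitting the term by the number of sets hitting *any* term
#' under the same namespace root. Scores whose denominator is zero are
#' omitted.
#'
#' @param set_ann A `set_annotation` from [annotate_sets()] (ancestor-closed).
#' @param sets The `homology_sets` the annotation refers to.
#' @param dag The `ontology_dag`.
#' @param terms Terms to tabulate; default the [high_level_terms()] of `dag`.
#' @return Data frame `term_id`, `namespace`, `score`, `hits`, `denom`,
#'   `proportion`.
#' @export
trend_points <- function(set_ann, sets, dag, terms = high_level_terms(dag)) {
  scores <- set_scores(sets)
  all_scores <- sort(unique(unname(scores)))
  out <- list()
  for (ns in unique(dag$namespace[terms])) {
    hitters <- namespace_hitters(set_ann, dag, ns)
    denom_by_score <- table(factor(scores[hitters], levels = all_scores))
    ns_terms <- terms[dag$namespace[terms] == ns]
    for (tm in ns_terms) {
      with_term <- unique(set_ann$set_id[set_ann$term_id == tm])
      hits_by_score <- table(factor(scores[with_term], levels = all_scores))
      keep <- denom_by_score > 0L
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        term_id = tm, namespace = ns,
        score = all_scores[keep],
        hits = as.integer(hits_by_score[keep]),
        denom = as.integer(denom_by_score[keep]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(term_id = character(), namespace = character(),
               score = integer(), hits = integer(), denom = integer())
  res$proportion <- res$hits / res$denom
  rownames(res) <- NULL
  res
}

#' Regression of set-level term presence on fractionation score
#'
#' Every homology set in the term's namespace population (sets annotated
#' with at least one term under the same namespace root) contributes one
#' data point: x = the set's fractionation score, y = 1 if the set is
#' annotated with the term, else 0. An ordinary least-squares line is
#' fitted; a negative slope means the category is depleted at high scores
#' (fractionation-*prone*), a positive slope means it is retained
#' (fractionation-*resistant*). Significance is the two-sided t-test on the
#' slope.
#'
#' @param term A term id.
#' @inheritParams trend_points
#' @param alpha_level Significance level for the prone/resistant call.
#' @return One-row data frame `term_id`, `namespace`, `slope`, `p_value`,
#'   `n_points`, `call` (`prone`, `resistant` or `neutral`).
#' @export
term_regression <- function(term, set_ann, sets, dag, alpha_level = 0.05) {
  ns <- dag$namespace[[term]]
  if (is.null(ns)) stopf("unknown term '%s'", term)
  pop <- namespace_hitters(set_ann, dag, ns)
  scores <- set_scores(sets)
  x <- unname(scores[pop])
  if (length(unique(x)) < 2L)
    stopf("degenerate design: fewer than two distinct scores in the population")
  y <- as.numeric(pop %in% set_ann$set_id[set_ann$term_id == term])
  if (stats::var(y) == 0) {
    slope <- 0; p <- 1
  } else {
    fit <- stats::lm(y ~ x)
    co <- summary(fit)$coefficients
    slope <- co["x", "Estimate"]
    p <- co["x", "Pr(>|t|)"]
  }
  call <- if (p < alpha_level && slope < 0) "prone"
          else if (p < alpha_level && slope > 0) "resistant"
          else "neutral"
  data.frame(term_id = term, namespace = ns, slope = slope, p_value = p,
             n_points = length(x), call = call, stringsAsFactors = FALSE)
}

#' Per-term trend table for one species group
#'
#' Runs [term_regression()] for each term. Terms whose namespace population
#' is empty or has a single distinct score are reported with `NA` slope and
#' call `"unclassified"`.
#'
#' @inheritParams term_regression
#' @param terms Terms to test; default [high_level_terms()].
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (per-term significance),
#'   `"BH"` available.
#' @param group_name Label stored with the table.
#' @return Object of class `trend_table`: data frame `term_id`, `namespace`,
#'   `slope`, `p_value`, `n_points`, `call`, with attribute `group`.
#' @export
trend_table <- function(set_ann, sets, dag, terms = high_level_terms(dag),
                        alpha_level = 0.05, p_adjust = "none",
                        group_name = sets$group$name) {
  rows <- lapply(terms, function(tm) {
    tryCatch(term_regression(tm, set_ann, sets, dag, alpha_level),
             error = function(e)
               data.frame(term_id = tm, namespace = dag$namespace[[tm]],
                          slope = NA_real_, p_value = NA_real_,
                          n_points = 0L, call = "unclassified",
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
    recall <- !is.na(out$p_value)
    out$call[recall] <- ifelse(
      out$p_value[recall] < alpha_level & out$slope[recall] < 0, "prone",
      ifelse(out$p_value[recall] < alpha_level & out$slope[recall] > 0,
             "resistant", "neutral"))
  }
  rownames(out) <- NULL
  attr(out, "group") <- group_name
  attr(out, "alpha_level") <- alpha_level
  class(out) <- c("trend_table", "data.frame")
  out
}

#' Cross-group consistency of term trends
#'
#' Compares per-term trends fitted independently in two or more species
#' groups. A term is `consistent` when it is significant (non-neutral call)
#' in at least one group and the fitted slopes agree in sign across all
#' groups where it was testable; `conflicting` when it is significant in
#' opposite directions in two or more groups; otherwise `unclassified`.
#'
#' @param tables List of `trend_table` objects sharing a term universe.
#' @return Data frame `term_id`, one slope/call column pair per group,
#'   `consistency`.
#' @export
cross_group_consistency <- function(tables) {
  if (length(tables) < 2L) stopf("need at least two trend tables")
  groups <- vapply(seq_along(tables), function(i)
    attr(tables[[i]], "group") %||% paste0("group", i), character(1L))
  terms <- sort(unique(unlist(lapply(tables, `[[`, "term_id"))))
  slope_mat <- sapply(tables, function(tb)
    tb$slope[match(terms, tb$term_id)])
  call_mat <- sapply(tables, function(tb)
    tb$call[match(terms, tb$term_id)])
  colnames(slope_mat) <- colnames(call_mat) <- groups
  consistency <- vapply(seq_along(terms), function(i) {
    sl <- slope_mat[i, ]; cl <- call_mat[i, ]
    cl[is.na(cl)] <- "unclassified"
    sig <- cl %in% c("prone", "resistant")
    if (sum(sig) >= 2L && length(unique(cl[sig])) > 1L) return("conflicting")
    if (any(is.na(sl)) || any(cl == "unclassified")) return("unclassified")
    if (any(sig) && (all(sl > 0) || all(sl < 0))) return("consistent")
    "unclassified"
  }, character(1L))
  out <- data.frame(term_id = terms, stringsAsFactors = FALSE)
  for (g in groups) {
    out[[paste0("slope_", g)]] <- slope_mat[, g]
    out[[paste0("call_", g)]] <- call_mat[, g]
  }
  out$consistency <- consistency
  out
}

#' Sample a background gene set, stratified by genome
#'
#' Draws genes uniformly without replacement, the same number from each
#' genome, to serve as an annotation background unconstrained by homology
#' or syntenic context.
#'
#' @param genes Gene table (`gene_id`, `genome_id`).
#' @param n_total Total background size (split equally across genomes).
#' @param seed Integer seed.
#' @return Character vector of gene ids.
#' @export
sample_background <- function(genes, n_total = 9000L, seed = 1L) {
  genomes <- unique(genes$genome_id)
  per <- floor(n_total / length(genomes))
  set.seed(seed)
  unlist(lapply(genomes, function(g) {
    pool <- genes$gene_id[genes$genome_id == g]
    sample(pool, min(per, length(pool)))
  }), use.names = FALSE)
}

#' Compare homology-set term proportions against a background gene sample
#'
#' For each term, computes the namespace-normalized proportion among
#' homology sets and among background genes (each background gene treated
#' as its own unit, annotated and ancestor-closed identically), their
#' difference, and a two-proportion z-test (chi-squared without continuity
#' correction) p-value.
#'
#' @inheritParams trend_points
#' @param background_ann Data frame `gene_id`, `term_id`: direct annotations
#'   of the background genes (will be ancestor-closed here).
#' @return Data frame `term_id`, `namespace`, `prop_sets`, `prop_background`,
#'   `difference`, `p_value`.
#' @export
compare_to_background <- function(set_ann, sets, background_ann, dag,
                                  terms = high_level_terms(dag)) {
  if (nrow(background_ann) == 0L) stopf("empty background annotation")
  bg <- close_annotations(background_ann, dag)
  roots <- namespace_roots(dag)
  out <- lapply(terms, function(tm) {
    ns <- dag$namespace[[tm]]
    root <- roots[[ns]]
    set_pop <- namespace_hitters(set_ann, dag, ns)
    bg_pop <- unique(bg$gene_id[bg$term_id == root])
    x1 <- sum(set_pop %in% set_ann$set_id[set_ann$term_id == tm])
    x2 <- sum(bg_pop %in% bg$gene_id[bg$term_id == tm])
    n1 <- length(set_pop); n2 <- length(bg_pop)
    p <- if (n1 == 0L || n2 == 0L) NA_real_
    else if ((x1 == 0L && x2 == 0L) || (x1 == n1 && x2 == n2)) 1
    else suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
    data.frame(term_id = tm, namespace = ns,
               prop_sets = if (n1 > 0L) x1 / n1 else NA_real_,
               prop_background = if (n2 > 0L) x2 / n2 else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$difference <- res$prop_sets - res$prop_background
  res <- res[, c("term_id", "namespace", "prop_sets", "prop_background",
                 "difference", "p_value")]
  rownames(res) <- NULL
  res
}

#' Plot normalized term proportions against fractionation score
#'
#' Reproduces the usual trend-figure style: one line per term, proportion
#' (in percent) on the y-axis, fractionation score on the x-axis, thick
#' lines for terms whose regression slope is significant.
#'
#' @param points Output of [trend_points()].
#' @param trends Optional matching [trend_table()] used to mark significance.
#' @return A ggplot object.
#' @export
plot_trends <- function(points, trends = NULL) {
  df <- points
  df$significant <- FALSE
  if (!is.null(trends)) {
    sig_terms <- trends$term_id[trends$call %in% c("prone", "resistant")]
    df$significant <- df$term_id %in% sig_terms
  }
  ggplot2::ggplot(df, ggplot2::aes(x = score, y = 100 * proportion,
                                   colour = term_id,
                                   linewidth = significant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4, `TRUE` = 1.4),
                                    guide = "none") +
    ggplot2::facet_wrap(~namespace) +
    ggplot2::labs(x = "fractionation score",
                  y = "normalized proportion (%)", colour = "term") +
    ggplot2::theme_minimal()
}
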