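#' Build a deterministic toy Gene Ontology
#'
#' Three namespace roots, each carrying a complete `branching`-ary tree of
#' the requested depth. Term ids are sequential (`GO:0000001`, ...), so the
#' same shape always yields the same ontology. Useful wherever a real GO
#' release would be overkill: unit tests, simulations, worked examples.
#'
#' @param depth Levels below each root (>= 1).
#' @param branching Children per internal term.
#' @return An `ontology_dag` (same class as [load_ontology()] returns).
#' @export
toy_ontology <- function(depth = 2L, branching = 2L) {
  stopifnot(depth >= 1L, branching >= 1L)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  ids <- character(0L); nsp <- character(0L); nms <- character(0L)
  parents <- list()
  for (ns in GO_NAMESPACES) {
    root <- new_id()
    ids <- c(ids, root); nsp <- c(nsp, ns); nms <- c(nms, paste0(ns, "_root"))
    parents[[root]] <- character(0L)
    level <- root
    for (d in seq_len(depth)) {
      nxt <- character(0L)
      for (par in level) {
        for (b in seq_len(branching)) {
          id <- new_id()
          ids <- c(ids, id); nsp <- c(nsp, ns)
          nms <- c(nms, sprintf("%s_d%d", ns, d))
          parents[[id]] <- par
          nxt <- c(nxt, id)
        }
      }
      level <- nxt
    }
  }
  structure(list(terms = ids,
                 parents = parents,
                 namespace = stats::setNames(nsp, ids),
                 name = stats::setNames(nms, ids),
                 obsolete = character(0L),
                 roots = ids[lengths(parents) == 0L],
                 cache = new.env(parent = emptyenv())),
            class = "ontology_dag")
}

#' Configuration for a fractionation simulation
#'
#' @param params A [retention_params()]: ancestral gene number `N`, loss
#'   probabilities, class mixture.
#' @param group A [genome_group()]; must have as many genomes as `params$q`
#'   has species.
#' @param dag Ontology used for annotation, usually a [toy_ontology()].
#' @param term_bias Named list: per term id, a numeric pair
#'   `c(class1, class2)` of per-gene inclusion probabilities. Class-biased
#'   terms are how functional composition differences between the fast and
#'   slow classes enter the simulated data. May be `NULL` (no annotation).
#' @param seed Integer seed (mandatory: simulations are reproducible by
#'   construction).
#' @param independent_phases If `TRUE`, the pre-speciation phase is redrawn
#'   independently per species, matching the independence idealization of
#'   the fitting likelihood instead of the biologically shared phase 1.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(params, group, dag = toy_ontology(),
                       term_bias = NULL, seed, independent_phases = FALSE) {
  stopifnot(inherits(params, "retention_params"),
            inherits(group, "genome_group"))
  if (length(params$q) != length(group$genomes))
    stopf("params$q must have one entry per genome of the group")
  if (missing(seed)) stopf("seed is mandatory")
  if (is.na(params$N) || params$N < 0) stopf("params$N must be set")
  if (!is.null(term_bias)) {
    if (is.null(names(term_bias))) stopf("term_bias must be named by term id")
    unknown <- setdiff(names(term_bias), dag$terms)
    if (length(unknown) > 0L)
      stopf("term_bias references unknown term(s): %s",
            paste(unknown, collapse = ", "))
    bad <- vapply(term_bias, function(b)
      length(b) != 2L || any(b < 0) || any(b > 1), logical(1L))
    if (any(bad)) stopf("term_bias entries must be probability pairs")
  }
  structure(list(params = params, group = group, dag = dag,
                 term_bias = term_bias, seed = as.integer(seed),
                 independent_phases = independent_phases),
            class = "sim_config")
}

#' Simulate triplication followed by two-phase fractionation
#'
#' Each of the `N` ancestral genes draws a class (`theta` fast, `1 - theta`
#' slow), is triplicated, and each copy then runs through two loss phases:
#' one pre-speciation draw per copy (survival `1 - p_class`, shared by all
#' descendant species -- the biologically faithful reading), then an
#' independent per-species draw (survival `1 - q_{i,class}`). Surviving
#' copies become genes named `g<ancestral>_<genome>_c<copy>`; homology
#' edges connect all surviving copies of the same ancestral gene (a
#' deterministic spanning structure: paralog chains within genomes,
#' ortholog links between consecutive represented genomes).
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result`: list with
#'   \describe{
#'     \item{genes}{gene table (`gene_id`, `genome_id`);}
#'     \item{edges}{edge list (`gene_a`, `gene_b`, `relation`, `block_id`);}
#'     \item{truth}{per ancestral gene: `ancestral_id`, `class` (1 fast /
#'       2 slow), per-genome copy counts and realized score;}
#'     \item{counts}{realized per-species `n2`/`n3` tallies (Table-1 shape);}
#'     \item{score_by_class}{realized score distribution per class;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_fractionation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pr <- config$params
  genomes <- config$group$genomes
  G <- length(genomes)
  N <- pr$N
  set.seed(config$seed)

  cls <- 1L + (stats::runif(N) >= pr$theta)          # 1 fast, 2 slow
  rate <- c(1, pr$alpha)[cls]
  # copies x genes survival through phase 1
  if (config$independent_phases) {
    # phase 1 redrawn per species below; mark all copies as candidates
    phase1 <- matrix(TRUE, nrow = 3L, ncol = N)
  } else {
    phase1 <- matrix(stats::runif(3L * N) >=
                       rep(rate * pr$p, each = 3L), nrow = 3L)
  }

  counts <- matrix(0L, nrow = N, ncol = G, dimnames = list(NULL, genomes))
  genes_list <- vector("list", G)
  surv_array <- array(FALSE, dim = c(3L, N, G))
  for (g in seq_len(G)) {
    keep_q <- matrix(stats::runif(3L * N) >=
                       rep(rate * pr$q[[g]], each = 3L), nrow = 3L)
    if (config$independent_phases) {
      keep_p <- matrix(stats::runif(3L * N) >=
                         rep(rate * pr$p, each = 3L), nrow = 3L)
      alive <- keep_p & keep_q
    } else {
      alive <- phase1 & keep_q
    }
    surv_array[, , g] <- alive
    counts[, g] <- colSums(alive)
  }

  # emit genes and a spanning set of homology edges per ancestral gene
  # (vectorized: one row per surviving copy, sorted by gene/genome/copy)
  idx <- which(surv_array, arr.ind = TRUE)   # cols: copy, ancestral, genome
  ord <- order(idx[, 2L], idx[, 3L], idx[, 1L])
  idx <- idx[ord, , drop = FALSE]
  anc <- idx[, 2L]; gnm <- idx[, 3L]; cpy <- idx[, 1L]
  gene_id <- sprintf("g%06d_%s_c%d", anc, genomes[gnm], cpy)
  genes <- data.frame(gene_id = gene_id, genome_id = genomes[gnm],
                      ancestral_id = sprintf("g%06d", anc),
                      stringsAsFactors = FALSE)

  n <- length(gene_id)
  if (n > 1L) {
    nxt <- 2:n
    # paralog chain: consecutive copies of the same ancestral gene & genome
    par_link <- anc[nxt] == anc[nxt - 1L] & gnm[nxt] == gnm[nxt - 1L]
    # ortholog chain: first copy in each represented genome, linked to the
    # first copy in the previous represented genome of the same gene
    first <- !c(FALSE, par_link)               # first copy per (gene, genome)
    fi <- which(first)
    ortho_from <- fi[-length(fi)]; ortho_to <- fi[-1L]
    keep_o <- anc[ortho_from] == anc[ortho_to]
    edges <- data.frame(
      gene_a = c(gene_id[which(par_link)], gene_id[ortho_from[keep_o]]),
      gene_b = c(gene_id[which(par_link) + 1L], gene_id[ortho_to[keep_o]]),
      relation = c(rep("paralog", sum(par_link)),
                   rep("ortholog", sum(keep_o))),
      block_id = sprintf("g%06d", c(anc[which(par_link)],
                                    anc[ortho_from[keep_o]])),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        relation = character(), block_id = character(),
                        stringsAsFactors = FALSE)
  }

  truth <- data.frame(ancestral_id = sprintf("g%06d", seq_len(N)),
                      class = cls, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(counts))
  truth$score <- fractionation_score(counts)

  tallies <- data.frame(
    species = genomes,
    n2 = vapply(seq_len(G), function(g) sum(counts[, g] == 2L), integer(1L)),
    n3 = vapply(seq_len(G), function(g) sum(counts[, g] == 3L), integer(1L)),
    stringsAsFactors = FALSE)

  score_by_class <- as.data.frame(table(
    class = factor(truth$class, levels = c(1L, 2L)),
    score = factor(truth$score, levels = 0:G)))
  names(score_by_class)[3L] <- "n_sets"

  structure(list(genes = genes, edges = edges, truth = truth,
                 counts = tallies, score_by_class = score_by_class,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulated fractionation: %d ancestral genes, %d surviving genes\n",
              x$config$params$N, nrow(x$genes)))
  print(x$counts)
  invisible(x)
}

#' Assign class-biased GO annotations to simulated genes
#'
#' Function is a property of the *ancestral* gene: each ancestral gene in
#' class `c` acquires each biased term with that term's class-`c` inclusion
#' probability, and every surviving copy inherits all of its ancestral
#' gene's terms. (Drawing per surviving copy instead would make set-level
#' term presence grow mechanically with the number of surviving copies,
#' confounding class composition with set size.) Only direct assignments
#' are made; ancestor closure is the ontology module's job
#' ([annotate_sets()]).
#'
#' @param sim A [simulate_fractionation()] result.
#' @param config The same [sim_config()] (for `term_bias` and `seed`).
#' @return Data frame `gene_id`, `term_id`.
#' @export
assign_annotations <- function(sim, config = sim$config) {
  if (is.null(config$term_bias))
    return(data.frame(gene_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  N <- config$params$N
  anc_ids <- sprintf("g%06d", seq_len(N))
  cls <- sim$truth$class[match(anc_ids, sim$truth$ancestral_id)]
  set.seed(config$seed + 1L)
  rows <- lapply(names(config$term_bias), function(tm) {
    pr <- config$term_bias[[tm]][cls]
    has_term <- anc_ids[stats::runif(N) < pr]
    hit <- sim$genes$ancestral_id %in% has_term
    data.frame(gene_id = sim$genes$gene_id[hit], term_id = tm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulation out as pipeline input files
#'
#' Emits the gene table, edge list, annotation TSV, toy OBO, realized
#' pair/triple counts and a ground-truth JSON, i.e. everything the analysis
#' stages read, so that simulated data can be round-tripped through the
#' same readers as real data.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @param ann Optional annotation table from [assign_annotations()].
#' @return Data frame manifest: `file`, `n_rows`.
#' @export
write_fixtures <- function(sim, dir, ann = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  put <- function(df, name) {
    write_tsv(df, file.path(dir, name))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = name, n_rows = nrow(df), stringsAsFactors = FALSE)
  }
  put(sim$genes[, c("gene_id", "genome_id")], "genes.tsv")
  put(sim$edges, "edges.tsv")
  put(sim$counts, "counts.tsv")
  if (!is.null(ann)) put(ann, "annotations.tsv")
  write_obo(sim$config$dag, file.path(dir, "ontology.obo"))
  manifest[[length(manifest) + 1L]] <- data.frame(
    file = "ontology.obo", n_rows = length(sim$config$dag$terms),
    stringsAsFactors = FALSE)
  truth <- list(seed = sim$config$seed,
                params = sim$config$params[c("p", "q", "theta", "alpha", "N")],
                counts = sim$counts,
                score_by_class = sim$score_by_class)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest[[length(manifest) + 1L]] <- data.frame(
    file = "truth.json", n_rows = NA_integer_, stringsAsFactors = FALSE)
  do.call(rbind, manifest)
}
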