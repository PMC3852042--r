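#' Parameters of the two-phase, two-class retention model
#'
#' The model follows one ancestral gene that was triplicated by a
#' whole-genome event. Each of its three copies is lost with probability
#' `p` during the shared period between the polyploidy event and
#' speciation, and a surviving copy is then lost with probability `q[i]`
#' independently in each descendant species `i`. Genes come in two classes:
#' a fraction `theta` fractionates at rates `(p, q_i)` and the remaining
#' `1 - theta` at rates `(alpha * p, alpha * q_i)`. Under the labelling
#' convention `alpha <= 1`, class 1 (share `theta`) is the faster,
#' fractionation-prone class.
#'
#' @param p Pre-speciation per-copy loss probability, in \[0, 1\].
#' @param q Numeric vector of per-species per-copy loss probabilities.
#' @param theta Share of class-1 genes, in \[0, 1\].
#' @param alpha Rate multiplier for class 2, > 0; `alpha * p` and every
#'   `alpha * q[i]` must stay within \[0, 1\].
#' @param N Assumed number of ancestral pre-triplication genes.
#' @return Object of class `retention_params`.
#' @export
retention_params <- function(p, q, theta = 1, alpha = 1, N = NA_integer_) {
  stopifnot(length(p) == 1L, length(theta) == 1L, length(alpha) == 1L)
  if (p < 0 || p > 1 || any(q < 0) || any(q > 1))
    stopf("loss probabilities must lie in [0, 1]")
  if (theta < 0 || theta > 1) stopf("theta must lie in [0, 1]")
  if (alpha <= 0) stopf("alpha must be positive")
  if (alpha * p > 1 || any(alpha * q > 1))
    stopf("alpha*p and alpha*q_i must not exceed 1")
  structure(list(p = p, q = as.numeric(q), theta = theta, alpha = alpha,
                 N = N), class = "retention_params")
}

#' @export
print.retention_params <- function(x, ...) {
  cat(sprintf("p = %.4f, theta = %.4f, alpha = %.4f, N = %s\n",
              x$p, x$theta, x$alpha, format(x$N)))
  cat("q_i:", paste(sprintf("%.4f", x$q), collapse = ", "), "\n")
  invisible(x)
}

#' Per-species retention probabilities of an ancestral triplet
#'
#' For a single gene class with rates `(p, q)`, the probability that an
#' ancestral triplet is observed in one species with 3, 2, 1 or 0 surviving
#' copies. Because each copy survives both phases independently with
#' probability `s = (1 - p)(1 - q)`, the four masses are the Binomial(3, s)
#' probabilities; they are assembled here phase by phase, which also makes
#' the two-phase structure explicit:
#' \deqn{P_3 = (1-p)^3 (1-q)^3}
#' \deqn{P_2 = (1-p)^3\,3q(1-q)^2 + 3p(1-p)^2 (1-q)^2}
#' \deqn{P_1 = (1-p)^3\,3q^2(1-q) + 3p(1-p)^2\,2q(1-q) + 3p^2(1-p)(1-q)}
#'
#' @param p Pre-speciation per-copy loss probability.
#' @param q Per-species per-copy loss probability.
#' @return Named numeric vector `c(P3, P2, P1, P0)` summing to 1.
#' @examples
#' retention_pmf(0.5, 0.5)
#' @export
retention_pmf <- function(p, q) {
  if (length(p) != 1L || length(q) != 1L)
    stopf("retention_pmf is scalar in p and q")
  if (is.na(p) || is.na(q) || p < 0 || p > 1 || q < 0 || q > 1)
    stopf("p and q must lie in [0, 1]")
  P3 <- (1 - p)^3 * (1 - q)^3
  P2 <- (1 - p)^3 * 3 * q * (1 - q)^2 + 3 * p * (1 - p)^2 * (1 - q)^2
  P1 <- (1 - p)^3 * 3 * q^2 * (1 - q) + 3 * p * (1 - p)^2 * 2 * q * (1 - q) +
    3 * p^2 * (1 - p) * (1 - q)
  c(P3 = P3, P2 = P2, P1 = P1, P0 = 1 - P3 - P2 - P1)
}

#' Two-class mixture retention probabilities for one species
#'
#' Component-wise mixture `theta * pmf(p, q_i) + (1 - theta) *
#' pmf(alpha p, alpha q_i)`.
#'
#' @param params A [retention_params()].
#' @param i Species index into `params$q`.
#' @return Named numeric vector `c(P3, P2, P1, P0)`.
#' @export
mixture_pmf <- function(params, i) {
  stopifnot(inherits(params, "retention_params"))
  if (i < 1L || i > length(params$q)) stopf("species index out of range")
  q <- params$q[[i]]
  if (params$alpha * params$p > 1 || params$alpha * q > 1)
    stopf("alpha*p and alpha*q_i must not exceed 1")
  params$theta * retention_pmf(params$p, q) +
    (1 - params$theta) * retention_pmf(params$alpha * params$p,
                                       params$alpha * q)
}

#' Read a per-species pair/triple count table
#'
#' @param path TSV with header and columns `species`, `n2` (pairs), `n3`
#'   (triples).
#' @return Data frame `species`, `n2`, `n3`.
#' @export
read_retention_counts <- function(path) {
  df <- read_tsv_strict(path, required = c("species", "n2", "n3"))
  df$species <- as.character(df$species)
  df$n2 <- as.integer(df$n2)
  df$n3 <- as.integer(df$n3)
  validate_counts(df)
  df[, c("species", "n2", "n3")]
}

validate_counts <- function(counts, N = NULL) {
  if (any(counts$n2 < 0L) || any(counts$n3 < 0L))
    stopf("pair/triple counts must be non-negative")
  if (!is.null(N) && any(counts$n2 + counts$n3 > N))
    stopf("n2 + n3 exceeds the assumed ancestral gene number N for species %s",
          counts$species[which(counts$n2 + counts$n3 > N)[1L]])
  invisible(TRUE)
}

#' Log-likelihood of the two-class retention model
#'
#' The observed data are, per species, the numbers of ancestral genes
#' surviving as triples (`n3`) and pairs (`n2`) out of `N` ancestral
#' triplets. Single-copy survivors are indistinguishable from full losses
#' in this data (single-copy genes belong largely to the mobile genome and
#' are not collected), so the remaining `N - n3 - n2` genes form one
#' unobserved-remainder category with probability `P1 + P0`. Species are
#' treated as independent, and each species contributes the multinomial
#' log-mass of `(n3, n2, N - n3 - n2)` under `(P3, P2, P1 + P0)` from
#' [mixture_pmf()], combinatorial constants included.
#'
#' @param params A [retention_params()] with `N` set (or pass `N`).
#' @param counts Data frame `species`, `n2`, `n3`.
#' @param N Ancestral gene number; defaults to `params$N`.
#' @return Log-likelihood (may be `-Inf` if a needed category has
#'   probability zero but positive count).
#' @export
retention_loglik <- function(params, counts, N = params$N) {
  stopifnot(inherits(params, "retention_params"))
  if (is.na(N)) stopf("N must be provided")
  if (length(params$q) != nrow(counts))
    stopf("params$q has %d species but counts has %d",
          length(params$q), nrow(counts))
  validate_counts(counts, N)
  ll <- 0
  for (i in seq_len(nrow(counts))) {
    pmf <- mixture_pmf(params, i)
    probs <- c(pmf[["P3"]], pmf[["P2"]], pmf[["P1"]] + pmf[["P0"]])
    x <- c(counts$n3[i], counts$n2[i], N - counts$n3[i] - counts$n2[i])
    if (any(probs == 0 & x > 0)) return(-Inf)
    ll <- ll + stats::dmultinom(x, prob = probs, log = TRUE)
  }
  ll
}

fit_box <- function(S, eps = 1e-4, alpha_max = 1) {
  list(lower = c(rep(eps, 1L + S), 1e-3, 1e-3),
       upper = c(rep(1 - 1e-6, 1L + S), 1 - 1e-3, alpha_max))
}

par_to_params <- function(par, S, N) {
  retention_params(p = par[1L], q = par[2:(S + 1L)], theta = par[S + 2L],
                   alpha = par[S + 3L], N = N)
}

#' Maximum-likelihood fit of the two-class retention model
#'
#' Maximizes [retention_loglik()] over `(p, q_1..q_S, theta, alpha)` with
#' `N` fixed, using bounded quasi-Newton (`L-BFGS-B`) from a seeded
#' Latin-hypercube of starting points. The box constrains all loss
#' probabilities to (0, 1) and `alpha` to (0, 1\]; the cap on `alpha`
#' resolves the label-switching symmetry of the mixture (swapping the
#' classes and replacing `alpha` by `1/alpha` leaves the likelihood
#' unchanged), so class 1 is always the faster-fractionating class.
#'
#' @param counts Data frame `species`, `n2`, `n3`.
#' @param N Assumed ancestral gene number (`>= max(n2 + n3)`).
#' @param n_starts Number of multistart points (default 32).
#' @param seed Integer seed for the start design.
#' @param alpha_max Upper bound for `alpha` (default 1, the labelling
#'   convention).
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return Object of class `retention_fit`: list with `params`
#'   ([retention_params()]), `loglik`, `counts`, `starts` (data frame of
#'   each start's converged value and convergence code) and `convergence`
#'   (0 for success of the best start).
#' @examples
#' fit <- fit_retention_model(rosid_retention_counts(), N = 7500, seed = 1)
#' fit
#' @export
fit_retention_model <- function(counts, N, n_starts = 32L, seed = 1L,
                                alpha_max = 1, reltol = 1e-9) {
  validate_counts(counts, N)
  if (N < max(counts$n2 + counts$n3))
    stopf("N must be at least the largest per-species n2 + n3")
  S <- nrow(counts)
  box <- fit_box(S, alpha_max = alpha_max)
  npar <- S + 3L

  negll <- function(par) {
    params <- try(par_to_params(par, S, N), silent = TRUE)
    if (inherits(params, "try-error")) return(1e10)
    ll <- retention_loglik(params, counts, N)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  set.seed(seed)
  design <- lhs::randomLHS(n_starts, npar)
  starts <- sweep(design, 2L, box$upper - box$lower, `*`)
  starts <- sweep(starts, 2L, box$lower, `+`)

  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      stats::optim(starts[s, ], negll, method = "L-BFGS-B",
                   lower = box$lower, upper = box$upper,
                   control = list(maxit = 2000L,
                                  factr = reltol / .Machine$double.eps)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stopf("no multistart converged; try more starts")
  vals <- vapply(fits[ok], `[[`, numeric(1L), "value")
  conv <- vapply(fits[ok], `[[`, numeric(1L), "convergence")
  best <- fits[ok][[which.min(vals)]]
  if (all(conv != 0) && best$value >= 1e10)
    stopf("optimizer failed to converge from any start")

  structure(list(
    params = par_to_params(best$par, S, N),
    loglik = -best$value,
    counts = counts,
    starts = data.frame(start = which(ok), value = -vals,
                        convergence = conv),
    convergence = best$convergence), class = "retention_fit")
}

#' Share of the larger fitted gene class, in percent
#' @param fit A `retention_fit`.
#' @return `100 * max(theta, 1 - theta)`.
#' @export
larger_class_share <- function(fit) {
  th <- fit$params$theta
  100 * max(th, 1 - th)
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("Two-class retention model fit (N = %d, logL = %.3f)\n",
              x$params$N, x$loglik))
  print(x$params)
  cat(sprintf("class shares: %.1f%% / %.1f%% (alpha = %.3f)\n",
              100 * x$params$theta, 100 * (1 - x$params$theta),
              x$params$alpha))
  invisible(x)
}

#' Refit the retention model across assumed ancestral gene numbers
#'
#' The ancestral gene number `N` cannot be observed directly; this profiles
#' the fit over a set of plausible values and reports how much each
#' parameter moves, to check which conclusions depend on `N`.
#'
#' @param counts Data frame `species`, `n2`, `n3`.
#' @param N_values Vector of ancestral gene numbers to fit at.
#' @param ... Passed to [fit_retention_model()].
#' @return Object of class `retention_profile`: list with `fits` (one
#'   `retention_fit` per `N`), `table` (one row per `N`: parameters and
#'   log-likelihood) and `drift` (named vector: max minus min across `N`
#'   for each parameter).
#' @export
profile_over_N <- function(counts, N_values, ...) {
  fits <- lapply(N_values, function(N)
    fit_retention_model(counts, N = N, ...))
  S <- nrow(counts)
  tab <- do.call(rbind, lapply(seq_along(fits), function(k) {
    pr <- fits[[k]]$params
    row <- data.frame(N = N_values[k], p = pr$p, theta = pr$theta,
                      alpha = pr$alpha, loglik = fits[[k]]$loglik)
    qs <- as.data.frame(as.list(stats::setNames(
      pr$q, paste0("q_", counts$species))))
    cbind(row, qs)
  }))
  drift <- apply(tab[, setdiff(names(tab), c("N", "loglik")), drop = FALSE],
                 2L, function(v) max(v) - min(v))
  structure(list(fits = fits, table = tab, drift = drift),
            class = "retention_profile")
}

#' @export
print.retention_profile <- function(x, ...) {
  print(x$table, digits = 4)
  cat("\nparameter drift (max - min) across N:\n")
  print(round(x$drift, 4))
  invisible(x)
}

# Poisson-binomial pmf over k successes among independent Bernoulli(prob)
poisson_binomial_pmf <- function(prob) {
  pmf <- 1
  for (m in prob) pmf <- c(pmf * (1 - m), 0) + c(0, pmf * m)
  pmf
}

#' Predicted fractionation-score distribution for each gene class
#'
#' Given fitted parameters, predicts for each class how surviving homology
#' sets distribute over fractionation scores 0..G in a chosen subset of G
#' genomes. The prediction conditions on full sets (at least one surviving
#' copy in every genome of the subset): per genome, a surviving set is
#' multi-copy with probability `m_i = (P3 + P2) / (P3 + P2 + P1)`, and the
#' score is the Poisson-binomial count of multi-copy genomes. Expected set
#' counts scale by `N`, the class share and the probability of surviving in
#' all genomes; the per-score relative class proportions are what
#' retention-pattern figures plot.
#'
#' @param params A [retention_params()] with `N` set.
#' @param species Indices into `params$q` selecting the G genomes.
#' @return Object of class `score_distribution`: data frame `class`
#'   (`"class1"` fast / `"class2"` slow), `score`, `probability`,
#'   `expected_sets`, `relative_proportion` (share of the class among the
#'   expected sets at that score).
#' @export
predict_score_distribution <- function(params, species = seq_along(params$q)) {
  stopifnot(inherits(params, "retention_params"))
  if (length(species) == 0L || any(species < 1L) ||
      any(species > length(params$q)))
    stopf("invalid species subset")
  G <- length(species)
  classes <- list(
    class1 = c(rate = 1, share = params$theta),
    class2 = c(rate = params$alpha, share = 1 - params$theta))
  rows <- list()
  for (cl in names(classes)) {
    r <- classes[[cl]][["rate"]]
    m <- numeric(G); surv <- numeric(G)
    for (j in seq_len(G)) {
      pmf <- retention_pmf(r * params$p, r * params$q[[species[j]]])
      alive <- pmf[["P3"]] + pmf[["P2"]] + pmf[["P1"]]
      if (alive == 0) stopf("species %d has zero survival probability",
                            species[j])
      surv[j] <- alive
      m[j] <- (pmf[["P3"]] + pmf[["P2"]]) / alive
    }
    prob <- poisson_binomial_pmf(m)
    n_exp <- params$N * classes[[cl]][["share"]] * prod(surv) * prob
    rows[[cl]] <- data.frame(class = cl, score = 0:G, probability = prob,
                             expected_sets = n_exp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  tot <- stats::ave(out$expected_sets, out$score, FUN = sum)
  out$relative_proportion <- ifelse(tot > 0, out$expected_sets / tot, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("score_distribution", "data.frame")
  out
}
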