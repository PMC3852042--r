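test_that("retention pmf matches hand-enumerated two-phase outcomes", {
  expect_equal(unname(retention_pmf(0, 0)), c(1, 0, 0, 0))
  expect_equal(retention_pmf(1, 0.3)[["P0"]], 1)
  expect_equal(retention_pmf(1, 0)[["P0"]], 1)
  # p = q = 0.5: per-copy survival 0.25, enumerate all 2-phase outcomes
  expect_equal(unname(retention_pmf(0.5, 0.5)),
               c(0.015625, 0.140625, 0.421875, 0.421875))
  expect_error(retention_pmf(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(retention_pmf(0.5, 1.2), "\\[0, 1\\]")
})

test_that("pmf equals Binomial(3, (1-p)(1-q)) and sums to one", {
  set.seed(123)
  for (r in 1:200) {
    p <- stats::runif(1); q <- stats::runif(1)
    pmf <- retention_pmf(p, q)
    s <- (1 - p) * (1 - q)
    expect_equal(unname(pmf), stats::dbinom(3:0, 3, s), tolerance = 1e-12)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_true(all(pmf >= 0 & pmf <= 1))
  }
})

test_that("mixture pmf is the convex combination of two class pmfs", {
  pr1 <- retention_params(p = 0.2, q = c(0.3, 0.5), theta = 1, alpha = 0.5)
  expect_equal(mixture_pmf(pr1, 1L), retention_pmf(0.2, 0.3))
  pr2 <- retention_params(p = 0.2, q = c(0.3, 0.5), theta = 0.3, alpha = 1)
  expect_equal(mixture_pmf(pr2, 2L), retention_pmf(0.2, 0.5))
  pr3 <- retention_params(p = 0.2, q = c(0.3, 0.5), theta = 0.5, alpha = 0.5)
  expect_equal(mixture_pmf(pr3, 1L),
               0.5 * retention_pmf(0.2, 0.3) + 0.5 * retention_pmf(0.1, 0.15))
  expect_error(retention_params(p = 0.9, q = 0.5, theta = 0.5, alpha = 1.2),
               "exceed")
  expect_error(mixture_pmf(pr3, 3L), "out of range")
})

test_that("log-likelihood matches direct multinomial computation", {
  pr <- retention_params(p = 0, q = 0, theta = 1, alpha = 1, N = 1)
  counts <- data.frame(species = "s1", n2 = 0L, n3 = 1L)
  expect_equal(retention_loglik(pr, counts), 0)

  pr2 <- retention_params(p = 0.2, q = 0.4, theta = 0.6, alpha = 0.5, N = 2)
  counts2 <- data.frame(species = "s1", n2 = 1L, n3 = 1L)
  pmf <- 0.6 * retention_pmf(0.2, 0.4) + 0.4 * retention_pmf(0.1, 0.2)
  # brute force: 2!/(1!1!0!) * P3^1 * P2^1 * (P1+P0)^0
  oracle <- log(factorial(2) * pmf[["P3"]] * pmf[["P2"]])
  expect_equal(retention_loglik(pr2, counts2), oracle)

  # a zero-probability category with positive count gives -Inf
  pr3 <- retention_params(p = 1, q = 0.5, theta = 1, alpha = 1, N = 5)
  expect_equal(retention_loglik(pr3, counts2), -Inf)
  expect_error(retention_loglik(pr2, data.frame(species = "s1",
                                                n2 = 2L, n3 = 1L)),
               "exceeds")
})

test_that("likelihood is invariant under label switching", {
  counts <- data.frame(species = c("s1", "s2"), n2 = c(40L, 30L),
                       n3 = c(10L, 5L))
  p <- 0.3; q <- c(0.4, 0.5); th <- 0.7; al <- 0.5
  a <- retention_params(p, q, th, al, N = 300)
  b <- retention_params(al * p, al * q, 1 - th, 1 / al, N = 300)
  expect_equal(retention_loglik(a, counts), retention_loglik(b, counts))
})

test_that("the fitted optimum is a local maximum of the likelihood", {
  pr_true <- retention_params(p = 0.35, q = c(0.45, 0.55, 0.65),
                              theta = 0.7, alpha = 0.6, N = 5000)
  cfg <- sim_config(pr_true, genome_group(c("A", "B", "C")), seed = 301)
  sim <- simulate_fractionation(cfg)
  fit <- fit_retention_model(sim$counts, N = 5000, seed = 11,
                             n_starts = 16L)
  expect_equal(fit$convergence, 0)
  expect_true(is.finite(fit$loglik))
  base <- fit$params
  for (delta in c(0.02, -0.02)) {
    for (what in c("p", "theta", "alpha")) {
      pert <- base
      val <- pert[[what]] + delta
      if (val <= 0 || val >= 1) next
      pert[[what]] <- val
      pert <- retention_params(pert$p, pert$q, pert$theta, pert$alpha,
                               pert$N)
      expect_lte(retention_loglik(pert, sim$counts), fit$loglik + 1e-3)
    }
  }
})

test_that("single-class data yields a boundary or alpha~1 fit with no
           two-class likelihood gain", {
  pr_true <- retention_params(p = 0.4, q = c(0.5, 0.55, 0.6), theta = 1,
                              alpha = 1, N = 8000)
  cfg <- sim_config(pr_true, genome_group(c("A", "B", "C")), seed = 555)
  sim <- simulate_fractionation(cfg)
  fit2 <- fit_retention_model(sim$counts, N = 8000, seed = 21)
  # one-class profile: optimize p, q at theta fixed to 1
  neg1 <- function(par) {
    pr <- retention_params(par[1L], par[2:4], theta = 1, alpha = 1, N = 8000)
    -retention_loglik(pr, sim$counts)
  }
  one <- stats::optim(c(0.5, 0.5, 0.5, 0.5), neg1, method = "L-BFGS-B",
                      lower = rep(1e-4, 4), upper = rep(1 - 1e-6, 4))
  lr <- 2 * (fit2$loglik - (-one$value))
  expect_gte(lr, -1e-4)     # two-class can only fit at least as well
  expect_lt(lr, stats::qchisq(0.999, df = 2))  # ...but not materially better
  near_single <- fit2$params$alpha > 0.9 ||
    fit2$params$theta > 0.95 || fit2$params$theta < 0.05
  expect_true(near_single)
})

test_that("estimator RMSE for theta and alpha shrinks as N grows", {
  rmse <- function(N, reps = 4L) {
    errs <- vapply(seq_len(reps), function(r) {
      pr <- retention_params(p = 0.4, q = c(0.5, 0.6, 0.7), theta = 0.7,
                             alpha = 0.55, N = N)
      cfg <- sim_config(pr, genome_group(c("A", "B", "C")),
                        seed = 9000 + 17L * r + N %% 97L)
      sim <- simulate_fractionation(cfg)
      fit <- fit_retention_model(sim$counts, N = N, seed = 40 + r,
                                 n_starts = 12L)
      c(fit$params$theta - 0.7, fit$params$alpha - 0.55)
    }, numeric(2L))
    sqrt(rowMeans(errs^2))
  }
  small <- rmse(1000L)
  large <- rmse(100000L)
  expect_lt(large[1L], small[1L] + 0.05)
  expect_lt(large[2L], small[2L] + 0.05)
  expect_lt(mean(large), mean(small))
})

test_that("profiling rejects N below the observed survivors", {
  counts <- rosid_retention_counts()
  expect_error(fit_retention_model(counts, N = 1000), "exceeds")
  expect_error(profile_over_N(counts, c(7500, 1000)), "exceeds")
})

test_that("score distribution: degenerate limits and exact enumeration", {
  pr0 <- retention_params(p = 0, q = c(0, 0, 0), theta = 0.6, alpha = 0.5,
                          N = 900)
  sd0 <- predict_score_distribution(pr0)
  expect_equal(sd0$probability[sd0$score == 3], c(1, 1))
  expect_equal(sum(sd0$expected_sets), 900)

  pr1 <- retention_params(p = 0.2, q = rep(1 - 1e-9, 3), theta = 1,
                          alpha = 1, N = 100)
  sd1 <- predict_score_distribution(pr1)
  expect_equal(sd1$probability[sd1$score == 0 & sd1$class == "class1"], 1,
               tolerance = 1e-6)

  # unequal m_i vs brute-force enumeration of the 2^3 multi/single patterns
  pr <- retention_params(p = 0.3, q = c(0.2, 0.5, 0.7), theta = 1,
                         alpha = 1, N = 1000)
  sdp <- predict_score_distribution(pr)
  m <- vapply(1:3, function(i) {
    pmf <- retention_pmf(0.3, pr$q[i])
    (pmf[["P3"]] + pmf[["P2"]]) / (pmf[["P3"]] + pmf[["P2"]] + pmf[["P1"]])
  }, numeric(1L))
  brute <- numeric(4L)
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    pr_pat <- prod(ifelse(c(b1, b2, b3) == 1, m, 1 - m))
    k <- b1 + b2 + b3
    brute[k + 1L] <- brute[k + 1L] + pr_pat
  }
  expect_equal(sdp$probability[sdp$class == "class1"], brute,
               tolerance = 1e-12)
  # per class the probabilities sum to one
  expect_equal(sum(sdp$probability[sdp$class == "class1"]), 1,
               tolerance = 1e-12)
  expect_error(predict_score_distribution(pr, species = 9L), "invalid")
})

test_that("per-score relative proportions compare the two classes", {
  pr <- retention_params(p = 0.4, q = c(0.5, 0.6, 0.7), theta = 0.75,
                         alpha = 0.6, N = 7500)
  sdp <- predict_score_distribution(pr)
  agg <- tapply(sdp$relative_proportion, sdp$score, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
  # the slow class (class2) should dominate at high scores
  r3 <- sdp$relative_proportion[sdp$score == 3]
  r0 <- sdp$relative_proportion[sdp$score == 0]
  expect_gt(r3[2L] / r3[1L], r0[2L] / r0[1L])
})

test_that("the shipped six-rosid counts load with the printed totals", {
  counts <- rosid_retention_counts()
  expect_equal(nrow(counts), 6L)
  expect_equal(counts$species[1L], "peach")
  expect_equal(sum(counts$n2), 5471L)
  expect_equal(sum(counts$n3), 788L)
})

test_that("two classes fit the six-rosid counts decisively better than
           one, yet (theta, alpha) sit on a flat likelihood plateau", {
  counts <- rosid_retention_counts()
  fit2 <- fit_retention_model(counts, N = 7500, seed = 1)
  # one-class profile: theta pinned to 1, optimize p and the q_i
  neg1 <- function(par) {
    pr <- retention_params(par[1L], par[2:7], theta = 1, alpha = 1,
                           N = 7500)
    ll <- retention_loglik(pr, counts)
    if (!is.finite(ll)) 1e10 else -ll
  }
  one <- stats::optim(rep(0.5, 7), neg1, method = "L-BFGS-B",
                      lower = rep(1e-4, 7), upper = rep(1 - 1e-6, 7))
  lr <- 2 * (fit2$loglik - (-one$value))
  expect_gt(lr, stats::qchisq(0.999, df = 2))   # heterogeneity is real
  # profile at class shares 25%/75% with alpha = 0.6: within a few
  # log-units of the optimum, i.e. the data barely distinguish the two
  negp <- function(par, th, al) {
    pr <- retention_params(par[1L], par[2:7], theta = th, alpha = al,
                           N = 7500)
    ll <- retention_loglik(pr, counts)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(8)
  prof <- min(vapply(1:20, function(k)
    stats::optim(stats::runif(7, 0.1, 0.9), negp, th = 0.25, al = 0.6,
                 method = "L-BFGS-B", lower = rep(1e-4, 7),
                 upper = rep(1 - 1e-6, 7))$value, numeric(1L)))
  expect_lt(fit2$loglik - (-prof), 3)
})
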