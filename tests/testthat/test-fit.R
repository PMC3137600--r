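test_that("conditional log-likelihood identities hold", {
  set.seed(4)
  K <- 4
  D <- matrix(rnorm(20 * K), 20, K)
  D <- D - rowMeans(D)                    # rows sum to zero as in real designs
  # beta = 0: every matched pair contributes log(1/2)
  expect_equal(conditional_loglik(rep(0, K), D), 20 * log(0.5))
  # a d = 0 family contributes log(1/2) regardless of beta
  D0 <- rbind(D, 0)
  beta <- rnorm(K)
  expect_equal(conditional_loglik(beta, D0),
               conditional_loglik(beta, D) + log(0.5))
  # shift invariance: adding a constant to all effects changes nothing
  expect_equal(conditional_loglik(beta + 1.7, D),
               conditional_loglik(beta, D), tolerance = 1e-12)
  expect_error(conditional_loglik(rep(0, 3), D), "cores")
  # empty design
  expect_equal(conditional_loglik(beta, D[0, , drop = FALSE]), 0)
})

test_that("log-posterior combines likelihood, MVN and inverse-gamma terms", {
  set.seed(8)
  D <- matrix(rnorm(12), 6, 2); D <- D - rowMeans(D)
  pr <- prior_spec(mean = 0, a = 2, b = 1)
  beta <- c(0.4, -0.2); s2 <- 0.7
  manual <- conditional_loglik(beta, D) +
    sum(dnorm(beta, 0, sqrt(s2), log = TRUE)) +
    (2 * log(1) - lgamma(2) - 3 * log(s2) - 1 / s2)
  expect_equal(log_posterior(beta, s2, D, pr), manual, tolerance = 1e-12)
  # at beta = mu the MVN term is its mode value
  expect_equal(log_posterior(c(0, 0), s2, D[0, , drop = FALSE], pr),
               -log(2 * pi * s2) + (-3 * log(s2) - 1 / s2 - lgamma(2)),
               tolerance = 1e-12)
  expect_error(log_posterior(beta, -1, D, pr), "positive")
})

test_that("the sigma2 Gibbs conditional matches its closed form", {
  pr <- prior_spec(mean = 0, a = 1, b = 2)
  cond <- uchap:::.sigma2_conditional(c(1, 3), pr)
  # shape = a + K/2 = 2; rate = b + (1 + 9)/2 = 7
  expect_equal(unname(cond["shape"]), 2)
  expect_equal(unname(cond["rate"]), 7)
})

test_that("with no data the sampler reproduces the prior hierarchy", {
  pr <- prior_spec(mean = 0.5, a = 3, b = 2)
  D <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("c1", "c2")))
  ch <- sample_posterior(D, prior = pr,
                         config = mcmc_config(chains = 1, burnin = 500,
                                              iter = 40000, thin = 10,
                                              seed = 3))
  s2 <- ch[[1]]$sigma2
  # sigma2 marginal is IG(a, b): Kolmogorov-Smirnov distance on the cdf
  u <- pgamma(1 / s2, shape = 3, rate = 2, lower.tail = FALSE)
  ks <- max(abs(sort(u) - seq_along(u) / length(u)))
  expect_lt(ks, 0.05)
  # beta | sigma2 is N(mu, sigma2): probability integral transform
  z <- pnorm(ch[[1]]$beta[, 1], 0.5, sqrt(s2))
  ks2 <- max(abs(sort(z) - seq_along(z) / length(z)))
  expect_lt(ks2, 0.05)
})

test_that("1-D posterior moments match a quadrature oracle", {
  set.seed(21)
  d <- matrix(c(1.5, -0.5, 2, 1, -1, 0.5, 1, 2, -0.5, 1), ncol = 1,
              dimnames = list(NULL, "c1"))
  pr <- prior_spec(mean = 0.3, a = 1, b = 1)
  target <- function(b) vapply(b, function(bb)
    exp(conditional_loglik(bb, d) + dnorm(bb, 0.3, 1, log = TRUE)), 1)
  Z <- integrate(target, -10, 10)$value
  m1 <- integrate(function(b) b * target(b), -10, 10)$value / Z
  m2 <- integrate(function(b) b^2 * target(b), -10, 10)$value / Z
  ch <- sample_posterior(d, prior = pr, fixed_sigma2 = 1,
                         config = mcmc_config(chains = 1, burnin = 1000,
                                              iter = 40000, thin = 4,
                                              seed = 17))
  draws <- ch[[1]]$beta[, 1]
  expect_equal(mean(draws), m1, tolerance = 0.03)
  expect_equal(sd(draws), sqrt(m2 - m1^2), tolerance = 0.05)
})

test_that("Gelman-Rubin matches the hand-computed textbook value", {
  c1 <- matrix(1:5, ncol = 1); c2 <- matrix(c(2, 4, 6, 8, 10), ncol = 1)
  # W = (2.5 + 10)/2 = 6.25; B = 5 * var(c(3, 6)) = 22.5
  # vhat = 4/5 * 6.25 + 22.5/5 = 9.5; R = sqrt(9.5/6.25)
  expect_equal(unname(gelman_rubin(list(c1, c2))), sqrt(9.5 / 6.25),
               tolerance = 1e-12)
  expect_error(gelman_rubin(list(c1)), "two chains")
  # IID chains from one distribution approach 1
  set.seed(2)
  iid <- lapply(1:3, function(i) matrix(rnorm(4000), ncol = 2))
  expect_equal(unname(gelman_rubin(iid)), c(1, 1), tolerance = 0.01)
  # offset means inflate the statistic
  off <- list(matrix(rnorm(500), ncol = 1), matrix(rnorm(500, 3), ncol = 1))
  expect_gt(gelman_rubin(off), 1.5)
})

test_that("posterior summaries report risk probabilities and calls", {
  # synthetic chains with known structure
  set.seed(14)
  B <- cbind(ref = rnorm(2000, -4.6, 0.1),
             up = rnorm(2000, -3.6, 0.1),
             same = rnorm(2000, -4.6, 0.1))
  ch <- structure(list(list(beta = B, sigma2 = rgamma(2000, 2))),
                  class = "uchap_chains", cores = colnames(B),
                  prior_mean = rep(-4.6, 3),
                  config = mcmc_config(chains = 1))
  s <- summarize_posterior(ch, reference = 1, threshold = 0.5)
  expect_equal(s$rr[1], 1)
  expect_true(is.na(s$prob_susceptible[1]))
  expect_gt(s$prob_susceptible[2], 0.99)
  expect_true(s$risk_call[2])
  expect_equal(s$prob_susceptible[3], 0.5, tolerance = 0.05)
  expect_equal(s$prob_rr[3], 0.5, tolerance = 0.05)
  # draws identical to the reference: strictly-greater fraction is 0, RR = 1
  B2 <- cbind(a = rnorm(100), b = 0, c = 0)
  B2[, 2] <- B2[, 1]; B2[, 3] <- B2[, 1] + 0.2
  ch2 <- structure(list(list(beta = B2, sigma2 = rep(1, 100))),
                   class = "uchap_chains", cores = colnames(B2),
                   prior_mean = rep(0, 3),
                   config = mcmc_config(chains = 1))
  s2 <- summarize_posterior(ch2, reference = 1)
  expect_equal(s2$prob_rr[2], 0)
  expect_equal(s2$rr[2], 1)
  expect_equal(s2$prob_rr[3], 1)
})

test_that("posterior mean contrasts agree with the conditional-ML oracle", {
  withr::local_package("survival")
  set.seed(77)
  fams <- sim_families(n = 200, grr = 2.0)
  des <- uncertainty_design(fams, ref_pool())
  # nearly flat prior so the posterior concentrates on the ML ridge
  ch <- sample_posterior(des, prior = prior_spec(mean = 0, a = 5, b = 400),
                         config = mcmc_config(chains = 1, burnin = 2000,
                                              iter = 20000, thin = 5,
                                              seed = 9))
  s <- summarize_posterior(ch)
  post_contrast <- s$mean - s$mean[1]

  n <- nrow(des$D)
  X <- rbind(des$Z1[, -1], des$Z0[, -1])
  st <- c(1:n, 1:n)
  fit <- survival::clogit(c(rep(1, n), rep(0, n)) ~ X + strata(st))
  mle <- unname(coef(fit))
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(post_contrast[-1] - mle) < pmax(2.5 * se, 0.2)))
})

test_that("effect contrasts are insensitive to shifting the prior mean", {
  set.seed(123)
  fams <- sim_families(n = 80, grr = 2.0)
  des <- uncertainty_design(fams, ref_pool())
  cfg <- function(s) mcmc_config(chains = 1, burnin = 1000, iter = 6000,
                                 thin = 2, seed = s)
  s_a <- summarize_posterior(sample_posterior(des, prior_spec(mean = -4.6),
                                              config = cfg(1)))
  s_b <- summarize_posterior(sample_posterior(des, prior_spec(mean = -2.0),
                                              config = cfg(2)))
  ca <- s_a$mean - s_a$mean[1]
  cb <- s_b$mean - s_b$mean[1]
  expect_true(all(abs(ca - cb) < 0.25))
})
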