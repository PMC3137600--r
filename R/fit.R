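# Bayesian conditional logistic regression on the uncertainty-coded
# matched-pair design: likelihood, posterior, MCMC sampling, convergence
# diagnostics and posterior risk summaries.

#' Prior specification for the haplotype effect vector
#'
#' Effects are a priori multivariate normal with every mean component
#' equal to the logit of the disease prevalence, covariance
#' `sigma2 * Sigma` with `Sigma` the identity by default (independent
#' priors) or compound-symmetric when `rho` is nonzero, and an
#' inverse-gamma hyperprior on `sigma2`.
#'
#' @param prevalence Disease prevalence whose logit is the common prior
#'   mean (default 0.01).
#' @param mean Optional explicit prior mean (scalar or length-K vector);
#'   overrides `prevalence`.
#' @param a,b Inverse-gamma shape and rate for `sigma2` (default 0.01 and
#'   0.01, weakly informative).
#' @param rho Common off-diagonal correlation of `Sigma` (default 0,
#'   i.e. identity).
#' @return List of class `"uchap_prior"`.
#' @export
prior_spec <- function(prevalence = 0.01, mean = NULL, a = 0.01, b = 0.01,
                       rho = 0) {
  if (a <= 0 || b <= 0) stop("inverse-gamma a, b must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)", call. = FALSE)
  if (is.null(mean)) {
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must be in (0, 1)", call. = FALSE)
    mean <- qlogis(prevalence)
  }
  structure(list(mean = mean, a = a, b = b, rho = rho), class = "uchap_prior")
}

.prior_matrices <- function(prior, K) {
  mu <- rep_len(prior$mean, K)
  Sigma <- diag(K)
  if (prior$rho != 0) Sigma[Sigma == 0] <- prior$rho
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("prior covariance is not positive definite", call. = FALSE)
  list(mu = mu, Sigma = Sigma, SigmaInv = solve(Sigma))
}

#' MCMC configuration
#'
#' Defaults follow the package's standard analysis protocol: three chains,
#' 5,000 burn-in iterations, then 10,000 iterations thinned to every 10th
#' draw, i.e. 3,000 retained posterior samples in total.
#'
#' @param chains Number of chains (>= 1).
#' @param burnin Burn-in iterations per chain (also the adaptation phase).
#' @param iter Post-burn-in iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer master seed; each chain uses a derived substream.
#'   `NULL` continues the caller's RNG stream.
#' @return List of class `"uchap_mcmc"`.
#' @export
mcmc_config <- function(chains = 3L, burnin = 5000L, iter = 10000L,
                        thin = 10L, seed = NULL) {
  stopifnot(chains >= 1, burnin >= 0, iter >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), burnin = as.integer(burnin),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = seed), class = "uchap_mcmc")
}

.design_D <- function(designs) {
  if (inherits(designs, "hap_design")) designs$D
  else if (is.matrix(designs)) designs
  else stop("designs must be a hap_design or a numeric matrix", call. = FALSE)
}

#' Conditional logistic log-likelihood of the matched pairs
#'
#' `sum_i log[ exp(b.z1_i) / (exp(b.z1_i) + exp(b.z0_i)) ]`, computed
#' stably through the within-pair difference `d_i = z1_i - z0_i` as
#' `-log(1 + exp(-b.d_i))`.  Because every `d_i` sums to zero over cores,
#' the likelihood is invariant to adding a constant to all effects; the
#' prior resolves that direction.
#'
#' @param beta Effect vector (length K).
#' @param designs A `"hap_design"` or a families-by-cores difference
#'   matrix `D`.
#' @return Scalar log-likelihood (0 for an empty design).
#' @export
conditional_loglik <- function(beta, designs) {
  D <- .design_D(designs)
  if (ncol(D) != length(beta))
    stop("beta length does not match the number of cores", call. = FALSE)
  if (nrow(D) == 0L) return(0)
  sum(plogis(drop(D %*% beta), log.p = TRUE))
}

#' Unnormalized log-posterior density
#'
#' Conditional log-likelihood plus the `MVN(mu, sigma2 Sigma)` log-density
#' of `beta` and the inverse-gamma `IG(a, b)` log-density of `sigma2`.
#'
#' @inheritParams conditional_loglik
#' @param sigma2 Prior scale parameter (positive).
#' @param prior A [prior_spec()].
#' @export
log_posterior <- function(beta, sigma2, designs, prior = prior_spec()) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  D <- .design_D(designs)
  K <- length(beta)
  pm <- .prior_matrices(prior, K)
  qf <- drop(t(beta - pm$mu) %*% pm$SigmaInv %*% (beta - pm$mu))
  ld <- as.numeric(determinant(pm$Sigma, logarithm = TRUE)$modulus)
  lp_beta <- -0.5 * (K * log(2 * pi * sigma2) + ld + qf / sigma2)
  lp_s2 <- prior$a * log(prior$b) - lgamma(prior$a) -
    (prior$a + 1) * log(sigma2) - prior$b / sigma2
  conditional_loglik(beta, D) + lp_beta + lp_s2
}

# closed-form inverse-gamma full conditional of sigma2 given beta
.sigma2_conditional <- function(beta, prior = prior_spec()) {
  K <- length(beta)
  pm <- .prior_matrices(prior, K)
  qf <- drop(t(beta - pm$mu) %*% pm$SigmaInv %*% (beta - pm$mu))
  c(shape = prior$a + K / 2, rate = prior$b + qf / 2)
}

#' Draw posterior samples by adaptive Metropolis-within-Gibbs
#'
#' Random-walk Metropolis updates for each effect component (step sizes
#' adapted toward 44% acceptance during burn-in) combined with the exact
#' inverse-gamma Gibbs update for the prior scale `sigma2`.  With an empty
#' design the draws reproduce the prior hierarchy.
#'
#' @inheritParams conditional_loglik
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param fixed_sigma2 Optional positive value freezing `sigma2` (no
#'   hyperprior); mainly for sensitivity checks and validation.
#' @return Object of class `"uchap_chains"`: list of per-chain lists with
#'   elements `beta` (kept draws x K) and `sigma2`; acceptance rates in
#'   attribute `"accept"`.  A warning is raised when any post-adaptation
#'   acceptance rate falls outside `[0.1, 0.6]`.
#' @export
sample_posterior <- function(designs, prior = prior_spec(),
                             config = mcmc_config(), fixed_sigma2 = NULL) {
  D <- .design_D(designs)
  K <- ncol(D)
  if (K < 1L) stop("design has no cores", call. = FALSE)
  pm <- .prior_matrices(prior, K)
  fx <- if (is.null(fixed_sigma2)) -1 else as.numeric(fixed_sigma2)

  chains <- vector("list", config$chains)
  acc <- matrix(NA_real_, config$chains, K)
  for (ch in seq_len(config$chains)) {
    if (!is.null(config$seed))
      set.seed((config$seed + 7919 * (ch - 1)) %% .Machine$integer.max)
    beta0 <- pm$mu + rnorm(K, 0, 0.1)
    res <- .mcmc_chain(D, pm$mu, pm$SigmaInv, prior$a, prior$b, fx,
                       config$burnin, config$iter, config$thin,
                       beta0, 1.0)
    colnames(res$beta) <- colnames(D)
    chains[[ch]] <- list(beta = res$beta, sigma2 = res$sigma2)
    acc[ch, ] <- res$accept
  }
  if (nrow(D) > 0L && (any(acc < 0.1, na.rm = TRUE) || any(acc > 0.6, na.rm = TRUE)))
    warning("MCMC acceptance rate outside [0.1, 0.6] after adaptation",
            call. = FALSE)
  structure(chains, class = "uchap_chains", accept = acc,
            cores = colnames(D), config = config, prior_mean = pm$mu)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between- and within-chain variances per parameter; values near
#' 1 indicate convergence.
#'
#' @param chains An `"uchap_chains"` object or a list of draw matrices of
#'   equal dimensions (>= 2 chains).
#' @return Named numeric vector of PSRF values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  mats <- if (inherits(chains, "uchap_chains"))
    lapply(chains, `[[`, "beta") else chains
  m <- length(mats)
  if (m < 2L) stop("need at least two chains", call. = FALSE)
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1L) stop("chains have unequal lengths", call. = FALSE)
  K <- ncol(mats[[1L]])
  out <- numeric(K)
  for (k in seq_len(K)) {
    draws <- vapply(mats, function(mm) mm[, k], numeric(n))
    means <- colMeans(draws)
    W <- mean(apply(draws, 2L, stats::var))
    B <- n * stats::var(means)
    vhat <- (n - 1) / n * W + B / n
    out[k] <- sqrt(vhat / W)
  }
  names(out) <- colnames(mats[[1L]])
  out
}

# effective sample size from the initial-positive autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- drop(acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf)[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Posterior risk summary over core haplotypes
#'
#' Pools the chains and reports, per core: posterior mean and sd of the
#' effect; the posterior mean relative risk versus the reference core
#' (core 1, the most common haplotype) and the draw fraction with
#' `RR_k > 1` (`prob_rr`); the posterior probability of susceptibility
#' `prob_susceptible`, i.e. the strict-inequality fraction of draws in
#' which the core's effect exceeds the baseline log-odds of disease (the
#' logit of the prevalence, which is the prior mean) -- a core is
#' susceptibility-associated when it raises risk above the population
#' baseline; and the risk call `prob_susceptible > T`.  The reference
#' core is never a decision unit.
#'
#' @param chains An `"uchap_chains"` object.
#' @param reference Index of the reference core (default 1).
#' @param threshold Posterior-probability call threshold `T` (default 0.5).
#' @param baseline Baseline log-odds against which susceptibility is
#'   measured; defaults to the prior mean recorded in `chains`.
#' @return A `data.frame` of class `"uchap_summary"` with per-core rows
#'   and attributes `"psrf"` (when >= 2 chains) and `"ess"`.
#' @export
summarize_posterior <- function(chains, reference = 1L, threshold = 0.5,
                                baseline = NULL) {
  stopifnot(inherits(chains, "uchap_chains"))
  B <- do.call(rbind, lapply(chains, `[[`, "beta"))
  K <- ncol(B)
  cores <- attr(chains, "cores") %||% paste0("core", seq_len(K))
  if (is.null(baseline)) baseline <- attr(chains, "prior_mean")[1L]
  contrast <- B - B[, reference]
  p_susc <- colMeans(B > baseline)
  out <- data.frame(
    core = cores,
    mean = colMeans(B),
    sd = apply(B, 2L, sd),
    rr = colMeans(exp(contrast)),
    prob_rr = colMeans(contrast > 0),
    prob_susceptible = p_susc,
    risk_call = p_susc > threshold,
    stringsAsFactors = FALSE)
  out$rr[reference] <- 1
  out$prob_rr[reference] <- NA_real_
  out$prob_susceptible[reference] <- NA_real_
  out$risk_call[reference] <- NA
  attr(out, "reference") <- reference
  attr(out, "threshold") <- threshold
  attr(out, "baseline") <- baseline
  attr(out, "ess") <- apply(B, 2L, .ess)
  if (length(chains) >= 2L) attr(out, "psrf") <- gelman_rubin(chains)
  class(out) <- c("uchap_summary", "data.frame")
  out
}
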