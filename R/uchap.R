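# The main model-fitting entry point: runs the whole uncertainty-coding
# workflow on a set of families and returns a fitted-model object.

#' Fit the Bayesian haplotype risk model to nuclear families
#'
#' Runs the complete workflow: (1) haplotype frequency estimation by EM
#' (unless a table is supplied), (2) core-haplotype selection and the
#' clustering matrix, (3) enumeration of phase/transmission explanations
#' per family, (4) case and pseudo-control uncertainty coding, (5)
#' projection onto the cores, and (6) MCMC sampling of the Bayesian
#' conditional logistic regression posterior.
#'
#' Families with Mendelian-inconsistent genotypes are dropped with a
#' warning.  Uninformative families (identical case and pseudo-control
#' core rows) are retained; they contribute a constant factor to the
#' likelihood and are counted in the result.
#'
#' @param families List of [hap_family()] objects, or a path to a PED file.
#' @param freq Optional known [hap_freqs()] table; `NULL` estimates it by
#'   [em_haplotype_frequencies()].
#' @param theta,max_rare Core-selection tuning, see [select_cores()].
#' @param support_tol Smallest estimated frequency at which a haplotype
#'   counts as identified in the data; haplotypes below it still receive a
#'   clustering row but do not enter core selection (default 1e-3).
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param threshold Risk-call threshold on the posterior probability of
#'   susceptibility (default 0.5).
#' @return Object of class `"uchap"`: list with the posterior `summary`,
#'   the `chains`, the matched-pair `design`, clustering matrix `C`,
#'   `cores`, the frequency table `freq` (with EM attributes when
#'   estimated), counts of dropped/uninformative families, and the call.
#' @examples
#' \donttest{
#' fams <- sim_dataset(1, seed = 1, n = 60, grr = 2.0)[[1]]
#' fit <- uchap(fams, mcmc = mcmc_config(chains = 1, burnin = 300,
#'                                       iter = 600, thin = 1, seed = 1))
#' summary(fit)
#' }
#' @export
uchap <- function(families, freq = NULL, theta = 0.90, max_rare = 0.05,
                  support_tol = 1e-3, prior = prior_spec(),
                  mcmc = mcmc_config(), threshold = 0.5) {
  cl <- match.call()
  if (is.character(families)) families <- read_ped(families)
  if (length(families) == 0L) stop("no families supplied", call. = FALSE)

  # drop Mendelian-inconsistent families up front
  probe <- lapply(families, function(f) {
    st <- .family_structure(f)
    nrow(st$quads) > 0L
  })
  ok <- unlist(probe)
  if (any(!ok))
    warning("excluding ", sum(!ok), " Mendelian-inconsistent famil",
            if (sum(!ok) == 1L) "y: " else "ies: ",
            paste(vapply(families[!ok], `[[`, "", "id"), collapse = ", "),
            call. = FALSE)
  families <- families[ok]
  if (length(families) == 0L)
    stop("no genotype-consistent families remain", call. = FALSE)

  em_attrs <- NULL
  if (is.null(freq)) {
    freq <- em_haplotype_frequencies(families)
    em_attrs <- attributes(freq)[c("loglik", "iterations", "converged")]
  } else freq <- validate_freq_table(freq)

  # identified haplotypes drive core selection; everything seen keeps a row
  support <- freq[freq$freq >= support_tol, , drop = FALSE]
  if (nrow(support) == 0L) stop("no haplotype passes support_tol", call. = FALSE)
  support <- hap_freqs(support$haplotype, support$freq / sum(support$freq))
  cores <- select_cores(support, theta = theta, max_rare = max_rare)

  design <- uncertainty_design(families, freq, cores = cores)
  C <- design$C
  chains <- sample_posterior(design, prior = prior, config = mcmc)
  summ <- summarize_posterior(chains, reference = 1L, threshold = threshold)
  summ$freq <- attr(cores, "freq")[match(summ$core, cores)]

  structure(list(summary = summ, chains = chains, design = design, C = C,
                 cores = cores, freq = freq, em = em_attrs,
                 n_families = length(families),
                 n_uninformative = sum(!design$informative),
                 n_dropped = sum(!ok),
                 n_support_haplotypes = nrow(support),
                 threshold = threshold, prior = prior, mcmc = mcmc,
                 call = cl),
            class = "uchap")
}

#' @export
print.uchap <- function(x, ...) {
  cat("Bayesian haplotype risk fit (conditional logistic, uncertainty-coded)\n")
  cat(sprintf("  %d families (%d uninformative, %d dropped), %d cores from %d haplotypes\n",
              x$n_families, x$n_uninformative, x$n_dropped,
              length(x$cores), x$n_support_haplotypes))
  cat("  cores:", paste(x$cores, collapse = " "), "\n")
  cat("  risk calls (P >", x$threshold, "):",
      paste(x$summary$core[which(x$summary$risk_call)], collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.uchap <- function(object, ...) {
  s <- object$summary
  cat("Posterior summary (reference core:", s$core[attr(s, "reference")], ")\n\n")
  df <- data.frame(core = s$core,
                   freq = round(s$freq, 4),
                   mean = round(s$mean, 3),
                   sd = round(s$sd, 3),
                   RR = round(s$rr, 3),
                   P_RR = round(s$prob_rr, 3),
                   P_susc = round(s$prob_susceptible, 3),
                   call = s$risk_call)
  print(df, row.names = FALSE)
  if (!is.null(attr(s, "psrf")))
    cat("\nGelman-Rubin PSRF:",
        paste(sprintf("%.3f", attr(s, "psrf")), collapse = " "), "\n")
  cat("Effective sample sizes:",
      paste(sprintf("%.0f", attr(s, "ess")), collapse = " "), "\n")
  invisible(s)
}

#' @export
coef.uchap <- function(object, contrast = TRUE, ...) {
  s <- object$summary
  if (contrast) {
    ref <- attr(s, "reference")
    setNames(s$mean - s$mean[ref], s$core)
  } else setNames(s$mean, s$core)
}

#' @export
confint.uchap <- function(object, parm, level = 0.95, ...) {
  B <- do.call(rbind, lapply(object$chains, `[[`, "beta"))
  ref <- attr(object$summary, "reference")
  contrast <- B - B[, ref]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(contrast, 2L, quantile, probs = probs))
  rownames(ci) <- object$summary$core
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Boxplots of posterior effect contrasts
#'
#' One box per non-reference core of the posterior draws of
#' `beta_k - beta_ref` (log relative risk versus the most common
#' haplotype).
#'
#' @param x A fitted `"uchap"` object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.uchap <- function(x, ...) {
  B <- do.call(rbind, lapply(x$chains, `[[`, "beta"))
  ref <- attr(x$summary, "reference")
  contrast <- B[, -ref, drop = FALSE] - B[, ref]
  boxplot(as.data.frame(contrast),
          ylab = "log relative risk vs reference core",
          las = 2, ...)
  abline(h = 0, lty = 2)
  invisible(x)
}
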