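# Replicate-level performance evaluation: risk/non-risk classification of
# core haplotypes, sensitivity / specificity / overall accuracy, ROC AUC,
# and core-recovery bookkeeping across simulation replicates.

#' Risk calls from posterior susceptibility probabilities
#'
#' A core is called a risk factor when its posterior probability of
#' positive relative risk strictly exceeds the threshold `T`; the
#' reference core is never a decision unit.
#'
#' @param p Numeric vector of per-core posterior probabilities (the
#'   reference core's entry may be `NA`).
#' @param threshold Call threshold in `(0, 1)`.
#' @return Logical vector of calls (`NA` where `p` is `NA`).
#' @export
classify_risk <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  p > threshold
}

#' Run the simulation-evaluation experiment grid
#'
#' For each (mode, genotype relative risk) setting, repeatedly simulates
#' ascertained families, runs the full uncertainty-coding fit, and records
#' the posterior susceptibility probability of every non-reference core
#' together with the truth labels needed for classification metrics.  The
#' "risk core" of a replicate is the core onto which the generative risk
#' haplotype clusters with the highest probability.
#'
#' @param modes Character vector of inheritance modes.
#' @param grrs Numeric vector of genotype relative risks.
#' @param reps Replicates per setting.
#' @param n_families Families per replicate (default 200).
#' @param table Generating haplotype pool.
#' @param risk_hap Generative risk haplotype.
#' @param prevalence Disease prevalence.
#' @param mcmc Per-replicate [mcmc_config()]; the default uses a single
#'   shortened chain suitable for replicate grids.
#' @param theta,support_tol Passed to [uchap()].
#' @param seed Master seed; each replicate derives its own substream.
#' @param progress Print one line per completed setting.
#' @return Object of class `"uchap_experiment"`: `calls` (one row per
#'   decision unit: setting, replicate, core, posterior probability,
#'   truth flag) and `reps` (one row per replicate: support haplotype
#'   count, recovery flags for the true cores, failure flag).
#' @export
run_experiment <- function(modes = "additive", grrs = 2.0, reps = 100L,
                           n_families = 200L, table = default_sim_freqs(),
                           risk_hap = "11111211", prevalence = 0.01,
                           mcmc = mcmc_config(chains = 1L, burnin = 1000L,
                                              iter = 2000L, thin = 1L),
                           theta = 0.90, support_tol = 1e-3,
                           seed = 1L, progress = FALSE) {
  true_cores <- select_cores(table, theta = theta)
  calls <- list(); repinfo <- list()
  si <- 0L
  for (mode in modes) for (grr in grrs) {
    si <- si + 1L
    for (r in seq_len(reps)) {
      set.seed((seed + 100003 * si + r) %% .Machine$integer.max)
      fams <- sim_families(n = n_families, table = table,
                           risk_hap = risk_hap, mode = mode, grr = grr,
                           prevalence = prevalence)
      fit <- tryCatch(
        uchap(fams, theta = theta, support_tol = support_tol,
              prior = prior_spec(prevalence = prevalence), mcmc = mcmc),
        error = function(e) e)
      if (inherits(fit, "error")) {
        repinfo[[length(repinfo) + 1L]] <- data.frame(
          mode = mode, grr = grr, rep = r, failed = TRUE,
          n_haplotypes = NA_integer_, risk_core_present = NA,
          t(setNames(rep(NA, length(true_cores)),
                     paste0("recovered_", seq_along(true_cores)))),
          stringsAsFactors = FALSE)
        next
      }
      s <- fit$summary
      risk_core <- .map_risk_core(fit, risk_hap)
      ref <- attr(s, "reference")
      keep <- setdiff(seq_len(nrow(s)), ref)
      calls[[length(calls) + 1L]] <- data.frame(
        mode = mode, grr = grr, rep = r,
        core = s$core[keep],
        p = s$prob_susceptible[keep],
        is_risk = s$core[keep] == risk_core & !is.na(risk_core),
        stringsAsFactors = FALSE)
      rec <- true_cores %in% fit$cores
      repinfo[[length(repinfo) + 1L]] <- data.frame(
        mode = mode, grr = grr, rep = r, failed = FALSE,
        n_haplotypes = fit$n_support_haplotypes,
        risk_core_present = !is.na(risk_core) && risk_core %in% s$core[keep],
        t(setNames(as.numeric(rec),
                   paste0("recovered_", seq_along(true_cores)))),
        stringsAsFactors = FALSE)
    }
    if (progress)
      message(sprintf("setting %s / grr %.1f done (%d reps)", mode, grr, reps))
  }
  structure(list(calls = do.call(rbind, calls),
                 reps = do.call(rbind, repinfo),
                 true_cores = true_cores, risk_hap = risk_hap),
            class = "uchap_experiment")
}

# which core absorbs the generative risk haplotype (highest clustering
# probability); NA when it has no clustering row
.map_risk_core <- function(fit, risk_hap) {
  if (!risk_hap %in% rownames(fit$C)) return(NA_character_)
  row <- fit$C[risk_hap, ]
  core <- colnames(fit$C)[which.max(row)]
  if (core == fit$cores[1L]) NA_character_ else core
}

.exp_calls <- function(experiment, mode = NULL, grr = NULL) {
  d <- experiment$calls
  if (!is.null(mode)) d <- d[d$mode == mode, , drop = FALSE]
  if (!is.null(grr)) d <- d[d$grr == grr, , drop = FALSE]
  d
}

#' Classification metrics pooled over replicates
#'
#' Sensitivity is the fraction of replicates whose true risk core is
#' called at threshold `T` (a replicate in which the risk core is not even
#' recovered counts as a miss); specificity is the fraction of non-risk
#' core decisions not called, pooled over cores and replicates; overall
#' accuracy pools all decisions.
#'
#' @param experiment An `"uchap_experiment"`.
#' @param threshold Call threshold (default 0.5).
#' @param mode,grr Optional filters selecting one setting.
#' @return `data.frame` with one row per setting: sensitivity,
#'   specificity, accuracy, and decision counts.
#' @export
aggregate_metrics <- function(experiment, threshold = 0.5,
                              mode = NULL, grr = NULL) {
  d <- .exp_calls(experiment, mode, grr)
  out <- list()
  for (m in unique(d$mode)) for (g in unique(d$grr[d$mode == m])) {
    dd <- d[d$mode == m & d$grr == g, , drop = FALSE]
    call <- classify_risk(dd$p, threshold)
    nrep <- length(unique(dd$rep))
    tp <- sum(call & dd$is_risk, na.rm = TRUE)
    sens <- tp / nrep                       # unrecovered risk cores = misses
    tn <- sum(!call & !dd$is_risk, na.rm = TRUE)
    n_neg <- sum(!dd$is_risk)
    spec <- tn / n_neg
    n_pos <- nrep
    acc <- (tp + tn) / (n_pos + n_neg)
    out[[length(out) + 1L]] <- data.frame(
      mode = m, grr = g, sensitivity = sens, specificity = spec,
      accuracy = acc, n_replicates = nrep,
      n_risk = n_pos, n_nonrisk = n_neg, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pooled ROC AUC of risk-core detection
#'
#' One score per non-reference core per replicate (its posterior
#' susceptibility probability), labelled by whether it is the replicate's
#' true risk core.  The AUC equals the Mann-Whitney probability that a
#' risk core outscores a non-risk core (ties counted half), which is
#' identical to the trapezoidal area under the ROC traced by sweeping the
#' call threshold.  A replicate whose risk core went unrecovered
#' contributes a positive with score 0 (it can never be called).
#'
#' @inheritParams aggregate_metrics
#' @param method `"rank"` (exact Mann-Whitney, default) or `"trapezoid"`
#'   (explicit threshold sweep).
#' @return Numeric AUC per setting (named vector when several settings).
#' @export
roc_auc <- function(experiment, mode = NULL, grr = NULL,
                    method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  d <- .exp_calls(experiment, mode, grr)
  settings <- unique(d[, c("mode", "grr")])
  out <- numeric(nrow(settings))
  for (i in seq_len(nrow(settings))) {
    dd <- d[d$mode == settings$mode[i] & d$grr == settings$grr[i], , drop = FALSE]
    # replicates without a recovered risk core: undetectable positive
    missed <- tapply(dd$is_risk, dd$rep, sum) == 0L
    scores <- c(dd$p, rep(0, sum(missed)))
    labels <- c(dd$is_risk, rep(TRUE, sum(missed)))
    out[i] <- .auc(scores, labels, method)
  }
  names(out) <- paste(settings$mode, settings$grr)
  if (length(out) == 1L) unname(out) else out
}

.auc <- function(scores, labels, method = "rank") {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  if (method == "rank") {
    r <- rank(scores)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    cuts <- sort(unique(scores))
    sens <- vapply(cuts, function(t) mean(scores[labels] >= t), 1)
    fpr <- vapply(cuts, function(t) mean(scores[!labels] >= t), 1)
    sens <- c(1, sens, 0); fpr <- c(1, fpr, 0)
    o <- order(fpr, sens)
    sum(diff(fpr[o]) * (head(sens[o], -1L) + tail(sens[o], -1L)) / 2)
  }
}

#' Core recovery and haplotype-count excess across replicates
#'
#' Fraction of replicates in which each true core haplotype survives the
#' core-selection step, and the fraction identifying more than
#' `max_haplotypes` distinct haplotypes from the genotype data.
#'
#' @inheritParams aggregate_metrics
#' @param max_haplotypes Haplotype count above which a replicate counts as
#'   excess (default: the size of the generating pool, 7).
#' @return List with `recovery` (named fraction per true core) and
#'   `excess_rate` (fraction of replicates with more than
#'   `max_haplotypes` identified haplotypes).
#' @export
core_recovery <- function(experiment, mode = NULL, grr = NULL,
                          max_haplotypes = 7L) {
  d <- experiment$reps
  if (!is.null(mode)) d <- d[d$mode == mode, , drop = FALSE]
  if (!is.null(grr)) d <- d[d$grr == grr, , drop = FALSE]
  d <- d[!d$failed, , drop = FALSE]
  rec_cols <- grep("^recovered_", colnames(d), value = TRUE)
  recovery <- colMeans(d[, rec_cols, drop = FALSE])
  names(recovery) <- experiment$true_cores
  list(recovery = recovery,
       excess_rate = mean(d$n_haplotypes > max_haplotypes))
}

#' @importFrom utils head tail
NULL
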