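# Family-data simulator: draws nuclear families from a haplotype pool
# under a genotype-relative-risk penetrance model, ascertained on one
# affected child, and emits unphased genotypes.

#' Penetrances implied by a genotype relative risk
#'
#' Returns the disease probabilities `(f0, f1, f2)` for carrying 0, 1 or 2
#' copies of the risk haplotype, using the conventional mode-specific
#' ladder: additive `f1 = g f0`, `f2 = (2g - 1) f0`; dominant
#' `f1 = f2 = g f0`; recessive `f1 = f0`, `f2 = g f0`.  The baseline `f0`
#' is solved so that the population prevalence matches under
#' Hardy-Weinberg genotype weights at risk-haplotype frequency `q`:
#' `f0 (1-q)^2 + 2 f1 q (1-q) + f2 q^2 = prevalence`.
#'
#' @param mode One of `"additive"`, `"dominant"`, `"recessive"`.
#' @param grr Genotype relative risk `g >= 1` (e.g. 1.2, 1.5, 2.0).
#' @param prevalence Population disease prevalence (default 0.01).
#' @param q Risk-haplotype population frequency.
#' @return Numeric vector `c(f0, f1, f2)` of penetrances in `[0, 1]`.
#' @export
penetrances <- function(mode = c("additive", "dominant", "recessive"),
                        grr, prevalence = 0.01, q) {
  mode <- match.arg(mode)
  if (grr < 1) stop("genotype relative risk must be >= 1", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  r <- switch(mode,
              additive  = c(1, grr, 2 * grr - 1),
              dominant  = c(1, grr, grr),
              recessive = c(1, 1, grr))
  w <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f0 <- prevalence / sum(w * r)
  f <- f0 * r
  if (any(f > 1)) stop("penetrance exceeds 1 under this configuration",
                       call. = FALSE)
  f
}

.risk_copies <- function(i, j, risk_idx) (i == risk_idx) + (j == risk_idx)

#' Simulate ascertained nuclear families
#'
#' The affected index child's haplotype pair is drawn first, with
#' probability proportional to its Hardy-Weinberg pair probability times
#' the penetrance of its risk-haplotype copy number (i.e. conditional on
#' the child being affected).  Two further haplotypes drawn from the pool
#' complete the parents' four haplotypes.  Each additional sibling
#' receives one haplotype from each parent by independent Mendelian
#' transmission and is affected with the penetrance of its own genotype
#' (siblings are not ascertained).  Family size is 3 plus a Poisson(`sib_mean`)
#' number of extra members, so every family has parents plus at least the
#' index child.  Genotypes are emitted unphased.
#'
#' @param n Number of families (default 200).
#' @param table Haplotype pool, a [hap_freqs()] table
#'   (default [default_sim_freqs()]).
#' @param risk_hap Risk haplotype string (must be in `table`).
#' @param mode,grr,prevalence Passed to [penetrances()].
#' @param sib_mean Mean of the Poisson sibling count (default 2).
#' @param missing_rate Optional per-locus probability of masking a
#'   genotype as missing (default 0; the index case is never masked).
#' @return List of [hap_family()] objects.  Attribute `"truth"` records
#'   the generating configuration and each family's phased haplotypes.
#' @export
sim_families <- function(n = 200L, table = default_sim_freqs(),
                         risk_hap = "11111211",
                         mode = "additive", grr = 1.0, prevalence = 0.01,
                         sib_mean = 2, missing_rate = 0) {
  table <- validate_freq_table(table)
  H <- nrow(table)
  risk_idx <- match(risk_hap, table$haplotype)
  if (is.na(risk_idx)) stop("risk haplotype not in the pool", call. = FALSE)
  f <- penetrances(mode, grr, prevalence, q = table$freq[risk_idx])

  # affected-child pair distribution over ordered pairs (i from father,
  # j from mother): p_i p_j f_{copies(i,j)}, normalized
  p <- table$freq
  grid_i <- rep(seq_len(H), times = H)
  grid_j <- rep(seq_len(H), each = H)
  cellp <- p[grid_i] * p[grid_j] * f[.risk_copies(grid_i, grid_j, risk_idx) + 1L]
  cellp <- cellp / sum(cellp)

  hapmat <- .hap_to_mat(table$haplotype)
  geno_of <- function(i, j) {
    a <- hapmat[i, ]; b <- hapmat[j, ]
    cbind(pmin(a, b), pmax(a, b))
  }
  mask <- function(g) {
    if (missing_rate > 0) {
      hit <- runif(nrow(g)) < missing_rate
      g[hit, ] <- NA_integer_
    }
    g
  }

  fams <- vector("list", n)
  truth <- vector("list", n)
  cells <- sample.int(H * H, n, replace = TRUE, prob = cellp)
  for (k in seq_len(n)) {
    tF <- grid_i[cells[k]]; tM <- grid_j[cells[k]]
    uF <- sample.int(H, 1L, prob = p)
    uM <- sample.int(H, 1L, prob = p)
    nsib <- rpois(1L, sib_mean)
    kid_f <- c(tF, ifelse(runif(nsib) < 0.5, tF, uF))
    kid_m <- c(tM, ifelse(runif(nsib) < 0.5, tM, uM))
    copies <- .risk_copies(kid_f, kid_m, risk_idx)
    aff <- c(TRUE, runif(nsib) < f[copies[-1L] + 1L])
    children <- lapply(seq_along(kid_f), function(s) {
      g <- geno_of(kid_f[s], kid_m[s])
      if (s == 1L) g else mask(g)
    })
    fams[[k]] <- hap_family(
      id = sprintf("F%04d", k),
      father = mask(geno_of(tF, uF)),
      mother = mask(geno_of(tM, uM)),
      children = children, affected = aff, case = 1L)
    truth[[k]] <- list(tF = tF, tM = tM, uF = uF, uM = uM,
                       kid_f = kid_f, kid_m = kid_m)
  }
  attr(fams, "truth") <- list(table = table, risk_hap = risk_hap,
                              mode = mode, grr = grr,
                              prevalence = prevalence, phases = truth)
  fams
}

#' Simulate replicate datasets
#'
#' Convenience wrapper drawing `reps` independent family sets under one
#' configuration; reproducible given `seed`.
#'
#' @param reps Number of replicates.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param ... Passed to [sim_families()].
#' @return List of family lists, each carrying its `"truth"` attribute.
#' @export
sim_dataset <- function(reps, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(r) sim_families(...))
}
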