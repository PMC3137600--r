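# Haplotype explanations: all (transmitted, non-transmitted) parental
# haplotype quadruples compatible with a family's unphased genotypes,
# weighted by population haplotype frequencies, and the EM estimator of
# those frequencies from pedigree data.

# Pseudo-frequency for haplotypes that are genotype-consistent but absent
# from the supplied table; prevents zero weights from annihilating valid
# phase configurations.
.EPS_FREQ <- 1e-8

# ---- phase expansion of one genotype -------------------------------------

# All unordered haplotype pairs (integer-coded) compatible with an L x 2
# genotype matrix.  Returns a 2-column matrix (h1 <= h2), or NULL when the
# direct expansion would exceed max_expand.
.expand_pairs <- function(gm, L, max_expand = 2^14) {
  A <- 0; B <- 0
  for (l in seq_len(L)) {
    bit <- 2^(l - 1)
    a <- gm[l, ]
    if (anyNA(a)) { da <- c(0, 0, 1, 1); db <- c(0, 1, 0, 1) }
    else if (a[1L] == a[2L]) { da <- a[1L] - 1; db <- da }
    else { da <- c(0, 1); db <- c(1, 0) }
    k <- length(da)
    if (length(A) * k > max_expand) return(NULL)
    n0 <- length(A)
    A <- rep(A, each = k) + rep(da * bit, times = n0)
    B <- rep(B, each = k) + rep(db * bit, times = n0)
  }
  lo <- pmin(A, B); hi <- pmax(A, B)
  keep <- !duplicated(lo * 2^L + hi)
  cbind(lo[keep], hi[keep])
}

# Pairs drawn from a candidate haplotype universe (integer codes) that are
# compatible with the observed loci of gm.  Fallback for genotypes whose
# direct expansion is too large (e.g. a fully untyped parent).
.universe_pairs <- function(gm, L, universe) {
  universe <- sort(unique(universe))
  M <- length(universe)
  if (M == 0L) return(cbind(numeric(0), numeric(0)))
  bits <- .int_to_bits(universe, L)
  obs <- which(!is.na(gm[, 1L]))
  i <- rep(seq_len(M), times = M); j <- rep(seq_len(M), each = M)
  keep <- i <= j
  i <- i[keep]; j <- j[keep]
  if (length(obs)) {
    target <- gm[obs, 1L] + gm[obs, 2L] - 2L
    S <- bits[i, obs, drop = FALSE] + bits[j, obs, drop = FALSE]
    ok <- rowSums(S != rep(target, each = length(i))) == 0L
    i <- i[ok]; j <- j[ok]
  }
  cbind(universe[i], universe[j])
}

.pair_set <- function(gm, L, universe, max_expand = 2^14) {
  p <- .expand_pairs(gm, L, max_expand)
  if (is.null(p)) p <- .universe_pairs(gm, L, universe)
  p
}

# ---- family explanation structure ----------------------------------------

# Enumerates, frequency-free, every quadruple (tF, tM, uF, uM) of
# integer-coded haplotypes compatible with all typed family members.
# Siblings constrain the parental phase but contribute no weight.
# extra_universe: haplotype codes (e.g. a frequency table's) added to the
# candidate set used when a parent's direct expansion is infeasible.
.family_structure <- function(fam, extra_universe = numeric(0),
                              max_expand = 2^14, max_combos = 2e6) {
  L <- fam$L
  kid_pairs <- lapply(fam$children, function(g) .expand_pairs(g, L, max_expand))
  universe <- unique(c(extra_universe, unlist(kid_pairs)))
  PF <- .pair_set(fam$father, L, universe, max_expand)
  PM <- .pair_set(fam$mother, L, universe, max_expand)
  nF <- nrow(PF); nM <- nrow(PM)
  if (nF == 0L || nM == 0L || nF * nM > max_combos)
    return(list(quads = matrix(numeric(0), 0L, 4L), L = L,
                overflow = nF * nM > max_combos))

  reg <- sort(unique(c(PF, PM)))
  bits <- .int_to_bits(reg, L)
  f1 <- match(rep(PF[, 1L], times = nM), reg)
  f2 <- match(rep(PF[, 2L], times = nM), reg)
  m1 <- match(rep(PM[, 1L], each = nF), reg)
  m2 <- match(rep(PM[, 2L], each = nF), reg)

  compat <- function(x, y, gm) {
    obs <- which(!is.na(gm[, 1L]))
    if (length(obs) == 0L) return(rep(TRUE, length(x)))
    target <- gm[obs, 1L] + gm[obs, 2L] - 2L
    S <- bits[x, obs, drop = FALSE] + bits[y, obs, drop = FALSE]
    rowSums(S != rep(target, each = length(x))) == 0L
  }

  # sibling filter: some transmission must fit each non-case child
  sibs <- setdiff(seq_along(fam$children), fam$case)
  for (s in sibs) {
    g <- fam$children[[s]]
    ok <- compat(f1, m1, g) | compat(f1, m2, g) |
          compat(f2, m1, g) | compat(f2, m2, g)
    f1 <- f1[ok]; f2 <- f2[ok]; m1 <- m1[ok]; m2 <- m2[ok]
    if (length(f1) == 0L) break
  }

  quads <- matrix(numeric(0), 0L, 4L)
  if (length(f1)) {
    g <- fam$children[[fam$case]]
    add <- function(tf, tm, uf, um) {
      ok <- compat(tf, tm, g)
      cbind(reg[tf[ok]], reg[tm[ok]], reg[uf[ok]], reg[um[ok]])
    }
    quads <- rbind(add(f1, m1, f2, m2), add(f1, m2, f2, m1),
                   add(f2, m1, f1, m2), add(f2, m2, f1, m1))
    if (nrow(quads) > 1L) {
      key <- paste(quads[, 1L], quads[, 2L], quads[, 3L], quads[, 4L])
      quads <- quads[!duplicated(key), , drop = FALSE]
    }
  }
  list(quads = quads, L = L, overflow = FALSE)
}

# frequency lookup (table + pseudo-frequency for novel haplotypes)
.freq_lookup <- function(haps, table, eps = .EPS_FREQ) {
  f <- table$freq[match(haps, table$haplotype)]
  f[is.na(f)] <- eps
  f
}

.quads_to_df <- function(quads, L, table, eps = .EPS_FREQ) {
  hap <- function(col) .int_to_hap(quads[, col], L)
  df <- data.frame(tF = hap(1L), tM = hap(2L), uF = hap(3L), uM = hap(4L),
                   stringsAsFactors = FALSE)
  w <- .freq_lookup(df$tF, table, eps) * .freq_lookup(df$uF, table, eps) *
       .freq_lookup(df$tM, table, eps) * .freq_lookup(df$uM, table, eps)
  df$w <- w / sum(w)
  df[order(df$tF, df$tM, df$uF, df$uM), , drop = FALSE]
}

#' Enumerate haplotype explanations for a nuclear family
#'
#' Lists every quadruple (paternal transmitted `tF`, maternal transmitted
#' `tM`, paternal non-transmitted `uF`, maternal non-transmitted `uM`)
#' compatible with the genotypes of all typed family members.  Siblings of
#' the index case constrain the parental phase but do not otherwise enter.
#' The weight of an explanation is proportional to the product of the four
#' founder haplotype frequencies (founder haplotypes are assumed to be an
#' independent sample from the population), normalized to sum to one.
#'
#' Haplotypes compatible with the genotypes but missing from `table`
#' receive a pseudo-frequency `eps` so that valid phase configurations are
#' never annihilated.
#'
#' @param family A [hap_family()].
#' @param table A [hap_freqs()] frequency table.
#' @param eps Pseudo-frequency for table-absent haplotypes.
#' @return A `data.frame` with columns `tF`, `tM`, `uF`, `uM`, `w`
#'   (weights summing to 1), rows in lexicographic order, with the family
#'   id in attribute `"family"`.
#' @examples
#' fam <- hap_family("ex", father = c("12", "12"), mother = c("00", "12"),
#'                   children = list(c("11", "11")), affected = 1)
#' tab <- hap_freqs(c("11", "12", "21", "22"), c(0.4, 0.3, 0.2, 0.1))
#' enumerate_explanations(fam, tab)
#' @export
enumerate_explanations <- function(family, table, eps = .EPS_FREQ) {
  table <- validate_freq_table(table)
  st <- .family_structure(family, extra_universe = .hap_to_int(table$haplotype))
  if (isTRUE(st$overflow))
    stop("family ", family$id, ": phase configuration space too large",
         call. = FALSE)
  if (nrow(st$quads) == 0L)
    stop("family ", family$id,
         ": Mendelian inconsistency, no haplotype explanation exists",
         call. = FALSE)
  out <- .quads_to_df(st$quads, st$L, table, eps)
  rownames(out) <- NULL
  attr(out, "family") <- family$id
  out
}

#' Brute-force oracle for explanation enumeration
#'
#' Independent reference implementation: expands every missing allele pair
#' and every phase of every family member via `expand.grid`, filters the
#' raw configurations on Mendelian consistency, and aggregates them to the
#' explanation quadruples of the index case.  Intended as a test oracle on
#' small panels; refuses more than `max_config` raw configurations.
#'
#' @inheritParams enumerate_explanations
#' @param max_config Guard on the raw configuration count.
#' @return Same shape as [enumerate_explanations()].
#' @export
brute_force_explanations <- function(family, table, eps = .EPS_FREQ,
                                     max_config = 1e6) {
  table <- validate_freq_table(table)
  L <- family$L

  # ordered haplotype pairs (rows: h1 alleles then h2 alleles) per member
  ordered_pairs <- function(gm) {
    opts <- vector("list", L)
    for (l in seq_len(L)) {
      a <- gm[l, ]
      opts[[l]] <- if (anyNA(a)) list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
      else if (a[1L] == a[2L]) list(c(a[1L], a[1L]))
      else list(c(1, 2), c(2, 1))
    }
    grid <- do.call(expand.grid, lapply(opts, seq_along))
    h1 <- matrix(0L, nrow(grid), L); h2 <- h1
    for (l in seq_len(L)) {
      ch <- do.call(rbind, opts[[l]])[grid[[l]], , drop = FALSE]
      h1[, l] <- ch[, 1L]; h2[, l] <- ch[, 2L]
    }
    cbind(apply(h1, 1L, paste, collapse = ""),
          apply(h2, 1L, paste, collapse = ""))
  }

  fa <- ordered_pairs(family$father)
  mo <- ordered_pairs(family$mother)
  kids <- lapply(family$children, ordered_pairs)
  raw <- nrow(fa) * nrow(mo) * prod(vapply(kids, nrow, 1))
  if (raw > max_config)
    stop("refusing brute-force expansion of ", raw, " raw configurations",
         call. = FALSE)

  quads <- character(0)
  for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(mo))) {
    F1 <- fa[i, 1L]; F2 <- fa[i, 2L]; M1 <- mo[j, 1L]; M2 <- mo[j, 2L]
    ok <- TRUE
    for (s in setdiff(seq_along(kids), family$case)) {
      sib_ok <- FALSE
      kp <- kids[[s]]
      for (r in seq_len(nrow(kp))) {
        if ((kp[r, 1L] %in% c(F1, F2)) && (kp[r, 2L] %in% c(M1, M2))) {
          sib_ok <- TRUE; break
        }
      }
      if (!sib_ok) { ok <- FALSE; break }
    }
    if (!ok) next
    kp <- kids[[family$case]]
    for (r in seq_len(nrow(kp))) {
      if (kp[r, 1L] == F1 && kp[r, 2L] == M1)
        quads <- c(quads, paste(F1, M1, F2, M2))
    }
  }
  quads <- unique(quads)
  if (length(quads) == 0L)
    stop("family ", family$id,
         ": Mendelian inconsistency, no haplotype explanation exists",
         call. = FALSE)
  parts <- do.call(rbind, strsplit(quads, " ", fixed = TRUE))
  df <- data.frame(tF = parts[, 1L], tM = parts[, 2L],
                   uF = parts[, 3L], uM = parts[, 4L],
                   stringsAsFactors = FALSE)
  w <- .freq_lookup(df$tF, table, eps) * .freq_lookup(df$uF, table, eps) *
       .freq_lookup(df$tM, table, eps) * .freq_lookup(df$uM, table, eps)
  df$w <- w / sum(w)
  df <- df[order(df$tF, df$tM, df$uF, df$uM), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "family") <- family$id
  df
}

# ---- EM haplotype frequency estimation -----------------------------------

#' EM estimate of haplotype frequencies from unphased family data
#'
#' Maximum-likelihood haplotype frequencies under independent sampling of
#' founder haplotypes.  The E-step distributes each family's probability
#' over its explanation quadruples proportionally to the product of the
#' four current founder-haplotype frequencies; the M-step normalizes the
#' expected founder haplotype counts (each parent contributes two
#' haplotypes; children act only through phase consistency).  Starts from
#' the uniform distribution over all genotype-consistent haplotypes
#' observed across families and iterates until `max |dp| < tol`.
#'
#' @param families List of [hap_family()] objects on a shared panel.
#' @param tol Convergence tolerance on the frequency update (default 1e-6).
#' @param max_iter Iteration cap; non-convergence raises a warning and
#'   returns the current estimate flagged via attribute `"converged"`.
#' @return A [hap_freqs()] table restricted to haplotypes with positive
#'   estimated frequency, with attributes `"loglik"` (trace of the
#'   observed-data log-likelihood, nondecreasing), `"iterations"` and
#'   `"converged"`.
#' @export
em_haplotype_frequencies <- function(families, tol = 1e-6, max_iter = 500L) {
  if (length(families) == 0L) stop("no families supplied", call. = FALSE)
  L <- families[[1L]]$L
  typed <- vapply(families, function(f) {
    any(!is.na(f$father)) || any(!is.na(f$mother)) ||
      any(vapply(f$children, function(g) any(!is.na(g)), TRUE))
  }, TRUE)
  if (!any(typed)) stop("all genotypes are missing", call. = FALSE)

  sts <- lapply(families, .family_structure)
  bad <- vapply(sts, function(s) nrow(s$quads) == 0L, TRUE)
  if (any(bad))
    stop("Mendelian inconsistency, no haplotype explanation exists for ",
         "family ", families[[which(bad)[1L]]]$id, call. = FALSE)

  quads <- do.call(rbind, lapply(sts, `[[`, "quads"))
  famidx <- rep(seq_along(sts), vapply(sts, function(s) nrow(s$quads), 1L))
  reg <- sort(unique(as.vector(quads)))
  Q <- matrix(match(quads, reg), ncol = 4L)
  R <- length(reg); nfam <- length(families)

  p <- rep(1 / R, R)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wraw <- p[Q[, 1L]] * p[Q[, 2L]] * p[Q[, 3L]] * p[Q[, 4L]]
    denom <- as.vector(rowsum(wraw, famidx))
    ll_trace <- c(ll_trace, sum(log(denom)))
    w <- wraw / denom[famidx]
    counts <- numeric(R)
    tt <- rowsum(rep(w, 4L), as.vector(Q))
    counts[as.integer(rownames(tt))] <- tt
    pnew <- counts / (4 * nfam)
    delta <- max(abs(pnew - p))
    p <- pnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)

  keep <- p > 0
  out <- hap_freqs(.int_to_hap(reg[keep], L), p[keep] / sum(p[keep]))
  attr(out, "loglik") <- ll_trace
  attr(out, "iterations") <- length(ll_trace)
  attr(out, "converged") <- converged
  out
}

#' Write an explanation set to a tab-separated audit file
#'
#' @param expl Result of [enumerate_explanations()].
#' @param path Output TSV (family, tF, tM, uF, uM, weight).
#' @export
write_explanations <- function(expl, path) {
  df <- cbind(family = attr(expl, "family"), expl)
  names(df)[names(df) == "w"] <- "weight"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
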