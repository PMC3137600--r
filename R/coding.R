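# Uncertainty coding: expected haplotype counts for the affected child
# (over transmitted haplotypes) and its matched pseudo-control (over
# non-transmitted haplotypes), and assembly of the matched-pair design on
# the core haplotypes.

.coding_row <- function(expl, cols) {
  haps <- unique(c(expl$tF, expl$tM, expl$uF, expl$uM))
  x <- setNames(numeric(length(haps)), haps)
  for (cl in cols) {
    s <- rowsum(expl$w, expl[[cl]])
    x[rownames(s)] <- x[rownames(s)] + s
  }
  x
}

#' Expected haplotype counts of the affected child
#'
#' Under additive haplotype effects, the case's weight on haplotype `h` is
#' the explanation-averaged count of transmitted copies of `h`:
#' `sum_m w_m (I(tF_m = h) + I(tM_m = h))`.  Weights always total 2.
#'
#' @param expl An explanation set from [enumerate_explanations()].
#' @return Named numeric vector over the haplotypes occurring in `expl`.
#' @export
case_coding <- function(expl) {
  if (is.null(expl) || nrow(expl) == 0L)
    stop("empty explanation set", call. = FALSE)
  .coding_row(expl, c("tF", "tM"))
}

#' Expected haplotype counts of the matched pseudo-control
#'
#' As [case_coding()] but over the non-transmitted haplotypes `uF`, `uM`:
#' the artificial sibling carrying what the parents did not transmit.
#'
#' @inheritParams case_coding
#' @export
pseudocontrol_coding <- function(expl) {
  if (is.null(expl) || nrow(expl) == 0L)
    stop("empty explanation set", call. = FALSE)
  .coding_row(expl, c("uF", "uM"))
}

#' Assemble the matched-pair regression design over core haplotypes
#'
#' For each family, projects the case and pseudo-control haplotype weight
#' rows through the clustering matrix (`z = x C`) and forms the within-pair
#' difference `d = z_case - z_ctrl` that drives the conditional logistic
#' likelihood.  Families whose explanations use a haplotype missing from
#' `C`'s rows are an error (the pipeline builds `C` over every haplotype
#' seen in any explanation).
#'
#' @param expl_sets List of explanation sets (one per family), each the
#'   result of [enumerate_explanations()].
#' @param C Clustering matrix with haplotype row names.
#' @return Object of class `"hap_design"`: list with matrices `Z1` (cases),
#'   `Z0` (pseudo-controls), `D = Z1 - Z0` (families x cores), the family
#'   ids, and the logical vector `informative` (`FALSE` where `d = 0`;
#'   those pairs contribute a constant 1/2 to the likelihood and are
#'   retained).
#' @export
assemble_design <- function(expl_sets, C) {
  n <- length(expl_sets)
  K <- ncol(C)
  Z1 <- matrix(0, n, K, dimnames = list(NULL, colnames(C)))
  Z0 <- Z1
  ids <- character(n)
  for (i in seq_len(n)) {
    e <- expl_sets[[i]]
    ids[i] <- attr(e, "family") %||% as.character(i)
    x1 <- case_coding(e)
    x0 <- pseudocontrol_coding(e)
    miss <- setdiff(names(x1)[x1 > 0] , rownames(C))
    miss <- c(miss, setdiff(names(x0)[x0 > 0], rownames(C)))
    if (length(miss))
      stop("family ", ids[i], ": haplotype ", miss[1L],
           " has no clustering row", call. = FALSE)
    full <- function(x) {
      v <- setNames(numeric(nrow(C)), rownames(C))
      v[names(x)[names(x) %in% rownames(C)]] <-
        x[names(x) %in% rownames(C)]
      v
    }
    Z1[i, ] <- reduce_design(full(x1), C)
    Z0[i, ] <- reduce_design(full(x0), C)
  }
  D <- Z1 - Z0
  structure(list(Z1 = Z1, Z0 = Z0, D = D, family = ids,
                 informative = rowSums(abs(D)) > 1e-12,
                 cores = colnames(C)),
            class = "hap_design")
}

#' Build the complete uncertainty-coded design for a family set
#'
#' Convenience wrapper around the coding steps: enumerates explanations
#' for every family under `table`, gives a clustering row to each
#' haplotype any explanation mentions (haplotypes outside `table` count as
#' vanishingly rare), and assembles the matched-pair design over `cores`.
#'
#' @param families List of [hap_family()] objects.
#' @param table A [hap_freqs()] table used for explanation weights.
#' @param cores Core haplotypes; defaults to [select_cores()] of `table`.
#' @return A `"hap_design"` with the clustering matrix attached as
#'   element `C`.
#' @export
uncertainty_design <- function(families, table, cores = NULL) {
  table <- validate_freq_table(table)
  if (is.null(cores)) cores <- select_cores(table)
  expl <- lapply(families, enumerate_explanations, table = table)
  seen <- unique(c(table$haplotype,
                   unlist(lapply(expl, function(e) c(e$tF, e$tM, e$uF, e$uM)))))
  extra <- setdiff(seen, table$haplotype)
  rowfreq <- c(table$freq, rep(.EPS_FREQ, length(extra)))
  rowtab <- hap_freqs(c(table$haplotype, extra), rowfreq / sum(rowfreq))
  C <- build_clustering_matrix(rowtab, cores)
  des <- assemble_design(expl, C)
  des$C <- C
  des
}

#' @export
print.hap_design <- function(x, ...) {
  cat("Matched-pair haplotype design:", nrow(x$D), "families,",
      ncol(x$D), "cores (", sum(!x$informative), "uninformative )\n")
  invisible(x)
}

#' Export a matched-pair design as TSV
#'
#' One row per individual (case and pseudo-control per family) with the
#' core-haplotype weights; the audit trail of the uncertainty-coding step.
#' @param design A `"hap_design"`.
#' @param path Output file.
#' @export
write_design <- function(design, path) {
  long <- rbind(
    data.frame(family = design$family, role = "case", design$Z1,
               check.names = FALSE),
    data.frame(family = design$family, role = "pseudo-control", design$Z0,
               check.names = FALSE))
  long <- long[order(long$family, long$role), , drop = FALSE]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  long <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
  cores <- setdiff(colnames(long), c("family", "role"))
  cs <- long[long$role == "case", , drop = FALSE]
  ct <- long[long$role == "pseudo-control", , drop = FALSE]
  ct <- ct[match(cs$family, ct$family), , drop = FALSE]
  Z1 <- as.matrix(cs[, cores, drop = FALSE])
  Z0 <- as.matrix(ct[, cores, drop = FALSE])
  rownames(Z1) <- rownames(Z0) <- NULL
  D <- Z1 - Z0
  structure(list(Z1 = Z1, Z0 = Z0, D = D, family = cs$family,
                 informative = rowSums(abs(D)) > 1e-12, cores = cores),
            class = "hap_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
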