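# Evolutionary-guided reduction of the haplotype set to ancestral core
# haplotypes, and the row-stochastic clustering matrix C that spreads each
# haplotype's weight over the cores.

#' Select ancestral core haplotypes by an entropy criterion
#'
#' Haplotypes are ranked by decreasing frequency (rare haplotypes are
#' evolutionarily "young", common ones ancient).  The number of cores `K`
#' is the smallest `k` such that the top-`k` haplotypes retain at least a
#' fraction `theta` of the pool's total Shannon information
#' `sum(-p log p)`, and every excluded haplotype is rare
#' (frequency < `max_rare`).  The most common haplotype is always core 1
#' and serves as the regression reference.
#'
#' @param table A [hap_freqs()] table.
#' @param theta Retained-information threshold in `(0, 1]` (default 0.90,
#'   calibrated so the reference 8-SNP pool of [default_sim_freqs()]
#'   reduces from seven haplotypes to its five most frequent).
#' @param max_rare Largest frequency an excluded haplotype may have
#'   (default 0.05).
#' @return Character vector of core haplotypes in decreasing-frequency
#'   order, with the frequency vector in attribute `"freq"`.
#' @export
select_cores <- function(table, theta = 0.90, max_rare = 0.05) {
  table <- validate_freq_table(table)
  p <- table$freq
  H <- length(p)
  info <- -p * log(p)
  # a single haplotype (or a degenerate pool) carries no information to lose
  if (sum(info) <= 0) {
    cores <- table$haplotype[1L]
    attr(cores, "freq") <- p[1L]
    return(cores)
  }
  ratio <- cumsum(info) / sum(info)
  K <- H
  for (k in seq_len(H)) {
    excl_ok <- if (k == H) TRUE else all(p[(k + 1L):H] < max_rare)
    if (ratio[k] >= theta && excl_ok) { K <- k; break }
  }
  cores <- table$haplotype[seq_len(K)]
  attr(cores, "freq") <- p[seq_len(K)]
  cores
}

#' Build the haplotype-to-core clustering probability matrix
#'
#' Row `h` gives the probabilities that haplotype `h` descends from each
#' core.  A core haplotype maps to itself with probability 1.  Every other
#' haplotype is assigned to the cores at minimal Hamming distance from it
#' (the mutation-count "generation" measure), with probability
#' proportional to core frequency among those nearest cores.  Rows sum to
#' one exactly.
#'
#' @param table A [hap_freqs()] table whose haplotypes form the rows.
#' @param cores Result of [select_cores()] (a subset of the table's
#'   haplotypes, reference first).
#' @return `H x K` numeric matrix with haplotype row names and core column
#'   names.
#' @export
build_clustering_matrix <- function(table, cores) {
  table <- validate_freq_table(table)
  if (!all(cores %in% table$haplotype))
    stop("cores must be haplotypes of the table", call. = FALSE)
  core_freq <- attr(cores, "freq")
  if (is.null(core_freq)) core_freq <- table$freq[match(cores, table$haplotype)]
  H <- nrow(table); K <- length(cores)
  C <- matrix(0, H, K, dimnames = list(table$haplotype, as.character(cores)))
  cores <- as.character(cores)
  for (h in seq_len(H)) {
    hap <- table$haplotype[h]
    j <- match(hap, cores)
    if (!is.na(j)) { C[h, j] <- 1; next }
    d <- hamming_distance(hap, cores)
    nearest <- which(d == min(d))
    w <- core_freq[nearest]
    C[h, nearest] <- w / sum(w)
  }
  C
}

#' Project haplotype-level weight rows onto core haplotypes
#'
#' Matrix product `Z = X C`.  Because every row of `C` sums to one, the
#' per-individual weight total (2, one per inherited haplotype) is
#' conserved exactly.
#'
#' @param X Numeric matrix (or vector) of per-individual weights over
#'   haplotypes; columns must match the rows of `C` (by name when both are
#'   named).
#' @param C Clustering matrix from [build_clustering_matrix()].
#' @return Matrix of weights over cores, same row count as `X`.
#' @export
reduce_design <- function(X, C) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  if (ncol(X) != nrow(C))
    stop("dimension mismatch between X and C", call. = FALSE)
  if (!is.null(colnames(X)) && !is.null(rownames(C))) {
    if (!setequal(colnames(X), rownames(C)))
      stop("haplotype names of X and C differ", call. = FALSE)
    X <- X[, rownames(C), drop = FALSE]
  }
  X %*% C
}

#' Write / read a clustering matrix as TSV
#'
#' Haplotype row labels in the first column, core haplotypes as headers.
#' @param C Clustering matrix.
#' @param path File path.
#' @export
write_clustering_matrix <- function(C, path) {
  df <- data.frame(haplotype = rownames(C), C, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clustering_matrix
#' @export
read_clustering_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = c("character"))
  C <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(C) <- "double"
  rownames(C) <- df[[1L]]
  C
}
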