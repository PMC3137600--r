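# Fundamental genetic objects: haplotypes over a biallelic SNP panel
# (alleles coded 1 = common, 2 = minor), haplotype frequency tables,
# multilocus genotypes and nuclear families.

# ---- internal haplotype codecs -------------------------------------------

# A haplotype over L loci is stored externally as a string of 1/2 characters
# ("11111211") and internally as a non-negative number whose bit l-1 is
# allele(l) - 1.  Exact integer arithmetic in doubles restricts L <= 26.
.MAX_LOCI <- 26L

.hap_to_int <- function(h) {
  m <- .hap_to_mat(h)
  as.numeric(m %*% 2^(seq_len(ncol(m)) - 1)) - sum(2^(seq_len(ncol(m)) - 1))
}

# matrix of allele codes, one haplotype per row
.hap_to_mat <- function(h) {
  L <- nchar(h[1])
  if (any(nchar(h) != L)) stop("haplotypes have unequal lengths", call. = FALSE)
  m <- matrix(as.integer(unlist(strsplit(h, "", fixed = TRUE))),
              nrow = length(h), ncol = L, byrow = TRUE)
  if (anyNA(m) || !all(m %in% c(1L, 2L)))
    stop("haplotype alleles must be coded 1 or 2", call. = FALSE)
  m
}

.int_to_hap <- function(x, L) {
  bits <- .int_to_bits(x, L)
  apply(bits + 1L, 1L, paste, collapse = "")
}

# rows = haplotypes, entries 0/1 (allele - 1)
.int_to_bits <- function(x, L) {
  out <- matrix(0L, length(x), L)
  for (l in seq_len(L)) out[, l] <- as.integer((x %/% 2^(l - 1)) %% 2)
  out
}

# ---- hamming distance ----------------------------------------------------

#' Hamming distance between two haplotypes
#'
#' Number of loci at which two haplotypes on the same SNP panel carry
#' different alleles.  Used as the "generation" count in the evolutionary
#' clustering of rare haplotypes onto ancestral cores.
#'
#' @param h1,h2 Haplotype strings over alleles `1`/`2` (e.g. `"11111211"`).
#'   Vectors are compared elementwise with recycling of length-1 arguments.
#' @return Integer vector of allele mismatch counts.
#' @examples
#' hamming_distance("12111211", "12111111")  # 1
#' @export
hamming_distance <- function(h1, h2) {
  if (any(nchar(h1) != nchar(h2)))
    stop("panel mismatch: haplotypes have different numbers of loci",
         call. = FALSE)
  m1 <- .hap_to_mat(h1)
  m2 <- .hap_to_mat(h2)
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
    else stop("incompatible haplotype vector lengths", call. = FALSE)
  }
  as.integer(rowSums(m1 != m2))
}

# ---- frequency tables ----------------------------------------------------

#' Construct and validate a haplotype frequency table
#'
#' A frequency table lists the haplotypes segregating in the population with
#' their proportions.  Frequencies must be positive and sum to one;
#' deviations up to `tol` are renormalized, larger deviations are an error.
#'
#' @param haplotype Character vector of haplotype strings, all of one length.
#' @param freq Numeric vector of proportions (percentages divided by 100).
#' @param tol Largest tolerated deviation of `sum(freq)` from 1 before
#'   normalization fails (default `1e-6`).
#' @return A `data.frame` of class `"hap_freqs"` with columns `haplotype`
#'   and `freq`, ordered by decreasing frequency.
#' @examples
#' hap_freqs(c("11", "12", "22"), c(0.5, 0.3, 0.2))
#' @export
hap_freqs <- function(haplotype, freq, tol = 1e-6) {
  if (length(haplotype) == 0L) stop("empty frequency table", call. = FALSE)
  if (length(haplotype) != length(freq))
    stop("haplotype and freq lengths differ", call. = FALSE)
  .hap_to_mat(haplotype)                       # validates allele codes
  if (anyDuplicated(haplotype))
    stop("duplicate haplotype in frequency table: ",
         haplotype[duplicated(haplotype)][1L], call. = FALSE)
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("haplotype frequencies must be positive", call. = FALSE)
  s <- sum(freq)
  if (abs(s - 1) > tol)
    stop(sprintf("haplotype frequencies sum to %.6f, not 1", s), call. = FALSE)
  freq <- freq / s
  o <- order(-freq, haplotype)
  out <- data.frame(haplotype = haplotype[o], freq = freq[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("hap_freqs", "data.frame")
  out
}

#' @rdname hap_freqs
#' @param table An object to check.
#' @export
validate_freq_table <- function(table, tol = 1e-6) {
  hap_freqs(table$haplotype, table$freq, tol = tol)
}

#' Per-locus minor allele frequencies implied by a haplotype table
#'
#' The minor allele frequency at locus `s` is the total frequency of
#' haplotypes carrying allele 2 there (allele 2 is the minor allele by the
#' input coding convention, not recomputed from data).
#'
#' @param table A [hap_freqs()] table.
#' @return Numeric vector of MAFs, one per locus, in `[0, 1]`.
#' @export
maf_from_frequencies <- function(table) {
  table <- validate_freq_table(table, tol = 1e-6)
  m <- .hap_to_mat(table$haplotype)
  as.vector(colSums((m == 2L) * table$freq))
}

#' Reference 8-SNP haplotype pool used by the simulator
#'
#' Seven phased haplotypes over eight SNPs on 12q24 with their population
#' frequencies; `11111211` (10%) is the conventional risk haplotype in the
#' simulation studies shipped with the package.
#'
#' @return A [hap_freqs()] table of 7 haplotypes over 8 SNPs.
#' @export
default_sim_freqs <- function() {
  hap_freqs(
    c("11111111", "12111111", "11111211", "21212121",
      "21212122", "12111211", "11222122"),
    c(49.44, 27.78, 10.00, 7.22, 3.89, 1.11, 0.56) / 100
  )
}

# ---- genotypes and families ----------------------------------------------

# A multilocus genotype is an L x 2 integer matrix of unordered allele
# pairs; a locus with any NA is treated as missing.  User-facing input is a
# character vector of per-locus pairs, e.g. c("12", "00", "22"), where "00"
# (or "--") marks a missing genotype.
.parse_geno <- function(g, L = NULL) {
  if (is.null(g)) {
    if (is.null(L)) stop("panel size unknown for untyped member", call. = FALSE)
    return(matrix(NA_integer_, L, 2L))
  }
  if (is.matrix(g)) {
    storage.mode(g) <- "integer"
    bad <- !is.na(g) & !(g %in% c(1L, 2L))
    if (any(bad)) stop("genotype alleles must be 1, 2 or missing", call. = FALSE)
    g[is.na(g[, 1L]) | is.na(g[, 2L]), ] <- NA_integer_
    return(g)
  }
  g <- gsub("-", "0", g, fixed = TRUE)
  if (any(nchar(g) != 2L)) stop("each locus genotype needs two alleles", call. = FALSE)
  a <- matrix(as.integer(unlist(strsplit(g, "", fixed = TRUE))),
              ncol = 2L, byrow = TRUE)
  if (anyNA(a) || !all(a %in% 0:2))
    stop("genotype alleles must be 0 (missing), 1 or 2", call. = FALSE)
  a[a == 0L] <- NA_integer_
  a[is.na(a[, 1L]) | is.na(a[, 2L]), ] <- NA_integer_
  # store sorted so the pair is explicitly unordered
  t(apply(a, 1L, function(r) if (anyNA(r)) c(NA_integer_, NA_integer_) else sort(r)))
}

#' Build a nuclear family record
#'
#' A family consists of both parents (possibly untyped), at least one
#' offspring with known affection status, and a designated affected index
#' case.  Genotypes are unordered allele pairs per locus; `"00"` or `"--"`
#' marks a missing locus, `NULL` an entirely untyped parent.
#'
#' @param id Family identifier.
#' @param father,mother Genotypes: character vectors of per-locus pairs
#'   (e.g. `c("12","12")`), `L x 2` matrices, or `NULL` for untyped.
#' @param children List of offspring genotypes in the same formats.
#' @param affected Logical/0-1 vector of offspring affection states.
#' @param case Index of the designated affected offspring used for the
#'   matched case/pseudo-control pair; defaults to the first affected child.
#' @return An object of class `"hap_family"`.
#' @export
hap_family <- function(id, father, mother, children, affected, case = NULL) {
  if (length(children) < 1L) stop("family needs at least one offspring", call. = FALSE)
  affected <- as.logical(affected)
  if (length(affected) != length(children))
    stop("affected must match the number of children", call. = FALSE)
  kids <- lapply(children, .parse_geno)
  L <- unique(vapply(kids, nrow, 1L))
  if (length(L) != 1L) stop("children genotyped on different panels", call. = FALSE)
  if (L > .MAX_LOCI) stop("panels above ", .MAX_LOCI, " loci are not supported", call. = FALSE)
  fa <- .parse_geno(father, L)
  mo <- .parse_geno(mother, L)
  if (nrow(fa) != L || nrow(mo) != L)
    stop("parents and children genotyped on different panels", call. = FALSE)
  if (is.null(case)) case <- which(affected)[1L]
  if (is.na(case) || !isTRUE(affected[case]))
    stop("family ", id, ": no affected offspring to serve as index case", call. = FALSE)
  structure(list(id = id, father = fa, mother = mo, children = kids,
                 affected = affected, case = as.integer(case), L = L),
            class = "hap_family")
}

#' @export
print.hap_family <- function(x, ...) {
  cat("Nuclear family", x$id, "-", x$L, "loci,",
      length(x$children), "offspring (case: child", x$case, ")\n")
  fmt <- function(g) paste(apply(g, 1L, function(r)
    if (anyNA(r)) "-/-" else paste(r, collapse = "/")), collapse = " ")
  cat("  father:", fmt(x$father), "\n  mother:", fmt(x$mother), "\n")
  for (i in seq_along(x$children))
    cat(sprintf("  child %d (%s): %s\n", i,
                if (x$affected[i]) "affected" else "unaffected",
                fmt(x$children[[i]])))
  invisible(x)
}

# ---- PED input / output --------------------------------------------------

#' Read nuclear families from a PED-style pedigree file
#'
#' Whitespace-delimited linkage format: famID, indivID, fatherID, motherID,
#' sex, affection (1 = unaffected, 2 = affected), then two allele columns
#' per SNP with 0 for a missing allele.  Founders carry parent IDs 0.
#' Individuals listed without genotype rows are not supported; an untyped
#' parent is a row with all-zero alleles.
#'
#' @param path File to read.
#' @return List of [hap_family()] objects, one per family ID.
#' @export
read_ped <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 8L || ncol(tab) %% 2L != 0L)
    stop("malformed PED file: need 6 id columns plus 2 allele columns per SNP",
         call. = FALSE)
  L <- (ncol(tab) - 6L) %/% 2L
  geno_of <- function(row) {
    a <- as.integer(row[6L + seq_len(2L * L)])
    m <- matrix(a, ncol = 2L, byrow = TRUE)
    m[m == 0L] <- NA_integer_
    m
  }
  out <- list()
  for (fid in unique(tab[[1L]])) {
    rows <- tab[tab[[1L]] == fid, , drop = FALSE]
    founders <- rows[[3L]] == "0" & rows[[4L]] == "0"
    kids <- rows[!founders, , drop = FALSE]
    if (nrow(kids) == 0L) stop("family ", fid, " has no offspring", call. = FALSE)
    faid <- unique(kids[[3L]]); moid <- unique(kids[[4L]])
    if (length(faid) != 1L || length(moid) != 1L)
      stop("family ", fid, " is not a single nuclear family", call. = FALSE)
    grab <- function(id) {
      i <- which(rows[[2L]] == id)
      if (length(i) == 0L) NULL else geno_of(unlist(rows[i[1L], ]))
    }
    out[[fid]] <- hap_family(
      id = fid,
      father = if (is.null(grab(faid))) NULL else grab(faid),
      mother = if (is.null(grab(moid))) NULL else grab(moid),
      children = lapply(seq_len(nrow(kids)), function(i) geno_of(unlist(kids[i, ]))),
      affected = kids[[6L]] == "2"
    )
  }
  out
}

#' Write families to a PED-style pedigree file
#'
#' @param families List of [hap_family()] objects.
#' @param path Output file.
#' @seealso [read_ped()] for the dialect.
#' @export
write_ped <- function(families, path) {
  lines <- character(0)
  for (fam in families) {
    gl <- function(g) {
      g[is.na(g)] <- 0L
      paste(t(g), collapse = " ")
    }
    fid <- fam$id
    lines <- c(lines,
               paste(fid, "1", "0", "0", "1", "1", gl(fam$father)),
               paste(fid, "2", "0", "0", "2", "1", gl(fam$mother)))
    for (i in seq_along(fam$children))
      lines <- c(lines, paste(fid, i + 2L, "1", "2", "1",
                              if (fam$affected[i]) "2" else "1",
                              gl(fam$children[[i]])))
  }
  writeLines(lines, path)
  invisible(path)
}
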