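# Shared fixtures: the reference haplotype pool, the two-locus worked
# example, and a generator of random small Mendelian-consistent pedigrees
# used by the oracle-equivalence property tests.

ref_pool <- function() default_sim_freqs()

# father double-het, mother with one missing locus, homozygous case child
worked_example <- function() {
  hap_family("WE1", father = c("12", "12"), mother = c("00", "12"),
             children = list(c("11", "11")), affected = 1)
}

worked_example_table <- function(p1 = 0.3, p2 = 0.1) {
  rest <- 1 - p1 - p2
  hap_freqs(c("11", "21", "12", "22"),
            c(rest * 0.7, rest * 0.3, p1, p2))
}

# synthetic 12-haplotype profile: 4 common + 8 rare (<5%), built to mimic
# a block where five cores absorb ~99% of the frequency mass
twelve_hap_table <- function() {
  hap_freqs(
    c("11111111", "21111111", "11211111", "11112111", "22111111",
      "11111112", "21111112", "11211112", "11112112", "12111111",
      "11121111", "11111211"),
    c(0.42, 0.28, 0.17, 0.09, 0.0295, rep(0.0015, 7)))
}

# genotype character vector from two haplotype strings
geno_from_haps <- function(h1, h2) {
  a1 <- strsplit(h1, "")[[1]]
  a2 <- strsplit(h2, "")[[1]]
  paste0(pmin(a1, a2), pmax(a1, a2))
}

# mask each locus independently with probability rate
mask_geno <- function(g, rate) {
  hit <- runif(length(g)) < rate
  g[hit] <- "00"
  g
}

# A random nuclear family drawn from a random haplotype pool; genotypes are
# Mendelian-consistent by construction, then partially masked.  Returns the
# family and the table it was drawn from.
random_small_pedigree <- function(L = sample(2:4, 1), n_children = sample(1:3, 1),
                                  miss_rate = 0.15, drop_parent = 0.15) {
  haps <- apply(expand.grid(rep(list(c("1", "2")), L)), 1, paste, collapse = "")
  f <- rgamma(length(haps), 1) + 0.05
  tab <- hap_freqs(haps, f / sum(f))
  draw <- function() sample(tab$haplotype, 2, replace = TRUE, prob = tab$freq)
  fa <- draw(); mo <- draw()
  kids <- lapply(seq_len(n_children), function(i)
    geno_from_haps(sample(fa, 1), sample(mo, 1)))
  kids <- lapply(kids, mask_geno, rate = miss_rate)
  father <- mask_geno(geno_from_haps(fa[1], fa[2]), miss_rate)
  mother <- mask_geno(geno_from_haps(mo[1], mo[2]), miss_rate)
  if (runif(1) < drop_parent) father <- NULL
  if (runif(1) < drop_parent) mother <- NULL
  aff <- rep(FALSE, n_children); aff[sample(n_children, 1)] <- TRUE
  fam <- hap_family("R1", father = father, mother = mother,
                    children = kids, affected = aff)
  list(family = fam, table = tab)
}

# canonical key for comparing explanation sets
expl_key <- function(e) paste(e$tF, e$tM, e$uF, e$uM)
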