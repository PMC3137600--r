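test_that("penetrance ladders solve the prevalence constraint", {
  # null model: every genotype has the prevalence as penetrance
  for (m in c("additive", "dominant", "recessive"))
    expect_equal(penetrances(m, 1, 0.01, 0.1), rep(0.01, 3))
  # recessive closed form: f0 = prev / (1 - q^2 + g q^2)
  f <- penetrances("recessive", 2, 0.01, 0.1)
  expect_equal(f[1], 0.01 / (1 - 0.01 + 2 * 0.01))
  expect_equal(f[2], f[1])
  expect_equal(f[3], 2 * f[1])
  # additive: prevalence identity under Hardy-Weinberg weights
  f <- penetrances("additive", 2, 0.01, 0.1)
  expect_equal(f[2] / f[1], 2)
  expect_equal(f[3] / f[1], 3)
  w <- c(0.9^2, 2 * 0.1 * 0.9, 0.1^2)
  expect_equal(sum(w * f), 0.01, tolerance = 1e-12)
  # dominant: f1 = f2
  f <- penetrances("dominant", 1.5, 0.01, 0.1)
  expect_equal(f[2], f[3])
  expect_error(penetrances("additive", 0.8, 0.01, 0.1), ">= 1")
  expect_error(penetrances("additive", 2, 0.99, 0.9), "exceeds 1")
})

test_that("under the null the ascertained child's pair is Hardy-Weinberg", {
  set.seed(555)
  fams <- sim_families(n = 1500, grr = 1.0)
  truth <- attr(fams, "truth")
  tab <- truth$table
  # chi-square on the unordered pair distribution of the index child
  pairs <- vapply(truth$phases, function(ph)
    paste(sort(c(ph$tF, ph$tM)), collapse = "-"), "")
  H <- nrow(tab)
  grid <- expand.grid(i = 1:H, j = 1:H)
  grid <- grid[grid$i <= grid$j, ]
  pexp <- ifelse(grid$i == grid$j, tab$freq[grid$i]^2,
                 2 * tab$freq[grid$i] * tab$freq[grid$j])
  key <- paste(grid$i, grid$j, sep = "-")
  obs <- table(factor(pairs, levels = key))
  keep <- pexp * 1500 >= 5
  chi <- sum((obs[keep] - 1500 * pexp[keep])^2 / (1500 * pexp[keep]))
  expect_lt(chi, qchisq(0.999, sum(keep) - 1))
})

test_that("risk-haplotype transmission is enriched exactly as the pair model implies", {
  # brute-force expectation over the 7 x 7 pair space with penetrance weights
  tab <- ref_pool()
  risk <- match("11111211", tab$haplotype)
  f <- penetrances("additive", 2, 0.01, tab$freq[risk])
  H <- nrow(tab)
  g <- expand.grid(i = 1:H, j = 1:H)
  copies <- (g$i == risk) + (g$j == risk)
  w <- tab$freq[g$i] * tab$freq[g$j] * f[copies + 1]
  exp_copies <- sum(copies * w) / sum(w)

  set.seed(808)
  fams <- sim_families(n = 4000, grr = 2.0)
  truth <- attr(fams, "truth")
  obs <- mean(vapply(truth$phases, function(ph)
    (ph$tF == risk) + (ph$tM == risk), 1))
  expect_equal(obs, exp_copies, tolerance = 0.05)
  expect_gt(obs, 2 * tab$freq[risk])   # enrichment above 2q
})

test_that("family sizes follow 3 + Poisson(2) with ~86% above three members", {
  set.seed(99)
  fams <- sim_families(n = 2000, grr = 1.2)
  extra <- vapply(fams, function(f) length(f$children) - 1L, 1L)
  expect_equal(mean(extra > 0), 1 - exp(-2), tolerance = 0.03)
  expect_equal(mean(extra), 2, tolerance = 0.1)
})

test_that("simulated genotypes are always Mendelian-consistent", {
  set.seed(321)
  for (mode in c("additive", "dominant", "recessive")) {
    fams <- sim_families(n = 30, mode = mode, grr = 2.0)
    for (f in fams) expect_no_error(enumerate_explanations(f, ref_pool()))
  }
  # also with missingness injected
  fams <- sim_families(n = 30, grr = 1.5, missing_rate = 0.1)
  for (f in fams) expect_no_error(enumerate_explanations(f, ref_pool()))
})

test_that("datasets are reproducible byte-for-byte given a seed", {
  d1 <- sim_dataset(2, seed = 7, n = 25, grr = 1.5)
  d2 <- sim_dataset(2, seed = 7, n = 25, grr = 1.5)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_ped(d1[[2]], p1)
  write_ped(d2[[2]], p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seeds differ
  d3 <- sim_dataset(1, seed = 8, n = 25, grr = 1.5)
  p3 <- withr::local_tempfile()
  write_ped(d3[[1]], p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})
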