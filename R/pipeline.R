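# End-to-end orchestration with file I/O: run the six-step workflow from a
# PED file, persisting every intermediate, plus packaged toy fixtures.

#' Write / read a haplotype frequency table as two-column text
#'
#' @param table A [hap_freqs()] table.
#' @param path File path (whitespace-delimited: haplotype, frequency).
#' @export
write_freq_table <- function(table, path) {
  write.table(data.frame(haplotype = table$haplotype, freq = table$freq),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric"))
  hap_freqs(df$haplotype, df$freq)
}

#' Run the full fit from files, persisting intermediates
#'
#' Reads families from a PED file, executes the six workflow steps
#' (frequency EM, core selection, clustering matrix, explanation sets,
#' uncertainty coding, posterior sampling) and writes each intermediate
#' plus the posterior summary under `out_dir`.  Configuration may be a
#' named list or a YAML/JSON file with entries `theta`, `support_tol`,
#' `prevalence`, `a`, `b`, `chains`, `burnin`, `iter`, `thin`, `seed`,
#' `threshold`.
#'
#' @param ped Path to the PED input.
#' @param out_dir Output directory (created if needed).
#' @param config Named list of options, or a path to a YAML file.
#' @return The fitted `"uchap"` object, invisibly.
#' @export
run_fit <- function(ped, out_dir, config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  g <- function(name, default) config[[name]] %||% default
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fit <- uchap(
    families = ped,
    theta = g("theta", 0.90),
    support_tol = g("support_tol", 1e-3),
    prior = prior_spec(prevalence = g("prevalence", 0.01),
                       a = g("a", 0.01), b = g("b", 0.01)),
    mcmc = mcmc_config(chains = g("chains", 3L), burnin = g("burnin", 5000L),
                       iter = g("iter", 10000L), thin = g("thin", 10L),
                       seed = g("seed", 1L)),
    threshold = g("threshold", 0.5))

  write_freq_table(fit$freq, file.path(out_dir, "frequencies.tsv"))
  write_clustering_matrix(fit$C, file.path(out_dir, "clustering.tsv"))
  write_design(fit$design, file.path(out_dir, "design.tsv"))
  draws <- do.call(rbind, lapply(seq_along(fit$chains), function(ch)
    data.frame(chain = ch, fit$chains[[ch]]$beta,
               sigma2 = fit$chains[[ch]]$sigma2, check.names = FALSE)))
  write.table(draws, file.path(out_dir, "posterior.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  s <- fit$summary
  write.table(
    data.frame(core = s$core, mean = s$mean, sd = s$sd, rr = s$rr,
               prob_susceptible = s$prob_susceptible, risk_call = s$risk_call),
    file.path(out_dir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(fit)
}

#' Write the packaged toy fixtures
#'
#' Creates, under `dir`: the two-locus worked-example family
#' (`example_trio.ped`: father 1/2 1/2, mother missing 1/2, affected child
#' 1/1 1/1), the reference 8-SNP frequency table (`freqs.tsv`), and a
#' simulated 10-family mini pedigree file (`mini.ped`, fixed seed).
#'
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trio <- hap_family("T1", father = c("12", "12"), mother = c("00", "12"),
                     children = list(c("11", "11")), affected = 1)
  p1 <- file.path(dir, "example_trio.ped")
  write_ped(list(trio), p1)
  p2 <- file.path(dir, "freqs.tsv")
  write_freq_table(default_sim_freqs(), p2)
  p3 <- file.path(dir, "mini.ped")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(42L)
  mini <- sim_families(n = 10L, grr = 1.5)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  write_ped(mini, p3)
  invisible(c(p1, p2, p3))
}
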