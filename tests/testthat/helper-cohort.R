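## Shared fixture builders (everything generated in code; no stored data).

## Small two-cohort pair with the same planted prognostic probes.
make_cohort_pair <- function(n_a = 150, n_b = 300, n_probes = 20,
                             effects = stats::setNames(c(0.9, -0.8),
                                                       c("probe_0001", "probe_0002")),
                             seed = 42) {
  list(a = generate_cohort(cohort_spec(n_a, n_probes,
                                       prognostic_effects = effects,
                                       censoring_rate = 0.1, seed = seed)),
       b = generate_cohort(cohort_spec(n_b, n_probes,
                                       prognostic_effects = effects,
                                       censoring_rate = 0.2, seed = seed + 1)))
}

## Two-class expression matrix with planted differential genes.
make_two_class <- function(n_genes = 100, n_per_class = 12, n_de = 20,
                           shift = 5, seed = 7) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * 2 * n_per_class), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
    classes <- rep(c("A", "B"), each = n_per_class)
    x[seq_len(n_de), classes == "B"] <- x[seq_len(n_de), classes == "B"] + shift
    list(x = x, classes = classes, de_genes = rownames(x)[seq_len(n_de)])
  })
}
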