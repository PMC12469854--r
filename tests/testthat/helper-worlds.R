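# Shared fixtures built in code.  The "tiny" scale keeps unit tests of the
# training loop in the seconds range; acceptance tests use package defaults.

tiny_synth_config <- function(seed = 7L, ...) {
  defaults <- list(n_genes = 30L, n_drugs = 12L, targets_per_drug_mean = 4,
                   n_cell_lines = 3L, module_size = 6L, n_combos = 120L,
                   seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

tiny_model_config <- function(seed = 7L, ...) {
  defaults <- list(d_model = 16L, n_heads = 4L, n_blocks = 2L,
                   head_hidden = c(12L, 8L), dropout = 0.1, batch_size = 32L,
                   max_epochs = 15L, patience = 5L, seed = seed)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

make_universe <- function(genes) convert_ids(genes)

# Exact hypergeometric upper tail by direct pmf summation with choose();
# independent of stats::phyper.
oracle_upper_tail <- function(x, n, K, N) {
  ks <- x:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
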