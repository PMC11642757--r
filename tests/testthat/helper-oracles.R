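# Independent oracles and shared fixtures used across test files.

# Explicit per-cell binary-tree lineage simulation: every cell of every
# round is represented; euploid daughters err independently (per-daughter
# convention). Brute-force counterpart to the binomial-recursion simulator.
tree_lineage_oracle <- function(n_embryos, meiotic, mitotic, n_rounds) {
  n_cells <- 2^n_rounds
  vapply(seq_len(n_embryos), function(i) {
    if (stats::runif(1) < meiotic) return(n_cells)
    cells <- FALSE  # one euploid zygote; TRUE = aneuploid
    for (r in seq_len(n_rounds)) {
      daughters <- rep(cells, each = 2)
      err <- stats::runif(length(daughters)) < mitotic
      cells <- daughters | err  # aneuploid cells breed true
    }
    sum(cells)
  }, integer(1))
}

# total-variation distance between an empirical count vector and a
# reference probability mass function over the same support
tv_distance <- function(obs_counts, ref_pmf) {
  sum(abs(obs_counts / sum(obs_counts) - ref_pmf)) / 2
}

# hypergeometric pmf of the biopsy aneuploid count
hyper_pmf <- function(k_aneuploid, n_cells, biopsy_size) {
  stats::dhyper(0:biopsy_size, k_aneuploid, n_cells - k_aneuploid,
                biopsy_size)
}

# lazily computed shared fixtures (built once per test run, on first use)
fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# headline fit: Capalbo target, dispersal 1, full settings
capalbo_d1_fit <- function() {
  fixture("capalbo_d1_fit", function() {
    set.seed(20260101)
    run_abc(
      published_targets()[1, ],
      config = model_config(dispersal = 1),
      control = abc_config(max_iterations = 40)
    )
  })
}

# million-embryo posterior predictive for the headline fit
capalbo_d1_predictive <- function() {
  fixture("capalbo_d1_predictive", function() {
    simulate_predictive(
      capalbo_d1_fit(),
      model_config(dispersal = 1),
      n_draws = 1000, n_embryos_per_draw = 1000,
      seed = 20260102
    )
  })
}

capalbo_d1_tables <- function() {
  fixture("capalbo_d1_tables", function() {
    predictive_tables(capalbo_d1_predictive())
  })
}
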