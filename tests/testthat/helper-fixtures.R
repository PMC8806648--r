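# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# mid-size synthetic cohort shared across modules
cohort500 <- function() {
  cached("cohort500", function() simulate_cohort(sim_config(n_samples = 500, seed = 42)))
}

# scores + truth-purity adjustment for cohort500
scores500 <- function() {
  cached("scores500", function() {
    co <- cohort500()
    ita <- ita_score(co$expr, co$marker_genes)
    emt <- emt_score(co$expr, co$gene_sets$HALLMARK_EMT)
    list(ita = ita, emt = emt,
         ita_adj = adjust_for_purity(ita, co$truth$purity),
         emt_adj = adjust_for_purity(emt, co$truth$purity))
  })
}

# tiny deterministic expression matrix
tiny_expr <- function(n_genes = 20, n_samples = 5, seed = 3) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, log(50), 1),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(m, "linear")
}

# small clinical table with exponential survival
tiny_clin <- function(n = 30, seed = 4, rate = 0.002, horizon = 1000) {
  set.seed(seed)
  t_ev <- stats::rexp(n, rate)
  cens <- stats::runif(n, 0, 2 * horizon)
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    os_time = pmin(t_ev, cens, horizon),
    os_event = as.integer(t_ev <= pmin(cens, horizon)),
    cohort = "test"
  )
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
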