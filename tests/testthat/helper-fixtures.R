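# Shared fixtures built in code. Expensive objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# the default synthetic study (frogs + humans), seed 1
default_gen <- function() {
  memo("default_gen", generate_cohort(default_study_plan(), 1))
}

# frog-only view of the default study
default_frogs <- function() {
  memo("default_frogs", filter_samples(default_gen()$cohort, cohort == "frog"))
}

# per-species screens and the Stouffer meta table for the default study
default_ewas <- function() {
  memo("default_ewas", {
    frogs <- default_frogs()
    screens <- list(
      laevis = correlation_screen(filter_samples(frogs, species == "laevis")),
      tropicalis = correlation_screen(filter_samples(frogs, species == "tropicalis"))
    )
    c(list(meta = stouffer_combine(screens)), screens)
  })
}

# small frog-only generator for fast model tests
small_gen <- function(seed = 7, n_cpgs = 250, ...) {
  plan <- default_study_plan()$plan
  cfg <- simulation_config(n_cpgs = n_cpgs, plan = plan[plan$cohort == "frog", ],
                           n_positive = 40, n_negative = 20, ...)
  generate_cohort(cfg, seed)
}

# a tiny deterministic cohort with an exact linear-in-transformed-age CpG
toy_cohort <- function(n = 16, n_cpgs = 12, species = "laevis", seed = 42) {
  reg <- default_species_registry()
  p <- reg[reg$species == species, ]
  withr::with_seed(seed, {
    ages <- seq(0.1, p$max_lifespan_years * 0.6, length.out = n)
    f <- loglinear_forward(ages, p$maturity_years)
    g <- (f - min(f)) / (max(f) - min(f))
    beta <- matrix(runif(n_cpgs * n, 0.2, 0.8), n_cpgs,
                   dimnames = list(sprintf("cg%03d", seq_len(n_cpgs)),
                                   sprintf("s%02d", seq_len(n))))
    beta[1, ] <- 0.2 + 0.6 * g # perfect signal in row 1
    samples <- tibble::tibble(
      sample_id = colnames(beta), species = species, tissue = "liver",
      age_years = ages, sex = "unknown", cohort = "frog"
    )
    assemble_cohort(beta, samples)
  })
}

# independent brute-force hypergeometric upper tail via binomial coefficients
brute_hyper_tail <- function(k, K, n, N) {
  j <- seq(max(0, n + K - N), min(n, K))
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  sum(pmf[j >= k])
}
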