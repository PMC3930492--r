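# shared helpers: tiny builders used across test files

RT0 <- thermo_constants()$RT

# single reaction A -> B with default-style symmetric bounds
single_rxn <- function(dg0 = 0) {
  pathway(list(reaction("R1", "A <=> B", dg0)))
}

# two-reaction chain with wide intermediate bounds; A at Cmax, C at Cmin at
# the optimum (both reaction shadow prices 0.5, metabolite price of A 0.5)
two_chain <- function(dg0 = -1) {
  list(pathway = pathway(list(reaction("R1", "A <=> B", dg0),
                              reaction("R2", "B <=> C", dg0))),
       constraints = concentration_constraints(
         default_lower = 1e-6, default_upper = 1e-2,
         lower = c(B = 1e-9), upper = c(B = 1e2)))
}

# seeded random chain spec with interior-optimum geometry not guaranteed;
# callers filter through chain_mdf_closed_form()'s guard
random_chain_spec <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  chain_spec(n, dg0 = round(stats::runif(n, -12, 2), 2),
             terminal_conc = 10^stats::runif(2, -4, 0),
             intermediate_bounds = c(1e-12, 1e6), seed = seed)
}

expect_kj <- function(object, expected, tol = 1e-6) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "mdftools")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)  # load_all runs
  p
}
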