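toy_sweep_pathway <- function(slopes = c(0, 0, 0), base = c(-8, -2, -6)) {
  mk <- function(i) {
    tab <- data.frame(ph = c(6, 8), dg0_prime = base[i] + slopes[i] * c(0, 2))
    reaction(paste0("R", i), paste(LETTERS[i], "<=>", LETTERS[i + 1]),
             dg0_prime = base[i], dg0_by_ph = tab)
  }
  pathway(lapply(1:3, mk))
}

sweep_cc <- concentration_constraints(fixed = c(A = 1e-3, D = 1e-3))

test_that("ph_sweep: constant tables give a constant MDF; grid rules hold", {
  pw <- toy_sweep_pathway()
  sw <- ph_sweep(pw, sweep_cc, ph_grid = seq(6, 8, by = 0.5))
  expect_equal(length(unique(round(sw$mdf_kj_mol, 9))), 1L)
  # each point equals a fresh solve (no caching drift)
  direct <- solve_mdf(pw, sweep_cc)
  expect_true(all(abs(sw$mdf_kj_mol - direct$mdf) < 1e-9))
  expect_error(ph_sweep(pw, sweep_cc, ph_grid = c(7, 6)), "strictly increasing")
  expect_error(ph_sweep(pw, sweep_cc, ph_grid = c(5, 7)), "outside")
  pw2 <- pathway(list(reaction("R1", "A <=> B", -1)))
  expect_error(ph_sweep(pw2, sweep_cc, 7), "no dg0_by_ph")
})

test_that("ph_sweep: slope bounded by shadow prices; feasibility crossing", {
  # one reaction's dG'0 falls 5.7 kJ/mol per pH unit: the MDF can rise at
  # most w * 5.7 <= 5.7 per unit
  pw <- toy_sweep_pathway(slopes = c(0, -5.7, 0))
  grid <- seq(6, 8, by = 0.25)
  sw <- ph_sweep(pw, sweep_cc, grid)
  slopes <- diff(sw$mdf_kj_mol) / diff(sw$ph)
  expect_true(all(abs(slopes) <= 5.7 + 1e-6))
  # a strongly rising energy drives the pathway infeasible inside the range
  pw2 <- toy_sweep_pathway(slopes = c(0, 19, 0), base = c(-8, -13, -6))
  sw2 <- ph_sweep(pw2, sweep_cc, grid)
  expect_true(sw2$mdf_kj_mol[1] > 0)
  expect_true(sw2$mdf_kj_mol[length(grid)] < 0)
  expect_true(any(diff(sign(sw2$mdf_kj_mol)) != 0))
  # bottleneck annotation matches positive shadow prices at each point
  res <- attr(sw2, "results")[[1]]
  expect_equal(sw2$bottlenecks[1],
               paste(names(which(res$reaction_shadow_prices > 1e-6)),
                     collapse = ";"))
})

test_that("atp_yield follows the P/O-type accounting rules", {
  expect_equal(atp_yield(list(substrate_level_atp = 2,
                              carriers = c(NADH = 2))), 5)
  expect_equal(atp_yield(list(substrate_level_atp = 0,
                              carriers = c(quinol = 1))), 1)
  expect_equal(atp_yield(list()), 0)
  expect_equal(atp_yield(NULL), 0)
  expect_equal(atp_yield(list(substrate_level_atp = 1,
                              carriers = c(NADPH = 1, Fd_pair = 2))), 5.5)
  expect_error(atp_yield(list(substrate_level_atp = 0,
                              carriers = c(FADH2 = 1))), "unknown carrier")
})

test_that("pareto_front: dominance, ties, idempotence, order-invariance", {
  expect_equal(pareto_front(c(1, 2, 0.5), c(1, 0.5, 2)), rep(TRUE, 3))
  expect_equal(pareto_front(c(1, 2), c(1, 2)), c(FALSE, TRUE))
  expect_equal(pareto_front(c(1, 1), c(1, 1)), c(TRUE, TRUE))  # tie rule
  set.seed(31)
  m <- stats::runif(12); y <- stats::runif(12)
  f <- pareto_front(m, y)
  expect_equal(pareto_front(m[f], y[f]), rep(TRUE, sum(f)))    # idempotent
  p <- sample(12)
  expect_equal(pareto_front(m[p], y[p]), f[p])                 # order-invariant
})

test_that("enzyme demand is the reciprocal efficacy, infinite at equilibrium", {
  ch <- make_chain(chain_spec(3, -7.3))
  r <- solve_mdf(ch$pathway, ch$constraints)
  rep <- enzyme_demand_report(r)
  expect_equal(rep$enzyme_factor, 1 / r$efficacy_opt, ignore_attr = TRUE)
  expect_kj(rep$enzyme_factor[1], 1 / 0.90, tol = 0.01)
  ch2 <- make_chain(chain_spec(2, -1, terminal_conc = c(1, exp(2 / RT0))))
  r2 <- solve_mdf(ch2$pathway, ch2$constraints)     # MDF = 0: at equilibrium
  expect_warning(rep2 <- enzyme_demand_report(r2), "equilibrium")
  expect_true(all(is.infinite(rep2$enzyme_factor)))
})

test_that("splitting a step halves per-step dissipation and lowers efficacy", {
  one <- make_chain(chain_spec(1, -2))
  two <- make_chain(chain_spec(2, -1))
  r1 <- solve_mdf(one$pathway, one$constraints)
  r2 <- solve_mdf(two$pathway, two$constraints)
  expect_kj(r1$mdf, 2); expect_kj(r2$mdf, 1)
  expect_kj(r1$efficacy_opt[[1]], 0.38, tol = 0.005)
  expect_kj(r2$efficacy_opt[[1]], 0.20, tol = 0.005)
  expect_lt(max(r2$efficacy_opt), min(r1$efficacy_opt))
})

test_that("compare_pathways flags the Pareto set over solved variants", {
  strong <- make_chain(chain_spec(2, -10))   # high MDF
  weak <- make_chain(chain_spec(2, -2))      # low MDF
  strong$pathway$atp_accounting <- list(substrate_level_atp = 1)
  weak$pathway$atp_accounting <- list(substrate_level_atp = 2,
                                      carriers = c(NADH = 1))
  cmp <- compare_pathways(list(strong = strong, weak = weak))
  expect_equal(cmp$on_pareto_front, c(TRUE, TRUE))  # trade-off: both on front
  weak2 <- make_chain(chain_spec(2, -2))
  weak2$pathway$atp_accounting <- list(substrate_level_atp = 1)
  cmp2 <- compare_pathways(list(strong = strong, weak2 = weak2))
  expect_equal(cmp2$on_pareto_front, c(TRUE, FALSE)) # dominated
})
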