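test_that("closed-form single-reaction and chain optima are reproduced", {
  # A -> B, dG'0 = 0, both in [1 uM, 10 mM]: MDF = RT ln(1e4)
  r <- solve_mdf(single_rxn(0), concentration_constraints())
  expect_kj(r$mdf, RT0 * log(1e4))
  expect_true(r$feasible)
  expect_equal(unname(r$concentrations), c(1e-2, 1e-6), tolerance = 1e-9)

  # +50 kJ/mol makes the pathway infeasible (verdict, not a solver failure)
  r2 <- solve_mdf(single_rxn(50), concentration_constraints())
  expect_equal(r2$solver_status, "optimal")
  expect_kj(r2$mdf, RT0 * log(1e4) - 50)
  expect_false(r2$feasible)

  # symmetric 4-chain: MDF 4, all driving forces equal, w = 0.25 each
  ch <- make_chain(chain_spec(4, -4))
  r3 <- solve_mdf(ch$pathway, ch$constraints)
  expect_kj(r3$mdf, 4)
  expect_equal(unname(r3$driving_forces), rep(4, 4), tolerance = 1e-6)
  expect_equal(unname(r3$reaction_shadow_prices), rep(0.25, 4),
               tolerance = 1e-8)
})

test_that("dual solution: sum(w) = 1, strong duality, complementary slackness", {
  cases <- list(
    solve_mdf(single_rxn(0), concentration_constraints()),
    solve_mdf(make_chain(chain_spec(4, -4))$pathway,
              make_chain(chain_spec(4, -4))$constraints),
    solve_mdf(two_chain()$pathway, two_chain()$constraints))
  for (r in cases) {
    expect_equal(sum(r$reaction_shadow_prices), 1, tolerance = 1e-8)
    expect_kj(r$dual_objective, r$mdf)
    expect_true(all(r$reaction_shadow_prices >= -1e-9))
    expect_true(all(r$u_max >= -1e-9) && all(r$u_min >= -1e-9))
    # w_j > 0 => reaction j at the MDF floor
    lim <- r$reaction_shadow_prices > 1e-6
    expect_true(all(abs(r$driving_forces[lim] - r$mdf) <= 1e-6))
    # u_max > 0 => at upper bound; u_min > 0 => at lower bound (range compounds)
    rng <- !r$bounds$fixed
    up <- r$u_max > 1e-6 & rng
    lo <- r$u_min > 1e-6 & rng
    expect_true(all(abs(r$x_opt[up] - log(r$bounds$upper[up])) <= 1e-6))
    expect_true(all(abs(r$x_opt[lo] - log(r$bounds$lower[lo])) <= 1e-6))
  }
})

test_that("slack reactions and interior compounds get zero shadow price", {
  # second reaction hugely downhill: never limiting
  pw <- pathway(list(reaction("R1", "A <=> B", 0),
                     reaction("R2", "B <=> C", -60)))
  r <- solve_mdf(pw, concentration_constraints())
  expect_lt(r$reaction_shadow_prices[["R2"]], 1e-8)
  ch <- make_chain(chain_spec(4, -4))
  r2 <- solve_mdf(ch$pathway, ch$constraints)
  inter <- paste0("C", 1:3)
  expect_true(all(r2$metabolite_shadow_prices[inter] < 1e-8))
})

test_that("the worked shadow-price arithmetic is reproduced", {
  # 0.25 x 4 kJ/mol -> +1 kJ/mol on the symmetric 4-chain
  ch <- make_chain(chain_spec(4, -4))
  base <- solve_mdf(ch$pathway, ch$constraints)
  sc <- sensitivity_check(ch$pathway, ch$constraints, base,
                          list(type = "reaction", id = "R3", delta = -4))
  expect_kj(sc$predicted, 1)
  expect_kj(sc$recomputed, 1)
  expect_true(sc$agree)

  # 2-chain: metabolite shadow price of A = 0.5; 10-fold upper-bound raise
  # gains 0.5 RT ln 10 ~ 2.85 kJ/mol
  tc <- two_chain()
  r <- solve_mdf(tc$pathway, tc$constraints)
  expect_equal(unname(r$reaction_shadow_prices), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(r$metabolite_shadow_prices[["A"]], 0.5, tolerance = 1e-8)
  sc2 <- sensitivity_check(tc$pathway, tc$constraints, r,
                           list(type = "bound", id = "A", side = "upper",
                                fold = 10))
  expect_kj(sc2$predicted, 0.5 * RT0 * log(10))
  expect_kj(sc2$recomputed, 0.5 * RT0 * log(10))

  # zero shadow price => zero predicted change
  pw <- pathway(list(reaction("R1", "A <=> B", 0),
                     reaction("R2", "B <=> C", -60)))
  r3 <- solve_mdf(pw, concentration_constraints())
  sc3 <- sensitivity_check(pw, concentration_constraints(), r3,
                           list(type = "reaction", id = "R2", delta = -1))
  expect_kj(sc3$predicted, 0)
  expect_kj(sc3$recomputed, 0)
})

test_that("ratio constraints pin log-differences but not absolute levels", {
  cc <- concentration_constraints(
    ratios = data.frame(numerator = "atp", denominator = "adp", ratio = 10))
  pw <- pathway(list(reaction("R1", "A + atp <=> B + adp", -20)))
  r <- solve_mdf(pw, cc)
  expect_equal(r$x_opt[["atp"]] - r$x_opt[["adp"]], log(10), tolerance = 1e-8)
  expect_true(all(r$concentrations >= 1e-6 - 1e-12))
  expect_true(all(r$concentrations <= 1e-2 + 1e-12))
})

test_that("inconsistent constraints fail before solving; conflicts -> status", {
  pw <- single_rxn(0)
  expect_error(
    solve_mdf(pw, concentration_constraints(lower = c(A = 1e-1),
                                            upper = c(A = 1e-3))),
    class = "mdf_constraint_error")
  # ratio equality irreconcilable with the members' boxes -> infeasible set
  cc <- concentration_constraints(
    ratios = data.frame(numerator = "A", denominator = "B", ratio = 1e12))
  r <- solve_mdf(pathway(list(reaction("R1", "A <=> B", 0))), cc)
  expect_equal(r$solver_status, "infeasible_constraints")
})

test_that("MDF is monotone under bound widening and energy relaxation", {
  set.seed(23)
  for (seed in 1:10) {
    inst <- random_instance(n_compounds = 4, n_reactions = 3, seed = seed)
    r <- solve_mdf(inst$pathway, inst$constraints)
    expect_equal(r$solver_status, "optimal")
    wide <- inst$constraints
    wide$default_lower <- 1e-7; wide$default_upper <- 1e-1
    r2 <- solve_mdf(inst$pathway, wide)
    expect_gte(r2$mdf, r$mdf - 1e-9)
    relaxed <- inst$pathway
    relaxed$reactions[[1]]$dg0_prime <- relaxed$reactions[[1]]$dg0_prime - 5
    r3 <- solve_mdf(relaxed, inst$constraints)
    expect_gte(r3$mdf, r$mdf - 1e-9)
  }
})

test_that("reported values are invariant to registration order", {
  rs <- list(reaction("R1", "A <=> B", -3), reaction("R2", "B + X <=> C", 2),
             reaction("R3", "C <=> D + X", -8))
  cc <- concentration_constraints()
  r1 <- solve_mdf(pathway(rs), cc)
  r2 <- solve_mdf(pathway(rs[c(2, 3, 1)]), cc)
  expect_kj(r2$mdf, r1$mdf)
  nm <- names(r1$reaction_shadow_prices)
  expect_equal(r2$reaction_shadow_prices[nm], r1$reaction_shadow_prices[nm],
               tolerance = 1e-8)
  expect_equal(r2$driving_forces[nm], r1$driving_forces[nm], tolerance = 1e-6)
})

test_that("brute-force oracle brackets the LP optimum", {
  ch <- make_chain(chain_spec(4, -4, intermediate_bounds = c(1e-6, 1e2)))
  lp <- solve_mdf(ch$pathway, ch$constraints)
  bf <- brute_force_mdf(ch$pathway, ch$constraints, resolution = 81)
  expect_lte(bf$mdf, lp$mdf + 1e-9)               # grid is a feasible subset
  expect_gte(bf$mdf, lp$mdf - bf$discretization_bound)
  expect_kj(bf$mdf, 4, tol = 0.05)                # fine grid converges
  # all compounds fixed: no free variables, exact minimum driving force
  cc <- concentration_constraints(fixed = c(A = 1e-3, B = 1e-4))
  pw <- single_rxn(0)
  bf2 <- brute_force_mdf(pw, cc)
  expect_kj(bf2$mdf, RT0 * log(10))
  expect_error(brute_force_mdf(make_chain(chain_spec(6, -1))$pathway,
                               make_chain(chain_spec(6, -1))$constraints),
               "too many free")
})

test_that("tie-break selects a maximal-total-driving-force profile", {
  # two independent branches: B's concentration is undetermined at the
  # optimum without a tie-break
  pw <- pathway(list(reaction("R1", "A <=> B", 0),
                     reaction("R2", "C <=> D", -40)))
  cc <- concentration_constraints()
  r <- solve_mdf(pw, cc, tie_break = TRUE)
  expect_equal(r$solver_status, "optimal")
  expect_kj(r$mdf, RT0 * log(1e4))
  # with the floor fixed, total driving force is maximal: R2's reactants hit
  # their extreme bounds too
  expect_equal(r$concentrations[["C"]], 1e-2, tolerance = 1e-8)
  expect_equal(r$concentrations[["D"]], 1e-6, tolerance = 1e-8)
  # and the tie-break never changes the MDF itself
  r0 <- solve_mdf(pw, cc)
  expect_kj(r$mdf, r0$mdf)
})
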