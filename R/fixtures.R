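# Deterministic synthetic pathways with known closed-form optima, plus
# seeded random instances. These are first-class generators (used by the
# test suite and usable from the CLI), not stored fixtures.

#' Specify a linear chain pathway
#'
#' A chain C0 -> C1 -> ... -> Cn with unit molecularities: the canonical
#' geometry for reasoning about max-min driving forces. With both terminal
#' concentrations fixed and wide intermediate bounds the optimum is interior
#' and has a closed form (see [chain_mdf_closed_form()]).
#'
#' @param n_reactions Number of reactions (>= 1).
#' @param dg0 Standard transformed reaction energies, kJ/mol; scalar
#'   (recycled) or length `n_reactions`.
#' @param terminal_conc Length-2 numeric, molar: fixed concentrations of the
#'   first and last compound.
#' @param intermediate_bounds Length-2 numeric, molar: common bounds for the
#'   intermediate compounds (wide by default so they do not bind).
#' @param seed Optional integer recorded in the spec (chains are
#'   deterministic; the seed is provenance only).
#' @return Object of class `chain_spec`.
#' @export
chain_spec <- function(n_reactions, dg0, terminal_conc = c(1, 1),
                       intermediate_bounds = c(1e-12, 1e6), seed = NULL) {
  stopifnot(n_reactions >= 1, length(terminal_conc) == 2,
            all(terminal_conc > 0), length(intermediate_bounds) == 2,
            intermediate_bounds[1] > 0,
            intermediate_bounds[1] <= intermediate_bounds[2])
  dg0 <- rep_len(dg0, n_reactions)
  structure(list(n_reactions = as.integer(n_reactions), dg0 = dg0,
                 terminal_conc = terminal_conc,
                 intermediate_bounds = intermediate_bounds, seed = seed),
            class = "chain_spec")
}

#' Build the pathway and constraints for a chain spec
#'
#' @param spec A [chain_spec()].
#' @return List with `pathway` (an `mdf_pathway`) and `constraints`
#'   (a `conc_constraints`: terminals fixed, intermediates ranged).
#' @export
make_chain <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_reactions
  cids <- paste0("C", 0:n)
  rxns <- lapply(seq_len(n), function(j) {
    reaction(sprintf("R%d", j), paste(cids[j], "<=>", cids[j + 1]),
             dg0_prime = spec$dg0[j])
  })
  pw <- pathway(rxns, metadata = list(
    name = sprintf("chain-%d", n),
    provenance = if (is.null(spec$seed)) "deterministic chain fixture"
                 else sprintf("chain fixture, seed %d", spec$seed)))
  fixed <- c(spec$terminal_conc[1], spec$terminal_conc[2])
  names(fixed) <- c(cids[1], cids[n + 1])
  cc <- concentration_constraints(
    default_lower = spec$intermediate_bounds[1],
    default_upper = spec$intermediate_bounds[2],
    fixed = fixed)
  list(pathway = pw, constraints = cc, spec = spec)
}

#' Closed-form MDF of an interior-optimum chain
#'
#' When both terminals are fixed and no intermediate bound binds, all driving
#' forces are equal at the optimum and
#' `MDF = -(sum(dg0) + RT * (ln c_end - ln c_start)) / n`.
#' The function verifies the interior-optimum geometry by reconstructing the
#' implied optimal log-concentrations and refuses (with a diagnostic) if any
#' intermediate would violate its bounds — in that case the formula does not
#' apply and the LP must be used.
#'
#' @param spec A [chain_spec()].
#' @param constants A [thermo_constants()] object.
#' @return The MDF in kJ/mol.
#' @export
chain_mdf_closed_form <- function(spec, constants = thermo_constants()) {
  stopifnot(inherits(spec, "chain_spec"))
  RT <- constants$RT
  n <- spec$n_reactions
  dx_total <- log(spec$terminal_conc[2]) - log(spec$terminal_conc[1])
  mdf <- -(sum(spec$dg0) + RT * dx_total) / n
  # implied interior profile: x_k = x_{k-1} + (-dg0_k - mdf)/RT
  x <- numeric(n + 1)
  x[1] <- log(spec$terminal_conc[1])
  for (k in seq_len(n)) x[k + 1] <- x[k] + (-spec$dg0[k] - mdf) / RT
  lo <- log(spec$intermediate_bounds[1]); up <- log(spec$intermediate_bounds[2])
  if (n > 1) {
    inner <- x[2:n]
    if (any(inner < lo - 1e-9) || any(inner > up + 1e-9)) {
      stop("interior-optimum geometry violated: implied intermediate ",
           "log-concentrations [", paste(round(inner, 3), collapse = ", "),
           "] leave the bounds [", round(lo, 3), ", ", round(up, 3),
           "]; use solve_mdf()", call. = FALSE)
    }
  }
  mdf
}

#' Random small pathway instance
#'
#' Seeded sparse random stoichiometries (molecularities 1 or 2) with
#' standard energies drawn uniformly from [-30, +10] kJ/mol — a range that
#' straddles feasibility so both verdicts occur. No claim of being
#' physically realizable chemistry; these exist to exercise the solver.
#'
#' @param n_compounds,n_reactions Sizes (1-26 compounds; >= 1 reactions).
#' @param seed Integer seed (mandatory: instances are reproducible).
#' @return List with `pathway` and `constraints` (default physiological
#'   ranges, no cofactors).
#' @export
random_instance <- function(n_compounds = 4, n_reactions = 3, seed) {
  stopifnot(n_compounds >= 2, n_compounds <= 26, n_reactions >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  cids <- letters[seq_len(n_compounds)]
  rxns <- vector("list", n_reactions)
  pick <- function(x) x[sample.int(length(x), 1)]   # sample() scalar gotcha
  for (j in seq_len(n_reactions)) {
    k <- pick(2:min(4, n_compounds))
    ids <- sample(cids, k)
    nsub <- pick(seq_len(k - 1))
    coef <- sample(c(1, 2), k, replace = TRUE) * c(rep(-1, nsub), rep(1, k - nsub))
    dg0 <- round(stats::runif(1, -30, 10), 3)
    rxns[[j]] <- reaction(sprintf("R%d", j), stats::setNames(coef, ids),
                          dg0_prime = dg0)
  }
  pw <- pathway(rxns, metadata = list(
    name = sprintf("random-%d-%d-seed%d", n_compounds, n_reactions, seed),
    provenance = sprintf("random_instance(seed = %d)", seed)))
  list(pathway = pw, constraints = concentration_constraints())
}
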