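# Pathway-level studies on top of the MDF solver.

#' Sweep the MDF across a pH grid
#'
#' Every reaction must carry a `dg0_by_ph` table covering the grid; energies
#' are linearly interpolated between table points (never extrapolated), the
#' LP is re-solved at every grid point, and bottleneck reactions (positive
#' shadow price) are recorded. The package performs no pH transform itself:
#' the tables are the input.
#'
#' @param pw A [pathway()] whose reactions have `dg0_by_ph` tables.
#' @param constraints,constants As in [solve_mdf()].
#' @param ph_grid Strictly increasing numeric vector of pH values.
#' @param bottleneck_tol Shadow prices above this count as bottlenecks
#'   (default 1e-6, the numerical noise floor).
#' @return Object of class `ph_sweep` (a data frame with columns `ph`,
#'   `mdf_kj_mol`, `feasible`, `bottlenecks` (semicolon-joined reaction
#'   ids)), with the per-point `mdf_result`s in attribute `"results"`.
#' @export
ph_sweep <- function(pw, constraints = default_constraints(), ph_grid,
                     constants = thermo_constants(), bottleneck_tol = 1e-6) {
  stopifnot(inherits(pw, "mdf_pathway"), is.numeric(ph_grid),
            length(ph_grid) >= 1)
  if (is.unsorted(ph_grid, strictly = TRUE)) {
    stop("ph_grid must be strictly increasing", call. = FALSE)
  }
  for (r in pw$reactions) {
    if (is.null(r$dg0_by_ph)) {
      stop("reaction ", r$id, " has no dg0_by_ph table", call. = FALSE)
    }
    rng <- range(r$dg0_by_ph$ph)
    out <- ph_grid < rng[1] - 1e-9 | ph_grid > rng[2] + 1e-9
    if (any(out)) {
      stop("pH ", paste(ph_grid[out], collapse = ", "),
           " outside the dg0_by_ph table range [", rng[1], ", ", rng[2],
           "] of reaction ", r$id, " (no extrapolation)", call. = FALSE)
    }
  }
  interp <- function(tab, ph) {
    if (nrow(tab) == 1L) return(tab$dg0_prime)
    stats::approx(tab$ph, tab$dg0_prime, xout = ph, rule = 1)$y
  }
  results <- vector("list", length(ph_grid))
  rows <- vector("list", length(ph_grid))
  for (i in seq_along(ph_grid)) {
    pw_i <- pw
    for (id in names(pw_i$reactions)) {
      pw_i$reactions[[id]]$dg0_prime <-
        interp(pw$reactions[[id]]$dg0_by_ph, ph_grid[i])
    }
    res <- solve_mdf(pw_i, constraints, constants)
    results[[i]] <- res
    bn <- if (res$solver_status == "optimal") {
      names(which(res$reaction_shadow_prices > bottleneck_tol))
    } else character(0)
    rows[[i]] <- data.frame(
      ph = ph_grid[i],
      mdf_kj_mol = if (res$solver_status == "optimal") res$mdf else NA_real_,
      feasible = if (res$solver_status == "optimal") res$feasible else NA,
      bottlenecks = paste(bn, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  class(out) <- c("ph_sweep", class(out))
  out
}

#' ATP yield from a declarative accounting stanza
#'
#' Yield per pathway turn = net substrate-level ATP plus reduced carriers
#' converted via oxidative-phosphorylation P/O-type rules. Default rules:
#' NADH, NADPH or a pair of reduced ferredoxins are each worth 1.5 ATP;
#' a reduced quinone is worth 1.0.
#'
#' @param accounting List with `substrate_level_atp` (numeric, may be 0) and
#'   optionally `carriers` (named counts, e.g. `c(NADH = 2, quinol = 1)`).
#'   `NULL` or empty yields 0.
#' @param po_rules Named ATP-per-carrier rules; unknown carrier names in
#'   `accounting` raise an error.
#' @return ATP yield (numeric scalar).
#' @examples
#' atp_yield(list(substrate_level_atp = 2, carriers = c(NADH = 2))) # 5
#' @export
atp_yield <- function(accounting,
                      po_rules = c(NADH = 1.5, NADPH = 1.5,
                                   Fd_pair = 1.5, quinol = 1.0)) {
  if (is.null(accounting) || !length(accounting)) return(0)
  slp <- accounting$substrate_level_atp
  if (is.null(slp)) slp <- 0
  carriers <- accounting$carriers
  if (is.null(carriers) || !length(carriers)) return(as.numeric(slp))
  carriers <- unlist(carriers)
  unknown <- setdiff(names(carriers), names(po_rules))
  if (length(unknown)) {
    stop("unknown carrier(s) in atp_accounting: ",
         paste(unknown, collapse = ", "), "; known: ",
         paste(names(po_rules), collapse = ", "), call. = FALSE)
  }
  as.numeric(slp) + sum(carriers * po_rules[names(carriers)])
}

#' Pareto front in the (MDF, ATP yield) plane
#'
#' Standard two-objective maximization dominance: a point is on the front
#' iff no other point is >= in both coordinates and > in at least one.
#' Duplicated points do not dominate each other, so ties stay on the front.
#'
#' @param mdf,yield Equal-length finite numeric vectors.
#' @return Logical vector: on the Pareto front.
#' @export
pareto_front <- function(mdf, yield) {
  stopifnot(length(mdf) == length(yield), all(is.finite(mdf)),
            all(is.finite(yield)))
  n <- length(mdf)
  vapply(seq_len(n), function(i) {
    dom <- mdf >= mdf[i] & yield >= yield[i] & (mdf > mdf[i] | yield > yield[i])
    !any(dom)
  }, logical(1))
}

#' Relative enzyme demand implied by an MDF solution
#'
#' For each reaction the factor `1 / efficacy` — the fold-excess of enzyme
#' needed, relative to a fully irreversible enzyme carrying the same net
#' flux, due to capacity wasted on reverse catalysis. A report only (the
#' max-min optimum also minimizes total enzyme mass in a linear chain under
#' equal specific activities, so the report is consistent with the
#' optimization, but no enzyme objective is solved here).
#'
#' @param result An optimal `mdf_result`.
#' @return Data frame with columns `reaction`, `drg_prime_kj_mol`,
#'   `efficacy`, `enzyme_factor`. A reaction at or beyond equilibrium at the
#'   reported optimum (efficacy <= 0) gets an infinite factor, with a
#'   warning.
#' @export
enzyme_demand_report <- function(result) {
  stopifnot(inherits(result, "mdf_result"), result$solver_status == "optimal")
  eff <- result$efficacy_opt
  fac <- ifelse(eff > 0, 1 / eff, Inf)
  if (any(eff <= 0)) {
    warning("reaction(s) at or beyond equilibrium at the reported optimum: ",
            paste(names(eff)[eff <= 0], collapse = ", "),
            "; enzyme factor is infinite", call. = FALSE)
  }
  data.frame(reaction = names(eff),
             drg_prime_kj_mol = unname(result$drg_prime_opt),
             efficacy = unname(eff),
             enzyme_factor = unname(fac),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare pathways by MDF and ATP yield
#'
#' Solves each pathway and flags the Pareto-optimal variants.
#'
#' @param pathways Named list; each element a list with `pathway`,
#'   `constraints` (optional, defaults to [default_constraints()]). ATP
#'   accounting is taken from each pathway's `atp_accounting`.
#' @param constants A [thermo_constants()] object.
#' @param po_rules Passed to [atp_yield()].
#' @return Data frame with `pathway_id`, `mdf_kj_mol`, `atp_yield`,
#'   `on_pareto_front`.
#' @export
compare_pathways <- function(pathways, constants = thermo_constants(),
                             po_rules = c(NADH = 1.5, NADPH = 1.5,
                                          Fd_pair = 1.5, quinol = 1.0)) {
  stopifnot(length(pathways) >= 1)
  ids <- names(pathways)
  if (is.null(ids)) ids <- paste0("pathway", seq_along(pathways))
  rows <- lapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    cc <- if (!is.null(p$constraints)) p$constraints else default_constraints()
    res <- solve_mdf(p$pathway, cc, constants)
    data.frame(pathway_id = ids[i],
               mdf_kj_mol = if (res$solver_status == "optimal") res$mdf else NA_real_,
               atp_yield = atp_yield(p$pathway$atp_accounting, po_rules),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$mdf_kj_mol)
  out$on_pareto_front <- FALSE
  out$on_pareto_front[ok] <- pareto_front(out$mdf_kj_mol[ok], out$atp_yield[ok])
  out
}
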