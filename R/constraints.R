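# Concentration constraints. All user-facing values are molar; natural-log
# transforms happen only inside the solver. Three constraint kinds:
#   range  — default or per-compound [lower, upper] bounds
#   fixed  — concentration pinned (encoded as equal bounds)
#   ratio  — [numerator]/[denominator] pinned: an exact equality on the
#            difference of log-concentrations; the pair's absolute level can
#            still move within each member's range bounds.

#' Concentration constraint set
#'
#' @param default_lower,default_upper Default bounds (molar) applied to every
#'   compound without an override. Physiological defaults are 1e-6 M (1 uM)
#'   and 1e-2 M (10 mM).
#' @param lower,upper Named numeric vectors of per-compound bound overrides
#'   (molar).
#' @param fixed Named numeric vector of fixed concentrations (molar).
#' @param ratios Data frame with columns `numerator`, `denominator`, `ratio`
#'   pinning [num]/[den] = ratio.
#' @return Object of class `conc_constraints`.
#' @export
concentration_constraints <- function(default_lower = 1e-6,
                                      default_upper = 1e-2,
                                      lower = numeric(),
                                      upper = numeric(),
                                      fixed = numeric(),
                                      ratios = NULL) {
  if (is.null(ratios)) {
    ratios <- data.frame(numerator = character(), denominator = character(),
                         ratio = numeric(), stringsAsFactors = FALSE)
  }
  ratios <- as.data.frame(ratios, stringsAsFactors = FALSE)
  stopifnot(default_lower > 0, default_upper >= default_lower,
            all(c("numerator", "denominator", "ratio") %in% names(ratios)))
  cc <- structure(list(default_lower = default_lower,
                       default_upper = default_upper,
                       lower = lower, upper = upper, fixed = fixed,
                       ratios = ratios),
                  class = "conc_constraints")
  validate_constraints(cc)
  cc
}

validate_constraints <- function(cc) {
  err <- function(...) {
    stop(structure(class = c("mdf_constraint_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
  }
  if (length(cc$fixed) && any(cc$fixed <= 0)) err("fixed concentration must be > 0")
  if (length(cc$lower) && any(cc$lower <= 0)) err("lower bounds must be > 0")
  if (nrow(cc$ratios)) {
    if (any(cc$ratios$ratio <= 0)) err("concentration ratio must be > 0")
    rc <- c(cc$ratios$numerator, cc$ratios$denominator)
    both <- intersect(rc, names(cc$fixed))
    if (length(both)) {
      err("compound(s) both fixed and ratio-constrained: ",
          paste(both, collapse = ", "))
    }
  }
  ov <- intersect(names(cc$lower), names(cc$upper))
  bad <- ov[cc$lower[ov] > cc$upper[ov]]
  if (length(bad)) {
    err("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  invisible(cc)
}

#' Physiological default constraints
#'
#' Range 1 uM - 10 mM for ordinary metabolites; cytoplasm-like cofactor
#' constraints: fixed \[orthophosphate\] = 10 mM, \[pyrophosphate\] = 1 mM,
#' \[CoA\] = 1 mM, \[CO2(aq)\] = 10 uM, and pinned ratios ATP/ADP = 10,
#' ADP/AMP = 1, NADH/NAD = 0.1, NADPH/NADP = 10, reduced/oxidized
#' ferredoxin = 1. All values can be overridden via the arguments or a
#' config file.
#'
#' @param ... Overrides forwarded to [concentration_constraints()].
#' @return A `conc_constraints` object.
#' @examples
#' cc <- default_constraints()
#' subset(cc$ratios, numerator == "atp")$ratio # 10
#' @export
default_constraints <- function(...) {
  base <- list(
    default_lower = 1e-6,
    default_upper = 1e-2,
    fixed = c(pi = 1e-2, ppi = 1e-3, coa = 1e-3, co2 = 1e-5),
    ratios = data.frame(
      numerator   = c("atp", "adp", "nadh", "nadph", "fd_red"),
      denominator = c("adp", "amp", "nad",  "nadp",  "fd_ox"),
      ratio       = c(10,    1,     0.1,    10,      1),
      stringsAsFactors = FALSE
    )
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(concentration_constraints, base)
}

# Resolve the constraint set against a compound id vector.
# Returns data.frame(id, lower, upper, fixed) with log bounds attached;
# fixed compounds get lower == upper == value.
resolve_bounds <- function(cc, compound_ids) {
  validate_constraints(cc)
  lo <- rep(cc$default_lower, length(compound_ids))
  up <- rep(cc$default_upper, length(compound_ids))
  names(lo) <- names(up) <- compound_ids
  ov <- intersect(names(cc$lower), compound_ids); lo[ov] <- cc$lower[ov]
  ov <- intersect(names(cc$upper), compound_ids); up[ov] <- cc$upper[ov]
  fx <- intersect(names(cc$fixed), compound_ids)
  lo[fx] <- up[fx] <- cc$fixed[fx]
  if (any(lo > up)) {
    bad <- compound_ids[lo > up]
    stop(structure(class = c("mdf_constraint_error", "error", "condition"),
                   list(message = paste0("lower bound exceeds upper bound for: ",
                                         paste(bad, collapse = ", ")),
                        call = NULL)))
  }
  # a ratio applies only when both members occur in the pathway; with one
  # member absent (e.g. the ADP/AMP default in an AMP-free pathway) the
  # constraint is vacuous and is dropped
  rt <- cc$ratios[cc$ratios$numerator %in% compound_ids &
                    cc$ratios$denominator %in% compound_ids, , drop = FALSE]
  list(bounds = data.frame(id = compound_ids, lower = lo, upper = up,
                           fixed = compound_ids %in% fx,
                           row.names = NULL, stringsAsFactors = FALSE),
       ratios = rt)
}
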