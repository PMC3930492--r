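# Max-min Driving Force LP.
#
# Primal (variables x = log-concentrations, B = common driving-force floor):
#   maximize B
#   s.t.  RT * t(S) x + B <= -G0          (one row per reaction; dual w >= 0)
#         x_i <= ln(Cmax_i)               (range compounds; dual u_max >= 0)
#         x_i >= ln(Cmin_i)               (range compounds; dual u_min >= 0)
#         x_i  = ln(c_i)                  (fixed compounds)
#         x_num - x_den = ln(ratio)       (ratio groups)
#
# B is free, so for consistent bounds the LP is always feasible; a pathway is
# thermodynamically feasible iff the optimum B (the MDF) is positive.
#
# Dual interpretation: w_j is the reaction shadow price (sum(w) = 1 at the
# optimum); the bound duals u_max/u_min come out of the LP in kJ/mol, and the
# unitless metabolite shadow price of the literature is max(|u_max|,|u_min|)
# divided by RT, so that raising a binding upper bound f-fold raises the MDF
# by price * RT * ln(f).

#' Solve the Max-min Driving Force problem
#'
#' Finds metabolite concentrations (within bounds) maximizing the smallest
#' reaction driving force of the pathway, and extracts the dual solution
#' (reaction and metabolite shadow prices).
#'
#' @param pw A [pathway()] object.
#' @param constraints A [concentration_constraints()] object; defaults to the
#'   physiological [default_constraints()].
#' @param constants A [thermo_constants()] object.
#' @param tie_break If `TRUE`, a second LP maximizes the sum of driving
#'   forces subject to the minimum staying at the MDF, selecting one
#'   well-defined profile among the (generally non-unique) optimal
#'   concentration sets. Shadow prices are always taken from the first solve.
#' @return An object of class `mdf_result`; see Details.
#' @details The result list contains: `mdf` (kJ/mol), `solver_status`
#'   (`"optimal"`, `"infeasible_constraints"`, `"numerical_failure"`),
#'   `feasible` (`mdf > 0`), `x_opt` (log molar), `concentrations` (molar),
#'   `drg_prime_opt` and `driving_forces` (kJ/mol), `efficacy_opt`,
#'   `reaction_shadow_prices` (`w`, unitless, summing to 1), `u_max`/`u_min`
#'   (kJ/mol bound duals), `metabolite_shadow_prices` (unitless),
#'   `ratio_duals`, `dual_objective` (kJ/mol), `degenerate` flag, and the
#'   `constants` used.
#' @examples
#' pw <- pathway(list(reaction("R1", "A <=> B", dg0_prime = 0)))
#' res <- solve_mdf(pw, concentration_constraints())
#' res$mdf # RT * ln(1e4) ~ 22.8 kJ/mol
#' @export
solve_mdf <- function(pw, constraints = default_constraints(),
                      constants = thermo_constants(), tie_break = FALSE) {
  stopifnot(inherits(pw, "mdf_pathway"))
  mats <- build_matrices(pw)
  S <- mats$S; G0 <- mats$G0
  rb <- resolve_bounds(constraints, rownames(S))
  bd <- rb$bounds; ratios <- rb$ratios
  RT <- constants$RT

  nc <- nrow(S); nr <- ncol(S)
  nv <- nc + 1L                               # variables: x (nc), B
  cids <- rownames(S); rids <- colnames(S)

  rows <- list(); senses <- character(0); rhs <- numeric(0)
  tag <- character(0)                         # row bookkeeping
  add_row <- function(a, s, b, t) {
    rows[[length(rows) + 1L]] <<- a
    senses[length(senses) + 1L] <<- s
    rhs[length(rhs) + 1L] <<- b
    tag[length(tag) + 1L] <<- t
  }

  for (j in seq_len(nr)) {
    a <- c(RT * S[, j], 1)
    add_row(a, "<=", -G0[j], paste0("rxn:", rids[j]))
  }
  for (i in seq_len(nc)) {
    ei <- c(as.numeric(seq_len(nc) == i), 0)
    if (bd$fixed[i]) {
      add_row(ei, "=", log(bd$lower[i]), paste0("fix:", cids[i]))
    } else {
      add_row(ei, "<=", log(bd$upper[i]), paste0("ub:", cids[i]))
      add_row(ei, ">=", log(bd$lower[i]), paste0("lb:", cids[i]))
    }
  }
  if (nrow(ratios)) {
    for (k in seq_len(nrow(ratios))) {
      a <- numeric(nv)
      a[match(ratios$numerator[k], cids)] <- 1
      a[match(ratios$denominator[k], cids)] <- -1
      add_row(a, "=", log(ratios$ratio[k]),
              paste0("ratio:", ratios$numerator[k], "/", ratios$denominator[k]))
    }
  }
  A <- do.call(rbind, rows)
  obj <- c(rep(0, nc), 1)

  lp <- lp_solve_dense(obj, A, rhs, senses, direction = "max")
  if (lp$status == "infeasible") {
    return(structure(list(solver_status = "infeasible_constraints",
                          mdf = NA_real_, message = "constraint set admits no concentration vector"),
                     class = "mdf_result"))
  }
  if (lp$status != "optimal") {
    return(structure(list(solver_status = "numerical_failure",
                          mdf = NA_real_, message = paste("LP solver status:", lp$status)),
                     class = "mdf_result"))
  }

  mdf <- lp$objective_value
  x <- stats::setNames(lp$solution[seq_len(nc)], cids)

  # dual extraction (always from the primary solve)
  d <- lp$duals
  w <- stats::setNames(pmax(d[seq_len(nr)], 0), rids)
  u_max <- u_min <- stats::setNames(rep(0, nc), cids)
  vr <- numeric(0)
  for (i in seq_along(tag)) {
    t2 <- strsplit(tag[i], ":", fixed = TRUE)[[1]]
    kind <- t2[1]; id <- t2[2]
    if (kind == "ub") u_max[id] <- max(d[i], 0)
    if (kind == "lb") u_min[id] <- max(-d[i], 0)     # >= row has dual <= 0
    if (kind == "fix") {                             # split free dual by sign
      if (d[i] >= 0) u_max[id] <- d[i] else u_min[id] <- -d[i]
    }
    if (kind == "ratio") vr <- c(vr, stats::setNames(d[i], id))
  }

  # dual objective: -w'G0 + u_max' ln(Cmax) - u_min' ln(Cmin) (+ ratio terms)
  lnup <- log(bd$upper); lnlo <- log(bd$lower)
  dual_obj <- -sum(w * G0) + sum(u_max * lnup) - sum(u_min * lnlo)
  if (length(vr)) dual_obj <- dual_obj + sum(vr * log(ratios$ratio))

  if (tie_break) {
    # fix the floor at the MDF, maximize total driving force (equivalently
    # minimize sum_j (S' x)_j); keeps x unique-ish for reporting
    A2 <- rbind(A, c(rep(0, nc), 1))
    rhs2 <- c(rhs, mdf)
    s2 <- c(senses, ">=")
    obj2 <- c(-RT * as.vector(S %*% rep(1, nr)), 0)
    lp2 <- lp_solve_dense(obj2, A2, rhs2, s2, direction = "max")
    if (lp2$status == "optimal") x <- stats::setNames(lp2$solution[seq_len(nc)], cids)
  }

  drg <- compute_drg_prime(G0, S, x, constants)
  active <- sum(abs(A %*% c(x, mdf) - rhs) < 1e-7)
  res <- list(
    solver_status = "optimal",
    mdf = mdf,
    feasible = mdf > 0,
    x_opt = x,
    concentrations = exp(x),
    drg_prime_opt = drg,
    driving_forces = -drg,
    efficacy_opt = flux_force_efficacy(drg, constants),
    reaction_shadow_prices = w,
    u_max = u_max,
    u_min = u_min,
    ratio_duals = vr,
    metabolite_shadow_prices = pmax(abs(u_max), abs(u_min)) / RT,
    dual_objective = dual_obj,
    degenerate = active > nv + 1L,
    tie_break = tie_break,
    bounds = bd,
    ratios = ratios,
    constants = constants
  )
  class(res) <- "mdf_result"
  res
}

#' @export
print.mdf_result <- function(x, ...) {
  cat("<mdf_result>\n")
  if (x$solver_status != "optimal") {
    cat("  status:", x$solver_status, "-", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  MDF = %.4f kJ/mol  (%s)\n", x$mdf,
              if (x$feasible) "thermodynamically feasible"
              else "infeasible: no concentration set gives all reactions a positive driving force"))
  df <- data.frame(drg_prime = round(x$drg_prime_opt, 4),
                   efficacy = round(x$efficacy_opt, 4),
                   shadow_price = round(x$reaction_shadow_prices, 4))
  print(df)
  invisible(x)
}

#' Shadow prices of an MDF solution
#'
#' @param result An optimal `mdf_result`.
#' @return List with `w` (reaction shadow prices, sum to 1), `u_max`, `u_min`
#'   (bound duals, kJ/mol) and `metabolite` (unitless metabolite shadow
#'   prices, `max(|u_max|, |u_min|) / RT`).
#' @export
shadow_prices <- function(result) {
  stopifnot(inherits(result, "mdf_result"), result$solver_status == "optimal")
  list(w = result$reaction_shadow_prices,
       u_max = result$u_max, u_min = result$u_min,
       metabolite = result$metabolite_shadow_prices)
}

#' Shadow-price sensitivity check
#'
#' Compares the first-order MDF change predicted by the shadow prices against
#' a full re-solve after perturbing either one reaction's dG'0 or one
#' compound's concentration bound. Disagreement (which occurs when the
#' perturbation changes the active set) is reported, not raised.
#'
#' @param pw,constraints,constants As in [solve_mdf()].
#' @param result The unperturbed optimal `mdf_result`.
#' @param perturbation A list: either
#'   `list(type = "reaction", id =, delta =)` adding `delta` kJ/mol to that
#'   reaction's dG'0 (predicted MDF change `-w_j * delta`), or
#'   `list(type = "bound", id =, side = "upper"|"lower", fold =)` scaling
#'   that bound by `fold` (predicted change `u_max * ln(fold)` or
#'   `-u_min * ln(fold)`, with the duals in kJ/mol).
#' @return List with `predicted`, `recomputed` (both kJ/mol MDF change) and
#'   `agree` (within 1e-6).
#' @export
sensitivity_check <- function(pw, constraints, result, perturbation,
                              constants = thermo_constants()) {
  stopifnot(inherits(result, "mdf_result"), result$solver_status == "optimal")
  p <- perturbation
  if (p$type == "reaction") {
    stopifnot(p$id %in% names(pw$reactions))
    predicted <- -result$reaction_shadow_prices[[p$id]] * p$delta
    pw2 <- pw
    pw2$reactions[[p$id]]$dg0_prime <- pw2$reactions[[p$id]]$dg0_prime + p$delta
    res2 <- solve_mdf(pw2, constraints, constants)
  } else if (p$type == "bound") {
    side <- match.arg(p$side, c("upper", "lower"))
    bd <- result$bounds
    cur <- bd[[side]][match(p$id, bd$id)]
    predicted <- if (side == "upper") {
      result$u_max[[p$id]] * log(p$fold)
    } else {
      -result$u_min[[p$id]] * log(p$fold)
    }
    cc2 <- constraints
    if (p$id %in% names(cc2$fixed)) {
      cc2$fixed[p$id] <- cur * p$fold
    } else if (side == "upper") {
      cc2$upper[p$id] <- cur * p$fold
    } else {
      cc2$lower[p$id] <- cur * p$fold
    }
    res2 <- solve_mdf(pw, cc2, constants)
  } else {
    stop("perturbation$type must be 'reaction' or 'bound'", call. = FALSE)
  }
  recomputed <- if (res2$solver_status == "optimal") res2$mdf - result$mdf else NA_real_
  list(predicted = unname(predicted), recomputed = unname(recomputed),
       agree = is.finite(recomputed) && abs(predicted - recomputed) <= 1e-6)
}

#' Brute-force grid oracle for the MDF
#'
#' Exhaustive grid search over the free log-concentration variables,
#' independent of the LP machinery; used to verify [solve_mdf()]. Compounds
#' that are fixed contribute no dimension; a ratio-constrained numerator is
#' substituted by its denominator plus `ln(ratio)` (with bounds intersected),
#' so each ratio pair contributes one dimension.
#'
#' @param pw,constraints,constants As in [solve_mdf()].
#' @param resolution Grid points per free dimension (default 41).
#' @param max_free Refuse instances with more free dimensions than this
#'   (default 4): the search is exponential by design.
#' @return List with `mdf` (grid optimum of the minimum driving force,
#'   kJ/mol; always <= the LP optimum + discretization bound), `x_best`, and
#'   `discretization_bound` (kJ/mol).
#' @export
brute_force_mdf <- function(pw, constraints = default_constraints(),
                            constants = thermo_constants(),
                            resolution = 41L, max_free = 4L) {
  mats <- build_matrices(pw)
  S <- mats$S; G0 <- mats$G0; RT <- constants$RT
  rb <- resolve_bounds(constraints, rownames(S))
  bd <- rb$bounds; ratios <- rb$ratios
  cids <- bd$id
  lnlo <- stats::setNames(log(bd$lower), cids)
  lnup <- stats::setNames(log(bd$upper), cids)

  # Tie each ratio numerator to its denominator's class: x_c = x_rep(c) + off_c.
  rep_of <- stats::setNames(cids, cids)
  offset <- stats::setNames(rep(0, length(cids)), cids)
  if (nrow(ratios)) {
    for (k in seq_len(nrow(ratios))) {
      num <- ratios$numerator[k]; den <- ratios$denominator[k]
      if (rep_of[num] == rep_of[den]) next   # already tied (chained ratios)
      delta <- offset[den] + log(ratios$ratio[k]) - offset[num]
      moved <- names(rep_of)[rep_of == rep_of[num]]
      offset[moved] <- offset[moved] + delta
      rep_of[moved] <- rep_of[den]
    }
  }
  fx <- stats::setNames(bd$fixed, cids)
  # representative bounds: intersection of every member's translated box
  reps <- unique(rep_of[!fx])
  rep_lo <- rep_up <- stats::setNames(numeric(length(reps)), reps)
  for (r in reps) {
    members <- names(rep_of)[rep_of == r]
    rep_lo[r] <- max(lnlo[members] - offset[members])
    rep_up[r] <- min(lnup[members] - offset[members])
  }
  free <- reps
  if (length(free) > max_free) {
    stop("too many free concentration variables (", length(free), " > ",
         max_free, ") for brute force", call. = FALSE)
  }
  if (any(rep_lo > rep_up + 1e-12)) {
    stop("inconsistent bounds after ratio substitution", call. = FALSE)
  }

  x <- stats::setNames(rep(NA_real_, length(cids)), cids)
  x[fx] <- log(bd$lower[fx])

  grids <- lapply(free, function(id) seq(rep_lo[id], rep_up[id], length.out = resolution))
  names(grids) <- free
  spacing <- vapply(grids, function(g) if (length(g) > 1) g[2] - g[1] else 0, 0)
  best <- -Inf; xbest <- x

  eval_x <- function(x) min(-(G0 + RT * as.vector(crossprod(S, x))))
  fill <- function(x, vals) {
    for (i in seq_along(free)) {
      members <- names(rep_of)[rep_of == free[i] & !fx]
      x[members] <- vals[i] + offset[members]
    }
    x
  }

  if (!length(free)) {
    best <- eval_x(x); xbest <- x
  } else {
    combos <- do.call(expand.grid, grids)
    for (i in seq_len(nrow(combos))) {
      xi <- fill(x, as.numeric(combos[i, ]))
      v <- eval_x(xi)
      if (v > best) { best <- v; xbest <- xi }
    }
  }
  disc <- if (length(spacing)) max(spacing) * RT * max(colSums(abs(S))) else 0
  list(mdf = best, x_best = xbest, discretization_bound = disc)
}
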