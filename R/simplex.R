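# Dense two-phase primal simplex with Bland's rule and dual extraction.
#
# No LP package can be assumed at runtime, and the MDF linear programs are
# tiny (tens of rows), so the package carries its own solver. All decision
# variables are free (log-concentrations and the max-min bound B), which is
# the only case the MDF formulation needs; free variables are split into
# positive and negative parts internally. Bland's rule guarantees finite
# termination on degenerate problems (fixed concentrations make the MDF LP
# degenerate routinely). After termination the basis is re-factorized once
# with solve() so the reported primal/dual values do not carry tableau
# round-off.

#' Solve a dense linear program with free variables
#'
#' Solves `max/min c'v` subject to `A v (<=|>=|=) b` with all variables free,
#' by a two-phase tableau simplex. Intended for the small, dense LPs arising
#' in max-min driving force analysis; not a general sparse LP code.
#'
#' @param objective Numeric objective coefficient vector (length n).
#' @param A Constraint matrix (m x n).
#' @param b Right-hand side vector (length m).
#' @param sense Character vector of length m with entries `"<="`, `">="`, `"="`.
#' @param direction `"max"` or `"min"`.
#' @param tol Numerical tolerance for pivoting and feasibility (default 1e-9).
#' @param maxit Iteration cap (default 10000).
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objective_value`, `solution` (length n), and
#'   `duals` (length m): `duals[i]` is d(objective optimum)/d(b[i]) in the
#'   stated direction, so for a maximization a `<=` row has a nonnegative
#'   dual and a `>=` row a nonpositive dual.
#' @keywords internal
#' @export
lp_solve_dense <- function(objective, A, b, sense,
                           direction = c("max", "min"),
                           tol = 1e-9, maxit = 10000L) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(objective) == n, length(b) == m, length(sense) == m,
            all(sense %in% c("<=", ">=", "=")))
  if (any(!is.finite(A)) || any(!is.finite(b)) || any(!is.finite(objective))) {
    stop("non-finite values in LP data", call. = FALSE)
  }

  cvec <- if (direction == "max") -objective else objective

  # split free variables: v = p - q, columns [p | q]
  Astd <- cbind(A, -A)
  cstd <- c(cvec, -cvec)
  bstd <- b
  flip <- rep(1, m)                  # accumulated row sign vs. user rows

  # ">=" rows -> "<="
  ge <- sense == ">="
  Astd[ge, ] <- -Astd[ge, , drop = FALSE]
  bstd[ge] <- -bstd[ge]
  flip[ge] <- -1
  sns <- ifelse(sense == "=", "=", "<=")

  # slack columns for inequality rows
  ineq <- which(sns == "<=")
  nslack <- length(ineq)
  Sl <- matrix(0, m, nslack)
  if (nslack) Sl[cbind(ineq, seq_len(nslack))] <- 1
  Astd <- cbind(Astd, Sl)
  cstd <- c(cstd, rep(0, nslack))

  # make rhs nonnegative
  neg <- bstd < 0
  Astd[neg, ] <- -Astd[neg, , drop = FALSE]
  bstd[neg] <- -bstd[neg]
  flip[neg] <- -flip[neg]

  # initial basis: slack columns that survived with +1; others get artificials
  ncore <- 2L * n
  basis <- integer(m)
  need_art <- logical(m)
  for (i in seq_len(m)) {
    if (sns[i] == "<=" && !neg[i]) {
      basis[i] <- ncore + match(i, ineq)
    } else {
      need_art[i] <- TRUE
    }
  }
  nart <- sum(need_art)
  if (nart) {
    Ar <- matrix(0, m, nart)
    Ar[cbind(which(need_art), seq_len(nart))] <- 1
    Astd <- cbind(Astd, Ar)
    cstd <- c(cstd, rep(0, nart))
    basis[need_art] <- ncore + nslack + seq_len(nart)
  }
  ntot <- ncol(Astd)
  art_cols <- if (nart) ncore + nslack + seq_len(nart) else integer(0)

  # tableau T = [B^{-1} A | B^{-1} b]; initial basis is an identity
  Tb <- cbind(Astd, bstd)

  run_phase <- function(Tb, basis, cost, banned, maxit, tol) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(Tb = Tb, basis = basis, status = "iteration_limit"))
      cb <- cost[basis]
      red <- cost - as.vector(crossprod(cb, Tb[, seq_len(ntot), drop = FALSE]))
      red[banned] <- 0            # banned columns may never enter
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- min(enter)             # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, ntot + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      leave <- cand[which.min(basis[cand])]   # Bland tie-break
      piv <- Tb[leave, j]
      Tb[leave, ] <- Tb[leave, ] / piv
      for (i in seq_len(nrow(Tb))) {
        if (i != leave && abs(Tb[i, j]) > 0) {
          Tb[i, ] <- Tb[i, ] - Tb[i, j] * Tb[leave, ]
        }
      }
      basis[leave] <- j
    }
  }

  drop_rows <- integer(0)
  if (nart) {
    c1 <- rep(0, ntot); c1[art_cols] <- 1
    ph1 <- run_phase(Tb, basis, c1, banned = integer(0), maxit = maxit, tol = tol)
    if (ph1$status != "optimal") {
      return(list(status = if (ph1$status == "unbounded") "infeasible" else ph1$status,
                  objective_value = NA_real_, solution = rep(NA_real_, n),
                  duals = rep(NA_real_, m)))
    }
    Tb <- ph1$Tb; basis <- ph1$basis
    if (sum(c1[basis] * Tb[, ntot + 1L]) > 1e-7) {
      return(list(status = "infeasible", objective_value = NA_real_,
                  solution = rep(NA_real_, n), duals = rep(NA_real_, m)))
    }
    # pivot lingering zero-level artificials out of the basis
    for (i in which(basis %in% art_cols)) {
      row <- Tb[i, seq_len(ntot)]
      row[art_cols] <- 0
      j <- which(abs(row) > tol)
      if (length(j)) {
        j <- min(j)
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv
        for (k in seq_len(nrow(Tb))) {
          if (k != i && abs(Tb[k, j]) > 0) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
        }
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)    # redundant row
      }
    }
  }

  ph2 <- run_phase(Tb, basis, cstd, banned = art_cols, maxit = maxit, tol = tol)
  if (ph2$status != "optimal") {
    return(list(status = if (ph2$status == "unbounded") "unbounded" else ph2$status,
                objective_value = NA_real_, solution = rep(NA_real_, n),
                duals = rep(NA_real_, m)))
  }
  basis <- ph2$basis

  # clean re-solve from the final basis (removes tableau drift)
  keep <- setdiff(seq_len(m), drop_rows)
  B <- Astd[keep, basis[keep], drop = FALSE]
  xb <- tryCatch(solve(B, bstd[keep]), error = function(e) NULL)
  yb <- tryCatch(solve(t(B), cstd[basis[keep]]), error = function(e) NULL)
  if (is.null(xb) || is.null(yb)) {
    # singular final basis: fall back to tableau values, duals via least squares
    xb <- Tb[keep, ntot + 1L]
    yb <- qr.coef(qr(t(Astd[keep, basis[keep], drop = FALSE])), cstd[basis[keep]])
    yb[is.na(yb)] <- 0
  }
  vstd <- numeric(ntot)
  vstd[basis[keep]] <- xb
  sol <- vstd[seq_len(n)] - vstd[n + seq_len(n)]
  y <- numeric(m)
  y[keep] <- yb
  obj_min <- sum(cstd * vstd)

  duals_min <- flip * y                       # d(min obj)/d(user b)
  if (direction == "max") {
    list(status = "optimal", objective_value = -obj_min, solution = sol,
         duals = -duals_min)
  } else {
    list(status = "optimal", objective_value = obj_min, solution = sol,
         duals = duals_min)
  }
}
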