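# Pathway data model: reactions with actual molecularities and standard
# transformed Gibbs energies; compounds registered in order of appearance.
# Water and protons are deliberately absent from the model: energies are
# transformed (fixed pH, ionic strength), so their contributions are already
# folded into dg0_prime, and they carry no concentration variable.

#' Define a reaction
#'
#' @param id Short identifier, unique within a pathway.
#' @param formula Either a formula string (see [parse_reaction_formula()]) or
#'   a named numeric stoichiometry vector (substrates negative, products
#'   positive, actual molecularities; forward = net pathway flux direction).
#' @param dg0_prime Standard transformed reaction Gibbs energy dG'0 in
#'   kJ/mol at the pathway's pH and ionic strength. May be `NA` if a
#'   `dg0_by_ph` table is supplied and energies are interpolated later.
#' @param name Free-text name (defaults to `id`).
#' @param dg0_by_ph Optional two-column table (`ph`, `dg0_prime`) for pH
#'   sweeps; linear interpolation between rows, no extrapolation.
#' @return An object of class `mdf_reaction`.
#' @export
reaction <- function(id, formula, dg0_prime = NA_real_, name = id,
                     dg0_by_ph = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- if (is.character(formula)) parse_reaction_formula(formula) else formula
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  if (any(stoich == 0)) stop("zero stoichiometric coefficient in ", id, call. = FALSE)
  if (!any(stoich < 0) || !any(stoich > 0)) {
    stop("reaction ", id, " needs at least one substrate and one product",
         call. = FALSE)
  }
  if (anyDuplicated(names(stoich))) {
    stop("duplicate compound in reaction ", id, call. = FALSE)
  }
  if (!is.null(dg0_by_ph)) {
    dg0_by_ph <- as.data.frame(dg0_by_ph)
    names(dg0_by_ph) <- c("ph", "dg0_prime")
    dg0_by_ph <- dg0_by_ph[order(dg0_by_ph$ph), , drop = FALSE]
    stopifnot(nrow(dg0_by_ph) >= 1L, all(is.finite(dg0_by_ph$ph)),
              all(is.finite(dg0_by_ph$dg0_prime)))
  }
  structure(list(id = id, name = name, stoichiometry = stoich,
                 dg0_prime = as.numeric(dg0_prime), dg0_by_ph = dg0_by_ph),
            class = "mdf_reaction")
}

#' Assemble a pathway model
#'
#' @param reactions List of [reaction()] objects, in pathway order.
#' @param compounds Optional data frame with columns `id`, `name`,
#'   `is_cofactor` pre-registering compounds (and fixing row order of the
#'   stoichiometric matrix). Compounds appearing in reactions but not listed
#'   are appended in order of first appearance.
#' @param metadata Named list; recognized keys include `name`, `ph`,
#'   `ionic_strength`, `temperature`, `provenance`.
#' @param atp_accounting Optional list with `substrate_level_atp` (net ATP
#'   from substrate-level phosphorylation per pathway turn) and `carriers`
#'   (named counts of reduced carriers produced, e.g. `c(NADH = 2)`), used by
#'   [atp_yield()].
#' @return Object of class `mdf_pathway`.
#' @export
pathway <- function(reactions, compounds = NULL, metadata = list(),
                    atp_accounting = NULL) {
  if (!length(reactions)) stop("pathway needs at least one reaction", call. = FALSE)
  stopifnot(all(vapply(reactions, inherits, TRUE, "mdf_reaction")))
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction id: ", rids[duplicated(rids)][1], call. = FALSE)
  }
  reg <- if (is.null(compounds)) {
    data.frame(id = character(), name = character(), is_cofactor = logical(),
               stringsAsFactors = FALSE)
  } else {
    compounds <- as.data.frame(compounds)
    if (is.null(compounds$name)) compounds$name <- compounds$id
    if (is.null(compounds$is_cofactor)) compounds$is_cofactor <- FALSE
    compounds[, c("id", "name", "is_cofactor")]
  }
  if (anyDuplicated(reg$id)) stop("duplicate compound id in registry", call. = FALSE)
  for (r in reactions) {
    new <- setdiff(names(r$stoichiometry), reg$id)
    if (length(new)) {
      reg <- rbind(reg, data.frame(id = new, name = new, is_cofactor = FALSE,
                                   stringsAsFactors = FALSE))
    }
  }
  names(reactions) <- rids
  structure(list(reactions = reactions, compounds = reg, metadata = metadata,
                 atp_accounting = atp_accounting),
            class = "mdf_pathway")
}

#' @export
print.mdf_pathway <- function(x, ...) {
  nm <- x$metadata$name
  cat("<mdf_pathway>", if (!is.null(nm)) nm else "", "\n")
  cat("  ", length(x$reactions), "reactions,", nrow(x$compounds), "compounds\n")
  for (r in x$reactions) {
    cat(sprintf("  %-8s %s   dG'0 = %s kJ/mol\n", r$id,
                format_reaction_formula(r$stoichiometry),
                format(r$dg0_prime)))
  }
  invisible(x)
}

#' Build the stoichiometric matrix and energy vector
#'
#' Returns `S` (compounds x reactions; `S[i, j]` is the signed coefficient of
#' compound i in reaction j) and `G0`, the vector of standard transformed
#' reaction energies, in registration order. Both are deterministic in the
#' order compounds/reactions were registered.
#'
#' @param pw An [pathway()] object.
#' @return List with `S` (dimnamed matrix) and `G0` (named vector, kJ/mol).
#' @export
build_matrices <- function(pw) {
  stopifnot(inherits(pw, "mdf_pathway"))
  cids <- pw$compounds$id
  rids <- names(pw$reactions)
  S <- matrix(0, length(cids), length(rids), dimnames = list(cids, rids))
  G0 <- stats::setNames(rep(NA_real_, length(rids)), rids)
  for (j in seq_along(pw$reactions)) {
    r <- pw$reactions[[j]]
    S[names(r$stoichiometry), j] <- r$stoichiometry
    G0[j] <- r$dg0_prime
  }
  if (any(!is.finite(G0))) {
    stop("missing dg0_prime for reaction(s): ",
         paste(rids[!is.finite(G0)], collapse = ", "), call. = FALSE)
  }
  list(S = S, G0 = G0)
}

#' Transformed reaction energies at given concentrations
#'
#' Computes dG' = G0 + RT * t(S) %*% x, where `x` holds natural-log molar
#' concentrations. The per-reaction driving forces are `-compute_drg_prime(...)`.
#'
#' @param G0 Named vector of standard transformed energies (kJ/mol).
#' @param S Stoichiometric matrix (compounds x reactions).
#' @param x Log-concentration vector (natural log, molar), length `nrow(S)`.
#' @param constants A [thermo_constants()] object.
#' @return Named numeric vector of dG' (kJ/mol), one per reaction.
#' @export
compute_drg_prime <- function(G0, S, x, constants = thermo_constants()) {
  if (length(G0) != ncol(S) || length(x) != nrow(S)) {
    stop("dimension mismatch: length(G0)=", length(G0), ", dim(S)=",
         paste(dim(S), collapse = "x"), ", length(x)=", length(x),
         call. = FALSE)
  }
  stats::setNames(as.vector(G0 + constants$RT * crossprod(S, x)), colnames(S))
}
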