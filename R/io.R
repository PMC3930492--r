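# Pathway/config file readers and report writers.
#
# Canonical pathway file: a YAML document with sections `metadata`,
# `compounds` (optional), `reactions` (formula string + dg0_prime, optional
# dg0_by_ph table), `constraints` (overrides on top of the physiological
# defaults), `atp_accounting`. A TSV dialect carries just the reaction table
# (columns id, formula, dg0_prime_kj_mol). Concentrations are molar in all
# files; logs are internal only.

mdf_parse_error <- function(...) {
  stop(structure(class = c("mdf_parse_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read a pathway file (YAML)
#'
#' @param path Path to a YAML pathway document.
#' @return List with `pathway` (an `mdf_pathway`) and `constraints`
#'   (a `conc_constraints`, the file's overrides merged over
#'   [default_constraints()] unless the file sets
#'   `constraints: {use_physiological_defaults: no}`).
#' @export
read_pathway <- function(path) {
  if (!file.exists(path)) mdf_parse_error("pathway file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) mdf_parse_error(
                    "cannot parse YAML in ", path, ": ", conditionMessage(e)))
  if (is.null(doc$reactions) || !length(doc$reactions)) {
    mdf_parse_error(path, ": no `reactions` section")
  }
  rxns <- lapply(seq_along(doc$reactions), function(k) {
    r <- doc$reactions[[k]]
    if (is.null(r$id) || is.null(r$formula)) {
      mdf_parse_error(path, ": reaction ", k, " needs `id` and `formula`")
    }
    tab <- NULL
    if (!is.null(r$dg0_by_ph)) {
      tab <- do.call(rbind, lapply(r$dg0_by_ph, function(p) {
        p <- unlist(p)
        if (length(p) != 2) mdf_parse_error(path, ": reaction ", r$id,
                                            ": dg0_by_ph entries must be [ph, dg0] pairs")
        data.frame(ph = as.numeric(p[1]), dg0_prime = as.numeric(p[2]))
      }))
    }
    tryCatch(
      reaction(r$id, r$formula,
               dg0_prime = if (is.null(r$dg0_prime)) NA_real_ else as.numeric(r$dg0_prime),
               name = if (is.null(r$name)) r$id else r$name,
               dg0_by_ph = tab),
      error = function(e) mdf_parse_error(path, ": reaction ", r$id, ": ",
                                          conditionMessage(e)))
  })
  comp <- NULL
  if (!is.null(doc$compounds)) {
    comp <- do.call(rbind, lapply(doc$compounds, function(cp) {
      data.frame(id = cp$id,
                 name = if (is.null(cp$name)) cp$id else cp$name,
                 is_cofactor = isTRUE(cp$is_cofactor),
                 stringsAsFactors = FALSE)
    }))
  }
  acc <- doc$atp_accounting
  if (!is.null(acc) && !is.null(acc$carriers)) acc$carriers <- unlist(acc$carriers)
  pw <- tryCatch(
    pathway(rxns, compounds = comp,
            metadata = c(list(name = doc$name), doc$metadata),
            atp_accounting = acc),
    error = function(e) mdf_parse_error(path, ": ", conditionMessage(e)))
  cc <- tryCatch(constraints_from_doc(doc$constraints),
                 error = function(e) {
                   if (inherits(e, "mdf_constraint_error")) {
                     stop(structure(class = class(e),
                                    list(message = paste0(path, ": ", conditionMessage(e)),
                                         call = NULL)))
                   }
                   mdf_parse_error(path, ": constraints: ", conditionMessage(e))
                 })
  list(pathway = pw, constraints = cc)
}

constraints_from_doc <- function(cs) {
  use_defaults <- is.null(cs$use_physiological_defaults) ||
    isTRUE(cs$use_physiological_defaults)
  cc <- if (use_defaults) default_constraints() else concentration_constraints()
  if (is.null(cs)) return(cc)
  if (!is.null(cs$default_lower)) cc$default_lower <- as.numeric(cs$default_lower)
  if (!is.null(cs$default_upper)) cc$default_upper <- as.numeric(cs$default_upper)
  for (b in cs$bounds) {
    if (!is.null(b$lower)) cc$lower[b$id] <- as.numeric(b$lower)
    if (!is.null(b$upper)) cc$upper[b$id] <- as.numeric(b$upper)
  }
  for (f in cs$fixed) cc$fixed[f$id] <- as.numeric(f$value)
  for (r in cs$ratios) {
    hit <- cc$ratios$numerator == r$numerator &
      cc$ratios$denominator == r$denominator
    if (any(hit)) {
      cc$ratios$ratio[hit] <- as.numeric(r$ratio)
    } else {
      cc$ratios <- rbind(cc$ratios,
                         data.frame(numerator = r$numerator,
                                    denominator = r$denominator,
                                    ratio = as.numeric(r$ratio),
                                    stringsAsFactors = FALSE))
    }
  }
  validate_constraints(cc)
  cc
}

#' Read the TSV reaction-table dialect
#'
#' Columns: `id`, `formula`, `dg0_prime_kj_mol` (tab-separated, header row).
#'
#' @param path TSV file path.
#' @return As [read_pathway()] (constraints are the physiological defaults).
#' @export
read_pathway_tsv <- function(path) {
  if (!file.exists(path)) mdf_parse_error("pathway file not found: ", path)
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) mdf_parse_error(path, ": ",
                                                      conditionMessage(e)))
  need <- c("id", "formula", "dg0_prime_kj_mol")
  if (!all(need %in% names(tab))) {
    mdf_parse_error(path, ": TSV needs columns ", paste(need, collapse = ", "))
  }
  rxns <- lapply(seq_len(nrow(tab)), function(k) {
    tryCatch(reaction(tab$id[k], tab$formula[k],
                      dg0_prime = tab$dg0_prime_kj_mol[k]),
             error = function(e) mdf_parse_error(
               path, " line ", k + 1L, " (reaction ", tab$id[k], "): ",
               conditionMessage(e)))
  })
  list(pathway = pathway(rxns, metadata = list(name = basename(path))),
       constraints = default_constraints())
}

#' Read a run configuration file
#'
#' YAML with any of: `temperature` (K), `gas_constant` (kJ/mol/K),
#' `default_lower`, `default_upper` (M), `cofactors` (same grammar as a
#' pathway `constraints` section), `solver` (only `"simplex"` is shipped),
#' `tie_break`, `outdir`, `verbosity`. Missing file or `NULL` path gives the
#' shipped defaults, which reproduce the physiological constraint set.
#'
#' @param path YAML config path or `NULL`.
#' @return Object of class `mdf_config`: list with `constants`,
#'   `constraints`, `solver`, `tie_break`, `outdir`, `verbosity`,
#'   `provenance`.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(constants = thermo_constants(),
              constraints = default_constraints(),
              solver = "simplex", tie_break = FALSE,
              outdir = ".", verbosity = 1L,
              provenance = "built-in defaults")
  if (!is.null(path)) {
    if (!file.exists(path)) mdf_parse_error("config file not found: ", path)
    doc <- yaml::read_yaml(path)
    R <- if (is.null(doc$gas_constant)) 8.314e-3 else as.numeric(doc$gas_constant)
    Tt <- if (is.null(doc$temperature)) 298.15 else as.numeric(doc$temperature)
    cfg$constants <- thermo_constants(R, Tt)
    cs <- doc$cofactors
    if (!is.null(doc$default_lower)) cs$default_lower <- doc$default_lower
    if (!is.null(doc$default_upper)) cs$default_upper <- doc$default_upper
    cfg$constraints <- constraints_from_doc(cs)
    if (!is.null(doc$solver)) {
      if (!identical(doc$solver, "simplex")) {
        mdf_parse_error(path, ": unknown solver ", sQuote(doc$solver),
                        "; available: simplex")
      }
      cfg$solver <- doc$solver
    }
    if (!is.null(doc$tie_break)) cfg$tie_break <- isTRUE(doc$tie_break)
    if (!is.null(doc$outdir)) cfg$outdir <- doc$outdir
    if (!is.null(doc$verbosity)) cfg$verbosity <- as.integer(doc$verbosity)
    cfg$provenance <- path
  }
  structure(cfg, class = "mdf_config")
}

#' Write an MDF report (JSON + TSV projections)
#'
#' The JSON file is the canonical report (full double precision, units in
#' field names); re-reading it reproduces every numeric field bit-exactly.
#' Two TSVs project the per-reaction and per-compound tables.
#'
#' @param result An optimal `mdf_result`.
#' @param pw The solved pathway.
#' @param prefix Output path prefix; writes `<prefix>.json`,
#'   `<prefix>_reactions.tsv`, `<prefix>_compounds.tsv`.
#' @return Invisibly, the report list.
#' @export
write_mdf_report <- function(result, pw, prefix) {
  stopifnot(inherits(result, "mdf_result"), result$solver_status == "optimal")
  mats <- build_matrices(pw)
  rids <- colnames(mats$S); cids <- rownames(mats$S)
  rep <- list(
    mdf_kj_mol = result$mdf,
    feasible = result$feasible,
    solver_status = result$solver_status,
    degenerate = result$degenerate,
    constants = list(gas_constant_R = result$constants$R,
                     temperature_T = result$constants$T,
                     RT_kj_mol = result$constants$RT),
    reactions = lapply(rids, function(id) list(
      id = id,
      dg0_prime_kj_mol = unname(mats$G0[[id]]),
      drg_prime_opt_kj_mol = unname(result$drg_prime_opt[[id]]),
      driving_force_kj_mol = unname(result$driving_forces[[id]]),
      efficacy = unname(result$efficacy_opt[[id]]),
      shadow_price = unname(result$reaction_shadow_prices[[id]]))),
    compounds = lapply(cids, function(id) {
      i <- match(id, result$bounds$id)
      list(id = id,
           concentration_m = unname(result$concentrations[[id]]),
           log_concentration = unname(result$x_opt[[id]]),
           lower_m = result$bounds$lower[i],
           upper_m = result$bounds$upper[i],
           fixed = result$bounds$fixed[i],
           shadow_price = unname(result$metabolite_shadow_prices[[id]]))
    }))
  # I(17) = 17 *significant* digits: doubles round-trip bit-exactly
  jsonlite::write_json(rep, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  rx <- do.call(rbind, lapply(rep$reactions, as.data.frame))
  cp <- do.call(rbind, lapply(rep$compounds, as.data.frame))
  utils::write.table(rx, paste0(prefix, "_reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cp, paste0(prefix, "_compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(rep)
}
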