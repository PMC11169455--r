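#' Objective vector for net production of a metabolite
#'
#' Linear coefficients over reactions equal to the summed stoichiometric
#' coefficients of the target species in each reaction, so maximising the
#' objective maximises net flux into the target. Metabolite ids matching the
#' target exactly, or the target plus a compartment suffix (e.g. `TMP`,
#' `TMP_p`, `TMP_c`), are pooled.
#'
#' @param model A `thiamsim_model`.
#' @param target Metabolite id or id stem (default `"TMP"`).
#' @return Named numeric vector over reaction ids.
#' @export
objective_net_production <- function(model, target = "TMP") {
  mids <- metabolite_ids(model)
  hit <- mids == target | startsWith(mids, paste0(target, "_"))
  if (!any(hit))
    stop("no metabolite matches target '", target, "'")
  N <- stoich_matrix(model)
  obj <- colSums(N[hit, , drop = FALSE])
  stats::setNames(obj, reaction_ids(model))
}

#' Build a stoichiometric (flux-balance) model
#'
#' Assembles the steady-state constraint N v = 0 over internal metabolites
#' (boundary/clamped species are excluded from the constraint, acting as
#' unbalanced reservoirs), box flux bounds, and a linear objective. Bounds
#' must be finite; the defaults are [0, 1000] for irreversible and
#' [-1000, 1000] for reversible reactions (nmol L^-1 s^-1).
#'
#' @param model A `thiamsim_model`.
#' @param lower,upper Optional named numeric vectors overriding default
#'   bounds for specific reaction ids.
#' @param objective Named numeric vector over reaction ids (missing entries
#'   are 0), or `NULL` for the default: maximise net production of `target`.
#' @param target Target metabolite stem for the default objective.
#' @param default_cap Magnitude of the default flux bounds.
#' @return An object of class `thiamsim_stoich` with components `N`
#'   (internal metabolites x reactions), `lower`, `upper`, `objective`.
#' @export
build_stoich <- function(model, lower = NULL, upper = NULL, objective = NULL,
                         target = "TMP", default_cap = 1000) {
  rids <- reaction_ids(model)
  rev <- vapply(model$reactions, `[[`, TRUE, "reversible")
  lb <- stats::setNames(ifelse(rev, -default_cap, 0), rids)
  ub <- stats::setNames(rep(default_cap, length(rids)), rids)
  check_named <- function(x, what) {
    if (is.null(x)) return(NULL)
    unknown <- setdiff(names(x), rids)
    if (length(unknown) > 0L)
      stop(what, " references unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    x
  }
  lower <- check_named(lower, "lower bounds")
  upper <- check_named(upper, "upper bounds")
  if (!is.null(lower)) lb[names(lower)] <- lower
  if (!is.null(upper)) ub[names(upper)] <- upper
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("flux bounds must be finite")
  if (is.null(objective)) objective <- objective_net_production(model, target)
  objective <- check_named(objective, "objective")
  obj <- stats::setNames(rep(0, length(rids)), rids)
  obj[names(objective)] <- objective
  structure(list(N = stoich_matrix(model, internal_only = TRUE),
                 lower = lb, upper = ub, objective = obj,
                 reaction_ids = rids),
            class = "thiamsim_stoich")
}

#' Solve a flux-balance linear programme
#'
#' Maximises the objective subject to N v = 0 (internal metabolites) and the
#' box bounds, via the two-phase simplex method ([boot::simplex()]) after
#' shifting fluxes by their lower bounds so all variables are non-negative.
#'
#' @param stoich A `thiamsim_stoich` from [build_stoich()].
#' @return A `thiamsim_flux` list: `flux` (named vector), `objective_value`,
#'   `status` (`"optimal"`, `"infeasible"`, or `"not_converged"`).
#'   Infeasibility is a status, never an error.
#' @export
solve_fba <- function(stoich) {
  rids <- stoich$reaction_ids
  lb <- stoich$lower; ub <- stoich$upper
  empty <- function(status)
    structure(list(flux = stats::setNames(rep(NA_real_, length(rids)), rids),
                   objective_value = NA_real_, status = status),
              class = "thiamsim_flux")
  if (any(lb > ub)) return(empty("infeasible"))
  # shift x = v - lb >= 0; N v = 0 becomes N x = -N lb; v <= ub becomes x <= ub - lb
  A3 <- stoich$N
  b3 <- as.numeric(-A3 %*% lb)
  # boot::simplex requires non-negative right-hand sides
  flip <- b3 < 0
  if (any(flip)) { A3[flip, ] <- -A3[flip, , drop = FALSE]; b3[flip] <- -b3[flip] }
  A1 <- diag(length(rids))
  b1 <- ub - lb
  res <- if (nrow(A3) > 0L)
    boot::simplex(a = stoich$objective, A1 = A1, b1 = b1,
                  A3 = A3, b3 = b3, maxi = TRUE,
                  n.iter = 50L * (length(rids) + nrow(A3)), eps = 1e-10)
  else
    boot::simplex(a = stoich$objective, A1 = A1, b1 = b1, maxi = TRUE,
                  n.iter = 50L * length(rids), eps = 1e-10)
  status <- switch(as.character(res$solved),
                   "1" = "optimal", "-1" = "infeasible", "not_converged")
  if (status != "optimal") return(empty(status))
  flux <- stats::setNames(as.numeric(res$soln[seq_along(rids)]) + lb, rids)
  structure(list(flux = flux,
                 objective_value = sum(stoich$objective * flux),
                 status = status),
            class = "thiamsim_flux")
}

#' @export
print.thiamsim_flux <- function(x, ...) {
  cat("<thiamsim flux solution>", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Gap-fill kinetic parameters from a flux-balance solution
#'
#' Each reaction flagged `needs_fba` receives a kinetic law whose rate at the
#' model's initial concentrations equals its predicted steady-state flux:
#' either an MM1 law with the configured `km_default` and Vmax back-solved as
#' flux (km + S0) / S0 over the reaction's first substrate (the default,
#' which keeps the gap-filled step responsive to substrate depletion), or a
#' `constant_flux` law carrying the flux directly. Reactions with zero
#' predicted flux always become `constant_flux` 0. The `needs_fba` flags are
#' cleared.
#'
#' @param model A `thiamsim_model`.
#' @param flux_solution A `thiamsim_flux` with status `"optimal"` covering
#'   every `needs_fba` reaction.
#' @param km_default Km (nmol/L) for back-solved MM1 laws.
#' @param mode `"mm1"` (default) or `"constant_flux"`; may be a named
#'   character vector keyed by reaction id to switch per reaction.
#' @return A new `thiamsim_model` with every law parameterised.
#' @export
gapfill_parameters <- function(model, flux_solution, km_default = 10,
                               mode = "mm1") {
  if (!inherits(flux_solution, "thiamsim_flux") ||
      flux_solution$status != "optimal")
    stop("gapfill_parameters requires an optimal flux solution")
  stopifnot(km_default > 0)
  problems <- character()
  model$reactions <- lapply(model$reactions, function(r) {
    if (!r$needs_fba) return(r)
    if (!r$id %in% names(flux_solution$flux)) {
      problems <<- c(problems, paste0("no predicted flux for reaction '", r$id, "'"))
      return(r)
    }
    f <- flux_solution$flux[[r$id]]
    m <- if (length(mode) > 1L || !is.null(names(mode)))
      (if (r$id %in% names(mode)) mode[[r$id]] else "mm1") else mode
    if (f < -1e-9) {
      problems <<- c(problems, paste0("reaction '", r$id,
        "': negative predicted flux (", format(f),
        ") cannot be expressed as an irreversible law"))
      return(r)
    }
    if (abs(f) <= 1e-9 || m == "constant_flux") {
      r$law <- kinetic_law("constant_flux", k = max(f, 0))
    } else {
      sub <- names(r$stoichiometry)[r$stoichiometry < 0]
      if (length(sub) == 0L) {
        problems <<- c(problems, paste0("reaction '", r$id,
          "': no consumed metabolite to anchor an MM1 law"))
        return(r)
      }
      s0 <- initial_state(model)[[sub[1L]]]
      if (s0 <= 0) {
        problems <<- c(problems, paste0("reaction '", r$id,
          "': zero initial concentration of substrate '", sub[1L],
          "' with nonzero predicted flux (", format(f), ") is unsatisfiable"))
        return(r)
      }
      r$law <- kinetic_law("MM1", substrate_ids = sub[1L],
                           vmax = f * (km_default + s0) / s0, km = km_default)
    }
    r$needs_fba <- FALSE
    r
  })
  if (length(problems) > 0L)
    stop("gap-fill failed:\n  ", paste(problems, collapse = "\n  "))
  model
}
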