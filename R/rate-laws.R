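# Solver excursion tolerance: states in (-NEG_CLAMP, 0) are treated as 0,
# anything below -NEG_CLAMP aborts the evaluation.
NEG_CLAMP <- 1e-9

#' Single-substrate Michaelis--Menten rate
#'
#' v = Vmax * S / (Km + S): 0 at S = 0, Vmax/2 at S = Km, and approaching
#' Vmax as S grows; strictly increasing and strictly below Vmax for finite S.
#'
#' @param vmax Maximal rate (nmol L^-1 s^-1), > 0.
#' @param km Michaelis constant (nmol/L), > 0.
#' @param s Substrate concentration (nmol/L), >= 0. Vectorised over `s`.
#' @return Rate(s) in nmol L^-1 s^-1.
#' @export
rate_mm1 <- function(vmax, km, s) {
  if (!is.numeric(vmax) || vmax <= 0 || !is.numeric(km) || km <= 0)
    stop("rate_mm1: vmax and km must be strictly positive")
  if (any(s < 0)) stop("rate_mm1: negative substrate concentration")
  vmax * s / (km + s)
}

#' Two-substrate Michaelis--Menten rate
#'
#' The default random-order ternary-complex (double-hyperbolic) form
#' v = Vmax A B / ((KmA + A)(KmB + B)); `variant = "pingpong"` gives
#' v = Vmax A B / (KmB A + KmA B + A B). Both are 0 if either substrate is
#' absent and approach Vmax when both saturate.
#'
#' @param vmax Maximal rate, > 0.
#' @param km_a,km_b Michaelis constants for substrates A and B, > 0.
#' @param a,b Substrate concentrations, >= 0.
#' @param variant `"ternary"` (default) or `"pingpong"`.
#' @return Rate in nmol L^-1 s^-1.
#' @export
rate_mm2 <- function(vmax, km_a, km_b, a, b, variant = c("ternary", "pingpong")) {
  variant <- match.arg(variant)
  if (!is.numeric(vmax) || vmax <= 0 || km_a <= 0 || km_b <= 0)
    stop("rate_mm2: vmax, km_a and km_b must be strictly positive")
  if (any(a < 0) || any(b < 0)) stop("rate_mm2: negative substrate concentration")
  if (variant == "ternary")
    vmax * a * b / ((km_a + a) * (km_b + b))
  else {
    denom <- km_b * a + km_a * b + a * b
    ifelse(denom == 0, 0, vmax * a * b / denom)
  }
}

#' Mass-action rate
#'
#' v = k * prod(substrates); first-order for single-substrate transport steps.
#'
#' @param k Rate constant, >= 0 (units depend on the reaction order).
#' @param substrates Numeric vector of substrate concentrations, >= 0.
#' @return Rate in nmol L^-1 s^-1.
#' @export
rate_mass_action <- function(k, substrates) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("rate_mass_action: k must be a single non-negative number")
  if (any(substrates < 0))
    stop("rate_mass_action: negative substrate concentration")
  k * prod(substrates)
}

# evaluate one law against a named concentration vector
.eval_law <- function(law, conc) {
  # a scaled-to-zero Vmax encodes a knockout: the reaction is silent
  if (law$law_type %in% c("MM1", "MM2") && law$vmax == 0) return(0)
  switch(law$law_type,
    MM1 = rate_mm1(law$vmax, law$km, conc[[law$substrate_ids[1L]]]),
    MM2 = rate_mm2(law$vmax, law$km_a, law$km_b,
                   conc[[law$substrate_ids[1L]]], conc[[law$substrate_ids[2L]]],
                   variant = law$variant),
    mass_action = rate_mass_action(law$k, unname(conc[law$substrate_ids])),
    constant_flux = law$k,
    stop("unknown law type: ", law$law_type))
}

#' Evaluate all reaction rates at a concentration state
#'
#' Dispatches each reaction to its rate law. Small negative excursions (above
#' -1e-9 nmol/L, the stiff-solver tolerance) are clamped to 0 before
#' evaluation; larger negative values or non-finite states abort with an
#' integration-failure error naming the offending metabolite.
#'
#' @param model A `thiamsim_model` with all laws parameterised.
#' @param conc Named numeric vector of concentrations in model metabolite
#'   order (names optional; order is authoritative).
#' @return Numeric rate vector ordered as `model$reactions`, named by
#'   reaction id.
#' @export
evaluate_rates <- function(model, conc) {
  ids <- metabolite_ids(model)
  if (length(conc) != length(ids))
    stop("evaluate_rates: state length ", length(conc),
         " does not match ", length(ids), " metabolites")
  conc <- stats::setNames(as.numeric(conc), ids)
  if (any(!is.finite(conc))) {
    bad <- ids[!is.finite(conc)][1L]
    stop("evaluate_rates: non-finite concentration for metabolite '", bad,
         "' (integration failure)")
  }
  if (any(conc < -NEG_CLAMP)) {
    bad <- ids[conc < -NEG_CLAMP][1L]
    stop("evaluate_rates: concentration of '", bad, "' below -",
         format(NEG_CLAMP), " nmol/L (integration failure)")
  }
  conc[conc < 0] <- 0
  rates <- vapply(model$reactions, function(r) {
    if (r$needs_fba || is.null(r$law))
      stop("evaluate_rates: reaction '", r$id,
           "' has no kinetic law (unresolved needs_fba flag)")
    .eval_law(r$law, conc)
  }, numeric(1L))
  stats::setNames(rates, reaction_ids(model))
}

#' Stoichiometric matrix of a model
#'
#' @param model A `thiamsim_model`.
#' @param internal_only If `TRUE`, drop rows for boundary (clamped) species.
#' @return Numeric matrix, metabolites x reactions, with signed coefficients.
#' @export
stoich_matrix <- function(model, internal_only = FALSE) {
  mids <- metabolite_ids(model)
  rids <- reaction_ids(model)
  N <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    N[names(st), j] <- unname(st)
  }
  if (internal_only) N <- N[setdiff(mids, boundary_ids(model)), , drop = FALSE]
  N
}
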