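COMPARTMENTS <- c("plastid", "cytosol", "mitochondrion", "external")
LAW_TYPES <- c("MM1", "MM2", "mass_action", "constant_flux")

#' Create a metabolite
#'
#' A metabolite is a chemical species with a compartment label and an initial
#' amount concentration. Compartments are labels only: all concentrations are
#' expressed in a common unit (nmol/L) and transport between compartments is
#' modelled as ordinary reactions, because compartment volumes are not part of
#' the model.
#'
#' @param id Short unique ASCII token (case-sensitive), e.g. `"TMP_c"`.
#' @param name Free-text display name (may carry unicode).
#' @param compartment One of `"plastid"`, `"cytosol"`, `"mitochondrion"`,
#'   `"external"`.
#' @param initial_conc Non-negative initial concentration in nmol/L.
#' @param boundary Logical; `TRUE` clamps the species at its initial value
#'   during simulation (boundary/reservoir species such as external feeds).
#' @return An object of class `thiamsim_metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "cytosol",
                       initial_conc = 0, boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!compartment %in% COMPARTMENTS)
    stop("unknown compartment '", compartment, "' for metabolite '", id,
         "'; must be one of: ", paste(COMPARTMENTS, collapse = ", "))
  if (!is.numeric(initial_conc) || length(initial_conc) != 1L ||
      is.na(initial_conc) || initial_conc < 0)
    stop("initial_conc for metabolite '", id, "' must be a single non-negative number")
  structure(list(id = id, name = name, compartment = compartment,
                 initial_conc = as.numeric(initial_conc),
                 boundary = isTRUE(boundary)),
            class = "thiamsim_metabolite")
}

#' Create a kinetic rate law
#'
#' Supported law types:
#' \describe{
#'   \item{MM1}{single-substrate Michaelis--Menten, v = Vmax S / (Km + S).}
#'   \item{MM2}{two-substrate law over substrates A and B. The default
#'     `variant = "ternary"` is the random-order ternary-complex
#'     (double-hyperbolic) form v = Vmax A B / ((KmA + A)(KmB + B));
#'     `variant = "pingpong"` selects
#'     v = Vmax A B / (KmB A + KmA B + A B) per reaction.}
#'   \item{mass_action}{v = k * prod(substrate concentrations); first-order
#'     for single-substrate transport steps.}
#'   \item{constant_flux}{fixed rate `k`, independent of state.}
#' }
#'
#' @param law_type One of `"MM1"`, `"MM2"`, `"mass_action"`, `"constant_flux"`.
#' @param substrate_ids Ordered character vector of substrate metabolite ids;
#'   length must match the law arity (MM1: 1, MM2: 2, mass_action: >= 1,
#'   constant_flux: 0).
#' @param vmax Maximal rate (nmol L^-1 s^-1), strictly positive, MM laws only.
#' @param km Michaelis constant (nmol/L), strictly positive, MM1 only.
#' @param km_a,km_b Michaelis constants for substrates A and B, MM2 only.
#' @param k Rate constant (mass_action, >= 0) or fixed flux (constant_flux).
#' @param variant Two-substrate mechanism, `"ternary"` or `"pingpong"`.
#' @return An object of class `thiamsim_law`.
#' @export
kinetic_law <- function(law_type, substrate_ids = character(),
                        vmax = NA_real_, km = NA_real_,
                        km_a = NA_real_, km_b = NA_real_, k = NA_real_,
                        variant = c("ternary", "pingpong")) {
  law_type <- match.arg(law_type, LAW_TYPES)
  variant <- match.arg(variant)
  substrate_ids <- as.character(substrate_ids)
  pos <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
  arity_ok <- switch(law_type,
    MM1 = length(substrate_ids) == 1L,
    MM2 = length(substrate_ids) == 2L,
    mass_action = length(substrate_ids) >= 1L,
    constant_flux = length(substrate_ids) == 0L)
  if (!arity_ok)
    stop("law_type ", law_type, " requires ",
         switch(law_type, MM1 = "exactly 1 substrate", MM2 = "exactly 2 substrates",
                mass_action = "at least 1 substrate", constant_flux = "no substrates"),
         ", got ", length(substrate_ids))
  if (law_type == "MM1" && !(pos(vmax) && pos(km)))
    stop("MM1 law requires vmax > 0 and km > 0")
  if (law_type == "MM2" && !(pos(vmax) && pos(km_a) && pos(km_b)))
    stop("MM2 law requires vmax > 0, km_a > 0 and km_b > 0")
  if (law_type %in% c("mass_action", "constant_flux") &&
      !(is.numeric(k) && length(k) == 1L && !is.na(k) && k >= 0))
    stop(law_type, " law requires k >= 0")
  structure(list(law_type = law_type, substrate_ids = substrate_ids,
                 vmax = as.numeric(vmax), km = as.numeric(km),
                 km_a = as.numeric(km_a), km_b = as.numeric(km_b),
                 k = as.numeric(k), variant = variant),
            class = "thiamsim_law")
}

#' Create a reaction
#'
#' @param id Short unique ASCII token.
#' @param enzyme Enzyme label (e.g. `"THIC"`, `"THI1"`, `"TH1"`, `"TH2"`,
#'   `"TDPK"`, `"THiM"`, `"transport"`). Several reactions may share a label
#'   (bifunctional enzymes): perturbations scale them together.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed, positive = produced).
#' @param law A [kinetic_law()], or `NULL` when `needs_fba = TRUE`.
#' @param reversible Logical.
#' @param needs_fba Logical; `TRUE` marks a reaction whose kinetics are unknown
#'   and must be gap-filled from a flux-balance solution
#'   (see [gapfill_parameters()]).
#' @return An object of class `thiamsim_reaction`.
#' @export
reaction <- function(id, enzyme, stoichiometry, law = NULL,
                     reversible = FALSE, needs_fba = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named numeric vector")
  if (needs_fba && !is.null(law))
    stop("reaction '", id, "': needs_fba reactions must not carry a kinetic law")
  if (!needs_fba && is.null(law))
    stop("reaction '", id, "': a kinetic law is required unless needs_fba = TRUE")
  if (!is.null(law) && !inherits(law, "thiamsim_law"))
    stop("reaction '", id, "': law must be a kinetic_law()")
  structure(list(id = id, enzyme = as.character(enzyme),
                 stoichiometry = stoichiometry, law = law,
                 reversible = isTRUE(reversible), needs_fba = isTRUE(needs_fba)),
            class = "thiamsim_reaction")
}

#' Assemble a pathway model
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param metadata Free-form provenance list.
#' @param check If `TRUE` (default), stop on any structural violation
#'   (see [validate_model()]).
#' @return An object of class `thiamsim_model` with components `metabolites`,
#'   `reactions`, `metadata`; `boundary_ids(model)`, `n_reactions(model)` and
#'   `n_metabolites(model)` query it.
#' @export
pathway_model <- function(metabolites, reactions, metadata = list(), check = TRUE) {
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          metadata = metadata),
                     class = "thiamsim_model")
  if (check) {
    rep <- validate_model(model)
    if (nrow(rep) > 0L)
      stop("invalid pathway model:\n  ",
           paste(rep$message, collapse = "\n  "))
  }
  model
}

#' @rdname pathway_model
#' @param model A `thiamsim_model`.
#' @export
n_reactions <- function(model) length(model$reactions)

#' @rdname pathway_model
#' @export
n_metabolites <- function(model) length(model$metabolites)

#' @rdname pathway_model
#' @export
metabolite_ids <- function(model) vapply(model$metabolites, `[[`, "", "id")

#' @rdname pathway_model
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' @rdname pathway_model
#' @export
boundary_ids <- function(model) {
  ids <- metabolite_ids(model)
  ids[vapply(model$metabolites, `[[`, TRUE, "boundary")]
}

#' @rdname pathway_model
#' @export
enzyme_labels <- function(model) unique(vapply(model$reactions, `[[`, "", "enzyme"))

#' Initial concentration vector of a model
#'
#' @param model A `thiamsim_model`.
#' @return Named numeric vector in metabolite order (nmol/L).
#' @export
initial_state <- function(model) {
  stats::setNames(vapply(model$metabolites, `[[`, 0, "initial_conc"),
                  metabolite_ids(model))
}

#' @export
print.thiamsim_model <- function(x, ...) {
  cat("<thiamsim pathway model>\n")
  cat("  metabolites:", n_metabolites(x),
      sprintf("(%d clamped)", length(boundary_ids(x))), "\n")
  cat("  reactions:  ", n_reactions(x),
      sprintf("(%d awaiting FBA gap-fill)",
              sum(vapply(x$reactions, `[[`, TRUE, "needs_fba"))), "\n")
  cat("  enzymes:    ", paste(enzyme_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Validate the structural invariants of a pathway model
#'
#' Checks referential integrity (every metabolite referenced by a
#' stoichiometry or a rate law exists), id uniqueness, compartment labels,
#' non-negative initial concentrations, law arity, parameter positivity, the
#' consistency between `needs_fba` flags and missing laws, and that every
#' substrate of a law appears with a negative stoichiometric coefficient.
#' Violations are report rows, never exceptions; the model is not mutated.
#'
#' @param model A `thiamsim_model`.
#' @return A data.frame with columns `rule`, `object`, `message`; zero rows
#'   means the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(rule, object, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, object = object,
                                       message = message, stringsAsFactors = FALSE)
  mids <- vapply(model$metabolites, `[[`, "", "id")
  if (anyDuplicated(mids))
    add("unique_id", mids[duplicated(mids)][1L],
        paste0("duplicate metabolite id '", mids[duplicated(mids)][1L], "'"))
  for (m in model$metabolites) {
    if (!m$compartment %in% COMPARTMENTS)
      add("compartment", m$id, paste0("metabolite '", m$id,
          "' has unknown compartment '", m$compartment, "'"))
    if (is.na(m$initial_conc) || m$initial_conc < 0)
      add("non_negative_c0", m$id, paste0("metabolite '", m$id,
          "' has negative or missing initial concentration"))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    add("unique_id", rids[duplicated(rids)][1L],
        paste0("duplicate reaction id '", rids[duplicated(rids)][1L], "'"))
  for (r in model$reactions) {
    dangling <- setdiff(names(r$stoichiometry), mids)
    for (d in dangling)
      add("dangling_reference", r$id, paste0("reaction '", r$id,
          "' references undeclared metabolite '", d, "'"))
    if (r$needs_fba && !is.null(r$law))
      add("needs_fba", r$id, paste0("reaction '", r$id,
          "' is flagged needs_fba but carries a kinetic law"))
    if (!r$needs_fba && is.null(r$law)) {
      add("missing_law", r$id, paste0("reaction '", r$id, "' has no kinetic law"))
      next
    }
    if (is.null(r$law)) next
    law <- r$law
    n_sub <- length(law$substrate_ids)
    arity_ok <- switch(law$law_type,
      MM1 = n_sub == 1L, MM2 = n_sub == 2L,
      mass_action = n_sub >= 1L, constant_flux = n_sub == 0L, FALSE)
    if (!arity_ok)
      add("law_arity", r$id, paste0("reaction '", r$id, "': ", law$law_type,
          " law has ", n_sub, " substrate(s)"))
    bad_sub <- setdiff(law$substrate_ids, mids)
    for (d in bad_sub)
      add("dangling_reference", r$id, paste0("reaction '", r$id,
          "' rate law references undeclared metabolite '", d, "'"))
    # substrates of the law must be consumed by the reaction
    for (s in intersect(law$substrate_ids, names(r$stoichiometry)))
      if (r$stoichiometry[[s]] >= 0)
        add("substrate_sign", r$id, paste0("reaction '", r$id, "': law substrate '",
            s, "' does not appear with a negative coefficient"))
    for (s in setdiff(law$substrate_ids, names(r$stoichiometry)))
      add("substrate_sign", r$id, paste0("reaction '", r$id, "': law substrate '",
          s, "' is absent from the stoichiometry"))
  }
  if (length(v) == 0L)
    return(data.frame(rule = character(), object = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# ---- tabular readers / writers ------------------------------------------

# autodetect comma vs tab on the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return("\t")
  if (grepl("\t", header)) "\t" else ","
}

.read_table <- function(path, required_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA"))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L)
    stop(what, " table ", path, ": missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    stop(what, " table ", path, ": no data rows")
  df
}

# parse "-1:HMP_P,+1:HMP_PP" into a named numeric vector
.parse_stoich <- function(s, row) {
  tokens <- strsplit(trimws(s), ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    stop("reactions table row ", row, ": empty stoichiometry")
  parts <- strsplit(tokens, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("reactions table row ", row, ": malformed stoichiometry token '",
         tokens[bad][1L], "' (expected 'coef:metabolite_id')")
  coef <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  ids <- vapply(parts, `[[`, "", 2L)
  if (anyNA(coef))
    stop("reactions table row ", row, ": non-numeric stoichiometric coefficient in '",
         tokens[is.na(coef)][1L], "'")
  stats::setNames(coef, ids)
}

.format_stoich <- function(st) {
  paste(sprintf("%+.10g:%s", unname(st), names(st)), collapse = ",")
}

.num_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(NA_real_)
  y <- suppressWarnings(as.numeric(x))
  y
}

#' Load a pathway model from metabolite and reaction tables
#'
#' Tables are UTF-8, comma- or tab-delimited (autodetected from the header
#' line). The metabolite table has columns
#' `id, name, compartment, initial_conc_nmol_per_L, boundary` (0/1); the
#' reaction table has
#' `id, enzyme, stoichiometry, law_type, vmax, km, km_a, km_b, k, substrates,
#' reversible, needs_fba`, with stoichiometry encoded as a
#' `"-1:HMP_P,+1:HMP_PP"` token list, substrates ordered and
#' semicolon-separated, and unused parameter cells empty. Rows with
#' `needs_fba = 1` carry no kinetic parameters and must be resolved with
#' [gapfill_parameters()] before simulation.
#'
#' @param reaction_table,metabolite_table File paths.
#' @param variant Default two-substrate mechanism for MM2 rows without an
#'   explicit `variant` column ("ternary" or "pingpong").
#' @return A validated `thiamsim_model`.
#' @seealso [write_model_tables()] for the inverse operation.
#' @export
load_model <- function(reaction_table, metabolite_table,
                       variant = c("ternary", "pingpong")) {
  variant <- match.arg(variant)
  met_df <- .read_table(metabolite_table,
                        c("id", "name", "compartment", "initial_conc_nmol_per_L",
                          "boundary"), "metabolites")
  rxn_df <- .read_table(reaction_table,
                        c("id", "enzyme", "stoichiometry", "law_type", "vmax",
                          "km", "km_a", "km_b", "k", "substrates", "reversible",
                          "needs_fba"), "reactions")
  mets <- lapply(seq_len(nrow(met_df)), function(i) {
    row <- met_df[i, ]
    c0 <- suppressWarnings(as.numeric(row$initial_conc_nmol_per_L))
    if (is.na(c0))
      stop("metabolites table row ", i, ": non-numeric initial concentration '",
           row$initial_conc_nmol_per_L, "'")
    tryCatch(
      metabolite(row$id, row$name, row$compartment, c0,
                 boundary = isTRUE(as.integer(row$boundary) == 1L)),
      error = function(e) stop("metabolites table row ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  has_variant <- "variant" %in% names(rxn_df)
  rxns <- lapply(seq_len(nrow(rxn_df)), function(i) {
    row <- rxn_df[i, ]
    st <- .parse_stoich(row$stoichiometry, i)
    needs <- isTRUE(as.integer(row$needs_fba) == 1L)
    law <- NULL
    if (!needs) {
      subs <- if (is.na(row$substrates)) character() else
        trimws(strsplit(row$substrates, ";", fixed = TRUE)[[1]])
      subs <- subs[nzchar(subs)]
      law <- tryCatch(
        kinetic_law(row$law_type, substrate_ids = subs,
                    vmax = .num_or_na(row$vmax), km = .num_or_na(row$km),
                    km_a = .num_or_na(row$km_a), km_b = .num_or_na(row$km_b),
                    k = .num_or_na(row$k),
                    variant = if (has_variant && !is.na(row$variant))
                      row$variant else variant),
        error = function(e) stop("reactions table row ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
    } else if (!all(is.na(c(.num_or_na(row$vmax), .num_or_na(row$km),
                            .num_or_na(row$km_a), .num_or_na(row$km_b),
                            .num_or_na(row$k))))) {
      stop("reactions table row ", i,
           ": needs_fba rows must leave all kinetic parameter cells empty")
    }
    tryCatch(
      reaction(row$id, row$enzyme, st, law,
               reversible = isTRUE(as.integer(row$reversible) == 1L),
               needs_fba = needs),
      error = function(e) stop("reactions table row ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  model <- pathway_model(mets, rxns, metadata = list(
    reaction_table = reaction_table, metabolite_table = metabolite_table),
    check = FALSE)
  rep <- validate_model(model)
  if (nrow(rep) > 0L)
    stop("model failed validation:\n  ", paste(rep$message, collapse = "\n  "))
  model
}

#' Write a model back to metabolite and reaction tables
#'
#' Emits the same schema that [load_model()] reads (tab-delimited), so
#' `load_model()` of the written files reproduces the model.
#'
#' @param model A `thiamsim_model`.
#' @param dir Output directory (created if absent); files are named
#'   `metabolites.tsv` and `reactions.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_model_tables <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  met_df <- data.frame(
    id = metabolite_ids(model),
    name = vapply(model$metabolites, `[[`, "", "name"),
    compartment = vapply(model$metabolites, `[[`, "", "compartment"),
    initial_conc_nmol_per_L = sprintf("%.17g",
      vapply(model$metabolites, `[[`, 0, "initial_conc")),
    boundary = as.integer(vapply(model$metabolites, `[[`, TRUE, "boundary")),
    stringsAsFactors = FALSE)
  g <- function(r, field) if (is.null(r$law)) NA_real_ else r$law[[field]]
  rxn_df <- data.frame(
    id = reaction_ids(model),
    enzyme = vapply(model$reactions, `[[`, "", "enzyme"),
    stoichiometry = vapply(model$reactions, function(r) .format_stoich(r$stoichiometry), ""),
    law_type = vapply(model$reactions, function(r)
      if (is.null(r$law)) "" else r$law$law_type, ""),
    vmax = fmt(vapply(model$reactions, g, 0, field = "vmax")),
    km = fmt(vapply(model$reactions, g, 0, field = "km")),
    km_a = fmt(vapply(model$reactions, g, 0, field = "km_a")),
    km_b = fmt(vapply(model$reactions, g, 0, field = "km_b")),
    k = fmt(vapply(model$reactions, g, 0, field = "k")),
    substrates = vapply(model$reactions, function(r)
      if (is.null(r$law)) "" else paste(r$law$substrate_ids, collapse = ";"), ""),
    reversible = as.integer(vapply(model$reactions, `[[`, TRUE, "reversible")),
    needs_fba = as.integer(vapply(model$reactions, `[[`, TRUE, "needs_fba")),
    variant = vapply(model$reactions, function(r)
      if (is.null(r$law)) "" else r$law$variant, ""),
    stringsAsFactors = FALSE)
  met_path <- file.path(dir, "metabolites.tsv")
  rxn_path <- file.path(dir, "reactions.tsv")
  utils::write.table(met_df, met_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rxn_df, rxn_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(reactions = rxn_path, metabolites = met_path))
}

#' Load the synthetic rice thiamin reference network
#'
#' A reconstruction of the de novo thiamin biosynthesis network of rice
#' (34 reactions, 29 metabolites over plastid, cytosol, mitochondrion and
#' external compartments), shipped as plain-text tables under
#' `inst/extdata/thiamin_rice_synthetic/`. The topology follows the canonical
#' plant pathway (THIC and THI1 branch syntheses, bifunctional TH1 kinase +
#' synthase condensation to TMP, TH2 dephosphorylation, TDPK activation, THiM
#' thiazole salvage, and inter-compartmental transport); the kinetic
#' parameters are synthetic placeholders on a plausible nmol/L scale, not
#' measured constants, so the network exercises the full modelling workflow
#' but makes no quantitative claim about rice.
#'
#' Several transport/utilisation reactions are flagged `needs_fba`; resolve
#' them with [gapfill_parameters()] (or `gapfill = TRUE`, which uses the
#' flux-balance bounds and objective shipped alongside the tables in
#' `fba_config.tsv`: precursor uptake caps on the supply reactions and
#' maximisation of the TMP-synthase flux) before simulating.
#'
#' @param gapfill If `TRUE`, run the configured flux-balance gap-fill so the
#'   returned model is ready for [simulate_pathway()].
#' @param km_default Km (nmol/L) assigned to gap-filled MM1 laws.
#' @return A validated `thiamsim_model`.
#' @export
thiamin_reference_model <- function(gapfill = FALSE, km_default = 10) {
  dir <- system.file("extdata", "thiamin_rice_synthetic", package = "thiamsim",
                     mustWork = TRUE)
  model <- load_model(file.path(dir, "reactions.tsv"),
                      file.path(dir, "metabolites.tsv"))
  if (gapfill) {
    cfg <- utils::read.delim(file.path(dir, "fba_config.tsv"),
                             stringsAsFactors = FALSE)
    pick <- function(col) {
      keep <- !is.na(cfg[[col]])
      stats::setNames(cfg[[col]][keep], cfg$reaction_id[keep])
    }
    stoich <- build_stoich(model, lower = pick("lower"), upper = pick("upper"),
                           objective = pick("objective"))
    sol <- solve_fba(stoich)
    if (sol$status != "optimal")
      stop("flux-balance gap-fill failed: solver status ", sol$status)
    model <- gapfill_parameters(model, sol, km_default = km_default)
  }
  model
}
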