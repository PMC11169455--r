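SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
THIAMSIM_NS <- "https://thiamsim.invalid/sbml-annotation"

.fmt17 <- function(x) sprintf("%.17g", x)

#' Export a pathway model to SBML Level 3 Version 2
#'
#' Species, compartments, reactions and stoichiometries map onto the
#' standard SBML elements (clamped species become `boundaryCondition`
#' species); rate-law parameters are written as `localParameter` elements at
#' full precision and the law type, substrate order, two-substrate variant
#' and gap-fill flag are carried in a package annotation, so
#' [import_sbml()] round-trips a model exactly. SBML files written by other
#' tools can be read only if each kinetic law carries this annotation;
#' arbitrary MathML rate laws are rejected as unsupported.
#'
#' @param model A validated `thiamsim_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:ts" = THIAMSIM_NS,
                            level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "thiamsim_model")
  comps <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true",
                        size = "1", spatialDimensions = "3")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites)
    xml2::xml_add_child(los, "species", id = m$id, name = m$name,
                        compartment = m$compartment,
                        initialConcentration = .fmt17(m$initial_conc),
                        boundaryCondition = tolower(as.character(m$boundary)),
                        constant = "false", hasOnlySubstanceUnits = "false")
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lor, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)))
    ann <- xml2::xml_add_child(rx, "annotation")
    xml2::xml_add_child(ann, "ts:reactionInfo", enzyme = r$enzyme,
                        needsFba = as.character(as.integer(r$needs_fba)))
    st <- r$stoichiometry
    reactants <- st[st < 0]; products <- st[st > 0]
    if (length(reactants) > 0L) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (id in names(reactants))
        xml2::xml_add_child(lr, "speciesReference", species = id,
                            stoichiometry = .fmt17(-reactants[[id]]),
                            constant = "true")
    }
    if (length(products) > 0L) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (id in names(products))
        xml2::xml_add_child(lp, "speciesReference", species = id,
                            stoichiometry = .fmt17(products[[id]]),
                            constant = "true")
    }
    if (!is.null(r$law)) {
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      kann <- xml2::xml_add_child(kl, "annotation")
      xml2::xml_add_child(kann, "ts:law", type = r$law$law_type,
                          substrates = paste(r$law$substrate_ids, collapse = " "),
                          variant = r$law$variant)
      lpms <- xml2::xml_add_child(kl, "listOfLocalParameters")
      for (p in c("vmax", "km", "km_a", "km_b", "k"))
        if (!is.na(r$law[[p]]))
          xml2::xml_add_child(lpms, "localParameter", id = p,
                              value = .fmt17(r$law[[p]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a pathway model from SBML Level 3
#'
#' @param path SBML file written by [export_sbml()] (or carrying the same
#'   kinetic-law annotation).
#' @return A validated `thiamsim_model`.
#' @export
import_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(species) == 0L) stop("SBML parse failure: no species found")
  a <- function(node, attr, default = NA_character_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else v
  }
  mets <- lapply(species, function(s)
    metabolite(a(s, "id"),
               name = a(s, "name", a(s, "id")),
               compartment = a(s, "compartment"),
               initial_conc = as.numeric(a(s, "initialConcentration", "0")),
               boundary = identical(a(s, "boundaryCondition"), "true")))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(rx) {
    id <- a(rx, "id")
    info <- xml2::xml_find_first(rx, "./annotation/*[local-name()='reactionInfo']")
    enzyme <- if (inherits(info, "xml_missing")) id else a(info, "enzyme", id)
    needs_fba <- !inherits(info, "xml_missing") &&
      identical(a(info, "needsFba"), "1")
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rx, xp)
      stats::setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      xml2::xml_attr(nodes, "species"))
    }
    st_r <- refs("./listOfReactants/speciesReference", -1)
    st_p <- refs("./listOfProducts/speciesReference", +1)
    st <- c(st_r, st_p)
    # merge duplicates (a species on both sides) by summing
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    law <- NULL
    if (!inherits(kl, "xml_missing")) {
      lann <- xml2::xml_find_first(kl, "./annotation/*[local-name()='law']")
      if (inherits(lann, "xml_missing"))
        stop("reaction '", id, "': unsupported rate-law form on import ",
             "(no thiamsim law annotation)")
      params <- xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter")
      pv <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                            xml2::xml_attr(params, "id"))
      getp <- function(nm) if (nm %in% names(pv)) pv[[nm]] else NA_real_
      subs <- strsplit(a(lann, "substrates", ""), " ", fixed = TRUE)[[1L]]
      subs <- subs[nzchar(subs)]
      law <- kinetic_law(a(lann, "type"), substrate_ids = subs,
                         vmax = getp("vmax"), km = getp("km"),
                         km_a = getp("km_a"), km_b = getp("km_b"),
                         k = getp("k"),
                         variant = a(lann, "variant", "ternary"))
    } else if (!needs_fba) {
      stop("reaction '", id, "': unsupported rate-law form on import ",
           "(no kineticLaw element and not flagged for gap-fill)")
    }
    reaction(id, enzyme, st, law,
             reversible = identical(a(rx, "reversible"), "true"),
             needs_fba = needs_fba)
  })
  model <- pathway_model(mets, rxns, metadata = list(sbml_path = path),
                         check = FALSE)
  rep <- validate_model(model)
  if (nrow(rep) > 0L)
    stop("imported SBML model failed validation:\n  ",
         paste(rep$message, collapse = "\n  "))
  model
}
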