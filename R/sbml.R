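## SBML-Level-3-shaped model exchange, written with xml2.  The document
## carries the standard skeleton (compartment, species with initial
## concentrations, reactions with stoichiometry and reversibility flags)
## so generic tools can read the topology; the kinetic content (rate-law
## kinds, velocities, Km/Ki, half-lives, cofactor pools) travels in a
## package annotation namespace from which import reconstructs the model
## exactly, so export -> import round-trips to the identical steady
## state.

ED_XMLNS <- "https://edflux.r-pkg/ns"

.xml_num_attrs <- function(x) {
  v <- as.numeric(unlist(x))
  setNames(v, names(unlist(x)))
}

#' Export a model instance to an SBML-style document
#'
#' @param model An `ed_model`.
#' @param path Output file path (XML).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  par <- model$parameters
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    "xmlns:edflux" = ED_XMLNS, level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "branched_ED_pathway")
  comp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "cytosol", size = "1",
                      constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$network$metabolites))) {
    m <- model$network$metabolites[i, ]
    xml2::xml_add_child(
      los, "species", id = m$id, name = m$name, compartment = "cytosol",
      initialConcentration = format(model$initial_state[[m$id]],
                                    digits = 17),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$network$reactions) {
    rn <- xml2::xml_add_child(lor, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)))
    if (length(r$substrates)) {
      ls <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_along(r$substrates))
        xml2::xml_add_child(ls, "speciesReference",
                            species = names(r$substrates)[j],
                            stoichiometry = format(r$substrates[[j]]),
                            constant = "true")
    }
    if (length(r$products)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_along(r$products))
        xml2::xml_add_child(lp, "speciesReference",
                            species = names(r$products)[j],
                            stoichiometry = format(r$products[[j]]),
                            constant = "true")
    }
    xml2::xml_add_child(rn, "edflux:rateLaw", kind = r$rate_law)
  }
  ann <- xml2::xml_add_child(mdl, "edflux:parameters",
                             temperature = format(par$temperature),
                             volume_factor = format(par$volume_factor,
                                                    digits = 17),
                             pgk_inhibitor = as.character(model$pgk_inhibitor))
  add_map <- function(tag, values, sds = NULL) {
    node <- xml2::xml_add_child(ann, paste0("edflux:", tag))
    for (i in seq_along(values)) {
      attrs <- list(name = names(values)[i],
                    value = format(values[[i]], digits = 17))
      if (!is.null(sds) && names(values)[i] %in% names(sds))
        attrs$sd <- format(sds[[names(values)[i]]], digits = 17)
      do.call(xml2::xml_add_child,
              c(list(node, paste0("edflux:", "entry")), attrs))
    }
  }
  add_map("vmax", par$vmax, par$vmax_sd)
  add_map("sink_rates", par$sink_rates)
  add_map("half_life", par$half_life)
  add_map("km", par$km)
  add_map("ki", par$ki)
  add_map("cofactor_pools", par$cofactors$pools)
  add_map("cofactor_km", par$cofactors$km)
  init <- model$initial_state
  add_map("initial_state", setNames(as.numeric(init), names(init)))
  xml2::write_xml(doc, path)
  invisible(path)
}

.read_map <- function(ann, tag, ns) {
  nodes <- xml2::xml_find_all(
    ann, paste0("./edflux:", tag, "/edflux:entry"), ns)
  vals <- as.numeric(xml2::xml_attr(nodes, "value"))
  if (any(is.na(vals)))
    stop("import error: missing or non-numeric parameter in <", tag, ">")
  sds <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, "sd")))
  out <- setNames(vals, xml2::xml_attr(nodes, "name"))
  attr(out, "sd") <- setNames(sds, names(out))
  out
}

#' Import a model instance from an SBML-style document
#'
#' Inverse of [write_sbml()]; validates that every required kinetic
#' parameter is present.
#'
#' @param path Path to a document written by [write_sbml()].
#' @return An `ed_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(sbml = "http://www.sbml.org/sbml/level3/version2/core",
          edflux = ED_XMLNS)
  ann <- xml2::xml_find_first(doc, ".//edflux:parameters", ns)
  if (inherits(ann, "xml_missing"))
    stop("import error: no kinetic parameter annotation found")
  vmax <- .read_map(ann, "vmax", ns)
  sds <- attr(vmax, "sd"); sds <- sds[!is.na(sds)]
  sinks <- .read_map(ann, "sink_rates", ns)
  hl <- .read_map(ann, "half_life", ns)
  km <- .read_map(ann, "km", ns)
  ki <- .read_map(ann, "ki", ns)
  pools <- .read_map(ann, "cofactor_pools", ns)
  ckm <- .read_map(ann, "cofactor_km", ns)
  init <- .read_map(ann, "initial_state", ns)
  temp <- as.numeric(xml2::xml_attr(ann, "temperature"))
  vf <- as.numeric(xml2::xml_attr(ann, "volume_factor"))
  inh <- xml2::xml_attr(ann, "pgk_inhibitor")
  par <- ed_parameters(temperature = temp, vmax = c(vmax),
                       vmax_sd = sds, sink_rates = c(sinks),
                       half_life = c(hl), km = c(km), ki = c(ki),
                       cofactors = list(pools = c(pools), km = c(ckm)),
                       volume_factor = vf)
  ed_model(par, initial_state = c(init),
           pgk_inhibitor = if (identical(inh, "NA")) NA_character_ else inh)
}
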