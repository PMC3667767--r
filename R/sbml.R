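#' Read a power-law (GMA) model from SBML
#'
#' A restricted SBML importer for models whose kinetic laws are products
#' of power laws (optionally sums of such products, which are split into
#' one flux per term). Species with `boundaryCondition="true"` or
#' `constant="true"` become independent variables; all others become
#' dependent variables with an ODE. Baselines are taken from the SBML
#' initial concentrations. Numeric literals and local kinetic-law
#' parameters multiply into the rate constant; `ci` factors and
#' `power(ci, cn)` pairs become kinetic orders. Any other MathML
#' construct raises a conversion error naming the reaction.
#'
#' Independent species are tagged as enzymes unless their `sboTerm`
#' declares a simple chemical (`SBO:0000247`); `SBO:0000014` explicitly
#' marks an enzyme.
#'
#' @param path Path to an SBML `.xml` file, or a `.zip` archive whose
#'   first `.xml` entry is read.
#' @return A [gma_model()].
#' @export
read_sbml_model <- function(path) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("sbml")
    files <- utils::unzip(path, exdir = exdir)
    xmls <- files[grepl("\\.xml$|\\.sbml$", files, ignore.case = TRUE)]
    if (!length(xmls)) stop("no SBML file found in archive", call. = FALSE)
    path <- xmls[1]
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML file contains no species", call. = FALSE)
  attr_or <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a)
    ifelse(is.na(v), default, v)
  }
  ids <- xml2::xml_attr(sp_nodes, "id")
  bc <- attr_or(sp_nodes, "boundaryCondition", "false") == "true" |
    attr_or(sp_nodes, "constant", "false") == "true"
  sbo <- xml2::xml_attr(sp_nodes, "sboTerm")
  vars <- tibble::tibble(
    id = ids,
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")), ids,
                  xml2::xml_attr(sp_nodes, "name")),
    role = ifelse(bc, "independent", "dependent"),
    baseline = as.numeric(attr_or(sp_nodes, "initialConcentration", "1")),
    enzyme = bc & (is.na(sbo) | sbo == "SBO:0000014")
  )

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  fluxes <- list()
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    sref <- function(xp) {
      nodes <- xml2::xml_find_all(rx, xp)
      if (!length(nodes)) return(NULL)
      s <- xml2::xml_attr(nodes, "stoichiometry")
      stats::setNames(ifelse(is.na(s), 1, as.numeric(s)),
                      xml2::xml_attr(nodes, "species"))
    }
    consumes <- sref("./listOfReactants/speciesReference")
    produces <- sref("./listOfProducts/speciesReference")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    catalyst <- if (length(modifiers)) modifiers[1] else NULL

    math <- xml2::xml_find_first(rx, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) {
      stop("reaction '", rid, "' has no kinetic law", call. = FALSE)
    }
    pars <- xml2::xml_find_all(
      rx, "./kineticLaw/listOfParameters/parameter | ./kineticLaw/listOfLocalParameters/localParameter")
    local <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))
    body <- xml2::xml_find_first(math, "./*")
    terms <- parse_power_law_math(body, local, rid)
    for (i in seq_along(terms)) {
      tid <- if (length(terms) == 1) rid else paste0(rid, "_", i)
      tm <- terms[[i]]
      fluxes[[length(fluxes) + 1]] <- power_law_flux(
        tid, tm$gamma, tm$ko, consumes = consumes, produces = produces,
        catalyst = catalyst)
    }
  }
  model_name <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "name")
  if (is.na(model_name)) model_name <- "SBML model"
  gma_model(vars, fluxes, name = model_name)
}

# Parse restricted MathML: returns a list of terms, each
# list(gamma = scalar, ko = named numeric). `local` maps local parameter
# ids to values (they fold into gamma).
parse_power_law_math <- function(node, local, rid) {
  fail <- function() {
    stop("reaction '", rid,
         "': kinetic law is not a (sum of) product(s) of power laws",
         call. = FALSE)
  }
  tag <- xml2::xml_name(node)
  if (tag == "apply") {
    kids <- xml2::xml_find_all(node, "./*")
    op <- xml2::xml_name(kids[[1]])
    args <- kids[-1]
    if (op == "plus") {
      return(unlist(lapply(args, parse_power_law_math, local = local,
                           rid = rid), recursive = FALSE))
    }
    if (op == "times") {
      term <- list(gamma = 1, ko = numeric())
      for (a in args) {
        sub <- parse_power_law_math(a, local, rid)
        if (length(sub) != 1) fail()
        term$gamma <- term$gamma * sub[[1]]$gamma
        for (v in names(sub[[1]]$ko)) {
          term$ko[v] <- (term$ko[v] %||0% 0) + sub[[1]]$ko[[v]]
        }
      }
      return(list(term))
    }
    if (op == "power") {
      if (length(args) != 2 || xml2::xml_name(args[[1]]) != "ci" ||
          xml2::xml_name(args[[2]]) != "cn") fail()
      v <- trimws(xml2::xml_text(args[[1]]))
      if (v %in% names(local)) fail()
      e <- as.numeric(xml2::xml_text(args[[2]]))
      return(list(list(gamma = 1, ko = stats::setNames(e, v))))
    }
    fail()
  }
  if (tag == "ci") {
    v <- trimws(xml2::xml_text(node))
    if (v %in% names(local)) {
      return(list(list(gamma = unname(local[v]), ko = numeric())))
    }
    return(list(list(gamma = 1, ko = stats::setNames(1, v))))
  }
  if (tag == "cn") {
    return(list(list(gamma = as.numeric(xml2::xml_text(node)), ko = numeric())))
  }
  fail()
}

`%||0%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
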