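#' Variable registry for the yeast sphingolipid pathway
#'
#' Maps the X-index symbols of the heat-stress model to enzyme/metabolite
#' names and to the pathway zones used to group activity trends: red
#' (de novo entry via SPT/KDHS reductase), blue (core redistribution and
#' the exit routes), green (complex-sphingolipid interconversion), yellow
#' (fatty-acid CoA supply), pink (serine metabolism) and tan (phospholipid
#' metabolism). Indices cited in the published figure legends are named
#' accordingly; the tan/pink split of the peripheral set is approximate
#' (assigned by enzyme function) and flagged in the `approx` column.
#'
#' @return A tibble with columns `index`, `name`, `zone`, `in_core`,
#'   `approx`.
#' @export
sphingo_registry <- function() {
  reg <- utils::read.csv(
    system.file("extdata", "sphingo_zones.csv", package = "sphingodyn"),
    stringsAsFactors = FALSE
  )
  tibble::as_tibble(reg)
}

#' Pathway zone of an enzyme
#'
#' @param id Character vector of registry indices (e.g. `"X57"`).
#' @return Character vector of zones.
#' @export
zone_of <- function(id) {
  reg <- sphingo_registry()
  i <- match(id, reg$index)
  if (anyNA(i)) {
    stop("unknown registry index: ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(reg$zone[i], id)
}

#' The six measured sphingolipid species
#'
#' The sphingoid bases DHS and PHS, their 1-phosphates, and the ceramides
#' DHC and PHC — the species whose heat-stress time courses drive the
#' activity inference.
#'
#' @return Character vector of species ids.
#' @export
measured_species <- function() c("DHS", "DHSP", "DHC", "PHS", "PHSP", "PHC")

#' Reduced core model of sphingolipid metabolism
#'
#' A ten-species GMA model of the central sphingolipid pathway: de novo
#' entry through serine palmitoyltransferase (X57) to 3-KDHS, reduction to
#' DHS (X27), the kinase/phosphatase cycles DHS/DHS-P and PHS/PHS-P (X36,
#' X41), ceramide synthesis and ceramidase back-reactions (X34, X29, X53),
#' 4-hydroxylation of the dihydro to the phyto branch (X54), the complex
#' sphingolipid chain IPC -> MIPC -> M(IP)2C (X33, X35, X55) with IPCase
#' retrieval to the ceramide pools (X51), and the two exit routes,
#' sphingosine-1-phosphate lyase (X50) and GPI remodelase (X43).
#'
#' All species baselines are normalised to 1 and the rate constants are
#' balanced so the baseline is an exact steady state. Kinetic orders
#' default to 1 for substrates and enzymes (configurable). Serine (`SER`)
#' is an independent, non-enzyme pool feeding SPT.
#'
#' @param substrate_order,enzyme_order Kinetic orders applied to the
#'   substrate and catalyst of every flux.
#' @return A [gma_model()] with 10 dependent and 15 independent variables
#'   (14 enzymes plus serine).
#' @export
sphingo_core_model <- function(substrate_order = 1, enzyme_order = 1) {
  species <- c("KDHS", "DHS", "DHSP", "DHC", "PHS", "PHSP", "PHC",
               "IPC", "MIPC", "MIP2C")
  enzymes <- c("X57", "X27", "X36", "X41", "X50", "X34", "X29", "X54",
               "X53", "X33", "X43", "X51", "X35", "X55")
  reg <- sphingo_registry()
  vars <- tibble::tibble(
    id = c(species, enzymes, "SER"),
    name = c("3-ketodihydrosphingosine", "dihydrosphingosine",
             "dihydrosphingosine 1-phosphate", "dihydroceramide",
             "phytosphingosine", "phytosphingosine 1-phosphate",
             "phytoceramide", "inositol phosphorylceramide",
             "mannosylinositol phosphorylceramide",
             "mannosyldiinositol phosphorylceramide",
             reg$name[match(enzymes, reg$index)], "serine"),
    role = c(rep("dependent", length(species)),
             rep("independent", length(enzymes) + 1)),
    baseline = 1,
    enzyme = c(rep(FALSE, length(species)), rep(TRUE, length(enzymes)), FALSE)
  )

  # edge fluxes chosen so every node balances exactly at the unit baseline
  edge <- function(id, gamma, enz, from = NULL, to = NULL, extra = NULL) {
    ko <- c(
      if (!is.null(from)) stats::setNames(substrate_order, from),
      stats::setNames(enzyme_order, enz),
      extra
    )
    power_law_flux(id, gamma, ko,
                   consumes = from, produces = to, catalyst = enz)
  }
  fluxes <- list(
    edge("spt",      1.0, "X57", to = "KDHS",
         extra = stats::setNames(substrate_order, "SER")),
    edge("reductase", 1.0, "X27", "KDHS", "DHS"),
    edge("kinase_d", 0.6, "X36", "DHS",  "DHSP"),
    edge("phosphatase_d", 0.4, "X41", "DHSP", "DHS"),
    edge("lyase_d",  0.2, "X50", "DHSP"),
    edge("cersynth_d", 0.8, "X34", "DHS", "DHC"),
    edge("cdase_d",  0.2, "X29", "DHC",  "DHS"),
    edge("hydroxylase_s", 0.2, "X54", "DHS", "PHS"),
    edge("kinase_p", 0.8, "X36", "PHS",  "PHSP"),
    edge("phosphatase_p", 0.5, "X41", "PHSP", "PHS"),
    edge("lyase_p",  0.3, "X50", "PHSP"),
    edge("cersynth_p", 0.2, "X34", "PHS", "PHC"),
    edge("cdase_p",  0.3, "X53", "PHC",  "PHS"),
    edge("hydroxylase_c", 0.3, "X54", "DHC", "PHC"),
    edge("ipcsynth_d", 0.3, "X33", "DHC", "IPC"),
    edge("ipcsynth_p", 0.5, "X33", "PHC", "IPC"),
    edge("remodelase_d", 0.2, "X43", "DHC"),
    edge("remodelase_p", 0.3, "X43", "PHC"),
    edge("ipcase_d", 0.2, "X51", "IPC",  "DHC"),
    edge("ipcase_p", 0.2, "X51", "IPC",  "PHC"),
    edge("mipcsynth", 0.4, "X35", "IPC", "MIPC"),
    edge("ipcase_m", 0.2, "X51", "MIPC", "PHC"),
    edge("mip2csynth", 0.2, "X55", "MIPC", "MIP2C"),
    edge("ipcase_m2", 0.2, "X51", "MIP2C", "PHC")
  )
  gma_model(vars, fluxes, name = "sphingolipid core model")
}

#' Load the full sphingolipid model from SBML
#'
#' Reads a power-law (GMA) model from an SBML file or zip archive via
#' [read_sbml_model()] and checks it against the published dimensions of
#' the full heat-stress model: 25 dependent and 41 independent variables.
#' A count mismatch raises a structural warning but still returns the
#' model. The package ships a synthetic stand-in with these dimensions in
#' `inst/extdata/sphingolipid_full_model_synthetic.xml` (the published
#' supplementary archive is not redistributed here).
#'
#' @param path Path to an SBML `.xml` file or a `.zip` archive holding one.
#' @return A [gma_model()].
#' @export
load_full_model <- function(path = system.file(
  "extdata", "sphingolipid_full_model_synthetic.xml", package = "sphingodyn")) {
  m <- read_sbml_model(path)
  if (n_dependent(m) != 25 || n_independent(m) != 41) {
    warning(sprintf(
      "structural mismatch: expected 25 dependent / 41 independent variables, got %d / %d",
      n_dependent(m), n_independent(m)), call. = FALSE)
  }
  m
}

#' Count influx and efflux terms of a species
#'
#' The number of producing and consuming power-law terms in one dependent
#' variable's ODE (e.g. the DHS equation of the pathway model has exactly
#' three of each).
#'
#' @param model A [gma_model()].
#' @param species Dependent-variable id.
#' @return Integer vector `c(influx = ..., efflux = ...)`.
#' @export
flux_counts <- function(model, species) {
  mm <- gma_matrices(model)
  if (!species %in% mm$dep_ids) stop("unknown species: ", species, call. = FALSE)
  c(influx = sum(mm$Sprod[species, ] > 0),
    efflux = sum(mm$Scons[species, ] > 0))
}
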