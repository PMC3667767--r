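#!/usr/bin/env Rscript
# Generates inst/extdata/sphingolipid_full_model_synthetic.xml: a synthetic
# full-scale stand-in for the yeast sphingolipid heat-stress model with the
# published dimensions (25 dependent / 41 independent variables; DHS node
# with 3 influx and 3 efflux terms), balanced so the unit baseline is an
# exact steady state. Run from the repository root after installing the
# package:  Rscript scripts/make-full-model-fixture.R

suppressMessages(pkgload::load_all(".", quiet = TRUE))

species <- c("KDHS", "DHS", "DHSP", "DHC", "PHS", "PHSP", "PHC",
             "IPCg", "MIPCg", "MIP2Cg", "IPCm", "MIPCm", "MIP2Cm",
             "DAG", "CDPDAG", "PS", "PA", "PI", "CDPE",
             "PalCoA", "C26CoA", "MalCoA", "AcCoA", "Serine", "Hexadecenal")
enzymes <- paste0("X", c(26, 27, 29, 31, 32, 33, 34, 35, 36, 38,
                         39, 40, 41, 42, 43, 44, 45, 46, 49, 50,
                         51, 52, 53, 54, 55, 56, 57, 59, 60, 63))
pools <- c("ATP", "Palmitate", "Acetate", "Phosphoserine", "Inositol",
           "CTP", "GDPMannose", "Ethanolamine", "Choline", "Glycerol3P",
           "CoA")
stopifnot(length(species) == 25, length(enzymes) + length(pools) == 41)

vars <- tibble::tibble(
  id = c(species, enzymes, pools),
  role = c(rep("dependent", length(species)),
           rep("independent", length(enzymes) + length(pools))),
  baseline = 1,
  enzyme = c(rep(FALSE, length(species)), rep(TRUE, length(enzymes)),
             rep(FALSE, length(pools)))
)

E <- function(id, gamma, enz = NULL, from = NULL, to = NULL) {
  ko <- c(
    if (!is.null(from)) stats::setNames(rep(1, length(from)), from),
    if (!is.null(enz)) stats::setNames(1, enz)
  )
  cons <- intersect(from, species)
  power_law_flux(id, gamma, ko,
                 consumes = if (length(cons)) cons else NULL,
                 produces = to, catalyst = enz)
}

fluxes <- list(
  # de novo entry and the sphingoid-base / ceramide core
  E("spt",           1.0, "X57", c("Serine", "PalCoA"), "KDHS"),
  E("reductase",     1.0, "X27", "KDHS", "DHS"),
  E("kinase_d",      0.6, "X36", "DHS", "DHSP"),
  E("phosphatase_d", 0.4, "X41", "DHSP", "DHS"),
  E("lyase_d",       0.2, "X50", "DHSP", "Hexadecenal"),
  E("cersynth_d",    0.8, "X34", c("DHS", "C26CoA"), "DHC"),
  E("cdase_d",       0.2, "X29", "DHC", "DHS"),
  E("hydroxylase_s", 0.2, "X54", "DHS", "PHS"),
  E("kinase_p",      0.8, "X36", "PHS", "PHSP"),
  E("phosphatase_p", 0.5, "X41", "PHSP", "PHS"),
  E("lyase_p",       0.3, "X50", "PHSP", "Hexadecenal"),
  E("cersynth_p",    0.2, "X34", c("PHS", "C26CoA"), "PHC"),
  E("cdase_p",       0.3, "X53", "PHC", "PHS"),
  E("hydroxylase_c", 0.3, "X54", "DHC", "PHC"),
  E("remodelase_d",  0.2, "X43", "DHC"),
  E("remodelase_p",  0.3, "X43", "PHC"),
  # complex sphingolipids: golgi synthesis, transport, membrane retrieval
  E("ipcsynth_d",    0.3, "X33", c("DHC", "PI"), c("IPCg", "DAG")),
  E("ipcsynth_p",    0.5, "X33", c("PHC", "PI"), c("IPCg", "DAG")),
  E("mipcsynth",     0.4, "X35", c("IPCg", "GDPMannose"), "MIPCg"),
  E("mip2csynth",    0.2, "X55", c("MIPCg", "Inositol"), "MIP2Cg"),
  E("transport_ipc",   0.4, NULL, "IPCg", "IPCm"),
  E("transport_mipc",  0.2, NULL, "MIPCg", "MIPCm"),
  E("transport_mip2c", 0.2, NULL, "MIP2Cg", "MIP2Cm"),
  E("ipcase_d",      0.2, "X51", "IPCm", "DHC"),
  E("ipcase_p",      0.2, "X51", "IPCm", "PHC"),
  E("ipcase_m",      0.2, "X51", "MIPCm", "PHC"),
  E("ipcase_m2",     0.2, "X51", "MIP2Cm", "PHC"),
  # fatty-acid CoA supply
  E("acs",           2.0, "X63", "Acetate", "AcCoA"),
  E("acc",           2.0, "X60", c("AcCoA", "ATP"), "MalCoA"),
  E("fas",           2.0, "X52", "MalCoA", "PalCoA"),
  E("elo",           1.0, "X59", "PalCoA", "C26CoA"),
  # serine metabolism
  E("pser_to_ser",   1.5, "X45", "Phosphoserine", "Serine"),
  E("ser_hmt",       0.2, "X49", "Serine"),
  # phospholipid metabolism
  E("pa_syn",        1.5, "X26", "Glycerol3P", "PA"),
  E("cds",           1.1, "X31", c("PA", "CTP"), "CDPDAG"),
  E("pap",           0.4, "X32", "PA", "DAG"),
  E("pis",           0.8, "X38", c("CDPDAG", "Inositol"), "PI"),
  E("pss",           0.3, "X39", c("CDPDAG", "Serine"), "PS"),
  E("psd",           0.3, "X44", "PS"),
  E("dag_use",       0.8, "X56", "DAG"),
  E("ecyt",          0.4, "X40", c("Ethanolamine", "CTP"), "CDPE"),
  E("eptransfer",    0.4, "X42", c("CDPE", "DAG")),
  E("hex_ox",        0.5, "X46", "Hexadecenal")
)

model <- gma_model(vars, fluxes, name = "sphingolipid full model (synthetic)")
res <- steady_state_residual(model)
stopifnot(n_dependent(model) == 25, n_independent(model) == 41, res < 1e-8)
cat("dependent:", n_dependent(model), " independent:", n_independent(model),
    " steady-state residual:", res, "\n")
print(flux_counts(model, "DHS"))

# ---- minimal SBML Level 2 writer (fixture generation only) ----
xml_math <- function(f) {
  factors <- c(sprintf("<cn> %g </cn>", f$rate_constant))
  for (v in names(f$kinetic_orders)) {
    e <- f$kinetic_orders[[v]]
    dep <- v %in% species
    factors <- c(factors, if (dep) {
      sprintf("<apply><power/><ci> %s </ci><cn> %g </cn></apply>", v, e)
    } else if (e == 1) {
      sprintf("<ci> %s </ci>", v)
    } else {
      sprintf("<apply><power/><ci> %s </ci><cn> %g </cn></apply>", v, e)
    })
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/>',
         paste(factors, collapse = ""), "</apply></math>")
}
sref <- function(x) {
  if (is.null(x)) return("")
  paste(sprintf('<speciesReference species="%s" stoichiometry="%g"/>',
                names(x), x), collapse = "")
}
rx_xml <- vapply(model$fluxes, function(f) {
  paste0(
    sprintf('<reaction id="%s" reversible="false">', f$id),
    if (!is.null(f$consumes))
      paste0("<listOfReactants>", sref(f$consumes), "</listOfReactants>"),
    if (!is.null(f$produces))
      paste0("<listOfProducts>", sref(f$produces), "</listOfProducts>"),
    if (!is.null(f$catalyst))
      sprintf('<listOfModifiers><modifierSpeciesReference species="%s"/></listOfModifiers>',
              f$catalyst),
    "<kineticLaw>", xml_math(f), "</kineticLaw></reaction>"
  )
}, character(1))

sp_xml <- vapply(seq_len(nrow(vars)), function(i) {
  v <- vars[i, ]
  sbo <- if (v$role == "independent") {
    if (v$enzyme) ' sboTerm="SBO:0000014"' else ' sboTerm="SBO:0000247"'
  } else ""
  sprintf(paste0('<species id="%s" name="%s" compartment="cell" ',
                 'initialConcentration="%g" boundaryCondition="%s"%s/>'),
          v$id, v$id, v$baseline, tolower(v$role == "independent"), sbo)
}, character(1))

doc <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>\n',
  '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
  '<!-- SYNTHETIC stand-in model: published dimensions and pathway topology,\n',
  '     normalized unit baselines, balanced rate constants. Generated by\n',
  '     scripts/make-full-model-fixture.R -->\n',
  '<model id="sphingolipid_full_synthetic" name="sphingolipid full model (synthetic)">\n',
  '<listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>\n',
  "<listOfSpecies>\n", paste(sp_xml, collapse = "\n"), "\n</listOfSpecies>\n",
  "<listOfReactions>\n", paste(rx_xml, collapse = "\n"), "\n</listOfReactions>\n",
  "</model>\n</sbml>\n"
)
out <- file.path("inst", "extdata", "sphingolipid_full_model_synthetic.xml")
writeLines(doc, out)
cat("wrote", out, "(", file.size(out), "bytes )\n")

# round-trip check through the package's SBML reader
m2 <- read_sbml_model(out)
stopifnot(n_dependent(m2) == 25, n_independent(m2) == 41,
          steady_state_residual(m2) < 1e-8,
          identical(unname(flux_counts(m2, "DHS")), c(3L, 3L)))
cat("round-trip OK\n")
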