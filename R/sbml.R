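## Minimal SBML Level 3 Version 1 export of the mass-action reaction scheme.
## Written directly as XML (no SBML toolkit dependency); import is not
## supported.

.SBML_REACTIONS <- list(
  list(id = "R1",  k = "k1",  react = c("H2O2", "sGC"), prod = "sGC_H2O2"),
  list(id = "R2",  k = "k2",  react = c("NO", "sGC"),   prod = "NO_sGC"),
  list(id = "R3",  k = "k3",  react = "NO_sGC",         prod = c("NO", "sGC")),
  list(id = "R4",  k = "k4",  react = c("sGC", "GTP"),  prod = "sGC_GTP"),
  list(id = "R5",  k = "k5",  react = "sGC_GTP",        prod = c("sGC", "GTP")),
  list(id = "R6",  k = "k6",  react = c("NO_sGC", "GTP"), prod = "NO_sGC_GTP"),
  list(id = "R7",  k = "k7",  react = "NO_sGC_GTP",     prod = c("NO_sGC", "GTP")),
  list(id = "R8",  k = "k8",  react = "sGC_GTP",        prod = c("sGC", "cGMP")),
  list(id = "R9",  k = "k9",  react = "NO_sGC_GTP",     prod = c("NO_sGC", "cGMP")),
  list(id = "R10", k = "k10", react = c("cGMP", "PDE"), prod = "cGMP_PDE"),
  list(id = "R11", k = "k11", react = "cGMP_PDE",       prod = c("cGMP", "PDE")),
  list(id = "R12", k = "k12", react = "cGMP_PDE",       prod = c("PDE", "GMP")),
  list(id = "R13", k = "k13", react = "NO",             prod = character()))

#' Export the pathway model as SBML Level 3
#'
#' Writes the 13 mass-action reactions, 12 species with their initial
#' concentrations, and the rate constants as global parameters. Species ids
#' follow the canonical names. The NO loss step (k13) is exported as a
#' degradation reaction with no products.
#'
#' @param params A [ParameterSet-class].
#' @param init An [InitialState-class].
#' @param path Output file path.
#' @param modelId Model id attribute (default "no_cgmp_pathway").
#' @return \code{path}, invisibly.
#' @export
exportSBML <- function(params, init, path, modelId = "no_cgmp_pathway") {
  stopifnot(is(params, "ParameterSet"), is(init, "InitialState"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  ln <- character()
  add <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'level="3" version="1">')
  add('  <model id="', esc(modelId), '" substanceUnits="micromole" ',
      'timeUnits="second" extentUnits="micromole">')
  add('    <listOfCompartments>')
  add('      <compartment id="cell" spatialDimensions="3" size="1" ',
      'constant="true"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (sp in speciesNames())
    add('      <species id="', sp, '" compartment="cell" ',
        'initialConcentration="', format(init@conc[[sp]], digits = 15),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
        'constant="false"/>')
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (kn in names(params@k))
    add('      <parameter id="', kn, '" value="',
        format(params@k[[kn]], digits = 15), '" constant="true"/>')
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (r in .SBML_REACTIONS) {
    add('      <reaction id="', r$id, '" reversible="false">')
    add('        <listOfReactants>')
    for (sp in r$react)
      add('          <speciesReference species="', sp,
          '" stoichiometry="1" constant="true"/>')
    add('        </listOfReactants>')
    if (length(r$prod)) {
      add('        <listOfProducts>')
      for (sp in r$prod)
        add('          <speciesReference species="', sp,
            '" stoichiometry="1" constant="true"/>')
      add('        </listOfProducts>')
    }
    add('        <kineticLaw>')
    add('          <math xmlns="http://www.w3.org/1998/Math/MathML">')
    factors <- c(r$k, r$react)
    if (length(factors) > 1L) {
      add('            <apply>')
      add('              <times/>')
      for (f in factors) add('              <ci> ', f, ' </ci>')
      add('            </apply>')
    } else {
      add('            <ci> ', factors, ' </ci>')
    }
    add('          </math>')
    add('        </kineticLaw>')
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  writeLines(ln, path)
  invisible(path)
}
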