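# Reaction definitions for SBML export: reactants/products/modifiers by
# species id, and the kinetic law as an R expression over those ids and the
# reaction's local parameters. Clamped species (fum, suc, Hplus, O2) are
# boundary species; E_out, alpha and vT are global parameters.
.sbml_species <- c("Fe3S4ox", "Fe3S4red", "Fe4S4ox", "Fe4S4red",
                   "Fe2S2ox", "Fe2S2red", "FAD", "FADfum", "FADHfum",
                   "FADH2fum", "FADsuc", "FADHsuc", "FADH2suc",
                   "FADH", "FADH2", "O2sup", "H2O2")
.sbml_boundary <- c("fum", "suc", "Hplus", "O2")

.sbml_reactions <- function() {
  r <- function(reactants, products, math, params, modifiers = character())
    list(reactants = reactants, products = products, modifiers = modifiers,
         math = str2lang(math), params = params)
  list(
    r1 = r("Fe3S4ox", "Fe3S4red",
           "k1 * (Fe3S4ox * exp(-alpha * E_out / vT) -
                  Fe3S4red * exp((1 - alpha) * E_out / vT) / Keq1)",
           c("k1", "Keq1")),
    r2 = r(c("Fe4S4ox", "Fe3S4red"), c("Fe4S4red", "Fe3S4ox"),
           "k2 * (Fe4S4ox * Fe3S4red - Fe4S4red * Fe3S4ox / Keq2)",
           c("k2", "Keq2")),
    r3 = r(c("Fe2S2ox", "Fe4S4red"), c("Fe2S2red", "Fe4S4ox"),
           "k3 * (Fe2S2ox * Fe4S4red - Fe2S2red * Fe4S4ox / Keq3)",
           c("k3", "Keq3")),
    r4 = r(c("FAD", "fum"), "FADfum",
           "k4 * (FAD * fum - FADfum / Keq4)", c("k4", "Keq4")),
    r5 = r(c("FADfum", "Fe2S2red", "Hplus"), c("FADHfum", "Fe2S2ox"),
           "k5 * (FADfum * Fe2S2red * Hplus - FADHfum * Fe2S2ox / Keq5)",
           c("k5", "Keq5")),
    r6 = r(c("FADHfum", "Fe2S2red", "Hplus"), c("FADH2fum", "Fe2S2ox"),
           "k6 * (FADHfum * Fe2S2red * Hplus - FADH2fum * Fe2S2ox / Keq6)",
           c("k6", "Keq6")),
    r7 = r("FADH2fum", "FADsuc",
           "k7 * (FADH2fum - FADsuc / Keq7)", c("k7", "Keq7")),
    r8 = r("FADsuc", c("FAD", "suc"),
           "k8 * (FADsuc - FAD * suc / Keq8)", c("k8", "Keq8")),
    r9 = r(c("FAD", "Fe2S2red", "Hplus"), c("FADH", "Fe2S2ox"),
           "k9 * (FAD * Fe2S2red * Hplus - FADH * Fe2S2ox / Keq9)",
           c("k9", "Keq9")),
    r10 = r(c("FADH", "fum"), "FADHfum",
            "k10 * (FADH * fum - FADHfum / Keq10)", c("k10", "Keq10")),
    r11 = r(c("FADH", "Fe2S2red", "Hplus"), c("FADH2", "Fe2S2ox"),
            "k11 * (FADH * Fe2S2red * Hplus - FADH2 * Fe2S2ox / Keq11)",
            c("k11", "Keq11")),
    r12 = r(c("FADH2", "fum"), "FADH2fum",
            "k12 * (FADH2 * fum - FADH2fum / Keq12)", c("k12", "Keq12")),
    r13 = r(c("FADsuc", "Fe2S2red", "Hplus"), c("FADHsuc", "Fe2S2ox"),
            "k13 * (FADsuc * Fe2S2red * Hplus - FADHsuc * Fe2S2ox / Keq13)",
            c("k13", "Keq13")),
    r14 = r("FADHsuc", c("FADH", "suc"),
            "k14 * (FADHsuc - FADH * suc / Keq14)", c("k14", "Keq14")),
    r15 = r(c("FADHsuc", "Fe2S2red", "Hplus"), c("FADH2suc", "Fe2S2ox"),
            "k15 * (FADHsuc * Fe2S2red * Hplus - FADH2suc * Fe2S2ox / Keq15)",
            c("k15", "Keq15")),
    r16 = r("FADH2suc", c("FADH2", "suc"),
            "k16 * (FADH2suc - FADH2 * suc / Keq16)", c("k16", "Keq16")),
    r17 = r(c("FADH2", "O2"), c("FAD", "H2O2"),
            "k17 * (FADH2 * O2 - FAD * H2O2 / Keq17)", c("k17", "Keq17")),
    r18 = r(c("FADH2", "O2"), c("FADH", "O2sup", "Hplus"),
            "k18 * (FADH2 * O2 - FADH * O2sup * Hplus / Keq18)",
            c("k18", "Keq18")),
    r19 = r(c("FADH", "O2"), c("FAD", "O2sup", "Hplus"),
            "k19 * (FADH * O2 - FAD * O2sup * Hplus / Keq19)",
            c("k19", "Keq19")),
    r20 = r(c("Fe3S4red", "O2"), c("Fe3S4ox", "O2sup"),
            "k20 * (Fe3S4red * O2 - Fe3S4ox * O2sup / Keq20)",
            c("k20", "Keq20")),
    r21 = r("O2sup", c("O2", "H2O2"),
            "Vmax21 * O2sup / (Km21 + O2sup)", c("Vmax21", "Km21")),
    r22 = r("H2O2", character(),
            "k22 * H2O2", c("k22")))
}

# stoichiometric multiplicity in the SBML reaction list (2 O2sup -> ...)
.sbml_stoich <- function(rid, side, sp) {
  if (rid == "r21" && side == "reactants" && sp == "O2sup") 2 else 1
}

# R call tree -> content MathML
.math_to_mathml <- function(e) {
  if (is.numeric(e)) return(sprintf("<cn> %.17g </cn>", e))
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(.math_to_mathml(e[[2L]]))
    args <- lapply(as.list(e)[-1L], .math_to_mathml)
    sym <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", "exp" = "exp",
                  stop("unsupported operator in kinetic law: ", op,
                       call. = FALSE))
    return(paste0("<apply><", sym, "/>",
                  paste(unlist(args), collapse = ""), "</apply>"))
  }
  stop("unsupported kinetic-law expression", call. = FALSE)
}

.param_value <- function(ps, env, nm) {
  if (nm %in% names(ps$k)) return(ps$k[[nm]])
  if (grepl("^Keq", nm)) return(ps$Keq[[nm]])
  switch(nm,
         Vmax21 = ps$Vmax21, Km21 = ps$Km21, k22 = ps$k22,
         alpha = ps$constants$alpha, vT = ps$constants$vT,
         E_out = env$E_out,
         stop("unknown parameter ", nm, call. = FALSE))
}

#' Export the reaction network as SBML Level 3
#'
#' Writes the full 22-reaction network as an SBML Level 3 Version 2 core
#' document: all 17 internal species (with initial concentrations from
#' \code{state}), the 4 clamped boundary species, global parameters for the
#' electrode (E_out, alpha, vT), and one reaction element per kinetic
#' process with its rate law as content MathML and local parameters (rate
#' and equilibrium constants). Conservation of the four moieties is implied
#' by the network stoichiometry.
#'
#' @param ps An \code{sdh_params} object.
#' @param env An [sdh_env()] object (supplies clamped concentrations and
#'   E_out).
#' @param file Output path.
#' @param state State used for the initial concentrations (default: fully
#'   oxidized).
#' @return Invisibly \code{file}.
#' @export
write_sbml <- function(ps, env, file, state = default_state(ps)) {
  validate_parameters(ps)
  comp <- complement_species(state, ps)
  conc <- c(Fe3S4ox = comp[["Fe3S4ox"]], Fe3S4red = state[["Fe3S4red"]],
            Fe4S4ox = comp[["Fe4S4ox"]], Fe4S4red = state[["Fe4S4red"]],
            Fe2S2ox = comp[["Fe2S2ox"]], Fe2S2red = state[["Fe2S2red"]],
            FAD = comp[["FAD"]], FADfum = state[["FAD.fum"]],
            FADHfum = state[["FADH.fum"]], FADH2fum = state[["FADH2.fum"]],
            FADsuc = state[["FAD.suc"]], FADHsuc = state[["FADH.suc"]],
            FADH2suc = state[["FADH2.suc"]], FADH = state[["FADH"]],
            FADH2 = state[["FADH2"]], O2sup = state[["O2sup"]],
            H2O2 = state[["H2O2"]])
  bconc <- c(fum = env$fum, suc = env$suc, Hplus = env$Hplus, O2 = env$O2)
  sp_xml <- c(
    vapply(names(conc), function(s) sprintf(
      paste0('<species id="%s" compartment="imb" ',
             'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="false" constant="false"/>'),
      s, conc[[s]]), ""),
    vapply(names(bconc), function(s) sprintf(
      paste0('<species id="%s" compartment="imb" ',
             'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="true" constant="true"/>'),
      s, bconc[[s]]), ""))
  glb <- c(E_out = env$E_out, alpha = ps$constants$alpha,
           vT = ps$constants$vT)
  par_xml <- vapply(names(glb), function(p) sprintf(
    '<parameter id="%s" value="%.17g" constant="true"/>', p, glb[[p]]), "")
  rx <- .sbml_reactions()
  rx_xml <- vapply(names(rx), function(rid) {
    rr <- rx[[rid]]
    ref <- function(side) {
      sps <- rr[[side]]
      if (!length(sps)) return("")
      inner <- vapply(sps, function(s) sprintf(
        '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
        s, .sbml_stoich(rid, side, s)), "")
      tag <- if (side == "reactants") "listOfReactants" else "listOfProducts"
      sprintf("<%s>%s</%s>", tag, paste(inner, collapse = ""), tag)
    }
    locals <- vapply(rr$params, function(p) sprintf(
      '<localParameter id="%s" value="%.17g"/>',
      p, .param_value(ps, env, p)), "")
    sprintf(paste0(
      '<reaction id="%s" reversible="true">%s%s<kineticLaw>',
      '<math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>',
      '<listOfLocalParameters>%s</listOfLocalParameters>',
      '</kineticLaw></reaction>'),
      rid, ref("reactants"), ref("products"),
      .math_to_mathml(rr$math), paste(locals, collapse = ""))
  }, "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">\n',
    '<model id="sdh_reverse_transfer" name="%s">\n',
    '<listOfCompartments>',
    '<compartment id="imb" spatialDimensions="3" size="1" constant="true"/>',
    '</listOfCompartments>\n',
    '<listOfSpecies>%s</listOfSpecies>\n',
    '<listOfParameters>%s</listOfParameters>\n',
    '<listOfReactions>%s</listOfReactions>\n',
    '</model>\n</sbml>\n'),
    ps$label, paste(sp_xml, collapse = ""),
    paste(par_xml, collapse = ""), paste(rx_xml, collapse = ""))
  # validate well-formedness before writing
  xml2::read_xml(doc)
  writeLines(doc, file)
  invisible(file)
}

#' Import an exported SBML document
#'
#' Reads a document written by [write_sbml()] and reconstructs the
#' parameter set, clamped environment and state from its species initial
#' concentrations and (local and global) parameters. The reconstruction is
#' exact, so recomputing the reaction rates on the imported state
#' round-trips the exported model.
#'
#' @param file SBML file path.
#' @return A list with elements \code{ps} (\code{sdh_params}), \code{env}
#'   (\code{sdh_env}), \code{state} (named state vector) and \code{rates}
#'   (the [reaction_rates()] of that state).
#' @export
read_sbml_model <- function(file) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  conc <- stats::setNames(
    as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    xml2::xml_attr(sp, "id"))
  glb <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  gpar <- stats::setNames(as.numeric(xml2::xml_attr(glb, "value")),
                          xml2::xml_attr(glb, "id"))
  loc <- xml2::xml_find_all(doc, ".//localParameter")
  lpar <- stats::setNames(as.numeric(xml2::xml_attr(loc, "value")),
                          xml2::xml_attr(loc, "id"))
  if (anyDuplicated(names(lpar)))
    lpar <- lpar[!duplicated(names(lpar))]
  constants <- sdh_constants(vT = gpar[["vT"]], alpha = gpar[["alpha"]])
  ps <- build_base_parameters(constants = constants)
  for (nm in names(ps$k)) if (nm %in% names(lpar)) ps$k[[nm]] <- lpar[[nm]]
  for (nm in names(ps$Keq)) if (nm %in% names(lpar))
    ps$Keq[[nm]] <- lpar[[nm]]
  ps$Vmax21 <- lpar[["Vmax21"]]; ps$Km21 <- lpar[["Km21"]]
  ps$k22 <- lpar[["k22"]]
  ps$kr[["km10"]] <- ps$k[["k10"]] / ps$Keq[["Keq10"]]
  ps$kr[["km12"]] <- ps$k[["k12"]] / ps$Keq[["Keq12"]]
  ps$kr[["km14"]] <- ps$k[["k14"]] / ps$Keq[["Keq14"]]
  ps$kr[["km16"]] <- ps$k[["k16"]] / ps$Keq[["Keq16"]]
  ps$pools <- c(Fe3S4 = conc[["Fe3S4ox"]] + conc[["Fe3S4red"]],
                Fe4S4 = conc[["Fe4S4ox"]] + conc[["Fe4S4red"]],
                Fe2S2 = conc[["Fe2S2ox"]] + conc[["Fe2S2red"]],
                FAD = sum(conc[c("FAD", "FADfum", "FADHfum", "FADH2fum",
                                 "FADsuc", "FADHsuc", "FADH2suc",
                                 "FADH", "FADH2")]))
  env <- sdh_env(fum = conc[["fum"]], suc = conc[["suc"]],
                 E_out = gpar[["E_out"]], O2 = conc[["O2"]],
                 Hplus = conc[["Hplus"]])
  state <- stats::setNames(
    conc[c("Fe3S4red", "Fe4S4red", "Fe2S2red", "FADfum", "FADHfum",
           "FADH2fum", "FADsuc", "FADHsuc", "FADH2suc", "FADH", "FADH2",
           "O2sup", "H2O2")], species_names())
  list(ps = ps, env = env, state = state,
       rates = reaction_rates(state, env, ps, check = FALSE))
}
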