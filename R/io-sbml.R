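# SBML model I/O built on xml2. The writer emits SBML Level 3 with
# FBC-v2 flux bounds and an FBC objective for the biomass reaction.
# The reader is dialect-tolerant: it sniffs the level/version, accepts
# FBC bounds, the older kinetic-law LOWER_BOUND/UPPER_BOUND parameter
# style, or falls back to defaults from the `reversible` flag
# (with a warning), so both modern and 2018-era supplementary files load.

sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML
#'
#' @param path Path to an SBML file.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  doc <- xml2::read_xml(path)
  params <- sbml_parameters(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  species <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), xml2::xml_attr(sp_nodes, "id")),
    compartment = compartment_label(xml2::xml_attr(sp_nodes, "compartment"),
                                    xml2::xml_attr(sp_nodes, "boundaryCondition")),
    molar_mass = vapply(sp_nodes, note_value, numeric(1), key = "MOLAR_MASS")
  )

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  warned <- FALSE
  rxns <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    st <- c(speciesref(node, "listOfReactants", -1), speciesref(node, "listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- setNames(as.numeric(st), names(st))
    b <- sbml_bounds(node, params)
    if (is.null(b)) {
      if (!warned) {
        warn(sprintf("%s: no flux bounds found (e.g. reaction '%s'); using defaults from the reversible flag",
                     basename(path), id))
        warned <<- TRUE
      }
      b <- if (rev) c(-1000, 1000) else c(0, 1000)
    }
    reaction(id, st[abs(st) > 0], lb = b[1], ub = b[2],
             name = xml2::xml_attr(node, "name") %na% "",
             subsystem = "", genes = "")
  })

  meta <- model_notes(doc)
  biomass_id <- sbml_objective(doc) %||% meta$biomass
  metabolic_model(
    rxns, species = if (nrow(species)) species else NULL,
    biomass_id = biomass_id,
    exchange_ids = if (!is.null(meta$exchange)) split_ids(meta$exchange) else NULL,
    gam = if (!is.null(meta$gam)) as.numeric(meta$gam) else 25,
    oxidation_ids = if (!is.null(meta$oxidation)) split_ids(meta$oxidation) else character()
  )
}

`%na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

compartment_label <- function(comp, boundary) {
  ifelse(!is.na(boundary) & boundary == "true", "boundary",
         ifelse(is.na(comp), "cytoplasm",
                ifelse(comp %in% c("p", "out", "outside", "periplasm"), "outside",
                       ifelse(comp %in% c("e", "b", "ext", "extracellular", "boundary"),
                              "boundary", "cytoplasm"))))
}

speciesref <- function(node, listname, sign) {
  refs <- xml2::xml_find_all(node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", listname))
  if (!length(refs)) return(setNames(numeric(0), character(0)))
  coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
  coef[is.na(coef)] <- 1
  setNames(sign * coef, xml2::xml_attr(refs, "species"))
}

sbml_parameters <- function(doc) {
  p <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  setNames(as.numeric(xml2::xml_attr(p, "value")), xml2::xml_attr(p, "id"))
}

sbml_bounds <- function(node, params) {
  lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(node, "upperFluxBound")
  if (!is.na(lb_ref) && !is.na(ub_ref) && lb_ref %in% names(params) && ub_ref %in% names(params))
    return(c(params[[lb_ref]], params[[ub_ref]]))
  kl <- xml2::xml_find_all(node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter' or local-name()='localParameter']")
  if (length(kl)) {
    ids <- toupper(xml2::xml_attr(kl, "id"))
    vals <- as.numeric(xml2::xml_attr(kl, "value"))
    lo <- vals[match("LOWER_BOUND", ids)]
    hi <- vals[match("UPPER_BOUND", ids)]
    if (!is.na(lo) && !is.na(hi)) return(c(lo, hi))
  }
  NULL
}

sbml_objective <- function(doc) {
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing")) return(NULL)
  xml2::xml_attr(fo, "reaction")
}

note_value <- function(node, key) {
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(NA_real_)
  txt <- xml2::xml_text(notes)
  m <- regmatches(txt, regexec(paste0(key, ":\\s*([-0-9.eE+]+)"), txt))[[1]]
  if (length(m) < 2) NA_real_ else as.numeric(m[2])
}

model_notes <- function(doc) {
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  notes <- xml2::xml_find_first(model, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(list())
  paras <- xml2::xml_find_all(notes, ".//*[local-name()='p']")
  lines <- if (length(paras)) xml2::xml_text(paras)
           else strsplit(xml2::xml_text(notes), "\n", fixed = TRUE)[[1]]
  out <- list()
  for (key in c("biomass", "gam", "oxidation", "exchange")) {
    hit <- grep(paste0("(?i)^\\s*", key, ":"), lines, perl = TRUE, value = TRUE)
    if (length(hit))
      out[[key]] <- trimws(sub("^[^:]*:", "", hit[1]))
  }
  out
}

#' Write a metabolic model as SBML (Level 3, FBC v2)
#'
#' Flux bounds are written as FBC bound parameters, the biomass
#' reaction as the FBC objective; molar masses and model metadata
#' travel in notes so that `read_sbml(write_sbml(m))` restores the
#' model up to ordering.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            sbml_ns, fbc_ns),
    sprintf('  <model id="model" fbc:strict="true">')
  )
  meta <- c(
    if (!is.null(model$biomass_id)) sprintf("biomass: %s", model$biomass_id),
    sprintf("gam: %s", num(model$gam)),
    if (length(model$oxidation_ids)) sprintf("oxidation: %s", paste(model$oxidation_ids, collapse = ",")),
    if (length(model$exchange_ids)) sprintf("exchange: %s", paste(model$exchange_ids, collapse = ","))
  )
  lines <- c(lines,
    '    <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf('      <p>%s</p>', esc(meta)),
    '    </body></notes>')

  comps <- unique(model$species$compartment)
  lines <- c(lines, '    <listOfCompartments>',
             sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
             '    </listOfCompartments>')

  sp_line <- function(i) {
    s <- model$species[i, ]
    notes <- if (!is.na(s$molar_mass))
      sprintf('><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>MOLAR_MASS: %s</p></body></notes></species>',
              num(s$molar_mass))
    else '/>'
    sprintf('      <species id="%s" name="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"%s',
            esc(s$id), esc(s$name), esc(s$compartment),
            if (s$compartment == "boundary") "true" else "false", notes)
  }
  lines <- c(lines, '    <listOfSpecies>',
             vapply(seq_len(nrow(model$species)), sp_line, character(1)),
             '    </listOfSpecies>')

  bd <- reaction_bounds(model)
  bvals <- sort(unique(c(bd$lb, bd$ub, 0)))
  bid <- function(v) sprintf("bnd_%s", gsub("[^0-9a-zA-Z]", "_", num(v)))
  lines <- c(lines, '    <listOfParameters>',
             vapply(bvals, function(v)
               sprintf('      <parameter id="%s" value="%s" constant="true"/>', bid(v), num(v)),
               character(1)),
             '    </listOfParameters>')

  rx_lines <- unlist(lapply(model$reactions, function(r) {
    refs <- function(st, tag) {
      if (!length(st)) return(character(0))
      c(sprintf('        <%s>', tag),
        vapply(names(st), function(s)
          sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc(s), num(abs(st[[s]]))), character(1)),
        sprintf('        </%s>', tag))
    }
    c(sprintf('      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
              esc(r$id), esc(r$name), if (is_reversible(r)) "true" else "false",
              bid(r$lb), bid(r$ub)),
      refs(r$stoich[r$stoich < 0], "listOfReactants"),
      refs(r$stoich[r$stoich > 0], "listOfProducts"),
      '      </reaction>')
  }))
  lines <- c(lines, '    <listOfReactions>', rx_lines, '    </listOfReactions>')

  if (!is.null(model$biomass_id))
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>', esc(model$biomass_id)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')

  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
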