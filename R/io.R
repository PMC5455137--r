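# Model input/output: SBML Level 3 with FBC-style flux bounds (tolerating the
# older dialect that stores bounds as kinetic-law parameters and gene
# associations in notes), a diff-able two-table TSV dialect, and JSON export
# of flux states.

#' Load a metabolic model from file
#'
#' @param path for `format = "sbml"` an `.xml`/`.sbml` file; for
#'   `format = "table"` a path prefix: `<prefix>_reactions.tsv`,
#'   `<prefix>_metabolites.tsv` and `<prefix>_model.tsv` are read.
#' @param format `"sbml"` or `"table"`; guessed from the extension by default.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "sbml", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "table"
  }
  switch(format, sbml = read_model_sbml(path), table = read_model_table(path))
}

#' Write a metabolic model to file
#'
#' `load_model(write_model(m, path))` round-trips all stoichiometry, bounds,
#' gene associations and maintenance parameters.
#'
#' @param model a [metabolic_model()].
#' @inheritParams load_model
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "table"
  }
  validate_model(model)
  switch(format,
         sbml = write_model_sbml(model, path),
         table = write_model_table(model, path))
  invisible(path)
}

## ---- SBML ------------------------------------------------------------------

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_attr <- function(x) formatC(x, format = "g", digits = 15)

write_model_sbml <- function(model, path) {
  met <- model$metabolites; rxn <- model$reactions
  bounds <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  bid <- stats::setNames(paste0("bnd_", seq_along(bounds)), num_attr(bounds))
  bval <- function(v) bid[[num_attr(v)]]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', xml_esc(model$id)),
    '    <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf('      <p>BIOMASS_REACTION: %s</p>', model$biomass_reaction_id %||% ""),
    sprintf('      <p>NGAM_REACTION: %s</p>', model$ngam_reaction_id %||% ""),
    sprintf('      <p>ATP_PRODUCING: %s</p>', paste(model$atp_producing_ids, collapse = "; ")),
    sprintf('      <p>GAM: %s</p>', num_attr(model$gam)),
    sprintf('      <p>NGAM: %s</p>', num_attr(model$ngam)),
    sprintf('      <p>GENES: %s</p>', paste(model$genes, collapse = "; ")),
    '    </body></notes>',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', unique(met$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  lines <- c(lines, vapply(seq_len(nrow(met)), function(i) {
    extra <- ""
    if (!is.na(met$formula[i])) {
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', met$formula[i]))
    }
    if (!is.na(met$charge[i])) {
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', as.integer(met$charge[i])))
    }
    sprintf('      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
            met$id[i], xml_esc(met$name[i]), met$compartment[i], extra)
  }, character(1)),
  '    </listOfSpecies>',
  '    <listOfParameters>',
  sprintf('      <parameter id="%s" value="%s" constant="true"/>', unname(bid), names(bid)),
  '    </listOfParameters>',
  '    <listOfReactions>')
  sto <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  for (i in seq_len(nrow(rxn))) {
    s <- sto[[rxn$id[i]]]
    notes <- c(
      if (nzchar(rxn$gpr[i])) sprintf('        <p>GENE_ASSOCIATION: %s</p>', xml_esc(rxn$gpr[i])),
      if (length(rxn$ec[[i]]) > 0) sprintf('        <p>EC Number: %s</p>', paste(rxn$ec[[i]], collapse = "; ")),
      if (!is.na(rxn$kegg_id[i])) sprintf('        <p>KEGG: %s</p>', rxn$kegg_id[i]))
    lines <- c(lines,
      sprintf('      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
              rxn$id[i], xml_esc(rxn$name[i]),
              if (rxn$lower_bound[i] < 0) "true" else "false",
              bval(rxn$lower_bound[i]), bval(rxn$upper_bound[i])),
      if (length(notes) > 0) c('      <notes><body xmlns="http://www.w3.org/1999/xhtml">', notes, '      </body></notes>'))
    neg <- s[s$coefficient < 0, , drop = FALSE]
    pos <- s[s$coefficient > 0, , drop = FALSE]
    if (nrow(neg) > 0) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         neg$metabolite_id, num_attr(-neg$coefficient)),
                 '        </listOfReactants>')
    }
    if (nrow(pos) > 0) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         pos$metabolite_id, num_attr(pos$coefficient)),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

attr_any <- function(attrs, names) {
  for (nm in names) if (nm %in% names(attrs)) return(attrs[[nm]])
  NA_character_
}

note_field <- function(notes, key) {
  hit <- grep(paste0("^\\s*", key, "\\s*:"), notes, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  trimws(sub(paste0("^\\s*", key, "\\s*:"), "", hit[[1]]))
}

split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ";")[[1]])
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model_node))) stop("SBML parse failure: no <model> element")
  pnotes <- xml2::xml_text(xml2::xml_find_all(model_node, "./notes//p"))

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met <- purrr::map_dfr(sp, function(s) {
    a <- xml2::xml_attrs(s)
    notes <- xml2::xml_text(xml2::xml_find_all(s, "./notes//p"))
    formula <- attr_any(a, c("fbc:chemicalFormula", "chemicalFormula"))
    if (is.na(formula)) formula <- note_field(notes, "FORMULA")
    ch <- attr_any(a, c("fbc:charge", "charge"))
    if (is.na(ch)) ch <- note_field(notes, "CHARGE")
    tibble::tibble(
      id = a[["id"]],
      name = if ("name" %in% names(a)) a[["name"]] else a[["id"]],
      formula = formula,
      charge = if (is.na(ch)) NA_real_ else as.numeric(ch),
      compartment = attr_any(a, "compartment"))
  })

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pmap <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0) stop("SBML parse failure: no <reaction> elements")
  sto_list <- list(); rows <- list()
  for (r in rx) {
    a <- xml2::xml_attrs(r)
    rid <- a[["id"]]
    notes <- xml2::xml_text(xml2::xml_find_all(r, "./notes//p"))
    lb_ref <- attr_any(a, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ub_ref <- attr_any(a, c("fbc:upperFluxBound", "upperFluxBound"))
    lb <- if (!is.na(lb_ref)) pmap[[lb_ref]] else NA_real_
    ub <- if (!is.na(ub_ref)) pmap[[ub_ref]] else NA_real_
    if (is.na(lb) || is.na(ub)) {     # legacy dialect: kinetic-law parameters
      kl <- xml2::xml_find_all(r, ".//localParameter|.//parameter")
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kval[match("LOWER_BOUND", kid)]
      if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kval[match("UPPER_BOUND", kid)]
    }
    rev <- identical(attr_any(a, "reversible"), "true")
    if (is.na(lb)) lb <- if (rev) -1000 else 0
    if (is.na(ub)) ub <- 1000
    reac <- xml2::xml_find_all(r, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(r, "./listOfProducts/speciesReference")
    coef <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
              as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    mids <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    if (length(mids) > 0) {
      sto_list[[rid]] <- tibble::tibble(reaction_id = rid, metabolite_id = mids,
                                        coefficient = coef)
    }
    rows[[rid]] <- tibble::tibble(
      id = rid, name = if ("name" %in% names(a)) a[["name"]] else rid,
      lower_bound = lb, upper_bound = ub,
      gpr = note_field(notes, "GENE_ASSOCIATION") %|na|% "",
      ec = list(split_semi(note_field(notes, "EC Number"))),
      kegg_id = note_field(notes, "KEGG"))
  }
  biomass <- note_field(pnotes, "BIOMASS_REACTION")
  if (is.na(biomass) || !nzchar(biomass)) {
    # fall back to an id/name mention of biomass
    rxn_all <- dplyr::bind_rows(rows)
    cand <- grep("biomass", paste(rxn_all$id, rxn_all$name), ignore.case = TRUE)
    if (length(cand) == 0) stop("model validation: no biomass reaction declared or detectable")
    biomass <- rxn_all$id[cand[[1]]]
  }
  ngam_id <- note_field(pnotes, "NGAM_REACTION")
  gam <- note_field(pnotes, "GAM"); ngam <- note_field(pnotes, "NGAM")
  metabolic_model(
    metabolites = met, reactions = dplyr::bind_rows(rows),
    stoichiometry = dplyr::bind_rows(sto_list),
    biomass_reaction_id = biomass,
    ngam_reaction_id = if (is.na(ngam_id) || !nzchar(ngam_id)) NULL else ngam_id,
    atp_producing_ids = split_semi(note_field(pnotes, "ATP_PRODUCING")),
    genes = split_semi(note_field(pnotes, "GENES")),
    gam = if (is.na(gam)) 40 else as.numeric(gam),
    ngam = if (is.na(ngam)) 5 else as.numeric(ngam),
    id = xml2::xml_attr(model_node, "id") %|na|% "model")
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## ---- tabular ---------------------------------------------------------------

equation_string <- function(sto, reversible) {
  term <- function(d) paste(sprintf("%s %s", num_attr(abs(d$coefficient)),
                                    d$metabolite_id), collapse = " + ")
  lhs <- term(sto[sto$coefficient < 0, , drop = FALSE])
  rhs <- term(sto[sto$coefficient > 0, , drop = FALSE])
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

parse_equation <- function(eq, rid) {
  sides <- strsplit(eq, "<=>|->")[[1]]
  if (length(sides) > 2) stop("malformed equation for ", rid, ": ", eq)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(NULL)
    terms <- trimws(strsplit(txt, "\\+")[[1]])
    terms <- terms[nzchar(terms)]
    coef <- rep(1, length(terms)); mid <- terms
    two <- grepl("\\s", terms)
    coef[two] <- as.numeric(sub("\\s.*$", "", terms[two]))
    mid[two] <- sub("^\\S+\\s+", "", terms[two])
    if (anyNA(coef)) stop("malformed equation for ", rid, ": ", eq)
    tibble::tibble(reaction_id = rid, metabolite_id = mid, coefficient = sign * coef)
  }
  dplyr::bind_rows(parse_side(sides[1], -1),
                   if (length(sides) == 2) parse_side(sides[2], 1))
}

write_model_table <- function(model, prefix) {
  sto <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  rxn <- model$reactions
  readr::write_tsv(tibble::tibble(
    id = rxn$id, name = rxn$name,
    equation = vapply(seq_len(nrow(rxn)), function(i)
      equation_string(sto[[rxn$id[i]]], rxn$lower_bound[i] < 0), character(1)),
    lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
    gpr = rxn$gpr,
    ec = vapply(rxn$ec, paste, character(1), collapse = "; "),
    kegg_id = rxn$kegg_id), paste0(prefix, "_reactions.tsv"))
  readr::write_tsv(model$metabolites, paste0(prefix, "_metabolites.tsv"))
  readr::write_tsv(tibble::tibble(
    key = c("id", "biomass_reaction_id", "ngam_reaction_id", "atp_producing_ids",
            "gam", "ngam", "genes"),
    value = c(model$id, model$biomass_reaction_id %||% "",
              model$ngam_reaction_id %||% "",
              paste(model$atp_producing_ids, collapse = "; "),
              num_attr(model$gam), num_attr(model$ngam),
              paste(model$genes, collapse = "; "))),
    paste0(prefix, "_model.tsv"))
  invisible(prefix)
}

read_model_table <- function(prefix) {
  fr <- paste0(prefix, "_reactions.tsv")
  fm <- paste0(prefix, "_metabolites.tsv")
  fo <- paste0(prefix, "_model.tsv")
  for (f in c(fr, fm, fo)) if (!file.exists(f)) stop("file not found: ", f)
  rxn <- readr::read_tsv(fr, show_col_types = FALSE)
  met <- readr::read_tsv(fm, show_col_types = FALSE,
                         col_types = readr::cols(formula = readr::col_character()))
  meta <- readr::read_tsv(fo, show_col_types = FALSE)
  kv <- stats::setNames(as.character(meta$value), meta$key)
  kv[is.na(kv)] <- ""
  sto <- dplyr::bind_rows(purrr::map2(rxn$equation, rxn$id, parse_equation))
  metabolic_model(
    metabolites = met,
    reactions = dplyr::select(rxn, -"equation"),
    stoichiometry = sto,
    biomass_reaction_id = if (nzchar(kv[["biomass_reaction_id"]])) kv[["biomass_reaction_id"]] else
      stop("model validation: no biomass reaction declared in ", fo),
    ngam_reaction_id = if (nzchar(kv[["ngam_reaction_id"]])) kv[["ngam_reaction_id"]] else NULL,
    atp_producing_ids = split_semi(kv[["atp_producing_ids"]]),
    genes = split_semi(kv[["genes"]]),
    gam = as.numeric(kv[["gam"]]), ngam = as.numeric(kv[["ngam"]]),
    id = kv[["id"]])
}

## ---- flux state JSON -------------------------------------------------------

#' Export a flux state to JSON
#'
#' @param flux a `flux_state` as returned by [solve_fba()].
#' @param path output file.
#' @export
write_flux_json <- function(flux, path) {
  jsonlite::write_json(
    list(objective_value = flux$objective_value, status = flux$status,
         objective = if (is.null(flux$objective)) "lp_biomass" else
           flux$objective$kind,
         w = flux$objective$w,
         fluxes = as.list(flux$fluxes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flux state from JSON
#'
#' @param path file written by [write_flux_json()].
#' @return a `flux_state`.
#' @export
read_flux_json <- function(path) {
  d <- jsonlite::fromJSON(path)
  new_flux_state(unlist(d$fluxes), d$objective_value, d$status)
}
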