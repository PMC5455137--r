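# The metabolic_model class: a list of tibbles describing a constraint-based
# (stoichiometric) model of metabolism. Fluxes are in mmol gDW^-1 h^-1 except
# the biomass reaction, whose flux is the specific growth rate in h^-1.

#' Construct a metabolic model
#'
#' @param metabolites tibble/data frame with columns `id`, `name` (optional),
#'   `formula` (elemental formula string, `NA` when unknown), `charge`
#'   (integer), `compartment` (`"c"` cytosol or `"e"` extracellular).
#' @param reactions tibble/data frame with columns `id`, `name` (optional),
#'   `lower_bound`, `upper_bound` (mmol gDW^-1 h^-1), `gpr` (boolean gene
#'   association string, may be `""`), `ec` (list-column of EC number character
#'   vectors, or a `;`-separated string column), `kegg_id` (optional).
#' @param stoichiometry tibble/data frame with columns `reaction_id`,
#'   `metabolite_id`, `coefficient` (negative = consumed).
#' @param biomass_reaction_id,ngam_reaction_id ids of the biomass reaction and
#'   of the non-growth-associated ATP maintenance reaction.
#' @param atp_producing_ids reaction ids counted as ATP producing by the
#'   weighted objective (see [solve_fba()]).
#' @param genes character vector of gene ids; defaults to the genes mentioned
#'   in the `gpr` strings.
#' @param gam growth-associated maintenance, mmol ATP gDW^-1 (default 40).
#' @param ngam non-growth-associated maintenance, mmol ATP gDW^-1 h^-1
#'   (default 5).
#' @param id model identifier.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            biomass_reaction_id, ngam_reaction_id = NULL,
                            atp_producing_ids = character(0),
                            genes = NULL, gam = 40, ngam = 5, id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"kegg_id" %in% names(reactions)) reactions$kegg_id <- NA_character_
  if (!"ec" %in% names(reactions)) reactions$ec <- list(character(0))
  if (is.character(reactions$ec)) {
    reactions$ec <- lapply(reactions$ec, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";\\s*")[[1]]
    })
  }
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(genes)) genes <- genes_from_gpr(reactions$gpr)
  # exchange reactions touch exactly one metabolite
  n_met <- table(factor(stoichiometry$reaction_id, levels = reactions$id))
  reactions$is_exchange <- as.integer(n_met[reactions$id]) == 1L
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = genes,
         biomass_reaction_id = biomass_reaction_id,
         ngam_reaction_id = ngam_reaction_id,
         atp_producing_ids = atp_producing_ids,
         gam = gam, ngam = ngam, id = id),
    class = "metabolic_model")
  validate_model(model)
}

genes_from_gpr <- function(gpr) {
  toks <- unlist(strsplit(gpr, "[()\\s]+"))
  sort(unique(setdiff(toks, c("", "and", "or", "AND", "OR"))))
}

validate_model <- function(model) {
  met <- model$metabolites; rxn <- model$reactions; sto <- model$stoichiometry
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids")
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    stop("lower_bound > upper_bound for: ",
         paste(rxn$id[rxn$lower_bound > rxn$upper_bound], collapse = ", "))
  }
  if (!all(sto$metabolite_id %in% met$id)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(setdiff(sto$metabolite_id, met$id), collapse = ", "))
  }
  if (!all(sto$reaction_id %in% rxn$id)) {
    stop("stoichiometry references unknown reactions: ",
         paste(setdiff(sto$reaction_id, rxn$id), collapse = ", "))
  }
  if (!is.null(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% rxn$id) {
    stop("biomass reaction '", model$biomass_reaction_id, "' not in model")
  }
  if (!is.null(model$ngam_reaction_id) && !model$ngam_reaction_id %in% rxn$id) {
    stop("NGAM reaction '", model$ngam_reaction_id, "' not in model")
  }
  missing_atp <- setdiff(model$atp_producing_ids, rxn$id)
  if (length(missing_atp) > 0) {
    stop("atp_producing_ids not in model: ", paste(missing_atp, collapse = ", "))
  }
  if (!is.numeric(met$charge)) stop("metabolite charge must be numeric")
  bad_charge <- !is.na(met$charge) & abs(met$charge - round(met$charge)) > 1e-9
  if (any(bad_charge)) {
    stop("non-integer metabolite charge: ", paste(met$id[bad_charge], collapse = ", "))
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)",
      "  genes: ", length(x$genes), "\n", sep = "")
  cat("  biomass: ", x$biomass_reaction_id %||% "<none>",
      "  GAM: ", x$gam, "  NGAM: ", x$ngam, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense stoichiometric matrix, metabolites x reactions
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  S[cbind(model$stoichiometry$metabolite_id, model$stoichiometry$reaction_id)] <-
    model$stoichiometry$coefficient
  S
}

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id: ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Summary counts of a metabolic model
#'
#' Partitions reactions into cytosolic, transport (non-exchange reactions that
#' touch more than one compartment) and exchange classes; counts genes, unique
#' EC numbers, and metabolites.
#'
#' @param model a [metabolic_model()].
#' @return a tibble with columns `feature` and `n`.
#' @export
model_summary <- function(model) {
  rxn <- model$reactions
  if (nrow(rxn) == 0) {
    cls <- character(0)
  } else {
    comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
    ncomp <- vapply(split(comp[model$stoichiometry$metabolite_id],
                          model$stoichiometry$reaction_id),
                    function(x) length(unique(x)), integer(1))
    cls <- ifelse(rxn$is_exchange, "exchange",
                  ifelse(ncomp[rxn$id] > 1, "transport", "cytosolic"))
    cls[is.na(cls)] <- "cytosolic"   # reactions with no participants
  }
  tibble::tibble(
    feature = c("genes", "enzymes", "total_reactions", "cytosolic_reactions",
                "transport_reactions", "exchange_reactions", "total_metabolites"),
    n = c(length(model$genes),
          length(unique(unlist(model$reactions$ec))),
          nrow(rxn),
          sum(cls == "cytosolic"), sum(cls == "transport"), sum(cls == "exchange"),
          nrow(model$metabolites)))
}

#' Check atom and charge balance of internal reactions
#'
#' Every non-exchange reaction is checked element-by-element and for net
#' charge. The biomass reaction is exempt unless its biomass metabolite has a
#' formula. Reactions touching a metabolite without a formula are reported as
#' `unverifiable` rather than failing.
#'
#' @param model a [metabolic_model()].
#' @param tol_formula atom-count tolerance (default 1e-4).
#' @return tibble with columns `reaction_id`, `element` (`"charge"` for charge
#'   imbalance, `NA` for unverifiable reactions), `imbalance`, `status`. Empty
#'   iff every checkable internal reaction balances.
#' @export
check_balance <- function(model, tol_formula = 1e-4) {
  met <- model$metabolites
  atoms <- lapply(stats::setNames(met$formula, met$id), function(f) {
    if (is.na(f)) NULL else parse_formula(f)
  })
  charge <- stats::setNames(met$charge, met$id)
  out <- list()
  biomass_id <- model$biomass_reaction_id
  biomass_met_formula_known <- FALSE
  if (!is.null(biomass_id)) {
    prods <- model$stoichiometry[model$stoichiometry$reaction_id == biomass_id &
                                   model$stoichiometry$coefficient > 0, ]
    biomass_met_formula_known <- nrow(prods) > 0 &&
      all(!is.na(met$formula[match(prods$metabolite_id, met$id)]))
  }
  for (rid in model$reactions$id[!model$reactions$is_exchange]) {
    if (!is.null(biomass_id) && rid == biomass_id && !biomass_met_formula_known) next
    sto <- model$stoichiometry[model$stoichiometry$reaction_id == rid, ]
    if (any(vapply(atoms[sto$metabolite_id], is.null, logical(1)))) {
      out[[length(out) + 1L]] <- tibble::tibble(
        reaction_id = rid, element = NA_character_, imbalance = NA_real_,
        status = "unverifiable")
      next
    }
    tot <- numeric(0)
    for (k in seq_len(nrow(sto))) {
      a <- atoms[[sto$metabolite_id[k]]] * sto$coefficient[k]
      for (e in names(a)) tot[e] <- (if (e %in% names(tot)) tot[e] else 0) + a[[e]]
    }
    bad <- tot[abs(tot) > tol_formula]
    if (length(bad) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        reaction_id = rid, element = names(bad), imbalance = unname(bad),
        status = "imbalance")
    }
    q <- sum(charge[sto$metabolite_id] * sto$coefficient)
    if (is.na(q)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        reaction_id = rid, element = NA_character_, imbalance = NA_real_,
        status = "unverifiable")
    } else if (abs(q) > tol_formula) {
      out[[length(out) + 1L]] <- tibble::tibble(
        reaction_id = rid, element = "charge", imbalance = q, status = "imbalance")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(reaction_id = character(0), element = character(0),
                          imbalance = numeric(0), status = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Elemental composition of biomass, normalized per carbon atom
#'
#' Sums the atoms of every metabolite consumed by the biomass reaction
#' (stoichiometric coefficient < 0) and divides by the total carbon, giving
#' the C1 biomass formula (e.g. `CH1.6O0.5N0.2`).
#'
#' @param model a [metabolic_model()].
#' @return named numeric vector of atoms per carbon; use [format_formula()]
#'   for display.
#' @export
biomass_elemental_composition <- function(model) {
  bid <- model$biomass_reaction_id
  if (is.null(bid)) stop("model has no biomass reaction")
  sto <- model$stoichiometry[model$stoichiometry$reaction_id == bid &
                               model$stoichiometry$coefficient < 0, ]
  if (nrow(sto) == 0) stop("biomass reaction consumes nothing")
  met <- model$metabolites
  f <- met$formula[match(sto$metabolite_id, met$id)]
  if (anyNA(f)) {
    stop("biomass precursors without formula: ",
         paste(sto$metabolite_id[is.na(f)], collapse = ", "))
  }
  tot <- numeric(0)
  for (k in seq_len(nrow(sto))) {
    a <- parse_formula(f[k]) * abs(sto$coefficient[k])
    for (e in names(a)) tot[e] <- (if (e %in% names(tot)) tot[e] else 0) + a[[e]]
  }
  if (!"C" %in% names(tot) || tot[["C"]] <= 0) {
    stop("biomass precursors contain no carbon; per-C composition undefined")
  }
  tot / tot[["C"]]
}
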