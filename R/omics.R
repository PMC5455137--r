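# Qualitative consistency scoring of predicted fluxes against expressed-enzyme
# lists (proteome or transcriptome). The comparison is EC-level and
# qualitative: an expressed enzyme is "predicted" when any reaction it
# catalyzes carries flux; enzymes blocked by network structure are excluded.

#' Expressed-enzyme list
#'
#' @param ecs character vector of EC numbers (`d.d.d.d`; trailing segments
#'   may be `-` for partial ECs, which match model ECs by prefix).
#'   Duplicates are dropped.
#' @param source `"proteome"`, `"transcriptome"` or `"synthetic"`.
#' @param provenance free-text label.
#' @return an `expression_set`.
#' @export
expression_set <- function(ecs, source = c("proteome", "transcriptome", "synthetic"),
                           provenance = NULL) {
  source <- match.arg(source)
  ecs <- unique(trimws(ecs))
  ok <- grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", ecs)
  if (any(!ok)) {
    stop("malformed EC numbers: ", paste(utils::head(ecs[!ok], 5), collapse = ", "))
  }
  structure(list(ecs = ecs, source = source, provenance = provenance),
            class = "expression_set")
}

#' Read an expression list from TSV
#'
#' Expects a two-column file (`ec`, `label`); extra columns are ignored.
#'
#' @param path TSV file.
#' @inheritParams expression_set
#' @export
read_expression_tsv <- function(path, source = "proteome") {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  expression_set(d[[1]], source = source, provenance = path)
}

# match an (possibly dashed) expression EC against model ECs
match_ec <- function(ec, model_ecs) {
  if (!grepl("-", ec)) return(model_ecs[model_ecs == ec])
  prefix <- sub("-.*$", "", ec)
  model_ecs[startsWith(model_ecs, prefix)]
}

#' Compare predicted fluxes with an expressed-enzyme list
#'
#' Enzymes shared between the model and the expression list are scored:
#' `excluded` when blocked by network structure (no reaction can ever carry
#' flux), `predicted` when any catalyzed reaction has `|v| > tol_zero` in the
#' supplied flux state, else `not_predicted`. The prediction rate is
#' `predicted / (shared - excluded)`.
#'
#' @param model a [metabolic_model()].
#' @param flux a `flux_state` solved under the culture condition matching the
#'   expression experiment.
#' @param coupling a `coupling_report` for the model (used for the blocked
#'   exclusion and per-enzyme class annotation).
#' @param expr an [expression_set()].
#' @param tol_zero activity threshold.
#' @return a `comparison_report`: list with `enzymes` (per shared enzyme:
#'   `ec`, `status`, `coupling_class`), `unshared` (expression ECs absent
#'   from the model), and `summary` (counts and `prediction_rate`).
#' @export
compare_expression <- function(model, flux, coupling, expr, tol_zero = 1e-6) {
  stopifnot(inherits(expr, "expression_set"))
  rxn <- model$reactions
  ec_map <- tibble::tibble(ec = unlist(rxn$ec),
                           reaction = rep(rxn$id, lengths(rxn$ec)))
  model_ecs <- unique(ec_map$ec)
  matched <- lapply(expr$ecs, match_ec, model_ecs = model_ecs)
  unshared <- expr$ecs[lengths(matched) == 0]
  shared <- unique(unlist(matched))
  cls <- stats::setNames(coupling$enzymes$class, coupling$enzymes$ec)
  v <- flux$fluxes
  enzymes <- purrr::map_dfr(shared, function(ec) {
    rids <- ec_map$reaction[ec_map$ec == ec]
    active <- any(abs(v[rids]) > tol_zero, na.rm = TRUE)
    cc <- unname(cls[ec]) %|na|% "uncoupled"
    status <- if (cc == "blocked") "excluded"
      else if (active) "predicted" else "not_predicted"
    tibble::tibble(ec = ec, status = status, coupling_class = cc)
  })
  n_shared <- nrow(enzymes)
  n_excl <- sum(enzymes$status == "excluded")
  n_pred <- sum(enzymes$status == "predicted")
  summary <- tibble::tibble(
    source = expr$source, shared = n_shared, excluded = n_excl,
    predicted = n_pred, not_predicted = n_shared - n_excl - n_pred,
    prediction_rate = if (n_shared > n_excl) n_pred / (n_shared - n_excl) else NaN)
  structure(list(enzymes = enzymes, unshared = unshared, summary = summary),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$summary)
  invisible(x)
}

#' Break down non-predicted enzymes by coupling class
#'
#' Expressed-but-inactive enzymes should only ever be directionally coupled
#' to growth (a fully or partially coupled enzyme must carry flux whenever
#' the culture grows); a warning is raised if that structural expectation is
#' violated.
#'
#' @param report a `comparison_report`.
#' @return tibble of non-predicted enzymes with `ec` and `coupling_class`,
#'   plus a `counts` attribute (per-class tally).
#' @export
unpredicted_breakdown <- function(report) {
  np <- report$enzymes[report$enzymes$status == "not_predicted", c("ec", "coupling_class")]
  if (any(np$coupling_class %in% c("full", "partial"))) {
    warning("non-predicted enzymes with full/partial growth coupling: ",
            "inconsistent with a growing flux state")
  }
  attr(np, "counts") <- table(np$coupling_class)
  np
}
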