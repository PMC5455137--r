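# Synthetic fixture models. The toy glycerol network reproduces, at ~20
# reactions, the structure the analysis assumes for an anaerobic PDO producer:
# an oxidative branch (glycerol -> pyruvate) yielding ATP and NADH with
# acetate/butyrate/lactate/ethanol/formate/H2 sinks, a reductive NADH-consuming
# branch (glycerol -> 3-HPA -> PDO), pyruvate:ferredoxin oxidoreductase, a
# reversible ferredoxin:NAD reductase, a hydrogenase, a biomass reaction with
# GAM, and an NGAM reaction. Every internal reaction is atom and charge
# balanced (textbook integer coefficients; NAD/NADH, ATP/ADP and ferredoxin
# carried with full formulas, ferredoxin as pseudo-element "Fd").

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

toy_metabolites <- function() {
  tibble::tribble(
    ~id,        ~name,                 ~formula,          ~charge, ~compartment,
    "glyc_e",   "glycerol (ext)",      "C3H8O3",           0,      "e",
    "glyc_c",   "glycerol",            "C3H8O3",           0,      "c",
    "glc_e",    "glucose (ext)",       "C6H12O6",          0,      "e",
    "glc_c",    "glucose",             "C6H12O6",          0,      "c",
    "pyr_c",    "pyruvate",            "C3H3O3",          -1,      "c",
    "acp_c",    "acetyl phosphate",    "C2H3O5P",         -2,      "c",
    "ac_c",     "acetate",             "C2H3O2",          -1,      "c",
    "but_c",    "butyrate",            "C4H7O2",          -1,      "c",
    "lac_c",    "lactate",             "C3H5O3",          -1,      "c",
    "etoh_c",   "ethanol",             "C2H6O",            0,      "c",
    "for_c",    "formate",             "CHO2",            -1,      "c",
    "h2_c",     "hydrogen",            "H2",               0,      "c",
    "co2_c",    "carbon dioxide",      "CO2",              0,      "c",
    "hpa_c",    "3-hydroxypropanal",   "C3H6O2",           0,      "c",
    "pdo_c",    "1,3-propanediol",     "C3H8O2",           0,      "c",
    "nad_c",    "NAD+",                "C21H26N7O14P2",   -1,      "c",
    "nadh_c",   "NADH",                "C21H27N7O14P2",   -2,      "c",
    "atp_c",    "ATP",                 "C10H12N5O13P3",   -4,      "c",
    "adp_c",    "ADP",                 "C10H12N5O10P2",   -3,      "c",
    "pi_c",     "phosphate",           "HO4P",            -2,      "c",
    "fdox_c",   "oxidized ferredoxin", "Fd",               0,      "c",
    "fdred_c",  "reduced ferredoxin (2 e-)", "Fd",        -2,      "c",
    "h2o_c",    "water",               "H2O",              0,      "c",
    "h_c",      "proton",              "H",                1,      "c",
    "nh4_c",    "ammonium",            "H4N",              1,      "c",
    "precc_c",  "carbon-skeleton precursor", "C3H5O2",    -1,      "c",
    "precn_c",  "nitrogen precursor",  "C3H7NO2",          0,      "c",
    "lipid_c",  "lipid precursor",     "C8H15O2",         -1,      "c",
    "biomass_c", "biomass",            NA_character_,     NA,      "c")
}

toy_reaction_defs <- function(gam, ngam) {
  # each row: id, name, stoichiometry string, lb, ub, gpr, ec, branch
  list(
    list("EX_glyc", "glycerol exchange", "1 glyc_e <=>", -10, 1000, "", character(0), "core"),
    list("T_glyc", "glycerol transport", "1 glyc_e -> 1 glyc_c", 0, 1000, "g_tglyc", character(0), "core"),
    list("OXI", "oxidative branch (glycerol -> pyruvate)",
         "1 glyc_c + 2 nad_c + 1 adp_c + 1 pi_c -> 1 pyr_c + 2 nadh_c + 1 atp_c + 1 h2o_c + 2 h_c",
         0, 1000, "g_oxi", "1.1.1.6", "core"),
    list("PFOR", "pyruvate:ferredoxin oxidoreductase",
         "1 pyr_c + 1 pi_c + 1 fdox_c -> 1 acp_c + 1 co2_c + 1 fdred_c + 1 h_c",
         0, 1000, "g_pfor", "1.2.7.1", "core"),
    list("PFL", "pyruvate formate lyase",
         "1 pyr_c + 1 pi_c -> 1 acp_c + 1 for_c", 0, 1000, "g_pfl", "2.3.1.54", "formate"),
    list("ACK", "acetate kinase",
         "1 acp_c + 1 adp_c -> 1 ac_c + 1 atp_c", 0, 1000, "g_ack", "2.7.2.1", "acetate"),
    list("BUK", "butyrate formation (lumped)",
         "2 acp_c + 2 nadh_c + 1 adp_c + 2 h_c -> 1 but_c + 1 atp_c + 2 nad_c + 1 pi_c + 1 h2o_c",
         0, 1000, "g_buk", "2.7.2.7", "butyrate"),
    list("LDH", "lactate dehydrogenase",
         "1 pyr_c + 1 nadh_c + 1 h_c -> 1 lac_c + 1 nad_c",
         0, 1000, "g_ldh1 or g_ldh2", c("1.1.1.27", "1.1.1.28"), "lactate"),
    list("ADHE", "ethanol formation (lumped)",
         "1 acp_c + 2 nadh_c + 2 h_c -> 1 etoh_c + 2 nad_c + 1 pi_c",
         0, 1000, "g_adhe", "1.1.1.1", "ethanol"),
    list("DHAT", "glycerol dehydratase",
         "1 glyc_c -> 1 hpa_c + 1 h2o_c", 0, 1000, "g_dhat", "4.2.1.30", "pdo"),
    list("PDODH", "PDO dehydrogenase",
         "1 hpa_c + 1 nadh_c + 1 h_c -> 1 pdo_c + 1 nad_c",
         0, 1000, "g_pdodh", "1.1.1.202", "pdo"),
    list("HYD", "hydrogenase",
         "1 fdred_c + 2 h_c -> 1 h2_c + 1 fdox_c", 0, 1000, "g_hyd", "1.12.7.2", "h2"),
    list("FNR", "ferredoxin:NAD reductase (reversible)",
         "1 nadh_c + 1 fdox_c <=> 1 nad_c + 1 fdred_c + 1 h_c",
         -1000, 1000, "g_fnr", "1.18.1.3", "ferredoxin"),
    list("ATPM", "non-growth-associated maintenance",
         "1 atp_c + 1 h2o_c -> 1 adp_c + 1 pi_c + 1 h_c", ngam, ngam, "", character(0), "core"),
    list("PC", "carbon-skeleton precursor synthesis",
         "1 pyr_c + 2 nadh_c + 2 h_c -> 1 precc_c + 2 nad_c + 1 h2o_c",
         0, 1000, "g_pc", "1.1.1.169", "core"),
    list("ALA", "nitrogen precursor synthesis",
         "1 pyr_c + 1 nh4_c + 1 nadh_c + 1 h_c -> 1 precn_c + 1 nad_c + 1 h2o_c",
         0, 1000, "g_ala", "2.6.1.2", "core"),
    list("LIP", "lipid precursor synthesis",
         "4 acp_c + 6 nadh_c + 5 h_c -> 1 lipid_c + 4 pi_c + 6 nad_c + 2 h2o_c",
         0, 1000, "g_lip", "2.3.1.85", "core"),
    list("BIOMASS", "biomass synthesis",
         sprintf("4.106 precc_c + 6.173 precn_c + 1.047 lipid_c + %g atp_c + %g h2o_c -> 1 biomass_c + %g adp_c + %g pi_c + %g h_c",
                 gam, gam, gam, gam, gam),
         0, 1000, "", character(0), "core"),
    list("GLYCL", "glycolysis (lumped)",
         "1 glc_c + 2 nad_c + 2 adp_c + 2 pi_c -> 2 pyr_c + 2 nadh_c + 2 atp_c + 2 h2o_c + 2 h_c",
         0, 1000, "g_glk", "2.7.1.2", "glucose"),
    list("T_glc", "glucose transport", "1 glc_e -> 1 glc_c", 0, 1000, "g_tglc", character(0), "glucose"),
    list("EX_glc", "glucose exchange", "1 glc_e <=>", 0, 1000, "", character(0), "glucose"),
    list("EX_biomass", "biomass sink", "1 biomass_c ->", 0, 1000, "", character(0), "core"),
    list("EX_ac", "acetate exchange", "1 ac_c <=>", 0, 1000, "", character(0), "acetate"),
    list("EX_but", "butyrate exchange", "1 but_c <=>", 0, 1000, "", character(0), "butyrate"),
    list("EX_lac", "lactate exchange", "1 lac_c <=>", 0, 1000, "", character(0), "lactate"),
    list("EX_etoh", "ethanol exchange", "1 etoh_c <=>", 0, 1000, "", character(0), "ethanol"),
    list("EX_for", "formate exchange", "1 for_c <=>", 0, 1000, "", character(0), "formate"),
    list("EX_h2", "hydrogen exchange", "1 h2_c <=>", 0, 1000, "", character(0), "h2"),
    list("EX_co2", "CO2 exchange", "1 co2_c <=>", 0, 1000, "", character(0), "core"),
    list("EX_pdo", "PDO exchange", "1 pdo_c <=>", 0, 1000, "", character(0), "pdo"),
    list("EX_h2o", "water exchange", "1 h2o_c <=>", -1000, 1000, "", character(0), "core"),
    list("EX_h", "proton exchange", "1 h_c <=>", -1000, 1000, "", character(0), "core"),
    list("EX_nh4", "ammonium exchange", "1 nh4_c <=>", -1000, 1000, "", character(0), "core"))
}

#' Synthetic anaerobic glycerol fermentation network
#'
#' Builds a small, fully atom- and charge-balanced model of anaerobic glycerol
#' metabolism with oxidative (ATP/NADH/acids/H2) and reductive (NADH-consuming
#' PDO) branches. All branches are optional except the biomass path; switching
#' a branch off removes its reactions, exchanges and orphaned metabolites.
#'
#' @param branches character vector of optional branches to include; any of
#'   `"acetate"`, `"butyrate"`, `"lactate"`, `"ethanol"`, `"formate"`, `"h2"`,
#'   `"pdo"`, `"ferredoxin"`, `"glucose"` (a lumped glycolysis entry used by
#'   the co-fermentation screens; off by default).
#' @param gam growth-associated maintenance, mmol ATP gDW^-1.
#' @param ngam non-growth-associated maintenance, mmol ATP gDW^-1 h^-1; the
#'   maintenance reaction is fixed at this rate.
#' @return a [metabolic_model()].
#' @examples
#' m <- toy_glycerol_model()
#' model_summary(m)
#' @export
toy_glycerol_model <- function(branches = c("acetate", "butyrate", "lactate",
                                            "ethanol", "formate", "h2", "pdo",
                                            "ferredoxin"),
                               gam = 40, ngam = 5) {
  known <- c("acetate", "butyrate", "lactate", "ethanol", "formate", "h2",
             "pdo", "ferredoxin", "glucose")
  bad <- setdiff(branches, known)
  if (length(bad) > 0) stop("unknown branches: ", paste(bad, collapse = ", "))
  defs <- toy_reaction_defs(gam, ngam)
  keep <- vapply(defs, function(d) d[[8]] == "core" || d[[8]] %in% branches,
                 logical(1))
  defs <- defs[keep]
  rxn <- tibble::tibble(
    id = vapply(defs, `[[`, character(1), 1),
    name = vapply(defs, `[[`, character(1), 2),
    lower_bound = vapply(defs, `[[`, numeric(1), 4),
    upper_bound = vapply(defs, `[[`, numeric(1), 5),
    gpr = vapply(defs, `[[`, character(1), 6),
    ec = lapply(defs, `[[`, 7),
    kegg_id = NA_character_)
  sto <- dplyr::bind_rows(purrr::map2(
    vapply(defs, `[[`, character(1), 3), rxn$id, parse_equation))
  met <- toy_metabolites()
  met <- met[met$id %in% unique(sto$metabolite_id), ]
  metabolic_model(
    metabolites = met, reactions = rxn, stoichiometry = sto,
    biomass_reaction_id = "BIOMASS", ngam_reaction_id = "ATPM",
    atp_producing_ids = intersect(c("OXI", "ACK", "BUK", "GLYCL"), rxn$id),
    gam = gam, ngam = ngam, id = "toy_glycerol")
}

#' Random mass-balanced test-bed model
#'
#' Generates a connected random network over `n_metabolites` single-carbon
#' metabolites with an uptake exchange, a terminal sink exchange (designated
#' as the growth/target reaction) and random internal conversions, all
#' trivially mass balanced. Deterministic for a given seed.
#'
#' @param n_metabolites,n_reactions network size; `n_reactions` must be at
#'   least `n_metabolites + 1` so the system stays underdetermined with both
#'   exchanges present.
#' @param seed integer seed.
#' @param p_reversible probability that an internal reaction is reversible.
#' @return a [metabolic_model()] whose `biomass_reaction_id` is the terminal
#'   sink exchange.
#' @export
random_model <- function(n_metabolites, n_reactions, seed = 1,
                         p_reversible = 0.3) {
  if (n_reactions < n_metabolites + 1) {
    stop("need n_reactions >= n_metabolites + 1 for an underdetermined network")
  }
  with_seed(seed, {
    mids <- sprintf("m%02d", seq_len(n_metabolites))
    met <- tibble::tibble(id = mids, name = mids, formula = "C",
                          charge = 0, compartment = "c")
    # backbone chain m1 -> m2 -> ... -> mk, then random extra conversions
    rows <- list(); sto <- list()
    add <- function(id, from, to, lb, ub) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        id = id, name = id, lower_bound = lb, upper_bound = ub,
        gpr = "", ec = list(sprintf("9.9.9.%d", length(rows) + 1L)),
        kegg_id = NA_character_)
      sto[[length(sto) + 1L]] <<- tibble::tibble(
        reaction_id = id,
        metabolite_id = c(from, to),
        coefficient = c(rep(-1, length(from)), rep(1, length(to))))
    }
    add("EX_up", "m01", character(0), -10, 0)    # uptake at negative flux
    for (k in seq_len(n_metabolites - 1)) {
      add(sprintf("R%02d", k), mids[k], mids[k + 1],
          if (stats::runif(1) < p_reversible) -1000 else 0, 1000)
    }
    n_extra <- n_reactions - (n_metabolites - 1) - 2
    for (k in seq_len(max(n_extra, 0))) {
      pair <- sample(n_metabolites, 2)
      add(sprintf("X%02d", k), mids[pair[1]], mids[pair[2]],
          if (stats::runif(1) < p_reversible) -1000 else 0, 1000)
    }
    add("EX_sink", mids[n_metabolites], character(0), 0, 1000)
    rxn <- dplyr::bind_rows(rows)
    sto <- dplyr::bind_rows(sto)
    sto$coefficient[sto$reaction_id == "EX_sink"] <- -1
    metabolic_model(metabolites = met, reactions = rxn, stoichiometry = sto,
                    biomass_reaction_id = "EX_sink", ngam_reaction_id = NULL,
                    gam = 0, ngam = 0,
                    id = sprintf("random_%dx%d_s%d", n_metabolites, n_reactions, seed))
  })
}

#' Synthetic expression list from a flux state
#'
#' Builds an expressed-enzyme list matching the active enzymes of a flux
#' state, with optional false-positive noise (inactive enzymes reported as
#' expressed) and false-negative noise (active enzymes dropped).
#'
#' @param model a [metabolic_model()].
#' @param flux a `flux_state` for the same model.
#' @param false_pos,false_neg noise rates in `[0, 1]`.
#' @param seed integer seed.
#' @param source label for the resulting [expression_set()].
#' @param tol_zero activity threshold on `|flux|`.
#' @return an [expression_set()].
#' @export
synthetic_expression <- function(model, flux, false_pos = 0, false_neg = 0,
                                 seed = 1, source = "synthetic",
                                 tol_zero = 1e-6) {
  stopifnot(false_pos >= 0, false_pos <= 1, false_neg >= 0, false_neg <= 1)
  v <- flux$fluxes[model$reactions$id]
  active_rxn <- model$reactions$id[abs(v) > tol_zero]
  by_rxn <- stats::setNames(model$reactions$ec, model$reactions$id)
  active <- sort(unique(unlist(by_rxn[active_rxn])))
  inactive <- setdiff(sort(unique(unlist(by_rxn))), active)
  with_seed(seed, {
    keep <- active[stats::runif(length(active)) >= false_neg]
    extra <- inactive[stats::runif(length(inactive)) < false_pos]
    expression_set(sort(c(keep, extra)), source = source)
  })
}
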