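# One entry point tying the analysis stages into a reproducible run with a
# plain-text config and a checksummed output manifest.

#' Read a run configuration
#'
#' Plain-text `key = value` format with `[stage]` sections, e.g.:
#' ```
#' model = toy
#' out_dir = runs/demo
#' stages = fba, fva
#' seed = 1
#' [fba]
#' objective = yield_per_flux
#' uptake = EX_glyc=14
#' acetate_constraint = on
#' [fva]
#' targets = EX_pdo, EX_h2
#' relaxation = 0.05
#' ```
#'
#' @param path config file.
#' @return a nested list: top-level keys plus one sub-list per stage section.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list(); section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (is.null(section)) cfg[[key]] <- val else cfg[[section]][[key]] <- val
    } else {
      stop("malformed config line: ", ln)
    }
  }
  cfg
}

split_commas <- function(x) trimws(strsplit(x, ",")[[1]])

cfg_objective <- function(stage_cfg) {
  kind <- stage_cfg$objective %||% "lp_biomass"
  if (kind == "weighted") {
    objective_spec("weighted", w = as.numeric(stage_cfg$w %||% 0.04))
  } else {
    objective_spec(kind)
  }
}

cfg_condition <- function(stage_cfg) {
  up <- c(EX_glyc = 10)
  if (!is.null(stage_cfg$uptake)) {
    parts <- split_commas(stage_cfg$uptake)
    up <- stats::setNames(as.numeric(sub("^.*=", "", parts)),
                          trimws(sub("=.*$", "", parts)))
  }
  culture_condition(up,
    acetate_constraint = identical(stage_cfg$acetate_constraint, "on"))
}

.stage_deps <- list(fba = character(0), coupling = character(0),
                    scan = character(0), perturb = character(0),
                    coferm = character(0),
                    fva = "fba", room = "fba", omics = c("fba", "coupling"))

#' Run the analysis pipeline
#'
#' Executes the configured stages in the given order (validated against
#' stage dependencies: FVA and ROOM need the FBA stage, the omics comparison
#' needs FBA and coupling), writes every stage output under `out_dir` and
#' returns a manifest with an md5 checksum per file. Deterministic stages
#' reproduce bit-identically for the same config and seed.
#'
#' @param config a file path (see [read_run_config()]) or an equivalent list.
#' @param model optional pre-loaded [metabolic_model()] overriding the
#'   config's `model` entry (`"toy"` or a model file path).
#' @return the manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, model = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- split_commas(config$stages %||% "fba")
  unknown <- setdiff(stages, names(.stage_deps))
  if (length(unknown) > 0) stop("unknown stages: ", paste(unknown, collapse = ", "))
  for (k in seq_along(stages)) {
    need <- setdiff(.stage_deps[[stages[k]]], stages[seq_len(k - 1)])
    if (length(need) > 0) {
      stop("stage '", stages[k], "' requires earlier stage(s): ",
           paste(need, collapse = ", "))
    }
  }
  seed <- as.integer(config$seed %||% 1)
  out_dir <- config$out_dir %||% "pdoflux_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(model)) {
    src <- config$model %||% "toy"
    model <- if (identical(src, "toy")) toy_glycerol_model() else load_model(src)
  }
  manifest <- list(model = model$id, seed = seed, stages = list())
  state <- list()
  for (st in stages) {
    scfg <- config[[st]] %||% list()
    outputs <- character(0)
    res <- switch(st,
      fba = {
        f <- solve_fba(model, cfg_condition(scfg), cfg_objective(scfg), seed = seed)
        state$fba <- f; state$fba_cfg <- scfg
        p <- file.path(out_dir, "flux.json"); write_flux_json(f, p); p
      },
      fva = {
        targets <- if (!is.null(scfg$targets)) split_commas(scfg$targets) else NULL
        r <- fva(model, cfg_condition(state$fba_cfg), cfg_objective(state$fba_cfg),
                 targets = targets,
                 relaxation = as.numeric(scfg$relaxation %||% 0.05),
                 incumbent = state$fba, seed = seed)
        p <- file.path(out_dir, "fva.tsv"); readr::write_tsv(r, p); p
      },
      coupling = {
        cp <- flux_coupling(model)
        state$coupling <- cp
        p <- file.path(out_dir, "coupling.tsv")
        readr::write_tsv(dplyr::mutate(cp$reactions,
          ec = vapply(.data$ec, paste, character(1), collapse = "; ")), p)
        p
      },
      omics = {
        expr <- read_expression_tsv(scfg$expression, source = scfg$source %||% "proteome")
        rep <- compare_expression(model, state$fba, state$coupling, expr)
        p <- file.path(out_dir, "omics.tsv"); readr::write_tsv(rep$enzymes, p)
        p2 <- file.path(out_dir, "omics_summary.json")
        jsonlite::write_json(rep$summary, p2, digits = NA)
        c(p, p2)
      },
      room = {
        r <- room(model, cfg_condition(state$fba_cfg),
                  deletions = split_commas(scfg$delete %||% ""),
                  wild_reference = state$fba, seed = seed)
        p <- file.path(out_dir, "room.json")
        jsonlite::write_json(list(deletions = r$deletions, n_changed = r$n_changed,
                                  viable = r$viable, fluxes = as.list(r$flux$fluxes)),
                             p, auto_unbox = TRUE, digits = NA)
        p
      },
      scan = {
        grid <- as.numeric(split_commas(scfg$grid %||% "0,5,10,15,20"))
        r <- robustness_scan(model, cfg_condition(scfg), cfg_objective(scfg),
                             uptake_grid = grid, seed = seed)
        p <- file.path(out_dir, "scan.tsv"); readr::write_tsv(r, p); p
      },
      perturb = {
        smp <- sample_biomass_compositions(model,
          n = as.integer(scfg$n %||% 200),
          rsd = as.numeric(scfg$rsd %||% 0.30), seed = seed)
        r <- perturbation_screen(model, cfg_condition(scfg), cfg_objective(scfg),
                                 smp, seed = seed)
        p <- file.path(out_dir, "perturb_correlations.tsv")
        readr::write_tsv(r$correlations, p); p
      },
      coferm = {
        r <- cofermentation_surface(model,
          glucose_grid = as.numeric(split_commas(scfg$glucose %||% "0,2,4")),
          glycerol_grid = as.numeric(split_commas(scfg$glycerol %||% "5,10")),
          seed = seed)
        p <- file.path(out_dir, "cofermentation.tsv"); readr::write_tsv(r, p); p
      })
    outputs <- res
    manifest$stages[[st]] <- list(
      outputs = lapply(outputs, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  }
  # manifest completeness: every file in out_dir is accounted for
  listed <- unlist(lapply(manifest$stages, function(s)
    vapply(s$outputs, `[[`, character(1), "file")))
  all_files <- setdiff(list.files(out_dir), "manifest.json")
  manifest$unlisted_files <- setdiff(all_files, listed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
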