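# broom-style tidiers for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux state into a reaction-flux tibble
#'
#' @param x a `flux_state`.
#' @param ... unused.
#' @return tibble with `reaction`, `flux`.
#' @method tidy flux_state
#' @export
tidy.flux_state <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux state
#'
#' @inheritParams tidy.flux_state
#' @return tibble with `objective_value`, `status`, `n_reactions`,
#'   `n_active` (|flux| > 1e-6).
#' @method glance flux_state
#' @export
glance.flux_state <- function(x, ...) {
  tibble::tibble(objective_value = x$objective_value, status = x$status,
                 n_reactions = length(x$fluxes),
                 n_active = sum(abs(x$fluxes) > 1e-6, na.rm = TRUE))
}

#' Tidy a coupling report
#'
#' @param x a `coupling_report`.
#' @param ... unused.
#' @return the per-reaction tibble with EC lists collapsed to strings.
#' @method tidy coupling_report
#' @export
tidy.coupling_report <- function(x, ...) {
  dplyr::mutate(x$reactions,
                ec = vapply(.data$ec, paste, character(1), collapse = "; "))
}

#' @rdname tidy.coupling_report
#' @method glance coupling_report
#' @export
glance.coupling_report <- function(x, ...) {
  counts <- table(factor(x$reactions$class,
                         levels = c("blocked", "directional", "partial",
                                    "full", "uncoupled")))
  out <- tibble::as_tibble(as.list(counts))
  out$target <- x$target
  out
}

#' Tidy a ROOM result
#'
#' @param x a `room_result`.
#' @param ... unused.
#' @return tibble of mutant vs wild fluxes with the changed flag.
#' @method tidy room_result
#' @export
tidy.room_result <- function(x, ...) {
  vw <- x$wild$fluxes[names(x$flux$fluxes)]
  vu <- vw + x$params$delta * abs(vw) + x$params$epsilon
  vl <- vw - x$params$delta * abs(vw) - x$params$epsilon
  tibble::tibble(reaction = names(x$flux$fluxes),
                 flux_mutant = unname(x$flux$fluxes),
                 flux_wild = unname(vw),
                 changed = unname(x$flux$fluxes > vu + 1e-9 |
                                    x$flux$fluxes < vl - 1e-9))
}

#' @rdname tidy.room_result
#' @method glance room_result
#' @export
glance.room_result <- function(x, ...) {
  tibble::tibble(deletions = paste(x$deletions, collapse = "+"),
                 n_changed = x$n_changed, viable = x$viable,
                 status = x$flux$status)
}

#' Tidy a perturbation screen result
#'
#' @param x a `perturbation_result`.
#' @param ... unused.
#' @return the per-precursor correlation tibble.
#' @method tidy perturbation_result
#' @export
tidy.perturbation_result <- function(x, ...) x$correlations

#' @rdname tidy.perturbation_result
#' @method glance perturbation_result
#' @export
glance.perturbation_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$yields), n_failed = x$n_failed,
                 rsd_y_x = unname(x$yield_rsd["y_x"]),
                 rsd_y_pdo = unname(x$yield_rsd["y_pdo"]))
}

#' Tidy an omics comparison report
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return the per-enzyme status tibble.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) x$enzymes

#' @rdname tidy.comparison_report
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) x$summary
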