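## broom-style accessors for result objects.

#' Tidy an attractor report
#'
#' Returns the per-node classification as a plain tibble (one row per node:
#' class, level, amplitude, period, steady-state residual).
#'
#' @param x An `fz_attractor`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fz_attractor
#' @export
tidy.fz_attractor <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Summarise an attractor report in one row
#'
#' @param x An `fz_attractor`.
#' @param ... Unused.
#' @return A one-row tibble: node counts by class, the largest steady-state
#'   residual among fixed nodes, and the dominant oscillation period (the
#'   median period over periodic nodes), with the analysis window length.
#' @method glance fz_attractor
#' @export
glance.fz_attractor <- function(x, ...) {
  fixed <- x$class == "fixed"
  tibble::tibble(
    n_nodes = nrow(x),
    n_fixed = sum(fixed),
    n_periodic = sum(!fixed),
    max_residual = if (any(fixed)) max(x$residual[fixed], na.rm = TRUE) else NA_real_,
    period = if (any(!fixed)) stats::median(x$period[!fixed], na.rm = TRUE) else NA_real_,
    window = attr(x, "window")
  )
}

#' Tidy a phenotype call
#'
#' @param x An `fz_phenotype`.
#' @param ... Unused.
#' @return A tibble with one row per lineage.
#' @method tidy fz_phenotype
#' @export
tidy.fz_phenotype <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Summarise a phenotype call in one row
#'
#' @param x An `fz_phenotype`.
#' @param ... Unused.
#' @return A one-row tibble: the expressed-profile signature, whether the
#'   call is a hybrid phenotype, the dominant lineage(s) and the truth
#'   threshold used.
#' @method glance fz_phenotype
#' @export
glance.fz_phenotype <- function(x, ...) {
  expressed <- x$status %in% c("stable", "oscillatory")
  tibble::tibble(
    signature = phenotype_signature(x),
    hybrid = isTRUE(attr(x, "hybrid")),
    dominant = paste(x$lineage[x$dominant], collapse = "+"),
    theta = attr(x, "theta")
  )
}

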