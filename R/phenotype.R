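## Phenotype classification, scenario runner, critical-level scans and the
## glutamine/hypoxia condition table.

#' Run a scenario with automatic horizon extension for oscillations
#'
#' Integrates the network, then checks the attractor: if any node is
#' oscillating but fewer than two full periods fit the analysis window, the
#' run is repeated with the horizon extended to `t_osc` so periodic regimes
#' are sampled properly.
#'
#' @param net A `fz_network`.
#' @param env A `fz_env`.
#' @param t_end Initial horizon (default 30 time units).
#' @param t_osc Extended horizon used when periodicity is suspected
#'   (default 120).
#' @param ... Passed to [simulate_network()].
#' @return A `fz_trajectory`.
#' @export
run_scenario <- function(net, env, t_end = 30, t_osc = 120, ...) {
  traj <- simulate_network(net, env, t_end = t_end, ...)
  rep <- steady_state(traj)
  win <- attr(rep, "window")
  moving <- rep$amplitude > 0.05
  periodic <- moving & !is.na(rep$period)
  undersampled <- periodic & (win / rep$period < 2)
  if (any(undersampled) && t_osc > t_end) {
    ## periodicity detected but fewer than two full periods fit the window
    return(simulate_network(net, env, t_end = t_osc, ...))
  }
  ## slow relaxations: double the horizon until the trailing window has
  ## stopped drifting and every fixed node meets the steady-state bound
  t_cur <- t_end
  repeat {
    fixed <- rep$class == "fixed" & !is.na(rep$residual)
    settled <- !any(moving & !periodic) &&
      (!any(fixed) || max(rep$residual[fixed]) < 1e-4)
    if (settled || t_cur >= 240 || any(rep$class == "periodic")) break
    t_cur <- max(2 * t_cur, 60)
    traj <- simulate_network(net, env, t_end = t_cur, ...)
    rep <- steady_state(traj)
    moving <- rep$amplitude > 0.05
    periodic <- moving & !is.na(rep$period)
  }
  traj
}

#' Classify lineage phenotypes from a trajectory
#'
#' For each lineage the status of its defining transcription factor is
#' called against the fuzzy truth threshold `theta`:
#' `stable` (steady level above theta), `transient` (peak above theta but
#' steady level at or below it), `oscillatory` (periodic with window peak
#' above theta), `off` (never above theta). Output cytokines associated with
#' each lineage are called the same way. A hybrid phenotype is two or more
#' lineages simultaneously not `off` at steady state; predominance is ranked
#' by steady (or oscillation-mean) level, with ties within `tie_band`
#' reported as co-dominant.
#'
#' @param traj A `fz_trajectory` of the CD4 model (or any network whose
#'   manifest maps lineages to nodes).
#' @param report Optional precomputed [steady_state()] report for `traj`.
#' @param manifest Role manifest, see [cd4_manifest()].
#' @param theta Truth threshold (default the manifest's, normally 0.5).
#' @param tie_band Levels within this distance of the top lineage are
#'   co-dominant (default 0.02).
#' @return A `fz_phenotype` tibble with one row per lineage: `lineage`,
#'   `tf`, `status`, `level`, `peak`, `amplitude`, `period`, `dominant`,
#'   plus a `cytokines` column summarising the lineage's output-cytokine
#'   statuses.
#' @export
classify_phenotypes <- function(traj, report = NULL, manifest = cd4_manifest(),
                                theta = NULL, tie_band = 0.02) {
  stopifnot(inherits(traj, "fz_trajectory"))
  if (is.null(report)) report <- steady_state(traj)
  if (is.null(theta)) theta <- if (!is.null(manifest$theta)) manifest$theta else 0.5
  net <- trajectory_network(traj)

  call_node <- function(nm) {
    if (!nm %in% names(net$nodes)) {
      stop_fz("manifest maps a role to unknown node '", nm, "'",
              class = "fuzzynet_config_error")
    }
    r <- report[report$node == nm, ]
    x <- traj[[nm]]
    peak <- max(x)
    if (r$class == "periodic") {
      status <- if (peak > theta) "oscillatory" else "off"
    } else if (r$level > theta) {
      status <- "stable"
    } else if (peak > theta) {
      status <- "transient"
    } else {
      status <- "off"
    }
    list(status = status, level = r$level, peak = peak,
         amplitude = r$amplitude, period = r$period)
  }

  rows <- purrr::imap(manifest$lineages, function(spec, lin) {
    tfc <- call_node(spec$tf)
    cyt <- purrr::map_chr(spec$cytokines, function(cn) {
      paste0(cn, ":", call_node(cn)$status)
    })
    tibble::tibble(lineage = lin, tf = spec$tf, status = tfc$status,
                   level = tfc$level, peak = tfc$peak,
                   amplitude = tfc$amplitude, period = tfc$period,
                   cytokines = paste(cyt, collapse = ", "))
  })
  out <- dplyr::bind_rows(rows)
  expressed <- out$status %in% c("stable", "oscillatory")
  top <- if (any(expressed)) max(out$level[expressed]) else NA_real_
  out$dominant <- expressed & !is.na(top) & (out$level >= top - tie_band)
  out <- dplyr::arrange(out, dplyr::desc(.data$level))
  structure(out, class = c("fz_phenotype", class(out)),
            theta = theta, hybrid = sum(expressed) >= 2)
}

#' @export
print.fz_phenotype <- function(x, ...) {
  expressed <- x$status %in% c("stable", "oscillatory")
  hdr <- if (any(expressed)) {
    paste(ifelse(x$dominant[expressed], toupper(x$lineage[expressed]),
                 x$lineage[expressed]), collapse = " / ")
  } else "no polarized phenotype"
  cat("<phenotype call> ", hdr,
      if (isTRUE(attr(x, "hybrid"))) "  [hybrid]", "\n", sep = "")
  NextMethod()
  invisible(x)
}

phenotype_signature <- function(ph) {
  expressed <- ph$status %in% c("stable", "oscillatory")
  if (!any(expressed)) return("none")
  paste(sort(ph$lineage[expressed]), collapse = "+")
}

#' Scan an input for the critical level at which the phenotype switches
#'
#' Sweeps the varied input over `range` on a coarse grid, identifies the
#' first adjacent pair of grid points whose expressed-phenotype signatures
#' differ, then bisects that bracket until it is narrower than `tol`. The
#' critical level is reported as the bracket midpoint rounded to two
#' decimals. If no switch occurs, a no-transition result is returned.
#'
#' @param net A `fz_network`.
#' @param env Background microenvironment (`fz_env`).
#' @param vary Name of the input node to vary.
#' @param range Length-2 numeric range to scan (default `c(0, 1)`); scanning
#'   proceeds from `range[1]` to `range[2]` in either direction.
#' @param tol Bracket width at which bisection stops (default 0.005).
#' @param coarse_step Coarse grid step (default 0.05).
#' @param t_end,manifest Passed to the scenario runner / classifier.
#' @return A one-row tibble: `input`, `critical` (NA if no transition),
#'   `phenotype_low`, `phenotype_high` (signatures on the `range[1]` and
#'   `range[2]` sides of the switch), `bracket_lo`, `bracket_hi`,
#'   `n_runs`, `transition`.
#' @export
scan_critical <- function(net, env, vary, range = c(0, 1), tol = 0.005,
                          coarse_step = 0.05, t_end = 30,
                          manifest = cd4_manifest()) {
  stopifnot(inherits(env, "fz_env"), length(range) == 2)
  if (!vary %in% names(env$levels)) {
    stop_fz("'", vary, "' is not a clamped input of this environment",
            class = "fuzzynet_config_error")
  }
  n_runs <- 0L
  sig_at <- function(level) {
    e <- env
    e$levels[vary] <- level
    n_runs <<- n_runs + 1L
    traj <- run_scenario(net, e, t_end = t_end)
    phenotype_signature(classify_phenotypes(traj, manifest = manifest))
  }

  lo <- range[1]; hi <- range[2]
  if (isTRUE(all.equal(lo, hi))) {
    s <- sig_at(lo)
    return(tibble::tibble(input = vary, critical = NA_real_,
                          phenotype_low = s, phenotype_high = s,
                          bracket_lo = lo, bracket_hi = hi,
                          n_runs = n_runs, transition = FALSE))
  }
  grid <- seq(lo, hi, by = if (lo <= hi) coarse_step else -coarse_step)
  if (grid[length(grid)] != hi) grid <- c(grid, hi)
  sigs <- vapply(grid, sig_at, "")
  flip <- which(sigs[-1] != sigs[-length(sigs)])
  if (!length(flip)) {
    return(tibble::tibble(input = vary, critical = NA_real_,
                          phenotype_low = sigs[1],
                          phenotype_high = sigs[length(sigs)],
                          bracket_lo = lo, bracket_hi = hi,
                          n_runs = n_runs, transition = FALSE))
  }
  i <- flip[1]
  a <- grid[i]; b <- grid[i + 1]
  sa <- sigs[i]; sb <- sigs[i + 1]
  while (abs(b - a) > tol) {
    m <- (a + b) / 2
    sm <- sig_at(m)
    if (sm == sa) a <- m else { b <- m; sb <- sm }
  }
  tibble::tibble(input = vary, critical = round((a + b) / 2, 2),
                 phenotype_low = sa, phenotype_high = sb,
                 bracket_lo = min(a, b), bracket_hi = max(a, b),
                 n_runs = n_runs, transition = TRUE)
}

#' Phenotype profiles under glutamine deficiency and hypoxia
#'
#' Runs the eleven glutamine/hypoxia/cytokine conditions (the Th1 column
#' sets the IL-12/IFN-gamma/IL-18/IL-33 group jointly; the IL-6/IL-21
#' column sets both cytokines) and reports the expressed profile of each,
#' with dominant lineages marked.
#'
#' @param net The CD4 network (default: the bundled model).
#' @param manifest Role manifest.
#' @param t_end Horizon per run (default 30, auto-extended for
#'   oscillations).
#' @return A tibble with one row per condition: the input levels, the
#'   `expressed` profile string (dominant lineage groups in upper case,
#'   separated by " / "), and a list-column `call` of the full
#'   [classify_phenotypes()] tibbles.
#' @export
run_table1 <- function(net = build_cd4_network(), manifest = cd4_manifest(),
                       t_end = 30) {
  rows <- tibble::tribble(
    ~GLN, ~Hyp, ~Th1, ~IL4, ~IL6_IL21, ~TGFb, ~IL10,
    1,    0,    1,    1,    1,    1, 1,
    0.50, 0,    1,    1,    1,    1, 1,
    0.50, 0,    1,    1,    0.65, 1, 1,
    0.50, 0,    1,    0.70, 1,    1, 1,
    0.50, 0,    1,    0.63, 1,    1, 1,
    0.50, 0,    1,    0.50, 1,    1, 1,
    0.00, 0,    1,    0,    0.71, 0, 1,
    0.40, 0.50, 1,    0.50, 0.30, 1, 1,
    0.50, 0.50, 1,    0.50, 1,    0, 1,
    0.50, 1,    1,    0.50, 1,    0, 1,
    0.50, 1,    1,    0.50, 0.30, 1, 1
  )
  th1 <- manifest$inputs$th1_group
  gln <- manifest$inputs$nutrients$glutamine
  hyp <- manifest$inputs$hypoxia
  calls <- vector("list", nrow(rows))
  expressed <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    lv <- c(setNames(rep(r$Th1, length(th1)), th1),
            IL4_e = r$IL4, IL6_e = r$IL6_IL21, IL21_e = r$IL6_IL21,
            TGFB_e = r$TGFb, IL10_e = r$IL10,
            setNames(r$GLN, gln), setNames(r$Hyp, hyp))
    env <- cd4_env(levels = lv, manifest = manifest)
    traj <- run_scenario(net, env, t_end = t_end)
    ph <- classify_phenotypes(traj, manifest = manifest)
    calls[[i]] <- ph
    on <- ph[ph$status %in% c("stable", "oscillatory"), ]
    expressed[i] <- if (nrow(on) == 0) "none" else {
      paste(ifelse(on$dominant, toupper(on$lineage), on$lineage),
            collapse = " / ")
    }
  }
  rows$expressed <- expressed
  rows$call <- calls
  rows
}
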