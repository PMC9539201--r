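## Bundled CD4+ T-cell network (synthetic reconstruction) and its manifest.

#' Load the bundled 68-node CD4+ T-cell network
#'
#' The model covers early activation and differentiation of naive CD4+
#' T cells: antigen presentation and co-stimulation, the TCR/CD28 signalling
#' core with the IL-2/CD25 feedback loop, CTLA-4 and NDRG1 regulation,
#' metabolic control (AMPK, mTORC1/mTORC2, glycolysis vs. oxidative
#' phosphorylation, glutaminolysis via alpha-ketoglutarate, HIF-1alpha),
#' the five lineage-defining transcription factors (T-bet, GATA3, RORgamma-t,
#' Foxp3, Bcl-6) and their output cytokines. 68 nodes in eight modules.
#'
#' The rule set is a synthetic reconstruction curated from the published
#' description of the network's topology and reported behaviour (see the
#' model file header in `inst/extdata`); the engine itself is
#' rule-set-agnostic and any model file in the same format can be used
#' instead.
#'
#' @return A validated `fz_network` with 68 nodes.
#' @export
build_cd4_network <- function() {
  read_network(system.file("extdata", "cd4_tcell_synthetic.net",
                           package = "fuzzynet", mustWork = TRUE))
}

#' Role manifest for the bundled CD4 model
#'
#' Maps scenario roles (lineage-defining transcription factors, output
#' cytokines, input groups, metabolic readouts, naive initial levels) to node
#' identifiers, so scenario logic never hard-codes node names.
#'
#' @param path Optional path to a manifest YAML; defaults to the bundled one.
#' @return A nested list.
#' @export
cd4_manifest <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cd4_manifest.yaml",
                        package = "fuzzynet", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

#' Build a CD4 microenvironment
#'
#' Starts from the naive defaults — all exogenous cytokines absent, optimal
#' nutrients (glutamine, tryptophan, glucose, fatty acids all 1), normoxia
#' (`HYP = 0`), step-stimulus schedules on the antigen-presentation and
#' co-stimulation inputs, and the manifest's naive initial levels (active
#' AMPK, low oxidative phosphorylation) — and applies the given clamp-level
#' overrides.
#'
#' @param levels Named numeric vector of clamp overrides in \eqn{[0,1]}
#'   (e.g. `c(IL4_e = 1, GLN = 0.5)`).
#' @param t_ctla4 CTLA-4 characteristic expression time; realized as a
#'   decay-rate override `alpha = 1/t_ctla4` on the CTLA-4 node. Values
#'   `<= 1` permit sustained activation; larger values arrest it. Default 1.
#' @param stimulus Named list of [step_stimulus()] overrides for the
#'   stimulation inputs (defaults: `A = D = 1`, `T = 15`, `beta_s = 1`).
#' @param manifest Role manifest, see [cd4_manifest()].
#' @return A `fz_env`.
#' @export
cd4_env <- function(levels = numeric(), t_ctla4 = 1, stimulus = list(),
                    manifest = cd4_manifest()) {
  cyt <- manifest$inputs$cytokines
  nut <- unlist(manifest$inputs$nutrients)
  lv <- c(setNames(rep(0, length(cyt)), cyt),
          setNames(rep(1, length(nut)), nut),
          setNames(0, manifest$inputs$hypoxia))
  if (length(levels)) {
    unknown <- setdiff(names(levels), names(lv))
    if (length(unknown)) {
      stop_fz("unknown input node(s) in levels: ",
              paste(unknown, collapse = ", "),
              class = "fuzzynet_config_error")
    }
    lv[names(levels)] <- levels
  }
  sched <- setNames(rep(list(step_stimulus()),
                        length(manifest$inputs$stimulation)),
                    manifest$inputs$stimulation)
  for (nm in names(stimulus)) sched[[nm]] <- stimulus[[nm]]
  if (t_ctla4 <= 0) {
    stop_fz("t_ctla4 must be > 0", class = "fuzzynet_config_error")
  }
  init <- unlist(manifest$initial)
  fz_env(levels = lv, schedules = sched,
         alpha_override = setNames(1 / t_ctla4, manifest$ctla4),
         init_override = init)
}

#' Microenvironment presets for the classic polarizing conditions
#'
#' * `none`: no exogenous cytokines.
#' * `Th1`: the Th1-inducing group (IL-12, IFN-gamma, IL-18, IL-33) at 1.
#' * `Th2`: IL-4 at 1.
#' * `Th17`: TGF-beta plus IL-6 and IL-21 at 1.
#' * `Treg`: TGF-beta plus IL-10 at 1.
#' * `TFH`: IL-6 and IL-21 at 1 with TGF-beta absent (its absence permits
#'   Bcl-6 expression).
#' * `all_type`: a uniform mixture of all nine exogenous cytokines at level
#'   `cl` (a cytokine-storm-like background).
#'
#' Nutrients default to optimal and oxygen to normoxia in every preset.
#'
#' @param kind Preset name.
#' @param cl Uniform cytokine level for `all_type`, in \eqn{[0,1]}.
#' @param manifest Role manifest.
#' @param ... Passed on to [cd4_env()] (e.g. extra `levels` overrides,
#'   `t_ctla4`).
#' @return A `fz_env`.
#' @export
preset_env <- function(kind = c("none", "Th1", "Th2", "Th17", "Treg", "TFH",
                                "all_type"),
                       cl = 1, manifest = cd4_manifest(), ...) {
  kind <- match.arg(kind)
  if (kind == "all_type" && (is.na(cl) || cl < 0 || cl > 1)) {
    stop_fz("all_type cytokine level must lie in [0,1]",
            class = "fuzzynet_config_error")
  }
  th1 <- manifest$inputs$th1_group
  lv <- switch(kind,
    none = numeric(),
    Th1 = setNames(rep(1, length(th1)), th1),
    Th2 = c(IL4_e = 1),
    Th17 = c(TGFB_e = 1, IL6_e = 1, IL21_e = 1),
    Treg = c(TGFB_e = 1, IL10_e = 1),
    TFH = c(IL6_e = 1, IL21_e = 1),
    all_type = setNames(rep(cl, length(manifest$inputs$cytokines)),
                        manifest$inputs$cytokines)
  )
  cd4_env(levels = lv, manifest = manifest, ...)
}
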