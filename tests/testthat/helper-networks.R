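# Shared fixtures: tiny networks and CD4 scenario shortcuts.

# biased toggle: an external input BIAS reinforces A in a mutual-repression
# pair; used for fold-location tests.
biased_toggle <- function() {
  fz_network(list(
    fz_node("BIAS", "cytokine-input"),
    fz_node("A", "activation-core", rule = "!B | BIAS"),
    fz_node("B", "activation-core", rule = "!A")
  ), name = "biased-toggle", version = "fixture")
}

toggle_manifest <- function() {
  list(theta = 0.5,
       lineages = list(Ahigh = list(tf = "A", cytokines = character()),
                       Bhigh = list(tf = "B", cytokines = character())))
}

# grid of truth values used by algebra property checks
VAL_GRID <- seq(0, 1, by = 0.25)

# evaluate a fuzzy expression string directly
fev <- function(text, ...) fz_eval(fz_parse(text), c(...))

# all 0/1 assignments for a set of variables
bool_states <- function(vars) {
  g <- do.call(expand.grid, stats::setNames(rep(list(c(0, 1)), length(vars)), vars))
  split(as.matrix(g), seq_len(nrow(g))) |>
    lapply(function(r) stats::setNames(as.numeric(r), vars))
}

# classical Boolean evaluation of a fz_expr under a 0/1 state
bool_eval <- function(expr, state) {
  switch(expr$kind,
    var = as.logical(state[[expr$name]]),
    const = as.logical(expr$value),
    and = bool_eval(expr$lhs, state) && bool_eval(expr$rhs, state),
    or = bool_eval(expr$lhs, state) || bool_eval(expr$rhs, state),
    not = !bool_eval(expr$arg, state)
  )
}

cd4_net_cached <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_cd4_network()
    net
  }
})

cd4_man_cached <- local({
  man <- NULL
  function() {
    if (is.null(man)) man <<- cd4_manifest()
    man
  }
})

# stable fingerprint of a trajectory's numeric content
digest_df <- function(traj) {
  paste(range(as.matrix(as.data.frame(traj))), collapse = "|")
}
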