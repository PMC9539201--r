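## Network specification: nodes, decay rates, module tags, and the
## line-oriented model-file format.

MODULE_TAGS <- c("stimulation-input", "cytokine-input", "nutrient-oxygen-input",
                 "activation-core", "metabolic", "regulatory", "lineage-TF",
                 "output-cytokine")

INPUT_TAGS <- c("stimulation-input", "cytokine-input", "nutrient-oxygen-input")

#' Declare a network node
#'
#' Internal nodes carry exactly one fuzzy rule and a first-order decay rate
#' `alpha` (characteristic expression time `tau = 1/alpha`); input nodes are
#' clamped by the microenvironment and have no rule.
#'
#' @param name Node identifier.
#' @param module One of the eight module tags (see [module_tags()]).
#' @param rule Rule string (parsed with [fz_parse()]) or `NULL` for inputs.
#' @param alpha Decay rate, must be positive. Default 1.
#' @param init Initial level in \eqn{[0,1]}. Default 0.
#' @return A `fz_node` list.
#' @export
fz_node <- function(name, module, rule = NULL, alpha = 1, init = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!module %in% MODULE_TAGS) {
    stop_fz("unknown module tag '", module, "' for node ", name,
            class = "fuzzynet_validation_error")
  }
  if (!is.null(rule) && is.character(rule)) rule <- fz_parse(rule)
  if (is.na(alpha) || alpha <= 0) {
    stop_fz("node ", name, ": decay rate alpha must be > 0, got ",
            format(alpha), class = "fuzzynet_validation_error")
  }
  is_input <- module %in% INPUT_TAGS
  if (is_input && !is.null(rule)) {
    stop_fz("input node ", name, " must not carry a rule",
            class = "fuzzynet_validation_error")
  }
  if (!is_input && is.null(rule)) {
    stop_fz("internal node ", name, " must carry a rule",
            class = "fuzzynet_validation_error")
  }
  structure(list(name = name, module = module, rule = rule,
                 alpha = alpha, init = init, is_input = is_input),
            class = "fz_node")
}

#' The eight module tags recognised in model files
#' @return Character vector of tags.
#' @export
module_tags <- function() MODULE_TAGS

#' Assemble and validate a network specification
#'
#' Checks that node names are unique, that every symbol referenced by any
#' rule is a declared node, and that decay rates are positive.
#'
#' @param nodes List of [fz_node()] objects.
#' @param name Network name.
#' @param version Version string.
#' @return A `fz_network`.
#' @export
fz_network <- function(nodes, name = "network", version = "0") {
  nms <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop_fz("duplicate node name(s): ",
            paste(unique(nms[duplicated(nms)]), collapse = ", "),
            class = "fuzzynet_validation_error")
  }
  names(nodes) <- nms
  for (nd in nodes) {
    if (!is.null(nd$rule)) {
      missing <- setdiff(fz_vars(nd$rule), nms)
      if (length(missing)) {
        stop_fz("rule for node ", nd$name,
                " references undeclared node(s): ",
                paste(missing, collapse = ", "),
                class = "fuzzynet_validation_error")
      }
    }
  }
  structure(list(name = name, version = version, nodes = nodes),
            class = "fz_network")
}

#' @export
print.fz_network <- function(x, ...) {
  tab <- table(vapply(x$nodes, `[[`, "", "module"))
  cat("<fz_network> ", x$name, " (version ", x$version, "): ",
      length(x$nodes), " nodes\n", sep = "")
  for (m in names(tab)) cat("  ", m, ": ", tab[[m]], "\n", sep = "")
  invisible(x)
}

#' Nodes of a network as a tibble
#'
#' @param net A `fz_network`.
#' @return A tibble with columns `name`, `module`, `is_input`, `alpha`,
#'   `tau`, `init`, `rule`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "fz_network"))
  tibble::tibble(
    name = vapply(net$nodes, `[[`, "", "name"),
    module = vapply(net$nodes, `[[`, "", "module"),
    is_input = vapply(net$nodes, `[[`, TRUE, "is_input"),
    alpha = vapply(net$nodes, `[[`, 1, "alpha"),
    tau = 1 / vapply(net$nodes, `[[`, 1, "alpha"),
    init = vapply(net$nodes, `[[`, 1, "init"),
    rule = vapply(net$nodes, function(n) {
      if (is.null(n$rule)) NA_character_ else fz_deparse(n$rule)
    }, "")
  )
}

input_names <- function(net) {
  names(net$nodes)[vapply(net$nodes, `[[`, TRUE, "is_input")]
}

internal_names <- function(net) {
  names(net$nodes)[!vapply(net$nodes, `[[`, TRUE, "is_input")]
}

#' Read a network model file
#'
#' Line-oriented text format: a header `NETWORK <name> VERSION <string>`,
#' one `INPUT <name> MODULE <tag>` line per clamped input, one
#' `NODE <name> MODULE <tag> ALPHA <float> RULE <expression>` line per
#' internal node, and `#` comments.
#'
#' @param path File path.
#' @return A validated `fz_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop_fz("model file not found: ", path, class = "fuzzynet_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^NETWORK\\s", lines[[1]])) {
    stop_fz("model file must start with a NETWORK header: ", path,
            class = "fuzzynet_io_error")
  }
  hd <- strsplit(lines[[1]], "\\s+")[[1]]
  if (length(hd) < 4L || hd[3] != "VERSION") {
    stop_fz("malformed NETWORK header: ", lines[[1]],
            class = "fuzzynet_io_error")
  }
  nodes <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (parts[1] == "INPUT") {
      if (length(parts) != 4L || parts[3] != "MODULE") {
        stop_fz("malformed INPUT line: ", ln, class = "fuzzynet_io_error")
      }
      nodes[[length(nodes) + 1L]] <- fz_node(parts[2], parts[4])
    } else if (parts[1] == "NODE") {
      if (length(parts) < 8L || parts[3] != "MODULE" || parts[5] != "ALPHA" ||
          parts[7] != "RULE") {
        stop_fz("malformed NODE line: ", ln, class = "fuzzynet_io_error")
      }
      rule <- paste(parts[-(1:7)], collapse = " ")
      nodes[[length(nodes) + 1L]] <- fz_node(parts[2], parts[4], rule = rule,
                                             alpha = as.numeric(parts[6]))
    } else {
      stop_fz("unrecognised line in model file: ", ln,
              class = "fuzzynet_io_error")
    }
  }
  fz_network(nodes, name = hd[2], version = paste(hd[-(1:3)], collapse = " "))
}

#' Write a network model file
#'
#' Inverse of [read_network()]; `read_network(write_network(net, f))`
#' reproduces `net`.
#'
#' @param net A `fz_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "fz_network"))
  out <- c(paste("NETWORK", net$name, "VERSION", net$version))
  for (nd in net$nodes) {
    out <- c(out, if (nd$is_input) {
      paste("INPUT", nd$name, "MODULE", nd$module)
    } else {
      paste("NODE", nd$name, "MODULE", nd$module, "ALPHA",
            format(nd$alpha, trim = TRUE), "RULE", fz_deparse(nd$rule))
    })
  }
  writeLines(out, path)
  invisible(path)
}

#' Step-like stimulus schedule
#'
#' Time-dependent binding strength
#' \eqn{s(t) = A - D / (1 + e^{-\beta_s (t - T)})}: an initial affinity `A`
#' depleted by `D` around onset time `T` at saturation rate `beta_s`. The
#' defaults (`A = D = 1`, `T = 15`, `beta_s = 1`) model antigen presentation
#' and co-stimulation that wane after 15 time units.
#'
#' @param A Initial affinity strength (default 1).
#' @param D Depletion factor (default 1).
#' @param T Onset of depletion in time units (default 15).
#' @param beta_s Saturation rate (default 1).
#' @return A `fz_stimulus`.
#' @export
step_stimulus <- function(A = 1, D = 1, T = 15, beta_s = 1) {
  structure(list(A = A, D = D, T = T, beta_s = beta_s),
            class = "fz_stimulus")
}

#' Evaluate a stimulus schedule at time t
#'
#' `stimulus_level(s, s$T)` equals `A - D/2` exactly for any parameters;
#' with `D = 0` the schedule is constant `A`.
#'
#' @param s A `fz_stimulus`.
#' @param t Numeric vector of times, `t >= 0`.
#' @return Numeric vector of levels.
#' @export
stimulus_level <- function(s, t) {
  stopifnot(inherits(s, "fz_stimulus"))
  s$A - s$D / (1 + exp(-s$beta_s * (t - s$T)))
}

#' Microenvironment: clamped input levels and stimulation schedules
#'
#' @param levels Named numeric vector of clamp levels in \eqn{[0,1]} for
#'   input nodes (cytokines, nutrients, hypoxia).
#' @param schedules Named list of [step_stimulus()] objects for inputs that
#'   follow a time-dependent schedule rather than a constant clamp
#'   (typically the antigen-presentation and co-stimulation nodes).
#' @param alpha_override Named numeric vector of decay-rate overrides for
#'   internal nodes (e.g. the CTLA-4 expression-time control
#'   `alpha = 1/T_CTLA4`).
#' @param init_override Named numeric vector of initial-level overrides.
#' @return A `fz_env`.
#' @export
fz_env <- function(levels = numeric(), schedules = list(),
                   alpha_override = numeric(), init_override = numeric()) {
  if (length(levels) && (anyNA(levels) || any(levels < 0) || any(levels > 1))) {
    stop_fz("clamp levels must lie in [0,1]",
            class = "fuzzynet_validation_error")
  }
  structure(list(levels = levels, schedules = schedules,
                 alpha_override = alpha_override,
                 init_override = init_override),
            class = "fz_env")
}

#' @export
print.fz_env <- function(x, ...) {
  cat("<fz_env> ", length(x$levels), " clamped input(s), ",
      length(x$schedules), " schedule(s)\n", sep = "")
  if (length(x$levels)) {
    cat("  ", paste0(names(x$levels), "=", format(x$levels, trim = TRUE),
                     collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

## Input levels at time t as a named vector covering every input node.
env_input_levels <- function(net, env, t) {
  ins <- input_names(net)
  lv <- setNames(numeric(length(ins)), ins)
  known <- intersect(names(env$levels), ins)
  lv[known] <- env$levels[known]
  for (nm in names(env$schedules)) {
    if (nm %in% ins) lv[nm] <- stimulus_level(env$schedules[[nm]], t)
  }
  missing <- setdiff(ins, c(names(env$levels), names(env$schedules)))
  if (length(missing)) {
    stop_fz("microenvironment does not cover input node(s): ",
            paste(missing, collapse = ", "),
            class = "fuzzynet_config_error")
  }
  lv
}

#' Toy fixture networks with known attractor structure
#'
#' * `"self-activator"`: one node with rule `A = A`; its fixed points are
#'   the roots of \eqn{q = \mu(q)}.
#' * `"toggle"`: two mutually repressing nodes (`A = !B`, `B = !A`) with two
#'   asymmetric stable fixed points and one unstable symmetric point.
#' * `"negative-feedback-loop"`: `A` activates `B`, `B` represses `A` (the
#'   AMPK--mTORC1 motif in the abstract).
#'
#' @param kind Fixture name.
#' @return A `fz_network`.
#' @export
make_fixture <- function(kind = c("self-activator", "toggle",
                                  "negative-feedback-loop")) {
  kind <- match.arg(kind)
  switch(kind,
    "self-activator" = fz_network(list(
      fz_node("A", "activation-core", rule = "A")
    ), name = "self-activator", version = "fixture"),
    "toggle" = fz_network(list(
      fz_node("A", "activation-core", rule = "!B"),
      fz_node("B", "activation-core", rule = "!A")
    ), name = "toggle", version = "fixture"),
    "negative-feedback-loop" = fz_network(list(
      fz_node("A", "metabolic", rule = "!B"),
      fz_node("B", "metabolic", rule = "A")
    ), name = "negative-feedback-loop", version = "fixture")
  )
}
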