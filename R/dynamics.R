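## ODE assembly, integration and attractor analysis.
##
## Each internal node k relaxes as dq_k/dt = mu[v_k(q)] - alpha_k q_k, with
## mu the sigmoid gate and v_k the node's fuzzy proposition evaluated on the
## current state plus the (possibly time-dependent) input levels.  Because
## 0 < mu < 1, trajectories started inside the unit hypercube stay inside it
## for alpha_k = 1.

#' Assemble the ODE right-hand side for a network under an environment
#'
#' Returns `function(state, t)` mapping a full named state vector (inputs
#' and internal nodes) to its derivative: internal nodes follow
#' \eqn{\dot q_k = \mu[v_k(q)] - \alpha_k q_k}; clamped inputs have
#' derivative 0 (scheduled inputs are algebraic and also report 0 — their
#' level is imposed, not integrated).
#'
#' @param net A `fz_network`.
#' @param env A `fz_env` covering every input node of `net`.
#' @param beta,theta Gate parameters (defaults 10 and 1/2).
#' @return A function `(state, t) -> derivative`, both named numeric vectors.
#' @export
assemble_rhs <- function(net, env, beta = 10, theta = 0.5) {
  stopifnot(inherits(net, "fz_network"), inherits(env, "fz_env"))
  env_input_levels(net, env, 0)  # fail fast if env does not cover inputs
  internal <- internal_names(net)
  alphas <- effective_alphas(net, env)
  compiled <- lapply(net$nodes[internal], function(nd) fz_compile(nd$rule))
  all_names <- names(net$nodes)
  function(state, t = 0) {
    stopifnot(!is.null(names(state)))
    ev <- list2env(as.list(state))
    for (nm in names(env$schedules)) {
      if (nm %in% all_names) {
        assign(nm, stimulus_level(env$schedules[[nm]], t), envir = ev)
      }
    }
    d <- setNames(numeric(length(all_names)), all_names)
    for (nm in internal) {
      v <- eval(compiled[[nm]], ev)
      d[nm] <- 1 / (1 + exp(-beta * (v - theta))) - alphas[nm] * state[[nm]]
    }
    d[names(state)[!names(state) %in% internal]] <- 0
    d[names(state)]
  }
}

effective_alphas <- function(net, env) {
  internal <- internal_names(net)
  a <- vapply(net$nodes[internal], `[[`, 1, "alpha")
  ov <- env$alpha_override
  ov <- ov[names(ov) %in% internal]
  if (length(ov)) {
    if (any(ov <= 0)) {
      stop_fz("alpha overrides must be > 0",
              class = "fuzzynet_validation_error")
    }
    a[names(ov)] <- ov
  }
  a
}

initial_state <- function(net, env) {
  internal <- internal_names(net)
  q0 <- vapply(net$nodes[internal], `[[`, 1, "init")
  ov <- env$init_override
  ov <- ov[names(ov) %in% internal]
  if (length(ov)) q0[names(ov)] <- ov
  q0
}

#' Integrate the fuzzy network ODE system
#'
#' Uses the stiff-capable adaptive `lsoda` integrator (via
#' \pkg{deSolve}) with tight tolerances, resampled on a uniform reporting
#' grid. The returned trajectory is a tibble with a `time` column and one
#' column per node (inputs included at their imposed levels).
#'
#' @param net A `fz_network`.
#' @param env A `fz_env`.
#' @param t_end End of the integration horizon (time units, default 30).
#'   `t_end = 0` returns the single-sample initial state.
#' @param dt Reporting grid step (default 0.05).
#' @param rtol,atol Integrator tolerances (defaults 1e-8 and 1e-10).
#' @param beta,theta Gate parameters.
#' @param q0 Optional named initial state for internal nodes (overrides the
#'   network/environment initial levels; used e.g. by attractor sampling).
#' @return A `fz_trajectory` tibble.
#' @export
simulate_network <- function(net, env = fz_env(), t_end = 30, dt = 0.05,
                             rtol = 1e-8, atol = 1e-10,
                             beta = 10, theta = 0.5, q0 = NULL) {
  stopifnot(inherits(net, "fz_network"), inherits(env, "fz_env"), t_end >= 0)
  internal <- internal_names(net)
  alphas <- effective_alphas(net, env)
  compiled <- lapply(net$nodes[internal], function(nd) fz_compile(nd$rule))
  start <- initial_state(net, env)
  if (!is.null(q0)) {
    stopifnot(!is.null(names(q0)), all(names(q0) %in% internal))
    start[names(q0)] <- q0
  }
  ins <- input_names(net)
  n_int <- length(internal)

  deriv <- fz_rhs_compiled(net, env, beta, theta)

  times <- if (t_end == 0) 0 else seq(0, t_end, by = dt)
  if (t_end > 0 && times[length(times)] < t_end) times <- c(times, t_end)

  if (t_end == 0 || n_int == 0L) {
    sol <- matrix(start, nrow = length(times), ncol = n_int, byrow = TRUE,
                  dimnames = list(NULL, internal))
    sol <- cbind(time = times, sol)
  } else {
    out <- deSolve::lsoda(y = start, times = times, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0) {
      stop_fz("lsoda failed (istate = ", attr(out, "istate")[1L],
              "); last good time ", max(out[, 1]),
              class = "fuzzynet_integration_error")
    }
    sol <- unclass(out)
    colnames(sol)[1] <- "time"
  }

  tb <- tibble::as_tibble(as.data.frame(sol))
  ## append imposed input levels so the trajectory covers every node
  if (length(ins)) {
    lv0 <- env_input_levels(net, env, 0)
    cols <- lapply(ins, function(nm) {
      s <- env$schedules[[nm]]
      if (is.null(s)) rep(lv0[[nm]], nrow(tb)) else stimulus_level(s, tb$time)
    })
    names(cols) <- ins
    tb <- dplyr::bind_cols(tb, tibble::as_tibble(cols))
  }
  tb <- tb[, c("time", names(net$nodes))]
  structure(tb, class = c("fz_trajectory", class(tb)),
            network = net, env = env,
            gate = c(beta = beta, theta = theta))
}

## Generate a single R function computing the full derivative vector: rules,
## clamp levels and stimulus schedules are inlined into one expression, so
## each lsoda callback is one evaluation of straight arithmetic.
fz_rhs_compiled <- function(net, env, beta, theta) {
  internal <- internal_names(net)
  alphas <- effective_alphas(net, env)
  lv0 <- env_input_levels(net, env, 0)

  bind_lines <- character()
  for (i in seq_along(internal)) {
    bind_lines <- c(bind_lines,
                    sprintf("`%s` <- q[[%dL]]", internal[i], i))
  }
  for (nm in names(lv0)) {
    s <- env$schedules[[nm]]
    rhs <- if (is.null(s)) {
      deparse(unname(lv0[[nm]]))
    } else {
      sprintf("%.17g - %.17g / (1 + exp(-%.17g * (t - %.17g)))",
              s$A, s$D, s$beta_s, s$T)
    }
    bind_lines <- c(bind_lines, sprintf("`%s` <- %s", nm, rhs))
  }
  exprs <- vapply(net$nodes[internal], function(nd) {
    paste(deparse(fz_compile(nd$rule), width.cutoff = 500L), collapse = " ")
  }, "")
  body_txt <- paste(
    c(bind_lines,
      paste0("v <- c(", paste(exprs, collapse = ",\n"), ")"),
      sprintf("list(1 / (1 + exp(-%.17g * (v - %.17g))) - .alphas * q)",
              beta, theta)),
    collapse = "\n")
  fn <- eval(parse(text = paste0("function(t, q, parms) {\n", body_txt,
                                 "\n}")))
  environment(fn) <- list2env(list(.alphas = unname(alphas)),
                              parent = baseenv())
  fn
}

trajectory_network <- function(traj) attr(traj, "network")
trajectory_env <- function(traj) attr(traj, "env")

#' Classify the attractor reached by a trajectory
#'
#' Analyses the trailing window of a trajectory (by default the trailing 25%
#' of the horizon, at least 10 time units). A node is classified `periodic`
#' if its peak-to-trough amplitude within the window exceeds
#' `osc_threshold` and at least two full periods are detected from interior
#' peak spacing; otherwise it is `fixed` at the window mean, with the
#' steady-state residual \eqn{|q - \mu[v(q)]/\alpha|} reported at the
#' window-mean state.
#'
#' @param traj A `fz_trajectory`.
#' @param window Window length in time units (`NULL` = trailing 25%, min 10,
#'   capped at the trajectory length).
#' @param osc_threshold Peak-to-trough amplitude above which a node is a
#'   candidate oscillator (default 0.05).
#' @param residual_tol Steady-state residual above which a low-amplitude
#'   node co-existing with periodic nodes is reclassified as a periodic
#'   follower of the limit cycle (default 1e-4).
#' @return An `fz_attractor` tibble with one row per node: `node`, `class`
#'   (`"fixed"`/`"periodic"`), `level` (fixed level or oscillation mean),
#'   `amplitude`, `period`, `residual`.
#' @export
steady_state <- function(traj, window = NULL, osc_threshold = 0.05,
                         residual_tol = 1e-4) {
  stopifnot(inherits(traj, "fz_trajectory"))
  net <- trajectory_network(traj)
  env <- trajectory_env(traj)
  gate <- attr(traj, "gate")
  tmax <- max(traj$time)
  if (is.null(window)) window <- min(tmax, max(0.25 * tmax, 10))
  if (window > tmax + 1e-9) {
    stop_fz("analysis window (", window, ") longer than trajectory (",
            tmax, ")", class = "fuzzynet_validation_error")
  }
  sel <- traj$time >= tmax - window - 1e-9
  tt <- traj$time[sel]
  nodes <- names(net$nodes)
  internal <- internal_names(net)
  alphas <- effective_alphas(net, env)

  rows <- lapply(nodes, function(nm) {
    x <- traj[[nm]][sel]
    amp <- max(x) - min(x)
    per <- NA_real_
    cls <- "fixed"
    if (amp > osc_threshold) {
      per <- estimate_period(tt, x)
      if (!is.na(per) && window / per >= 2) cls <- "periodic"
    }
    tibble::tibble(node = nm, class = cls,
                   level = mean(x), amplitude = amp, period = per,
                   residual = NA_real_)
  })
  rep <- dplyr::bind_rows(rows)

  ## Eq.-4 residual at the window-mean state (inputs at end-of-run levels)
  mean_state <- vapply(nodes, function(nm) mean(traj[[nm]][sel]), numeric(1))
  lv <- env_input_levels(net, env, tmax)
  mean_state[names(lv)] <- lv
  for (i in seq_len(nrow(rep))) {
    nm <- rep$node[i]
    if (nm %in% internal && rep$class[i] == "fixed") {
      ## raw evaluation: decay-rate overrides (tau > 1) may legitimately
      ## hold levels above 1, which fz_eval's domain check would reject
      v <- fz_eval_rec(net$nodes[[nm]]$rule, mean_state)
      mu <- fz_gate(v, gate[["beta"]], gate[["theta"]])
      rep$residual[i] <- abs(rep$level[i] - mu / alphas[[nm]])
    }
  }

  ## On a limit-cycle attractor, nodes driven by the oscillators move with
  ## small amplitude: they are periodic followers, not fixed points. The
  ## steady-state residual separates the two cases.
  if (any(rep$class == "periodic")) {
    per <- stats::median(rep$period[rep$class == "periodic"], na.rm = TRUE)
    forced <- rep$class == "fixed" & !is.na(rep$residual) &
      rep$residual > residual_tol
    rep$class[forced] <- "periodic"
    rep$period[forced] <- per
    rep$residual[forced] <- NA_real_
  }
  structure(rep, class = c("fz_attractor", class(rep)),
            window = window, network = net)
}

## Period from mean spacing of interior local maxima (prominence implicit in
## the amplitude gate applied by the caller).
estimate_period <- function(tt, x) {
  n <- length(x)
  if (n < 5) return(NA_real_)
  thr <- min(x) + 0.5 * (max(x) - min(x))
  i <- 2:(n - 1)
  pk <- i[x[i] >= x[i - 1] & x[i] > x[i + 1] & x[i] > thr]
  if (length(pk) >= 2) {
    ## collapse plateau-adjacent picks
    keep <- c(TRUE, diff(tt[pk]) > 1e-6)
    pk <- pk[keep]
  }
  if (length(pk) < 2) return(NA_real_)
  mean(diff(tt[pk]))
}

#' Brute-force fixed-point oracle for small networks
#'
#' Independent verification tool: scans the internal-state hypercube on a
#' regular grid and polishes each start with a damped Newton iteration on
#' the steady-state residual \eqn{R(q) = \mu[v(q)]/\alpha - q}; distinct
#' converged roots (including unstable ones) are returned. Refuses networks
#' with more than `max_free` internal nodes. Intended for tests; the
#' production path is [simulate_network()] + [steady_state()].
#'
#' @param net A small `fz_network`.
#' @param env A `fz_env`.
#' @param grid_step Grid resolution in each dimension (default 0.1).
#' @param beta,theta Gate parameters.
#' @param max_free Maximum number of internal nodes accepted (default 4).
#' @param tol Residual norm below which a root is accepted (default 1e-10).
#' @return A tibble with one row per fixed point and one column per internal
#'   node, plus a `residual` column.
#' @export
fixed_point_oracle <- function(net, env = fz_env(), grid_step = 0.1,
                               beta = 10, theta = 0.5, max_free = 4,
                               tol = 1e-10) {
  internal <- internal_names(net)
  n <- length(internal)
  if (n > max_free) {
    stop_fz("fixed_point_oracle refuses networks with more than ", max_free,
            " free nodes (got ", n, ")", class = "fuzzynet_refusal_error")
  }
  alphas <- effective_alphas(net, env)
  compiled <- lapply(net$nodes[internal], function(nd) fz_compile(nd$rule))
  lv <- if (length(input_names(net))) env_input_levels(net, env, Inf) else
    numeric()

  resid <- function(q) {
    ev <- list2env(c(as.list(setNames(q, internal)), as.list(lv)))
    v <- vapply(compiled, eval, numeric(1), envir = ev)
    1 / (1 + exp(-beta * (v - theta))) / alphas - q
  }

  grid1 <- seq(0, 1, by = grid_step)
  starts <- as.matrix(do.call(expand.grid, rep(list(grid1), n)))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    q <- starts[k, ]
    ok <- FALSE
    for (it in 1:60) {
      r <- resid(q)
      if (sqrt(sum(r^2)) < tol) { ok <- TRUE; break }
      J <- num_jacobian(resid, q)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
      q <- pmin(pmax(q + step, -0.25), 1.25)
    }
    if (ok && all(q >= -1e-6) && all(q <= 1 + 1e-6)) {
      roots[[length(roots) + 1L]] <- pmin(pmax(q, 0), 1)
    }
  }
  if (!length(roots)) {
    out <- matrix(numeric(), 0, n, dimnames = list(NULL, internal))
    return(tibble::as_tibble(as.data.frame(out)))
  }
  rm <- do.call(rbind, roots)
  ## dedupe
  keep <- rep(TRUE, nrow(rm))
  for (i in seq_len(nrow(rm))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && max(abs(rm[i, ] - rm[j, ])) < 1e-6) keep[i] <- FALSE
    }
  }
  rm <- rm[keep, , drop = FALSE]
  colnames(rm) <- internal
  out <- tibble::as_tibble(as.data.frame(rm))
  out$residual <- apply(rm, 1, function(q) sqrt(sum(resid(q)^2)))
  out
}

num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
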