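#' Bell slip-bond parameters
#'
#' The Bell model describes a force-accelerated (or, with negative
#' transition distance, force-suppressed) rate
#' \deqn{k(f) = k_0 \exp(\Delta f / k_BT)}
#' where `k0` is the zero-force rate and `delta` the distance to the
#' transition state along the pulling coordinate.
#'
#' @param k0 zero-force rate in 1/s (>= 0)
#' @param delta transition distance in nm (positive: force-accelerated;
#'   negative: force-suppressed, as for refolding and re-pairing)
#' @return an object of class `bell_params`
#' @export
bell_params <- function(k0, delta) {
  if (!is.numeric(k0) || length(k0) != 1L || !is.finite(k0) || k0 < 0)
    stop("'k0' must be a single non-negative number (1/s)")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("'delta' must be a single finite number (nm)")
  structure(list(k0 = k0, delta = delta), class = "bell_params")
}

#' Force-dependent Bell rate
#'
#' Evaluates \eqn{k_0 \exp(\Delta f/k_BT)}. The exponent is capped at 700
#' before exponentiation and rates are capped at 1e12 1/s (effectively
#' instantaneous); both guards are far outside the physical regime.
#'
#' @param params a [bell_params()]
#' @param force force in pN (>= 0; vectorised)
#' @param env a [polymer_env()]
#' @return rate in 1/s
#' @examples
#' bell_rate(bell_params(1e-3, 0.8), 20)
#' @export
bell_rate <- function(params, force, env = polymer_env()) {
  stopifnot(inherits(params, "bell_params"))
  if (any(force < 0)) stop("'force' must be non-negative (pN)")
  ex <- pmin(params$delta * force / env$kBT, 700)
  pmin(params$k0 * exp(ex), 1e12)
}

#' Un-pairing/re-pairing kinetics of a domain pair
#'
#' @param unpair [bell_params()] for boundary un-pairing (delta typically
#'   positive)
#' @param repair [bell_params()] for re-pairing; its delta must be <= 0 so
#'   the re-pairing rate never increases with force
#' @return an object of class `pair_kinetics`
#' @export
pair_kinetics <- function(unpair, repair = bell_params(0, 0)) {
  stopifnot(inherits(unpair, "bell_params"), inherits(repair, "bell_params"))
  if (repair$delta > 0)
    stop("re-pairing must not accelerate with force (repair delta must be <= 0)")
  structure(list(unpair = unpair, repair = repair), class = "pair_kinetics")
}

#' Unfolding/refolding kinetics of a force-bearing domain
#'
#' @param unfold [bell_params()] for unfolding
#' @param refold [bell_params()] for refolding; delta must be <= 0
#' @return an object of class `domain_kinetics`
#' @export
domain_kinetics <- function(unfold, refold = bell_params(0, 0)) {
  stopifnot(inherits(unfold, "bell_params"), inherits(refold, "bell_params"))
  if (refold$delta > 0)
    stop("refolding must not accelerate with force (refold delta must be <= 0)")
  structure(list(unfold = unfold, refold = refold), class = "domain_kinetics")
}

#' Multivalent dimer kinetic model
#'
#' A dimer held by `n_pairs` domain pairs in a row. Under force the
#' dissociation path initiates from the force-bearing ends: only boundary
#' pairs of the remaining intact block may un-pair. An un-paired domain is
#' pulled onto the force path, where it may unfold and refold; an unfolded
#' domain cannot re-pair, and only the un-paired (folded) domain adjacent to
#' the intact block can re-pair. Rupture -- all pairs un-paired -- is
#' absorbing. This interplay of boundary un-pairing, rapid re-pairing and
#' unfolding-gated re-pairing is what amplifies the lifetime of multivalent
#' dimers.
#'
#' @param n_pairs number of domain pairs (>= 1; exact solutions are
#'   practical for n <= 5)
#' @param pair a [pair_kinetics()] shared by all pairs, or a list of one per
#'   pair
#' @param domain a [domain_kinetics()] shared by all pairs (or list); use the
#'   default zero rates to disable unfolding
#' @param peel_from `"both"` (default: both force-bearing ends are
#'   boundaries) or `"one"` (peeling from a single end)
#' @return an object of class `mdk_model`
#' @export
multivalent_dimer_model <- function(n_pairs, pair,
                                    domain = domain_kinetics(bell_params(0, 0)),
                                    peel_from = c("both", "one")) {
  peel_from <- match.arg(peel_from)
  if (n_pairs < 1) stop("'n_pairs' must be >= 1")
  as_list <- function(x, cls) {
    if (inherits(x, cls)) x <- replicate(n_pairs, x, simplify = FALSE)
    stopifnot(length(x) == n_pairs,
              all(vapply(x, inherits, logical(1), what = cls)))
    x
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 pair = as_list(pair, "pair_kinetics"),
                 domain = as_list(domain, "domain_kinetics"),
                 peel_from = peel_from),
            class = "mdk_model")
}

#' @export
print.mdk_model <- function(x, ...) {
  cat(sprintf("<mdk_model> %d domain pair(s), peeling from %s end(s)\n",
              x$n_pairs, if (x$peel_from == "both") "both" else "one"))
  p1 <- x$pair[[1]]; d1 <- x$domain[[1]]
  cat(sprintf("  pair 1: unpair k0=%g/s delta=%g nm; repair k0=%g/s delta=%g nm\n",
              p1$unpair$k0, p1$unpair$delta, p1$repair$k0, p1$repair$delta))
  cat(sprintf("  domain 1: unfold k0=%g/s delta=%g nm; refold k0=%g/s delta=%g nm\n",
              d1$unfold$k0, d1$unfold$delta, d1$refold$k0, d1$refold$delta))
  invisible(x)
}

# ---- internal state machinery ------------------------------------------
# A state is list(i, j, out): intact contiguous block pairs i..j, and for
# every pair outside the block a status "F" (un-paired, folded) or "U"
# (un-paired, unfolded). The absorbing rupture state is the string "RUPTURED".

mdk_state_id <- function(s) {
  if (identical(s, "RUPTURED")) return("RUPTURED")
  paste0(s$i, ":", s$j, "|", paste(s$out, collapse = ""))
}

mdk_initial_state <- function(model) {
  list(i = 1L, j = model$n_pairs, out = character(0))
}

# out is a named character vector keyed by pair index (as character)
mdk_transitions <- function(model, state, force, env) {
  if (identical(state, "RUPTURED")) return(list())
  n <- model$n_pairs
  i <- state$i; j <- state$j; out <- state$out
  res <- list()
  add <- function(to, rate, type, pair) {
    if (rate > 0)
      res[[length(res) + 1L]] <<- list(to = to, rate = rate, type = type,
                                       pair = pair)
  }
  set_out <- function(out, p, v) { out[as.character(p)] <- v; out }
  drop_out <- function(out, p) out[setdiff(names(out), as.character(p))]
  # un-pairing of boundary pairs of the intact block
  left_rate <- bell_rate(model$pair[[i]]$unpair, force, env)
  if (i == j) {
    add("RUPTURED", left_rate, "unpair", i)
    if (model$peel_from == "both" && j > i) NULL # unreachable
  } else {
    add(list(i = i + 1L, j = j, out = set_out(out, i, "F")),
        left_rate, "unpair", i)
    if (model$peel_from == "both")
      add(list(i = i, j = j - 1L, out = set_out(out, j, "F")),
          bell_rate(model$pair[[j]]$unpair, force, env), "unpair", j)
  }
  # re-pairing of the folded un-paired pair adjacent to the block
  if (i > 1L && identical(unname(out[as.character(i - 1L)]), "F"))
    add(list(i = i - 1L, j = j, out = drop_out(out, i - 1L)),
        bell_rate(model$pair[[i - 1L]]$repair, force, env), "repair", i - 1L)
  if (model$peel_from == "both" && j < n &&
      identical(unname(out[as.character(j + 1L)]), "F"))
    add(list(i = i, j = j + 1L, out = drop_out(out, j + 1L)),
        bell_rate(model$pair[[j + 1L]]$repair, force, env), "repair", j + 1L)
  # unfolding / refolding of un-paired force-path domains
  for (p in as.integer(names(out))) {
    if (out[as.character(p)] == "F")
      add(list(i = i, j = j, out = set_out(out, p, "U")),
          bell_rate(model$domain[[p]]$unfold, force, env), "unfold", p)
    else
      add(list(i = i, j = j, out = set_out(out, p, "F")),
          bell_rate(model$domain[[p]]$refold, force, env), "refold", p)
  }
  res
}

# Enumerate all states reachable from the fully paired state and build the
# transition-rate table. Returns list(states, ids, trans) where trans is a
# data.frame(from, to, rate, type).
mdk_enumerate <- function(model, force, env) {
  init <- mdk_initial_state(model)
  states <- list(); ids <- character(0)
  queue <- list(init)
  trans <- list()
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    id <- mdk_state_id(s)
    if (id %in% ids) next
    ids <- c(ids, id); states[[id]] <- s
    for (tr in mdk_transitions(model, s, force, env)) {
      to_id <- mdk_state_id(tr$to)
      trans[[length(trans) + 1L]] <- data.frame(
        from = id, to = to_id, rate = tr$rate, type = tr$type,
        stringsAsFactors = FALSE)
      if (to_id != "RUPTURED" && !(to_id %in% ids))
        queue[[length(queue) + 1L]] <- tr$to
    }
  }
  list(states = states, ids = ids,
       trans = if (length(trans)) do.call(rbind, trans)
               else data.frame(from = character(), to = character(),
                               rate = numeric(), type = character()))
}

#' Exact mean lifetime of a multivalent dimer at constant force
#'
#' Mean first-passage time from the fully paired state to rupture, obtained
#' from the linear system of the continuous-time Markov chain over the
#' reachable state space (no detailed balance assumed; only rate positivity
#' and reachability of the absorbing rupture state are required).
#'
#' @param model a [multivalent_dimer_model()]
#' @param force force in pN (vectorised)
#' @param env a [polymer_env()]
#' @return mean lifetime in s
#' @examples
#' m <- multivalent_dimer_model(2, pair_kinetics(bell_params(0.1, 0.5),
#'                                               bell_params(5, -0.5)))
#' mean_lifetime_exact(m, 10)
#' @export
mean_lifetime_exact <- function(model, force, env = polymer_env()) {
  stopifnot(inherits(model, "mdk_model"))
  vapply(force, function(f) {
    en <- mdk_enumerate(model, f, env)
    ids <- en$ids
    nT <- length(ids)
    Q <- matrix(0, nT, nT, dimnames = list(ids, ids))
    outflow <- setNames(numeric(nT), ids)
    reaches_absorbing <- FALSE
    for (r in seq_len(nrow(en$trans))) {
      tr <- en$trans[r, ]
      outflow[tr$from] <- outflow[tr$from] + tr$rate
      if (tr$to == "RUPTURED") reaches_absorbing <- TRUE
      else Q[tr$from, tr$to] <- Q[tr$from, tr$to] + tr$rate
    }
    if (!reaches_absorbing)
      stop("model error: the rupture state is unreachable at this force")
    diag(Q) <- diag(Q) - outflow
    tvec <- tryCatch(solve(Q, rep(-1, nT)),
                     error = function(e) stop(
                       "model error: singular first-passage system (",
                       conditionMessage(e), ")"))
    tvec[mdk_state_id(mdk_initial_state(model))]
  }, numeric(1))
}

#' Gillespie simulation of dimer rupture at constant force
#'
#' Stochastic simulation of the multivalent dimer model: exact
#' continuous-time trajectories from the fully paired state until rupture
#' (or `max_time`). Empirical mean rupture times converge to
#' [mean_lifetime_exact()].
#'
#' @param model a [multivalent_dimer_model()]
#' @param force force in pN
#' @param n_runs number of trajectories (>= 1)
#' @param rng_seed integer seed; `NULL` uses the current RNG state
#' @param max_time censor trajectories at this time (default `Inf`)
#' @param env a [polymer_env()]
#' @param record_events keep per-run event sequences (default `TRUE`)
#' @return an object of class `mdk_sim`: list with `times` (rupture times,
#'   `NA` where censored), `censored` (logical), `events` (list of per-run
#'   data frames) and the seed used
#' @export
simulate_constant_force <- function(model, force, n_runs, rng_seed = NULL,
                                    max_time = Inf, env = polymer_env(),
                                    record_events = TRUE) {
  stopifnot(inherits(model, "mdk_model"), n_runs >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  times <- numeric(n_runs); censored <- logical(n_runs)
  events <- if (record_events) vector("list", n_runs) else NULL
  for (run in seq_len(n_runs)) {
    t <- 0; s <- mdk_initial_state(model)
    ev <- list()
    repeat {
      trs <- mdk_transitions(model, s, force, env)
      rates <- vapply(trs, `[[`, numeric(1), "rate")
      R <- sum(rates)
      if (R == 0) { times[run] <- NA_real_; censored[run] <- TRUE; break }
      t <- t + stats::rexp(1, R)
      if (t >= max_time) { times[run] <- NA_real_; censored[run] <- TRUE; break }
      k <- sample.int(length(trs), 1, prob = rates)
      if (record_events)
        ev[[length(ev) + 1L]] <- data.frame(
          time_s = t, type = trs[[k]]$type, pair = trs[[k]]$pair,
          stringsAsFactors = FALSE)
      s <- trs[[k]]$to
      if (identical(s, "RUPTURED")) { times[run] <- t; break }
    }
    if (record_events)
      events[[run]] <- if (length(ev)) do.call(rbind, ev)
                       else data.frame(time_s = numeric(), type = character(),
                                       pair = integer())
  }
  structure(list(times = times, censored = censored, events = events,
                 force_pN = force, n_runs = n_runs, seed = rng_seed),
            class = "mdk_sim")
}

#' @export
print.mdk_sim <- function(x, ...) {
  nc <- sum(x$censored)
  cat(sprintf("<mdk_sim> %d run(s) at %g pN: mean rupture time %.4g s (%d censored)\n",
              x$n_runs, x$force_pN,
              mean(x$times, na.rm = TRUE), nc))
  invisible(x)
}

#' Simulate trajectories of a multivalent dimer model
#'
#' `simulate()` method delegating to [simulate_constant_force()].
#'
#' @param object a [multivalent_dimer_model()]
#' @param nsim number of trajectories
#' @param seed integer seed or `NULL`
#' @param force force in pN
#' @param ... passed on to [simulate_constant_force()]
#' @return an object of class `mdk_sim`
#' @export
simulate.mdk_model <- function(object, nsim = 1, seed = NULL, force, ...) {
  simulate_constant_force(object, force = force, n_runs = nsim,
                          rng_seed = seed, ...)
}

#' Force protocols
#'
#' Describes how force is applied over time: a constant clamp, a linear
#' ramp, or a force-jump cycle (low-force re-formation phase followed by an
#' instantaneous jump to a clamped hold).
#'
#' @param kind `"constant"`, `"ramp"` or `"jump"`
#' @param force clamp force in pN (constant)
#' @param duration clamp duration in s (constant)
#' @param from,to ramp start/end force in pN
#' @param rate loading rate in pN/s (ramp; a warning is issued outside the
#'   +/-10 pN/s regime the slow-ramp extension model assumes)
#' @param low_force,low_duration low-force phase of a jump cycle
#' @param hold_force,hold_duration clamped hold phase of a jump cycle
#' @param n_cycles number of jump cycles
#' @return an object of class `force_protocol`
#' @export
force_protocol <- function(kind = c("constant", "ramp", "jump"),
                           force = NULL, duration = NULL,
                           from = NULL, to = NULL, rate = NULL,
                           low_force = 1, low_duration = 2,
                           hold_force = NULL, hold_duration = NULL,
                           n_cycles = 1) {
  kind <- match.arg(kind)
  p <- switch(kind,
    constant = {
      if (is.null(force)) stop("constant protocol needs 'force'")
      list(force = force, duration = duration %||% Inf)
    },
    ramp = {
      if (is.null(from) || is.null(to) || is.null(rate))
        stop("ramp protocol needs 'from', 'to' and 'rate'")
      if (rate == 0 || sign(to - from) != sign(rate))
        stop("'rate' must be nonzero and point from 'from' towards 'to'")
      if (abs(rate) > 10)
        warning("loading rates beyond +/-10 pN/s are outside the slow-ramp regime")
      list(from = from, to = to, rate = rate)
    },
    jump = {
      if (is.null(hold_force) || is.null(hold_duration))
        stop("jump protocol needs 'hold_force' and 'hold_duration'")
      list(low_force = low_force, low_duration = low_duration,
           hold_force = hold_force, hold_duration = hold_duration,
           n_cycles = n_cycles)
    })
  structure(c(list(kind = kind), p), class = "force_protocol")
}

#' Most probable rupture force of a Bell bond under constant loading
#'
#' The Evans--Ritchie modal rupture force
#' \deqn{F^* = (k_BT/\Delta)\,\ln\!\big(r\Delta/(k_0 k_BT)\big)}
#' for a single Bell bond loaded at rate `r` from zero force.
#'
#' @param params a [bell_params()] with positive delta
#' @param loading_rate loading rate r in pN/s (> 0)
#' @param env a [polymer_env()]
#' @return modal rupture force in pN
#' @export
evans_ritchie_modal_force <- function(params, loading_rate,
                                      env = polymer_env()) {
  stopifnot(inherits(params, "bell_params"))
  if (params$delta <= 0 || params$k0 <= 0)
    stop("modal force requires k0 > 0 and delta > 0")
  if (loading_rate <= 0) stop("'loading_rate' must be positive")
  env$kBT / params$delta *
    log(loading_rate * params$delta / (params$k0 * env$kBT))
}

#' Simulate rupture under a linear force ramp
#'
#' Time-stepped stochastic simulation with piecewise-constant force; the
#' force increment per step is at most `force_step` (default 0.01 pN), which
#' makes the single-bond simulation converge to the inhomogeneous-Poisson
#' closed form. For a single Bell bond the runs are vectorised; for a full
#' multivalent model each run is an individual Gillespie trajectory with the
#' force frozen within each step.
#'
#' @param x a [bell_params()] (single bond) or [multivalent_dimer_model()]
#' @param protocol a ramp [force_protocol()]
#' @param n_runs number of runs
#' @param rng_seed integer seed or `NULL`
#' @param env a [polymer_env()]
#' @param force_step maximal force discretisation in pN
#' @return an object of class `ramp_sim`: list with `forces` (rupture force
#'   per run, `NA` if the bond survived the ramp), `censored`, the protocol
#'   and seed
#' @examples
#' pr <- force_protocol("ramp", from = 0, to = 100, rate = 5)
#' sim <- simulate_ramp(bell_params(1e-3, 0.5), pr, n_runs = 200, rng_seed = 1)
#' mean(sim$forces)
#' @export
simulate_ramp <- function(x, protocol, n_runs, rng_seed = NULL,
                          env = polymer_env(), force_step = 0.01) {
  stopifnot(inherits(protocol, "force_protocol"))
  if (protocol$kind != "ramp") stop("'protocol' must be a ramp protocol")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  r <- protocol$rate
  grid <- seq(protocol$from, protocol$to, by = sign(r) * force_step)
  dt <- force_step / abs(r)
  if (inherits(x, "bell_params")) {
    forces <- rep(NA_real_, n_runs)
    alive <- rep(TRUE, n_runs)
    for (m in seq_along(grid)) {
      if (!any(alive)) break
      p <- 1 - exp(-bell_rate(x, max(grid[m], 0), env) * dt)
      idx <- which(alive)
      hit <- idx[stats::runif(length(idx)) < p]
      forces[hit] <- grid[m]
      alive[hit] <- FALSE
    }
    censored <- is.na(forces)
  } else if (inherits(x, "mdk_model")) {
    forces <- rep(NA_real_, n_runs)
    for (run in seq_len(n_runs)) {
      s <- mdk_initial_state(x)
      t <- 0; t_end <- (protocol$to - protocol$from) / r
      repeat {
        f <- max(protocol$from + r * t, 0)
        trs <- mdk_transitions(x, s, f, env)
        rates <- vapply(trs, `[[`, numeric(1), "rate")
        R <- sum(rates)
        if (R == 0) { t <- t + dt } else {
          w <- stats::rexp(1, R)
          if (w > dt) { t <- t + dt } else {
            t <- t + w
            k <- sample.int(length(trs), 1, prob = rates)
            s <- trs[[k]]$to
            if (identical(s, "RUPTURED")) {
              forces[run] <- protocol$from + r * t
              break
            }
          }
        }
        if (t >= t_end) break
      }
    }
    censored <- is.na(forces)
  } else stop("'x' must be a bell_params or mdk_model object")
  structure(list(forces = forces, censored = censored, protocol = protocol,
                 n_runs = n_runs, seed = rng_seed),
            class = "ramp_sim")
}

#' @export
print.ramp_sim <- function(x, ...) {
  cat(sprintf(
    "<ramp_sim> %d run(s), %g pN/s: mean rupture force %.4g pN (%d censored)\n",
    x$n_runs, x$protocol$rate, mean(x$forces, na.rm = TRUE), sum(x$censored)))
  invisible(x)
}

#' Modal rupture force from simulated or measured ramp data
#'
#' Fits the single-Bell rupture-force distribution under constant loading
#' (maximum likelihood in `log k0` and `log delta`) and returns the modal
#' force of the fitted distribution. More stable than a kernel-density mode
#' at moderate sample sizes.
#'
#' @param forces rupture forces in pN (censored runs removed)
#' @param loading_rate loading rate in pN/s
#' @param env a [polymer_env()]
#' @param f_start force at the start of the ramp (pN)
#' @return list with `k0`, `delta` and `modal_force`
#' @export
ramp_modal_force <- function(forces, loading_rate, env = polymer_env(),
                             f_start = 0) {
  forces <- forces[is.finite(forces)]
  if (length(forces) < 10) stop("need at least 10 rupture forces")
  r <- abs(loading_rate)
  nll <- function(par) {
    k0 <- exp(par[1]); d <- exp(par[2])
    H <- k0 * env$kBT / (d * r) *
      (exp(pmin(d * forces / env$kBT, 700)) - exp(d * f_start / env$kBT))
    -sum(log(k0) + d * forces / env$kBT - H)
  }
  d0 <- env$kBT / stats::sd(forces)
  k00 <- r * d0 / env$kBT * exp(-d0 * mean(forces) / env$kBT)
  fit <- stats::optim(c(log(max(k00, 1e-12)), log(d0)), nll,
                      method = "Nelder-Mead")
  k0 <- exp(fit$par[1]); delta <- exp(fit$par[2])
  list(k0 = k0, delta = delta,
       modal_force = evans_ritchie_modal_force(bell_params(k0, delta), r, env))
}

#' Mean lifetime versus number of domain pairs
#'
#' Tabulates the exact mean lifetime of a family of multivalent dimer
#' models sharing per-pair kinetics, over a force grid. The lifetime grows
#' with the pair count -- the multivalency amplification.
#'
#' @param pair a [pair_kinetics()] shared by all pairs
#' @param domain a [domain_kinetics()] shared by all pairs
#' @param n_pairs integer vector of pair counts (default 1:4)
#' @param forces force grid in pN
#' @param env a [polymer_env()]
#' @param peel_from passed to [multivalent_dimer_model()]
#' @return a data frame with columns `n_pairs`, `force_pN`,
#'   `mean_lifetime_s`
#' @export
lifetime_vs_pairs <- function(pair, domain = domain_kinetics(bell_params(0, 0)),
                              n_pairs = 1:4, forces,
                              env = polymer_env(),
                              peel_from = "both") {
  rows <- lapply(n_pairs, function(n) {
    m <- multivalent_dimer_model(n, pair, domain, peel_from = peel_from)
    data.frame(n_pairs = n, force_pN = forces,
               mean_lifetime_s = mean_lifetime_exact(m, forces, env))
  })
  do.call(rbind, rows)
}
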