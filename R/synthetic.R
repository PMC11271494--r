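#' Measurement noise model
#'
#' Gaussian bead-height noise and sampling rate of the emulated instrument
#' (1-2 nm tracking resolution plus thermal fluctuations give an effective
#' height uncertainty of roughly 2-5 nm at 200 Hz).
#'
#' @param height_sd height noise standard deviation in nm (>= 0)
#' @param sampling_rate sampling rate in Hz (> 0)
#' @return an object of class `noise_model`
#' @export
noise_model <- function(height_sd = 3, sampling_rate = 200) {
  if (height_sd < 0) stop("'height_sd' must be >= 0")
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive")
  structure(list(height_sd = height_sd, sampling_rate = sampling_rate),
            class = "noise_model")
}

#' Generate force-clamp dwell times from a Bell bond
#'
#' Draws i.i.d. exponential dwell times at the Bell rate for the given
#' force, optionally right-censored at `censor_at` (the hold duration of
#' the emulated jump cycle).
#'
#' @param params a [bell_params()]
#' @param force clamp force in pN
#' @param n number of dwells (>= 1)
#' @param censor_at right-censoring time in s, or `NULL` for none
#' @param rng_seed integer seed or `NULL`
#' @param env a [polymer_env()]
#' @return a [dwell_records()] data frame; the generating rate and seed are
#'   attached as attributes
#' @export
generate_dwells <- function(params, force, n, censor_at = NULL,
                            rng_seed = NULL, env = polymer_env()) {
  stopifnot(inherits(params, "bell_params"), n >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rate <- bell_rate(params, force, env)
  d <- stats::rexp(n, rate)
  if (!is.null(censor_at)) {
    cens <- d > censor_at
    d[cens] <- censor_at
  } else cens <- rep(FALSE, n)
  out <- dwell_records(rep(force, n), d, cens)
  attr(out, "true_rate") <- rate
  attr(out, "seed") <- rng_seed
  out
}

#' Generate dwell times from slowly interconverting sub-states
#'
#' Emulates clustered lifetime populations: a hidden sub-state persists
#' across consecutive cycles (switching with a small per-cycle
#' probability), and each dwell is exponential at the active sub-state's
#' Bell rate. With a single sub-state this reduces to [generate_dwells()].
#'
#' @param substates list of `list(params = bell_params(), weight =)`;
#'   weights must sum to 1
#' @param switch_prob per-cycle probability of re-drawing the sub-state
#' @param force clamp force in pN
#' @param n number of dwells
#' @param rng_seed integer seed or `NULL`
#' @param censor_at optional right-censoring time in s
#' @param env a [polymer_env()]
#' @return a [dwell_records()] data frame with an extra hidden-label column
#'   `substate`
#' @export
generate_clustered_dwells <- function(substates, switch_prob, force, n,
                                      rng_seed = NULL, censor_at = NULL,
                                      env = polymer_env()) {
  w <- vapply(substates, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("sub-state weights must sum to 1")
  if (switch_prob < 0 || switch_prob > 1) stop("'switch_prob' must be in [0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rates <- vapply(substates, function(s) bell_rate(s$params, force, env),
                  numeric(1))
  lab <- integer(n)
  lab[1] <- sample.int(length(w), 1, prob = w)
  for (i in seq_len(n - 1L))
    lab[i + 1L] <- if (stats::runif(1) < switch_prob)
      sample.int(length(w), 1, prob = w) else lab[i]
  d <- stats::rexp(n, rates[lab])
  if (!is.null(censor_at)) {
    cens <- d > censor_at
    d[cens] <- censor_at
  } else cens <- rep(FALSE, n)
  out <- dwell_records(rep(force, n), d, cens)
  out$substate <- lab
  attr(out, "true_rates") <- rates
  attr(out, "seed") <- rng_seed
  out
}

# Map a multivalent-model state to a tether_state of the construct: paired
# domains are shielded in the dimer, un-paired folded domains are small
# rigid bodies on the force path, un-paired unfolded domains are chains.
mdk_to_tether_state <- function(model, s, n_domains) {
  if (identical(s, "RUPTURED")) s <- list(i = 0L, j = -1L, out = NULL)
  doms <- rep("shielded", n_domains)
  if (!is.null(s$out) && length(s$out))
    doms[as.integer(names(s$out))] <- ifelse(s$out == "F", "folded", "unfolded")
  dimerized <- !is.null(s$i) && s$i >= 1L && s$j >= s$i
  if (!dimerized) doms[doms == "shielded"] <- "folded"
  tether_state(dimerized, doms, n_domains = n_domains)
}

# Bead height of a state at a force, measured as the force-path extension
# plus the geometric span of the looped linker while the dimer is intact
# (so a pure rupture step equals the loop's extension gain on release).
state_height <- function(construct, state, force, env) {
  series_extension(state_to_series(construct, state), force, env) +
    if (state$dimerized) construct$loop_end_to_end else 0
}

# wrap a single Bell bond as a 1-pair irreversible model
as_mdk <- function(model) {
  if (inherits(model, "bell_params"))
    multivalent_dimer_model(1, pair_kinetics(model))
  else model
}

#' Generate a synthetic bead-height trace with ground truth
#'
#' Simulates the conformational state path of a tethered dimer with the
#' kinetic engine, maps every state to its mechanical extension at the
#' instantaneous force, adds Gaussian measurement noise, and records every
#' transition in a ground-truth table. Heights are reported relative to the
#' initial state's extension at the initial force.
#'
#' Supported protocol kinds:
#' * `"constant"`: Gillespie path of the model until rupture (or the
#'   protocol duration). A [pair_kinetics()] model instead yields a
#'   reversible two-level hopping trace (dimerized/ruptured telegraph), as
#'   seen near the rupture equilibrium force of weak dimers.
#' * `"ramp"`: linear force ramp with rupture (concurrent with unfolding of
#'   the force-bearing domains by default).
#' * `"jump"`: force-jump cycles; each cycle holds at low force, jumps to
#'   the clamp force (with an optional decaying bead re-orientation
#'   artifact excluded from the ground truth), and records the rupture
#'   step. The hold windows are written into the trace metadata for
#'   [extract_dwell_times()].
#'
#' @param construct a [construct_spec()]
#' @param model a [bell_params()] (single rupture bond),
#'   [multivalent_dimer_model()] (its pair count must match the construct's
#'   domains), or [pair_kinetics()] (hopping, constant force only)
#' @param protocol a [force_protocol()]
#' @param noise a [noise_model()]
#' @param rng_seed integer seed or `NULL`
#' @param env a [polymer_env()]
#' @param rupture_unfolds_domains in ramp/jump protocols, make rupture
#'   concurrent with unfolding of all force-bearing domains (default
#'   `TRUE`, the behaviour seen at high clamp forces)
#' @param jump_artifact_nm amplitude of the decaying force-jump transient
#'   (default 4 nm, decay constant 0.08 s, truncated at 0.25 s)
#' @return list with `trace` (an [mt_trace()]) and `truth` (data frame
#'   `time_s`, `transition`, `step_nm`)
#' @export
generate_trace <- function(construct, model, protocol,
                           noise = noise_model(), rng_seed = NULL,
                           env = polymer_env(),
                           rupture_unfolds_domains = TRUE,
                           jump_artifact_nm = 4) {
  stopifnot(inherits(construct, "construct_spec"),
            inherits(protocol, "force_protocol"),
            inherits(noise, "noise_model"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fs <- noise$sampling_rate
  nd <- length(construct$rod$domains)
  truth <- list()
  add_truth <- function(t, label, step)
    truth[[length(truth) + 1L]] <<- data.frame(time_s = t, transition = label,
                                               step_nm = step)

  if (protocol$kind == "constant") {
    f <- protocol$force
    if (inherits(model, "pair_kinetics")) {
      # reversible two-level hopping: dimerized <-> ruptured telegraph
      dur <- protocol$duration
      if (!is.finite(dur)) stop("hopping traces need a finite protocol duration")
      k_off <- bell_rate(model$unpair, f, env)
      k_on <- bell_rate(model$repair, f, env)
      st_dim <- tether_state(TRUE, "shielded", n_domains = nd)
      st_rup <- tether_state(FALSE, "folded", n_domains = nd)
      t <- 0; dim_now <- TRUE
      times <- numeric(0); labels <- character(0)
      while (t < dur) {
        t <- t + stats::rexp(1, if (dim_now) k_off else k_on)
        if (t >= dur) break
        times <- c(times, t); labels <- c(labels, if (dim_now) "rupture" else "re-dimerize")
        dim_now <- !dim_now
      }
      tt <- seq(0, dur - 1 / fs, by = 1 / fs)
      h_dim <- state_height(construct, st_dim, f, env)
      h_rup <- state_height(construct, st_rup, f, env)
      state_idx <- findInterval(tt, times)   # even = dimerized
      h <- ifelse(state_idx %% 2 == 0, h_dim, h_rup) - h_dim
      for (i in seq_along(times))
        add_truth(times[i], labels[i],
                  if (labels[i] == "rupture") h_rup - h_dim else h_dim - h_rup)
      hn <- h + stats::rnorm(length(h), 0, noise$height_sd)
      tr <- mt_trace(tt, rep(f, length(tt)), hn, fs,
                     metadata = list(protocol = "constant-hopping",
                                     construct = construct$name,
                                     seed = rng_seed))
      return(list(trace = tr,
                  truth = if (length(truth)) do.call(rbind, truth)
                          else data.frame(time_s = numeric(),
                                          transition = character(),
                                          step_nm = numeric())))
    }
    if (inherits(model, "bell_params")) {
      # whole-dimer rupture as one Bell step
      before <- tether_state(TRUE, "shielded", n_domains = nd)
      after <- tether_state(FALSE,
                            if (rupture_unfolds_domains) "unfolded" else "folded",
                            n_domains = nd)
      t_rup <- stats::rexp(1, bell_rate(model, f, env))
      dur <- if (is.finite(protocol$duration)) protocol$duration else t_rup + 1
      tt <- seq(0, dur - 1 / fs, by = 1 / fs)
      h0 <- state_height(construct, before, f, env)
      h <- rep(0, length(tt))
      if (t_rup < dur) {
        step <- state_height(construct, after, f, env) - h0
        h[tt >= t_rup] <- step
        add_truth(t_rup, "rupture", step)
      }
      hn <- h + stats::rnorm(length(h), 0, noise$height_sd)
      tr <- mt_trace(tt, rep(f, length(tt)), hn, fs,
                     metadata = list(protocol = "constant",
                                     construct = construct$name,
                                     seed = rng_seed))
      return(list(trace = tr,
                  truth = if (length(truth)) do.call(rbind, truth)
                          else data.frame(time_s = numeric(),
                                          transition = character(),
                                          step_nm = numeric())))
    }
    mdl <- model
    if (mdl$n_pairs != nd)
      stop("model pair count must match the construct's domain count")
    sim <- simulate_constant_force(mdl, f, 1, rng_seed = NULL,
                                   max_time = protocol$duration, env = env)
    ev <- sim$events[[1]]
    dur <- if (is.finite(protocol$duration)) protocol$duration
           else (if (sim$censored[1]) max(ev$time_s, 1) else sim$times[1]) + 1
    tt <- seq(0, dur - 1 / fs, by = 1 / fs)
    # replay the event sequence into tether states
    s <- mdk_initial_state(mdl)
    st <- mdk_to_tether_state(mdl, s, nd)
    h0 <- state_height(construct, st, f, env)
    h <- rep(0, length(tt))
    prev_h <- 0
    if (nrow(ev)) {
      for (r in seq_len(nrow(ev))) {
        trs <- mdk_transitions(mdl, s, f, env)
        hit <- Find(function(x) x$type == ev$type[r] && x$pair == ev$pair[r], trs)
        s <- hit$to
        st <- mdk_to_tether_state(mdl, s, nd)
        new_h <- state_height(construct, st, f, env) - h0
        add_truth(ev$time_s[r], ev$type[r], new_h - prev_h)
        h[tt >= ev$time_s[r]] <- new_h
        prev_h <- new_h
      }
    }
    hn <- h + stats::rnorm(length(h), 0, noise$height_sd)
    tr <- mt_trace(tt, rep(f, length(tt)), hn, fs,
                   metadata = list(protocol = "constant",
                                   construct = construct$name, seed = rng_seed))
  } else if (protocol$kind == "ramp") {
    r <- protocol$rate
    mdl <- as_mdk(model)
    sim <- simulate_ramp(mdl, protocol, n_runs = 1, rng_seed = NULL, env = env)
    f_rup <- sim$forces[1]
    t_end <- (protocol$to - protocol$from) / r
    tt <- seq(0, t_end - 1 / fs, by = 1 / fs)
    ff <- protocol$from + r * tt
    before <- tether_state(TRUE, "shielded", n_domains = nd)
    after <- tether_state(FALSE,
                          if (rupture_unfolds_domains) "unfolded" else "folded",
                          n_domains = nd)
    h <- vapply(seq_along(tt), function(i) {
      st <- if (!is.na(f_rup) && ff[i] >= f_rup) after else before
      state_height(construct, st, max(ff[i], 1e-3), env)
    }, numeric(1))
    h <- h - h[1]
    if (!is.na(f_rup)) {
      t_rup <- (f_rup - protocol$from) / r
      step <- state_height(construct, after, f_rup, env) -
              state_height(construct, before, f_rup, env)
      add_truth(t_rup, "rupture", step)
    }
    hn <- h + stats::rnorm(length(h), 0, noise$height_sd)
    tr <- mt_trace(tt, ff, hn, fs,
                   metadata = list(protocol = "ramp", loading_rate = r,
                                   construct = construct$name, seed = rng_seed))
  } else { # jump cycles
    mdl <- as_mdk(model)
    lo_n <- round(protocol$low_duration * fs)
    hi_n <- round(protocol$hold_duration * fs)
    cyc_n <- lo_n + hi_n
    ncyc <- protocol$n_cycles
    tt <- (seq_len(cyc_n * ncyc) - 1L) / fs
    ff <- numeric(length(tt)); h <- numeric(length(tt))
    before <- tether_state(TRUE, "shielded", n_domains = nd)
    after <- tether_state(FALSE,
                          if (rupture_unfolds_domains) "unfolded" else "folded",
                          n_domains = nd)
    holds <- data.frame(start_s = numeric(ncyc), end_s = numeric(ncyc),
                        force_pN = numeric(ncyc))
    fhi <- protocol$hold_force
    h_lo <- state_height(construct, before, protocol$low_force, env)
    h_before <- state_height(construct, before, fhi, env)
    h_after <- state_height(construct, after, fhi, env)
    for (c in seq_len(ncyc)) {
      off <- (c - 1L) * cyc_n
      lo_idx <- off + seq_len(lo_n)
      hi_idx <- off + lo_n + seq_len(hi_n)
      ff[lo_idx] <- protocol$low_force
      ff[hi_idx] <- fhi
      h[lo_idx] <- 0
      t_jump <- tt[hi_idx[1]]
      sim <- simulate_constant_force(mdl, fhi, 1, rng_seed = NULL,
                                     max_time = protocol$hold_duration,
                                     env = env, record_events = FALSE)
      dwell <- sim$times[1]
      base_hi <- h_before - h_lo
      if (!is.na(dwell)) {
        t_rup <- t_jump + dwell
        h[hi_idx] <- base_hi + ifelse(tt[hi_idx] >= t_rup,
                                      h_after - h_before, 0)
        add_truth(t_rup, "rupture", h_after - h_before)
      } else {
        h[hi_idx] <- base_hi
      }
      if (jump_artifact_nm != 0) {
        art <- tt[hi_idx] - t_jump
        sel <- art <= 0.25
        h[hi_idx][sel] <- h[hi_idx][sel] +
          jump_artifact_nm * exp(-art[sel] / 0.08)
      }
      holds$start_s[c] <- t_jump
      holds$end_s[c] <- tt[hi_idx[hi_n]]
      holds$force_pN[c] <- fhi
    }
    hn <- h + stats::rnorm(length(h), 0, noise$height_sd)
    tr <- mt_trace(tt, ff, hn, fs,
                   metadata = list(protocol = "jump", holds = holds,
                                   construct = construct$name, seed = rng_seed))
  }
  list(trace = tr,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(time_s = numeric(), transition = character(),
                               step_nm = numeric()))
}
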