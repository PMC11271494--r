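# Shared fixtures built in code at test time.

# piecewise-constant height trace with programmed steps and Gaussian noise
make_step_trace <- function(step_times, step_sizes, duration = 10,
                            sigma = 3, fs = 200, force = 45, seed = NULL,
                            offset = 0) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  h <- rep(offset, length(tt))
  for (i in seq_along(step_times))
    h[tt >= step_times[i]] <- h[tt >= step_times[i]] + step_sizes[i]
  h <- h + stats::rnorm(length(tt), 0, sigma)
  mt_trace(tt, rep(force, length(tt)), h, fs)
}

# default force-clamp dwell fixture across several forces
make_dwell_table <- function(params, forces, n_per_force, seed) {
  do.call(rbind, lapply(seq_along(forces), function(i)
    generate_dwells(params, forces[i], n_per_force,
                    rng_seed = seed * 1000L + i)))
}
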