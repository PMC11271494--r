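#' Domain specification
#'
#' A single folded domain on the force-bearing path: a spectrin-repeat-like
#' three-helix bundle by default (~110 residues folding into a ~5 nm body).
#'
#' @param name domain label
#' @param n_residues residues in the domain (>= 1)
#' @param folded_span span of the folded body in nm; must be positive and
#'   below the domain's contour length
#' @param l0 contour length per residue used for the validity check (nm)
#' @return an object of class `domain_spec`
#' @export
domain_spec <- function(name = "SR", n_residues = 110, folded_span = 5,
                        l0 = 0.38) {
  if (n_residues < 1) stop("'n_residues' must be >= 1")
  if (folded_span <= 0) stop("'folded_span' must be positive")
  if (folded_span >= n_residues * l0)
    stop("'folded_span' must be below the domain contour length")
  structure(list(name = name, n_residues = n_residues,
                 folded_span = folded_span),
            class = "domain_spec")
}

#' Rod specification
#'
#' An ordered run of domains plus inter-domain helical linkers that together
#' fold into one rigid rod. `total_residues` may exceed the sum of the
#' domain residues; the remainder accounts for the helical linkers.
#'
#' @param domains list of [domain_spec()] objects (default: four spectrin
#'   repeats)
#' @param total_residues residues in the whole rod including linkers
#' @param folded_span rigid span of the intact rod in nm
#' @return an object of class `rod_spec`
#' @export
rod_spec <- function(domains = replicate(4, domain_spec(), simplify = FALSE),
                     total_residues = 480, folded_span = 24) {
  stopifnot(all(vapply(domains, inherits, logical(1), what = "domain_spec")))
  if (total_residues < sum(vapply(domains, `[[`, numeric(1), "n_residues")))
    stop("'total_residues' must be at least the sum of domain residues")
  if (folded_span <= 0) stop("'folded_span' must be positive")
  structure(list(domains = domains, total_residues = total_residues,
                 folded_span = folded_span),
            class = "rod_spec")
}

#' Single-molecule construct specification
#'
#' Describes a looped dimer construct pulled in either shear geometry (both
#' interfaces loaded in parallel; anti-parallel rods pulled from same-side
#' termini) or unzip geometry (interfaces peeled from one end). The two rods
#' dimerise; a long flexible linker connects them and is looped inside the
#' dimer until rupture releases it onto the force path.
#'
#' @param geometry `"shear"` or `"unzip"`
#' @param rod the force-bearing [rod_spec()] (rods assumed identical)
#' @param loop_residues residues of the looped flexible linker
#' @param dimer_span_before rigid span (nm) of the intact dimer
#' @param dimer_span_after numeric vector of rigid spans (nm) on the force
#'   path after rupture (e.g. `c(24, 24)` for the unzip geometry where both
#'   rods end up in series)
#' @param loop_end_to_end geometrically imposed end-to-end distance (nm) of
#'   the looped linker while the dimer is intact
#' @param name optional construct label
#' @return an object of class `construct_spec`
#' @export
construct_spec <- function(geometry = c("shear", "unzip"),
                           rod = rod_spec(),
                           loop_residues = 170,
                           dimer_span_before = 24,
                           dimer_span_after = 24,
                           loop_end_to_end = 24,
                           name = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(rod, "rod_spec"))
  if (dimer_span_before <= 0 || any(dimer_span_after <= 0))
    stop("all dimer spans must be positive")
  if (loop_end_to_end < 0) stop("'loop_end_to_end' must be non-negative")
  if (loop_residues < 1) stop("'loop_residues' must be >= 1")
  structure(list(geometry = geometry, rod = rod,
                 loop_residues = loop_residues,
                 dimer_span_before = dimer_span_before,
                 dimer_span_after = dimer_span_after,
                 loop_end_to_end = loop_end_to_end,
                 name = name %||% sprintf("%s construct", geometry)),
            class = "construct_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("<construct_spec> %s (%s geometry)\n", x$name, x$geometry))
  cat(sprintf("  rod: %d domains, %d residues, span %g nm\n",
              length(x$rod$domains), x$rod$total_residues, x$rod$folded_span))
  cat(sprintf("  loop linker: %d residues, in-dimer end-to-end %g nm\n",
              x$loop_residues, x$loop_end_to_end))
  cat(sprintf("  dimer span: %g nm before, %s nm after rupture\n",
              x$dimer_span_before, paste(x$dimer_span_after, collapse = " + ")))
  invisible(x)
}

#' Conformational state of a tethered construct
#'
#' Describes which mechanical elements bear force. While the dimer is intact
#' (`dimerized = TRUE`) the interface contributes its rigid span and
#' individual domains are either shielded inside the dimer (`"shielded"`),
#' stretched but folded (`"folded"`, a small rigid body), or unfolded
#' (`"unfolded"`, a flexible chain). After rupture no domain can be
#' shielded and the released loop linker joins the force path.
#'
#' @param dimerized logical flag
#' @param domains character vector (one entry per rod domain) with values
#'   `"shielded"`, `"folded"` or `"unfolded"`; recycled from a single value
#' @param n_domains number of domains (used when `domains` is length 1)
#' @return an object of class `tether_state`
#' @export
tether_state <- function(dimerized = TRUE, domains = "shielded",
                         n_domains = 4) {
  if (length(domains) == 1L) domains <- rep(domains, n_domains)
  if (!all(domains %in% c("shielded", "folded", "unfolded")))
    stop("domain states must be 'shielded', 'folded' or 'unfolded'")
  if (!dimerized && any(domains == "shielded"))
    stop("inconsistent state: no domain can be shielded after rupture")
  structure(list(dimerized = dimerized, domains = domains,
                 loop_released = !dimerized),
            class = "tether_state")
}

#' Map a conformational state to its mechanical series
#'
#' The intact dimer contributes one rigid segment of span
#' `dimer_span_before`; each stretched folded domain contributes a rigid
#' segment of its folded span; each unfolded domain contributes a flexible
#' chain of its residues. The unreleased loop contributes nothing (its
#' end-to-end distance is geometrically imposed, not force-borne). After
#' rupture the released loop contributes its flexible chain and the rod
#' contributes either its post-rupture rigid spans (domains folded) or, if
#' every domain has unfolded, a single flexible chain of the rod's total
#' residues (the helical linkers unravel with the domains).
#'
#' @param construct a [construct_spec()]
#' @param state a [tether_state()]
#' @return a [mechanical_series()]
#' @examples
#' cs <- construct_spec()
#' state_to_series(cs, tether_state(TRUE))               # intact dimer
#' state_to_series(cs, tether_state(FALSE, "unfolded"))  # fully unravelled
#' @export
state_to_series <- function(construct, state) {
  stopifnot(inherits(construct, "construct_spec"),
            inherits(state, "tether_state"))
  doms <- construct$rod$domains
  if (length(state$domains) != length(doms))
    stop(sprintf("state describes %d domains but the rod has %d",
                 length(state$domains), length(doms)))
  segs <- list()
  add <- function(s) segs[[length(segs) + 1L]] <<- s
  if (state$dimerized) {
    add(rigid_segment(construct$dimer_span_before))
    for (i in seq_along(doms)) {
      st <- state$domains[i]
      if (st == "folded") add(rigid_segment(doms[[i]]$folded_span))
      if (st == "unfolded") add(flexible_chain(doms[[i]]$n_residues))
    }
  } else {
    if (all(state$domains == "unfolded")) {
      add(flexible_chain(construct$rod$total_residues))
    } else {
      for (b in construct$dimer_span_after) add(rigid_segment(b))
      for (i in seq_along(doms))
        if (state$domains[i] == "unfolded")
          add(flexible_chain(doms[[i]]$n_residues))
    }
    add(flexible_chain(construct$loop_residues))
  }
  mechanical_series(segs)
}

#' Named standard transitions of a construct
#'
#' Convenience constructor for the transitions observed in the experiments:
#' * `"unfold_one"`: one stretched folded domain unfolds (folded body ->
#'   chain) while the dimer stays intact.
#' * `"rupture_folded"`: the intact, fully folded dimer ruptures, releasing
#'   the loop linker; domains stay folded.
#' * `"rupture_unfold_rest"`: rupture concurrent with unfolding of all
#'   remaining folded domains, starting from a state with `n_pre_unfolded`
#'   domains already unfolded.
#' * `"redimerize"` / `"refold"`: the reverse of the first two (negative
#'   steps).
#'
#' @param construct a [construct_spec()]
#' @param labels character vector of transition names (any of the above)
#' @param n_pre_unfolded domains already unfolded before a
#'   `"rupture_unfold_rest"` transition
#' @return a named list of `list(before =, after =)` state pairs
#' @export
standard_transitions <- function(construct,
                                 labels = c("unfold_one", "rupture_folded",
                                            "rupture_unfold_rest"),
                                 n_pre_unfolded = 1) {
  nd <- length(construct$rod$domains)
  mk <- function(...) tether_state(..., n_domains = nd)
  one_folded <- rep("shielded", nd); one_folded[1] <- "folded"
  one_unfolded <- rep("shielded", nd); one_unfolded[1] <- "unfolded"
  pre <- rep("shielded", nd)
  pre[seq_len(min(n_pre_unfolded, nd))] <- "unfolded"
  out <- list(
    unfold_one = list(before = mk(TRUE, one_folded),
                      after  = mk(TRUE, one_unfolded)),
    rupture_folded = list(before = mk(TRUE, "shielded"),
                          after  = mk(FALSE, "folded")),
    rupture_unfold_rest = list(before = mk(TRUE, pre),
                               after  = mk(FALSE, "unfolded")),
    redimerize = list(before = mk(FALSE, "folded"),
                      after  = mk(TRUE, "shielded")),
    refold = list(before = mk(TRUE, one_unfolded),
                  after  = mk(TRUE, one_folded))
  )
  unknown <- setdiff(labels, names(out))
  if (length(unknown))
    stop("unknown transition label(s): ", paste(unknown, collapse = ", "))
  out[labels]
}

# Number of unfolded domains in a state
n_unfolded <- function(state) sum(state$domains == "unfolded")

#' Predicted step-size table over a force grid
#'
#' Evaluates the transition step size of each listed transition at each
#' force. For a pure rupture (loop release with no concurrent change in the
#' number of unfolded domains) the geometrically imposed in-dimer end-to-end
#' distance of the loop is subtracted, so that the step equals the extension
#' difference of the looped linker (plus any rigid-span change) before and
#' after rupture. Composite rupture-plus-unfolding steps are reported as the
#' plain extension difference of the published residue bookkeeping.
#'
#' @param construct a [construct_spec()]
#' @param transitions a named list of `list(before =, after =)`
#'   [tether_state()] pairs, e.g. from [standard_transitions()]
#' @param forces positive, ascending force grid in pN
#' @param env a [polymer_env()]
#' @param loop_correction apply the in-dimer end-to-end subtraction for pure
#'   loop-release transitions (default `TRUE`)
#' @return a data frame with columns `transition`, `force_pN`, `step_nm`
#' @examples
#' cs <- construct_spec()
#' predicted_step_table(cs, standard_transitions(cs), forces = c(45, 56))
#' @export
predicted_step_table <- function(construct, transitions, forces,
                                 env = polymer_env(), loop_correction = TRUE) {
  if (length(forces) && (any(forces <= 0) || is.unsorted(forces)))
    stop("'forces' must be positive and ascending")
  if (length(transitions) == 0L || length(forces) == 0L)
    return(data.frame(transition = character(), force_pN = numeric(),
                      step_nm = numeric()))
  if (is.null(names(transitions)))
    names(transitions) <- sprintf("transition_%d", seq_along(transitions))
  rows <- lapply(names(transitions), function(nm) {
    tr <- transitions[[nm]]
    step <- transition_step_size(forces,
                                 state_to_series(construct, tr$before),
                                 state_to_series(construct, tr$after), env)
    if (loop_correction) {
      releases <- tr$before$dimerized && !tr$after$dimerized
      captures <- !tr$before$dimerized && tr$after$dimerized
      pure <- n_unfolded(tr$before) == n_unfolded(tr$after)
      if (releases && pure) step <- step - construct$loop_end_to_end
      if (captures && pure) step <- step + construct$loop_end_to_end
    }
    data.frame(transition = nm, force_pN = forces, step_nm = step)
  })
  do.call(rbind, rows)
}

#' Built-in construct presets
#'
#' Presets for the dimer constructs studied experimentally, loaded from the
#' editable YAML file shipped in `inst/extdata/constructs.yaml`. Spans for
#' the partial rods (three- and two-repeat constructs) are proportional
#' estimates from the full rod; see the file for details.
#'
#' @param name preset name; call with no arguments to list available presets
#' @return a [construct_spec()], or a character vector of preset names
#' @examples
#' construct_presets()
#' construct_presets("actn1_shear_full")
#' @export
construct_presets <- function(name = NULL) {
  path <- system.file("extdata", "constructs.yaml", package = "mtdimer")
  defs <- yaml::read_yaml(path)
  if (is.null(name)) return(names(defs))
  if (!name %in% names(defs))
    stop(sprintf("unknown construct preset '%s'; available: %s",
                 name, paste(names(defs), collapse = ", ")))
  d <- defs[[name]]
  doms <- replicate(d$n_domains,
                    domain_spec(n_residues = d$domain_residues,
                                folded_span = d$domain_span),
                    simplify = FALSE)
  construct_spec(geometry = d$geometry,
                 rod = rod_spec(doms, total_residues = d$rod_residues,
                                folded_span = d$rod_span),
                 loop_residues = d$loop_residues,
                 dimer_span_before = d$dimer_span_before,
                 dimer_span_after = unlist(d$dimer_span_after),
                 loop_end_to_end = d$loop_end_to_end,
                 name = name)
}
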