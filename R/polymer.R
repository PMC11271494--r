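#' Polymer environment: thermal energy and chain constants
#'
#' Bundles the physical constants used by every force--extension model in the
#' package: the thermal energy \eqn{k_BT}, the bending persistence length
#' \eqn{A} of an unfolded peptide chain, and the contour length per residue
#' \eqn{l_0}. Defaults correspond to experiments at 22 degrees C with an
#' unstructured polypeptide (\eqn{k_BT = 4.075} pN nm, \eqn{A = 0.8} nm,
#' \eqn{l_0 = 0.38} nm).
#'
#' All quantities in the package are in pN, nm, s and pN nm; no unit
#' conversion happens inside any operation.
#'
#' @param kBT thermal energy in pN nm (> 0)
#' @param A persistence length of the unfolded chain in nm (> 0)
#' @param l0 contour length per residue in nm (> 0)
#' @return an object of class `polymer_env`
#' @examples
#' env <- polymer_env()
#' env$kBT
#' @export
polymer_env <- function(kBT = 4.075, A = 0.8, l0 = 0.38) {
  if (!is.numeric(kBT) || length(kBT) != 1L || !is.finite(kBT) || kBT <= 0)
    stop("'kBT' must be a single positive number (pN nm)")
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive number (nm)")
  if (!is.numeric(l0) || length(l0) != 1L || !is.finite(l0) || l0 <= 0)
    stop("'l0' must be a single positive number (nm)")
  structure(list(kBT = kBT, A = A, l0 = l0), class = "polymer_env")
}

#' @export
print.polymer_env <- function(x, ...) {
  cat(sprintf("<polymer_env> kBT = %g pN nm, A = %g nm, l0 = %g nm/residue\n",
              x$kBT, x$A, x$l0))
  invisible(x)
}

#' Rigid segment: a folded body on the force path
#'
#' A folded domain or dimer interface is modelled as a rigid body whose
#' force--extension behaviour is the single-segment freely-jointed chain
#' (orientational averaging of a rod of span `b` between the two
#' force-attachment points).
#'
#' @param b span between force-attachment points in nm (> 0)
#' @return an object of class `rigid_segment`
#' @seealso [rigid_extension()]
#' @export
rigid_segment <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("rigid segment span 'b' must be a single positive number (nm)")
  structure(list(b = b), class = c("rigid_segment", "mech_segment"))
}

#' Flexible chain: an unfolded peptide on the force path
#'
#' An unfolded stretch of `n_residues` amino acids, modelled as a worm-like
#' chain with contour length `n_residues * l0`.
#'
#' @param n_residues number of residues (>= 1)
#' @return an object of class `flexible_chain`
#' @seealso [wlc_force()], [wlc_extension()]
#' @export
flexible_chain <- function(n_residues) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L ||
      !is.finite(n_residues) || n_residues < 1)
    stop("'n_residues' must be a single number >= 1")
  structure(list(n_residues = as.numeric(n_residues)),
            class = c("flexible_chain", "mech_segment"))
}

#' Contour length of a flexible chain
#' @param chain a [flexible_chain()]
#' @param env a [polymer_env()]
#' @return contour length in nm
#' @export
contour_length <- function(chain, env = polymer_env()) {
  stopifnot(inherits(chain, "flexible_chain"))
  chain$n_residues * env$l0
}

# Langevin function coth(a) - 1/a, stable for small and large arguments.
# Series a/3 - a^3/45 below 1e-4 avoids catastrophic cancellation.
langevin <- function(a) {
  out <- numeric(length(a))
  small <- abs(a) < 1e-4
  out[small] <- a[small] / 3 - a[small]^3 / 45
  ab <- a[!small]
  out[!small] <- 1 / tanh(ab) - 1 / ab
  out
}

#' Extension of a rigid body under force (single-segment FJC)
#'
#' \deqn{x(f) = b\,[\coth(fb/k_BT) - k_BT/(fb)]}
#'
#' The extension is 0 in the zero-force limit and approaches the span `b`
#' at high force.
#'
#' @param force applied force in pN (> 0; vectorised)
#' @param segment a [rigid_segment()]
#' @param env a [polymer_env()]
#' @return extension in nm, same length as `force`
#' @examples
#' rigid_extension(45, rigid_segment(5))
#' @export
rigid_extension <- function(force, segment, env = polymer_env()) {
  stopifnot(inherits(segment, "rigid_segment"))
  if (any(!is.finite(force)) || any(force < 0))
    stop("'force' must be finite and non-negative (pN)")
  segment$b * langevin(force * segment$b / env$kBT)
}

#' Force of a stretched worm-like chain (Marko--Siggia)
#'
#' The Marko--Siggia interpolation
#' \deqn{\frac{fA}{k_BT} = \frac{1}{4(1-x/L)^2} - \frac14 + \frac{x}{L}}
#' with contour length \eqn{L = N l_0}. Diverges as the extension approaches
#' the contour length, so `extension` must be strictly below it.
#'
#' @param extension end-to-end extension in nm (0 <= extension < contour
#'   length; vectorised)
#' @param chain a [flexible_chain()]
#' @param env a [polymer_env()]
#' @return force in pN
#' @examples
#' wlc_force(24, flexible_chain(170)) # ~3.8 pN
#' @export
wlc_force <- function(extension, chain, env = polymer_env()) {
  stopifnot(inherits(chain, "flexible_chain"))
  L <- contour_length(chain, env)
  if (any(!is.finite(extension)) || any(extension < 0))
    stop("'extension' must be finite and non-negative (nm)")
  if (any(extension >= L))
    stop(sprintf(
      "extension (%g nm) must be below the contour length (%g nm): the WLC force diverges",
      max(extension), L))
  u <- extension / L
  env$kBT / env$A * (1 / (4 * (1 - u)^2) - 0.25 + u)
}

# dF/dx of the Marko-Siggia formula (used for Newton polishing)
wlc_force_deriv <- function(extension, chain, env) {
  L <- contour_length(chain, env)
  u <- extension / L
  env$kBT / env$A * (1 / (2 * L * (1 - u)^3) + 1 / L)
}

#' Extension of a worm-like chain at a given force
#'
#' Numerical inversion of [wlc_force()]: a bracketed root solve on
#' \eqn{[0, L(1-10^{-9})]} followed by Newton polishing to an absolute force
#' residual below 1e-9 pN. Deterministic; no randomness.
#'
#' @param force applied force in pN (>= 0; vectorised)
#' @param chain a [flexible_chain()]
#' @param env a [polymer_env()]
#' @return extension in nm within `[0, contour_length)`
#' @examples
#' wlc_extension(45, flexible_chain(110)) # ~34.5 nm
#' @export
wlc_extension <- function(force, chain, env = polymer_env()) {
  stopifnot(inherits(chain, "flexible_chain"))
  if (any(!is.finite(force)) || any(force < 0))
    stop("'force' must be finite and non-negative (pN)")
  L <- contour_length(chain, env)
  hi <- L * (1 - 1e-9)
  vapply(force, function(f) {
    if (f == 0) return(0)
    if (wlc_force(hi, chain, env) < f)
      stop(sprintf("force %g pN not bracketed below extension %g nm", f, hi))
    x <- stats::uniroot(function(x) wlc_force(x, chain, env) - f,
                        interval = c(0, hi), tol = 1e-12 * max(1, L))$root
    # Newton polish to the declared force tolerance
    for (i in 1:50) {
      r <- wlc_force(x, chain, env) - f
      if (abs(r) <= 1e-9) break
      x <- x - r / wlc_force_deriv(x, chain, env)
      x <- min(max(x, 0), hi)
    }
    if (abs(wlc_force(x, chain, env) - f) > 1e-6)
      stop(sprintf("WLC inversion did not converge at f = %g pN (residual %g pN)",
                   f, wlc_force(x, chain, env) - f))
    x
  }, numeric(1))
}

#' Force exerted by a looped flexible linker
#'
#' A flexible linker looped inside a dimer with a geometrically imposed
#' end-to-end distance can pull the dimer together with at most the
#' worm-like-chain force at that end-to-end distance. This is [wlc_force()]
#' evaluated at `end_to_end`, named for its interpretation.
#'
#' @param chain the linker as a [flexible_chain()]
#' @param end_to_end imposed end-to-end distance in nm
#' @param env a [polymer_env()]
#' @return maximal linker force in pN
#' @examples
#' loop_force(flexible_chain(170), 24) # ~3.8 pN
#' loop_force(flexible_chain(170), 18) # ~2.6 pN
#' @export
loop_force <- function(chain, end_to_end, env = polymer_env()) {
  wlc_force(end_to_end, chain, env)
}

#' Mechanical series of segments
#'
#' Segments in mechanical series all carry the same force; the total
#' extension is the sum of member extensions.
#'
#' @param ... rigid segments and flexible chains
#' @return an object of class `mech_series`
#' @export
mechanical_series <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) &&
      !inherits(segs[[1]], "mech_segment"))
    segs <- segs[[1]]
  if (length(segs) == 0L) stop("a mechanical series must contain at least one segment")
  ok <- vapply(segs, inherits, logical(1), what = "mech_segment")
  if (!all(ok)) stop("all members must be rigid_segment, flexible_chain or const_segment objects")
  structure(segs, class = "mech_series")
}

#' Constant-extension pseudo-segment
#'
#' Represents a geometrically imposed end-to-end distance (e.g. a looped
#' linker held at fixed span inside a dimer) that contributes a fixed,
#' force-independent extension.
#'
#' @param x fixed extension in nm (>= 0)
#' @return an object of class `const_segment`
#' @export
const_segment <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("'x' must be a single non-negative number (nm)")
  structure(list(x = x), class = c("const_segment", "mech_segment"))
}

#' Extension of a single segment at a force
#' @param segment a segment object
#' @param force force in pN
#' @param env a [polymer_env()]
#' @return extension in nm
#' @export
segment_extension <- function(segment, force, env = polymer_env()) {
  UseMethod("segment_extension")
}

#' @export
segment_extension.rigid_segment <- function(segment, force, env = polymer_env()) {
  rigid_extension(force, segment, env)
}

#' @export
segment_extension.flexible_chain <- function(segment, force, env = polymer_env()) {
  wlc_extension(force, segment, env)
}

#' @export
segment_extension.const_segment <- function(segment, force, env = polymer_env()) {
  rep(segment$x, length(force))
}

#' Total extension of a mechanical series
#' @param series a [mechanical_series()] (a bare list of segments is accepted)
#' @param force force in pN (vectorised)
#' @param env a [polymer_env()]
#' @return total extension in nm
#' @export
series_extension <- function(series, force, env = polymer_env()) {
  if (!inherits(series, "mech_series")) series <- mechanical_series(series)
  exts <- vapply(series, segment_extension, numeric(length(force)),
                 force = force, env = env)
  if (length(force) == 1L) sum(exts) else rowSums(matrix(exts, nrow = length(force)))
}

#' Force-dependent transition step size
#'
#' The predicted bead-height step of a conformational transition at a given
#' force: the difference between the total extension of the mechanical
#' series after and before the transition, evaluated at that force.
#' Positive steps correspond to extension gains (unfolding, rupture).
#'
#' @param force transition force in pN (> 0; vectorised)
#' @param before mechanical series before the transition
#' @param after mechanical series after the transition
#' @param env a [polymer_env()]
#' @return signed step size in nm
#' @examples
#' # one ~110-residue domain unfolding from a 5 nm folded body at 45 pN
#' transition_step_size(45, mechanical_series(rigid_segment(5)),
#'                      mechanical_series(flexible_chain(110)))
#' @export
transition_step_size <- function(force, before, after, env = polymer_env()) {
  if (any(force <= 0)) stop("'force' must be positive (pN)")
  series_extension(after, force, env) - series_extension(before, force, env)
}
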