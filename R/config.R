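#' Model configuration for a pair of bound oscillatory process systems
#'
#' Describes two linear oscillatory subsystems — `n` "space" processes
#' `p_1..p_n` with auxiliaries `x_1..x_n`, and `m` "time" processes
#' `q_1..q_m` with auxiliaries `z_1..z_m` — whose within-block interactions
#' are squared-distance relation matrices (see [distance_matrix()]) scaled
#' by `epsilon` (space) and `alpha` (time), and whose cross-block binding is
#' controlled by the binding strength `omega` under a named coupling scheme.
#'
#' Negative `epsilon`/`alpha` mean mutual inhibition between processes of a
#' block, positive values mutual activation. The coupling schemes are only
#' defined for `n = m = 2`:
#'
#' * `"direct"`: the space equations receive `+omega * q_i`, the time
#'   equations `-omega * p_i` — a negative feedback loop across the blocks.
#' * `"difference"`: the blocks exchange the differences `q_1 - q_2` and
#'   `p_2 - p_1` (and their negations).
#' * `"none"`: the blocks evolve independently; equivalent to `omega = 0`.
#'
#' @param n Number of space processes (>= 1).
#' @param m Number of time processes (>= 1).
#' @param epsilon Relation scale of the space block (default -1, mutual
#'   inhibition).
#' @param alpha Relation scale of the time block (default -1).
#' @param omega Binding strength (>= 0).
#' @param scheme Coupling scheme: `"direct"`, `"difference"`, or `"none"`.
#'
#' @return An object of class `binding_config`.
#' @examples
#' binding_config(omega = 0.5)
#' binding_config(n = 4, m = 3, scheme = "none")
#' @export
binding_config <- function(n = 2, m = 2, epsilon = -1, alpha = -1,
                           omega = 0, scheme = c("direct", "difference", "none")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a single integer >= 1.", class = "bindsim_invalid_parameter")
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    abort("`m` must be a single integer >= 1.", class = "bindsim_invalid_parameter")
  }
  for (nm in c("epsilon", "alpha", "omega")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "bindsim_invalid_parameter")
    }
  }
  if (omega < 0) {
    abort("`omega` must be >= 0.", class = "bindsim_invalid_parameter")
  }
  if (scheme != "none" && (n != 2 || m != 2)) {
    abort("Coupling schemes are only defined for n = m = 2; use scheme = \"none\" otherwise.",
          class = "bindsim_invalid_parameter")
  }
  structure(
    list(n = as.integer(n), m = as.integer(m),
         epsilon = as.numeric(epsilon), alpha = as.numeric(alpha),
         omega = as.numeric(omega), scheme = scheme),
    class = "binding_config"
  )
}

#' @export
print.binding_config <- function(x, ...) {
  cat("<binding_config>\n")
  cat(sprintf("  space block: n = %d, epsilon = %g\n", x$n, x$epsilon))
  cat(sprintf("  time block:  m = %d, alpha = %g\n", x$m, x$alpha))
  cat(sprintf("  binding:     omega = %g, scheme = %s\n", x$omega, x$scheme))
  invisible(x)
}

#' Squared-distance relation matrix
#'
#' Builds the hollow symmetric matrix with entries `(i - j)^2 * scale`
#' encoding the Euclidean squared-distance relationships among the `size`
#' processes of one block (matrix `A` for the space block with
#' `scale = epsilon`, matrix `B` for the time block with `scale = alpha`).
#'
#' @param size Matrix dimension (number of processes in the block, >= 1).
#' @param scale Relation scale (`epsilon` or `alpha`).
#' @return A `size` x `size` numeric matrix, hollow and symmetric.
#' @examples
#' distance_matrix(2, -1)
#' distance_matrix(3, 0.5)
#' @export
distance_matrix <- function(size, scale) {
  if (!is.numeric(size) || length(size) != 1 || size < 1 || size != round(size)) {
    abort("`size` must be a single integer >= 1.", class = "bindsim_invalid_parameter")
  }
  i <- seq_len(size)
  outer(i, i, function(a, b) (a - b)^2 * scale)
}

# Component names of the flat state vector (p1..pn, x1..xn, q1..qm, z1..zm).
state_names <- function(n, m) {
  c(paste0("p", seq_len(n)), paste0("x", seq_len(n)),
    paste0("q", seq_len(m)), paste0("z", seq_len(m)))
}

#' Assemble a flat state vector
#'
#' The canonical flat ordering of the system state is
#' `(p_1..p_n, x_1..x_n, q_1..q_m, z_1..z_m)`; all components are
#' unrestricted reals (processes oscillate around zero).
#'
#' @param p,q Space / time process values (length `n` / `m`).
#' @param x,z Auxiliary process values; default zero.
#' @return A named numeric vector of length `2n + 2m`.
#' @examples
#' binding_state(p = c(1000, 0), q = c(1, 0))
#' @export
binding_state <- function(p, q, x = numeric(length(p)), z = numeric(length(q))) {
  stopifnot(length(x) == length(p), length(z) == length(q))
  setNames(c(p, x, q, z), state_names(length(p), length(q)))
}

# Validate a state vector against a config; returns unnamed numeric vector.
check_state <- function(state, config) {
  d <- 2L * config$n + 2L * config$m
  if (!is.numeric(state) || length(state) != d) {
    abort(sprintf("State must be numeric of length %d (2n + 2m); got length %d.",
                  d, length(state)),
          class = "bindsim_invalid_state")
  }
  if (any(!is.finite(state))) {
    abort("State contains non-finite values.", class = "bindsim_invalid_state")
  }
  as.numeric(state)
}
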