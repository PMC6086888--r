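#' Network parameters for the cascaded normalization circuit
#'
#' Bundles the connectivity and timescales of the two-stage (fast/slow)
#' divisive-normalization network. Each of the `n_options` choice options
#' is represented by one excitatory/inhibitory pair in each subcircuit.
#' The fast gain-control units pool fast excitatory activity (weights
#' `omega`) and slow excitatory activity (weights `alpha`); the slow
#' gain-control units pool slow excitatory activity (weights `beta`).
#' The default all-ones weights make inhibition global within each stage
#' and assume no a priori excitation/inhibition asymmetry.
#'
#' Only the ratio `tau_slow / tau_fast` affects network behavior up to a
#' rescaling of time, so the ratio is the natural free parameter; the
#' default `tau_fast = 100` ms reflects the intra-trial timescale of
#' value-coding dynamics in decision-related cortex, and the default
#' ratio of 600 puts the slow circuit at 60 s, the timescale at which
#' adaptation best tracks block-wise reward statistics.
#'
#' @param n_options Number of choice options `N` (positive integer).
#' @param tau_fast Fast-circuit time constant, ms.
#' @param tau_ratio Ratio `tau_slow / tau_fast`; used when `tau_slow`
#'   is `NULL`.
#' @param tau_slow Slow-circuit time constant, ms. Overrides `tau_ratio`.
#' @param omega,alpha,beta Nonnegative weight matrices (`N` by `N`), or
#'   scalars recycled to a constant matrix. `omega`: fast R -> fast G;
#'   `alpha`: slow R -> fast G; `beta`: slow R -> slow G.
#' @return An object of class `norm_params`.
#' @examples
#' norm_params()                      # 2 options, tau 100 ms / 60 s
#' norm_params(tau_ratio = 1000)
#' norm_params(alpha = 0)             # decoupled: fast circuit alone
#' @export
norm_params <- function(n_options = 2, tau_fast = 100, tau_ratio = 600,
                        tau_slow = NULL, omega = 1, alpha = 1, beta = 1) {
  if (length(n_options) != 1 || n_options < 1 || n_options %% 1 != 0) {
    abort("`n_options` must be a single positive integer.")
  }
  n <- as.integer(n_options)
  if (is.null(tau_slow)) {
    if (length(tau_ratio) != 1 || !is.finite(tau_ratio) || tau_ratio <= 0) {
      abort("`tau_ratio` must be a single positive number.")
    }
    tau_slow <- tau_fast * tau_ratio
  }
  if (length(tau_fast) != 1 || !is.finite(tau_fast) || tau_fast <= 0) {
    abort("`tau_fast` must be a single positive number.")
  }
  if (length(tau_slow) != 1 || !is.finite(tau_slow) || tau_slow <= 0) {
    abort("`tau_slow` must be a single positive number.")
  }
  as_weight <- function(w, name) {
    if (length(w) == 1) w <- matrix(as.double(w), n, n)
    w <- as.matrix(w)
    if (!all(dim(w) == c(n, n))) {
      abort(sprintf("`%s` must be a %d x %d matrix or a scalar.", name, n, n))
    }
    if (any(!is.finite(w)) || any(w < 0)) {
      abort(sprintf("`%s` entries must be finite and nonnegative.", name))
    }
    storage.mode(w) <- "double"
    w
  }
  structure(
    list(
      n_options = n,
      tau_fast = as.double(tau_fast),
      tau_slow = as.double(tau_slow),
      omega = as_weight(omega, "omega"),
      alpha = as_weight(alpha, "alpha"),
      beta = as_weight(beta, "beta")
    ),
    class = "norm_params"
  )
}

#' @export
print.norm_params <- function(x, ...) {
  cat(sprintf(
    "<norm_params> %d options; tau_fast = %g ms, tau_slow = %g ms (ratio %g)\n",
    x$n_options, x$tau_fast, x$tau_slow, x$tau_slow / x$tau_fast
  ))
  all_const <- function(w) length(unique(as.vector(w))) == 1
  if (all_const(x$omega) && all_const(x$alpha) && all_const(x$beta)) {
    cat(sprintf(
      "  weights: omega = %g, alpha = %g, beta = %g (uniform)\n",
      x$omega[1], x$alpha[1], x$beta[1]
    ))
  } else {
    cat("  weights: non-uniform matrices (see $omega, $alpha, $beta)\n")
  }
  invisible(x)
}

#' Network state of the cascaded circuit
#'
#' Instantaneous activity of all four unit populations: fast excitatory
#' (`r_fast`), fast inhibitory (`g_fast`), slow excitatory (`r_slow`),
#' and slow inhibitory (`g_slow`), each a length-`N` vector in firing-rate
#' units. The all-zero state is the baseline (and the fixed point under
#' zero value input).
#'
#' @param n_options Number of options; used when vectors are omitted.
#' @param r_fast,g_fast,r_slow,g_slow Length-`N` nonnegative vectors.
#' @return An object of class `norm_state`.
#' @examples
#' norm_state(2)                       # baseline (all zero)
#' norm_state(r_fast = c(1, 2), g_fast = c(3, 3),
#'            r_slow = c(0, 0), g_slow = c(0, 0))
#' @export
norm_state <- function(n_options = NULL, r_fast = NULL, g_fast = NULL,
                       r_slow = NULL, g_slow = NULL) {
  if (is.null(r_fast)) {
    if (is.null(n_options)) {
      abort("Provide either `n_options` or the four state vectors.")
    }
    n <- as.integer(n_options)
    r_fast <- g_fast <- r_slow <- g_slow <- rep(0, n)
  }
  n <- length(r_fast)
  for (nm in c("r_fast", "g_fast", "r_slow", "g_slow")) {
    v <- get(nm)
    if (length(v) != n || any(!is.finite(v))) {
      abort(sprintf("`%s` must be a finite vector of length %d.", nm, n))
    }
  }
  structure(
    list(
      r_fast = as.double(r_fast), g_fast = as.double(g_fast),
      r_slow = as.double(r_slow), g_slow = as.double(g_slow)
    ),
    class = "norm_state"
  )
}

#' @export
print.norm_state <- function(x, ...) {
  cat("<norm_state>\n")
  m <- rbind(r_fast = x$r_fast, g_fast = x$g_fast,
             r_slow = x$r_slow, g_slow = x$g_slow)
  colnames(m) <- paste0("option_", seq_len(ncol(m)))
  print(m)
  invisible(x)
}

# state <-> flat vector (r_fast, g_fast, r_slow, g_slow)
state_to_vector <- function(state) {
  c(state$r_fast, state$g_fast, state$r_slow, state$g_slow)
}

vector_to_state <- function(v, n) {
  norm_state(
    r_fast = v[seq_len(n)],
    g_fast = v[n + seq_len(n)],
    r_slow = v[2 * n + seq_len(n)],
    g_slow = v[3 * n + seq_len(n)]
  )
}

check_values <- function(values, params) {
  if (length(values) != params$n_options) {
    abort(sprintf(
      "`values` must have length %d (one entry per option).",
      params$n_options
    ))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and nonnegative.")
  }
  as.double(values)
}
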