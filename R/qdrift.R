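# Stochastic (qDRIFT) emulation of real-time evolution.  Hamiltonian terms
# are drawn i.i.d. with probability p_j = |h_j| / lambda and each draw
# appends the fixed-angle exponential exp(-i lambda t sgn(h_j) sigma_j / N)
# to the product, with segment count N = ceil(2 lambda^2 t^2 / eps).  The
# full exponent convention (no extra 1/2) is fixed here and checked against
# a dense matrix-exponential oracle in the tests.

#' qDRIFT segment count
#'
#' `N = ceil(2 lambda^2 t^2 / eps)` segments reach diamond-norm precision
#' `eps` on the evolution channel; the count depends on the Hamiltonian only
#' through its l1 norm.
#'
#' @param lambda_norm l1 norm of the Hamiltonian
#' @param t evolution time (non-negative)
#' @param epsilon target channel precision (> 0)
#' @return integer segment count
#' @examples
#' qdrift_sample_count(2, 3, 0.1)  # 720
#' @export
qdrift_sample_count <- function(lambda_norm, t, epsilon) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (t < 0) stop("t must be non-negative")
  as.integer(ceiling(2 * lambda_norm^2 * t^2 / epsilon))
}

#' Sample one qDRIFT realization of the evolution operator
#'
#' @param H a `qsci_pauli` Hamiltonian (identity excluded, as constructed by
#'   [jordan_wigner()])
#' @param t evolution time
#' @param epsilon target channel precision
#' @param seed RNG seed (the sequence is a pure function of the inputs + seed)
#' @return object of class `qsci_qdrift_seq`: term indices, per-segment
#'   rotation angles `lambda * t * sgn(h_j) / N`, and bookkeeping fields
#' @export
sample_qdrift_sequence <- function(H, t, epsilon, seed) {
  stopifnot(inherits(H, "qsci_pauli"))
  if (length(H$coeff) == 0L) stop("cannot sample from an empty Hamiltonian")
  lambda <- H$lambda
  N <- qdrift_sample_count(lambda, t, epsilon)
  idx <- if (N == 0L) integer(0) else with_seed(seed, {
    sample.int(length(H$coeff), N, replace = TRUE, prob = abs(H$coeff) / lambda)
  })
  structure(
    list(idx = idx,
         angles = if (N == 0L) numeric(0) else lambda * t * sign(H$coeff[idx]) / N,
         x = H$x[idx], z = H$z[idx],
         n_qubits = H$n_qubits, t = t, N = N, epsilon = epsilon,
         lambda = lambda, seed = seed),
    class = "qsci_qdrift_seq"
  )
}

#' @export
print.qsci_qdrift_seq <- function(x, ...) {
  cat(sprintf("<qsci_qdrift_seq> %d segments, t = %.4f, lambda = %.4f, seed = %d\n",
              x$N, x$t, x$lambda, x$seed))
  invisible(x)
}

# P v for canonical Pauli (x, z): P|b> = i^nY (-1)^(popcount(z & b)) |b xor x>
.apply_pauli <- function(v, x, z, b) {
  nY <- popcount(bitwAnd(x, z))
  phase <- (1i)^nY * (1 - 2 * (popcount(bitwAnd(z, b)) %% 2L))
  out <- complex(length(v))
  out[bitwXor(b, x) + 1L] <- phase * v
  out
}

#' Propagate a reference determinant through a qDRIFT sequence
#'
#' Starts from the computational-basis state of `ref` and applies each Pauli
#' rotation `exp(-i theta sigma) = cos(theta) I - i sin(theta) sigma` in
#' order, realized by bit-mask index arithmetic (never by building 2^n
#' matrices).
#'
#' @param ref reference determinant (masks over `n_qubits / 2` orbitals)
#' @param seq a [sample_qdrift_sequence()] result
#' @param qubit_cap refuse statevectors beyond this many qubits (default 16)
#' @return complex statevector of length `2^n_qubits` (unit norm)
#' @export
propagate_statevector <- function(ref, seq, qubit_cap = 16L) {
  n <- seq$n_qubits
  if (n > qubit_cap) {
    stop(sprintf("statevector on %d qubits exceeds the cap of %d", n, qubit_cap))
  }
  M <- n %/% 2L
  ref <- as_det_matrix(ref)
  dim <- 2^n
  b <- 0:(dim - 1L)
  v <- complex(dim)
  v[ref[1L, 1L] + ref[1L, 2L] * 2^M + 1L] <- 1 + 0i
  for (j in seq_along(seq$idx)) {
    theta <- seq$angles[j]
    v <- cos(theta) * v - 1i * sin(theta) * .apply_pauli(v, seq$x[j], seq$z[j], b)
  }
  v
}

#' Sample computational-basis measurements from a statevector
#'
#' @param state normalized complex statevector
#' @param shots number of measurement shots
#' @param seed RNG seed
#' @param provenance optional provenance list stored on the result
#' @return a [measurement_set()]
#' @export
sample_measurements <- function(state, shots, seed, provenance = list()) {
  p <- Mod(state)^2
  if (abs(sum(p) - 1) > 1e-8) stop("state is not normalized")
  n <- as.integer(round(log2(length(state))))
  draws <- with_seed(seed, {
    sample.int(length(state), shots, replace = TRUE, prob = p)
  })
  tab <- table(draws)
  counts <- as.integer(tab)
  names(counts) <- int_to_bitstring(as.numeric(names(tab)) - 1, n)
  measurement_set(counts, n, c(provenance, list(shot_seed = seed)))
}

# deterministic sub-seed stream (Lehmer step, stays below 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i) %% 2147483647)
}

#' Run the full time-evolution measurement grid
#'
#' For each time step `k = 1..K` at `t = k tau`, draws `n_instances`
#' independent qDRIFT realizations, propagates the reference through each,
#' extracts `shots` measurement shots per instance, and aggregates the shots
#' of a step into one measurement set.  The whole output is a pure function
#' of the inputs and `seed`.
#'
#' @param H a `qsci_pauli` Hamiltonian
#' @param ref reference determinant
#' @param tau time increment
#' @param K number of time steps
#' @param n_instances qDRIFT realizations per step
#' @param shots measurement shots per realization
#' @param epsilon qDRIFT target precision
#' @param seed RNG seed
#' @param qubit_cap statevector qubit cap
#' @return list of `K` [measurement_set()]s (one per time step)
#' @export
run_time_grid <- function(H, ref, tau, K, n_instances, shots, epsilon, seed,
                          qubit_cap = 16L) {
  if (K < 0L) stop("K must be non-negative")
  out <- vector("list", K)
  ctr <- 0L
  for (k in seq_len(K)) {
    t <- k * tau
    agg <- new.env(parent = emptyenv())
    for (inst in seq_len(n_instances)) {
      seq_k <- sample_qdrift_sequence(H, t, epsilon, derive_seed(seed, ctr))
      v <- propagate_statevector(ref, seq_k, qubit_cap = qubit_cap)
      ms <- sample_measurements(v, shots, derive_seed(seed, ctr + 1L))
      ctr <- ctr + 2L
      for (bs in names(ms$counts)) {
        prev <- if (is.null(agg[[bs]])) 0L else agg[[bs]]
        agg[[bs]] <- prev + ms$counts[[bs]]
      }
    }
    keys <- sort(ls(agg))
    counts <- vapply(keys, function(k2) agg[[k2]], integer(1))
    names(counts) <- keys
    out[[k]] <- measurement_set(
      counts, H$n_qubits,
      list(step = k, t = t, tau = tau, instances = n_instances,
           shots_per_instance = shots, epsilon = epsilon, seed = seed)
    )
  }
  out
}

#' Export a qDRIFT sequence as a generic gate list
#'
#' Writes a JSON array of `{"pauli": word, "angle": theta}` records for
#' consumption by circuit frameworks.
#'
#' @param seq a [sample_qdrift_sequence()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
export_sequence_json <- function(seq, path) {
  n <- seq$n_qubits
  words <- vapply(seq_along(seq$idx), function(j) {
    xb <- bitwAnd(bitwShiftR(seq$x[j], 0:(n - 1L)), 1L)
    zb <- bitwAnd(bitwShiftR(seq$z[j], 0:(n - 1L)), 1L)
    paste(c("I", "X", "Z", "Y")[1L + xb + 2L * zb], collapse = "")
  }, character(1))
  jsonlite::write_json(
    lapply(seq_along(words), function(j) {
      list(pauli = words[j], angle = seq$angles[j])
    }),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
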