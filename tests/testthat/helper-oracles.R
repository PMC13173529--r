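# Independent brute-force oracles used across the suite.  Everything here is
# built from first principles (explicit ladder-operator matrices in the full
# occupation-number basis, Kronecker-product Pauli matrices, dense matrix
# exponentials) and never calls the package code paths under test.

# Fock-space convention: basis state index b has bit i = occupation of spin
# orbital i; alpha_p is spin orbital p, beta_p is spin orbital M + p
# (blocked ordering), so b = alpha_mask + beta_mask * 2^M.

# dense annihilation operator for spin orbital P on n spin orbitals
oracle_annihilation <- function(P, n) {
  dim <- 2^n
  A <- matrix(0, dim, dim)
  mask <- bitwShiftL(1L, P)
  below <- mask - 1L
  for (b in 0:(dim - 1L)) {
    if (bitwAnd(b, mask) != 0L) {
      sgn <- (-1)^sum(bitwAnd(bitwShiftR(bitwAnd(b, below), 0:max(0L, P - 1L)), 1L))
      if (P == 0L) sgn <- 1
      A[b - mask + 1L, b + 1L] <- sgn
    }
  }
  A
}

# full second-quantized Hamiltonian on the 2^(2M) Fock space, chemists'
# notation: H = E_core + sum h[p,q] a+_{p s} a_{q s}
#                + 1/2 sum (pq|rs) a+_{p s} a+_{r t} a_{s t} a_{q s}
oracle_fock_hamiltonian <- function(ints) {
  M <- ints$M
  n <- 2L * M
  dim <- 2^n
  ann <- lapply(0:(n - 1L), function(P) oracle_annihilation(P, n))
  cre <- lapply(ann, t)
  H <- diag(ints$E_core, dim)
  for (sp in 0:1) {
    off <- sp * M
    for (p in 0:(M - 1L)) for (q in 0:(M - 1L)) {
      if (ints$h[p + 1L, q + 1L] != 0) {
        H <- H + ints$h[p + 1L, q + 1L] * (cre[[p + off + 1L]] %*% ann[[q + off + 1L]])
      }
    }
  }
  for (sp in 0:1) for (tp in 0:1) {
    offs <- sp * M; offt <- tp * M
    for (p in 0:(M - 1L)) for (q in 0:(M - 1L)) {
      for (r in 0:(M - 1L)) for (s in 0:(M - 1L)) {
        gv <- ints$g[p + 1L, q + 1L, r + 1L, s + 1L]
        if (gv != 0) {
          H <- H + 0.5 * gv * (cre[[p + offs + 1L]] %*% cre[[r + offt + 1L]] %*%
                               ann[[s + offt + 1L]] %*% ann[[q + offs + 1L]])
        }
      }
    }
  }
  H
}

# Fock-space index of each determinant row (alpha + beta * 2^M)
oracle_fock_index <- function(dets, M) {
  dets <- as_det_matrix(dets)
  dets[, 1L] + dets[, 2L] * 2^M
}

# dense sector Hamiltonian in the order of the supplied determinant list
oracle_sector_hamiltonian <- function(ints, dets) {
  Hf <- oracle_fock_hamiltonian(ints)
  idx <- oracle_fock_index(dets, ints$M) + 1
  Hf[idx, idx, drop = FALSE]
}

# random symmetric integral set (decaying two-electron magnitudes),
# independent of the package fixture generator
oracle_random_ints <- function(M, seed) {
  set.seed(seed)
  h <- matrix(rnorm(M * M, sd = 0.5), M)
  h <- (h + t(h)) / 2
  diag(h) <- sort(rnorm(M, mean = -1))
  g <- array(rnorm(M^4, sd = 0.3), rep(M, 4L))
  g <- (g + aperm(g, c(2L, 1L, 3L, 4L))) / 2
  g <- (g + aperm(g, c(1L, 2L, 4L, 3L))) / 2
  g <- (g + aperm(g, c(3L, 4L, 1L, 2L))) / 2
  molecular_integrals(rnorm(1), h, g)
}

# dense matrix of a canonical Pauli word (letters over I, X, Y, Z;
# character position i + 1 acts on qubit i) via Kronecker products.
# Qubit i corresponds to Fock bit i, so the single-qubit factor of qubit 0
# must be the *innermost* Kronecker factor.
oracle_pauli_matrix <- function(letters_string) {
  mats <- list(
    I = diag(2),
    X = matrix(c(0, 1, 1, 0), 2),
    Y = matrix(c(0, 1i, -1i, 0), 2),
    Z = matrix(c(1, 0, 0, -1), 2)
  )
  letters <- strsplit(letters_string, "")[[1]]
  out <- matrix(1 + 0i, 1, 1)
  for (l in letters) out <- kronecker(mats[[l]], out)
  out
}

# dense matrix of a Pauli-sum Hamiltonian (package object, but assembled via
# the independent Kronecker route)
oracle_pauli_sum_matrix <- function(H) {
  strs <- pauli_strings(H)
  dim <- 2^H$n_qubits
  out <- diag(H$e_offset + 0i, dim)
  for (j in seq_along(strs)) {
    out <- out + H$coeff[j] * oracle_pauli_matrix(strs[j])
  }
  out
}

# exact evolved state exp(-i H t) |psi0> from a dense Hermitian matrix
oracle_evolve <- function(Hmat, psi0, t) {
  eig <- eigen((Hmat + Conj(t(Hmat))) / 2, symmetric = TRUE)
  V <- eig$vectors
  V %*% (exp(-1i * eig$values * t) * (Conj(t(V)) %*% psi0))
}

# trace distance between two density matrices
oracle_trace_distance <- function(rho, sigma) {
  d <- rho - sigma
  d <- (d + Conj(t(d))) / 2
  sum(abs(eigen(d, symmetric = TRUE, only.values = TRUE)$values)) / 2
}
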