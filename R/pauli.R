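# Pauli-sum Hamiltonians on 2M qubits.  A term is stored in symplectic form
# as a pair of bit masks (x, z) over the qubits: x-bit set means X or Y at
# that position, z-bit set means Z or Y; both set means Y.  Identity terms
# are kept out of the term list -- they contribute only a global energy
# offset (tracked in `e_offset`) and would otherwise inflate the l1 norm
# that controls qDRIFT circuit depth.

#' Construct a Pauli-sum Hamiltonian from letter strings
#'
#' @param strings character vector of Pauli words over `I`, `X`, `Y`, `Z`;
#'   character `i + 1` acts on qubit `i` (leftmost character = qubit 0)
#' @param coeffs real coefficients, one per string
#' @param e_offset identity (energy offset) coefficient
#' @return object of class `qsci_pauli` with fields `n_qubits`, `x`, `z`,
#'   `coeff`, `e_offset` and `lambda` (the l1 norm of `coeff`)
#' @examples
#' H <- pauli_hamiltonian(c("ZI", "IX"), c(0.5, -0.25))
#' l1_norm(H)  # 0.75
#' @export
pauli_hamiltonian <- function(strings, coeffs, e_offset = 0) {
  if (length(strings) != length(coeffs)) stop("strings and coeffs differ in length")
  n <- if (length(strings)) nchar(strings[1L]) else 0L
  if (length(strings) && any(nchar(strings) != n)) stop("Pauli words differ in length")
  if (anyDuplicated(strings)) stop("duplicate Pauli strings")
  x <- integer(length(strings))
  z <- integer(length(strings))
  for (j in seq_along(strings)) {
    letters <- strsplit(strings[j], "")[[1L]]
    if (!all(letters %in% c("I", "X", "Y", "Z"))) {
      stop("invalid Pauli letter in ", strings[j])
    }
    x[j] <- mask_from_bits(which(letters %in% c("X", "Y")) - 1L)
    z[j] <- mask_from_bits(which(letters %in% c("Z", "Y")) - 1L)
  }
  keep <- !(x == 0L & z == 0L)
  new_pauli(n, x[keep], z[keep], coeffs[keep],
            e_offset + sum(coeffs[!keep]))
}

new_pauli <- function(n_qubits, x, z, coeff, e_offset) {
  ord <- order(x * 2^n_qubits + z)
  structure(
    list(n_qubits = as.integer(n_qubits), x = x[ord], z = z[ord],
         coeff = coeff[ord], e_offset = e_offset, lambda = sum(abs(coeff))),
    class = "qsci_pauli"
  )
}

#' l1 norm of a Pauli Hamiltonian
#'
#' The sum of absolute coefficients over the non-identity terms; this is the
#' quantity that fixes the qDRIFT segment count `N = ceil(2 lambda^2 t^2 / eps)`.
#'
#' @param H a `qsci_pauli` object
#' @return non-negative scalar
#' @export
l1_norm <- function(H) {
  stopifnot(inherits(H, "qsci_pauli"))
  H$lambda
}

#' Pauli words of a Hamiltonian as letter strings
#'
#' @param H a `qsci_pauli` object
#' @return character vector, one word per term (leftmost letter = qubit 0)
#' @export
pauli_strings <- function(H) {
  n <- H$n_qubits
  vapply(seq_along(H$coeff), function(j) {
    xb <- bitwAnd(bitwShiftR(H$x[j], 0:(n - 1L)), 1L)
    zb <- bitwAnd(bitwShiftR(H$z[j], 0:(n - 1L)), 1L)
    paste(c("I", "X", "Z", "Y")[1L + xb + 2L * zb], collapse = "")
  }, character(1))
}

#' @export
print.qsci_pauli <- function(x, ...) {
  cat(sprintf("<qsci_pauli> %d terms on %d qubits, lambda = %.6f, offset = %.6f\n",
              length(x$coeff), x$n_qubits, x$lambda, x$e_offset))
  invisible(x)
}

# ---- internal XZ-term algebra -------------------------------------------
# A term c * X^x Z^z; product rule
# (X^x1 Z^z1)(X^x2 Z^z2) = (-1)^(z1 . x2) X^(x1 xor x2) Z^(z1 xor z2).

.xz_mult <- function(A, B) {
  nA <- length(A$c); nB <- length(B$c)
  ia <- rep(seq_len(nA), each = nB)
  ib <- rep.int(seq_len(nB), nA)
  sgn <- 1 - 2 * (popcount(bitwAnd(A$z[ia], B$x[ib])) %% 2L)
  list(c = A$c[ia] * B$c[ib] * sgn,
       x = bitwXor(A$x[ia], B$x[ib]),
       z = bitwXor(A$z[ia], B$z[ib]))
}

# Jordan-Wigner ladder operator on spin orbital P (0-based):
# a_P   = Z_{<P} (X_P - X_P Z_P) / 2
# a+_P  = Z_{<P} (X_P + X_P Z_P) / 2
.jw_ladder <- function(P, dagger) {
  zlow <- if (P == 0L) 0L else bitwShiftL(1L, P) - 1L
  xp <- bitwShiftL(1L, P)
  s <- if (dagger) 0.5 else -0.5
  list(c = c(0.5 + 0i, s + 0i), x = c(xp, xp), z = c(zlow, bitwXor(zlow, xp)))
}

#' Jordan-Wigner qubit Hamiltonian from molecular integrals
#'
#' Maps the second-quantized Hamiltonian onto 2M qubits under the blocked
#' spin-orbital ordering (qubit `i < M` is alpha orbital `i`, qubit `M + i`
#' is beta orbital `i`).  Under this mapping the computational-basis bit of
#' qubit `i` equals the occupation of spin orbital `i`, which is what lets
#' measured bitstrings be read directly as orbital occupancies.
#'
#' @param basis a [spin_basis()]
#' @param ints a [molecular_integrals()]
#' @param drop_tol coefficients with `|h_j| <= drop_tol` are removed
#'   (default `1e-10`: below integral-symmetry noise, above float epsilon)
#' @return a `qsci_pauli` Hamiltonian; the identity component (including
#'   `E_core`) is carried in `e_offset`
#' @export
jordan_wigner <- function(basis, ints, drop_tol = 1e-10) {
  M <- ints$M
  if (M != basis$M) stop("basis and integrals disagree on orbital count")
  n <- 2L * M

  cs <- list(); xs <- list(); zs <- list(); k <- 0L
  push <- function(t) {
    k <<- k + 1L
    cs[[k]] <<- t$c; xs[[k]] <<- t$x; zs[[k]] <<- t$z
  }

  # precompute ladder terms for all spin orbitals
  ann <- lapply(0:(n - 1L), .jw_ladder, dagger = FALSE)
  cre <- lapply(0:(n - 1L), .jw_ladder, dagger = TRUE)

  for (sp in 0:1) {
    off <- sp * M
    for (p in 1:M) for (q in 1:M) {
      hv <- ints$h[p, q]
      if (hv == 0) next
      t <- .xz_mult(cre[[p + off]], ann[[q + off]])
      t$c <- t$c * hv
      push(t)
    }
  }
  for (sp in 0:1) for (tp in 0:1) {
    offs <- sp * M; offt <- tp * M
    for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
      gv <- ints$g[p, q, r, s]
      if (gv == 0) next
      t <- .xz_mult(.xz_mult(cre[[p + offs]], cre[[r + offt]]),
                    .xz_mult(ann[[s + offt]], ann[[q + offs]]))
      t$c <- t$c * (0.5 * gv)
      push(t)
    }
  }

  cc <- unlist(cs); xx <- unlist(xs); zz <- unlist(zs)
  key <- xx * 2^n + zz
  grp <- match(key, unique(key))
  agg <- rowsum(cbind(Re(cc), Im(cc)), group = grp, reorder = FALSE)
  ukey <- unique(key)
  ux <- floor(ukey / 2^n)
  uz <- ukey - ux * 2^n

  # convert X^x Z^z to canonical Pauli words: each qubit with both bits set
  # contributes XZ = -iY, so c * X^x Z^z = c * (-i)^nY * (canonical word).
  cxz <- complex(real = agg[, 1L], imaginary = agg[, 2L])
  nY <- popcount(bitwAnd(as.integer(ux), as.integer(uz)))
  coef <- cxz * (-1i)^nY
  if (max(abs(Im(coef))) > 1e-9) {
    stop("Jordan-Wigner produced non-real Pauli coefficients; integrals not Hermitian?")
  }
  coef <- Re(coef)

  ident <- ux == 0 & uz == 0
  e_offset <- ints$E_core + sum(coef[ident])
  keep <- !ident & abs(coef) > drop_tol
  new_pauli(n, as.integer(ux[keep]), as.integer(uz[keep]), coef[keep], e_offset)
}
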