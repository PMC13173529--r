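# Slater determinants as pairs of occupation bit masks (alpha, beta), with a
# blocked spin-orbital ordering: spin orbital i in [0, M) is alpha_i and
# spin orbital M + i is beta_i.  Determinant lists are two-column integer
# matrices with columns "alpha" and "beta".

#' Spin-orbital basis descriptor
#'
#' Describes the one-particle basis underlying all determinant operations:
#' `M` spatial orbitals holding `n_alpha` spin-up and `n_beta` spin-down
#' electrons.  The spin-orbital ordering is blocked (all alpha orbitals first,
#' then all beta orbitals), so per-spin occupancy vectors stay contiguous in
#' qubit space.
#'
#' @param M number of spatial orbitals (1 to 30)
#' @param n_alpha,n_beta electron counts per spin channel, each in `[0, M]`
#' @return an object of class `qsci_basis`
#' @examples
#' b <- spin_basis(4, 2, 2)
#' space_dimension(b$M, b$n_alpha, b$n_beta)
#' @export
spin_basis <- function(M, n_alpha, n_beta) {
  M <- as.integer(M)
  n_alpha <- as.integer(n_alpha)
  n_beta <- as.integer(n_beta)
  if (M < 1L || M > 30L) stop("M must be between 1 and 30")
  if (n_alpha < 0L || n_alpha > M) stop("n_alpha must lie in [0, M]")
  if (n_beta < 0L || n_beta > M) stop("n_beta must lie in [0, M]")
  structure(
    list(M = M, n_alpha = n_alpha, n_beta = n_beta, ordering = "blocked"),
    class = "qsci_basis"
  )
}

#' @export
print.qsci_basis <- function(x, ...) {
  cat(sprintf(
    "<qsci_basis> M = %d spatial orbitals, N_alpha = %d, N_beta = %d (%s ordering)\n",
    x$M, x$n_alpha, x$n_beta, x$ordering
  ))
  invisible(x)
}

#' Construct a determinant from occupation masks
#'
#' @param alpha,beta integer occupation masks (bit i = spatial orbital i)
#' @return named integer vector `c(alpha =, beta =)`
#' @export
determinant_masks <- function(alpha, beta) {
  c(alpha = as.integer(alpha), beta = as.integer(beta))
}

#' Assemble a determinant list
#'
#' @param alpha,beta integer vectors of occupation masks
#' @return a two-column integer matrix with columns `alpha`, `beta`
#' @export
det_list <- function(alpha, beta) {
  cbind(alpha = as.integer(alpha), beta = as.integer(beta))
}

# normalise a single determinant or a matrix of determinants to matrix form
as_det_matrix <- function(d) {
  if (is.matrix(d)) {
    storage.mode(d) <- "integer"
    colnames(d) <- c("alpha", "beta")
    return(d)
  }
  matrix(as.integer(d), ncol = 2L, dimnames = list(NULL, c("alpha", "beta")))
}

# unique double key per determinant (exact for M <= 26)
det_keys <- function(d, M) {
  d <- as_det_matrix(d)
  d[, 1L] * 2^M + d[, 2L]
}

det_sector_valid <- function(d, basis) {
  d <- as_det_matrix(d)
  popcount(d[, 1L]) == basis$n_alpha & popcount(d[, 2L]) == basis$n_beta
}

#' Hartree-Fock (aufbau) reference determinant
#'
#' Occupies the lowest-index `n_alpha` alpha orbitals and `n_beta` beta
#' orbitals under the orbital ordering of the integral file.
#'
#' @param basis a [spin_basis()]
#' @return determinant as a named integer vector
#' @examples
#' hartree_fock_determinant(spin_basis(3, 2, 1))
#' @export
hartree_fock_determinant <- function(basis) {
  stopifnot(inherits(basis, "qsci_basis"))
  fill <- function(n) if (n == 0L) 0L else bitwShiftL(1L, n) - 1L
  determinant_masks(fill(basis$n_alpha), fill(basis$n_beta))
}

#' Excitation degree between two determinants
#'
#' Half the Hamming distance between the concatenated alpha/beta occupation
#' masks, i.e. the number of electron moves relating the two determinants.
#'
#' @param d1,d2 determinants over a common basis
#' @return non-negative integer
#' @export
excitation_degree <- function(d1, d2) {
  d1 <- as_det_matrix(d1)
  d2 <- as_det_matrix(d2)
  if (sum(popcount(d1[, 1L])) + sum(popcount(d1[, 2L])) !=
      sum(popcount(d2[, 1L])) + sum(popcount(d2[, 2L]))) {
    stop("determinants carry different electron counts (basis mismatch)")
  }
  as.integer((popcount(bitwXor(d1[, 1L], d2[, 1L])) +
              popcount(bitwXor(d1[, 2L], d2[, 2L]))) / 2L)
}

#' Dimension of the full CI space
#'
#' The number of valid electronic configurations of `n_alpha` spin-up and
#' `n_beta` spin-down electrons in `M` spatial orbitals,
#' `choose(M, n_alpha) * choose(M, n_beta)`.  Exact as long as the product
#' stays below 2^53 (binary double precision).
#'
#' @param M spatial orbital count
#' @param n_alpha,n_beta electron counts
#' @return exact count as a double
#' @examples
#' space_dimension(21, 9, 9)  # 86,394,844,900
#' @export
space_dimension <- function(M, n_alpha, n_beta) {
  if (M < 0 || n_alpha < 0 || n_beta < 0) stop("arguments must be non-negative")
  if (n_alpha > M || n_beta > M) stop("electron count exceeds orbital count")
  choose(M, n_alpha) * choose(M, n_beta)
}

#' Number of distinct single excitations
#'
#' `S = n_alpha (M - n_alpha) + n_beta (M - n_beta)`: each occupied orbital of
#' a spin channel can be moved to each empty orbital of the same channel.
#'
#' @param basis a [spin_basis()]
#' @return integer
#' @export
singles_count <- function(basis) {
  with(basis, as.integer(n_alpha * (M - n_alpha) + n_beta * (M - n_beta)))
}

# all masks with n bits set among M positions, as an integer vector
all_masks <- function(M, n) {
  if (n == 0L) return(0L)
  if (n == M) return(bitwShiftL(1L, M) - 1L)
  combs <- utils::combn(M, n) - 1L
  as.integer(colSums(matrix(bitwShiftL(1L, combs), nrow = n)))
}

#' Enumerate the full CI determinant space
#'
#' @param basis a [spin_basis()]
#' @return determinant matrix of `space_dimension()` rows
#' @export
fci_space <- function(basis) {
  a <- all_masks(basis$M, basis$n_alpha)
  b <- all_masks(basis$M, basis$n_beta)
  det_list(rep(a, each = length(b)), rep(b, times = length(a)))
}

#' Enumerate a complete-active-space determinant list
#'
#' Freezes the core below the active window, keeps virtuals above it empty,
#' and distributes the active electrons over the `M_act` window orbitals in
#' every way.  The window is placed directly above the closed-shell core,
#' i.e. symmetrically around the Fermi level (the usual naive HOMO-LUMO
#' choice).
#'
#' @param basis a [spin_basis()]
#' @param M_act active orbital count
#' @param N_act active electron count (must leave a closed-shell core)
#' @return determinant matrix
#' @examples
#' nrow(cas_space(spin_basis(4, 2, 2), 2, 2))  # 4
#' @export
cas_space <- function(basis, M_act, N_act) {
  M_act <- as.integer(M_act)
  N_act <- as.integer(N_act)
  N <- basis$n_alpha + basis$n_beta
  if (M_act < 0L || M_act > basis$M) stop("M_act must lie in [0, M]")
  if (N_act < 0L || N_act > N) stop("N_act must lie in [0, N]")
  n_frozen <- N - N_act
  if (n_frozen %% 2L != 0L) stop("frozen core must be closed-shell (N - N_act even)")
  n_core <- n_frozen %/% 2L
  na_act <- basis$n_alpha - n_core
  nb_act <- basis$n_beta - n_core
  if (na_act < 0L || nb_act < 0L || na_act > M_act || nb_act > M_act) {
    stop("infeasible active electron/orbital split")
  }
  if (n_core + M_act > basis$M) stop("active window exceeds orbital count")
  core <- if (n_core == 0L) 0L else bitwShiftL(1L, n_core) - 1L
  a <- bitwOr(core, bitwShiftL(all_masks(M_act, na_act), n_core))
  b <- bitwOr(core, bitwShiftL(all_masks(M_act, nb_act), n_core))
  det_list(rep(a, each = length(b)), rep(b, times = length(a)))
}

#' All determinants connected by single or double excitations
#'
#' Yields every sector-valid determinant at excitation degree 1 or 2 from
#' `d`, each exactly once.  These are the only candidates with a non-zero
#' Hamiltonian matrix element against `d`, since the molecular Hamiltonian
#' contains one- and two-body terms only.
#'
#' @param d a determinant
#' @param basis a [spin_basis()]
#' @return determinant matrix (possibly zero rows)
#' @export
connected_determinants <- function(d, basis) {
  d <- as_det_matrix(d)
  if (!det_sector_valid(d, basis)) stop("determinant is not sector-valid")
  M <- basis$M
  a <- d[1L, 1L]; b <- d[1L, 2L]
  occ_a <- bits_of(a); vir_a <- setdiff(0:(M - 1L), occ_a)
  occ_b <- bits_of(b); vir_b <- setdiff(0:(M - 1L), occ_b)

  excite <- function(mask, p, q) bitwOr(bitwAnd(mask, bitwNot(bitwShiftL(1L, p))),
                                        bitwShiftL(1L, q))

  singles <- function(mask, occ, vir) {
    if (length(occ) == 0L || length(vir) == 0L) return(integer(0))
    grid <- expand.grid(p = occ, q = vir)
    mapply(function(p, q) excite(mask, p, q), grid$p, grid$q)
  }
  doubles_same <- function(mask, occ, vir) {
    if (length(occ) < 2L || length(vir) < 2L) return(integer(0))
    po <- utils::combn(occ, 2L)
    pv <- utils::combn(vir, 2L)
    out <- integer(ncol(po) * ncol(pv))
    k <- 1L
    for (i in seq_len(ncol(po))) {
      m1 <- bitwAnd(mask, bitwNot(bitwOr(bitwShiftL(1L, po[1L, i]),
                                         bitwShiftL(1L, po[2L, i]))))
      for (j in seq_len(ncol(pv))) {
        out[k] <- bitwOr(m1, bitwOr(bitwShiftL(1L, pv[1L, j]),
                                    bitwShiftL(1L, pv[2L, j])))
        k <- k + 1L
      }
    }
    out
  }

  sa <- singles(a, occ_a, vir_a)
  sb <- singles(b, occ_b, vir_b)
  out_a <- c(sa, doubles_same(a, occ_a, vir_a))
  out_b <- c(sb, doubles_same(b, occ_b, vir_b))

  parts <- list()
  if (length(out_a)) parts$a <- det_list(out_a, rep(b, length(out_a)))
  if (length(out_b)) parts$b <- det_list(rep(a, length(out_b)), out_b)
  if (length(sa) && length(sb)) {
    parts$ab <- det_list(rep(sa, each = length(sb)), rep(sb, times = length(sa)))
  }
  if (length(parts) == 0L) {
    return(det_list(integer(0), integer(0)))
  }
  do.call(rbind, unname(parts))
}
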