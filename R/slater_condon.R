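# Slater-Condon rules: closed-form Hamiltonian matrix elements between
# determinants differing in at most two spin orbitals, including the
# fermionic phase determined by the orbitals common to both determinants.
#
# Phase convention: spin orbitals are ordered by ascending index within the
# blocked (alpha-then-beta) layout, and the sign of moving one electron from
# orbital p to orbital q is (-1)^(number of occupied orbitals strictly
# between p and q).  Double excitations apply the two moves sequentially,
# updating the occupation mask in between.  Because the ordering is blocked,
# an excitation never crosses the opposite spin block, so each phase is read
# off the same-spin mask alone.

# hole/particle of a same-spin single excitation: d1 -> d2
.single_move <- function(m1, m2) {
  x <- bitwXor(m1, m2)
  list(p = bits_of(bitwAnd(x, m1)), q = bits_of(bitwAnd(x, m2)))
}

.single_sign <- function(mask, p, q) {
  if (bits_between(mask, p, q) %% 2L == 0L) 1 else -1
}

# diagonal element <d|H|d>
.sc_diagonal <- function(occ_a, occ_b, ints) {
  h <- ints$h; g <- ints$g
  e <- ints$E_core
  occ <- c(occ_a, occ_b)
  spin <- c(rep(0L, length(occ_a)), rep(1L, length(occ_b)))
  if (length(occ)) {
    e <- e + sum(h[cbind(occ + 1L, occ + 1L)])
    for (i in seq_along(occ)) {
      for (j in seq_along(occ)) {
        e <- e + 0.5 * g[occ[i] + 1L, occ[i] + 1L, occ[j] + 1L, occ[j] + 1L]
        if (spin[i] == spin[j]) {
          e <- e - 0.5 * g[occ[i] + 1L, occ[j] + 1L, occ[j] + 1L, occ[i] + 1L]
        }
      }
    }
  }
  e
}

# single excitation p -> q in spin channel `sp`, with the other channel's
# occupation `occ_other` and same-channel common occupation `occ_same`
.sc_single <- function(p, q, occ_same, occ_other, ints) {
  h <- ints$h; g <- ints$g
  val <- h[p + 1L, q + 1L]
  for (i in occ_same) {
    val <- val + g[p + 1L, q + 1L, i + 1L, i + 1L] - g[p + 1L, i + 1L, i + 1L, q + 1L]
  }
  for (i in occ_other) {
    val <- val + g[p + 1L, q + 1L, i + 1L, i + 1L]
  }
  val
}

#' Hamiltonian matrix element between two determinants
#'
#' Evaluates `<d1|H|d2>` via the Slater-Condon rules, including the fermionic
#' sign.  Returns 0 when the determinants differ by more than a double
#' excitation; the diagonal includes `E_core`.
#'
#' @param d1,d2 determinants over a common basis
#' @param ints a [molecular_integrals()] object
#' @return scalar energy (Hartree)
#' @export
slater_condon_element <- function(d1, d2, ints) {
  d1 <- as_det_matrix(d1); d2 <- as_det_matrix(d2)
  a1 <- d1[1L, 1L]; b1 <- d1[1L, 2L]
  a2 <- d2[1L, 1L]; b2 <- d2[1L, 2L]
  M <- ints$M
  if (max(a1, b1, a2, b2) >= bitwShiftL(1L, M)) {
    stop("determinant references an orbital outside the integral set")
  }
  xa <- bitwXor(a1, a2); xb <- bitwXor(b1, b2)
  da <- popcount(xa) %/% 2L
  db <- popcount(xb) %/% 2L
  deg <- da + db
  if (popcount(xa) %% 2L != 0L || popcount(xb) %% 2L != 0L) return(0)
  if (deg > 2L) return(0)

  if (deg == 0L) {
    return(.sc_diagonal(bits_of(a1), bits_of(b1), ints))
  }

  if (deg == 1L) {
    if (da == 1L) {
      mv <- .single_move(a1, a2)
      common <- bits_of(bitwAnd(a1, a2))
      val <- .sc_single(mv$p, mv$q, common, bits_of(b1), ints)
      return(.single_sign(a1, mv$p, mv$q) * val)
    } else {
      mv <- .single_move(b1, b2)
      common <- bits_of(bitwAnd(b1, b2))
      val <- .sc_single(mv$p, mv$q, common, bits_of(a1), ints)
      return(.single_sign(b1, mv$p, mv$q) * val)
    }
  }

  g <- ints$g
  if (da == 1L && db == 1L) {
    # opposite-spin double: p->r in alpha, q->s in beta
    mva <- .single_move(a1, a2)
    mvb <- .single_move(b1, b2)
    sgn <- .single_sign(a1, mva$p, mva$q) * .single_sign(b1, mvb$p, mvb$q)
    return(sgn * g[mva$p + 1L, mva$q + 1L, mvb$p + 1L, mvb$q + 1L])
  }

  # same-spin double
  m1 <- if (da == 2L) a1 else b1
  m2 <- if (da == 2L) a2 else b2
  x <- bitwXor(m1, m2)
  holes <- bits_of(bitwAnd(x, m1))      # ascending p < q
  parts <- bits_of(bitwAnd(x, m2))      # ascending r < s
  p <- holes[1L]; q <- holes[2L]
  r <- parts[1L]; s <- parts[2L]
  # apply p -> r first, then q -> s on the updated mask
  s1 <- .single_sign(m1, p, r)
  mid <- bitwOr(bitwAnd(m1, bitwNot(bitwShiftL(1L, p))), bitwShiftL(1L, r))
  s2 <- .single_sign(mid, q, s)
  sgn <- s1 * s2
  sgn * (g[p + 1L, r + 1L, q + 1L, s + 1L] - g[p + 1L, s + 1L, q + 1L, r + 1L])
}
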