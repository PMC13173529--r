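# Subspace CI engine: interaction-matrix construction, diagonalization, and
# the Heatbath CI benchmark with the delta-halving schedule.

#' Subspace wavefunction
#'
#' @param dets determinant matrix (K rows)
#' @param coeffs real coefficient vector of length K (unit 2-norm)
#' @param energy eigenvalue (Rayleigh quotient of `coeffs`)
#' @param root_index which root (0 = ground state)
#' @return object of class `qsci_wavefunction`
#' @export
subspace_wavefunction <- function(dets, coeffs, energy, root_index = 0L) {
  dets <- as_det_matrix(dets)
  if (nrow(dets) != length(coeffs)) stop("dets and coeffs disagree in length")
  if (abs(sum(coeffs^2) - 1) > 1e-10) stop("coefficients are not normalized")
  structure(
    list(dets = dets, coeffs = as.numeric(coeffs), energy = as.numeric(energy),
         root_index = as.integer(root_index)),
    class = "qsci_wavefunction"
  )
}

#' @export
print.qsci_wavefunction <- function(x, ...) {
  cat(sprintf("<qsci_wavefunction> K = %d determinants, root %d, energy = %.10f\n",
              nrow(x$dets), x$root_index, x$energy))
  invisible(x)
}

# dense interaction block between two determinant lists (Slater-Condon);
# a vectorised excitation-degree prefilter keeps the per-pair evaluation
# loop on the sparse set of connected pairs only
interaction_block <- function(Da, Db, ints, symmetric = FALSE) {
  Da <- as_det_matrix(Da); Db <- as_det_matrix(Db)
  na <- nrow(Da); nb <- nrow(Db)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  dist <- popcount(outer(Da[, 1L], Db[, 1L], bitwXor)) +
          popcount(outer(Da[, 2L], Db[, 2L], bitwXor))
  dim(dist) <- c(na, nb)
  hit <- which(dist <= 4L, arr.ind = TRUE)
  if (symmetric) hit <- hit[hit[, 1L] <= hit[, 2L], , drop = FALSE]
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1L]; j <- hit[r, 2L]
    v <- slater_condon_element(Da[i, ], Db[j, ], ints)
    out[i, j] <- v
    if (symmetric) out[j, i] <- v
  }
  out
}

#' Build the subspace interaction matrix
#'
#' Entry `(k, l)` is `<Phi_k|H|Phi_l>` via the Slater-Condon rules; entries
#' between determinants differing by more than a double excitation are
#' structurally zero.
#'
#' @param D duplicate-free determinant matrix
#' @param ints a [molecular_integrals()]
#' @return symmetric sparse matrix (`Matrix::dsCMatrix`)
#' @export
build_interaction_matrix <- function(D, ints) {
  D <- as_det_matrix(D)
  if (anyDuplicated(det_keys(D, ints$M))) stop("duplicate determinants in subspace")
  Matrix::forceSymmetric(Matrix::Matrix(
    interaction_block(D, D, ints, symmetric = TRUE), sparse = TRUE))
}

# lowest eigenpairs of a symmetric matrix; dense below the cutoff,
# ARPACK (smallest-algebraic) above it
lowest_eigen <- function(Hm, n_roots, dense_cutoff = 1500L) {
  K <- nrow(Hm)
  if (K <= dense_cutoff || n_roots > K %/% 4L) {
    e <- eigen(as.matrix(Hm), symmetric = TRUE)
    ord <- seq_len(K)  # eigen() returns decreasing values
    sel <- K:(K - n_roots + 1L)
    list(values = e$values[sel], vectors = e$vectors[, sel, drop = FALSE])
  } else {
    Hs <- Matrix::Matrix(Hm, sparse = TRUE)
    res <- tryCatch(
      igraph::arpack(function(v, extra) as.numeric(extra %*% v), extra = Hs,
                     sym = TRUE,
                     options = list(n = K, nev = n_roots,
                                    ncv = min(K, max(4L * n_roots + 1L, 20L)),
                                    which = "SA", maxiter = 10000L)),
      error = function(e) stop("sparse eigensolver failed to converge: ",
                               conditionMessage(e))
    )
    vec <- res$vectors
    if (is.null(dim(vec))) vec <- matrix(vec, ncol = n_roots)
    ord <- order(res$values)[seq_len(n_roots)]
    list(values = res$values[ord], vectors = vec[, ord, drop = FALSE])
  }
}

#' Diagonalize the Hamiltonian in a determinant subspace
#'
#' Returns the lowest `n_roots` eigenpairs of the interaction matrix, each as
#' a [subspace_wavefunction()].  The deterministic sign convention makes the
#' largest-magnitude coefficient positive.
#'
#' @param D determinant matrix (K rows, duplicate-free)
#' @param ints a [molecular_integrals()]
#' @param n_roots number of roots (default 1, the ground state)
#' @param dense_cutoff subspace size above which the iterative sparse solver
#'   takes over from dense diagonalization
#' @return list of `n_roots` wavefunctions, lowest energy first
#' @export
solve_subspace <- function(D, ints, n_roots = 1L, dense_cutoff = 1500L) {
  D <- as_det_matrix(D)
  K <- nrow(D)
  if (K < n_roots || n_roots < 1L) stop("need K >= n_roots >= 1")
  Hm <- interaction_block(D, D, ints, symmetric = TRUE)
  eig <- lowest_eigen(Hm, n_roots, dense_cutoff)
  lapply(seq_len(n_roots), function(j) {
    v <- eig$vectors[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    subspace_wavefunction(D, v, eig$values[j], root_index = j - 1L)
  })
}

# -- heatbath screening ----------------------------------------------------

# all single/double connected determinants of d together with the exact
# matrix-element magnitude |H_kl|.  Doubles read their magnitudes straight
# off the two-electron array (they depend only on the moved indices);
# singles need the occupied-orbital sums and are evaluated in full.
connected_with_mag <- function(d, ints, basis) {
  d <- as_det_matrix(d)
  M <- basis$M
  a <- d[1L, 1L]; b <- d[1L, 2L]
  occ_a <- bits_of(a); vir_a <- setdiff(0:(M - 1L), occ_a)
  occ_b <- bits_of(b); vir_b <- setdiff(0:(M - 1L), occ_b)
  g <- ints$g

  excite <- function(mask, p, q) bitwOr(bitwAnd(mask, bitwNot(bitwShiftL(1L, p))),
                                        bitwShiftL(1L, q))

  alpha <- integer(0); beta <- integer(0); mag <- numeric(0)
  add <- function(al, be, mg) {
    alpha <<- c(alpha, al); beta <<- c(beta, be); mag <<- c(mag, mg)
  }

  # singles (full Slater-Condon magnitude)
  single_block <- function(mask, occ, vir, occ_same_full, occ_other) {
    if (length(occ) == 0L || length(vir) == 0L) {
      return(list(mask = integer(0), mag = numeric(0),
                  p = integer(0), q = integer(0)))
    }
    grid <- expand.grid(p = occ, q = vir)
    masks <- mapply(function(p, q) excite(mask, p, q), grid$p, grid$q)
    mg <- mapply(function(p, q) {
      abs(.sc_single(p, q, setdiff(occ_same_full, p), occ_other, ints))
    }, grid$p, grid$q)
    list(mask = as.integer(masks), mag = as.numeric(mg),
         p = grid$p, q = grid$q)
  }
  sa <- single_block(a, occ_a, vir_a, occ_a, occ_b)
  sb <- single_block(b, occ_b, vir_b, occ_b, occ_a)
  if (length(sa$mask)) add(sa$mask, rep(b, length(sa$mask)), sa$mag)
  if (length(sb$mask)) add(rep(a, length(sb$mask)), sb$mask, sb$mag)

  # same-spin doubles: |(pr|qs) - (ps|qr)|
  same_spin <- function(mask, occ, vir) {
    if (length(occ) < 2L || length(vir) < 2L) {
      return(list(mask = integer(0), mag = numeric(0)))
    }
    po <- utils::combn(occ, 2L); pv <- utils::combn(vir, 2L)
    no <- ncol(po); nv <- ncol(pv)
    p <- rep(po[1L, ], each = nv); q <- rep(po[2L, ], each = nv)
    r <- rep(pv[1L, ], times = no); s <- rep(pv[2L, ], times = no)
    mg <- abs(g[cbind(p + 1L, r + 1L, q + 1L, s + 1L)] -
              g[cbind(p + 1L, s + 1L, q + 1L, r + 1L)])
    hole <- bitwShiftL(1L, p) + bitwShiftL(1L, q)
    part <- bitwShiftL(1L, r) + bitwShiftL(1L, s)
    list(mask = bitwOr(bitwAnd(mask, bitwNot(hole)), part), mag = mg)
  }
  da <- same_spin(a, occ_a, vir_a)
  db <- same_spin(b, occ_b, vir_b)
  if (length(da$mask)) add(da$mask, rep(b, length(da$mask)), da$mag)
  if (length(db$mask)) add(rep(a, length(db$mask)), db$mask, db$mag)

  # opposite-spin doubles: |(pr|qs)| over alpha single x beta single
  if (length(sa$mask) && length(sb$mask)) {
    ia <- rep(seq_along(sa$mask), each = length(sb$mask))
    ib <- rep.int(seq_along(sb$mask), length(sa$mask))
    mg <- abs(g[cbind(sa$p[ia] + 1L, sa$q[ia] + 1L, sb$p[ib] + 1L, sb$q[ib] + 1L)])
    add(sa$mask[ia], sb$mask[ib], mg)
  }

  list(dets = det_list(alpha, beta), mag = mag)
}

#' One heatbath expansion of a subspace
#'
#' Appends every determinant outside the current subspace for which some
#' in-subspace determinant `Phi_k` gives `|H_kl v_k| > delta`.
#'
#' @param psi a solved [subspace_wavefunction()]
#' @param delta heatbath threshold (> 0)
#' @param ints a [molecular_integrals()]
#' @param basis a [spin_basis()]
#' @param method `"direct"` reads double-excitation magnitudes off the
#'   integral arrays; `"scan"` is the reference per-determinant
#'   Slater-Condon scan.  Both give identical results.
#' @return determinant matrix (superset of the input subspace)
#' @export
hci_expand <- function(psi, delta, ints, basis, method = c("direct", "scan")) {
  method <- match.arg(method)
  if (delta <= 0) stop("delta must be positive")
  D <- psi$dets
  M <- ints$M
  seen <- new.env(parent = emptyenv())
  for (k in as.character(det_keys(D, M))) seen[[k]] <- TRUE
  new_a <- integer(0); new_b <- integer(0)
  for (k in seq_len(nrow(D))) {
    vk <- abs(psi$coeffs[k])
    if (vk == 0) next
    if (method == "direct") {
      cand <- connected_with_mag(D[k, ], ints, basis)
      keep <- cand$mag * vk > delta
      cd <- cand$dets[keep, , drop = FALSE]
    } else {
      cd <- connected_determinants(D[k, ], basis)
      mg <- vapply(seq_len(nrow(cd)), function(i) {
        abs(slater_condon_element(D[k, ], cd[i, ], ints))
      }, numeric(1))
      cd <- cd[mg * vk > delta, , drop = FALSE]
    }
    for (i in seq_len(nrow(cd))) {
      key <- as.character(cd[i, 1L] * 2^M + cd[i, 2L])
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        new_a <- c(new_a, cd[i, 1L]); new_b <- c(new_b, cd[i, 2L])
      }
    }
  }
  if (length(new_a) == 0L) return(D)
  ord <- order(new_a, new_b)
  rbind(D, det_list(new_a[ord], new_b[ord]))
}

#' Run Heatbath CI with the delta-halving schedule
#'
#' Starts from the Hartree-Fock determinant with threshold `delta0`.  At each
#' threshold level the subspace is enlarged through successive expansion +
#' diagonalization passes until no further connected configurations satisfy
#' `|H_kl v_k| > delta`; the threshold is then halved.  The run stops when an
#' expansion would push the subspace beyond `D_cap`, when the full CI space
#' has been reached, or when `delta` underflows `min_delta`.
#'
#' @param ints a [molecular_integrals()]
#' @param basis a [spin_basis()]
#' @param delta0 initial threshold (default 0.1)
#' @param D_cap maximum permitted subspace dimension
#' @param min_delta stop once `delta` falls below this (default 1e-9)
#' @param dense_cutoff passed to [solve_subspace()]
#' @return list with `wavefunction` (final ground state) and `trace`
#'   (data frame of per-level `delta`, `K`, `energy`)
#' @export
hci_run <- function(ints, basis, delta0 = 0.1, D_cap, min_delta = 1e-9,
                    dense_cutoff = 1500L) {
  if (delta0 <= 0) stop("delta0 must be positive")
  if (D_cap < 1L) stop("D_cap must be at least 1")
  fci_dim <- space_dimension(basis$M, basis$n_alpha, basis$n_beta)
  D <- as_det_matrix(hartree_fock_determinant(basis))
  psi <- solve_subspace(D, ints, dense_cutoff = dense_cutoff)[[1L]]
  trace <- data.frame(delta = numeric(0), K = integer(0), energy = numeric(0))
  delta <- delta0
  capped <- FALSE
  while (delta >= min_delta && !capped && nrow(D) < fci_dim) {
    repeat {
      D2 <- hci_expand(psi, delta, ints, basis)
      if (nrow(D2) == nrow(D)) break
      if (nrow(D2) > D_cap) {
        capped <- TRUE
        break
      }
      D <- D2
      psi <- solve_subspace(D, ints, dense_cutoff = dense_cutoff)[[1L]]
      if (nrow(D) >= fci_dim) break
    }
    trace <- rbind(trace, data.frame(delta = delta, K = nrow(D), energy = psi$energy))
    delta <- delta / 2
  }
  list(wavefunction = psi, trace = trace)
}

#' Collate determinant subspaces from neighboring calculations
#'
#' Deduplicated union of several subspaces (e.g. neighboring points along a
#' potential energy curve), truncated to `D_cap` by descending best
#' coefficient magnitude, ties broken by lexicographic determinant order.
#'
#' @param subspaces list of [subspace_wavefunction()]s (or bare determinant
#'   matrices, which rank with coefficient 0)
#' @param D_cap maximum size of the collated list
#' @param M spatial orbital count (needed only when all inputs are bare
#'   matrices; otherwise inferred)
#' @return determinant matrix with at most `D_cap` rows
#' @export
collate_neighborhood <- function(subspaces, D_cap, M = NULL) {
  best <- new.env(parent = emptyenv())
  rec_a <- integer(0); rec_b <- integer(0); rec_v <- numeric(0)
  if (is.null(M)) M <- 30L
  for (sub in subspaces) {
    if (inherits(sub, "qsci_wavefunction")) {
      dets <- sub$dets; v <- abs(sub$coeffs)
    } else {
      dets <- as_det_matrix(sub); v <- rep(0, nrow(dets))
    }
    keys <- as.character(det_keys(dets, M))
    for (i in seq_along(keys)) {
      cur <- best[[keys[i]]]
      if (is.null(cur)) {
        rec_a <- c(rec_a, dets[i, 1L]); rec_b <- c(rec_b, dets[i, 2L])
        rec_v <- c(rec_v, v[i])
        best[[keys[i]]] <- length(rec_v)
      } else if (v[i] > rec_v[cur]) {
        rec_v[cur] <- v[i]
      }
    }
  }
  ord <- order(-rec_v, rec_a, rec_b)
  keep <- ord[seq_len(min(D_cap, length(ord)))]
  keep <- keep[order(rec_a[keep], rec_b[keep])]
  det_list(rec_a[keep], rec_b[keep])
}
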