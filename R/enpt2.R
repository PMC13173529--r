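# Epstein-Nesbet second-order perturbation correction and the extrapolation
# of subspace energies to the zero-correction (full CI) limit.
#
# The model Hamiltonian is the full block inside the configuration subspace
# plus the bare diagonal outside it, so the perturber denominators use the
# variational subspace energy (Epstein-Nesbet partitioning), not orbital
# energies.  For the ground state every summand is non-positive, hence the
# correction is non-positive and decays to zero as the subspace approaches
# the full CI space.

#' Epstein-Nesbet second-order correction
#'
#' Computes `-sum_k |<Phi_k|V|Psi>|^2 / (<Phi_k|H|Phi_k> - eps)` over all
#' determinants `Phi_k` outside the subspace that connect to it by a single
#' or double excitation, with `<Phi_k|V|Psi> = sum_l H_kl v_l`.  External
#' contributions are accumulated determinant-by-determinant in a hash-keyed
#' accumulator, so memory scales with the connected complement, never the
#' full space.
#'
#' @param psi a solved [subspace_wavefunction()] (ground state)
#' @param ints a [molecular_integrals()]
#' @param basis a [spin_basis()]
#' @return scalar correction (non-positive for the ground state), with
#'   attribute `n_external` giving the number of contributing external
#'   determinants
#' @export
enpt2_correction <- function(psi, ints, basis) {
  D <- psi$dets
  M <- ints$M
  inside <- new.env(parent = emptyenv())
  for (k in as.character(det_keys(D, M))) inside[[k]] <- TRUE

  acc <- new.env(parent = emptyenv())   # key -> c(V_sum, alpha, beta)
  for (l in seq_len(nrow(D))) {
    vl <- psi$coeffs[l]
    if (vl == 0) next
    cand <- connected_determinants(D[l, ], basis)
    if (nrow(cand) == 0L) next
    keys <- as.character(det_keys(cand, M))
    for (i in seq_len(nrow(cand))) {
      if (!is.null(inside[[keys[i]]])) next
      hkl <- slater_condon_element(cand[i, ], D[l, ], ints)
      if (hkl == 0) next
      cur <- acc[[keys[i]]]
      if (is.null(cur)) {
        acc[[keys[i]]] <- c(hkl * vl, cand[i, 1L], cand[i, 2L])
      } else {
        cur[1L] <- cur[1L] + hkl * vl
        acc[[keys[i]]] <- cur
      }
    }
  }

  keys <- ls(acc)
  total <- 0
  for (k in keys) {
    rec <- acc[[k]]
    ext <- determinant_masks(rec[2L], rec[3L])
    denom <- slater_condon_element(ext, ext, ints) - psi$energy
    if (abs(denom) < 1e-12) {
      stop(sprintf(
        "vanishing Epstein-Nesbet denominator at determinant (alpha=%d, beta=%d)",
        rec[2L], rec[3L]))
    }
    total <- total - rec[1L]^2 / denom
  }
  structure(total, n_external = length(keys))
}

#' Extrapolate subspace energies to the zero-correction limit
#'
#' Ordinary least-squares line of the subspace energy against its
#' second-order correction; the intercept at zero correction estimates the
#' full CI energy.  Regressing the correlation energy (energy minus a
#' constant reference) instead of the total energy shifts the intercept by
#' exactly that constant, so `e_ref` merely relabels the axis.
#'
#' @param records data frame with columns `qsci_energy` and `pt2`
#'   (and optionally `subspace_size`), one row per checkpoint
#' @param e_ref optional reference energy subtracted before the fit and
#'   added back to the intercept (default 0)
#' @return list with `estimate` (intercept at `pt2 = 0`), `slope`,
#'   `r_squared` and `stderr` (standard error of the intercept)
#' @export
extrapolate_to_zero <- function(records, e_ref = 0) {
  records <- as.data.frame(records)
  if (!all(c("qsci_energy", "pt2") %in% names(records))) {
    stop("records must carry columns 'qsci_energy' and 'pt2'")
  }
  if (nrow(records) < 2L || length(unique(records$pt2)) < 2L) {
    stop("need at least 2 records with distinct pt2 values")
  }
  fit <- stats::lm((qsci_energy - e_ref) ~ pt2, data = records)
  sm <- suppressWarnings(summary(fit))  # collinear input is legitimate here
  list(
    estimate = unname(stats::coef(fit)[1L]) + e_ref,
    slope = unname(stats::coef(fit)[2L]),
    r_squared = sm$r.squared,
    stderr = sm$coefficients[1L, 2L]
  )
}
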