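# Orchestration of the occupancy-guided QSCI loop: initialize from the
# Hartree-Fock determinant plus rectified measurements, then for each time
# step's measurement set run sampling rounds that diagonalize, prune, draw
# occupancy-guided excitations from the dominant configurations, screen them,
# and append the best scorers -- with directly admitted sector-valid
# measurements alongside, so higher-order excitations seen in the
# time-evolved state can enter in a single iteration.

#' QSCI hyperparameter configuration
#'
#' Defaults follow the reference operating point: subspace cap
#' `D_max = 5e4`, `N_rounds = 10` sampling rounds per measurement set,
#' `N_samples = 100` draws per screened configuration per round,
#' dominant-configuration threshold `eps_screen = 1e-2`, and wavefunction
#' pruning threshold `eps_wf = 1e-5`.
#'
#' @param D_max maximum subspace dimension
#' @param N_rounds sampling rounds per measurement set
#' @param N_samples excitation draws per dominant configuration per round
#' @param eps_screen coefficient magnitude above which a configuration is
#'   treated as dominant (and used as an excitation source)
#' @param eps_wf configurations with coefficient magnitude below this are
#'   pruned from the subspace (the Hartree-Fock determinant is never pruned)
#' @param append_per_round cap on appended determinants per round;
#'   `NULL` means 10 times the number of dominant configurations
#' @param transform occupancy weight transform passed to
#'   [transform_weights()]
#' @param seed RNG seed driving every stochastic choice of the run
#' @param dense_cutoff passed to [solve_subspace()]
#' @return object of class `qsci_config`
#' @export
qsci_config <- function(D_max = 5e4, N_rounds = 10L, N_samples = 100L,
                        eps_screen = 1e-2, eps_wf = 1e-5,
                        append_per_round = NULL, transform = "identity",
                        seed = 1L, dense_cutoff = 1500L) {
  if (D_max < 1) stop("D_max must be at least 1")
  if (eps_screen <= 0 || eps_wf <= 0) stop("thresholds must be positive")
  structure(
    list(D_max = D_max, N_rounds = as.integer(N_rounds),
         N_samples = as.integer(N_samples), eps_screen = eps_screen,
         eps_wf = eps_wf, append_per_round = append_per_round,
         transform = transform, seed = as.integer(seed),
         dense_cutoff = as.integer(dense_cutoff)),
    class = "qsci_config"
  )
}

# deduplicating append helper with a hard cap; env maps key -> TRUE
.append_dets <- function(D, new, M, seen, cap) {
  for (i in seq_len(nrow(new))) {
    if (nrow(D) >= cap) break
    key <- as.character(new[i, 1L] * 2^M + new[i, 2L])
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      D <- rbind(D, new[i, , drop = FALSE])
    }
  }
  D
}

#' Run occupancy-guided QSCI over a time-evolution measurement grid
#'
#' @param ints a [molecular_integrals()]
#' @param basis a [spin_basis()]
#' @param measurements list of [measurement_set()]s, one per time step, in
#'   time order (as produced by [run_time_grid()])
#' @param cfg a [qsci_config()]
#' @return list with elements `wavefunction` (final ground state),
#'   `pt2_records` (data frame of `subspace_size`, `qsci_energy`, `pt2` at
#'   the per-time-step checkpoints) and `trace` (per-round data frame of
#'   `step`, `round`, `K`, `energy`)
#' @export
qsci_run <- function(ints, basis, measurements, cfg = qsci_config()) {
  if (length(measurements) == 0L) stop("empty measurement input")
  for (ms in measurements) {
    if (ms$n_qubits != 2L * basis$M) stop("measurement sets have wrong qubit count")
  }
  M <- basis$M
  hf <- as_det_matrix(hartree_fock_determinant(basis))
  hf_key <- as.character(det_keys(hf, M))

  seen <- new.env(parent = emptyenv())
  seen[[hf_key]] <- TRUE
  D <- hf
  D <- .append_dets(D, rectify_measurements(measurements[[1L]], basis),
                    M, seen, cfg$D_max)

  trace <- data.frame(step = integer(0), round = integer(0),
                      K = integer(0), energy = numeric(0))
  checkpoints <- vector("list", length(measurements))
  ctr <- 0L

  for (s in seq_along(measurements)) {
    dist <- transform_weights(occupancy_distribution(measurements[[s]], basis),
                              cfg$transform)
    rect <- rectify_measurements(measurements[[s]], basis)
    for (r in seq_len(cfg$N_rounds)) {
      psi <- solve_subspace(D, ints, dense_cutoff = cfg$dense_cutoff)[[1L]]

      # prune low-coefficient determinants (never the HF reference)
      keys <- det_keys(D, M)
      keep <- abs(psi$coeffs) >= cfg$eps_wf | keys == det_keys(hf, M)
      if (!all(keep)) {
        for (key in as.character(keys[!keep])) rm(list = key, envir = seen)
        D <- D[keep, , drop = FALSE]
        psi_coeffs <- psi$coeffs[keep]
      } else {
        psi_coeffs <- psi$coeffs
      }

      dominant <- which(abs(psi_coeffs) > cfg$eps_screen)
      if (length(dominant) && nrow(D) < cfg$D_max) {
        cap <- if (is.null(cfg$append_per_round)) {
          10L * length(dominant)
        } else {
          cfg$append_per_round
        }
        # gather candidates from every dominant configuration; a candidate
        # generated by several sources keeps its maximum score
        pool <- new.env(parent = emptyenv())
        pa <- integer(0); pb <- integer(0); psc <- numeric(0)
        for (k in dominant) {
          ctr <- ctr + 1L
          cands <- sample_excitations(D[k, ], dist, cfg$N_samples,
                                      derive_seed(cfg$seed, ctr), basis)
          if (nrow(cands) == 0L) next
          scored <- screen_candidates(cands, D[k, ], ints)
          for (i in seq_len(nrow(scored))) {
            key <- as.character(scored$alpha[i] * 2^M + scored$beta[i])
            if (!is.null(seen[[key]])) next
            cur <- pool[[key]]
            if (is.null(cur)) {
              pa <- c(pa, scored$alpha[i]); pb <- c(pb, scored$beta[i])
              psc <- c(psc, scored$score[i])
              pool[[key]] <- length(psc)
            } else if (scored$score[i] > psc[cur]) {
              psc[cur] <- scored$score[i]
            }
          }
        }
        if (length(psc)) {
          ord <- order(-psc, pa, pb)
          ord <- ord[psc[ord] > 0]
          take <- ord[seq_len(min(cap, length(ord)))]
          D <- .append_dets(D, det_list(pa[take], pb[take]), M, seen, cfg$D_max)
        }
      }

      # admit the step's directly sampled sector-valid configurations
      D <- .append_dets(D, rect, M, seen, cfg$D_max)

      stopifnot(all(det_sector_valid(D, basis)))
      trace <- rbind(trace, data.frame(step = s, round = r,
                                       K = nrow(D), energy = psi$energy))
    }
    checkpoints[[s]] <- D
  }

  psi_final <- solve_subspace(D, ints, dense_cutoff = cfg$dense_cutoff)[[1L]]
  pt2_records <- do.call(rbind, lapply(checkpoints, function(Dc) {
    p <- solve_subspace(Dc, ints, dense_cutoff = cfg$dense_cutoff)[[1L]]
    corr <- enpt2_correction(p, ints, basis)
    data.frame(subspace_size = nrow(Dc), qsci_energy = p$energy,
               pt2 = as.numeric(corr))
  }))
  list(wavefunction = psi_final, pt2_records = pt2_records, trace = trace)
}
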