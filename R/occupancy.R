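# Occupancy statistics from measured bitstrings, and the occupancy-guided
# excitation sampler.  Under the Jordan-Wigner blocked ordering the
# computational-basis bit of qubit i *is* the occupation of spin orbital i,
# so the shot-weighted mean bit values are exactly the orbital occupancy
# distribution of the measured ensemble.

#' Orbital occupancy distribution of a measurement set
#'
#' Per spin channel, `mean_occ` holds the shot-weighted average bit value of
#' each spatial orbital (a number in `[0, 1]`), and `norm_occ` the same
#' vector normalized to unit sum -- the selection weights used for occupied
#' orbitals in the excitation sampler.
#'
#' @param ms a [measurement_set()] over `2 M` qubits
#' @param basis a [spin_basis()]
#' @return object of class `qsci_occdist` with per-spin `mean_occ` and
#'   `norm_occ` lists
#' @export
occupancy_distribution <- function(ms, basis) {
  if (ms$n_qubits != 2L * basis$M) stop("bitstring length must equal 2M")
  if (ms$n_shots == 0L) stop("measurement set carries zero shots")
  B <- bit_matrix(ms)
  w <- ms$counts / ms$n_shots
  nbar <- as.numeric(crossprod(B, w))
  M <- basis$M
  mean_occ <- list(alpha = nbar[1:M], beta = nbar[(M + 1L):(2L * M)])
  norm1 <- function(v) if (sum(v) > 0) v / sum(v) else v
  structure(
    list(mean_occ = mean_occ,
         norm_occ = lapply(mean_occ, norm1),
         n_shots = ms$n_shots),
    class = "qsci_occdist"
  )
}

#' Transform occupancy selection weights
#'
#' `identity` returns the distribution unchanged; `fractional_boost`
#' replaces each mean occupancy `n` by `n (1 - n)` before renormalization,
#' which zeroes fully occupied and fully empty orbitals and peaks at
#' half-filling -- favouring orbitals where delocalization is strongest.
#'
#' @param dist a [occupancy_distribution()]
#' @param mode `"identity"` or `"fractional_boost"`
#' @return a transformed `qsci_occdist`
#' @export
transform_weights <- function(dist, mode = c("identity", "fractional_boost")) {
  mode <- match.arg(mode)
  if (mode == "identity") return(dist)
  norm1 <- function(v) if (sum(v) > 0) v / sum(v) else v
  mean_occ <- lapply(dist$mean_occ, function(v) v * (1 - v))
  structure(
    list(mean_occ = mean_occ, norm_occ = lapply(mean_occ, norm1),
         n_shots = dist$n_shots),
    class = "qsci_occdist"
  )
}

#' Admit sector-valid measured bitstrings as determinants
#'
#' Returns the distinct measured bitstrings whose per-spin electron counts
#' match the basis sector, converted to determinants.  Strings outside the
#' sector contribute to occupancy statistics but never enter the
#' configuration pool.
#'
#' @param ms a [measurement_set()]
#' @param basis a [spin_basis()]
#' @return determinant matrix (possibly zero rows)
#' @export
rectify_measurements <- function(ms, basis) {
  if (length(ms$counts) == 0L) return(det_list(integer(0), integer(0)))
  M <- basis$M
  ints_full <- bitstring_to_int(names(ms$counts))
  lowmask <- bitwShiftL(1L, M) - 1L
  alpha <- bitwAnd(as.integer(ints_full %% 2^M), lowmask)
  beta <- as.integer(ints_full %/% 2^M)
  ok <- popcount(alpha) == basis$n_alpha & popcount(beta) == basis$n_beta
  d <- det_list(alpha[ok], beta[ok])
  d <- d[!duplicated(det_keys(d, M)), , drop = FALSE]
  d[order(d[, 1L], d[, 2L]), , drop = FALSE]
}

# restricted, renormalized weight vector; NULL if no positive weight
.restrict_weights <- function(w, idx) {
  if (length(idx) == 0L) return(NULL)
  v <- w[idx + 1L]
  s <- sum(v)
  if (s <= 0) return(NULL)
  v / s
}

#' Sample occupancy-guided excitations from a configuration
#'
#' Draws `n_samples` single or double excitations away from `phi_k`.  Each
#' draw first picks a channel uniformly among the available ones (single
#' alpha / single beta / same-spin double per spin / opposite-spin double),
#' then picks orbital indices: occupied indices with the normalized
#' occupancy weights restricted to orbitals occupied in `phi_k`, unoccupied
#' indices with weights proportional to one minus the mean occupancy,
#' restricted to orbitals empty in `phi_k`.  Same-spin index pairs are drawn
#' by rejection (i.i.d. redraw while the two indices coincide) so pair
#' frequencies follow the product weights on distinct pairs.  Every
#' candidate is sector-valid by construction.  Duplicate candidates across
#' draws are merged keeping the largest recorded probability.
#'
#' @param phi_k sector-valid determinant
#' @param dist a [occupancy_distribution()]
#' @param n_samples number of draws
#' @param seed RNG seed
#' @param basis a [spin_basis()]
#' @return data frame with columns `alpha`, `beta`, `prob`; attribute
#'   `skipped_channels` lists channels without positive-weight support
#' @export
sample_excitations <- function(phi_k, dist, n_samples, seed, basis) {
  phi_k <- as_det_matrix(phi_k)
  if (!det_sector_valid(phi_k, basis)) stop("phi_k is not sector-valid")
  M <- basis$M
  a <- phi_k[1L, 1L]; b <- phi_k[1L, 2L]
  occ <- list(alpha = bits_of(a), beta = bits_of(b))
  vir <- list(alpha = setdiff(0:(M - 1L), occ$alpha),
              beta = setdiff(0:(M - 1L), occ$beta))
  w_occ <- list(alpha = .restrict_weights(dist$norm_occ$alpha, occ$alpha),
                beta = .restrict_weights(dist$norm_occ$beta, occ$beta))
  w_vir <- list(alpha = .restrict_weights(1 - dist$mean_occ$alpha, vir$alpha),
                beta = .restrict_weights(1 - dist$mean_occ$beta, vir$beta))

  ok1 <- function(s) !is.null(w_occ[[s]]) && !is.null(w_vir[[s]])
  ok2 <- function(s) ok1(s) && sum(w_occ[[s]] > 0) >= 2L && sum(w_vir[[s]] > 0) >= 2L
  channels <- c(
    if (ok1("alpha")) "sa", if (ok1("beta")) "sb",
    if (ok2("alpha")) "daa", if (ok2("beta")) "dbb",
    if (ok1("alpha") && ok1("beta")) "dab"
  )
  all_channels <- c("sa", "sb", "daa", "dbb", "dab")
  skipped <- setdiff(all_channels, channels)
  if (length(channels) == 0L) {
    out <- data.frame(alpha = integer(0), beta = integer(0), prob = numeric(0))
    attr(out, "skipped_channels") <- skipped
    return(out)
  }

  draw1 <- function(idx, w, n) {
    if (length(idx) == 1L) rep(idx, n) else sample(idx, n, replace = TRUE, prob = w)
  }
  # i.i.d. pair with rejection of equal indices
  draw_pair <- function(idx, w, n) {
    p <- draw1(idx, w, n); q <- draw1(idx, w, n)
    while (any(bad <- p == q)) q[bad] <- draw1(idx, w, sum(bad))
    list(p = p, q = q)
  }
  wt <- function(s, set, i) {
    idx <- if (set == "occ") occ[[s]] else vir[[s]]
    w <- if (set == "occ") w_occ[[s]] else w_vir[[s]]
    w[match(i, idx)]
  }
  excite <- function(mask, p, q) {
    bitwOr(bitwAnd(mask, bitwNot(bitwShiftL(1L, p))), bitwShiftL(1L, q))
  }

  with_seed(seed, {
    ch <- sample(channels, n_samples, replace = TRUE)
    alpha <- integer(n_samples); beta <- integer(n_samples)
    prob <- numeric(n_samples)
    for (cname in unique(ch)) {
      sel <- which(ch == cname)
      n <- length(sel)
      if (cname %in% c("sa", "sb")) {
        s <- if (cname == "sa") "alpha" else "beta"
        p <- draw1(occ[[s]], w_occ[[s]], n)
        q <- draw1(vir[[s]], w_vir[[s]], n)
        m <- mapply(excite, rep(if (s == "alpha") a else b, n), p, q)
        alpha[sel] <- if (s == "alpha") m else a
        beta[sel] <- if (s == "alpha") b else m
        prob[sel] <- wt(s, "occ", p) * wt(s, "vir", q)
      } else if (cname %in% c("daa", "dbb")) {
        s <- if (cname == "daa") "alpha" else "beta"
        hp <- draw_pair(occ[[s]], w_occ[[s]], n)
        pp <- draw_pair(vir[[s]], w_vir[[s]], n)
        base <- if (s == "alpha") a else b
        m <- mapply(function(p1, p2, r1, r2) excite(excite(base, p1, r1), p2, r2),
                    hp$p, hp$q, pp$p, pp$q)
        alpha[sel] <- if (s == "alpha") m else a
        beta[sel] <- if (s == "alpha") b else m
        prob[sel] <- wt(s, "occ", hp$p) * wt(s, "occ", hp$q) *
                     wt(s, "vir", pp$p) * wt(s, "vir", pp$q)
      } else {  # dab: one alpha move, one beta move (p = q, r = s allowed)
        pa <- draw1(occ$alpha, w_occ$alpha, n)
        ra <- draw1(vir$alpha, w_vir$alpha, n)
        qb <- draw1(occ$beta, w_occ$beta, n)
        sb_ <- draw1(vir$beta, w_vir$beta, n)
        alpha[sel] <- mapply(excite, rep(a, n), pa, ra)
        beta[sel] <- mapply(excite, rep(b, n), qb, sb_)
        prob[sel] <- wt("alpha", "occ", pa) * wt("beta", "occ", qb) *
                     wt("alpha", "vir", ra) * wt("beta", "vir", sb_)
      }
    }
    keys <- alpha * 2^M + beta
    ord <- order(keys, -prob)
    first <- !duplicated(keys[ord])
    out <- data.frame(alpha = alpha[ord][first], beta = beta[ord][first],
                      prob = prob[ord][first])
    attr(out, "skipped_channels") <- skipped
    out
  })
}

#' Score sampled candidates for subspace inclusion
#'
#' Heatbath-inspired screening metric: each candidate `Phi_l` carries the
#' score `|H_kl| * P(Phi_l)`, the Hamiltonian matrix-element magnitude
#' against the generating configuration times the recorded sampling
#' probability.  Sorted by descending score with a deterministic
#' lexicographic tie-break.
#'
#' @param candidates data frame from [sample_excitations()]
#' @param phi_k the generating determinant
#' @param ints a [molecular_integrals()]
#' @return the candidate data frame with a `score` column, sorted
#' @export
screen_candidates <- function(candidates, phi_k, ints) {
  if (nrow(candidates) == 0L) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  hmag <- vapply(seq_len(nrow(candidates)), function(i) {
    abs(slater_condon_element(
      phi_k, determinant_masks(candidates$alpha[i], candidates$beta[i]), ints))
  }, numeric(1))
  candidates$score <- hmag * candidates$prob
  ord <- order(-candidates$score, candidates$alpha, candidates$beta)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
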