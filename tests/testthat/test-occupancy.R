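# Occupancy statistics, rectification, the occupancy-guided excitation
# sampler and the QSCI orchestration loop.

# hand-built occupancy distribution (bypasses measurement plumbing)
occdist_of <- function(alpha_mean, beta_mean) {
  norm1 <- function(v) if (sum(v) > 0) v / sum(v) else v
  structure(
    list(mean_occ = list(alpha = alpha_mean, beta = beta_mean),
         norm_occ = list(alpha = norm1(alpha_mean), beta = norm1(beta_mean)),
         n_shots = NA_integer_),
    class = "qsci_occdist"
  )
}

test_that("occupancy distribution averages bits shot-weighted", {
  b <- spin_basis(2, 1, 1)
  # all shots on the HF bitstring reproduce its occupancy pattern exactly
  d <- occupancy_distribution(ms_of("1010", 100L), b)
  expect_equal(d$mean_occ$alpha, c(1, 0))
  expect_equal(d$mean_occ$beta, c(1, 0))
  # equally weighted complementary bitstrings average to one half
  d2 <- occupancy_distribution(ms_of(c("1001", "0110"), c(50L, 50L)), b)
  expect_equal(d2$mean_occ$alpha, c(0.5, 0.5))
  expect_equal(d2$mean_occ$beta, c(0.5, 0.5))
  # random multiset against independent per-bit tallying
  set.seed(12)
  strs <- vapply(1:20, function(i) {
    paste(sample(c("0", "1"), 6, replace = TRUE), collapse = "")
  }, character(1))
  cnt <- sample(1:9, 20, replace = TRUE)
  keep <- !duplicated(strs)
  ms <- ms_of(strs[keep], cnt[keep])
  d3 <- occupancy_distribution(ms, spin_basis(3, 1, 1))
  bits <- do.call(rbind, lapply(strsplit(names(ms$counts), ""),
                                function(x) as.integer(x == "1")))
  manual <- colSums(bits * ms$counts) / ms$n_shots
  expect_equal(c(d3$mean_occ$alpha, d3$mean_occ$beta), unname(manual))
  expect_error(occupancy_distribution(ms_of("10", 1L), b), "2M")
})

test_that("the fractional-boost transform vanishes at the endpoints", {
  d <- occdist_of(c(1, 0, 0.5, 0.3), c(0.5, 0.5, 1, 0))
  t1 <- transform_weights(d, "identity")
  expect_identical(t1$mean_occ, d$mean_occ)
  expect_identical(transform_weights(t1, "identity")$mean_occ, d$mean_occ)
  t2 <- transform_weights(d, "fractional_boost")
  expect_equal(t2$mean_occ$alpha[1:2], c(0, 0))
  expect_equal(t2$mean_occ$beta[3:4], c(0, 0))
  # half filling maximizes n (1 - n)
  expect_equal(which.max(t2$mean_occ$alpha), 3L)
  expect_equal(sum(t2$norm_occ$alpha), 1)
})

test_that("rectification admits exactly the sector-valid strings", {
  b <- spin_basis(2, 1, 1)
  # noiseless HF measurement admits only HF
  r <- rectify_measurements(ms_of("1010", 64L), b)
  expect_identical(nrow(r), 1L)
  expect_identical(unname(r[1L, ]), c(1L, 1L))
  # complemented half-filled strings with unequal counts: empty set
  b2 <- spin_basis(3, 1, 1)
  r2 <- rectify_measurements(ms_of("011011", 10L), b2)
  expect_identical(nrow(r2), 0L)
  # mixed multiset equals brute-force popcount filtering
  set.seed(8)
  strs <- unique(vapply(1:40, function(i) {
    paste(sample(c("0", "1"), 6, replace = TRUE), collapse = "")
  }, character(1)))
  ms <- ms_of(strs, rep(1L, length(strs)))
  r3 <- rectify_measurements(ms, b2)
  brute <- strs[vapply(strs, function(s) {
    bits <- as.integer(strsplit(s, "")[[1]] == "1")
    sum(bits[1:3]) == 1L && sum(bits[4:6]) == 1L
  }, logical(1))]
  expect_identical(nrow(r3), length(brute))
  expect_true(all(det_sector_valid(r3, b2)))
})

test_that("excitation sampling follows the conditional product formula", {
  b <- spin_basis(4, 2, 2)
  hf <- hartree_fock_determinant(b)
  na <- c(0.8, 0.4, 0.3, 0.1)
  nb <- c(0.7, 0.5, 0.2, 0.4)
  dist <- occdist_of(na, nb)

  cands <- sample_excitations(hf, dist, 4000L, seed = 21, basis = b)
  expect_true(all(det_sector_valid(det_list(cands$alpha, cands$beta), b)))
  expect_identical(anyDuplicated(cands$alpha * 16 + cands$beta), 0L)

  # enumeration oracle for the recorded probabilities: occupied factors from
  # the normalized occupancy restricted to occupied orbitals; virtual factors
  # from 1 - mean occupancy restricted to empty orbitals
  wo <- function(m, occ) {
    v <- (m / sum(m))[occ + 1]
    v / sum(v)
  }
  wv <- function(m, vir) {
    v <- (1 - m)[vir + 1]
    v / sum(v)
  }
  woa <- wo(na, c(0L, 1L)); wva <- wv(na, c(2L, 3L))
  wob <- wo(nb, c(0L, 1L)); wvb <- wv(nb, c(2L, 3L))
  prob_of <- function(alpha, beta) {
    moved_a <- bitwXor(alpha, hf[["alpha"]])
    moved_b <- bitwXor(beta, hf[["beta"]])
    pa <- bits_of(bitwAnd(moved_a, hf[["alpha"]]))
    qa <- bits_of(bitwAnd(moved_a, alpha))
    pb <- bits_of(bitwAnd(moved_b, hf[["beta"]]))
    qb <- bits_of(bitwAnd(moved_b, beta))
    prod(c(woa[pa + 1], wva[qa - 1], wob[pb + 1], wvb[qb - 1]))
  }
  for (i in seq_len(nrow(cands))) {
    expect_equal(cands$prob[i], prob_of(cands$alpha[i], cands$beta[i]),
                 tolerance = 1e-12)
  }

  # empirical frequencies over repeated single draws against the enumerated
  # channel-mixture distribution, 3-sigma multinomial bounds
  n_draws <- 4000L
  draws <- vapply(seq_len(n_draws), function(i) {
    cd <- sample_excitations(hf, dist, 1L, seed = 1000L + i, basis = b)
    cd$alpha[1] * 16 + cd$beta[1]
  }, numeric(1))
  # enumerate the exact mixture: each of the 5 channels weight 1/5
  expected <- new.env(parent = emptyenv())
  addp <- function(alpha, beta, p) {
    k <- as.character(alpha * 16 + beta)
    expected[[k]] <- (if (is.null(expected[[k]])) 0 else expected[[k]]) + p / 5
  }
  for (p in 0:1) for (q in 2:3) {   # single alpha / single beta
    addp(bitwXor(hf[["alpha"]], bitwOr(2^p, 2^q)), hf[["beta"]],
         woa[p + 1] * wva[q - 1])
    addp(hf[["alpha"]], bitwXor(hf[["beta"]], bitwOr(2^p, 2^q)),
         wob[p + 1] * wvb[q - 1])
  }
  addp(12L, hf[["beta"]], 1)        # same-spin doubles are forced pairs
  addp(hf[["alpha"]], 12L, 1)
  for (p in 0:1) for (r in 2:3) for (q in 0:1) for (s in 2:3) {
    addp(bitwXor(hf[["alpha"]], bitwOr(2^p, 2^r)),
         bitwXor(hf[["beta"]], bitwOr(2^q, 2^s)),
         woa[p + 1] * wva[r - 1] * wob[q + 1] * wvb[s - 1])
  }
  for (k in ls(expected)) {
    pk <- expected[[k]]
    emp <- mean(draws == as.numeric(k))
    expect_lt(abs(emp - pk), 3 * sqrt(pk * (1 - pk) / n_draws) + 1e-9)
  }
})

test_that("degenerate occupancies concentrate on one excitation", {
  b <- spin_basis(3, 1, 0)
  d <- determinant_masks(1L, 0L)
  dist <- occdist_of(c(0.5, 0, 1), c(0, 0, 0))
  cands <- sample_excitations(d, dist, 200L, seed = 2, basis = b)
  # only the alpha single channel is available; virtual weight forces 0 -> 1
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$alpha[1], 2L)
  expect_true(all(c("sb", "daa", "dbb", "dab") %in%
                    attr(cands, "skipped_channels")))
})

test_that("uniform occupancies give symmetric channel draws", {
  b <- spin_basis(4, 2, 2)
  hf <- hartree_fock_determinant(b)
  dist <- occdist_of(rep(0.5, 4), rep(0.5, 4))
  cands <- sample_excitations(hf, dist, 5000L, seed = 3, basis = b)
  singles_a <- cands[bitwXor(cands$alpha, hf[["alpha"]]) != 0 &
                       cands$beta == hf[["beta"]] &
                       popcount(bitwXor(cands$alpha, hf[["alpha"]])) == 2, ]
  expect_identical(nrow(singles_a), 4L)          # all 4 alpha singles appear
  expect_equal(singles_a$prob, rep(0.25, 4))     # and are equiprobable
})

test_that("screening scores are |H_kl| times the recorded probability", {
  fx <- load_fixture("toy4")
  b <- fx$basis
  hf <- hartree_fock_determinant(b)
  dist <- occdist_of(c(0.9, 0.7, 0.2, 0.1), c(0.9, 0.7, 0.2, 0.1))
  cands <- sample_excitations(hf, dist, 500L, seed = 5, basis = b)
  scored <- screen_candidates(cands, hf, fx$ints)
  for (i in seq_len(nrow(scored))) {
    expect_equal(scored$score[i],
                 abs(slater_condon_element(
                   hf, determinant_masks(scored$alpha[i], scored$beta[i]),
                   fx$ints)) * scored$prob[i],
                 tolerance = 1e-12)
  }
  expect_true(all(diff(scored$score) <= 1e-15))
  # zero probability gives zero score regardless of the matrix element
  z <- screen_candidates(data.frame(alpha = 6L, beta = 3L, prob = 0), hf, fx$ints)
  expect_identical(z$score, 0)
})

test_that("QSCI stays at HF for decoupled Hamiltonians and is deterministic", {
  # diagonal two-electron classes only: every off-diagonal element vanishes
  M <- 3
  h <- diag(c(-1.5, -0.8, -0.2))
  g <- array(0, rep(M, 4))
  for (p in 1:M) for (q in 1:M) {
    g[p, p, q, q] <- 0.3
  }
  ints <- molecular_integrals(0.1, h, g)
  b <- spin_basis(3, 1, 1)
  hf <- hartree_fock_determinant(b)
  ms <- ms_of("100100", 256L)
  cfg <- qsci_config(D_max = 9, N_rounds = 2, N_samples = 40, seed = 4)
  res <- qsci_run(ints, b, list(ms), cfg)
  expect_identical(nrow(res$wavefunction$dets), 1L)
  expect_equal(res$wavefunction$energy, slater_condon_element(hf, hf, ints))

  # determinism: identical runs from identical seeds
  fx <- load_fixture("random", M = 3, seed = 6)
  grid <- small_grid(fx, K = 2, instances = 5, shots = 128, seed = 3)
  cfg2 <- qsci_config(D_max = 9, N_rounds = 3, N_samples = 30, seed = 11)
  r1 <- qsci_run(fx$ints, fx$basis, grid, cfg2)
  r2 <- qsci_run(fx$ints, fx$basis, grid, cfg2)
  expect_identical(r1$wavefunction$dets, r2$wavefunction$dets)
  expect_equal(r1$wavefunction$energy, r2$wavefunction$energy)
  expect_identical(r1$trace, r2$trace)
})

test_that("QSCI reaches FCI on a small fixture and keeps the sector", {
  fx <- load_fixture("random", M = 3, seed = 6)
  e_fci <- fci_ground_energy(fx$ints, fx$basis)
  grid <- small_grid(fx, K = 3, instances = 10, shots = 256, seed = 7)
  cfg <- qsci_config(D_max = 9, N_rounds = 4, N_samples = 60,
                     eps_screen = 1e-3, seed = 2)
  res <- qsci_run(fx$ints, fx$basis, grid, cfg)
  expect_equal(res$wavefunction$energy, e_fci, tolerance = 1e-8)
  expect_true(all(det_sector_valid(res$wavefunction$dets, fx$basis)))
  # energy checkpoints non-increasing while the subspace grows
  tr <- res$trace
  expect_true(all(diff(tr$energy) <= 1e-8))
  # noisy measurements never break the particle sector
  noisy <- lapply(grid, apply_readout_noise, p_flip = 0.1, seed = 13)
  resn <- qsci_run(fx$ints, fx$basis, noisy, cfg)
  expect_true(all(det_sector_valid(resn$wavefunction$dets, fx$basis)))
})
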