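# qDRIFT sampling, statevector propagation, and measurement extraction.

test_that("the segment-count formula is evaluated exactly", {
  expect_identical(qdrift_sample_count(1, 1, 2), 1L)
  expect_identical(qdrift_sample_count(1, 0, 0.5), 0L)
  expect_identical(qdrift_sample_count(2, 3, 0.1), 720L)
  expect_error(qdrift_sample_count(1, 1, 0), "positive")
  expect_error(qdrift_sample_count(1, -1, 1), "non-negative")
})

test_that("term draws follow |h_j|/lambda and are seed-deterministic", {
  H1 <- pauli_hamiltonian("XZ", 0.7)
  s1 <- sample_qdrift_sequence(H1, 1, 0.1, seed = 4)
  expect_true(all(s1$idx == 1L))
  expect_true(all(abs(s1$angles) == H1$lambda * 1 / s1$N))

  fx <- load_fixture("random", M = 3, seed = 2)
  H <- jordan_wigner(fx$basis, fx$ints)
  sA <- sample_qdrift_sequence(H, 0.8, 0.2, seed = 10)
  sB <- sample_qdrift_sequence(H, 0.8, 0.2, seed = 10)
  expect_identical(sA$idx, sB$idx)
  # empirical frequencies over 1e5 draws: chi-squared goodness of fit plus
  # per-term 3-sigma bounds in the normal-approximation regime
  n_draws <- 1e5
  eps <- 2 * H$lambda^2 * 1^2 / n_draws
  s <- sample_qdrift_sequence(H, 1, eps, seed = 1)
  expect_lte(abs(s$N - n_draws), 1L)   # ceiling rounding only
  n_draws <- s$N
  p <- abs(H$coeff) / H$lambda
  obs <- tabulate(s$idx, nbins = length(p))
  chi <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(chi$p.value, 1e-3)
  big <- which(n_draws * p >= 50)
  zmax <- max(abs(obs[big] / n_draws - p[big]) /
                sqrt(p[big] * (1 - p[big]) / n_draws))
  expect_lt(zmax, 3)
  expect_error(sample_qdrift_sequence(pauli_hamiltonian(character(0), numeric(0)),
                                      1, 0.1, 1), "empty")
})

test_that("propagation is unitary, trivial for empty and Z-only sequences", {
  fx <- load_fixture("random", M = 2, seed = 3)
  b <- fx$basis
  H <- jordan_wigner(b, fx$ints)
  ref <- hartree_fock_determinant(b)
  empty <- sample_qdrift_sequence(H, 0, 0.5, seed = 1)
  v0 <- propagate_statevector(ref, empty)
  expect_equal(Mod(v0[ref[["alpha"]] + ref[["beta"]] * 4 + 1]), 1)
  # Z-only rotation on a basis state: global phase, populations unchanged
  zseq <- structure(list(idx = 1L, angles = 0.73, x = 0L,
                         z = mask_from_bits(c(0L, 2L)), n_qubits = 4L,
                         t = 1, N = 1L, epsilon = 1, lambda = 1, seed = 1L),
                    class = "qsci_qdrift_seq")
  vz <- propagate_statevector(ref, zseq)
  expect_equal(Mod(vz), Mod(v0), tolerance = 1e-12)
  # norm preservation through a long random sequence
  long <- sample_qdrift_sequence(H, 1.5, 0.02, seed = 6)
  vl <- propagate_statevector(ref, long)
  expect_lt(abs(sum(Mod(vl)^2) - 1), 1e-10)
  expect_error(propagate_statevector(ref, long, qubit_cap = 2L), "cap")
})

test_that("qDRIFT fidelity against the dense propagator improves with epsilon", {
  fx <- load_fixture("random", M = 2, seed = 3)
  b <- fx$basis
  H <- jordan_wigner(b, fx$ints)
  ref <- hartree_fock_determinant(b)
  Hm <- oracle_pauli_sum_matrix(H)
  t <- 0.7
  psi0 <- complex(16)
  psi0[ref[["alpha"]] + ref[["beta"]] * 4 + 1] <- 1
  exact <- oracle_evolve(Hm, psi0, t)
  infid <- vapply(c(1, 0.25, 0.05), function(eps) {
    f <- vapply(1:40, function(s) {
      v <- propagate_statevector(ref, sample_qdrift_sequence(H, t, eps, s))
      Mod(sum(Conj(exact) * v))^2
    }, numeric(1))
    1 - mean(f)
  }, numeric(1))
  expect_true(all(diff(infid) < 0))
  expect_lt(infid[3], 0.02)
})

test_that("measurement sampling reproduces basis states and uniform draws", {
  # basis state: all shots identical
  v <- complex(8); v[6] <- 1
  ms <- sample_measurements(v, 50, seed = 2)
  expect_identical(length(ms$counts), 1L)
  expect_identical(ms$n_shots, 50L)
  expect_identical(names(ms$counts), "101")
  # uniform 2-qubit superposition: each outcome within 3 sigma of 1/4
  u <- rep(0.5 + 0i, 4)
  msu <- sample_measurements(u, 1e5, seed = 3)
  expect_identical(sum(msu$counts), 100000L)
  sigma <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(msu$counts / 1e5 - 0.25) < 3 * sigma))
  expect_error(sample_measurements(c(1, 1 + 0i), 10, 1), "normalized")
})

test_that("readout noise flips bits as specified", {
  ms <- ms_of(c("1100", "0011"), c(30L, 20L))
  expect_identical(apply_readout_noise(ms, 0, seed = 1)$counts, ms$counts)
  flipped <- apply_readout_noise(ms, 1, seed = 1)
  expect_identical(sort(names(flipped$counts)), c("0011", "1100"))
  expect_identical(flipped$counts[["0011"]], 30L)
  expect_identical(flipped$counts[["1100"]], 20L)
  # sector-valid fraction decays as p_flip grows (HF measurement fixture)
  b <- spin_basis(2, 1, 1)
  hf_ms <- ms_of("1010", 10000L)
  frac <- vapply(c(0.02, 0.1, 0.3), function(p) {
    noisy <- apply_readout_noise(hf_ms, p, seed = 5)
    valid <- vapply(names(noisy$counts), function(s) {
      bits <- as.integer(strsplit(s, "")[[1]] == "1")
      sum(bits[1:2]) == 1L && sum(bits[3:4]) == 1L
    }, logical(1))
    sum(noisy$counts[valid]) / noisy$n_shots
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("the time grid aggregates shots with full provenance", {
  fx <- load_fixture("toy2")
  H <- jordan_wigner(fx$basis, fx$ints)
  ref <- hartree_fock_determinant(fx$basis)
  grid <- run_time_grid(H, ref, tau = 2 * pi / 5, K = 2, n_instances = 3,
                        shots = 64, epsilon = 1, seed = 9)
  expect_identical(length(grid), 2L)
  expect_true(all(vapply(grid, function(g) g$n_shots, integer(1)) == 192L))
  expect_equal(grid[[2]]$provenance$t, 2 * 2 * pi / 5)
  # determinism
  grid2 <- run_time_grid(H, ref, tau = 2 * pi / 5, K = 2, n_instances = 3,
                         shots = 64, epsilon = 1, seed = 9)
  expect_identical(grid[[1]]$counts, grid2[[1]]$counts)
  expect_identical(run_time_grid(H, ref, 1, 0, 1, 1, 1, 1), list())
  # diagonal Hamiltonian: only the reference bitstring is ever observed
  hz <- pauli_hamiltonian(c("ZIII", "IZII"), c(0.4, -0.3))
  gz <- run_time_grid(hz, ref, tau = 1, K = 2, n_instances = 2, shots = 32,
                      epsilon = 0.5, seed = 1)
  for (g in gz) expect_identical(names(g$counts), "1010")
})

test_that("measurement sets round-trip through the text format", {
  ms <- ms_of(c("0110", "1001", "1111"), c(5L, 7L, 1L))
  ms$provenance <- list(step = 2, t = 1.5)
  path <- tempfile()
  write_measurements(ms, path)
  back <- read_measurements(path)
  expect_identical(back$counts[order(names(back$counts))],
                   ms$counts[order(names(ms$counts))])
  expect_identical(back$n_qubits, 4L)
  expect_equal(back$provenance$t, 1.5)
  unlink(path)
})
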