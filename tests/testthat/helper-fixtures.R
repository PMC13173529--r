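# Shared in-code fixtures.  Everything is generated programmatically; the
# only files involved are written to tempdirs by the tests themselves.

# package-built toy integral sets, loaded through the FCIDUMP round trip
load_fixture <- function(name, ...) {
  path <- tempfile(fileext = ".fcidump")
  on.exit(unlink(path))
  make_fixture(name, path, ...)
  read_fcidump(path)
}

# dense FCI ground energy through the package path (solve over the full space)
fci_ground_energy <- function(ints, basis) {
  solve_subspace(fci_space(basis), ints)[[1L]]$energy
}

# noiseless measurement grid for a fixture, small budget
small_grid <- function(fd, K = 3L, instances = 10L, shots = 256L,
                       epsilon = 1, seed = 7L) {
  H <- jordan_wigner(fd$basis, fd$ints)
  run_time_grid(H, hartree_fock_determinant(fd$basis), tau = 2 * pi / 5,
                K = K, n_instances = instances, shots = shots,
                epsilon = epsilon, seed = seed)
}

# a measurement set with prescribed bitstrings/counts
ms_of <- function(bitstrings, counts) {
  stats::setNames(counts, bitstrings)
  measurement_set(stats::setNames(as.integer(counts), bitstrings),
                  nchar(bitstrings[1L]))
}
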