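# Computational-basis measurement sets.  A bitstring is written qubit-0-first:
# the leftmost character is spin orbital 0 (alpha_0 under the blocked
# ordering).  On disk, one record per line "<bitstring> <count>" below a
# header line "# qubits=2M shots=N".

#' Construct a measurement set
#'
#' @param counts named integer vector: names are bitstrings (characters `0`
#'   and `1`, leftmost = qubit 0), values are shot multiplicities
#' @param n_qubits bitstring length
#' @param provenance free-form list recording how the set was produced
#'   (time-step index, instance index, seeds)
#' @return object of class `qsci_measurements`
#' @export
measurement_set <- function(counts, n_qubits, provenance = list()) {
  counts <- counts[counts > 0]
  if (length(counts) && any(nchar(names(counts)) != n_qubits)) {
    stop("all bitstrings must have length n_qubits")
  }
  structure(
    list(counts = counts, n_qubits = as.integer(n_qubits),
         n_shots = as.integer(sum(counts)), provenance = provenance),
    class = "qsci_measurements"
  )
}

#' @export
print.qsci_measurements <- function(x, ...) {
  cat(sprintf("<qsci_measurements> %d shots over %d distinct bitstrings (%d qubits)\n",
              x$n_shots, length(x$counts), x$n_qubits))
  invisible(x)
}

# state index <-> bitstring (bit i of the integer = qubit i = character i + 1)
int_to_bitstring <- function(b, n) {
  vapply(b, function(v) {
    paste(bitwAnd(bitwShiftR(as.integer(v), 0:(n - 1L)), 1L), collapse = "")
  }, character(1))
}

bitstring_to_int <- function(s) {
  vapply(strsplit(s, ""), function(bits) {
    sum(bitwShiftL(as.integer(bits == "1"), seq_along(bits) - 1L))
  }, numeric(1))
}

# per-qubit bit matrix (rows = bitstrings, cols = qubits)
bit_matrix <- function(ms) {
  if (length(ms$counts) == 0L) {
    return(matrix(integer(0), 0L, ms$n_qubits))
  }
  t(vapply(strsplit(names(ms$counts), ""),
           function(b) as.integer(b == "1"), integer(ms$n_qubits)))
}

#' Write a measurement set to a text file
#'
#' @param ms a [measurement_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_measurements <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qubits=%d shots=%d", ms$n_qubits, ms$n_shots), con)
  for (nm in names(ms$provenance)) {
    val <- ms$provenance[[nm]]
    if (is.numeric(val) && length(val) == 1L) {
      writeLines(sprintf("# %s=%s", nm, format(val, digits = 15)), con)
    }
  }
  ord <- order(names(ms$counts))
  writeLines(sprintf("%s %d", names(ms$counts)[ord], ms$counts[ord]), con)
  invisible(path)
}

#' Read a measurement set from a text file
#'
#' @param path file path
#' @return a [measurement_set()]
#' @export
read_measurements <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1L]
  m <- regmatches(hdr, regexec("#\\s*qubits=(\\d+)\\s+shots=(\\d+)", hdr))[[1L]]
  if (length(m) < 3L) stop("missing '# qubits=... shots=...' header in ", path)
  n_qubits <- as.integer(m[2L])
  prov <- list()
  body <- lines[-1L]
  extra <- grepl("^#", body)
  for (ln in body[extra]) {
    pm <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)=([-0-9.eE+]+)", ln))[[1L]]
    if (length(pm) == 3L) prov[[pm[2L]]] <- as.numeric(pm[3L])
  }
  body <- body[!extra & nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  counts <- vapply(toks, function(t) as.integer(t[2L]), integer(1))
  names(counts) <- vapply(toks, `[`, character(1), 1L)
  ms <- measurement_set(counts, n_qubits, prov)
  if (ms$n_shots != as.integer(m[3L])) {
    stop("shot total in header disagrees with records in ", path)
  }
  ms
}

#' Corrupt a measurement set with independent readout bit flips
#'
#' Noise fixture emulating hardware readout corruption: each bit of each shot
#' is flipped independently with probability `p_flip`; the shot total is
#' preserved.
#'
#' @param ms a [measurement_set()]
#' @param p_flip flip probability in `[0, 1]`
#' @param seed RNG seed
#' @return a new [measurement_set()]
#' @export
apply_readout_noise <- function(ms, p_flip, seed) {
  if (p_flip < 0 || p_flip > 1) stop("p_flip must lie in [0, 1]")
  if (p_flip == 0) return(ms)
  n <- ms$n_qubits
  states <- rep(bitstring_to_int(names(ms$counts)), times = ms$counts)
  flipped <- with_seed(seed, {
    masks <- numeric(length(states))
    for (i in 0:(n - 1L)) {
      masks <- masks + bitwShiftL(1L, i) * stats::rbinom(length(states), 1L, p_flip)
    }
    bitwXor(as.integer(states), as.integer(masks))
  })
  tab <- table(flipped)
  counts <- as.integer(tab)
  names(counts) <- int_to_bitstring(as.numeric(names(tab)), n)
  measurement_set(counts, n, c(ms$provenance, list(p_flip = p_flip, noise_seed = seed)))
}

# save/seed/restore helper so package randomness never clobbers user RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
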