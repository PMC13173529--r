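# Qubit counting for small molecules in standard Gaussian basis sets.
# Table-driven: contracted shell counts per element, spherical-harmonic
# component counts per angular momentum (s = 1, p = 3, d = 5).

.shell_tables <- list(
  "6-31G" = list(
    H = c(s = 2L),
    Si = c(s = 4L, p = 3L)
  ),
  "6-31G(d)" = list(
    H = c(s = 2L),
    Si = c(s = 4L, p = 3L, d = 1L)
  ),
  "cc-pVDZ" = list(
    H = c(s = 2L, p = 1L),
    Si = c(s = 4L, p = 3L, d = 1L)
  )
)

.l_degeneracy <- c(s = 1L, p = 3L, d = 5L, f = 7L)

# parse a simple molecular formula like "SiH4" into element counts
.parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  parts <- regmatches(formula, list(m))[[1L]]
  if (sum(nchar(parts)) != nchar(formula)) stop("unparseable formula: ", formula)
  out <- integer(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (nchar(n)) as.integer(n) else 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

#' Count spatial basis functions for a molecule in a Gaussian basis set
#'
#' Uses spherical-harmonic shell components (5 per d shell).
#'
#' @param formula molecular formula, e.g. `"SiH4"`
#' @param basis_set one of `"6-31G"`, `"6-31G(d)"`, `"cc-pVDZ"`
#' @return integer count of spatial orbitals
#' @examples
#' count_spatial_orbitals("SiH4", "6-31G")  # 21
#' @export
count_spatial_orbitals <- function(formula, basis_set = "6-31G") {
  tab <- .shell_tables[[basis_set]]
  if (is.null(tab)) {
    stop("unknown basis set: ", basis_set, " (have: ",
         paste(names(.shell_tables), collapse = ", "), ")")
  }
  elems <- .parse_formula(formula)
  total <- 0L
  for (el in names(elems)) {
    shells <- tab[[el]]
    if (is.null(shells)) stop("no shell data for element ", el, " in ", basis_set)
    total <- total + elems[[el]] *
      sum(shells * .l_degeneracy[names(shells)])
  }
  as.integer(total)
}

#' Count spin orbitals (qubits) for a molecule in a Gaussian basis set
#'
#' Twice the spatial orbital count: one qubit per spin orbital under the
#' Jordan-Wigner mapping.
#'
#' @inheritParams count_spatial_orbitals
#' @return integer qubit count
#' @examples
#' count_spin_orbitals("SiH4", "6-31G")    # 42
#' count_spin_orbitals("SiH4", "cc-pVDZ")  # 76
#' @export
count_spin_orbitals <- function(formula, basis_set = "6-31G") {
  2L * count_spatial_orbitals(formula, basis_set)
}
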