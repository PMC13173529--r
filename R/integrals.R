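# Molecular integral container.  One-electron integrals h[p, q] are symmetric;
# two-electron integrals g[p, q, r, s] are stored densely in chemists'
# notation (pq|rs) with the 8-fold real-orbital permutational symmetry.
# All internal indices are 0-based at call sites; R's 1-based array indexing
# is applied at the last moment.

#' Molecular integral set
#'
#' @param E_core scalar energy offset (nuclear repulsion plus any frozen-core
#'   contribution)
#' @param h `M x M` symmetric one-electron integral matrix
#' @param g `M x M x M x M` two-electron integral array in chemists' notation
#'   `(pq|rs)` with 8-fold permutational symmetry
#' @param check validate the symmetries (default `TRUE`)
#' @param tol symmetry tolerance
#' @return object of class `qsci_ints`
#' @export
molecular_integrals <- function(E_core, h, g, check = TRUE, tol = 1e-8) {
  h <- as.matrix(h)
  M <- nrow(h)
  if (ncol(h) != M) stop("h must be square")
  if (!identical(dim(g), rep(M, 4L)) && !identical(dim(g), as.integer(rep(M, 4L)))) {
    stop("g must be an M^4 array matching h")
  }
  if (check) {
    if (max(abs(h - t(h))) > tol) stop("h is not symmetric within tolerance")
    gp <- aperm(g, c(2L, 1L, 3L, 4L))   # (qp|rs)
    gr <- aperm(g, c(3L, 4L, 1L, 2L))   # (rs|pq)
    gs <- aperm(g, c(1L, 2L, 4L, 3L))   # (pq|sr)
    dev <- max(abs(g - gp), abs(g - gr), abs(g - gs))
    if (dev > tol) stop(sprintf("g violates 8-fold symmetry (max deviation %.3e)", dev))
  }
  structure(list(E_core = as.numeric(E_core), h = h, g = g, M = M),
            class = "qsci_ints")
}

#' @export
print.qsci_ints <- function(x, ...) {
  cat(sprintf("<qsci_ints> M = %d orbitals, E_core = %.8f, max|h| = %.4f, max|g| = %.4f\n",
              x$M, x$E_core, max(abs(x$h)), max(abs(x$g))))
  invisible(x)
}
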