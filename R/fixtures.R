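# Synthetic FCIDUMP fixture generator.  All fixtures are self-contained
# synthetic integral sets (no external chemistry code needed): small enough
# to diagonalize exactly, with non-trivial but bounded off-diagonal
# couplings so that every pipeline stage has something to do.

# H2-scale two-orbital toy integrals (minimal-basis-like magnitudes)
.toy2_ints <- function(g_scale = 1) {
  h <- diag(c(-1.2524, -0.4759))
  g <- array(0, rep(2L, 4L))
  g[1, 1, 1, 1] <- 0.6746
  g[2, 2, 2, 2] <- 0.6975
  g[1, 1, 2, 2] <- 0.6636; g[2, 2, 1, 1] <- 0.6636
  idx <- rbind(c(1, 2, 1, 2), c(2, 1, 1, 2), c(1, 2, 2, 1), c(2, 1, 2, 1))
  g[idx] <- 0.1813
  molecular_integrals(0.7137, h, g * g_scale)
}

# deterministic four-orbital chain with distance-decaying repulsion
.toy4_ints <- function(g_scale = 1) {
  M <- 4L
  h <- diag(c(-1.1, -0.7, -0.35, -0.15))
  for (p in 1:(M - 1L)) {
    h[p, p + 1L] <- -0.25
    h[p + 1L, p] <- -0.25
  }
  g <- array(0, rep(M, 4L))
  for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
    g[p, q, r, s] <- 0.5 * exp(-0.7 * (abs(p - q) + abs(r - s))) *
      exp(-0.3 * abs((p + q) - (r + s)) / 2)
  }
  molecular_integrals(0.52, h, g * g_scale)
}

# half-filled chain with on-site repulsion only
.hubbard_ints <- function(M, U = 2, t = 1, g_scale = 1) {
  h <- matrix(0, M, M)
  for (p in 1:(M - 1L)) {
    h[p, p + 1L] <- -t
    h[p + 1L, p] <- -t
  }
  g <- array(0, rep(M, 4L))
  for (p in 1:M) g[p, p, p, p] <- U
  molecular_integrals(0, h, g * g_scale)
}

# random integrals with decaying off-diagonal magnitudes (8-fold symmetric
# by construction), so lambda stays bounded as M grows
.random_ints <- function(M, seed, g_scale = 1) {
  with_seed(seed, {
    h <- matrix(stats::rnorm(M * M, sd = 0.15), M)
    h <- (h + t(h)) / 2 * exp(-0.8 * abs(outer(1:M, 1:M, "-")))
    diag(h) <- sort(stats::rnorm(M, mean = -0.8, sd = 0.5))
    g <- array(stats::rnorm(M^4, sd = 0.2), rep(M, 4L))
    decay <- array(0, rep(M, 4L))
    for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
      decay[p, q, r, s] <- exp(-0.6 * (abs(p - q) + abs(r - s)))
    }
    g <- g * decay
    g <- (g + aperm(g, c(2L, 1L, 3L, 4L))) / 2
    g <- (g + aperm(g, c(1L, 2L, 4L, 3L))) / 2
    g <- (g + aperm(g, c(3L, 4L, 1L, 2L))) / 2
    for (p in 1:M) g[p, p, p, p] <- abs(g[p, p, p, p]) + 0.3
    molecular_integrals(stats::rnorm(1, sd = 0.2), h, g * g_scale)
  })
}

#' Generate a synthetic FCIDUMP fixture
#'
#' @param name one of `"toy2"` (two-orbital H2-scale toy), `"toy4"`
#'   (four-orbital chain), `"hubbard_like"` (hopping + on-site repulsion),
#'   `"random"` (seeded random integrals with decaying magnitudes)
#' @param path output FCIDUMP path
#' @param M spatial orbital count (fixed at 2 or 4 for the toys)
#' @param n_alpha,n_beta electron counts (defaults: half filling)
#' @param seed RNG seed (used by `"random"` only)
#' @param g_scale multiplier on the two-electron part (0 gives a
#'   non-interacting system)
#' @return `path`, invisibly; the file round-trips through [read_fcidump()]
#' @export
make_fixture <- function(name = c("toy2", "toy4", "hubbard_like", "random"),
                         path, M = NULL, n_alpha = NULL, n_beta = NULL,
                         seed = 1L, g_scale = 1) {
  name <- match.arg(name)
  M <- switch(name, toy2 = 2L, toy4 = 4L, as.integer(M))
  if (is.null(M) || is.na(M)) stop("M is required for this fixture type")
  if (M > 12L) stop("bundled fixtures are capped at M = 12")
  ints <- switch(name,
    toy2 = .toy2_ints(g_scale),
    toy4 = .toy4_ints(g_scale),
    hubbard_like = .hubbard_ints(M, g_scale = g_scale),
    random = .random_ints(M, seed, g_scale)
  )
  if (is.null(n_alpha)) n_alpha <- if (name == "toy2") 1L else M %/% 2L
  if (is.null(n_beta)) n_beta <- n_alpha
  basis <- spin_basis(M, n_alpha, n_beta)
  write_fcidump(basis, ints, path)
  invisible(path)
}
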