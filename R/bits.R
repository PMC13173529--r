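# Bit-mask utilities shared across the package.  Occupation masks are stored
# in base R integers (bit i = spatial orbital i), so M is limited to 30
# orbitals -- far beyond anything the in-memory solvers can handle anyway.

.qsci <- new.env(parent = emptyenv())

.popcount_table <- function() {
  tab <- .qsci$popcount_tab
  if (is.null(tab)) {
    b <- 0:65535
    tab <- integer(65536L)
    for (i in 0:15) tab <- tab + bitwAnd(bitwShiftR(b, i), 1L)
    .qsci$popcount_tab <- tab
  }
  tab
}

#' Count set bits of non-negative integers (vectorised)
#' @param x integer vector of masks (each < 2^30)
#' @return integer vector of set-bit counts
#' @keywords internal
popcount <- function(x) {
  tab <- .popcount_table()
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

# 0-based positions of set bits of a single mask
bits_of <- function(mask) {
  if (mask == 0L) return(integer(0))
  n <- 0L
  out <- integer(popcount(mask))
  j <- 1L
  while (mask != 0L) {
    if (bitwAnd(mask, 1L) == 1L) {
      out[j] <- n
      j <- j + 1L
    }
    mask <- bitwShiftR(mask, 1L)
    n <- n + 1L
  }
  out
}

mask_from_bits <- function(bits) {
  if (length(bits) == 0) return(0L)
  sum(bitwShiftL(1L, as.integer(bits)))
}

# count of set bits strictly between positions a and b (exclusive)
bits_between <- function(mask, a, b) {
  lo <- min(a, b)
  hi <- max(a, b)
  if (hi - lo < 2L) return(0L)
  window <- bitwAnd(bitwShiftL(1L, hi) - 1L, bitwNot(bitwShiftL(1L, lo + 1L) - 1L))
  popcount(bitwAnd(mask, window))
}
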