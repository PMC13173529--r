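# FCIDUMP reader/writer.  The dialect accepted: a namelist header starting
# with &FCI carrying NORB, NELEC, MS2 (comma- or whitespace-separated,
# unknown keys ignored), terminated by &END or /, followed by integral lines
# "value p q r s" with 1-based indices.  Lines with r = s = 0 carry
# one-electron integrals, the p = q = r = s = 0 line carries the core energy,
# and all other lines carry two-electron integrals in chemists' notation,
# expanded to the full 8-fold symmetric dense array on read.

#' Read an FCIDUMP integral file
#'
#' @param path file path
#' @return list with elements `basis` (a [spin_basis()]) and
#'   `ints` (a [molecular_integrals()])
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty FCIDUMP file: ", path)

  # ---- header ----
  header_end <- NA_integer_
  header_txt <- character(0)
  for (i in seq_along(lines)) {
    header_txt <- c(header_txt, lines[i])
    if (grepl("(&END|/\\s*$)", lines[i], ignore.case = TRUE)) {
      header_end <- i
      break
    }
  }
  if (is.na(header_end)) stop("FCIDUMP header not terminated by &END or / : ", path)
  hdr <- paste(header_txt, collapse = " ")
  if (!grepl("&FCI", hdr, ignore.case = TRUE)) {
    stop("line 1: FCIDUMP header must start with &FCI")
  }
  grab <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*(-?[0-9]+)"), hdr,
                                 ignore.case = TRUE))[[1]]
    if (length(m) < 2L) stop("FCIDUMP header missing ", key)
    as.integer(m[2L])
  }
  norb <- grab("NORB")
  nelec <- grab("NELEC")
  ms2 <- tryCatch(grab("MS2"), error = function(e) 0L)
  if ((nelec + ms2) %% 2L != 0L) {
    stop(sprintf("line 1: NELEC=%d and MS2=%d have incompatible parity", nelec, ms2))
  }
  n_alpha <- (nelec + ms2) %/% 2L
  n_beta <- (nelec - ms2) %/% 2L
  basis <- spin_basis(norb, n_alpha, n_beta)

  # ---- integral records ----
  h <- matrix(0, norb, norb)
  g <- array(0, rep(norb, 4L))
  E_core <- 0
  for (i in seq(header_end + 1L, length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (nchar(ln) == 0L) next
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) != 5L) {
      stop(sprintf("line %d: expected 'value p q r s', got %d fields", i, length(toks)))
    }
    val <- suppressWarnings(as.numeric(toks[1L]))
    idx <- suppressWarnings(as.integer(toks[2:5]))
    if (is.na(val) || anyNA(idx)) stop(sprintf("line %d: unparseable record '%s'", i, ln))
    if (any(idx > norb)) {
      stop(sprintf("line %d: orbital index %d exceeds NORB=%d", i, max(idx), norb))
    }
    p <- idx[1L]; q <- idx[2L]; r <- idx[3L]; s <- idx[4L]
    if (p == 0L && q == 0L && r == 0L && s == 0L) {
      E_core <- val
    } else if (r == 0L && s == 0L) {
      if (p == 0L || q == 0L) stop(sprintf("line %d: malformed one-electron record", i))
      h[p, q] <- val
      h[q, p] <- val
    } else {
      if (any(idx == 0L)) stop(sprintf("line %d: malformed two-electron record", i))
      g[p, q, r, s] <- val; g[q, p, r, s] <- val
      g[p, q, s, r] <- val; g[q, p, s, r] <- val
      g[r, s, p, q] <- val; g[s, r, p, q] <- val
      g[r, s, q, p] <- val; g[s, r, q, p] <- val
    }
  }
  list(basis = basis, ints = molecular_integrals(E_core, h, g, check = FALSE))
}

#' Write an FCIDUMP integral file
#'
#' Emits one canonical representative per 8-fold symmetry class
#' (`p >= q`, `r >= s`, `(p,q) >= (r,s)` in composite order), with 1-based
#' indices.  Symmetry of the inputs is enforced before anything is written.
#'
#' @param basis a [spin_basis()]
#' @param ints a [molecular_integrals()]
#' @param path output file path
#' @param tol integral drop/symmetry tolerance
#' @return `path`, invisibly
#' @export
write_fcidump <- function(basis, ints, path, tol = 1e-12) {
  M <- ints$M
  if (M != basis$M) stop("basis and integrals disagree on orbital count")
  if (max(abs(ints$h - t(ints$h))) > 1e-8) {
    stop("refusing to write: h is not symmetric within tolerance")
  }
  gp <- aperm(ints$g, c(2L, 1L, 3L, 4L))
  gr <- aperm(ints$g, c(3L, 4L, 1L, 2L))
  gs <- aperm(ints$g, c(1L, 2L, 4L, 3L))
  if (max(abs(ints$g - gp), abs(ints$g - gr), abs(ints$g - gs)) > 1e-8) {
    stop("refusing to write: g violates 8-fold symmetry")
  }

  con <- file(path, "w")
  on.exit(close(con))
  nelec <- basis$n_alpha + basis$n_beta
  ms2 <- basis$n_alpha - basis$n_beta
  writeLines(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", M, nelec, ms2), con)
  writeLines("  ORBSYM=" %+% paste(rep("1,", M), collapse = ""), con)
  writeLines(" &END", con)
  fmt <- function(val, p, q, r, s) sprintf(" %22.16E %4d %4d %4d %4d", val, p, q, r, s)
  out <- character(0)
  for (p in 1:M) for (q in 1:p) {
    pq <- p * (p - 1L) / 2L + q
    for (r in 1:p) for (s in 1:r) {
      rs <- r * (r - 1L) / 2L + s
      if (rs > pq) next
      val <- ints$g[p, q, r, s]
      if (abs(val) > tol) out <- c(out, fmt(val, p, q, r, s))
    }
  }
  for (p in 1:M) for (q in 1:p) {
    if (abs(ints$h[p, q]) > tol) out <- c(out, fmt(ints$h[p, q], p, q, 0L, 0L))
  }
  out <- c(out, fmt(ints$E_core, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
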