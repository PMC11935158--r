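# Reed-Solomon over GF(256), field polynomial 0x11D, generator element 2,
# first consecutive root alpha^0. Systematic encoding: codeword = message
# followed by parity. n parity symbols correct floor(n/2) symbol errors.

.gf <- new.env(parent = emptyenv())

gf_tables <- function() {
  if (is.null(.gf$exp)) {
    exp_t <- integer(510)
    log_t <- integer(256)
    x <- 1L
    for (i in 0:254) {
      exp_t[i + 1L] <- x
      log_t[x + 1L] <- i
      x <- bitwShiftL(x, 1L)
      if (bitwAnd(x, 0x100L) != 0L) x <- bitwXor(x, 0x11DL)
    }
    exp_t[256:510] <- exp_t[1:255]
    .gf$exp <- exp_t
    .gf$log <- log_t
  }
  .gf
}

gf_mul <- function(a, b) {
  g <- gf_tables()
  out <- integer(max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out))
  b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- g$exp[((g$log[a[nz] + 1L] + g$log[b[nz] + 1L]) %% 255L) + 1L]
  out
}

gf_div <- function(a, b) {
  g <- gf_tables()
  if (any(b == 0L)) stop("division by zero in GF(256)")
  out <- integer(length(a))
  nz <- a != 0L
  out[nz] <- g$exp[((g$log[a[nz] + 1L] - g$log[b + 1L] + 255L) %% 255L) + 1L]
  out
}

gf_inv <- function(a) gf_div(1L, a)

gf_pow2 <- function(i) {
  g <- gf_tables()
  g$exp[(as.integer(i) %% 255L) + 1L]
}

# Polynomials as integer vectors, highest-degree coefficient first.
gf_poly_scale <- function(p, x) gf_mul(p, rep(x, length(p)))

gf_poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  r <- integer(n)
  r[(n - length(p) + 1L):n] <- p
  r[(n - length(q) + 1L):n] <- bitwXor(r[(n - length(q) + 1L):n], q)
  r
}

gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    r[i:(i + length(q) - 1L)] <- bitwXor(r[i:(i + length(q) - 1L)],
                                         gf_mul(p[i], q))
  }
  r
}

gf_poly_eval <- function(p, x) {
  y <- p[1]
  for (i in seq_along(p)[-1]) y <- bitwXor(gf_mul(y, x)[1], p[i])
  y
}

rs_generator_poly <- function(n_parity) {
  g <- 1L
  for (i in 0:(n_parity - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow2(i)))
  g
}

as_bytes_int <- function(x) {
  if (is.raw(x)) return(as.integer(x))
  x <- as.integer(x)
  if (any(x < 0L | x > 255L)) stop("byte values must lie in 0..255", call. = FALSE)
  x
}

#' Reed-Solomon encode
#'
#' Systematic encoding over GF(256): the codeword is the message followed by
#' `n_parity` parity bytes, allowing correction of up to `floor(n_parity/2)`
#' corrupted bytes anywhere in the codeword. The codec's two protection
#' layers both use `n_parity = 2` (8 nt at 2 bits per base).
#'
#' @param message Raw vector or integers in 0..255; at most `255 - n_parity`
#'   bytes.
#' @param n_parity Number of parity bytes.
#' @return Integer vector: `c(message, parity)`.
#' @seealso [rs_decode()]
#' @export
rs_encode <- function(message, n_parity = 2L) {
  message <- as_bytes_int(message)
  n_parity <- as.integer(n_parity)
  if (length(message) + n_parity > 255L)
    stop("message too long: RS over GF(256) caps codewords at 255 bytes", call. = FALSE)
  gen <- rs_generator_poly(n_parity)
  rem <- c(message, integer(n_parity))
  for (i in seq_along(message)) {
    coef <- rem[i]
    if (coef != 0L) {
      idx <- i + seq_len(length(gen) - 1L)
      rem[idx] <- bitwXor(rem[idx], gf_mul(gen[-1], rep(coef, length(gen) - 1L)))
    }
  }
  c(message, rem[(length(message) + 1L):(length(message) + n_parity)])
}

rs_syndromes <- function(codeword, n_parity) {
  vapply(0:(n_parity - 1L),
         function(i) gf_poly_eval(codeword, gf_pow2(i)),
         integer(1))
}

# Berlekamp-Massey: error locator polynomial from syndromes.
rs_error_locator <- function(synd) {
  err_loc <- 1L
  old_loc <- 1L
  for (i in seq_along(synd)) {
    delta <- synd[i]
    L <- length(err_loc)
    if (L >= 2L) for (j in seq_len(L - 1L)) {
      if (i - j >= 1L)
        delta <- bitwXor(delta, gf_mul(err_loc[L - j], synd[i - j])[1])
    }
    old_loc <- c(old_loc, 0L)
    if (delta != 0L) {
      if (length(old_loc) > length(err_loc)) {
        new_loc <- gf_poly_scale(old_loc, delta)
        old_loc <- gf_poly_scale(err_loc, gf_inv(delta))
        err_loc <- new_loc
      }
      err_loc <- gf_poly_add(err_loc, gf_poly_scale(old_loc, delta))
    }
  }
  while (length(err_loc) > 1L && err_loc[1] == 0L) err_loc <- err_loc[-1]
  err_loc
}

#' Reed-Solomon decode
#'
#' Corrects up to `floor(n_parity/2)` corrupted bytes. Uncorrectable
#' codewords are reported, never silently mis-decoded: the result carries
#' `ok = FALSE` whenever the syndrome equations cannot be satisfied.
#'
#' @param codeword Raw vector or integers in 0..255 (message plus parity).
#' @param n_parity Number of parity bytes used at encode time.
#' @return A list with `ok` (logical), `message` (integer vector, `NULL` on
#'   failure), and `n_corrected` (number of corrected bytes).
#' @export
rs_decode <- function(codeword, n_parity = 2L) {
  cw <- as_bytes_int(codeword)
  n_parity <- as.integer(n_parity)
  n <- length(cw)
  if (n <= n_parity) stop("codeword shorter than its parity region", call. = FALSE)
  fail <- list(ok = FALSE, message = NULL, n_corrected = NA_integer_)
  synd <- rs_syndromes(cw, n_parity)
  if (all(synd == 0L))
    return(list(ok = TRUE, message = cw[seq_len(n - n_parity)], n_corrected = 0L))
  loc <- rs_error_locator(synd)
  n_err <- length(loc) - 1L
  if (n_err == 0L || 2L * n_err > n_parity) return(fail)
  # Chien search: alpha^j is a root of the reversed locator iff an error sits
  # at the term of degree j (position n-1-j from the left).
  rloc <- rev(loc)
  pos <- integer(0)
  for (i in 0:(n - 1L)) {
    if (gf_poly_eval(rloc, gf_pow2(i)) == 0L) pos <- c(pos, n - 1L - i)
  }
  if (length(pos) != n_err) return(fail)
  # Solve the syndrome linear system for error magnitudes over GF(256):
  # S_k = sum_i e_i * alpha^(j_i * k), with j_i the term degree of position i.
  deg <- n - 1L - pos
  A <- matrix(0L, nrow = n_err, ncol = n_err)
  for (k in seq_len(n_err)) A[k, ] <- gf_pow2(deg * (k - 1L))
  mag <- gf_solve(A, synd[seq_len(n_err)])
  if (is.null(mag)) return(fail)
  cw2 <- cw
  cw2[pos + 1L] <- bitwXor(cw2[pos + 1L], mag)
  if (any(rs_syndromes(cw2, n_parity) != 0L)) return(fail)
  list(ok = TRUE, message = cw2[seq_len(n - n_parity)], n_corrected = n_err)
}

# Gaussian elimination over GF(256); returns NULL if singular.
gf_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (col in seq_len(n)) {
    piv <- which(M[col:n, col] != 0L)
    if (length(piv) == 0L) return(NULL)
    piv <- piv[1] + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- gf_div(M[col, ], M[col, col])
    for (r in seq_len(n)) {
      if (r != col && M[r, col] != 0L)
        M[r, ] <- bitwXor(M[r, ], gf_mul(M[col, ], rep(M[r, col], ncol(M))))
    }
  }
  M[, n + 1L]
}
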