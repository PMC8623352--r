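#' Wigner 3-j symbol
#'
#' Racah closed-form evaluation of the Wigner 3-j symbol. Arguments may be
#' integers or half-integers; the symbol is zero unless the usual triangle
#' and projection conditions hold.
#'
#' @param j1,j2,j3 Angular momenta (non-negative, integer or half-integer).
#' @param m1,m2,m3 Projections.
#' @return The value of the 3-j symbol (a length-1 numeric).
#' @export
#' @examples
#' wigner3j(1, 2, 1, -1, 0, 1)
wigner3j <- function(j1, j2, j3, m1, m2, m3) {
  stopifnot(length(j1) == 1L)
  if (!is_half_integer(c(j1, j2, j3, m1, m2, m3))) {
    stop("wigner3j: arguments must be integers or half-integers")
  }
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3) return(0)
  if (abs(m1 + m2 + m3) > 1e-9) return(0)
  if (!triangle_ok(j1, j2, j3)) return(0)
  # projections must differ from j by integers
  if (!is_integerish(c(j1 - m1, j2 - m2, j3 - m3))) return(0)

  lf <- function(n) lgamma(round(n) + 1)
  delta <- 0.5 * (lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
                    lf(j1 + j2 + j3 + 1))
  pref <- 0.5 * (lf(j1 + m1) + lf(j1 - m1) + lf(j2 + m2) + lf(j2 - m2) +
                   lf(j3 + m3) + lf(j3 - m3))
  tmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  tmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  if (tmax < tmin) return(0)
  s <- 0
  for (t in seq(tmin, tmax)) {
    lt <- lf(t) + lf(j3 - j2 + t + m1) + lf(j3 - j1 + t - m2) +
      lf(j1 + j2 - j3 - t) + lf(j1 - t - m1) + lf(j2 - t + m2)
    s <- s + (-1)^round(t) * exp(delta + pref - lt)
  }
  (-1)^round(j1 - j2 - m3) * s
}

#' Wigner 6-j symbol
#'
#' Racah closed-form evaluation of the Wigner 6-j symbol
#' \{j1 j2 j3; j4 j5 j6\}.
#'
#' @param j1,j2,j3,j4,j5,j6 Angular momenta (integer or half-integer).
#' @return The value of the 6-j symbol.
#' @export
#' @examples
#' wigner6j(1, 1, 1, 1, 1, 1)  # 1/6
wigner6j <- function(j1, j2, j3, j4, j5, j6) {
  if (!is_half_integer(c(j1, j2, j3, j4, j5, j6))) {
    stop("wigner6j: arguments must be integers or half-integers")
  }
  triads <- list(c(j1, j2, j3), c(j1, j5, j6), c(j4, j2, j6), c(j4, j5, j3))
  for (tr in triads) {
    if (!triangle_ok(tr[1], tr[2], tr[3])) return(0)
    if (!is_integerish(sum(tr))) return(0)
  }
  lf <- function(n) lgamma(round(n) + 1)
  tri <- function(a, b, c) {
    0.5 * (lf(a + b - c) + lf(a - b + c) + lf(-a + b + c) - lf(a + b + c + 1))
  }
  w <- tri(j1, j2, j3) + tri(j1, j5, j6) + tri(j4, j2, j6) + tri(j4, j5, j3)
  a1 <- j1 + j2 + j3; a2 <- j1 + j5 + j6; a3 <- j4 + j2 + j6; a4 <- j4 + j5 + j3
  b1 <- j1 + j2 + j4 + j5; b2 <- j2 + j3 + j5 + j6; b3 <- j3 + j1 + j6 + j4
  tmin <- max(a1, a2, a3, a4)
  tmax <- min(b1, b2, b3)
  if (tmax < tmin) return(0)
  s <- 0
  for (t in seq(tmin, tmax)) {
    lt <- lf(t - a1) + lf(t - a2) + lf(t - a3) + lf(t - a4) +
      lf(b1 - t) + lf(b2 - t) + lf(b3 - t)
    s <- s + (-1)^round(t) * exp(w + lf(t + 1) - lt)
  }
  s
}

#' Clebsch-Gordan coefficient <j1 m1 j2 m2 | J M>
#'
#' @param j1,m1,j2,m2 Coupled angular momenta and projections.
#' @param J,M Resultant angular momentum and projection.
#' @return The vector-coupling coefficient.
#' @export
clebsch_gordan <- function(j1, m1, j2, m2, J, M) {
  (-1)^round(j1 - j2 + M) * sqrt(2 * J + 1) * wigner3j(j1, j2, J, m1, m2, -M)
}

## Closed-form Clebsch-Gordan <J k 1 q | Jp kq> for dipole couplings,
## vectorised over k (Condon-Shortley phases). Used on hot paths where the
## general Racah sum would dominate runtime.
cg_dipole <- function(J, k, q, Jp) {
  kq <- k + q
  out <- numeric(length(k))
  ok <- abs(k) <= J & abs(kq) <= Jp
  k <- k[ok]; kq <- kq[ok]
  val <- if (Jp == J + 1) {
    if (q == 0) {
      sqrt(((J + 1)^2 - k^2) / ((J + 1) * (2 * J + 1)))
    } else if (q == 1) {
      sqrt((J + k + 1) * (J + k + 2) / ((2 * J + 1) * (2 * J + 2)))
    } else {
      sqrt((J - k + 1) * (J - k + 2) / ((2 * J + 1) * (2 * J + 2)))
    }
  } else if (Jp == J) {
    if (J == 0) {
      rep(0, length(k))
    } else if (q == 0) {
      k / sqrt(J * (J + 1))
    } else if (q == 1) {
      -sqrt((J - k) * (J + k + 1) / (2 * J * (J + 1)))
    } else {
      sqrt((J + k) * (J - k + 1) / (2 * J * (J + 1)))
    }
  } else if (Jp == J - 1) {
    if (q == 0) {
      -sqrt((J^2 - k^2) / (J * (2 * J + 1)))
    } else if (q == 1) {
      sqrt((J - k) * (J - k - 1) / (2 * J * (2 * J + 1)))
    } else {
      sqrt((J + k) * (J + k - 1) / (2 * J * (2 * J + 1)))
    }
  } else {
    stop("cg_dipole: |J' - J| must be <= 1")
  }
  out[ok] <- val
  out
}

is_half_integer <- function(x) all(abs(2 * x - round(2 * x)) < 1e-9)
is_integerish <- function(x) all(abs(x - round(x)) < 1e-9)
triangle_ok <- function(a, b, c) (c >= abs(a - b) - 1e-9) && (c <= a + b + 1e-9)
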