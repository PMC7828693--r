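# Vectorized exact rational arithmetic on integer-valued doubles.
#
# Stoichiometric coefficients and the packaged accounting fluxes are exact
# halves and small integers; all mass-balance audits and the accounting
# verification run in this arithmetic so "exact" means exact, not
# within-epsilon. Numerators/denominators are stored in doubles and guarded
# well below 2^53 so every operation stays integral.

RAT_GUARD <- 2^48

rat <- function(num, den = rep(1, length(num))) {
  if (any(den == 0)) stop("rational with zero denominator", call. = FALSE)
  rat_reduce(list(num = as.numeric(num), den = as.numeric(den)))
}

rat_gcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(t != 0, t, a)
  }
  ifelse(a == 0, 1, a)
}

rat_reduce <- function(x) {
  if (any(abs(x$num) > RAT_GUARD) || any(abs(x$den) > RAT_GUARD)) {
    stop("rational arithmetic overflow guard exceeded", call. = FALSE)
  }
  s <- ifelse(x$den < 0, -1, 1)
  num <- x$num * s
  den <- x$den * s
  g <- rat_gcd(num, den)
  list(num = num / g, den = den / g)
}

rat_add <- function(x, y) {
  rat_reduce(list(num = x$num * y$den + y$num * x$den, den = x$den * y$den))
}

rat_sub <- function(x, y) rat_add(x, list(num = -y$num, den = y$den))

rat_mul <- function(x, y) {
  # cross-reduce before multiplying to keep magnitudes small
  g1 <- rat_gcd(x$num, y$den)
  g2 <- rat_gcd(y$num, x$den)
  rat_reduce(list(
    num = (x$num / g1) * (y$num / g2),
    den = (x$den / g2) * (y$den / g1)
  ))
}

rat_sum <- function(x) {
  out <- list(num = 0, den = 1)
  for (i in seq_along(x$num)) {
    out <- rat_add(out, list(num = x$num[i], den = x$den[i]))
  }
  out
}

rat_as_numeric <- function(x) x$num / x$den

rat_is_zero <- function(x) x$num == 0

rat_format <- function(x) {
  ifelse(x$den == 1, format(x$num, scientific = FALSE),
         paste0(format(x$num, scientific = FALSE), "/",
                format(x$den, scientific = FALSE)))
}

# Best rational approximation of a numeric vector by continued fractions,
# with a hard error if the value is not (close to) a small rational. Bounds
# and user parameters enter the exact arithmetic path through this gate.
rat_approx <- function(x, max_den = 1e6, tol = 1e-9) {
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    target <- x[i]
    h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
    b <- target
    repeat {
      a <- floor(b)
      h <- a * h1 + h0; k <- a * k1 + k0
      if (k > max_den) break
      h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
      if (abs(target - h / k) < .Machine$double.eps * max(1, abs(target))) break
      b <- 1 / (b - a)
      if (!is.finite(b)) break
    }
    num[i] <- h1; den[i] <- k1
    if (abs(target - h1 / k1) > tol) {
      stop("value ", target, " is not a small rational", call. = FALSE)
    }
  }
  rat(num, den)
}

# Exact Gaussian elimination with partial (first nonzero) pivoting for small
# square rational systems A x = b. Used for unit-cycle flux solves and the
# brute-force vertex enumerator.
rat_solve <- function(Anum, Aden, bnum, bden) {
  n <- nrow(Anum)
  stopifnot(ncol(Anum) == n, length(bnum) == n)
  # augmented matrix rows as rational vectors
  M <- lapply(seq_len(n), function(i) {
    list(num = c(Anum[i, ], bnum[i]), den = c(Aden[i, ], bden[i]))
  })
  for (col in seq_len(n)) {
    piv <- NULL
    for (r in col:n) if (M[[r]]$num[col] != 0) { piv <- r; break }
    if (is.null(piv)) return(NULL) # singular
    tmp <- M[[col]]; M[[col]] <- M[[piv]]; M[[piv]] <- tmp
    p <- list(num = M[[col]]$num[col], den = M[[col]]$den[col])
    M[[col]] <- rat_mul(M[[col]], list(num = rep(p$den, n + 1),
                                       den = rep(p$num, n + 1)))
    for (r in seq_len(n)) {
      if (r == col || M[[r]]$num[col] == 0) next
      f <- list(num = M[[r]]$num[col], den = M[[r]]$den[col])
      M[[r]] <- rat_sub(M[[r]], rat_mul(M[[col]],
                                        list(num = rep(f$num, n + 1),
                                             den = rep(f$den, n + 1))))
    }
  }
  list(num = vapply(M, function(r) r$num[n + 1], numeric(1)),
       den = vapply(M, function(r) r$den[n + 1], numeric(1)))
}

#' Parse exact rational numbers from text
#'
#' Accepts integers (`"2"`, `"-1"`), fractions (`"1/2"`, `"-3/2"`) and finite
#' decimals (`"0.5"`); each is converted to an exactly reduced
#' numerator/denominator pair. Used wherever the package reads stoichiometric
#' coefficients or flux values from text, so that no decimal round-off enters
#' the mass-balance arithmetic.
#'
#' @param x Character vector of numbers.
#' @return A list with components `num` and `den` (numeric vectors of the same
#'   length as `x`, representing reduced fractions with positive denominator).
#' @examples
#' vickerflux:::rat_parse(c("1/2", "0.5", "-3"))
#' @keywords internal
#' @noRd
rat_parse <- function(x) {
  x <- trimws(x)
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed rational: '", s, "'", call. = FALSE)
      num[i] <- suppressWarnings(as.numeric(parts[1]))
      den[i] <- suppressWarnings(as.numeric(parts[2]))
    } else if (grepl(".", s, fixed = TRUE)) {
      parts <- strsplit(s, ".", fixed = TRUE)[[1]]
      frac <- parts[2]
      scale <- 10^nchar(frac)
      num[i] <- suppressWarnings(as.numeric(gsub(".", "", s, fixed = TRUE)))
      den[i] <- scale
    } else {
      num[i] <- suppressWarnings(as.numeric(s))
      den[i] <- 1
    }
    if (is.na(num[i]) || is.na(den[i])) {
      stop("malformed rational: '", s, "'", call. = FALSE)
    }
    if (num[i] != round(num[i]) || den[i] != round(den[i])) {
      stop("non-integral rational parts in '", s, "'", call. = FALSE)
    }
  }
  rat(num, den)
}
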