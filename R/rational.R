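# Exact-rational helpers for stoichiometric bookkeeping.
#
# Table-style reaction coefficients are short decimals (12.25, 3.75, 0.5);
# element/charge balance must distinguish "exactly zero" from floating drift,
# so coefficients are carried as integer numerator/denominator pairs and
# residuals are accumulated over a common denominator in exact integer
# arithmetic (well within the 2^53 exact-integer range of doubles).

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

.lcm2 <- function(a, b) a / .gcd(a, b) * b

# Parse decimal-string or numeric coefficients to reduced num/den pairs.
# Numerics are accepted only when they are exactly a short decimal (up to 6
# places), which covers every coefficient this domain prints; anything else
# is a construction error, not something to round silently.
as_rational <- function(x) {
  if (is.numeric(x)) x <- vapply(x, format_exact_decimal, character(1))
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^([+-]?)([0-9]+)(?:\\.([0-9]+))?$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    abort(sprintf("coefficient(s) not exact decimal rationals: %s",
                  paste(x[bad], collapse = ", ")))
  }
  parse1 <- function(p) {
    sign <- if (p[[2]] == "-") -1 else 1
    frac <- p[[4]]
    den <- 10^nchar(frac)
    num <- sign * (as.numeric(p[[3]]) * den +
                     if (nzchar(frac)) as.numeric(frac) else 0)
    g <- max(.gcd(num, den), 1)
    c(num = num / g, den = den / g)
  }
  out <- t(vapply(m, parse1, c(num = 0, den = 0)))
  tibble(num = out[, "num"], den = out[, "den"])
}

format_exact_decimal <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (abs(as.numeric(s) - x) > 0) {
    abort(sprintf("coefficient %.17g is not an exact short decimal", x))
  }
  s
}

# Exact signed sum of rational coefficients times integer weights.
# Returns the sum as a reduced rational (num, den); num == 0 <=> exact zero.
rational_weighted_sum <- function(num, den, weight) {
  stopifnot(length(num) == length(den), length(num) == length(weight))
  if (length(num) == 0L) return(c(num = 0, den = 1))
  den_common <- Reduce(.lcm2, den)
  total <- sum(num * (den_common / den) * weight)
  g <- max(.gcd(total, den_common), 1)
  c(num = total / g, den = den_common / g)
}
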