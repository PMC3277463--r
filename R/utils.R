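# Small shared helpers: exact rational coefficients, seeded evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

.gcd_v <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return(1)
  Reduce(.gcd2, abs(x))
}

.lcm2 <- function(a, b) a / .gcd2(a, b) * b

.lcm_v <- function(x) Reduce(.lcm2, abs(x))

#' Parse a stoichiometric coefficient exactly
#'
#' Coefficients in published reaction strings can be integers, decimals
#' (biomass equations) or explicit fractions. They are stored as reduced
#' integer numerator/denominator pairs so that all balancing arithmetic is
#' exact; the numeric value is carried alongside for display and LP use.
#'
#' @param text coefficient text, e.g. `"2"`, `"0.05"`, `"1/3"`; `""` means 1.
#' @return numeric vector `c(num, den)` with `den > 0` and `gcd(num, den) = 1`.
#' @keywords internal
parse_coef <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(c(num = 1, den = 1))
  if (grepl("^[0-9]+$", text)) return(c(num = as.numeric(text), den = 1))
  m <- regmatches(text, regexec("^([0-9]+)/([0-9]+)$", text))[[1]]
  if (length(m) == 3) {
    num <- as.numeric(m[2]); den <- as.numeric(m[3])
    if (den == 0) stop("zero denominator in coefficient: ", text, call. = FALSE)
    g <- .gcd2(num, den)
    return(c(num = num / g, den = den / g))
  }
  m <- regmatches(text, regexec("^([0-9]*)\\.([0-9]+)$", text))[[1]]
  if (length(m) == 3) {
    whole <- if (nzchar(m[2])) as.numeric(m[2]) else 0
    frac <- m[3]
    den <- 10^nchar(frac)
    num <- whole * den + as.numeric(frac)
    g <- .gcd2(num, den)
    return(c(num = num / g, den = den / g))
  }
  stop("cannot parse coefficient: '", text, "'", call. = FALSE)
}

# Render a reduced rational as text ("2", "1/3").
fmt_coef <- function(num, den) {
  if (den == 1) format(num, scientific = FALSE) else paste0(num, "/", den)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
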