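# Independent brute-force oracles, kept deliberately separate from the
# implementations they check.

# Two-pass mean/variance evaluation of the CV (percent).
cv_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  100 * sqrt(v) / m
}

# Explicit-sums product-moment formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

fixtures <- load_published_tables()
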