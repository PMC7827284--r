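# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately share no code with the package.

# Naive O(n) sliding-window TA scan.
ta_brute <- function(s) {
  s <- toupper(s)
  if (nchar(s) < 2) return(integer(0))
  hits <- vapply(seq_len(nchar(s) - 1), function(i) {
    substr(s, i, i + 1) == "TA"
  }, logical(1))
  which(hits) - 1L
}

# Poisson-binomial upper tail by full outcome enumeration (n <= ~14).
pb_tail_enum <- function(probs, k) {
  n <- length(probs)
  if (k <= 0) return(1)
  if (k > n) return(0)
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  pr <- apply(grid, 1, function(x) prod(ifelse(x == 1, probs, 1 - probs)))
  sum(pr[rowSums(grid) >= k])
}

# Textbook Yates chi-square from the four cells.
yates_by_hand <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, c, b, d), 2)
  sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
}

# Random DNA string.
random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
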