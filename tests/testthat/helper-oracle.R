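# Naive window-scan word-count oracle, independent of the package's
# compiled counting path: enumerate every window with substring() and keep
# those made only of A/C/G/T.
naiveCountWords <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence too short")
  windows <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", windows)
  list(counts = table(windows[ok]), usable = sum(ok))
}

# random sequence over ACGT, optionally salted with ambiguity codes
randomSeq <- function(n, pN = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (pN > 0) {
    amb <- sample(c("N", "R", "Y"), n, replace = TRUE)
    pick <- runif(n) < pN
    s[pick] <- amb[pick]
  }
  paste(s, collapse = "")
}

randomWord <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                                collapse = "")

# small annotated synthetic chromosome used across test files
makeAnnotatedChromosome <- function(lengthBp = 3e5, seed = 1,
                                    word = NULL, ratePerMb = 0) {
  planted <- if (is.null(word)) NULL else
    data.frame(word = word, ratePerMb = ratePerMb)
  sp <- syntheticSpec(lengthBp, gc = 0.5, planted = planted, seed = seed)
  generateSyntheticChromosome(sp)
}
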