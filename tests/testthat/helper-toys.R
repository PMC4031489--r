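# small builders used across test files

toy_keys <- function(n, chrom = "chr1") {
  normalize_key(chrom, seq(100L, by = 100L, length.out = n),
                rep(c("A", "C", "G", "T"), length.out = n),
                rep(c("G", "T", "A", "C"), length.out = n))
}

# callset from a named list sample -> carried key indices
toy_callset <- function(keys, carriers, callers = "one") {
  samples <- names(carriers)
  m <- matrix(FALSE, nrow(keys), length(samples),
              dimnames = list(keys$key, samples))
  for (s in samples) m[carriers[[s]], s] <- TRUE
  cohort_callset(keys, samples,
                 stats::setNames(rep(list(m), length(callers)), callers))
}

trio_ped <- function() {
  pedigree(
    id = c("mom", "dad", "kid", "aunt"),
    sex = c("female", "male", "female", "female"),
    father_id = c(NA, NA, "dad", NA),
    mother_id = c(NA, NA, "mom", NA),
    affected = c(TRUE, FALSE, TRUE, FALSE)
  )
}

# naive point-in-interval scan, the oracle for annotate_context
naive_context <- function(keys, track) {
  iv <- track$intervals
  vapply(seq_len(nrow(keys)), function(i) {
    for (j in seq_len(nrow(iv))) {
      if (keys$chrom[i] == iv$chrom[j] &&
          keys$pos[i] >= iv$start[j] && keys$pos[i] <= iv$end[j]) {
        return(iv$label[j])
      }
    }
    NA_character_
  }, character(1))
}

# brute-force two-sided exact p: direct probability products, no log space
brute_fisher_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d; r1 <- a + b; c1 <- a + c
  probs <- c()
  for (x in 0:n) {
    bb <- r1 - x; cc <- c1 - x; dd <- n - r1 - cc
    if (bb < 0 || cc < 0 || dd < 0) next
    probs[as.character(x)] <-
      choose(r1, x) * choose(n - r1, cc) / choose(n, c1)
  }
  p_obs <- probs[[as.character(a)]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
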