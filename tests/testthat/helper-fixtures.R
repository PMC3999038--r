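# Shared fixture builders; everything is generated in code.

# concrete expansion of a degenerate primer with wildcards filled
concrete_expansion <- function(primer_seq, fill = "G", k = 1L) {
  gsub("N", fill, expand_degenerate(primer_seq)[k])
}

random_nt <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 4-taxon alignment: n_const constant columns, n1 columns supporting
# the AB|CD split, n2 supporting AC|BD
four_taxon_msa <- function(n_const, n1, n2) {
  c(A = paste(c(rep("A", n_const), rep("A", n1), rep("A", n2)), collapse = ""),
    B = paste(c(rep("A", n_const), rep("A", n1), rep("T", n2)), collapse = ""),
    C = paste(c(rep("A", n_const), rep("T", n1), rep("A", n2)), collapse = ""),
    D = paste(c(rep("A", n_const), rep("T", n1), rep("T", n2)), collapse = ""))
}

# additive distance matrix of the tree ((A:1,B:2):1,(C:3,D:4))
additive_4taxon <- function() {
  matrix(c(0, 3, 5, 6,
           3, 0, 6, 7,
           5, 6, 0, 7,
           6, 7, 7, 0), 4, 4,
         dimnames = list(LETTERS[1:4], LETTERS[1:4]))
}

# independent resampling oracle for the 4-taxon bootstrap: resamples
# column-type counts and decides the split by the informative majority,
# never touching the alignment or NJ machinery
bootstrap_oracle <- function(n_const, n1, n2, replicates, seed) {
  set.seed(seed)
  n <- n_const + n1 + n2
  hits <- replicate(replicates, {
    x <- stats::rmultinom(1, n, c(n_const, n1, n2) / n)
    x[2] > x[3]
  })
  100 * mean(hits)
}
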