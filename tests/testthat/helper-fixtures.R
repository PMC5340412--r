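# shared fixtures, built in code

# tiny 3-taxon x 4-sample count table
tiny_table <- function() {
  vals <- matrix(c(5, 0, 3,
                   2, 1, 4,
                   7, 2, 0,
                   1, 3, 2), nrow = 3)
  otu_table(vals, c("otuA", "otuB", "otuC"), sample_days = c(1, 2, 4, 5))
}

# TSV fixture on disk matching the tiny table layout
tiny_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "taxon_id\ts1\ts2\ts3\ts4",
    "#day\t1\t2\t4\t5",
    "otuA\t5\t2\t7\t1",
    "otuB\t0\t1\t2\t3",
    "otuC\t3\t4\t0\t2"
  ), path)
  path
}

# positive mean-reverting AR(1) trajectories as a fraction-free table
ar1_table <- function(n = 20, m = 300, phi = 0.3, level = 0.02,
                      scale = 0.005, seed = 1) {
  set.seed(seed)
  vals <- t(vapply(seq_len(n), function(i) {
    pmax(level + scale * as.numeric(stats::arima.sim(list(ar = phi), m)), 0)
  }, numeric(m)))
  otu_table(vals, sprintf("t%02d", seq_len(n)), seq_len(m))
}

# one-off JSD by the definition (independent of the package implementation)
jsd_reference <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log(a[keep] / b[keep]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# aligned FASTA with balanced base composition and a known number of
# differences between the first two sequences
write_test_alignment <- function(path = tempfile(fileext = ".fasta"),
                                 len = 300, n_diff = 30) {
  base <- rep(c("a", "c", "g", "t"), length.out = len)
  s1 <- base
  s2 <- base
  # transversion-style changes at evenly spaced sites
  swap <- c(a = "c", c = "a", g = "t", t = "g")
  idx <- seq(1, len, length.out = n_diff)
  s2[idx] <- swap[s2[idx]]
  writeLines(c(">seqA", paste(s1, collapse = ""),
               ">seqB", paste(s2, collapse = ""),
               ">seqC", paste(s1, collapse = "")), path)
  path
}
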