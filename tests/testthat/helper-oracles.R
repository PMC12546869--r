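# Independent brute-force oracles used across the suite.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration over the
# support; N = background, K = annotated, n = study draw.
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random peptidoform for round-trip/property tests
random_peptidoform <- function() {
  aas <- c("G", "A", "S", "P", "V", "T", "L", "N", "D", "Q", "K", "E",
           "H", "F", "R", "Y", "W")
  n <- sample(5:20, 1)
  seq <- paste(sample(aas, n, replace = TRUE), collapse = "")
  p <- modified_peptide(seq)
  k_pos <- which(strsplit(seq, "")[[1]] == "K")
  mods <- c("propionyl", "methyl", "dimethyl", "trimethyl",
            "propionyl-methyl")
  for (i in k_pos) {
    if (runif(1) < 0.7) {
      p <- ptmstoich:::.set_mod(p, i, sample(mods, 1))
    }
  }
  p
}

make_methyl_records <- function(areas, sample = "s", replicate = 1,
                                charge = NULL) {
  x <- data.frame(form_id = names(areas), area = unname(areas),
                  sample = sample, replicate = replicate,
                  stringsAsFactors = FALSE)
  if (!is.null(charge)) x$charge <- charge
  x
}
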