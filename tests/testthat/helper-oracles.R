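# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed forms, brute-force enumeration, and
# direct arithmetic.

# Balanced one-way ANOVA closed form for the random-intercept model:
# q groups of r observations; REML optimum equals the method-of-moments
# solution sigma2_b = (MSB - MSW) / r (when positive), sigma2_e = MSW.
anova_oracle <- function(y, group) {
  group <- factor(group)
  r <- as.vector(table(group))[1]
  means <- tapply(y, group, mean)
  msb <- r * sum((means - mean(y))^2) / (nlevels(group) - 1)
  msw <- sum((y - means[group])^2) / (length(y) - nlevels(group))
  list(sigma2_b = max((msb - msw) / r, 0), sigma2_e = msw,
       msb = msb, msw = msw)
}

# Hypergeometric upper-tail P(X >= x) by direct summation of choose() terms
# (the one-sided Fisher p for overrepresentation).
hyper_tail_oracle <- function(x, K, N, n) {
  hi <- min(K, n)
  if (x > hi) return(0)
  ks <- x:hi
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Step-up Benjamini-Hochberg by its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# A small balanced design: q trees with r replicates each, trees split
# between two provenances/sites, one date.
balanced_samples <- function(q = 10, r = 4) {
  data.frame(
    library_id = sprintf("L%03d", seq_len(q * r)),
    TREE = rep(sprintf("T%02d", seq_len(q)), each = r),
    PROVENANCE = rep(rep(c("AR", "LA"), each = q / 2), each = r),
    SITE = "s1", DATE = "d1",
    stringsAsFactors = FALSE
  )
}

# Tiny diamond ontology: root -> a, b; a,b -> c (diamond); c -> leaf.
diamond_ontology <- function() {
  structure(list(
    terms = data.frame(
      id = c("GO:r", "GO:a", "GO:b", "GO:c", "GO:d", "GO:leaf"),
      name = c("root", "a", "b", "c", "d", "leaf"),
      namespace = "biological_process", stringsAsFactors = FALSE),
    parents = list(
      "GO:r" = character(0), "GO:a" = "GO:r", "GO:b" = "GO:r",
      "GO:c" = c("GO:a", "GO:b"), "GO:d" = "GO:b",
      "GO:leaf" = c("GO:c", "GO:d"))
  ), class = "plast_ontology")
}

small_config <- function(...) {
  sim_config(n_trees_per_provenance = 16, n_transcripts = 60, ...)
}
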