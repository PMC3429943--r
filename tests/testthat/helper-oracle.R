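# Independent brute-force oracle for sibling-set likelihoods.
#
# Sums over ordered parental allele 4-tuples (f1, f2, m1, m2) drawn from an
# explicit full allele universe whose frequencies sum to 1 — a different
# decomposition from the package engine (which sums over unordered parental
# genotypes with HWE priors and aggregates unobserved mass into a
# pseudo-allele), so agreement is a real cross-check.

oracle_sib_lik <- function(genotypes, p) {
  stopifnot(abs(sum(p) - 1) < 1e-12)
  al <- names(p)
  m <- length(al)
  gr <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m), seq_len(m)))
  pr <- p[gr[, 1]] * p[gr[, 2]] * p[gr[, 3]] * p[gr[, 4]]
  for (ch in genotypes) {
    x <- match(ch[1], al); y <- match(ch[2], al)
    stopifnot(!is.na(x), !is.na(y))
    tfx <- ((gr[, 1] == x) + (gr[, 2] == x)) / 2
    tmy <- ((gr[, 3] == y) + (gr[, 4] == y)) / 2
    if (x == y) pc <- tfx * tmy
    else {
      tfy <- ((gr[, 1] == y) + (gr[, 2] == y)) / 2
      tmx <- ((gr[, 3] == x) + (gr[, 4] == x)) / 2
      pc <- tfx * tmy + tfy * tmx
    }
    pr <- pr * pc
  }
  sum(pr)
}

oracle_hwe <- function(g, p)
  unname(if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]])

oracle_trio_lr <- function(s1, s2, s3, p) {
  R <- oracle_sib_lik(list(s1, s2, s3), p)
  U <- oracle_sib_lik(list(s1, s2), p) * oracle_hwe(s3, p)
  if (R <= 0) 0 else R / U
}

oracle_duo_si <- function(g1, g2, p) {
  oracle_sib_lik(list(g1, g2), p) / (oracle_hwe(g1, p) * oracle_hwe(g2, p))
}

# Classical IBD-coefficient form of the duo sibling index:
# LR = k0 + k1 * P(G2 | G1 share 1 IBD)/P(G2) + k2 * 1{G1 == G2}/P(G2),
# with (k0, k1, k2) = (1/4, 1/2, 1/4) for full siblings.
kappa_duo_si <- function(g1, g2, p) {
  pg2 <- oracle_hwe(g2, p)
  po_given_shared <- function(s) {
    x <- g2[1]; y <- g2[2]
    if (x == y) (s == x) * p[x]
    else (s == x) * p[y] + (s == y) * p[x]
  }
  p1 <- mean(vapply(g1, po_given_shared, numeric(1)))
  ident <- setequal(g1, g2) && (sum(g1 == g1[1]) == sum(g2 == g2[1]))
  unname(1/4 + 1/2 * p1 / pg2 + 1/4 * (if (ident) 1 / pg2 else 0))
}

# locus_freqs from a named full-universe vector, optionally dropping the
# filler allele so the engine must aggregate unobserved mass itself
as_lf <- function(p, locus = "L1", drop = character(0)) {
  keep <- setdiff(names(p), drop)
  locus_freqs(locus, keep, unname(p[keep]))
}

# random full universe of m alleles named "1".."m", frequencies summing to 1
rand_universe <- function(m) {
  v <- stats::runif(m, 0.05, 1)
  stats::setNames(v / sum(v), as.character(seq_len(m)))
}

# instantiate a canonical pattern class on concrete allele labels
.letter_alleles <- c(A = "1", B = "2", C = "3", D = "4", X = "5", Y = "6")

pattern_genotypes <- function(cls) {
  lapply(strsplit(cls, " ")[[1]], function(s)
    unname(.letter_alleles[strsplit(s, "")[[1]]]))
}

# full universe over the six letter alleles plus a filler "7"; observed-letter
# frequencies (a, b, c, d) sum to < 0.9
rand_pattern_universe <- function() {
  v <- stats::runif(6, 0.02, 1)
  v <- v / sum(v) * stats::runif(1, 0.3, 0.9)
  stats::setNames(c(v, 1 - sum(v)), as.character(1:7))
}
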