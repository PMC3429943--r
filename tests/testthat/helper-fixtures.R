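# Fixtures built in code.

case_profiles <- function() {
  read_profiles(system.file("extdata", "case_trio_profiles.csv",
                            package = "sibtrio"))
}

# Synthetic frequency database covering every allele of the worked case
# profiles (the population table the case was originally scored against is
# not shipped; any valid table exercises the structure, and the
# frequency-free cells do not depend on it).  Each observed allele gets an
# equal share of 0.9; 0.1 is left as residual mass.
case_panel_synthetic <- function() {
  profs <- case_profiles()
  loci <- names(profs$S1$genotypes)
  loci <- loci[is_autosomal_locus(loci)]
  freq_db(lapply(loci, function(l) {
    al <- sort_alleles(unique(unlist(lapply(profs, function(p)
      p$genotypes[[l]]))))
    locus_freqs(l, al, rep(0.9 / length(al), length(al)))
  }))
}

# tiny two-locus database handy for combined-LR unit tests
mini_db <- function() {
  freq_db(list(locus_freqs("L1", c("A", "B", "C"), c(0.1, 0.2, 0.3)),
               locus_freqs("L2", c("A", "B", "C"), c(0.25, 0.25, 0.5))))
}

mini_profile <- function(id, g1, g2) {
  str_profile(id, list(L1 = g1, L2 = g2))
}
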