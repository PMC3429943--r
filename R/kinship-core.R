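# Likelihood engine for the full-sibling vs unrelated hypotheses.
#
# The joint probability of a set of full-sibling genotypes at one locus is the
# sum over ordered parental genotype pairs (father, mother) of the parents'
# Hardy-Weinberg priors times the product of Mendelian transmission
# probabilities for each child.  Parental alleles outside the set observed in
# the children are aggregated into a single pseudo-allele carrying all
# remaining frequency mass: the aggregation is exact because no child carries
# an unobserved allele, so the transmission factors are identical for every
# unobserved allele and the sum over them telescopes into one term.

# Engine pieces shared by the sibling-set likelihoods at one locus.
# genos: list of integer pairs indexing into the allele universe 1..m
# p:     frequency vector over the universe (observed alleles + pseudo-allele)
# Returns parent-pair prior vector and one G x G child-compatibility matrix
# per genotype, where G indexes unordered parental genotypes; the ordered-pair
# sum is the quadratic form prior' (M1 * M2 * ...) prior.
.sib_engine <- function(genos, p) {
  m <- length(p)
  ij <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  G <- length(i)
  prior <- ifelse(i == j, p[i]^2, 2 * p[i] * p[j])
  trans <- matrix(0, G, m)
  trans[cbind(seq_len(G), i)] <- trans[cbind(seq_len(G), i)] + 0.5
  trans[cbind(seq_len(G), j)] <- trans[cbind(seq_len(G), j)] + 0.5
  mats <- lapply(genos, function(g) {
    if (g[1] == g[2]) tcrossprod(trans[, g[1]])
    else tcrossprod(trans[, g[1]], trans[, g[2]]) +
         tcrossprod(trans[, g[2]], trans[, g[1]])
  })
  list(prior = prior, mats = mats)
}

.quad_form <- function(prior, M) drop(crossprod(prior, M %*% prior))

# Map genotypes at one locus onto the observed-allele universe plus a
# pseudo-allele for all unobserved mass; returns integer-coded genotypes and
# the universe frequency vector.
.locus_universe <- function(genotypes, freqs) {
  # canonical allele order keeps floating-point summation order, and hence
  # the result bit pattern, invariant under permuting the input genotypes
  obs <- sort_alleles(unique(unlist(genotypes, use.names = FALSE)))
  .check_alleles_known(obs, freqs)
  p_obs <- unname(unclass(freqs)[obs])
  rest <- max(0, 1 - sum(p_obs))
  p <- if (rest > 0) c(p_obs, rest) else p_obs
  genos <- lapply(genotypes, function(g) match(g, obs))
  list(p = p, genos = genos, obs = obs)
}

#' Joint probability of a set of full-sibling genotypes
#'
#' Probability that full siblings of unknown parents show the given genotypes
#' at one locus, obtained by exact summation over ordered parental genotype
#' pairs with Hardy-Weinberg priors and Mendelian transmission.
#'
#' @param genotypes non-empty list of genotypes (each a length-2 character
#'   vector) at the same locus.
#' @param freqs a [locus_freqs()] object covering every observed allele.
#' @return probability.
#' @examples
#' f <- locus_freqs("L1", c("A", "B", "C"), c(0.1, 0.2, 0.3))
#' sib_set_likelihood(list(c("A", "A")), f)             # HWE marginal: a^2
#' sib_set_likelihood(list(c("A", "A"), c("A", "B")), f)
#' @export
sib_set_likelihood <- function(genotypes, freqs) {
  if (!length(genotypes)) stop("at least one genotype is required")
  genotypes <- lapply(genotypes, .as_genotype)
  u <- .locus_universe(genotypes, freqs)
  eng <- .sib_engine(u$genos, u$p)
  .quad_form(eng$prior, Reduce(`*`, eng$mats))
}

.locus_result <- function(locus, R, U) {
  lr <- if (U > 0) R / U else 0
  list(locus = locus, numerator_R = R, denominator_U = U,
       lr = lr, excluded = (R <= 0))
}

#' Trio sibship likelihood ratio at one locus
#'
#' Tests individual `s3` against reference full siblings `s1` and `s2`.
#' The numerator is the joint probability of all three genotypes under the
#' hypothesis that the three are full siblings; the denominator is the joint
#' probability of `s1`, `s2` as full siblings times the Hardy-Weinberg
#' probability of `s3` as an unrelated individual.  A trio whose numerator is
#' zero is a genetic inconsistency (exclusion) and carries `lr = 0`.
#'
#' @param s1,s2,s3 genotypes at the same locus (length-2 character vectors);
#'   `s1` and `s2` are the reference siblings, `s3` the tested individual.
#' @param freqs a [locus_freqs()] object.
#' @return list with elements `locus`, `numerator_R`, `denominator_U`, `lr`,
#'   `excluded`.
#' @examples
#' f <- locus_freqs("L1", c("A", "B", "C"), c(0.1, 0.2, 0.3))
#' trio_lr_locus(c("A", "A"), c("A", "B"), c("A", "C"), f)$lr  # 1/(8a + 8a^2)
#' @export
trio_lr_locus <- function(s1, s2, s3, freqs) {
  gs <- lapply(list(s1, s2, s3), .as_genotype)
  u <- .locus_universe(gs, freqs)
  eng <- .sib_engine(u$genos, u$p)
  M12 <- eng$mats[[1]] * eng$mats[[2]]
  R  <- .quad_form(eng$prior, M12 * eng$mats[[3]])
  U2 <- .quad_form(eng$prior, M12)
  .locus_result(attr(freqs, "locus"), R, U2 * genotype_prob_hwe(gs[[3]], freqs))
}

#' Duo sibling index at one locus
#'
#' Likelihood ratio for two individuals being full siblings versus unrelated:
#' joint sibling probability over the product of their Hardy-Weinberg
#' probabilities.  Two genotypes are always compatible with some parental
#' pair, so a duo is never excluded; when the pair shares no allele the index
#' is exactly 1/4 (the probability that full siblings share no allele
#' identical by descent), independent of allele frequencies.
#'
#' @param g1,g2 genotypes at the same locus.
#' @param freqs a [locus_freqs()] object.
#' @return list as in [trio_lr_locus()] (with `excluded` always `FALSE`).
#' @export
duo_si_locus <- function(g1, g2, freqs) {
  gs <- lapply(list(g1, g2), .as_genotype)
  u <- .locus_universe(gs, freqs)
  eng <- .sib_engine(u$genos, u$p)
  R <- .quad_form(eng$prior, eng$mats[[1]] * eng$mats[[2]])
  U <- genotype_prob_hwe(gs[[1]], freqs) * genotype_prob_hwe(gs[[2]], freqs)
  .locus_result(attr(freqs, "locus"), R, U)
}

#' Combined multi-locus likelihood ratio (sibling index)
#'
#' Multiplies per-locus likelihood ratios over the autosomal loci shared by
#' the profiles and the frequency database.  With three profiles the trio LR
#' (first two = reference siblings, third = tested individual) is computed;
#' with two, the duo sibling index.  Loci with a genetic inconsistency have a
#' per-locus LR of zero; so that the multi-locus product stays finite they
#' contribute a small surrogate value (`floor_value`) instead.
#'
#' @param profiles list of two or three [str_profile()] objects.
#' @param db a [freq_db()].
#' @param floor_value surrogate LR substituted at excluded loci
#'   (default 0.001).
#' @param floor_scope `"locus"` (default) substitutes `floor_value` at each
#'   excluded locus; `"profile"` substitutes it once for the whole profile
#'   set when at least one locus excludes, with non-excluded loci still
#'   multiplied in.
#' @return object of class `combined_lr`: list with `per_locus` (data frame:
#'   locus, lr, excluded, numerator_R, denominator_U), `floor_value`,
#'   `floor_scope`, `combined`, `log10_combined`, `n_excluded`.
#' @export
combined_lr <- function(profiles, db, floor_value = 0.001,
                        floor_scope = c("locus", "profile")) {
  floor_scope <- match.arg(floor_scope)
  stopifnot(inherits(db, "freq_db"), floor_value > 0)
  k <- length(profiles)
  if (!k %in% 2:3)
    stop("combined_lr needs two (duo) or three (trio) profiles")
  loci <- Reduce(intersect, lapply(profiles, function(p) names(p$genotypes)))
  loci <- intersect(loci[is_autosomal_locus(loci)], names(db))
  if (!length(loci))
    stop("profiles share no autosomal locus covered by the frequency database")
  res <- lapply(loci, function(l) {
    gs <- lapply(profiles, function(p) p$genotypes[[l]])
    if (k == 3L) trio_lr_locus(gs[[1]], gs[[2]], gs[[3]], db[[l]])
    else duo_si_locus(gs[[1]], gs[[2]], db[[l]])
  })
  per_locus <- data.frame(
    locus = loci,
    lr = vapply(res, `[[`, numeric(1), "lr"),
    excluded = vapply(res, `[[`, logical(1), "excluded"),
    numerator_R = vapply(res, `[[`, numeric(1), "numerator_R"),
    denominator_U = vapply(res, `[[`, numeric(1), "denominator_U"))
  combined <- switch(floor_scope,
    locus = prod(pmax(per_locus$lr, ifelse(per_locus$excluded, floor_value, 0))),
    profile = prod(per_locus$lr[!per_locus$excluded]) *
      (if (any(per_locus$excluded)) floor_value else 1))
  structure(list(per_locus = per_locus, floor_value = floor_value,
                 floor_scope = floor_scope, combined = combined,
                 log10_combined = log10(combined),
                 n_excluded = sum(per_locus$excluded)),
            class = "combined_lr")
}

#' @export
print.combined_lr <- function(x, ...) {
  cat(sprintf("<combined_lr> %d loci, %d excluded\n",
              nrow(x$per_locus), x$n_excluded))
  cat(sprintf("  combined LR = %.6g  (log10 = %.4f; floor %.3g per %s)\n",
              x$combined, x$log10_combined, x$floor_value, x$floor_scope))
  invisible(x)
}
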