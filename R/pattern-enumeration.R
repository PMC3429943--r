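# Canonical trio genotype classes at a single locus.
#
# A trio (S1, S2, S3) of single-locus genotypes is classified up to allele
# relabelling: letters A-D denote alleles observed in the reference pair
# (S1, S2), X and Y denote distinct alleles seen only in the tested
# individual S3.  Within each of the 7 reference-pair classes (AA/AA, AA/AB,
# AA/BB, AA/BC, AB/AB, AB/AC, AB/CD) the possible S3 classes are enumerated,
# giving 63 classes in all, of which 37 are compatible with some parental
# pair (non-excluded) and carry a closed-form LR as a rational function of
# the observed-allele frequencies a, b, c, d.

.LETTER_RANK <- c(A = 1L, B = 2L, C = 3L, D = 4L, X = 5L, Y = 6L)

.sort_letters <- function(x) x[order(.LETTER_RANK[x])]

# Does an ordered parental genotype pair exist that can produce all children?
# Decided combinatorially over the children's alleles plus two wildcard
# parental alleles; exact and frequency-independent.
.parents_exist <- function(children) {
  univ <- c(unique(unlist(children, use.names = FALSE)), ".w1", ".w2")
  m <- length(univ)
  ij <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  pg <- lapply(seq_len(nrow(ij)), function(k) univ[ij[k, ]])
  for (p1 in pg) for (p2 in pg) {
    ok <- all(vapply(children, function(ch) {
      (ch[1] %in% p1 && ch[2] %in% p2) || (ch[2] %in% p1 && ch[1] %in% p2)
    }, logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

# The 37 closed-form LR formulas, keyed by canonical class (X/Y spelling for
# alleles unobserved in the reference pair).  `alias` is the equivalent
# spelling that names unobserved alleles with the next free letters, as such
# formulas are conventionally printed.  Each rational function was derived by
# exact symbolic summation over ordered parental genotype pairs and is
# verified against the numeric brute-force oracle in the test suite; some
# previously published tabulations of these formulas drop terms arising from
# heterozygote x heterozygote parental pairs (e.g. they give (1 + 3a) rather
# than (1 + 3a + b) for AA/AB/AB) and do not reproduce the enumeration.
# Each formula involves only frequencies of alleles observed in S1/S2: terms
# in an unobserved allele's frequency always cancel between numerator and
# denominator.
.FORMULAS <- list(
  "AA AA AA" = list(alias = "AA AA AA",
    display = "(1 + 6a + 9a^2)/(4a^2 + 8a^3 + 4a^4)",
    fn = function(a, b, c, d) (1 + 6*a + 9*a^2)/(4*a^2 + 8*a^3 + 4*a^4)),
  "AA AA AX" = list(alias = "AA AA AB",
    display = "(1 + 3a)/(4a + 8a^2 + 4a^3)",
    fn = function(a, b, c, d) (1 + 3*a)/(4*a + 8*a^2 + 4*a^3)),
  "AA AA XX" = list(alias = "AA AA BB",
    display = "1/(4 + 8a + 4a^2)",
    fn = function(a, b, c, d) 1/(4 + 8*a + 4*a^2)),
  "AA AA XY" = list(alias = "AA AA BC",
    display = "1/(4 + 8a + 4a^2)",
    fn = function(a, b, c, d) 1/(4 + 8*a + 4*a^2)),
  "AA AB AA" = list(alias = "AA AB AA",
    display = "(1 + 3a)/(4a^2 + 4a^3)",
    fn = function(a, b, c, d) (1 + 3*a)/(4*a^2 + 4*a^3)),
  "AA AB AB" = list(alias = "AA AB AB",
    display = "(1 + 3a + b)/(8ab + 8a^2b)",
    fn = function(a, b, c, d) (1 + 3*a + b)/(8*a*b + 8*a^2*b)),
  "AA AB BB" = list(alias = "AA AB BB",
    display = "1/(4b + 4ab)",
    fn = function(a, b, c, d) 1/(4*b + 4*a*b)),
  "AA AB AX" = list(alias = "AA AB AC",
    display = "1/(8a + 8a^2)",
    fn = function(a, b, c, d) 1/(8*a + 8*a^2)),
  "AA AB BX" = list(alias = "AA AB BC",
    display = "1/(8b + 8ab)",
    fn = function(a, b, c, d) 1/(8*b + 8*a*b)),
  "AA BB AA" = list(alias = "AA BB AA",
    display = "1/(4a^2)",
    fn = function(a, b, c, d) 1/(4*a^2)),
  "AA BB AB" = list(alias = "AA BB AB",
    display = "1/(4ab)",
    fn = function(a, b, c, d) 1/(4*a*b)),
  "AA BB BB" = list(alias = "AA BB BB",
    display = "1/(4b^2)",
    fn = function(a, b, c, d) 1/(4*b^2)),
  "AA BC AA" = list(alias = "AA BC AA",
    display = "1/(4a^2)",
    fn = function(a, b, c, d) 1/(4*a^2)),
  "AA BC AB" = list(alias = "AA BC AB",
    display = "1/(8ab)",
    fn = function(a, b, c, d) 1/(8*a*b)),
  "AA BC AC" = list(alias = "AA BC AC",
    display = "1/(8ac)",
    fn = function(a, b, c, d) 1/(8*a*c)),
  "AA BC BC" = list(alias = "AA BC BC",
    display = "1/(8bc)",
    fn = function(a, b, c, d) 1/(8*b*c)),
  "AB AB AA" = list(alias = "AB AB AA",
    display = "(1 + 3a + b)/(4a + 4ab + 4a^2 + 8a^2b)",
    fn = function(a, b, c, d) (1 + 3*a + b)/(4*a + 4*a*b + 4*a^2 + 8*a^2*b)),
  "AB AB AB" = list(alias = "AB AB AB",
    display = "(1 + 3a + 3b + 12ab)/(8ab + 8a^2b + 8ab^2 + 16a^2b^2)",
    fn = function(a, b, c, d)
      (1 + 3*a + 3*b + 12*a*b)/(8*a*b + 8*a^2*b + 8*a*b^2 + 16*a^2*b^2)),
  "AB AB BB" = list(alias = "AB AB BB",
    display = "(1 + a + 3b)/(4b + 4ab + 4b^2 + 8ab^2)",
    fn = function(a, b, c, d) (1 + a + 3*b)/(4*b + 4*a*b + 4*b^2 + 8*a*b^2)),
  "AB AB AX" = list(alias = "AB AB AC",
    display = "(1 + 4a)/(8a + 8a^2 + 8ab + 16a^2b)",
    fn = function(a, b, c, d) (1 + 4*a)/(8*a + 8*a^2 + 8*a*b + 16*a^2*b)),
  "AB AB BX" = list(alias = "AB AB BC",
    display = "(1 + 4b)/(8b + 8ab + 8b^2 + 16ab^2)",
    fn = function(a, b, c, d) (1 + 4*b)/(8*b + 8*a*b + 8*b^2 + 16*a*b^2)),
  "AB AB XX" = list(alias = "AB AB CC",
    display = "1/(4 + 4a + 4b + 8ab)",
    fn = function(a, b, c, d) 1/(4 + 4*a + 4*b + 8*a*b)),
  "AB AB XY" = list(alias = "AB AB CD",
    display = "1/(4 + 4a + 4b + 8ab)",
    fn = function(a, b, c, d) 1/(4 + 4*a + 4*b + 8*a*b)),
  "AB AC AA" = list(alias = "AB AC AA",
    display = "1/(4a + 8a^2)",
    fn = function(a, b, c, d) 1/(4*a + 8*a^2)),
  "AB AC AB" = list(alias = "AB AC AB",
    display = "(1 + 4a)/(8ab + 16a^2b)",
    fn = function(a, b, c, d) (1 + 4*a)/(8*a*b + 16*a^2*b)),
  "AB AC AC" = list(alias = "AB AC AC",
    display = "(1 + 4a)/(8ac + 16a^2c)",
    fn = function(a, b, c, d) (1 + 4*a)/(8*a*c + 16*a^2*c)),
  "AB AC BB" = list(alias = "AB AC BB",
    display = "1/(4b + 8ab)",
    fn = function(a, b, c, d) 1/(4*b + 8*a*b)),
  "AB AC BC" = list(alias = "AB AC BC",
    display = "(a + b + c)/(8bc + 16abc)",
    fn = function(a, b, c, d) (a + b + c)/(8*b*c + 16*a*b*c)),
  "AB AC CC" = list(alias = "AB AC CC",
    display = "1/(4c + 8ac)",
    fn = function(a, b, c, d) 1/(4*c + 8*a*c)),
  "AB AC CX" = list(alias = "AB AC CD",
    display = "1/(8c + 16ac)",
    fn = function(a, b, c, d) 1/(8*c + 16*a*c)),
  "AB AC BX" = list(alias = "AB AC BD",
    display = "1/(8b + 16ab)",
    fn = function(a, b, c, d) 1/(8*b + 16*a*b)),
  "AB CD AB" = list(alias = "AB CD AB",
    display = "1/(8ab)",
    fn = function(a, b, c, d) 1/(8*a*b)),
  "AB CD AC" = list(alias = "AB CD AC",
    display = "1/(16ac)",
    fn = function(a, b, c, d) 1/(16*a*c)),
  "AB CD AD" = list(alias = "AB CD AD",
    display = "1/(16ad)",
    fn = function(a, b, c, d) 1/(16*a*d)),
  "AB CD BC" = list(alias = "AB CD BC",
    display = "1/(16bc)",
    fn = function(a, b, c, d) 1/(16*b*c)),
  "AB CD BD" = list(alias = "AB CD BD",
    display = "1/(16bd)",
    fn = function(a, b, c, d) 1/(16*b*d)),
  "AB CD CD" = list(alias = "AB CD CD",
    display = "1/(8cd)",
    fn = function(a, b, c, d) 1/(8*c*d)))

.ALIAS_TO_CLASS <- stats::setNames(
  names(.FORMULAS), vapply(.FORMULAS, `[[`, character(1), "alias"))

.pattern_string <- function(g1, g2, g3)
  paste(vapply(list(g1, g2, g3),
               function(g) paste(.sort_letters(g), collapse = ""),
               character(1)),
        collapse = " ")

#' Enumerate all canonical trio genotype classes
#'
#' Exhaustively lists the canonical single-locus genotype classes for two
#' reference siblings plus one tested individual: for each of the 7
#' reference-pair classes, every S3 class over the observed letters and the
#' unobserved-allele placeholders X, Y.  Each class is marked excluded or
#' non-excluded by a combinatorial search for a compatible parental genotype
#' pair, and non-excluded classes carry their closed-form LR.
#'
#' The enumeration yields 63 classes: 37 non-excluded and 26 excluded.
#' (The class AB/CD/BC is non-excluded — parents AC x BD produce all three
#' genotypes — although tabulations that count it among the exclusions as
#' well arrive at totals of 64 and 27.)
#'
#' @return data frame with columns `class`, `s1`, `s2`, `s3`, `excluded`,
#'   `formula` (display text, `NA` for excluded classes) and `alias` (the
#'   spelling naming unobserved alleles with the next free letters).
#' @export
enumerate_trio_patterns <- function() {
  refs <- list(c("AA", "AA"), c("AA", "AB"), c("AA", "BB"), c("AA", "BC"),
               c("AB", "AB"), c("AB", "AC"), c("AB", "CD"))
  split2 <- function(s) strsplit(s, "")[[1]]
  rows <- lapply(refs, function(r) {
    g1 <- split2(r[1]); g2 <- split2(r[2])
    obs <- unique(c(g1, g2))
    s3s <- c(
      unlist(lapply(seq_along(obs), function(i)
        lapply(seq(i, length(obs)), function(j) c(obs[i], obs[j]))),
        recursive = FALSE),
      lapply(obs, function(o) .sort_letters(c(o, "X"))),
      list(c("X", "X"), c("X", "Y")))
    do.call(rbind, lapply(s3s, function(g3) {
      cls <- .pattern_string(g1, g2, g3)
      excl <- !.parents_exist(list(g1, g2, g3))
      f <- .FORMULAS[[cls]]
      data.frame(class = cls, s1 = r[1], s2 = r[2],
                 s3 = paste(.sort_letters(g3), collapse = ""),
                 excluded = excl,
                 formula = if (is.null(f)) NA_character_ else f$display,
                 alias = if (is.null(f)) NA_character_ else f$alias)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonicalize a concrete genotype trio into its pattern class
#'
#' Maps three genotypes at one locus onto the canonical class of
#' [enumerate_trio_patterns()], returning the letter-to-allele bindings so
#' the class's closed-form LR can be evaluated on concrete frequencies.
#' The canonical form is the lexicographically smallest pattern string over
#' the reference-pair orientation (S1/S2 are exchangeable) and the scan
#' order of each genotype's two alleles, so the result is invariant under
#' allele relabelling and under swapping the reference siblings.
#'
#' @param s1,s2,s3 genotypes at the same locus (length-2 character vectors);
#'   `s3` is the tested individual.
#' @return object of class `trio_pattern`: list with `class`, `s1_pattern`,
#'   `s2_pattern`, `s3_pattern`, `bindings` (named character: letter ->
#'   allele label), `excluded`, and `formula` (display text or `NULL`).
#' @examples
#' canonicalize_trio(c("12", "17"), c("13", "15"), c("12", "15"))$class
#' @export
canonicalize_trio <- function(s1, s2, s3) {
  gs <- lapply(list(s1, s2, s3), function(g) sort_alleles(.as_genotype(g)))
  scan_orders <- function(g) if (g[1] == g[2]) list(g) else list(g, rev(g))
  best <- NULL
  for (ori in list(c(1L, 2L), c(2L, 1L)))
    for (o1 in scan_orders(gs[[ori[1]]]))
      for (o2 in scan_orders(gs[[ori[2]]]))
        for (o3 in scan_orders(gs[[3]])) {
          seen <- unique(c(o1, o2))
          map <- stats::setNames(LETTERS[seq_along(seen)], seen)
          unseen <- unique(o3[!o3 %in% seen])
          map <- c(map, stats::setNames(c("X", "Y")[seq_along(unseen)], unseen))
          cls <- .pattern_string(map[o1], map[o2], map[o3])
          if (is.null(best) || cls < best$class) {
            best <- list(class = cls,
                         bindings = stats::setNames(names(map), unname(map)))
          }
        }
  parts <- strsplit(best$class, " ")[[1]]
  f <- .FORMULAS[[best$class]]
  structure(list(class = best$class,
                 s1_pattern = parts[1], s2_pattern = parts[2],
                 s3_pattern = parts[3],
                 bindings = best$bindings,
                 excluded = is.null(f),
                 formula = if (is.null(f)) NULL else f$display),
            class = "trio_pattern")
}

#' @export
print.trio_pattern <- function(x, ...) {
  cat(sprintf("<trio_pattern> %s  [%s]\n", x$class,
              if (x$excluded) "excluded" else paste("LR =", x$formula)))
  cat("  bindings:",
      paste(names(x$bindings), x$bindings, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form LR of a non-excluded trio pattern class
#'
#' @param class canonical class string (e.g. `"AA AB AX"`) or its
#'   letter-spelling alias (e.g. `"AA AB AC"`); a `trio_pattern` object is
#'   also accepted.
#' @return list with `class`, `alias`, `display` (formula text) and `fn`, a
#'   function of the observed-allele frequencies `(a, b, c, d)` (unused
#'   letters may be left `NA`).
#' @export
closed_form_lr <- function(class) {
  if (inherits(class, "trio_pattern")) class <- class$class
  key <- if (class %in% names(.FORMULAS)) class
         else if (class %in% names(.ALIAS_TO_CLASS)) .ALIAS_TO_CLASS[[class]]
         else NA_character_
  if (is.na(key))
    stop(sprintf("no closed-form LR for pattern '%s' (excluded or unknown class)",
                 class))
  f <- .FORMULAS[[key]]
  list(class = key, alias = f$alias, display = f$display, fn = f$fn)
}

#' Evaluate the closed-form trio LR for concrete genotypes
#'
#' Canonicalizes the trio and evaluates its pattern's closed-form LR at the
#' frequencies of the alleles bound to letters A-D.  Provided as an
#' independent route to the same quantity as [trio_lr_locus()]; errors on an
#' excluded trio.
#'
#' @inheritParams trio_lr_locus
#' @return the likelihood ratio.
#' @export
closed_form_lr_value <- function(s1, s2, s3, freqs) {
  pat <- canonicalize_trio(s1, s2, s3)
  f <- closed_form_lr(pat)
  val <- function(letter) {
    al <- pat$bindings[letter]
    if (is.na(al)) NA_real_ else unname(unclass(freqs)[al])
  }
  f$fn(val("A"), val("B"), val("C"), val("D"))
}
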