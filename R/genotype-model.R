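# Core domain types: allele frequency tables, genotypes, multi-locus profiles,
# and the Hardy-Weinberg / Mendelian primitives everything else is built on.
#
# Allele labels are opaque text ("9.3", "30.2"): microvariant designations are
# never parsed into floats for identity, only for canonical display ordering.

.FREQ_SUM_TOL <- 1e-9

#' Canonical allele ordering
#'
#' Sorts allele labels numerically where they parse as numbers (the usual STR
#' repeat designations, including microvariants such as "9.3"), with any
#' non-numeric labels after them in lexicographic order.  Used for canonical
#' display of genotypes; allele identity is always exact string equality.
#'
#' @param alleles character vector of allele labels.
#' @return the labels in canonical order.
#' @export
sort_alleles <- function(alleles) {
  num <- suppressWarnings(as.numeric(alleles))
  alleles[order(is.na(num), num, alleles)]
}

#' Single-locus allele frequency table
#'
#' @param locus locus name.
#' @param alleles character vector of allele labels (unique).
#' @param freq numeric vector of frequencies, all in (0, 1], same length as
#'   `alleles`.  The frequencies may sum to less than 1: published tables
#'   routinely omit rare alleles, and the unaccounted mass is retained as
#'   `residual_mass`.  A sum exceeding 1 (beyond 1e-9) is an error.
#' @return an object of class `locus_freqs`: a named numeric vector with
#'   attributes `locus` and `residual_mass`.
#' @examples
#' locus_freqs("FGA", c("21", "22", "23"), c(0.2, 0.3, 0.4))
#' @export
locus_freqs <- function(locus, alleles, freq) {
  alleles <- as.character(alleles)
  if (length(alleles) != length(freq))
    stop("alleles and freq must have the same length")
  if (anyDuplicated(alleles))
    stop(sprintf("locus %s: duplicate allele labels", locus))
  if (!is.numeric(freq) || anyNA(freq))
    stop(sprintf("locus %s: non-numeric frequency", locus))
  if (any(freq <= 0))
    stop(sprintf("locus %s: frequencies must be strictly positive", locus))
  s <- sum(freq)
  if (s > 1 + .FREQ_SUM_TOL)
    stop(sprintf("locus %s: frequencies sum to %.6f > 1", locus, s))
  f <- stats::setNames(as.numeric(freq), alleles)
  structure(f, locus = locus, residual_mass = max(0, 1 - s),
            class = "locus_freqs")
}

#' @export
print.locus_freqs <- function(x, ...) {
  cat(sprintf("<locus_freqs> %s: %d alleles, residual mass %.4g\n",
              attr(x, "locus"), length(x), attr(x, "residual_mass")))
  print(unclass(x)[sort_alleles(names(x))])
  invisible(x)
}

#' Multi-locus frequency database
#'
#' @param tables list of [locus_freqs()] objects with unique locus names.
#' @return object of class `freq_db`: a named list of `locus_freqs`.
#' @export
freq_db <- function(tables) {
  if (!length(tables)) stop("empty frequency database")
  ok <- vapply(tables, inherits, logical(1), "locus_freqs")
  if (!all(ok)) stop("all elements must be locus_freqs objects")
  nms <- vapply(tables, attr, character(1), "locus")
  if (anyDuplicated(nms)) stop("duplicate locus names in frequency database")
  structure(stats::setNames(tables, nms), class = "freq_db")
}

#' @export
print.freq_db <- function(x, ...) {
  n_all <- vapply(x, length, integer(1))
  cat(sprintf("<freq_db> %d loci (%s), %d-%d alleles per locus\n",
              length(x), paste(utils::head(names(x), 4), collapse = ", "),
              min(n_all), max(n_all)))
  invisible(x)
}

#' @export
`[.freq_db` <- function(x, i) {
  structure(NextMethod(), class = "freq_db")
}

#' Read an allele frequency table from CSV
#'
#' Expects a UTF-8 CSV with header `locus,allele,frequency` and one row per
#' allele.  Per-locus frequency sums are validated; mass not accounted for by
#' the listed alleles is retained as the residual of each locus.
#'
#' @param path file path (or connection).
#' @return a [freq_db()].
#' @export
read_frequency_table <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "character", "character"),
                       strip.white = TRUE)
  need <- c("locus", "allele", "frequency")
  if (!all(need %in% names(d)))
    stop("frequency CSV must have header locus,allele,frequency")
  fr <- suppressWarnings(as.numeric(d$frequency))
  if (anyNA(fr)) {
    bad <- d$frequency[is.na(fr)][1]
    stop(sprintf("non-numeric frequency value: '%s'", bad))
  }
  key <- paste(d$locus, d$allele, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate row for locus %s allele %s", dup$locus, dup$allele))
  }
  tabs <- lapply(split(seq_len(nrow(d)), factor(d$locus, unique(d$locus))),
                 function(i) locus_freqs(d$locus[i[1]], d$allele[i], fr[i]))
  freq_db(tabs)
}

#' Write an allele frequency table to CSV
#'
#' @param db a [freq_db()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(db, path) {
  stopifnot(inherits(db, "freq_db"))
  rows <- do.call(rbind, lapply(db, function(f) {
    a <- sort_alleles(names(f))
    # %.17g keeps full double precision so the CSV round-trips exactly
    data.frame(locus = attr(f, "locus"), allele = a,
               frequency = sprintf("%.17g", unname(unclass(f)[a])))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- genotypes and profiles -------------------------------------------------

#' Construct a genotype observation
#'
#' A genotype is an unordered pair of allele labels at one locus; a homozygote
#' repeats the label.  Most sibtrio functions accept a plain length-2
#' character vector wherever a genotype is expected; this constructor merely
#' validates and canonically orders one.
#'
#' @param a1,a2 allele labels.
#' @return length-2 character vector in canonical allele order.
#' @export
genotype <- function(a1, a2) {
  g <- as.character(c(a1, a2))
  if (length(g) != 2 || anyNA(g) || any(!nzchar(g)))
    stop("a genotype is exactly two allele labels")
  sort_alleles(g)
}

.as_genotype <- function(g) {
  g <- as.character(g)
  if (length(g) != 2 || anyNA(g)) stop("a genotype is exactly two allele labels")
  g
}

#' Multi-locus STR profile
#'
#' @param sample_id sample identifier.
#' @param genotypes named list: locus name -> length-2 character vector of
#'   allele labels.  The sex-typing locus AMEL may be present; it is flagged
#'   non-autosomal and skipped by all likelihood computations.
#' @return object of class `str_profile`.
#' @export
str_profile <- function(sample_id, genotypes) {
  if (!length(genotypes) || is.null(names(genotypes)) ||
      any(!nzchar(names(genotypes))))
    stop("genotypes must be a non-empty named list (locus -> allele pair)")
  if (anyDuplicated(names(genotypes)))
    stop("one genotype per locus: duplicated locus names")
  genotypes <- lapply(genotypes, .as_genotype)
  structure(list(sample_id = as.character(sample_id), genotypes = genotypes),
            class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat(sprintf("<str_profile> %s (%d loci)\n", x$sample_id, length(x$genotypes)))
  g <- vapply(x$genotypes, function(p) paste(sort_alleles(p), collapse = ","),
              character(1))
  print(g)
  invisible(x)
}

#' Which locus names are autosomal?
#'
#' AMEL (amelogenin, also accepted as "AMELOGENIN") is the sex-typing marker
#' of the common forensic multiplexes; it carries no kinship information in
#' this model and is excluded from all LR products.
#'
#' @param loci character vector of locus names.
#' @return logical vector.
#' @export
is_autosomal_locus <- function(loci) {
  !(toupper(loci) %in% c("AMEL", "AMELOGENIN"))
}

#' Read STR profiles from CSV
#'
#' Expects header `sample_id,locus,allele1,allele2`; homozygotes repeat the
#' allele label.
#'
#' @param path file path.
#' @return named list of [str_profile()] objects, in order of appearance.
#' @export
read_profiles <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("sample_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("profile CSV must have header sample_id,locus,allele1,allele2")
  out <- lapply(split(seq_len(nrow(d)), factor(d$sample_id, unique(d$sample_id))),
                function(i) {
                  if (anyDuplicated(d$locus[i]))
                    stop(sprintf("sample %s: duplicated locus", d$sample_id[i[1]]))
                  g <- Map(function(a, b) c(a, b), d$allele1[i], d$allele2[i])
                  str_profile(d$sample_id[i[1]], stats::setNames(g, d$locus[i]))
                })
  out
}

#' Write STR profiles to CSV
#'
#' @param profiles list of [str_profile()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    g <- lapply(p$genotypes, sort_alleles)
    data.frame(sample_id = p$sample_id, locus = names(g),
               allele1 = vapply(g, `[`, character(1), 1),
               allele2 = vapply(g, `[`, character(1), 2))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- HWE and Mendelian primitives ------------------------------------------

.check_alleles_known <- function(alleles, freqs) {
  miss <- setdiff(unique(alleles), names(freqs))
  if (length(miss)) {
    loc <- attr(freqs, "locus")
    stop(sprintf("allele(s) %s not in frequency table%s",
                 paste(sQuote(miss), collapse = ", "),
                 if (is.null(loc)) "" else sprintf(" for locus %s", loc)))
  }
}

#' Hardy-Weinberg genotype probability
#'
#' `a^2` for a homozygote with allele frequency `a`, `2ab` for a heterozygote
#' with allele frequencies `a` and `b`.
#'
#' @param g genotype: length-2 character vector of allele labels.
#' @param freqs a [locus_freqs()] object (or named numeric vector of
#'   frequencies).  Both alleles of `g` must be present.
#' @return probability in \[0, 1\].
#' @examples
#' f <- locus_freqs("L1", c("A", "B"), c(0.2, 0.3))
#' genotype_prob_hwe(c("A", "A"), f)  # 0.04
#' genotype_prob_hwe(c("A", "B"), f)  # 0.12
#' @export
genotype_prob_hwe <- function(g, freqs) {
  g <- .as_genotype(g)
  .check_alleles_known(g, freqs)
  p <- unname(freqs[g])
  if (g[1] == g[2]) p[1]^2 else 2 * p[1] * p[2]
}

#' Mendelian transmission probability
#'
#' Probability that a parent with the given genotype transmits the given
#' allele: 1 if homozygous for it, 1/2 if heterozygous carrying it, 0
#' otherwise.
#'
#' @param parent parental genotype (length-2 character vector).
#' @param allele allele label.
#' @return 0, 0.5 or 1.
#' @export
transmission_prob <- function(parent, allele) {
  parent <- .as_genotype(parent)
  sum(parent == as.character(allele)) / 2
}
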