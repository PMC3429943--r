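# Virtual population simulator.
#
# Families are nuclear: both parents drawn from Hardy-Weinberg equilibrium at
# every locus, children built by picking one allele per locus from each
# parent.  Four population modes:
#   3S   two reference siblings + a true third sibling (all share parents)
#   2S1U two reference siblings + an independent HWE individual
#   2S   one reference sibling pair (duo control)
#   2U   two independent HWE individuals (duo control)
# Trio populations are scored with the trio LR, duo populations with the duo
# sibling index.  A single root seed spawns one RNG substream per family
# (L'Ecuyer-CMRG), so populations are reproducible and order-independent.

.save_rng <- function() {
  list(kind = RNGkind(),
       seed = if (exists(".Random.seed", envir = globalenv()))
         get(".Random.seed", envir = globalenv()) else NULL)
}

.restore_rng <- function(state) {
  do.call(RNGkind, as.list(state$kind))
  if (is.null(state$seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state$seed, envir = globalenv())
  invisible(NULL)
}

.set_stream <- function(s) assign(".Random.seed", s, envir = globalenv())

# Frequency mass not listed in a table is given to one explicit synthetic
# allele so every simulated profile can be scored against the same table.
.OTHER_ALLELE <- "_OTHER"

.augment_residual <- function(db) {
  freq_db(lapply(db, function(f) {
    r <- attr(f, "residual_mass")
    if (r > 1e-12)
      locus_freqs(attr(f, "locus"), c(names(f), .OTHER_ALLELE),
                  c(unname(unclass(f)), r))
    else f
  }))
}

#' Generate a synthetic allele-frequency panel
#'
#' Stands in for a published population table: `n_loci` autosomal STR-like
#' loci, each with `n_alleles` alleles whose frequencies are drawn from a
#' symmetric Dirichlet distribution (so they sum to exactly 1 per locus).
#' The default concentration 2 over 8 alleles gives an expected
#' heterozygosity of about 0.82, typical of forensic STR multiplexes;
#' `concentration = Inf` gives equifrequent alleles.
#'
#' @param n_loci number of loci (default 15).
#' @param n_alleles alleles per locus (default 8).
#' @param concentration symmetric Dirichlet concentration parameter
#'   (default 2); `Inf` for equifrequent alleles.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param locus_names optional locus names (default `L01`, `L02`, ...).
#' @return a [freq_db()] whose per-locus frequencies sum to 1.
#' @export
synthetic_panel <- function(n_loci = 15, n_alleles = 8, concentration = 2,
                            seed = NULL, locus_names = NULL) {
  stopifnot(n_loci >= 1, n_alleles >= 1, concentration > 0)
  if (is.null(locus_names)) locus_names <- sprintf("L%02d", seq_len(n_loci))
  stopifnot(length(locus_names) == n_loci)
  labels <- as.character(seq(6, length.out = n_alleles))
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  freq_db(lapply(locus_names, function(l) {
    p <- if (is.finite(concentration)) {
      g <- stats::rgamma(n_alleles, shape = concentration)
      while (any(g <= 0)) g <- stats::rgamma(n_alleles, shape = concentration)
      g / sum(g)
    } else rep(1 / n_alleles, n_alleles)
    locus_freqs(l, labels, p)
  }))
}

#' Draw one individual from Hardy-Weinberg equilibrium
#'
#' Two alleles per locus, sampled independently from the locus allele
#' frequencies (residual table mass is sampled as the synthetic allele
#' `"_OTHER"`).  Uses the current RNG state.
#'
#' @param db a [freq_db()].
#' @param sample_id identifier for the returned profile.
#' @return an [str_profile()].
#' @export
sample_parent <- function(db, sample_id = "parent") {
  stopifnot(inherits(db, "freq_db"))
  db <- .augment_residual(db)
  g <- lapply(db, function(f)
    sample(names(f), 2L, replace = TRUE, prob = unclass(f)))
  str_profile(sample_id, g)
}

#' Draw a child of two parents by Mendelian segregation
#'
#' One allele per locus picked uniformly from each parent.  Uses the current
#' RNG state.
#'
#' @param father,mother [str_profile()] objects covering the same loci.
#' @param sample_id identifier for the returned profile.
#' @return an [str_profile()].
#' @export
sample_child <- function(father, mother, sample_id = "child") {
  loci <- names(father$genotypes)
  if (!setequal(loci, names(mother$genotypes)))
    stop("parents must cover the same loci")
  g <- lapply(loci, function(l)
    c(sample(father$genotypes[[l]], 1L), sample(mother$genotypes[[l]], 1L)))
  str_profile(sample_id, stats::setNames(g, loci))
}

# fast internal draws on 2 x L character matrices
.draw_hwe_mat <- function(fl, L) {
  m <- matrix(NA_character_, 2L, L)
  for (l in seq_len(L))
    m[, l] <- sample(fl[[l]]$a, 2L, replace = TRUE, prob = fl[[l]]$p)
  m
}

.draw_child_mat <- function(father, mother, L) {
  rbind(father[cbind(sample.int(2L, L, replace = TRUE), seq_len(L))],
        mother[cbind(sample.int(2L, L, replace = TRUE), seq_len(L))])
}

#' Simulate a scored trio or duo population
#'
#' Generates `n` independent families and scores each set with the combined
#' likelihood ratio over all loci of the frequency database: the trio LR for
#' modes `"3S"` (two reference siblings + true sibling) and `"2S1U"` (two
#' reference siblings + unrelated individual), the duo sibling index for the
#' control modes `"2S"` (sibling pair) and `"2U"` (unrelated pair).  Loci
#' with a genetic inconsistency enter the product at `floor_value`.
#'
#' @param db a [freq_db()].
#' @param n number of families (>= 1).
#' @param mode one of `"3S"`, `"2S1U"`, `"2S"`, `"2U"`.
#' @param seed integer root seed; one RNG substream is spawned per family.
#' @param floor_value surrogate LR for excluded loci (default 0.001).
#' @param floor_scope see [combined_lr()].
#' @return object of class `trio_population`: list with `mode`, `n`, `seed`,
#'   `loci`, `floor_value`, `lr` (combined LR per family, post-floor),
#'   `log10_lr`, `n_excluded` (excluding loci per family), `exclusions`
#'   (n x loci logical matrix) and `genotypes` (one `n x loci` character
#'   matrix of `"a/b"` strings per member).
#' @export
simulate_population <- function(db, n, mode = c("3S", "2S1U", "2S", "2U"),
                                seed = 1L, floor_value = 0.001,
                                floor_scope = c("locus", "profile")) {
  mode <- match.arg(mode)
  floor_scope <- match.arg(floor_scope)
  stopifnot(inherits(db, "freq_db"), n >= 1, floor_value > 0)
  db <- .augment_residual(db)
  loci <- names(db)[is_autosomal_locus(names(db))]
  db <- db[loci]
  L <- length(loci)
  if (!L) stop("frequency database has no autosomal locus")
  fl <- lapply(db, function(f) list(a = names(f), p = unname(unclass(f))))
  trio <- mode %in% c("3S", "2S1U")
  k <- if (trio) 3L else 2L

  a1 <- lapply(seq_len(k), function(i) matrix(NA_character_, n, L))
  a2 <- lapply(seq_len(k), function(i) matrix(NA_character_, n, L))

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(n)) {
    s <- parallel::nextRNGSubStream(s)
    .set_stream(s)
    members <- switch(mode,
      "3S" = {
        f <- .draw_hwe_mat(fl, L); m <- .draw_hwe_mat(fl, L)
        list(.draw_child_mat(f, m, L), .draw_child_mat(f, m, L),
             .draw_child_mat(f, m, L))
      },
      "2S1U" = {
        f <- .draw_hwe_mat(fl, L); m <- .draw_hwe_mat(fl, L)
        list(.draw_child_mat(f, m, L), .draw_child_mat(f, m, L),
             .draw_hwe_mat(fl, L))
      },
      "2S" = {
        f <- .draw_hwe_mat(fl, L); m <- .draw_hwe_mat(fl, L)
        list(.draw_child_mat(f, m, L), .draw_child_mat(f, m, L))
      },
      "2U" = list(.draw_hwe_mat(fl, L), .draw_hwe_mat(fl, L)))
    for (j in seq_len(k)) {
      g <- members[[j]]
      a1[[j]][i, ] <- pmin(g[1, ], g[2, ])
      a2[[j]][i, ] <- pmax(g[1, ], g[2, ])
    }
  }

  lr_loc <- matrix(NA_real_, n, L, dimnames = list(NULL, loci))
  excl <- matrix(FALSE, n, L, dimnames = list(NULL, loci))
  keys <- lapply(seq_len(k), function(j)
    matrix(paste(a1[[j]], a2[[j]], sep = "/"), n, L,
           dimnames = list(NULL, loci)))
  for (l in seq_len(L)) {
    f <- db[[l]]
    cache <- new.env(hash = TRUE, parent = emptyenv())
    k1 <- keys[[1]][, l]; k2 <- keys[[2]][, l]
    pair_lo <- pmin(k1, k2); pair_hi <- pmax(k1, k2)
    ckey <- if (trio) paste(pair_lo, pair_hi, keys[[3]][, l])
            else paste(pair_lo, pair_hi)
    for (i in seq_len(n)) {
      hit <- cache[[ckey[i]]]
      if (is.null(hit)) {
        res <- if (trio)
          trio_lr_locus(c(a1[[1]][i, l], a2[[1]][i, l]),
                        c(a1[[2]][i, l], a2[[2]][i, l]),
                        c(a1[[3]][i, l], a2[[3]][i, l]), f)
        else
          duo_si_locus(c(a1[[1]][i, l], a2[[1]][i, l]),
                       c(a1[[2]][i, l], a2[[2]][i, l]), f)
        hit <- c(res$lr, res$excluded)
        cache[[ckey[i]]] <- hit
      }
      lr_loc[i, l] <- hit[1]
      excl[i, l] <- as.logical(hit[2])
    }
  }

  n_excluded <- rowSums(excl)
  lr <- switch(floor_scope,
    locus = apply(pmax(lr_loc, ifelse(excl, floor_value, 0)), 1L, prod),
    profile = {
      base <- lr_loc; base[excl] <- 1
      apply(base, 1L, prod) * ifelse(n_excluded > 0, floor_value, 1)
    })

  structure(list(mode = mode, n = n, seed = seed, loci = loci,
                 floor_value = floor_value, floor_scope = floor_scope,
                 lr = lr, log10_lr = log10(lr),
                 n_excluded = as.integer(n_excluded), exclusions = excl,
                 genotypes = keys),
            class = "trio_population")
}

#' @export
print.trio_population <- function(x, ...) {
  cat(sprintf("<trio_population> mode %s, n = %d, %d loci, seed %d\n",
              x$mode, x$n, length(x$loci), x$seed))
  cat(sprintf("  log10 combined LR: median %.3f [%.3f, %.3f]\n",
              stats::median(x$log10_lr), min(x$log10_lr), max(x$log10_lr)))
  invisible(x)
}

#' Export a simulated population as a data frame
#'
#' One row per family: member genotype strings per locus, the combined LR and
#' its log10, and the number of excluding loci.
#'
#' @param pop a `trio_population`.
#' @return data frame.
#' @export
population_table <- function(pop) {
  stopifnot(inherits(pop, "trio_population"))
  out <- data.frame(family_id = seq_len(pop$n))
  for (j in seq_along(pop$genotypes)) {
    g <- as.data.frame(pop$genotypes[[j]])
    names(g) <- paste0("s", j, "_", pop$loci)
    out <- cbind(out, g)
  }
  out$combined_lr <- pop$lr
  out$log10_lr <- pop$log10_lr
  out$n_excluded <- pop$n_excluded
  out
}
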