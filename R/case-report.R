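# Case report for a tested individual against two reference siblings:
# per-locus duo sibling indices in both orientations, the trio sibling index,
# and the three combined products.

#' Duo and trio sibship case report
#'
#' For reference siblings `s1`, `s2` and tested individual `s3`, reports per
#' autosomal locus the duo sibling index of `s3` against each reference alone
#' and the trio sibling index against both, plus the three combined
#' (multi-locus product) values.  AMEL, if present, is shown without indices.
#'
#' @param s1,s2,s3 [str_profile()] objects (`s3` is the tested individual).
#' @param db a [freq_db()].
#' @param floor_value surrogate LR for excluded trio loci (default 0.001);
#'   duos are never excluded.
#' @param floor_scope see [combined_lr()].
#' @return object of class `case_report`: a data frame with columns `locus`,
#'   `s1`, `s2`, `s3`, `si_s1_s3`, `si_s2_s3`, `si_trio`, `trio_excluded`,
#'   and attributes `combined` (named numeric: duo_s1_s3, duo_s2_s3, trio),
#'   `floor_value`, `floor_scope`.
#' @export
case_report <- function(s1, s2, s3, db, floor_value = 0.001,
                        floor_scope = c("locus", "profile")) {
  floor_scope <- match.arg(floor_scope)
  profs <- list(s1, s2, s3)
  stopifnot(all(vapply(profs, inherits, logical(1), "str_profile")),
            inherits(db, "freq_db"))
  shared <- Reduce(intersect, lapply(profs, function(p) names(p$genotypes)))
  loci <- intersect(shared[is_autosomal_locus(shared)], names(db))
  if (!length(loci))
    stop("profiles share no autosomal locus covered by the frequency database")

  gstr <- function(p, l) paste(sort_alleles(p$genotypes[[l]]), collapse = ",")
  rows <- lapply(loci, function(l) {
    g <- lapply(profs, function(p) p$genotypes[[l]])
    d13 <- duo_si_locus(g[[1]], g[[3]], db[[l]])
    d23 <- duo_si_locus(g[[2]], g[[3]], db[[l]])
    tr <- trio_lr_locus(g[[1]], g[[2]], g[[3]], db[[l]])
    data.frame(locus = l,
               s1 = gstr(s1, l), s2 = gstr(s2, l), s3 = gstr(s3, l),
               si_s1_s3 = d13$lr, si_s2_s3 = d23$lr,
               si_trio = tr$lr, trio_excluded = tr$excluded)
  })
  out <- do.call(rbind, rows)
  amel <- shared[!is_autosomal_locus(shared)]
  if (length(amel)) {
    out <- rbind(out, data.frame(
      locus = amel, s1 = vapply(amel, gstr, character(1), p = s1),
      s2 = vapply(amel, gstr, character(1), p = s2),
      s3 = vapply(amel, gstr, character(1), p = s3),
      si_s1_s3 = NA_real_, si_s2_s3 = NA_real_, si_trio = NA_real_,
      trio_excluded = NA))
  }
  rownames(out) <- NULL
  auto <- !is.na(out$si_trio)
  trio_floored <- switch(floor_scope,
    locus = prod(pmax(out$si_trio[auto],
                      ifelse(out$trio_excluded[auto], floor_value, 0))),
    profile = prod(out$si_trio[auto][!out$trio_excluded[auto]]) *
      (if (any(out$trio_excluded[auto])) floor_value else 1))
  combined <- c(duo_s1_s3 = prod(out$si_s1_s3[auto]),
                duo_s2_s3 = prod(out$si_s2_s3[auto]),
                trio = trio_floored)
  structure(out, combined = combined, floor_value = floor_value,
            floor_scope = floor_scope,
            class = c("case_report", "data.frame"))
}

#' @export
print.case_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  for (col in c("si_s1_s3", "si_s2_s3", "si_trio"))
    df[[col]] <- round_half_up(df[[col]], digits)
  print(df, row.names = FALSE)
  cm <- attr(x, "combined")
  cat(sprintf("Combined SI: S1-S3 %.3f | S2-S3 %.3f | trio %.3f\n",
              cm["duo_s1_s3"], cm["duo_s2_s3"], cm["trio"]))
  invisible(x)
}
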