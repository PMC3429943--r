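test_that("enumeration finds 63 classes: 37 non-excluded, 26 excluded", {
  pat <- enumerate_trio_patterns()
  expect_equal(nrow(pat), 63)
  expect_false(anyDuplicated(pat$class) > 0)
  expect_equal(sum(!pat$excluded), 37)
  expect_equal(sum(pat$excluded), 26)
  # every non-excluded class carries a formula, no excluded class does
  expect_true(all(!is.na(pat$formula[!pat$excluded])))
  expect_true(all(is.na(pat$formula[pat$excluded])))
  # spot checks
  expect_false(pat$excluded[pat$class == "AB AB XY"])
  expect_true(pat$excluded[pat$class == "AA BB XX"])
  # AB/CD/BC is genuinely non-excluded: parents AC x BD fit all three
  expect_false(pat$excluded[pat$class == "AB CD BC"])
})

test_that("canonicalization maps concrete trios onto their class", {
  p <- canonicalize_trio(c("12", "17"), c("13", "15"), c("12", "15"))
  expect_equal(p$class, "AB CD AC")
  expect_equal(unname(p$bindings[c("A", "C")]), c("12", "15"))
  expect_equal(canonicalize_trio(c("15", "15"), c("15", "17"),
                                 c("17", "17"))$class, "AA AB BB")
  expect_equal(canonicalize_trio(c("9", "9"), c("9", "9"),
                                 c("9", "9"))$class, "AA AA AA")
  # shared allele sorting last in both references still lands on AB AC
  expect_equal(canonicalize_trio(c("1", "3"), c("2", "3"),
                                 c("1", "2"))$class, "AB AC BC")
})

test_that("canonicalization is idempotent and relabelling/swap invariant", {
  pat <- enumerate_trio_patterns()
  gs_all <- lapply(pat$class, pattern_genotypes)
  for (gs in gs_all) {
    base <- canonicalize_trio(gs[[1]], gs[[2]], gs[[3]])
    # idempotence: canonical form maps to itself
    reg <- pattern_genotypes(base$class)
    expect_equal(canonicalize_trio(reg[[1]], reg[[2]], reg[[3]])$class,
                 base$class)
    # swap of the reference pair
    expect_equal(canonicalize_trio(gs[[2]], gs[[1]], gs[[3]])$class,
                 base$class)
  }
  set.seed(31)
  for (rep in 1:50) {
    gs <- gs_all[[sample(length(gs_all), 1)]]
    relab <- stats::setNames(sample(as.character(10:19), 6), as.character(1:6))
    gs2 <- lapply(gs, function(g) unname(relab[g]))
    expect_equal(canonicalize_trio(gs2[[1]], gs2[[2]], gs2[[3]])$class,
                 canonicalize_trio(gs[[1]], gs[[2]], gs[[3]])$class)
  }
})

test_that("every concrete trio maps to exactly one enumerated class", {
  pat <- enumerate_trio_patterns()
  set.seed(32)
  for (rep in 1:100) {
    al <- as.character(sample(5:30, 6))
    gs <- lapply(1:3, function(i) sample(al, 2, replace = TRUE))
    cls <- canonicalize_trio(gs[[1]], gs[[2]], gs[[3]])$class
    expect_equal(sum(pat$class == cls), 1)
  }
})

test_that("closed forms are retrievable by class or alias and behave at limits", {
  f <- closed_form_lr("AA AB AX")
  expect_equal(f$alias, "AA AB AC")
  expect_equal(f$fn(a = 0.1), 1 / (8 * 0.1 + 8 * 0.01))
  expect_equal(closed_form_lr("AA AB AC")$class, "AA AB AX")
  expect_equal(closed_form_lr("AB CD CD")$fn(c = 0.2, d = 0.3, a = NA, b = NA),
               1 / (8 * 0.2 * 0.3))
  # rare-allele limit of AA AA (unseen homozygote): 1/4
  expect_equal(closed_form_lr("AA AA BB")$fn(a = 0), 0.25)
  expect_error(closed_form_lr("AA BB XX"), "excluded or unknown")
})

test_that("all 37 closed forms agree with the brute-force oracle", {
  pat <- enumerate_trio_patterns()
  ok <- pat$class[!pat$excluded]
  set.seed(33)
  for (cls in ok) {
    gs <- pattern_genotypes(cls)
    f <- closed_form_lr(cls)$fn
    for (rep in 1:20) {
      p <- rand_pattern_universe()
      lr_formula <- f(a = p[["1"]], b = p[["2"]], c = p[["3"]], d = p[["4"]])
      lr_oracle <- oracle_trio_lr(gs[[1]], gs[[2]], gs[[3]], p)
      expect_equal(lr_formula, lr_oracle, tolerance = 1e-9,
                   label = sprintf("formula LR for %s", cls))
      # and the likelihood engine agrees with both
      lf <- as_lf(p, drop = "7")
      expect_equal(trio_lr_locus(gs[[1]], gs[[2]], gs[[3]], lf)$lr,
                   lr_oracle, tolerance = 1e-9,
                   label = sprintf("engine LR for %s", cls))
    }
  }
})

test_that("closed-form evaluation on concrete genotypes matches the engine", {
  set.seed(34)
  for (rep in 1:50) {
    p <- rand_pattern_universe()
    lf <- as_lf(p, drop = "7")
    al <- as.character(1:6)
    gs <- lapply(1:3, function(i) sample(al, 2, replace = TRUE))
    eng <- trio_lr_locus(gs[[1]], gs[[2]], gs[[3]], lf)
    if (eng$excluded) {
      expect_error(closed_form_lr_value(gs[[1]], gs[[2]], gs[[3]], lf))
    } else {
      expect_equal(closed_form_lr_value(gs[[1]], gs[[2]], gs[[3]], lf),
                   eng$lr, tolerance = 1e-9)
    }
  }
})

test_that("combinatorial exclusion agrees with a vanishing likelihood", {
  pat <- enumerate_trio_patterns()
  set.seed(35)
  p <- rand_pattern_universe()
  lf <- as_lf(p, drop = "7")
  for (i in seq_len(nrow(pat))) {
    gs <- pattern_genotypes(pat$class[i])
    r <- trio_lr_locus(gs[[1]], gs[[2]], gs[[3]], lf)
    expect_equal(r$excluded, pat$excluded[i],
                 label = sprintf("exclusion status of %s", pat$class[i]))
    expect_equal(r$numerator_R <= 0, pat$excluded[i])
  }
})
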