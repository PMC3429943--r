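test_that("sibling-set likelihoods match hand enumeration", {
  f <- locus_freqs("L1", c("A", "B", "C"), c(0.1, 0.2, 0.3))
  # one sibling: marginal is plain HWE
  expect_equal(sib_set_likelihood(list(c("A", "A")), f), 0.01)
  # two siblings AA, AB: a^2 b (1 + a) / 2 from the four parental rows
  expect_equal(sib_set_likelihood(list(c("A", "A"), c("A", "B")), f),
               0.1^2 * 0.2 * 1.1 / 2)
  # three siblings AA, AB, AC force parents AB x AC: a^2 b c / 8
  expect_equal(
    sib_set_likelihood(list(c("A", "A"), c("A", "B"), c("A", "C")), f),
    7.5e-5)
  expect_error(sib_set_likelihood(list(), f), "at least one")
})

test_that("pseudo-allele aggregation equals the full-universe brute force", {
  set.seed(21)
  for (rep in 1:30) {
    p <- rand_universe(5)
    al <- names(p)
    gs <- lapply(seq_len(sample(1:3, 1)), function(i) sample(al, 2, replace = TRUE))
    # engine sees only a partial table (drop one allele unused by the sibs)
    unused <- setdiff(al, unique(unlist(gs)))
    drop <- if (length(unused)) unused[1] else character(0)
    f <- as_lf(p, drop = drop)
    expect_equal(sib_set_likelihood(gs, f), oracle_sib_lik(gs, p),
                 tolerance = 1e-12)
  }
})

test_that("trio LR reproduces the worked family-comparison example", {
  f <- locus_freqs("L1", c("A", "B", "C"), c(0.1, 0.2, 0.3))
  r <- trio_lr_locus(c("A", "A"), c("A", "B"), c("A", "C"), f)
  expect_equal(r$lr, 1 / (8 * 0.1 + 8 * 0.1^2))
  expect_false(r$excluded)
  expect_equal(trio_lr_locus(c("A", "A"), c("B", "B"), c("A", "B"), f)$lr,
               1 / (4 * 0.1 * 0.2))
  # S3 carrying an allele absent from both references and from one parent slot
  r0 <- trio_lr_locus(c("A", "A"), c("B", "B"), c("A", "C"), f)
  expect_true(r0$excluded)
  expect_equal(r0$lr, 0)
})

test_that("trio LR is exactly symmetric in the reference siblings", {
  set.seed(22)
  for (rep in 1:25) {
    p <- rand_universe(4)
    f <- as_lf(p)
    gs <- lapply(1:3, function(i) sample(names(p), 2, replace = TRUE))
    a <- trio_lr_locus(gs[[1]], gs[[2]], gs[[3]], f)
    b <- trio_lr_locus(gs[[2]], gs[[1]], gs[[3]], f)
    expect_identical(a$lr, b$lr)
    expect_identical(a$excluded, b$excluded)
  }
})

test_that("summing the trio likelihood over all S3 recovers the pair likelihood", {
  set.seed(23)
  for (rep in 1:10) {
    p <- rand_universe(4)
    f <- as_lf(p)
    al <- names(p)
    s1 <- sample(al, 2, replace = TRUE)
    s2 <- sample(al, 2, replace = TRUE)
    tot <- 0
    for (i in seq_along(al)) for (j in seq(i, length(al)))
      tot <- tot + sib_set_likelihood(list(s1, s2, c(al[i], al[j])), f)
    expect_equal(tot, sib_set_likelihood(list(s1, s2), f), tolerance = 1e-9)
  }
})

test_that("duo sibling index matches brute force and known values", {
  f <- locus_freqs("FGA", c("19", "21", "22"), c(0.1, 0.15, 0.2))
  # no shared allele: exactly the 0-IBD coefficient 1/4, frequency-free
  expect_equal(duo_si_locus(c("21", "21"), c("19", "22"), f)$lr, 0.25)
  f5 <- locus_freqs("L1", c("A", "B"), c(0.5, 0.5))
  expect_equal(duo_si_locus(c("A", "A"), c("A", "A"), f5)$lr,
               (1 + 0.5)^2 / (4 * 0.5^2))        # (1+a)^2 / 4a^2
  # both heterozygous AB at a = b = 1/2: brute force gives 5/4
  expect_equal(duo_si_locus(c("A", "B"), c("A", "B"), f5)$lr, 1.25)
  expect_equal(oracle_duo_si(c("A", "B"), c("A", "B"),
                             c(A = 0.5, B = 0.5)), 1.25)
  expect_false(duo_si_locus(c("A", "A"), c("B", "B"), f5)$excluded ||
                 duo_si_locus(c("21", "21"), c("19", "22"), f)$excluded)
})

test_that("duo sibling index equals the IBD kappa closed form", {
  set.seed(24)
  for (rep in 1:1000) {
    p <- rand_universe(sample(3:6, 1))
    f <- as_lf(p)
    g1 <- sample(names(p), 2, replace = TRUE)
    g2 <- sample(names(p), 2, replace = TRUE)
    expect_equal(duo_si_locus(g1, g2, f)$lr, kappa_duo_si(g1, g2, p),
                 tolerance = 1e-10)
  }
})

test_that("combined LR multiplies loci and floors exclusions", {
  db <- mini_db()
  s1 <- mini_profile("S1", c("A", "A"), c("A", "A"))
  s2 <- mini_profile("S2", c("A", "B"), c("A", "A"))
  s3 <- mini_profile("S3", c("A", "C"), c("A", "A"))
  res <- combined_lr(list(s1, s2, s3), db)
  expect_equal(nrow(res$per_locus), 2)
  expect_equal(res$combined, prod(res$per_locus$lr))
  expect_equal(res$log10_combined, log10(res$combined))

  # single locus: combined equals the per-locus LR
  one <- combined_lr(list(s1, s2, s3), db["L1"])
  expect_equal(one$combined, one$per_locus$lr[1])

  # exclusion at L2 drives the floor policy
  s3x <- mini_profile("S3", c("A", "C"), c("B", "C"))
  s1x <- mini_profile("S1", c("A", "A"), c("A", "A"))
  s2x <- mini_profile("S2", c("A", "B"), c("C", "C"))
  resx <- combined_lr(list(s1x, s2x, s3x), db)
  expect_true(any(resx$per_locus$excluded))
  lr_ok <- resx$per_locus$lr[!resx$per_locus$excluded]
  expect_equal(resx$combined, prod(lr_ok) * 0.001)
  # profile-scope flooring coincides here (one excluded locus)
  resp <- combined_lr(list(s1x, s2x, s3x), db, floor_scope = "profile")
  expect_equal(resp$combined, resx$combined)
})

test_that("combined LR is non-increasing as the floor decreases", {
  db <- mini_db()
  s1 <- mini_profile("S1", c("A", "A"), c("A", "A"))
  s2 <- mini_profile("S2", c("A", "B"), c("C", "C"))
  s3 <- mini_profile("S3", c("A", "C"), c("B", "C"))
  floors <- c(0.1, 0.01, 0.001, 1e-6)
  vals <- vapply(floors, function(fl)
    combined_lr(list(s1, s2, s3), db, floor_value = fl)$combined, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("combined LR skips AMEL and demands shared loci", {
  db <- mini_db()
  p1 <- str_profile("S1", list(L1 = c("A", "A"), AMEL = c("X", "Y")))
  p2 <- str_profile("S2", list(L1 = c("A", "B"), AMEL = c("X", "X")))
  p3 <- str_profile("S3", list(L1 = c("A", "C"), AMEL = c("X", "X")))
  res <- combined_lr(list(p1, p2, p3), db)
  expect_equal(res$per_locus$locus, "L1")
  q1 <- str_profile("Q1", list(L2 = c("A", "A")))
  expect_error(combined_lr(list(q1, p2, p3), db), "share no autosomal locus")
})
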