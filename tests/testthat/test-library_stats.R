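test_that("exact completeness matches brute-force outcome enumeration", {
  set.seed(42)
  cases <- list(
    c(x = 0.5, y = 0.5),
    c(x = 0.3, y = 0.2),            # off-target mass 0.5
    c(x = 0.5, y = 0.3, z = 0.2),
    c(x = 0.4, y = 0.3, z = 0.1)    # off-target mass 0.2
  )
  for (p in cases) {
    d <- variant_distribution(p)
    for (L in 0:6) {
      expect_equal(completeness_probability(d, L, names(p), method = "exact"),
                   oracle_completeness(p, L), tolerance = 1e-12,
                   info = sprintf("p = {%s}, L = %d",
                                  paste(p, collapse = ","), L))
    }
  }
  # hand-checkable case: two p = 0.5 variants, two clones, 2 of 4 outcomes hit
  expect_equal(completeness_probability(variant_distribution(c(a = .5, b = .5)),
                                        2, c("a", "b"), method = "exact"), 0.5)
})

test_that("completeness edge cases behave", {
  d <- variant_distribution(c(a = 0.5, b = 0.5))
  expect_equal(completeness_probability(d, 0, c("a", "b")), 0)
  expect_equal(completeness_probability(d, 5, character(0)), 1)
  # a zero-probability target forces 0 at any L
  expect_equal(completeness_probability("NNM", 1e6, c("L", "M")), 0)
  expect_error(
    completeness_probability(variant_distribution(
      stats::setNames(rep(1 / 23, 23), paste0("v", 1:23))),
      10, paste0("v", 1:23), method = "exact"),
    "product")
})

test_that("completeness is nondecreasing in L with exact <= product bracketing", {
  schemes <- list(NNN = amino_acids(), NNK = amino_acids(),
                  NNM = reachable_variants("NNM", include_stop = FALSE))
  for (s in names(schemes)) {
    Ls <- seq(50, 300, 25)
    ex <- vapply(Ls, function(L)
      completeness_probability(s, L, schemes[[s]], method = "exact"), 0)
    pr <- vapply(Ls, function(L)
      completeness_probability(s, L, schemes[[s]], method = "product"), 0)
    expect_true(all(diff(ex) >= 0))
    expect_true(all(diff(pr) >= 0))
    expect_true(all(ex < 1) && all(pr < 1))
    expect_true(all(ex <= pr + 1e-12))        # negative correlation bracket
    expect_true(all((pr - ex)[Ls >= 150] < 5e-3))
  }
})

test_that("min_library_size reproduces the published 95% thresholds", {
  expect_identical(min_library_size(library_design("NNN", "all20")), 240L)
  expect_identical(min_library_size(library_design("NNM")), 163L)
  # boundary property at theta for several designs and both methods
  for (m in c("product", "exact")) {
    for (d in list(library_design("NNN", "all20"), library_design("NNM"),
                   library_design("NNK", "all20", threshold = 0.99),
                   library_design("NNM", threshold = 0.5))) {
      L <- min_library_size(d, method = m)
      expect_gte(completeness_probability(d$dist, L, d$targets, method = m),
                 d$threshold)
      expect_lt(completeness_probability(d$dist, L - 1L, d$targets, method = m),
                d$threshold)
    }
  }
})

test_that("min_library_size handles trivial and impossible designs", {
  d <- variant_distribution(c(a = 1))
  expect_identical(min_library_size(library_design("TGG", "W")), 1L)
  expect_error(min_library_size(library_design("NNM", "all20")),
               "unreachable.*M.*W")
})

test_that("expected_distinct and expected_missing are exact complements", {
  expect_equal(expected_distinct(variant_distribution(c(a = .5, b = .5)), 1), 1.0)
  expect_equal(expected_distinct("NNM", 21), 11.4527, tolerance = 1e-4)
  expect_equal(expected_missing("NNM", 21, amino_acids()), 8.5473,
               tolerance = 1e-4)
  expect_equal(expected_missing("NNM", 0, amino_acids()), 20)
  # unreachable-only target sets stay fully missing forever
  expect_equal(expected_missing("NNM", 1e5, c("M", "W")), 2)
  set.seed(7)
  for (rep in 1:20) {
    p <- random_small_dist(sample(2:8, 1), off_mass = runif(1, 0, 0.3))
    d <- variant_distribution(p)
    n <- sample(0:200, 1)
    expect_equal(expected_distinct(d, n, names(p)) +
                   expected_missing(d, n, names(p)),
                 length(p), tolerance = 1e-9)
    expect_equal(expected_distinct(d, n, names(p)),
                 oracle_expected_distinct(p, n), tolerance = 1e-12)
  }
  # large-L limit approaches the reachable target count
  expect_equal(expected_distinct("NNM", 1e4), 18, tolerance = 1e-6)
})

test_that("expected_collection_time matches closed-form coupon collectors", {
  expect_equal(expected_collection_time(variant_distribution(c(a = .5, b = .5))), 3.0)
  # n uniform coupons: n * H_n
  expect_equal(expected_collection_time(variant_distribution(
    stats::setNames(rep(1 / 3, 3), letters[1:3]))), 3 * (1 + 1 / 2 + 1 / 3))
  # off-target mass scales waiting time by 1 / P(on target) (Wald)
  expect_equal(expected_collection_time(variant_distribution(
    c(a = 0.25, b = 0.25))), 6.0)
  expect_error(expected_collection_time("NNM", c("L", "W")), "unreachable")
})

test_that("probability_monotypic is direct exponentiation", {
  expect_equal(probability_monotypic("NNM", "L", 21), (3 / 32)^21)
  expect_equal(probability_monotypic("NNM", "L", 0), 1)
  expect_equal(probability_monotypic(variant_distribution(c(a = 1)), "a", 5), 1)
  expect_error(probability_monotypic("NNM", "B", 3), "unknown variant")
})

test_that("expected_counts scales probabilities by screen size", {
  ec <- expected_counts(32, "NNM")
  expect_equal(ec[["L"]], 3)
  expect_equal(ec[["C"]], 1)
  expect_equal(ec[["*"]], 2)
  expect_true(all(expected_counts(0, "NNK") == 0))
  u <- variant_distribution(stats::setNames(rep(0.25, 4), letters[1:4]))
  expect_true(all(expected_counts(8, u) == 2))
})

test_that("write_size_report emits a well-formed table", {
  tf <- tempfile(fileext = ".tsv")
  rep <- write_size_report(list(library_design("NNN", "all20"),
                                library_design("NNM")), path = tf)
  expect_identical(rep$L_star, c(240L, 163L))
  back <- read.delim(tf)
  expect_identical(back$L_star, c(240L, 163L))
  expect_true(all(back$P_at_L >= 0.95 & back$P_below < 0.95))
  tj <- tempfile(fileext = ".json")
  write_size_report(library_design("NNM"), path = tj, format = "json")
  expect_identical(jsonlite::fromJSON(tj)$L_star, 163L)
})
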