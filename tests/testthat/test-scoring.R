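test_that("label codes encode masked/exposed character counts", {
  expect_identical(label_code("name", 0), 3L)
  expect_identical(label_code("name", 1), 12L)
  expect_identical(label_code("name", 2), 21L)
  expect_identical(label_code("name", 3), 30L)
  expect_identical(label_code("age", 0), 2L)
  expect_identical(label_code("age", 2), 20L)
  expect_identical(label_code("phone", "none"), 8L)
  expect_identical(label_code("phone", "partial"), 17L)
  expect_identical(label_code("phone", "full"), 80L)
  expect_identical(label_code("blood", FALSE), 1L)
  expect_identical(label_code("illness", TRUE), 0L)
  expect_error(label_code("age", 5), "unknown masking level")
  expect_error(label_code("phone", "half"), "unknown masking level")
})

test_that("usability is the digit product rule over the label codes", {
  worked <- c(name = 12, age = 11, phone = 17, blood = 1, region = 1,
              illness = 0, smoking = 1)
  expect_identical(usability(worked), 13L)
  all_masked <- c(name = 30, age = 20, phone = 80, blood = 0, region = 0,
                  illness = 0, smoking = 0)
  expect_identical(usability(all_masked), 0L)
  # fully unmasked: name 03 and phone 08 contribute 0 by the digit product
  all_clear <- c(name = 3, age = 2, phone = 8, blood = 1, region = 1,
                 illness = 1, smoking = 1)
  expect_identical(usability(all_clear), 4L)
  expect_error(usability(c(name = 12, age = 11)), "entries")
})

test_that("usability depends only on the labels, never on the cohort", {
  pol <- masking_policy(name_level = 2, phone_level = "partial")
  u <- usability(label_policy(pol))
  for (s in c(11, 12)) {
    expect_identical(score_policy(generate_cohort(50, seed = s), pol)$usability,
                     u)
  }
})

test_that("distinct group counting matches the pairwise brute-force oracle", {
  same <- data.frame(a = rep("x", 4), b = rep("y", 4))
  expect_identical(distinct_groups(same), 1L)
  alldiff <- data.frame(a = letters[1:5], b = LETTERS[1:5])
  expect_identical(distinct_groups(alldiff), 5L)

  six <- data.frame(
    name = c("* Ka Na", "* Ka Na", "* Jun Hak", "* Jun Hak", "* Seo Yun",
             "* Mi Rae"),
    age = c("2*", "2*", "3*", "3*", "2*", "4*"),
    stringsAsFactors = FALSE)
  expect_identical(distinct_groups(six), 4L)
  expect_identical(distinct_groups(six), brute_distinct_groups(six))
  expect_error(distinct_groups(six[0, ]), "empty")
})

test_that("field values that merely concatenate alike are not conflated", {
  tricky <- data.frame(a = c("ab", "a"), b = c("c", "bc"),
                       stringsAsFactors = FALSE)
  expect_identical(distinct_groups(tricky), 2L)
})

test_that("confidentiality percentage divides groups by original rows", {
  fx <- make_fixtures(1)
  fully <- apply_policy(fx$cohorts$n5, fx$policies$full)
  expect_equal(confidentiality_pct(fully, 5), 20)
  clear <- apply_policy(fx$cohorts$n200, fx$policies$clear)
  expect_equal(confidentiality_pct(clear, 200), 100)  # unique phones
  six <- data.frame(x = c("a", "a", "b", "b", "c", "d"))
  expect_equal(confidentiality_pct(six, 6), 400 / 6, tolerance = 1e-12)
  expect_error(confidentiality_pct(six, 0), "positive")
})

test_that("confidentiality banding follows the documented boundary rules", {
  cases <- rbind(
    c(0.5, 15), c(20, 15), c(20.01, 12), c(40, 12), c(50, 9), c(60, 9),
    c(60.5, 6), c(80, 6), c(80.5, 3), c(98.9, 3), c(99, 1), c(99.9, 1),
    c(100, 0))
  for (i in seq_len(nrow(cases))) {
    expect_identical(confidentiality_value(cases[i, 1]),
                     as.integer(cases[i, 2]))
  }
  expect_identical(sort(unique(vapply(
    c(10, 30, 50, 70, 90, 99.5, 100), confidentiality_value, integer(1)))),
    c(0L, 1L, 3L, 6L, 9L, 12L, 15L))
  expect_error(confidentiality_value(0), "\\(0, 100\\]")
  expect_error(confidentiality_value(100.1), "\\(0, 100\\]")
})

test_that("the final score sums usability and the confidentiality band", {
  expect_identical(final_score(13, 20)$final_score, 28L)
  expect_identical(final_score(0, 100)$final_score, 0L)
  expect_identical(final_score(4, 100)$final_score, 4L)
  fx <- make_fixtures(1)
  sc <- score_policy(fx$cohorts$n5, fx$policies$full)
  expect_identical(sc$usability + sc$confidentiality_value, sc$final_score)
  expect_identical(sc$final_score, 15L)
})

test_that("deduplication agrees with the brute-force oracle on random policies", {
  spec <- default_demographics()
  set.seed(41)
  for (i in 1:10) {
    cohort <- generate_cohort(sample(20:120, 1), spec,
                              seed = sample.int(1e6, 1))
    masked <- apply_policy(cohort, random_policy())
    expect_identical(distinct_groups(masked), brute_distinct_groups(masked))
  }
})

test_that("masking more never increases groups nor decreases the band score", {
  spec <- default_demographics()
  set.seed(17)
  cohort <- generate_cohort(150, spec, seed = 99)
  for (i in 1:20) {
    a <- random_policy()
    b <- escalate_policy(a)
    ga <- distinct_groups(apply_policy(cohort, a))
    gb <- distinct_groups(apply_policy(cohort, b))
    expect_lte(gb, ga)
    expect_gte(confidentiality_value(gb / 150 * 100),
               confidentiality_value(ga / 150 * 100))
  }
})
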