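# Four herbs whose cross-pair AS is 3 + Dice(function sets): all pairs above
# threshold with graded, distinct totals.
graded_block <- function() {
  dplyr::bind_rows(
    make_herb("a1", "cold", "sweet", "lung", paste0("f", 1:4), "ind a1"),
    make_herb("a2", "cold", "sweet", "lung", paste0("f", c(1, 2, 5, 6)), "ind a2"),
    make_herb("b1", "cold", "sweet", "lung", paste0("f", c(1, 2, 3, 7)), "ind b1"),
    make_herb("b2", "cold", "sweet", "lung", paste0("f", c(1, 8, 9, 10)), "ind b2")
  )
}

test_that("the case-study matching keeps exactly the one high-AS pair", {
  fx <- fixture_case_study()
  i1 <- match("fdhjst", fx$formulae$name); i2 <- match("fft", fx$formulae$name)
  sh <- shared_herbs(fx$formulae, "fdhjst", "fft")
  m <- match_high_as_pairs(fx$herbs,
                           setdiff(fx$formulae$herbs[[i1]], sh$herb),
                           setdiff(fx$formulae$herbs[[i2]], sh$herb))
  expect_equal(nrow(m), 1)
  expect_equal(m$herb1, "root of doubleteeth pubescent angelica")
  expect_equal(m$herb2, "notopterygium root")
  expect_gt(m$as_total, 3)
})

test_that("no pair above threshold gives an empty matching", {
  herbs <- dplyr::bind_rows(
    make_herb("x", "cold", "sweet", "lung", "fn a", "ind a"),
    make_herb("y", "hot", "bitter", "heart", "fn b", "ind b")
  )
  expect_equal(nrow(match_high_as_pairs(herbs, "x", "y")), 0)
})

test_that("greedy matching keeps the highest-AS disjoint pairs in a 2x2 block", {
  herbs <- graded_block()
  m <- match_high_as_pairs(herbs, c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(m), 2)
  # oracle: enumerate both perfect matchings of the 2x2 block
  score <- function(p) as_score(herbs, p[[1]], p[[2]])$as_total
  m1 <- list(c("a1", "b1"), c("a2", "b2"))
  m2 <- list(c("a1", "b2"), c("a2", "b1"))
  best_first <- max(vapply(c(m1, m2), score, numeric(1)))
  expect_equal(m$as_total[[1]], best_first)            # top pair kept first
  expect_setequal(paste(m$herb1, m$herb2), c("a1 b1", "a2 b2"))
})

test_that("the case-study simplification takes new_F1 and emits the 6-herb formula", {
  fx <- fixture_case_study()
  res <- simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
  expect_equal(res$branch, "new_F1")
  expect_equal(res$k_shared, 5)
  expect_equal(res$p, 1); expect_equal(res$q, 1)
  expect_equal(res$sum_wp, 1)
  expect_equal(res$sum_wq, 0.375)
  expect_equal(nrow(res$new_formulae), 1)
  emitted <- res$new_formulae$herbs[[1]]
  ffdht <- fx$formulae$herbs[[match("ffdht", fx$formulae$name)]]
  expect_length(emitted, 6)
  expect_setequal(emitted, ffdht)
  # matched-herb weights recomputed independently at their original positions
  h1 <- fx$formulae$herbs[[match("fdhjst", fx$formulae$name)]]
  h2 <- fx$formulae$herbs[[match("fft", fx$formulae$name)]]
  expect_equal(res$sum_wp,
               sum(1 + (1 - match(res$matched_pairs$herb1, h1)) / length(h1)))
  expect_equal(res$sum_wq,
               sum(1 + (1 - match(res$matched_pairs$herb2, h2)) / length(h2)))
})

test_that("swapping the arguments mirrors the branch with the same herb sets", {
  fx <- fixture_case_study()
  a <- simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
  b <- simplify_pair(fx$formulae, "fft", "fdhjst", fx$herbs, fx$ontology)
  expect_equal(b$branch, "new_F2")
  expect_setequal(a$new_formulae$herbs[[1]], b$new_formulae$herbs[[1]])
  expect_equal(b$p, a$q); expect_equal(b$q, a$p)
})

test_that("determinism: identical inputs give identical results", {
  fx <- fixture_case_study()
  a <- simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
  b <- simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
  expect_identical(a, b)
})

test_that("tied P and total weight emits both reduced formulae", {
  herbs <- dplyr::bind_rows(
    graded_block(),
    make_herb("shared herb", "ping", "salty", "spleen", "fn s", "ind s")
  )
  f <- dplyr::bind_rows(
    make_formula("left", c("shared herb", "a1")),
    make_formula("right", c("shared herb", "b1"))
  )
  res <- simplify_pair(f, "left", "right", herbs, force = TRUE)
  expect_equal(res$p, 1); expect_equal(res$q, 1)
  expect_equal(res$sum_wp, res$sum_wq)
  expect_equal(res$branch, "both")
  expect_equal(nrow(res$new_formulae), 2)
  expect_equal(res$new_formulae$herbs[[1]], c("shared herb", "a1"))
  expect_equal(res$new_formulae$herbs[[2]], c("shared herb", "b1"))
})

test_that("an empty matching reduces both sides to the shared herbs", {
  herbs <- dplyr::bind_rows(
    make_herb("shared herb", "ping", "salty", "spleen", "fn s", "ind s"),
    make_herb("u1", "cold", "sweet", "lung", "fn a", "ind a"),
    make_herb("u2", "hot", "bitter", "heart", "fn b", "ind b")
  )
  f <- dplyr::bind_rows(
    make_formula("left", c("shared herb", "u1")),
    make_formula("right", c("shared herb", "u2"))
  )
  res <- simplify_pair(f, "left", "right", herbs, force = TRUE)
  expect_equal(res$branch, "both")
  expect_equal(res$p, 0); expect_equal(res$q, 0)
  expect_equal(res$new_formulae$herbs[[1]], "shared herb")
  expect_equal(res$new_formulae$herbs[[2]], "shared herb")
})

test_that("a caller-supplied unbalanced matching drives the least-herbs branches", {
  herbs <- dplyr::bind_rows(
    graded_block(),
    make_herb("shared herb", "ping", "salty", "spleen", "fn s", "ind s")
  )
  f <- dplyr::bind_rows(
    make_formula("left", c("shared herb", "a1", "a2")),
    make_formula("right", c("shared herb", "b1"))
  )
  # both F1 herbs pair with the single F2 herb: P = 2 > Q = 1 -> keep F2 side
  matched <- tibble::tibble(herb1 = c("a1", "a2"), herb2 = c("b1", "b1"),
                            as_total = c(3.75, 3.5))
  res <- simplify_pair(f, "left", "right", herbs, force = TRUE,
                       matched = matched)
  expect_equal(res$p, 2); expect_equal(res$q, 1)
  expect_equal(res$branch, "new_F2")
  expect_equal(res$new_formulae$herbs[[1]], c("shared herb", "b1"))
  # mirrored: P = 1 < Q = 2 -> keep F1 side
  res2 <- simplify_pair(f, "right", "left", herbs, force = TRUE,
                        matched = tibble::tibble(
                          herb1 = c("b1", "b1"), herb2 = c("a1", "a2"),
                          as_total = c(3.75, 3.5)))
  expect_equal(res2$branch, "new_F1")
  expect_equal(res2$new_formulae$herbs[[1]], c("shared herb", "b1"))
})

test_that("new formulae never exceed their parents or invent herbs", {
  fx <- fixture_case_study()
  res <- simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
  h1 <- fx$formulae$herbs[[match("fdhjst", fx$formulae$name)]]
  h2 <- fx$formulae$herbs[[match("fft", fx$formulae$name)]]
  emitted <- res$new_formulae$herbs[[1]]
  expect_lte(length(emitted), min(length(h1), length(h2)))
  expect_true(all(emitted %in% union(h1, h2)))
})

test_that("band preconditions are enforced and name which band failed", {
  fx <- fixture_case_study()
  expect_error(simplify_pair(fx$formulae, "ssjy", "skt", fx$herbs, fx$ontology),
               "CD band")
  # 4 of 5 herbs shared -> raw CD 2.8, cd 0.373 (middle) but no DOIDs -> Sim
  f <- dplyr::bind_rows(
    make_formula("x", c("s1", "s2", "s3", "s4", "u1"), doids = character(0)),
    make_formula("y", c("s1", "s2", "s3", "s4", "u2"), doids = character(0))
  )
  herbs <- dplyr::bind_rows(
    purrr::map(paste0("s", 1:4),
               ~ make_herb(.x, "cold", "sweet", "lung", "fn", "ind")),
    make_herb("u1", "hot", "salty", "heart", "fn2", "ind2"),
    make_herb("u2", "warm", "spicy", "liver", "fn3", "ind3")
  )
  expect_error(simplify_pair(f, "x", "y", herbs), "Sim band")
})

test_that("tidy and glance expose the audit trail", {
  fx <- fixture_case_study()
  res <- simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
  expect_equal(nrow(tidy(res)), 1)
  g <- glance(res)
  expect_equal(g$branch, "new_F1")
  expect_equal(g$new_size, 6)
})
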