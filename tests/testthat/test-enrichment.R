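test_that("formula targets are the union over its herbs", {
  f <- dplyr::bind_rows(make_formula("f", c("ha", "hb")),
                        make_formula("empty", "hz"))
  tm <- tibble::tibble(herb = c("ha", "ha", "hb", "hb"),
                       gene = c("g1", "g2", "g2", "g3"))
  class(tm) <- c("target_map", class(tm))
  expect_equal(collect_targets(f, "f", tm), c("g1", "g2", "g3"))
  expect_warning(g <- collect_targets(f, "empty", tm), "no mapped targets")
  expect_length(g, 0)
})

test_that("shared targets intersect herb-level sets, or join via compounds", {
  f <- dplyr::bind_rows(make_formula("f1", "ha"), make_formula("f2", "hb"),
                        make_formula("f3", "hc"))
  tm <- tibble::tibble(herb = c("ha", "ha", "hb", "hc"),
                       gene = c("g1", "g2", "g2", "g9"))
  class(tm) <- c("target_map", class(tm))
  expect_equal(shared_targets(f, "f1", "f2", tm), "g2")
  expect_length(shared_targets(f, "f1", "f3", tm), 0)
  expect_equal(shared_targets(f, "f1", "f1", tm), c("g1", "g2"))

  tm3 <- tibble::tibble(herb = c("ha", "hb", "ha"),
                        compound = c("c1", "c1", "c2"),
                        gene = c("g5", "g6", "g7"))
  class(tm3) <- c("target_map", class(tm3))
  # compound c1 occurs in herbs of both formulae: all its genes are shared
  expect_setequal(shared_targets(f, "f1", "f2", tm3), c("g5", "g6"))
})

test_that("the bundled case-study pair shares exactly 78 target genes", {
  fx <- fixture_case_study()
  g <- shared_targets(fx$formulae, "ssjy", "skt", fx$targets)
  expect_length(g, 78)
  # the post-replacement formula carries the same shared-target set
  g_new <- collect_targets(fx$formulae, "sjzby", fx$targets)
  expect_true(all(g %in% g_new))
})

test_that("a fully contained query reproduces the closed-form tail", {
  pc <- new_pathway_collection(list(
    hit = paste0("g", 1:5),
    rest = paste0("g", 6:50)
  ))
  res <- overrepresentation(paste0("g", 1:5), pc, alpha = 1, top = 20)
  expect_equal(res$p_value[res$pathway == "hit"], 1 / choose(50, 5))
})

test_that("zero overlap everywhere yields an empty result", {
  pc <- new_pathway_collection(list(a = c("g1", "g2"), b = c("g3", "g4")))
  res <- suppressWarnings(overrepresentation("zz", pc))
  expect_equal(nrow(res), 0)
})

test_that("larger overlap at fixed margins strictly decreases the p-value", {
  pc <- new_pathway_collection(list(pw = paste0("g", 1:10),
                                    bg = paste0("g", 11:100)))
  p_small <- overrepresentation(c(paste0("g", 1:2), paste0("g", 11:20)),
                                pc, alpha = 1, top = 99)
  p_large <- overrepresentation(c(paste0("g", 1:4), paste0("g", 21:28)),
                                pc, alpha = 1, top = 99)
  expect_lt(p_large$p_value[p_large$pathway == "pw"],
            p_small$p_value[p_small$pathway == "pw"])
})

test_that("p-values equal exhaustive subset enumeration on small universes", {
  set.seed(31)
  universe <- paste0("g", 1:16)
  for (k in 1:5) {
    pw <- sample(universe, sample(3:8, 1))
    pc <- new_pathway_collection(list(pw = pw, all = universe))
    query <- sample(universe, 6)
    res <- overrepresentation(query, pc, alpha = 1.0000001, top = 99)
    got <- res$p_value[res$pathway == "pw"]
    want <- oracle_hyper_tail(universe, pw, length(query),
                              length(intersect(query, pw)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rows sort by ascending p with name tie-breaks, truncated to top", {
  pc <- new_pathway_collection(list(
    bbb = paste0("g", 1:5), aaa = paste0("g", 1:5),
    weak = c(paste0("g", 1:2), paste0("g", 40:49)),
    rest = paste0("g", 6:60)
  ))
  res <- overrepresentation(paste0("g", 1:5), pc, alpha = 1, top = 3)
  expect_equal(nrow(res), 3)
  expect_equal(res$pathway[1:2], c("aaa", "bbb"))   # equal p, name order
  expect_true(!is.unsorted(res$p_value))
})

test_that("query genes outside the universe are dropped with a warning", {
  pc <- new_pathway_collection(list(a = c("g1", "g2", "g3"),
                                    b = c("g4", "g5")))
  expect_warning(res <- overrepresentation(c("g1", "nope"), pc, alpha = 1),
                 "dropped")
  expect_equal(res$query_size[[1]], 1)
  expect_error(overrepresentation("g1", list()), "pathway_collection")
})

test_that("the case-study shared targets enrich the inflammatory pathway", {
  fx <- fixture_case_study()
  g <- shared_targets(fx$formulae, "ssjy", "skt", fx$targets)
  res <- overrepresentation(g, fx$pathways)
  expect_true("cytokines and inflammatory response" %in% res$pathway)
  expect_true(all(res$p_value < 0.01))
  expect_lte(nrow(res), 20)
})
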