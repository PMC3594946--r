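test_that("normalize_label lowercases, squishes and trims, and is idempotent", {
  expect_equal(normalize_label("Thunberg  Fritillary Bulb "),
               "thunberg fritillary bulb")
  expect_equal(normalize_label("Liquorice"), "liquorice")
  expect_error(normalize_label("  "), "empty after normalization")
  expect_error(normalize_label(" ,. "), "empty after normalization")
  raw <- c("  Mixed CASE  label ", "a;b", "(parenthetical)", "Reed rhizome")
  once <- normalize_label(raw)
  expect_identical(normalize_label(once), once)
})

test_that("herb table reader parses annotations through the lexicon", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tnatures\ttastes\tchannels\tfunctions\tindications",
    "Herb A\tping\tsweet\tlung|heart\t\t",
    "herb b\tslight cold\tbitter\tlung\tfn one|fn two\tcough"
  ), path)
  h <- read_herb_table(path)
  expect_equal(h$nature_vec[[1]], c(cold = 0.25, cool = 0.25, warm = 0.25, hot = 0.25))
  expect_equal(unname(h$channel_vec[[1]][c("lung", "heart")]), c(1, 1))
  expect_equal(sum(h$channel_vec[[1]]), 2)
  expect_length(h$functions[[1]], 0)
  expect_equal(h$nature_vec[[2]][["cold"]], 0.8)
})

test_that("herb table reader reports unknown tokens and duplicate names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tnatures\ttastes\tchannels\tfunctions\tindications",
    "herb a\tlukewarm\tsweet\tlung\t\t"
  ), path)
  expect_error(read_herb_table(path), "lukewarm")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tnatures\ttastes\tchannels\tfunctions\tindications",
    "herb a\tcold\tsweet\tlung\tfirst\t",
    "herb a\twarm\tsweet\tlung\tsecond\t"
  ), path2)
  expect_warning(h <- read_herb_table(path2), "Duplicate herb")
  expect_equal(nrow(h), 1)
  expect_equal(h$functions[[1]], "second")
})

test_that("formula table reader preserves 1-based order and flags duplicates", {
  fx <- fixture_case_study()
  ssjy <- fx$formulae$herbs[[match("ssjy", fx$formulae$name)]]
  expect_length(ssjy, 8)
  expect_equal(ssjy[[8]], "liquorice")
  expect_equal(ssjy[[3]], "forsythia suspensa")
  # formulae without DOIDs are accepted
  ab <- fx$formulae[fx$formulae$name == "abstract pair f1", ]
  expect_length(ab$doids[[1]], 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\therbs\tdiseases\tdoids", "bad\ta|a\t\t"), path)
  expect_error(read_formula_table(path), "duplicate herb")
})

test_that("herb and formula tables round-trip through TSV and JSON", {
  fx <- fixture_case_study()
  for (ext in c(".tsv", ".json")) {
    hp <- withr::local_tempfile(fileext = ext)
    write_herb_table(fx$herbs, hp)
    expect_equal(read_herb_table(hp), fx$herbs)
    fp <- withr::local_tempfile(fileext = ext)
    write_formula_table(fx$formulae, fp)
    expect_equal(read_formula_table(fp), fx$formulae)
  }
})

test_that("synonym table aliases labels before matching", {
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("alias\tcanonical", "forsythia suspense\tforsythia suspensa"), sp)
  syn <- read_synonym_table(sp)
  fp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\therbs\tdiseases\tdoids",
               "f\tForsythia suspense|liquorice\t\t"), fp)
  f <- read_formula_table(fp, synonyms = syn)
  expect_equal(f$herbs[[1]][[1]], "forsythia suspensa")
})

test_that("OBO reader builds a validated DAG and rejects cycles", {
  op <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: mid", "is_a: R ! root", "",
    "[Term]", "id: B", "name: leaf", "is_a: A ! mid"
  ), op)
  dag <- read_obo(op)
  expect_equal(nrow(dag$terms), 3)
  expect_equal(nrow(dag$edges), 2)
  expect_equal(dag$roots, "R")

  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "is_a: A"
  ), cyc)
  expect_error(read_obo(cyc), "cycle")

  undecl <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "is_a: GHOST"), undecl)
  expect_error(read_obo(undecl), "not declared")
})

test_that("GMT reader collects pathways and their gene universe", {
  gp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tg1\tg2", "pw2\tdesc\tg2\tg3"), gp)
  pc <- read_gmt(gp)
  expect_equal(pc$pathways$pw1, c("g1", "g2"))
  expect_setequal(pc$universe, c("g1", "g2", "g3"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_name\tdesc", bad)
  expect_error(read_gmt(bad), "line 1")
})

test_that("target table reader accepts two and three column dialects", {
  tp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb\tgene", "Herb A\tg1", "herb a\tg2"), tp)
  tm <- read_target_table(tp)
  expect_equal(sort(tm$gene[tm$herb == "herb a"]), c("g1", "g2"))
  tp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("herb\tcompound\tgene", "h\tc1\tg1"), tp3)
  expect_true("compound" %in% names(read_target_table(tp3)))
})
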