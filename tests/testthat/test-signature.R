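test_that("signatures rank by absolute score with lexicographic tie-break", {
  sig <- gene_signature(c("b", "a", "c", "d"), c(1.0, -0.5, 0.3, -0.5))
  expect_equal(sig$entries$symbol, c("B", "A", "D", "C"))
  expect_equal(sig$entries$score, c(1.0, -0.5, -0.5, 0.3))
  d <- signature_directions(sig)
  expect_setequal(c(d$up, d$down), sig$entries$symbol)
  expect_true(all(d$up %in% c("B", "C")) && all(d$down %in% c("A", "D")))
})

test_that("zero and non-finite scores are rejected", {
  expect_error(gene_signature("A", 0), "zero or non-finite")
  expect_error(gene_signature(c("A", "B"), c(1, NaN)), "zero or non-finite")
  expect_error(gene_signature(" ", 1), "empty gene symbols")
})

test_that("duplicate symbols keep the largest absolute score", {
  expect_warning(sig <- gene_signature(c("Gfap", "GFAP"), c(0.4, -1.1)),
                 "duplicate")
  expect_equal(nrow(sig$entries), 1)
  expect_equal(sig$entries$score, -1.1)
})

test_that("DEG tables round-trip exactly and dedup deterministically", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2fc\tp_value",
               "gene1\t1.0\t0.01", "gene2\t-0.5\t0.2", "gene3\t0.3\t0.04"), f)
  sig <- read_deg_table(f)
  expect_equal(sig$entries$symbol, c("GENE1", "GENE2", "GENE3"))

  # round trip at full precision, including an irrational-ish score
  sig2 <- gene_signature(c("A", "B"), c(log2(1.2), -pi / 7),
                         p_values = c(0.01, 0.5))
  f2 <- tempfile(fileext = ".tsv")
  write_deg_table(sig2, f2)
  back <- read_deg_table(f2)
  expect_identical(back$entries$symbol, sig2$entries$symbol)
  expect_identical(back$entries$score, sig2$entries$score)
  expect_identical(back$entries$p_value, sig2$entries$p_value)

  # duplicating input rows does not change the result (dedup is deterministic)
  writeLines(c("gene\tlog2fc", "Gfap\t0.4", "Gfap\t-1.1", "Gfap\t0.4"), f)
  expect_warning(dup <- read_deg_table(f), "duplicate")
  expect_equal(dup$entries$score, -1.1)
})

test_that("linear fold changes convert to log2, rejecting bad rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tscore", "up\t1.2", "down\t-1.5", "zero\t0"), f)
  expect_message(sig <- read_deg_table(f, score_column_is_log2 = FALSE),
                 "dropped")
  e <- sig$entries
  expect_equal(e$score[e$symbol == "UP"], log2(1.2))
  expect_equal(e$score[e$symbol == "DOWN"], -log2(1.5))
  expect_false("ZERO" %in% e$symbol)
})

test_that("malformed DEG tables are format errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("symbol\tfc", "A\t1"), f)
  expect_error(read_deg_table(f), "must have columns")
  writeLines("gene\tlog2fc", f)
  expect_error(read_deg_table(f), "empty")
})

test_that("GMT parsing enforces the dialect", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tb\tD"), f)
  gc <- read_gmt(f)
  expect_length(gc$sets, 2)
  expect_equal(gc$sets$S1, c("A", "B", "C"))
  expect_equal(gc$sets$S2, c("B", "D"))  # case-normalized

  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), f)
  expect_error(read_gmt(f), "duplicate")
  writeLines("S1\tdesc", f)
  expect_error(read_gmt(f), "fewer than 3 fields")

  lines <- sprintf("SET%02d\td\t%s", 1:15,
                   vapply(1:15, function(i)
                     paste(sprintf("G%d_%d", i, 1:4), collapse = "\t"), ""))
  writeLines(lines, f)
  expect_length(read_gmt(f)$sets, 15)

  # write/read round trip
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(read_gmt(f), f2)
  expect_equal(read_gmt(f2)$sets, read_gmt(f)$sets)
})

test_that("harmonize upper-cases, maps orthologs and reports losses", {
  sig <- gene_signature(c("Bdnf", "Xyz1"), c(1, -2), species = "mouse")
  h <- harmonize(sig)
  expect_equal(h$entries$symbol, c("XYZ1", "BDNF"))

  map <- c(BDNF = "BDNF_H")
  expect_message(hm <- harmonize(sig, map), "dropped 1")
  expect_equal(hm$entries$symbol, "BDNF_H")
  expect_equal(attr(hm, "n_dropped"), 1L)

  # two sources collapsing onto one target keep the max-|score| entry
  sig2 <- gene_signature(c("A1", "A2"), c(0.8, -1.5))
  expect_message(hm2 <- harmonize(sig2, c(A1 = "TGT", A2 = "TGT")), "merged 1")
  expect_equal(hm2$entries$score, -1.5)

  # identity map equals the no-map route up to case
  idmap <- setNames(toupper(c("Bdnf", "Xyz1")), toupper(c("Bdnf", "Xyz1")))
  expect_equal(harmonize(sig, idmap)$entries, harmonize(sig)$entries)
})

test_that("ortholog maps must be functional", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("source_gene\ttarget_gene", "A\tX", "A\tY"), f)
  expect_error(read_ortholog_map(f), "not functional")
  writeLines(c("source_gene\ttarget_gene", "A\tX", "a\tx", "B\tY"), f)
  m <- read_ortholog_map(f)
  expect_equal(unname(m[c("A", "B")]), c("X", "Y"))
})

test_that("universe modes behave as set operations", {
  expect_equal(build_universe(c("A", "B", "C"), c("B", "C", "D"))$size, 2)
  expect_equal(build_universe(c("A", "B", "C"), c("B", "C", "D"),
                              mode = "union")$size, 4)
  expect_equal(build_universe(sprintf("g%04d", 1:1000))$size, 1000)
  expect_error(build_universe(c("A"), c("B")), "union")
})
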