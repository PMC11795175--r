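three_refs <- function(seed = 1) {
  generate_references(small_config(seed))
}

test_that("disjointify removes multiply-assigned genes from all signatures", {
  refs <- three_refs()
  # already pairwise disjoint: unchanged
  out <- disjointify(refs$maturity, refs$ph, refs$hyperexcitation)
  expect_equal(out$maturity$entries, refs$maturity$entries)
  expect_equal(sum(attr(out, "removed")), 0)

  # plant a gene shared by all three
  add <- function(sig, g, s) gene_signature(c(sig$entries$symbol, g),
                                            c(sig$entries$score, s),
                                            name = sig$name)
  m <- add(refs$maturity, "GFAP", 1)
  p <- add(refs$ph, "GFAP", -2)
  h <- add(refs$hyperexcitation, "GFAP", 0.5)
  out2 <- suppressMessages(disjointify(m, p, h))
  expect_false(any(vapply(out2, function(s) "GFAP" %in% s$entries$symbol, TRUE)))
  expect_equal(nrow(out2$maturity$entries), nrow(refs$maturity$entries))

  # idempotence
  out3 <- disjointify(out2$maturity, out2$ph, out2$hyperexcitation)
  expect_equal(lapply(out3, `[[`, "entries"), lapply(out2, `[[`, "entries"))

  # emptying a signature is an error
  tiny <- gene_signature("GFAP", 1, name = "tiny")
  expect_error(suppressMessages(disjointify(tiny, p, h)), "empty")
})

test_that("similarity index is the signed -log10 of the overall p", {
  expect_equal(round(similarity_index(9.7e-9, "negative")$value, 2), -8.01)
  expect_equal(similarity_index(1, "negative")$value, 0)
  expect_equal(similarity_index(0.1, "positive")$value, 1)
  expect_error(similarity_index(0, "positive"), "0, 1")
  expect_error(similarity_index(0.5, "sideways"), "dominant")

  # magnitude strictly decreasing in p
  ps <- c(1e-8, 1e-4, 0.01, 0.5, 1)
  vals <- vapply(ps, function(p) abs(similarity_index(p, "positive")$value), 1)
  expect_true(all(diff(vals) < 0 | (ps[-1] == 1 & vals[-1] == 0)))
})

test_that("index flips sign exactly under reference negation", {
  set.seed(23)
  pool <- sprintf("P%04d", 1:800)
  uni <- build_universe(pool, mode = "union")
  q <- random_signature(pool, 80, "q")
  r <- random_signature(pool, 60, "r")
  a <- similarity_index(signature_overlap(q, r, uni))
  b <- similarity_index(signature_overlap(q, negate_signature(r), uni))
  expect_equal(b$value, -a$value)
})

test_that("index table has one row per dataset and flags failures", {
  cfg <- small_config(3)
  refs <- generate_references(cfg)
  uni <- synthetic_universe(cfg)
  d1 <- generate_dataset(cfg, refs, "d1",
                         planted = list(maturity = c(0.5, 0)), seed = 31)
  d2 <- generate_dataset(cfg, refs, "d2", seed = 32)
  degs <- lapply(list(d1, d2), function(d) call_degs(d$matrix, name = d$name))
  names(degs) <- c("d1", "d2")
  tab <- build_index_table(degs, refs, uni)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dataset, c("d1", "d2"))
  expect_true(all(tab$complete))
  # strong concordant planting on maturity only -> strongly positive there
  expect_gt(tab$maturity_index[1], 3)
  expect_gt(tab$maturity_index[1], abs(tab$ph_index[1]))

  # a dataset outside the universe is flagged incomplete, not fatal
  rogue <- gene_signature(c("NOT_IN_UNIVERSE", "ALSO_NOT"), c(1, -1))
  tab2 <- suppressWarnings(
    build_index_table(c(degs, list(rogue = rogue)), refs, uni))
  expect_false(tab2$complete[3])
  expect_equal(sum(tab2$complete), 2)
})

test_that("correlation matches the closed-form Pearson and OLS line", {
  tab <- data.frame(dataset = letters[1:5],
                    maturity_index = c(1, 2, 3, 4, 5),
                    ph_index = c(3, 5, 7, 9, 11),  # exactly 2x + 1
                    hyperexcitation_index = c(2.3, -1.1, 0.7, 4.2, -3.5),
                    complete = TRUE)
  out <- correlate_indices(tab, "maturity_ph")
  expect_equal(out$r, 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)

  # hand-computed Pearson for an arbitrary pair
  x <- tab$maturity_index; y <- tab$hyperexcitation_index
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out2 <- correlate_indices(tab, "maturity_hyperexcitation")
  expect_equal(out2$r, r_hand)
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(out2$p, 2 * pt(abs(t_hand), 3, lower.tail = FALSE))

  # invariant to row order and joint positive rescaling
  out3 <- correlate_indices(tab[sample(5), ], "maturity_hyperexcitation")
  expect_equal(out3$r, out2$r)
  tab2 <- tab
  tab2$maturity_index <- 3.7 * tab2$maturity_index
  tab2$hyperexcitation_index <- 0.2 * tab2$hyperexcitation_index
  expect_equal(correlate_indices(tab2, "maturity_hyperexcitation")$r, out2$r)

  expect_error(correlate_indices(tab[1:2, ], "maturity_ph"), "at least 3")
  tab$ph_index <- 1
  expect_error(correlate_indices(tab, "maturity_ph"), "zero variance")
})
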