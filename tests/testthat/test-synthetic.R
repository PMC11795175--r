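test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(universe_size = 100, maturity_size = 90,
                                hyper_size = 90, seed = 1), "exceed")
  expect_error(synthetic_config(rho_concordant = 0.7, rho_discordant = 0.5,
                                seed = 1), "sum <= 1")
  expect_error(synthetic_config(universe_size = 100), "seed")
  cfg <- synthetic_config(seed = 1)
  expect_equal(c(cfg$ph_up_size, cfg$ph_down_size), c(39L, 268L))
  expect_equal(cfg$n_case, 3L)
  expect_equal(cfg$effect_log2fc, 1.0)
})

test_that("reference generation is deterministic with exact pH counts", {
  cfg <- synthetic_config(seed = 4)
  refs <- generate_references(cfg)
  expect_equal(sum(refs$ph$entries$score > 0), 39)
  expect_equal(sum(refs$ph$entries$score < 0), 268)
  expect_equal(nrow(refs$maturity$entries), 800)
  expect_equal(nrow(refs$hyperexcitation$entries), 1200)

  # pairwise disjoint by construction
  syms <- lapply(refs, function(s) s$entries$symbol)
  expect_length(intersect(syms[[1]], syms[[2]]), 0)
  expect_length(intersect(syms[[1]], syms[[3]]), 0)
  expect_length(intersect(syms[[2]], syms[[3]]), 0)

  # same seed twice -> identical signatures
  expect_identical(generate_references(cfg), refs)
})

test_that("planted counts follow the floor rule and the truth record", {
  cfg <- small_config(7)
  refs <- generate_references(cfg)
  d <- generate_dataset(cfg, refs, planted = list(maturity = c(0.5, 0)),
                        seed = 7)
  expect_length(d$truth$maturity$concordant, floor(0.5 * 120))
  expect_length(d$truth$maturity$discordant, 0)
  expect_length(d$truth$ph$concordant, 0)
  expect_true(all(d$truth$maturity$concordant %in%
                  refs$maturity$entries$symbol))
  expect_length(d$truth$background, 30)

  d0 <- generate_dataset(cfg, refs, seed = 8)  # rho (0,0) everywhere
  expect_true(all(lengths(d0$truth$maturity) == 0))
})

test_that("noise-free generation recovers planted structure exactly", {
  cfg <- small_config(9, noise_sd = 0)
  refs <- generate_references(cfg)
  rho <- list(maturity = c(0.3, 0.2), ph = c(0.1, 0.4),
              hyperexcitation = c(0, 0.25))
  d <- generate_dataset(cfg, refs, planted = rho, seed = 21)
  degs <- suppressWarnings(call_degs(d$matrix))
  planted <- sort(unlist(lapply(d$truth, unlist), use.names = FALSE))
  expect_setequal(degs$entries$symbol, planted)

  # directional partition counts equal truth-record counts per reference
  for (r in names(refs)) {
    parts <- directional_partition(degs, refs[[r]])
    expect_equal(length(parts$up_up) + length(parts$down_down),
                 length(d$truth[[r]]$concordant))
    expect_equal(length(parts$up_down) + length(parts$down_up),
                 length(d$truth[[r]]$discordant))
    ov <- signature_overlap(degs, refs[[r]], synthetic_universe(cfg))
    expect_equal(ov$total_shared,
                 length(d$truth[[r]]$concordant) +
                 length(d$truth[[r]]$discordant))
  }
})

test_that("DEG calling recovers planted genes at the power the design allows", {
  # At the generator defaults (|log2FC| ~ 1.0, log2 noise sd 0.25, 3 + 3
  # samples) the two-sided Welch test has theoretical power ~0.88, so
  # recovery is asserted against 0.85 and the false-call rate against 0.07.
  cfg <- synthetic_config(universe_size = 3000, maturity_size = 500,
                          hyper_size = 600, seed = 13)
  refs <- generate_references(cfg)
  hits <- misses <- false_calls <- unplanted <- 0
  for (s in 1:5) {
    d <- generate_dataset(cfg, refs, planted = list(maturity = c(0.4, 0.1)),
                          seed = 100 + s)
    degs <- call_degs(d$matrix)
    planted <- unlist(lapply(d$truth, unlist), use.names = FALSE)
    hits <- hits + sum(planted %in% degs$entries$symbol)
    misses <- misses + sum(!planted %in% degs$entries$symbol)
    false_calls <- false_calls + sum(!degs$entries$symbol %in% planted)
    unplanted <- unplanted + cfg$universe_size - length(planted)
  }
  expect_gte(hits / (hits + misses), 0.85)
  expect_lte(false_calls / unplanted, 0.07)
})

test_that("cohort generation is deterministic and writes a complete fixture tree", {
  cfg <- small_config(17)
  st1 <- generate_cohort(cfg, n_datasets = 4, n_gmt_terms = 10,
                         gmt_term_size = 8)
  st2 <- generate_cohort(cfg, n_datasets = 4, n_gmt_terms = 10,
                         gmt_term_size = 8)
  expect_identical(st1$truth, st2$truth)
  expect_identical(st1$datasets$dataset_01$matrix$values,
                   st2$datasets$dataset_01$matrix$values)
  expect_identical(st1$gmt$sets, st2$gmt$sets)
  expect_error(generate_cohort(cfg, n_datasets = 2), ">= 3")

  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  write_study(st1, d1); write_study(st2, d2)
  files <- list.files(d1)
  expect_true(all(c("reference_maturity.tsv", "gene_sets.gmt",
                    "truth.json", "dataset_01_matrix.tsv",
                    "dataset_01_groups.tsv") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # fixtures round-trip through the readers
  ref_back <- read_deg_table(file.path(d1, "reference_maturity.tsv"))
  expect_setequal(ref_back$entries$symbol,
                  st1$references$maturity$entries$symbol)
  m_back <- read_expression_matrix(file.path(d1, "dataset_01_matrix.tsv"),
                                   file.path(d1, "dataset_01_groups.tsv"))
  expect_equal(unname(m_back$values),
               unname(st1$datasets$dataset_01$matrix$values))
})

test_that("null cohorts show no planted overlap", {
  cfg <- small_config(19)
  st <- generate_cohort(cfg, n_datasets = 3, trend = "null",
                        n_gmt_terms = 5, gmt_term_size = 5)
  expect_true(all(vapply(st$truth, function(tr)
    all(lengths(tr$maturity) == 0) && all(lengths(tr$ph) == 0), TRUE)))
})
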