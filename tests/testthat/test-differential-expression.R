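p4 <- analysis_params()

test_that("stage-vs-rest t-test matches the df-2 closed form", {
  # focal y = 8.0, others 2.0/2.1/1.9: strong upregulation
  tab <- table_from_y(c(8.0, 2.0, 2.1, 1.9))
  cl <- stage_specific_calls(tab, p4, focal_stages = "PRE")
  tstat <- (2.0 - 8.0) / (0.1 / sqrt(3))
  p_closed <- 1 - abs(tstat) / sqrt(tstat^2 + 2)   # two-tailed CDF, df = 2
  expect_equal(cl$p_value, p_closed, tolerance = 1e-12)
  expect_lt(cl$p_value, 0.001)
  expect_equal(cl$log2_ratio, 6)                   # fold 2^6 = 64
  expect_equal(cl$direction, "up")
  # symmetric case: focal below the others
  cl2 <- stage_specific_calls(table_from_y(c(2.0, 8.0, 8.1, 7.9)), p4,
                              focal_stages = "PRE")
  expect_equal(cl2$direction, "down")
  expect_equal(cl2$log2_ratio, -6)
})

test_that("stage-specific filters are a conjunction of fold and significance", {
  # focal equals the mean of the others: ratio 0, unchanged
  cl <- stage_specific_calls(table_from_y(c(7.0, 6.9, 7.0, 7.1)), p4,
                             focal_stages = "PRE")
  expect_equal(cl$log2_ratio, 0)
  expect_equal(cl$direction, "unchanged")
  # ~3-fold with tiny p still fails the four-fold filter
  cl2 <- stage_specific_calls(table_from_y(c(8.585, 7.0, 7.0, 7.01)), p4,
                              focal_stages = "PRE")
  expect_lt(cl2$p_value, 0.01)
  expect_lt(abs(cl2$log2_ratio), 2)
  expect_equal(cl2$direction, "unchanged")
  # degenerate: non-focal values identical, focal different -> p = 0, flagged
  cl3 <- stage_specific_calls(table_from_y(c(12, 7, 7, 7)), p4,
                              focal_stages = "PRE")
  expect_equal(cl3$p_value, 0)
  expect_true(cl3$degenerate)
  cl4 <- stage_specific_calls(table_from_y(c(7, 7, 7, 7)), p4)
  expect_true(all(cl4$p_value == 1))
})

test_that("settlement contrast pools 2-vs-2 with df 2", {
  # larval y {8.0, 8.1} vs benthic {2.0, 2.1}: 64-fold drop after settlement
  tab <- table_from_y(c(8.0, 8.1, 2.0, 2.1))
  cl <- settlement_calls(tab, p4)
  expect_equal(cl$contrast, "settlement")
  expect_equal(cl$log2_ratio, -6)
  sp2 <- (2 * 0.005 + 2 * 0.005) / 2 / 2     # pooled variance of 2+2 values
  tstat <- -6 / sqrt((0.005 + 0.005) / 2)
  expect_equal(cl$p_value, 2 * pt(-abs(tstat), df = 2), tolerance = 1e-10)
  expect_lt(cl$p_value, 0.05)
  expect_equal(cl$direction, "down")
  # identical groups: unchanged
  cl2 <- settlement_calls(table_from_y(c(7, 7, 7, 7)), p4)
  expect_equal(cl2$direction, "unchanged")
  # means exactly log2(4) apart with near-zero spread: inclusive boundary call
  cl3 <- settlement_calls(table_from_y(c(7.0, 7.0002, 9.0, 9.0002)), p4)
  expect_equal(cl3$log2_ratio, 2, tolerance = 1e-6)
  expect_equal(cl3$direction, "up")
})

test_that("transition classification combines fold and the 5*sqrt(N) gate", {
  mk <- function(n1, n2) {
    m <- matrix(c(n1, n2, 0, 0), 1,
                dimnames = list("g1", c("PRE", "COMP", "POST", "ADULT")))
    toy_counts(m, normalized = TRUE)
  }
  tp <- list(c("PRE", "COMP"))
  # 64 -> 260: fold 4.06 and |196| > 5*sqrt(260) = 80.6 -> up
  cl <- transition_calls(mk(64, 260), p4, transitions = tp)
  expect_equal(cl$direction, "up")
  expect_true(cl$passed_error_gate)
  expect_equal(cl$log2_ratio, log2(260 / 64))
  # no change
  cl2 <- transition_calls(mk(100, 100), p4, transitions = tp)
  expect_equal(cl2$direction, "unchanged")
  # fold 5 but |4| < 5*sqrt(5): the error gate blocks the call
  lax <- analysis_params(threshold = 1)
  cl3 <- transition_calls(mk(1, 5), lax, transitions = tp)
  expect_equal(cl3$direction, "unchanged")
  expect_false(cl3$passed_error_gate)
  # genes below detection in both stages are excluded entirely
  cl4 <- transition_calls(mk(10, 50), p4, transitions = tp)
  expect_equal(nrow(cl4), 0L)
  # 64 -> 256 is exactly four-fold (floored counts), inclusive cutoff
  cl5 <- transition_calls(mk(64, 256), p4, transitions = tp)
  expect_equal(cl5$direction, "up")
})

test_that("swapping transition stages swaps up and down", {
  set.seed(77)
  m <- matrix(rpois(400, 150) * sample(c(1, 8), 400, replace = TRUE), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100),
                              c("PRE", "COMP", "POST", "ADULT")))
  tab <- toy_counts(m, normalized = TRUE)
  fwd <- transition_calls(tab, p4, transitions = list(c("PRE", "COMP")))
  rev <- transition_calls(tab, p4, transitions = list(c("COMP", "PRE")))
  swap <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(unname(swap[fwd$direction]), rev$direction)
})

test_that("two-fold call sets contain the four-fold call sets", {
  set.seed(12)
  m <- matrix(rpois(2000, 200) * sample(c(1, 3, 6), 2000, replace = TRUE),
              500, 4, dimnames = list(sprintf("g%03d", 1:500),
                                      c("PRE", "COMP", "POST", "ADULT")))
  tab <- toy_counts(m, normalized = TRUE)
  p2 <- analysis_params(fold_cutoff = 2)
  for (calls in list(transition_calls, stage_specific_calls)) {
    c4 <- calls(tab, p4); c2 <- calls(tab, p2)
    key <- function(x) paste(x$gene_id, x$contrast, x$direction)
    called4 <- key(c4[c4$direction != "unchanged", ])
    called2 <- key(c2[c2$direction != "unchanged", ])
    expect_true(all(called4 %in% called2))
  }
})

test_that("extreme upregulation uses the max log2 deviation from the rest", {
  tab <- toy_counts(matrix(c(1023, 0, 0, 0), 1,
                           dimnames = list("g1",
                                           c("PRE", "COMP", "POST", "ADULT"))),
                    normalized = TRUE)
  ex <- extreme_upregulation(tab, p4)
  expect_equal(ex$max_upregulation, 10)    # log2(1024) - 0
  expect_true(ex$is_extreme)               # 10 >= log2(100)
  expect_equal(ex$focal_stage, "PRE")
  # 255 vs 3/3/3: statistic 6 falls short of the 100-fold line (~6.644)
  tab2 <- toy_counts(matrix(c(255, 3, 3, 3), 1,
                            dimnames = list("g1",
                                            c("PRE", "COMP", "POST",
                                              "ADULT"))), normalized = TRUE)
  ex2 <- extreme_upregulation(tab2, p4)
  expect_equal(ex2$max_upregulation, 6)
  expect_false(ex2$is_extreme)
  # constant gene scores 0
  tab3 <- toy_counts(matrix(7, 1, 4,
                            dimnames = list("g1",
                                            c("PRE", "COMP", "POST",
                                              "ADULT"))), normalized = TRUE)
  expect_equal(extreme_upregulation(tab3, p4)$max_upregulation, 0)
})

test_that("relative expression rescales each gene to [0, 1]", {
  m <- matrix(c(0, 10, 40, 100,
                5, 5, 5, 5,
                80, 20, 160, 40), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("PRE", "COMP", "POST", "ADULT")))
  rel <- relative_expression(toy_counts(m, normalized = TRUE), p4)
  expect_equal(unname(rel["g1", c("PRE", "ADULT")]), c(0, 1))
  expect_true(all(rel["g2", ] == 0.5))     # constant gene -> 0.5 everywhere
  expect_equal(unname(apply(rel[c("g1", "g3"), ], 1, min)), c(0, 0))
  expect_equal(unname(apply(rel[c("g1", "g3"), ], 1, max)), c(1, 1))
})

test_that("planted stage-specific signals are recovered with correct sign", {
  # 8-fold planted effects on strong baselines (Poisson noise)
  cfg <- synth_config(seed = 15, n_genes = 800, n_reads = 1000,
                      baseline_log2_mean = 7, baseline_log2_sd = 0.8,
                      effect_log2_range = c(3, 3),
                      class_fractions = c(constant = 0.7,
                                          stage_specific = 0.2,
                                          transition = 0, silent = 0.1))
  d <- generate_dataset(cfg)
  norm <- normalize_depth(d$counts, "PRE")
  sc <- stage_specific_calls(norm, p4)
  ev <- evaluate_calls(d$truth, stage_calls = sc)
  expect_gte(ev$stage_specific$sensitivity, 0.9)
  expect_gte(ev$stage_specific$direction_accuracy, 0.99)
})
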