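mk_epoch_table <- function() {
  data.frame(animal_id = rep(c("a1", "a2"), each = 4),
             group = "ChR2",
             stage = rep(c("CS1", "CS2", "CS3", "CS4"), 2),
             percent_freezing = c(80, 60, 40, 20, 50, 50, 50, 50))
}

test_that("stage means average epochs per animal and flag missing epochs", {
  tbl <- mk_epoch_table()
  out <- stage_means(tbl, list(CS_1_4 = c("CS1", "CS2", "CS3", "CS4")))
  expect_equal(out$percent_freezing[out$animal_id == "a1"], 50)
  expect_equal(out$percent_freezing[out$animal_id == "a2"], 50)
  # single-epoch stage is the epoch itself
  one <- stage_means(tbl, list(CS1 = "CS1"))
  expect_equal(one$percent_freezing[one$animal_id == "a1"], 80)
  # an animal missing an epoch is excluded from that stage with a warning
  miss <- tbl[-3, ]  # drop a1's CS3
  expect_warning(out2 <- stage_means(miss, list(CS_1_4 = c("CS1", "CS2", "CS3", "CS4"))),
                 "a1")
  expect_false("a1" %in% out2$animal_id)
  expect_true("a2" %in% out2$animal_id)
  expect_error(stage_means(tbl, list(x = "CS9")), "unknown epoch")
})

test_that("extinction criterion: strict threshold, seven-day cutoff", {
  rec <- data.frame(animal_id = "a1", day = 1:3, mean_freezing = c(80, 70, 59))
  out <- extinction_filter(rec)
  expect_equal(out$days_to_criterion, 3)
  expect_true(out$included)
  stuck <- data.frame(animal_id = "a2", day = 1:7,
                      mean_freezing = c(95, 90, 85, 80, 75, 70, 65))
  out2 <- extinction_filter(stuck)
  expect_true(is.na(out2$days_to_criterion))
  expect_false(out2$included)
  # exactly 60 does not reach criterion (strict <); 59.9 on day 1 does
  border <- data.frame(animal_id = c("b1", "b2"), day = 1,
                       mean_freezing = c(60, 59.9))
  out3 <- extinction_filter(border)
  expect_false(out3$included[out3$animal_id == "b1"])
  expect_true(out3$included[out3$animal_id == "b2"])
  expect_equal(out3$days_to_criterion[out3$animal_id == "b2"], 1)
  # reaching criterion after the cutoff still excludes
  late <- data.frame(animal_id = "c1", day = 1:8,
                     mean_freezing = c(rep(90, 7), 40))
  expect_false(extinction_filter(late)$included)
  expect_error(extinction_filter(rec[0, ]), "non-empty")
})

test_that("planned pooled-variance t-test matches the closed form", {
  a <- c(1, 2, 3); b <- c(3, 4, 5)
  ct <- planned_ttest(a, b)
  oracle <- pooled_t_oracle(a, b)
  expect_equal(ct$t, oracle$t, tolerance = 1e-12)
  expect_equal(ct$t, -2.449, tolerance = 1e-3)
  expect_equal(ct$df, 4)
  expect_equal(ct$p, oracle$p, tolerance = 1e-12)
  expect_equal(ct$p, 0.0705, tolerance = 1e-3)
  # groups of 7 and 7 give the pooled df of 12
  set.seed(2)
  ct7 <- planned_ttest(rnorm(7), rnorm(7))
  expect_equal(ct7$df, 12)
  # degenerate inputs
  same <- planned_ttest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(planned_ttest(c(5, 5, 5), c(7, 7, 7)), "zero pooled variance")
  expect_error(planned_ttest(1, c(1, 2)), "at least 2")
})

test_that("planned t-test agrees with a permutation oracle on toy groups", {
  a <- c(12, 15, 11, 19)
  b <- c(21, 24, 17, 26, 23)
  p_t <- planned_ttest(a, b)$p
  p_perm <- perm_p_oracle(a, b, n_perm = 2e4, seed = 42)
  se <- sqrt(p_perm * (1 - p_perm) / 2e4)
  # permutation p is discrete over C(9,4)=126 splits; allow granularity
  expect_lt(abs(p_t - p_perm), 2 * se + 1 / 126 + 0.01)
})

test_that("t_to_p: symmetry, monotonicity, normal limit, vectorization", {
  expect_equal(t_to_p(0, 5), 1)
  expect_equal(t_to_p(2.3, 10), t_to_p(-2.3, 10))
  ts <- c(0.5, 1, 2, 3)
  expect_true(all(diff(t_to_p(ts, 8)) < 0))
  expect_equal(t_to_p(1.96, 1e6), 2 * pnorm(1.96, lower.tail = FALSE),
               tolerance = 1e-5)
  expect_error(t_to_p(1, 0.5), "df")
})

test_that("control pooling: pooled when indistinguishable, refused otherwise", {
  tbl <- gen_freezing_dataset(freezing_spec(seed = 2), "ABA")
  pc <- pool_controls_check(tbl)
  expect_true(pc$pooled)
  expect_equal(nrow(pc$table), nrow(tbl))
  expect_setequal(pc$table$animal_id, tbl$animal_id)
  expect_equal(sum(pc$table$group == "pooled_control"),
               sum(tbl$group %in% c("control_GFP", "control_nolaser")))
  # a stage with a large built-in difference blocks pooling
  sep <- tbl
  sel_gfp <- sep$group == "control_GFP" & sep$stage == "CS"
  sel_nl <- sep$group == "control_nolaser" & sep$stage == "CS"
  set.seed(1)
  sep$percent_freezing[sel_gfp] <- rnorm(sum(sel_gfp), 10, 5)
  sep$percent_freezing[sel_nl] <- rnorm(sum(sel_nl), 90, 5)
  sep$percent_freezing <- pmin(pmax(sep$percent_freezing, 0), 100)
  pc2 <- pool_controls_check(sep)
  expect_false(pc2$pooled)
  expect_lt(pc2$comparisons$p[pc2$comparisons$stage == "CS"], 0.05)
  expect_true(all(c("control_GFP", "control_nolaser") %in% pc2$table$group))
  expect_error(pool_controls_check(tbl[tbl$group != "control_GFP", ]),
               "absent")
})

test_that("timecourse comparison localizes the laser effect; corrections are monotone", {
  tbl <- gen_freezing_dataset(freezing_spec(laser_stage_delta = 25, seed = 7),
                              "ABA")
  pc <- pool_controls_check(tbl)
  out <- timecourse_compare(pc$table)
  expect_equal(nrow(out), 5)
  expect_lt(out$p[out$stage == "baseline_laser"], 0.05)
  expect_equal(out$df, rep(10 + 18 - 2, 5))
  holm <- timecourse_compare(pc$table, correction = "holm")
  expect_true(all(holm$p_adj >= holm$p - 1e-15))
  bonf <- timecourse_compare(pc$table, correction = "bonferroni")
  expect_true(all(bonf$p_adj >= bonf$p - 1e-15))
  expect_error(timecourse_compare(pc$table, stages = "nope"), "not present")
  expect_error(timecourse_compare(tbl), "pooled_control")
})
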