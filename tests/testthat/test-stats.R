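test_that("rout_outliers flags gross outliers and respects the Q limit", {
  set.seed(11)
  x <- c(rnorm(19, 1, 0.01), 100)
  mask <- rout_outliers(x)
  expect_identical(which(mask), 20L)
  # the flagged point's t-ratio dominates every threshold by brute force
  center <- attr(mask, "center"); rsdr <- attr(mask, "rsdr")
  tr <- abs(x - center) / rsdr
  expect_identical(which.max(tr), 20L)
  expect_lt(2 * pt(-max(tr), df = 19), 0.01)
  # vanishing Q shrinks the threshold below any moderate deviation
  expect_identical(sum(rout_outliers(c(rnorm(19), 6), Q = 1e-12)), 0L)
  expect_error(rout_outliers(rnorm(5)), "n >= 10")
  expect_error(rout_outliers(rnorm(20), Q = 0.5), "Q")
})

test_that("rout_outliers stays near its FDR level on clean normal samples", {
  set.seed(12)
  flags <- replicate(200, mean(rout_outliers(rnorm(20, 5, 0.3))))
  expect_lte(mean(flags), 2 * 0.01)
})

test_that("matched_field_exclusion removes flagged fields from all periods", {
  tab <- cohort_table(
    fov_id = rep(paste0("f", 1:10), times = 3),
    animal_id = rep(rep(c("a1", "a2"), each = 5), 3),
    group_label = rep(rep(c("control", "FIP"), each = 5), 3),
    imaging_period = rep(1:3, each = 10),
    value = rnorm(30))
  # no flags: unchanged
  masks0 <- list(`1` = rep(FALSE, 10), `2` = rep(FALSE, 10),
                 `3` = rep(FALSE, 10))
  expect_identical(nrow(matched_field_exclusion(tab, masks0)), 30L)
  # one fov flagged only at period 2 disappears from every period
  masks1 <- masks0; masks1[["2"]][4] <- TRUE
  out <- matched_field_exclusion(tab, masks1)
  expect_false("f4" %in% out$fov_id)
  expect_identical(nrow(out), 27L)
  expect_identical(attr(out, "excluded_fovs"), "f4")
  # three distinct fovs flagged once each leave 21 of 30 rows
  masks3 <- masks0
  masks3[["1"]][1] <- TRUE; masks3[["2"]][5] <- TRUE; masks3[["3"]][9] <- TRUE
  out3 <- matched_field_exclusion(tab, masks3)
  expect_identical(nrow(out3), 21L)
  # idempotent: re-excluding with recomputed empty masks changes nothing
  masks_none <- lapply(1:3, function(p) rep(FALSE, 7))
  names(masks_none) <- 1:3
  expect_identical(nrow(matched_field_exclusion(out3, masks_none)), 21L)
})

# Independent brute-force two-way sums-of-squares oracle for balanced
# tables, straight from the textbook decomposition.
anova_oracle <- function(values, group, period) {
  grand <- mean(values)
  ga <- tapply(values, group, mean); gb <- tapply(values, period, mean)
  cell <- tapply(values, list(group, period), mean)
  n_cell <- table(group, period)[1, 1]
  a <- length(ga); b <- length(gb)
  ssa <- n_cell * b * sum((ga - grand)^2)
  ssb <- n_cell * a * sum((gb - grand)^2)
  ssab <- n_cell * sum((sweep(sweep(cell, 1, ga), 2, gb) + grand)^2)
  sse <- sum((values - cell[cbind(group, period)])^2)
  dfe <- length(values) - a * b
  list(F_group = (ssa / (a - 1)) / (sse / dfe),
       F_period = (ssb / (b - 1)) / (sse / dfe),
       F_int = (ssab / ((a - 1) * (b - 1))) / (sse / dfe))
}

test_that("two_way_anova matches the brute-force oracle on balanced tables", {
  vals <- c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 7)
  tab <- cohort_table(
    fov_id = paste0("f", 1:12),
    animal_id = rep(c("a", "a", "b", "b"), 3),
    group_label = rep(c("control", "FIP"), each = 6),
    imaging_period = rep(rep(1:3, each = 2), 2),
    value = vals)
  res <- two_way_anova(tab)
  orc <- anova_oracle(vals, rep(c("control", "FIP"), each = 6),
                      rep(rep(1:3, each = 2), 2))
  eff <- setNames(res$effects$F, res$effects$term)
  expect_equal(eff[["group"]], orc$F_group, tolerance = 1e-9)
  expect_equal(eff[["period"]], orc$F_period, tolerance = 1e-9)
  expect_equal(eff[["interaction"]], orc$F_int, tolerance = 1e-9)
  # and on a randomized balanced table
  set.seed(33)
  vals2 <- rnorm(30)
  tab2 <- cohort_table(paste0("g", 1:30), rep("a", 30),
                       rep(c("control", "FIP"), each = 15),
                       rep(rep(1:3, each = 5), 2), vals2)
  res2 <- two_way_anova(tab2)
  orc2 <- anova_oracle(vals2, tab2$group_label, tab2$imaging_period)
  eff2 <- setNames(res2$effects$F, res2$effects$term)
  expect_equal(eff2[["group"]], orc2$F_group, tolerance = 1e-9)
  expect_equal(eff2[["period"]], orc2$F_period, tolerance = 1e-9)
  expect_equal(eff2[["interaction"]], orc2$F_int, tolerance = 1e-9)
})

test_that("degenerate and malformed tables are handled", {
  tab <- cohort_table(paste0("f", 1:12), rep("a", 12),
                      rep(c("control", "FIP"), each = 6),
                      rep(rep(1:3, each = 2), 2), rep(4, 12))
  res <- two_way_anova(tab)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$P == 1))
  # empty cell is named in the error
  bad <- tab[!(tab$group_label == "FIP" & tab$imaging_period == 2), ]
  expect_error(two_way_anova(bad), "FIP, period 2")
  expect_error(cohort_table("f1", "a", "treated", 1, 1), "group_label")
  expect_error(cohort_table(c("f1", "f1"), c("a", "a"),
                            c("FIP", "FIP"), c(1, 1), c(1, 2)),
               "duplicated")
})

test_that("Bonferroni post-hoc multiplies raw P by the number of periods", {
  set.seed(44)
  tab <- cohort_table(paste0("f", 1:30), rep(c("a", "b"), 15),
                      rep(c("control", "FIP"), each = 15),
                      rep(rep(1:3, each = 5), 2),
                      rnorm(30) + rep(c(0, 1), each = 15))
  res <- two_way_anova(tab)
  expect_equal(res$posthoc$p_adj, pmin(1, res$posthoc$p_raw * 3))
  expect_identical(nrow(res$posthoc), 3L)
})

test_that("summarize_groups reports mean and SEM per cell", {
  tab <- cohort_table(paste0("f", 1:6), rep("a", 6),
                      rep(c("control", "FIP"), each = 3),
                      rep(1, 6), c(1, 2, 3, 7, 7, 7))
  s <- summarize_groups(tab)
  ctrl <- s[s$group_label == "control", ]
  expect_equal(ctrl$mean, 2)
  expect_equal(ctrl$sem, 0.5774, tolerance = 1e-4)
  expect_equal(s[s$group_label == "FIP", "sem"], 0)
  one <- cohort_table(c("f1", "f2"), c("a", "a"), c("control", "FIP"),
                      c(1, 1), c(1, 2))
  expect_warning(s1 <- summarize_groups(one), "n = 1")
  expect_true(all(is.na(s1$sem)))
})

test_that("power_heatmap_table arranges fields by animal and period", {
  tab <- data.frame(
    fov_id = rep(c("r2_f1", "r1_f1"), each = 3),
    animal_id = rep(c("r2", "r1"), each = 3),
    imaging_period = rep(1:3, 2),
    value = c(4, 5, 6, 1, 2, 3))
  m <- power_heatmap_table(tab)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(rownames(m), c("r1_f1", "r2_f1"))   # animal order first
  expect_equal(unname(m["r1_f1", ]), c(1, 2, 3))
  # missing cells stay NA, the rest intact
  m2 <- power_heatmap_table(tab[-6, ])
  expect_true(is.na(m2["r1_f1", "period3"]))
  expect_equal(unname(m2["r1_f1", 1:2]), c(1, 2))
  expect_error(power_heatmap_table(rbind(tab, tab[1, ])), "duplicate")
})
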