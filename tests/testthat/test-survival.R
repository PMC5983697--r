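clin <- function(ids, time, event)
  data.frame(sample_id = ids, time = time, event = as.integer(event),
             stringsAsFactors = FALSE)

test_that("median split: hand-computed medians, ties to low, degenerate error", {
  cl <- clin(sprintf("s%d", 1:5), c(10, 20, 30, 40, 50), c(1, 1, 0, 1, 0))
  x <- setNames(c(1, 2, 3, 4, 5), cl$sample_id)
  g <- median_split(x, cl)
  expect_equal(g$split_value, 3)
  expect_setequal(g$low$sample_id, c("s1", "s2", "s3"))  # 3 <= median
  expect_setequal(g$high$sample_id, c("s4", "s5"))

  x4 <- setNames(c(1, 1, 2, 2), cl$sample_id[1:4])
  g4 <- median_split(x4, cl[1:4, ])
  expect_equal(g4$split_value, 1.5)
  expect_equal(nrow(g4$low), 2L)
  expect_equal(nrow(g4$high), 2L)

  expect_error(median_split(setNames(rep(7, 4), cl$sample_id[1:4]), cl),
               "degenerate")
  # samples present in only one input are dropped with a count
  x6 <- setNames(c(1, 2, 3, 4, 9), c("s1", "s2", "s3", "s4", "extra"))
  g6 <- median_split(x6, cl)
  expect_equal(g6$n_dropped, 2L)  # 'extra' and clinical-only 's5'
})

test_that("Kaplan-Meier product-limit estimates match hand computations", {
  none <- km_curve(c(5, 8, 13), c(0, 0, 0))
  expect_equal(none$survival, 1)  # all censored: flat at 1

  all_ev <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all_ev$survival, c(1, 2/3, 1/3, 0))

  cens <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cens$time, c(0, 1, 3))
  expect_equal(cens$survival, c(1, 2/3, 0))  # 2/3 * (1 - 1/1)

  # validity: starts at 1, non-increasing, within [0, 1]
  set.seed(12)
  k <- km_curve(rexp(50, 0.1), rbinom(50, 1, 0.6))
  expect_equal(k$survival[1], 1)
  expect_true(all(diff(k$survival) <= 0))
  expect_true(all(k$survival >= 0 & k$survival <= 1))
})

test_that("Kaplan-Meier agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(13)
  for (rep in 1:5) {
    time <- round(rexp(40, 0.05), 1) + 0.1
    event <- rbinom(40, 1, 0.7)
    ours <- km_curve(time, event)
    ref <- survival::survfit(survival::Surv(time, event) ~ 1)
    at_events <- ref$n.event > 0
    expect_equal(ours$survival[-1], ref$surv[at_events], tolerance = 1e-12)
    expect_equal(ours$time[-1], ref$time[at_events])
  }
})

test_that("log-rank on the frozen hand-computed fixture matches to 1e-9", {
  # low  = {(2,1), (4,1), (6,0)}, high = {(1,1), (3,1), (5,1)}
  # event-time table (O1/E1/V per pooled event time):
  #  t=1: n=6, n1=3, d=1 -> E1=1/2,  V=1/4
  #  t=2: n=5, n1=3, d=1 -> E1=3/5,  V=6/25
  #  t=3: n=4, n1=2, d=1 -> E1=1/2,  V=1/4
  #  t=4: n=3, n1=2, d=1 -> E1=2/3,  V=2/9
  #  t=5: n=2, n1=1, d=1 -> E1=1/2,  V=1/4
  # O1=2, E1=83/30, V=1091/900 -> stat=(2-83/30)^2/(1091/900)=529/1091
  # HR = (2/(83/30)) / (3/(67/30)) = 134/249
  g <- structure(list(low = clin(c("a", "b", "c"), c(2, 4, 6), c(1, 1, 0)),
                      high = clin(c("d", "e", "f"), c(1, 3, 5), c(1, 1, 1)),
                      split_value = 0, n_dropped = 0L),
                 class = "grouped_survival")
  lr <- logrank_test(g)
  expect_equal(lr$statistic, 529 / 1091, tolerance = 1e-9)
  expect_equal(unname(lr$expected["low"]), 83 / 30, tolerance = 1e-9)
  expect_equal(unname(lr$expected["high"]), 67 / 30, tolerance = 1e-9)
  expect_equal(unname(lr$observed), c(2, 3))
  expect_equal(lr$hazard_ratio, 134 / 249, tolerance = 1e-9)
  expect_equal(lr$p_value, pchisq(529 / 1091, 1, lower.tail = FALSE))
  # expected totals partition the events
  expect_equal(sum(lr$expected), sum(lr$observed), tolerance = 1e-9)
})

test_that("log-rank is symmetric: identical groups give 0, label swap inverts HR", {
  same <- structure(list(low = clin(c("a", "b"), c(3, 7), c(1, 1)),
                         high = clin(c("c", "d"), c(3, 7), c(1, 1)),
                         split_value = 0, n_dropped = 0L),
                    class = "grouped_survival")
  lr <- logrank_test(same)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$hazard_ratio, 1)

  set.seed(14)
  g <- structure(list(low = clin(sprintf("a%d", 1:20), rexp(20, 0.2) + 0.1,
                                 rbinom(20, 1, 0.8)),
                      high = clin(sprintf("b%d", 1:25), rexp(25, 0.1) + 0.1,
                                  rbinom(25, 1, 0.8)),
                      split_value = 0, n_dropped = 0L),
                 class = "grouped_survival")
  swapped <- structure(list(low = g$high, high = g$low, split_value = 0,
                            n_dropped = 0L), class = "grouped_survival")
  expect_equal(logrank_test(g)$statistic, logrank_test(swapped)$statistic,
               tolerance = 1e-12)
  expect_equal(logrank_test(g)$hazard_ratio,
               1 / logrank_test(swapped)$hazard_ratio, tolerance = 1e-12)

  noev <- structure(list(low = clin("a", 5, 0), high = clin("b", 6, 0),
                         split_value = 0, n_dropped = 0L),
                    class = "grouped_survival")
  expect_error(logrank_test(noev), "no events")
})

test_that("log-rank statistic matches survival::survdiff on random censored data", {
  skip_if_not_installed("survival")
  set.seed(15)
  for (rep in 1:8) {
    n1 <- sample(10:30, 1); n2 <- sample(10:30, 1)
    g <- structure(list(
      low = clin(sprintf("a%d", 1:n1), round(rexp(n1, 0.1), 1) + 0.1,
                 rbinom(n1, 1, 0.7)),
      high = clin(sprintf("b%d", 1:n2), round(rexp(n2, 0.05), 1) + 0.1,
                  rbinom(n2, 1, 0.7)),
      split_value = 0, n_dropped = 0L), class = "grouped_survival")
    if (sum(g$low$event) + sum(g$high$event) == 0) next
    lr <- logrank_test(g)
    df <- rbind(cbind(g$low, grp = 1), cbind(g$high, grp = 2))
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
    expect_equal(lr$statistic, unname(ref$chisq), tolerance = 1e-8)
    expect_equal(unname(lr$expected), unname(ref$exp), tolerance = 1e-8)
  }
})

test_that("the planted hazard ratio is recovered in the mean by a consistent estimator", {
  # The O/E display estimator is conservative (attenuated toward 1) far
  # from the null, so the planted-effect recovery is checked with a Cox
  # partial-likelihood fit on the same grouped data.
  skip_if_not_installed("survival")
  lhr <- vapply(1:100, function(i) {
    cfg <- sim_config(seed = 60000L + i, n_genes = 10L)  # planted HR 0.4
    sv <- simulate_survival(cfg, list(reporter_gene = "g00001"))
    grp <- median_split(sv$reporter_expression, sv$clinical)
    df <- rbind(cbind(grp$low, g = 1), cbind(grp$high, g = 0))
    unname(stats::coef(survival::coxph(survival::Surv(time, event) ~ g,
                                       data = df)))
  }, numeric(1))
  expect_lt(abs(mean(lhr) - log(0.4)), 3 * sd(lhr) / sqrt(length(lhr)))
  # and the O/E estimate agrees in direction essentially always
  expect_true(all(exp(lhr) < 1.3))
})

test_that("survival screen reports per-gene results and explicit skip reasons", {
  cl <- clin(sprintf("s%d", 1:6), c(5, 10, 15, 20, 25, 30), c(1, 1, 1, 1, 1, 0))
  v <- rbind(gA = c(1, 2, 3, 4, 5, 6),
             gConst = rep(2, 6),
             gB = c(6, 5, 4, 3, 2, 1))
  colnames(v) <- cl$sample_id
  em <- expr_matrix(v, "linear")
  scr <- survival_screen(em, cl, c("gA", "gConst", "gB"))
  expect_equal(scr$skipped, c(FALSE, TRUE, FALSE))
  expect_match(scr$skip_reason[2], "degenerate")
  expect_equal(scr$n_low[1], 3L)
  # gA and gB induce mirrored splits: same statistic, reciprocal HR
  expect_equal(scr$statistic[1], scr$statistic[3], tolerance = 1e-12)
  expect_equal(scr$hazard_ratio[1], 1 / scr$hazard_ratio[3], tolerance = 1e-12)
  expect_error(survival_screen(em, cl, "nope"), "not in the matrix")
})
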