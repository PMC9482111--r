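test_that("assumption gate routes clean normal data to the parametric path", {
  withr::with_seed(2024, {
    hits <- replicate(200, {
      v <- rnorm(150)
      g <- rep(c("a", "b", "c"), each = 50)
      gate_assumptions(v, g)$gate == "parametric"
    })
    # four alpha = 0.05 gates in series pass jointly ~0.95^4 ~ 0.81 of
    # the time on truly clean data
    expect_gte(mean(hits), 0.75)
  })
})

test_that("assumption gate detects a non-normal group", {
  withr::with_seed(2025, {
    hits <- replicate(200, {
      v <- c(rnorm(100), rexp(50))
      g <- rep(c("a", "b", "c"), each = 50)
      gate_assumptions(v, g)$gate == "nonparametric"
    })
    expect_gte(mean(hits), 0.80)
  })
})

test_that("degenerate and tiny groups fall back with a warning", {
  v <- rep(c(1, 2, 3), each = 10)
  g <- rep(c("a", "b", "c"), each = 10)
  expect_warning(res <- gate_assumptions(v, g), "nonparametric")
  expect_equal(res$gate, "nonparametric")
  expect_warning(gate_assumptions(c(1, 2, 3, 4, 5), c("a", "a", "a", "b", "b")),
                 "n < 3")
})

test_that("identical groups give omnibus p = 1 and no significant pairs", {
  v <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- suppressWarnings(compare_groups(v, g))
  expect_equal(res$omnibus_p, 1, tolerance = 1e-9)
  expect_false(any(res$pairwise$significant))
  # fully constant data exercises the p = 1 path explicitly
  res2 <- suppressWarnings(compare_groups(rep(5, 12), rep(c("a", "b"), 6)))
  expect_equal(res2$omnibus_p, 1)
  expect_true(all(res2$pairwise$stars == "ns"))
})

test_that("parametric path reproduces a brute-force ANOVA", {
  v <- c(1, 2, 3, 4, 2, 3, 4, 5, 7, 8, 9, 10)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  # sum-of-squares oracle
  grand <- mean(v)
  means <- tapply(v, g, mean)
  ssb <- sum(4 * (means - grand)^2)
  ssw <- sum((v - means[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  p_oracle <- stats::pf(f_oracle, 2, 9, lower.tail = FALSE)
  res <- compare_groups(v, g, gate = "parametric")
  expect_equal(res$omnibus_stat, f_oracle, tolerance = 1e-10)
  expect_equal(res$omnibus_p, p_oracle, tolerance = 1e-10)
  expect_lt(res$omnibus_p, 0.001)
  # only pairs involving the shifted third group separate
  pw <- res$pairwise
  p12 <- pw$p[(pw$group_a == "g2" & pw$group_b == "g1") |
                (pw$group_a == "g1" & pw$group_b == "g2")]
  expect_gt(p12, 0.05)
  p13 <- pw$p[(pw$group_a == "g3" & pw$group_b == "g1") |
                (pw$group_a == "g1" & pw$group_b == "g3")]
  p23 <- pw$p[(pw$group_a == "g3" & pw$group_b == "g2") |
                (pw$group_a == "g2" & pw$group_b == "g3")]
  expect_lt(p13, 0.05)
  expect_lt(p23, 0.05)
})

test_that("nonparametric path agrees with kruskal.test and is label-symmetric", {
  withr::with_seed(77, {
    v <- c(rexp(20), rexp(20) + 1, rexp(20))
    g <- rep(c("a", "b", "c"), each = 20)
    res <- compare_groups(v, g, gate = "nonparametric")
    kw <- stats::kruskal.test(v, factor(g))
    expect_equal(res$omnibus_stat, unname(kw$statistic))
    expect_equal(res$omnibus_p, kw$p.value)
    # permuting group labels permutes, but does not change, pairwise p
    perm <- c(a = "b", b = "c", c = "a")
    res2 <- compare_groups(v, perm[g], gate = "nonparametric")
    key1 <- with(res$pairwise,
                 paste(pmin(perm[group_a], perm[group_b]),
                       pmax(perm[group_a], perm[group_b])))
    key2 <- with(res2$pairwise, paste(pmin(group_a, group_b),
                                      pmax(group_a, group_b)))
    expect_equal(res$pairwise$p[order(key1)], res2$pairwise$p[order(key2)],
                 tolerance = 1e-12)
  })
})

test_that("large shift alternatives are detected with high power", {
  withr::with_seed(31, {
    hits <- replicate(200, {
      v <- c(rnorm(30), rnorm(30), rnorm(30, 3))
      g <- rep(c("unl", "phys", "path"), each = 30)
      res <- compare_groups(v, g)
      pw <- res$pairwise
      r <- pw[(pw$group_a == "path" & pw$group_b == "unl") |
                (pw$group_a == "unl" & pw$group_b == "path"), ]
      r$significant
    })
    expect_gte(mean(hits), 0.95)
  })
})

test_that("star codes follow the conventional thresholds", {
  pw <- suppressWarnings(compare_groups(
    c(rnorm(5), rnorm(5, 10)), rep(c("x", "y"), each = 5)))$pairwise
  expect_true(all(pw$stars %in% c("ns", "*", "**", "***")))
  expect_equal(scleromech:::star_code(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})

test_that("box summaries use type-7 quartiles and 1.5 IQR whiskers", {
  s <- summarise_box(1:9, rep("g", 9))
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 9)
  expect_equal(lengths(s$outliers), 0L)
  # constant group: zero-height box
  s0 <- summarise_box(rep(4, 6), rep("g", 6))
  expect_equal(s0$q1, s0$q3)
  expect_equal(s0$whisker_low, s0$whisker_high)
  # an extreme point is flagged, whiskers stop at the data
  s1 <- summarise_box(c(1:9, 100), rep("g", 10))
  q <- quantile(c(1:9, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(c(s1$q1, s1$q3), q)
  expect_equal(s1$outliers[[1]], 100)
  expect_equal(s1$whisker_high, 9)
})
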