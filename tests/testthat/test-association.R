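test_that("contingency tables partition clone screens exhaustively", {
  rec <- data.frame(line = 1, clone_id = paste0("c", 1:4), variant_id = "v1",
                    fruits = c(0, 0, 1, 1), carries = c(1, 0, 1, 0))
  tab <- build_contingency(rec, "line")[["1"]]
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  expect_equal(tab$total, nrow(rec))

  expect_equal(length(build_contingency(rec[0, ], "line")), 0)

  # a clone screened for two variants of one region counts once, as carrier
  rec2 <- data.frame(line = 1, clone_id = "c1", variant_id = c("v1", "v2"),
                     fruits = 0, carries = c(1, 0))
  tab2 <- build_contingency(rec2, "region",
                            region_map = c(v1 = "5prime", v2 = "5prime"))
  expect_equal(tab2[["5prime"]]$a, 1)
  expect_equal(tab2[["5prime"]]$total, 1)
  expect_error(build_contingency(rec2, "region", region_map = c(v1 = "5prime")),
               "without region")

  # full penetrance, only 5prime planted: no fruiting carriers
  g <- make_reference(1, 20000, 3, seed = 15)
  cfg <- sim_config(n_lines = 2, penetrance_nonfruiting = 1, seed = 101)
  tr <- simulate_evolution(g, cfg, planted = data.frame(
    line = 1:2, class = "5prime", arise_passage = 1, init_freq = 0.5))
  scr <- simulate_clone_screen(tr, 50, seed = 102)
  tabs <- build_contingency(scr, "variant")
  for (t in tabs) expect_equal(t$c, 0)
})

test_that("Fisher's exact p matches enumeration, closed forms and the reference implementation", {
  expect_equal(fisher_exact(contingency_table(1, 0, 0, 1)), 1.0)
  expect_equal(fisher_exact(contingency_table(5, 0, 0, 5)), 2 / 252)

  # exhaustive: every table with total <= 14
  for (n in 1:14) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[parts$a + parts$b + parts$c <= n, ]
    parts$d <- n - parts$a - parts$b - parts$c
    for (r in seq_len(nrow(parts))) {
      p <- fisher_exact(contingency_table(parts$a[r], parts$b[r],
                                          parts$c[r], parts$d[r]))
      expect_equal(p, fisher_enum_oracle(parts$a[r], parts$b[r],
                                         parts$c[r], parts$d[r]),
                   tolerance = 1e-10,
                   label = paste(parts$a[r], parts$b[r], parts$c[r],
                                 parts$d[r]))
    }
  }

  # random larger tables, cross-checked against stats::fisher.test too
  set.seed(7)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(15:60, 1), rep(0.25, 4)))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    p <- fisher_exact(t)
    expect_equal(p, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                       cells[4]), tolerance = 1e-10)
    m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-8)
  }
})

test_that("Fisher p is invariant under transposition and monotone in table concordance", {
  set.seed(8)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(8:50, 1), rep(0.25, 4)))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    # simultaneous row and column swap: (a,b,c,d) -> (d,c,b,a)
    t2 <- contingency_table(cells[4], cells[3], cells[2], cells[1])
    expect_equal(fisher_exact(t), fisher_exact(t2), tolerance = 1e-12)
  }
  # once a table is at or beyond independence (ad >= bc), moving further
  # mass from discordant to concordant cells never increases p (for a
  # negatively associated start, p first rises toward independence)
  for (start in list(c(5, 5, 5, 5), c(8, 6, 7, 9), c(3, 10, 9, 2))) {
    t <- start
    p_prev <- NA_real_
    while (t[2] > 0 && t[3] > 0) {
      t <- t + c(1, -1, -1, 1)
      p_new <- fisher_exact(contingency_table(t[1], t[2], t[3], t[4]))
      if (!is.na(p_prev) && (t[1] - 1) * (t[4] - 1) >= (t[2] + 1) * (t[3] + 1)) {
        expect_lte(p_new, p_prev + 1e-12)
      }
      p_prev <- p_new
    }
  }
})

test_that("the exact test is conservative under a null clone screen", {
  set.seed(9)
  n_sim <- 1000
  rejections <- 0
  for (i in 1:n_sim) {
    carries <- stats::rbinom(40, 1, 0.5)
    fruits <- stats::rbinom(40, 1, 0.5)   # independent of carriage
    t <- contingency_table(sum(carries & !fruits), sum(!carries & !fruits),
                           sum(carries & fruits), sum(!carries & fruits))
    if (fisher_exact(t) < 0.05) rejections <- rejections + 1
  }
  mc_err <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rejections / n_sim, 0.05 + 2 * mc_err)
})

test_that("odds ratios follow direct arithmetic with explicit degenerate markers", {
  expect_equal(odds_ratio(contingency_table(2, 1, 1, 2)), 4.0)
  expect_equal(odds_ratio(contingency_table(5, 0, 0, 5)), Inf)
  expect_true(is.nan(odds_ratio(contingency_table(0, 3, 0, 4))))
  set.seed(10)
  for (i in 1:25) {
    cells <- sample(1:20, 4, replace = TRUE)
    expect_equal(odds_ratio(contingency_table(cells[1], cells[2], cells[3],
                                              cells[4])),
                 (cells[1] * cells[4]) / (cells[2] * cells[3]))
  }
})

test_that("screen reports compute pooled percentages and per-line tests", {
  rec <- do.call(rbind, list(
    data.frame(line = 1, clone_id = paste0("c", 1:20), variant_id = "v5",
               fruits = rep(c(0, 1), c(12, 8)),
               carries = rep(c(1, 0, 0, 1), c(11, 1, 7, 1))),
    data.frame(line = 2, clone_id = paste0("c", 1:10), variant_id = "v3",
               fruits = rep(c(0, 1), c(5, 5)),
               carries = rep(c(1, 0, 1, 0), c(5, 0, 4, 1)))))
  rep_ <- screen_report(rec, c(v5 = "5prime", v3 = "3prime"))
  expect_setequal(rep_$per_line$line, c("1", "2"))
  r5 <- rep_$per_region[rep_$per_region$region == "5prime", ]
  expect_equal(r5$a, 11)
  expect_equal(r5$pct_carrier_nonfruiting, 100 * 11 / 12)
  expect_equal(r5$pct_carrier_fruiting, 100 * 1 / 8)

  # all-fruiting input: nonfruiter percentage is an explicit no-data NA
  allf <- data.frame(line = 1, clone_id = paste0("c", 1:5), variant_id = "v5",
                     fruits = 1, carries = c(1, 1, 0, 0, 0))
  repf <- screen_report(allf, c(v5 = "5prime"))
  expect_true(is.na(repf$per_region$pct_carrier_nonfruiting))
})

test_that("prevalence intervals invert the exact binomial and match the beta-quantile oracle", {
  p0 <- prevalence(0, 958, 0.95)
  expect_equal(p0$proportion, 0)
  expect_equal(p0$lower, 0)

  p75 <- prevalence(75, 1000, 0.95)
  expect_equal(p75$proportion, 0.075)

  set.seed(11)
  for (i in 1:40) {
    n <- sample(1:2000, 1)
    k <- sample(0:n, 1)
    conf <- sample(c(0.9, 0.95, 0.99), 1)
    got <- prevalence(k, n, conf)
    want <- cp_beta_oracle(k, n, conf)
    expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-7)
    expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-7)
  }
  expect_error(prevalence(0, 0), "n must be")
})
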