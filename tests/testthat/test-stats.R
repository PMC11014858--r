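test_that("Mann-Whitney U matches hand-enumerated exact cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)           # 2/20 rank arrangements as extreme
  expect_equal(r$method, "exact")

  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$U, 1)
  expect_equal(r2$p, 2 / 3)        # 4/6 arrangements

  # identical multisets: ties force the normal path, p = 1
  r3 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(r3$p, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "at least one")
})

test_that("exact p-values agree with wilcox.test across tie-free inputs", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(4:14, 1)
    n1 <- sample(seq_len(n - 1), 1)
    vals <- sample(100, n)  # distinct -> tie-free
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    ours <- mann_whitney_u(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE,
                                               correct = FALSE))
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$U, unname(min(ref$statistic,
                                    n1 * (n - n1) - ref$statistic)))
  }
})

test_that("normal-approximation path is sane for larger/tied samples", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30) + 2
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(r$p, unname(ref$p.value), tolerance = 1e-10)
  # all values identical: zero variance, p = 1
  expect_equal(mann_whitney_u(rep(1, 20), rep(1, 20))$p, 1)
})

test_that("Holm adjustment reproduces the step-down formula", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.5), 0.5)
  expect_equal(holm_adjust(c(1, 1)), c(1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (i in 1:100) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, method = "holm"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("density curves integrate to one and are translation-equivariant", {
  set.seed(4)
  x <- rnorm(2000)
  d <- density_estimate(x)
  trap <- sum((d$density[-1] + d$density[-length(d$density)]) / 2 *
                diff(d$grid))
  expect_equal(trap, 1, tolerance = 1e-6)
  expect_true(all(d$density >= 0))
  # mode near 0 for a standard normal sample
  expect_lt(abs(d$grid[which.max(d$density)]), 0.3)

  shift <- density_estimate(x + 5)
  expect_equal(shift$grid, d$grid + 5)
  expect_equal(shift$density, d$density)
  expect_equal(shift$bw, d$bw)

  sym <- density_estimate(c(-1, 1))
  w <- sum(sym$grid * sym$density) / sum(sym$density)
  expect_equal(w, 0, tolerance = 1e-9)

  expect_error(density_estimate(1), "at least 2")
})

test_that("mouse means average over non-empty trials only", {
  trials <- data.frame(
    mouse_id = c("m1", "m1", "m2", "m2", "m2"),
    group = "g", age_group = "18m", trial_id = c(1, 2, 1, 2, 3),
    major_hind = c(2, 4, 1, 5, 100),
    empty = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  s <- mouse_means(trials)
  expect_equal(s$major_hind[s$mouse_id == "m1"], 3)
  expect_equal(s$major_hind[s$mouse_id == "m2"], 3)
  expect_equal(s$n_trials, c(2L, 2L))

  one <- mouse_means(trials[1, ])
  expect_equal(one$major_hind, 2)
})

test_that("group comparisons build per-measure Holm families with stars", {
  set.seed(6)
  trials <- simulate_mouse_summaries(
    c(control = 20, modelA = 0, modelB = 18), n_mice = 6, seed = 42)
  s <- mouse_means(trials)
  cmp <- compare_groups(s, "pos_belly")
  expect_equal(nrow(cmp), 3)  # C(3,2) pairs
  expect_true(all(cmp$p_adj >= cmp$p_raw))
  expect_true(all(cmp$U >= 0 & cmp$U <= cmp$n_a * cmp$n_b))
  # the strongly shifted pair is the family minimum
  ab <- cmp$p_adj[cmp$group_a == "control" & cmp$group_b == "modelA"]
  expect_equal(ab, min(cmp$p_adj))
  expect_lt(ab, 0.05)

  # identical groups: nothing significant
  trials_eq <- simulate_mouse_summaries(c(g1 = 10, g2 = 10, g3 = 10),
                                        n_mice = 6, between_sd = 0,
                                        trial_sd = 0, seed = 1)
  cmp_eq <- compare_groups(mouse_means(trials_eq), "pos_belly")
  expect_true(all(cmp_eq$p_adj == 1))

  # undersized group skipped with a warning
  s_small <- s[s$group != "modelB" | s$mouse_id == "modelB_m01", ]
  expect_warning(cmp_small <- compare_groups(s_small, "pos_belly"),
                 "skipped")
  expect_equal(nrow(cmp_small), 1)
})
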