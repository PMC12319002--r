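test_that("indicator_stats uses population SD and reproduces reference rows", {
  # brute-force over explicit multisets, cross-checked against the published
  # rows they correspond to
  cases <- list(
    list(scores = c(rep(5, 5), rep(4, 10)), mean = 4.33, sd = 0.47, cv = 0.11),
    list(scores = rep(5, 15), mean = 5.00, sd = 0.00, cv = 0.00),
    list(scores = c(rep(5, 13), rep(4, 2)), mean = 4.87, sd = 0.34, cv = 0.07))
  for (cs in cases) {
    m <- mean(cs$scores)
    expect_equal(round2dp(m), cs$mean)
    expect_equal(round2dp(sqrt(sum((cs$scores - m)^2) / length(cs$scores))), cs$sd)
    p <- score_panel(matrix(cs$scores, ncol = 1, dimnames = list(NULL, "x")))
    st <- indicator_stats(p)
    expect_equal(round2dp(st$mean), cs$mean)
    expect_equal(round2dp(st$sd), cs$sd)
    expect_equal(round2dp(st$cv), cs$cv)
  }
})

test_that("score panels validate scores, votes and authority inputs", {
  m <- matrix(3, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_s3_class(score_panel(m), "score_panel")
  m2 <- m; m2[1, 1] <- 6
  expect_error(score_panel(m2), "integer in 1..5")
  m2[1, 1] <- 2.5
  expect_error(score_panel(m2), "integer in 1..5")
  expect_error(score_panel(m, necessity = matrix(FALSE, 3, 2)), "dimensions")
  expect_error(score_panel(m, judgment = data.frame(theory = c("large", "huge"),
                                                    practice = "large",
                                                    reference = "large",
                                                    intuition = "large")),
               "large/medium/small")
  expect_error(indicator_stats(score_panel(matrix(numeric(0), 0, 2,
    dimnames = list(NULL, c("a", "b"))))), "empty")
})

test_that("response_rate is returned_valid/sent with guarded domain", {
  expect_identical(response_rate(15, 15), 1)
  expect_identical(response_rate(15, 0), 0)
  expect_identical(response_rate(20, 15), 0.75)
  expect_error(response_rate(0, 0), "positive")
  expect_error(response_rate(10, 11), "\\[0, sent\\]")
})

test_that("authority coefficient follows the grade tables and Cr = (Ca+Cs)/2", {
  m <- matrix(4, 3, 2, dimnames = list(NULL, c("a", "b")))
  j <- data.frame(theory = c("large", "large", "small"),
                  practice = c("large", "medium", "small"),
                  reference = "large", intuition = "medium",
                  stringsAsFactors = FALSE)
  p <- score_panel(m, judgment = j, familiarity = c(5, 4, 1))
  a <- authority_coefficient(p)
  expect_equal(a$experts$Ca, c(1.0, 0.9, 0.6))
  expect_equal(a$experts$Cs, c(1.0, 0.8, 0.2))
  expect_equal(a$experts$Cr, (a$experts$Ca + a$experts$Cs) / 2)
  expect_equal(a$experts$Cr[1:2], c(1.0, 0.85))
  expect_equal(a$panel_cr, mean(a$experts$Cr))
  # grade-table range and the 0.7 credibility threshold
  expect_true(all(a$experts$Cr >= 0.4 & a$experts$Cr <= 1.0))
  expect_identical(a$credible, a$panel_cr >= 0.7)
  expect_false(authority_coefficient(p, credible_min = 0.99)$credible)
  expect_error(authority_coefficient(score_panel(m)), "lacks judgment")
})

test_that("Cr stays in [0.4, 1] over all grade/familiarity combinations", {
  grades <- c("large", "medium", "small")
  combos <- expand.grid(t = grades, pr = grades, f = 1:5,
                        stringsAsFactors = FALSE)
  m <- matrix(4, nrow(combos), 1, dimnames = list(NULL, "a"))
  p <- score_panel(m, judgment = data.frame(theory = combos$t,
                                            practice = combos$pr,
                                            reference = "small",
                                            intuition = "large"),
                   familiarity = combos$f)
  cr <- authority_coefficient(p)$experts$Cr
  expect_true(all(cr >= 0.4 & cr <= 1.0))
})

test_that("kendalls_w matches hand-derived values and the chi-square identity", {
  # three experts, identical tie-free rankings of 4 items
  s <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  colnames(s) <- paste0("I", 1:4)
  expect_equal(kendalls_w(score_panel(s))$W, 1)

  # rank sums (5,6,7), S = 2, W = 12*2/(9*24)
  s <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  colnames(s) <- paste0("I", 1:3)
  k <- kendalls_w(score_panel(s))
  expect_equal(k$W, 12 * 2 / (9 * 24))
  expect_equal(k$chi2, k$m * (k$n - 1) * k$W)

  # two exactly reversed rankings
  s <- rbind(c(1, 2, 3), c(3, 2, 1))
  colnames(s) <- paste0("I", 1:3)
  k <- kendalls_w(score_panel(s))
  expect_lt(k$W, 0.2)
  expect_equal(k$chi2, k$m * (k$n - 1) * k$W)

  expect_error(kendalls_w(score_panel(matrix(1:3, 1, 3,
    dimnames = list(NULL, paste0("I", 1:3))))), "at least 2")
  expect_error(kendalls_w(matrix(2, 3, 4)), "identically")
})

test_that("kendalls_w agrees with the brute-force oracle on small tied panels", {
  for (seed in 1:25) {
    m <- 2 + seed %% 3; n <- 2 + (seed * 7) %% 3
    p <- rand_panel(m, n, seed)
    expect_equal(kendalls_w(p)$W, oracle_w(p$scores), tolerance = 1e-12,
                 info = sprintf("seed %d", seed))
  }
})

test_that("W is invariant under expert relabeling; uniform experts never raise W", {
  p <- rand_panel(5, 6, 42)
  w0 <- kendalls_w(p)$W
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(nrow(p$scores))
    expect_equal(kendalls_w(p$scores[perm, ])$W, w0)
  }
  with_uniform <- rbind(p$scores, E6 = rep(3, ncol(p$scores)))
  expect_lte(kendalls_w(with_uniform)$W, w0 + 1e-12)
})

test_that("screening verdicts follow the rule bands and are monotone in mean", {
  st <- function(mean, cv, nn = 0) {
    data.frame(indicator_id = "x", mean = mean, cv = cv, pct_not_necessary = nn)
  }
  expect_identical(screen_indicators(st(4.87, 0.07))$verdict, "retain")
  expect_identical(screen_indicators(st(4.5, 0.2, nn = 0.4))$verdict, "delete")
  expect_match(screen_indicators(st(4.5, 0.2, nn = 0.4))$rules, "votes_gt_30pct")
  expect_identical(screen_indicators(st(3.80, 0.17))$verdict, "review")
  expect_identical(screen_indicators(st(3.2, 0.1))$verdict, "delete")
  expect_identical(screen_indicators(st(4.5, 0.35))$verdict, "delete")
  # boundaries: retain band is mean >= 4 and cv < 0.25
  expect_identical(screen_indicators(st(4.0, 0.25))$verdict, "review")
  expect_identical(screen_indicators(st(4.0, 0.249))$verdict, "retain")

  ord <- c(delete = 1, review = 2, retain = 3)
  for (cv in c(0.05, 0.2, 0.28, 0.35)) {
    for (nn in c(0, 0.2, 0.5)) {
      v <- ord[vapply(seq(3.0, 5.0, by = 0.1), function(m)
        screen_indicators(st(m, cv, nn))$verdict, character(1))]
      expect_true(all(diff(v) >= 0),
                  info = sprintf("cv=%.2f nn=%.1f", cv, nn))
    }
  }
})

test_that("run_round aggregates stats and flags convergence", {
  h <- final_hierarchy()
  mu <- stats::setNames(reference_table()$mean, reference_table()$id)
  lo <- run_round(h, simulate_panel(panel_sim_config(mu = mu, sigma = 0.2, seed = 7)))
  expect_true(lo$converged)
  hi <- run_round(h, simulate_panel(panel_sim_config(mu = mu, sigma = 2.0, seed = 7)))
  expect_false(hi$converged)
  expect_identical(nrow(lo$stats), length(mu))
  expect_identical(nrow(lo$decisions), length(mu))

  bad <- simulate_panel(panel_sim_config(mu = c(mu, "9.9" = 4), sigma = 0.2, seed = 7))
  expect_error(run_round(h, bad), "'9.9'")
})
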