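# shared fixtures and independent oracles, built in code

# a minimal two-branch, three-level hierarchy
tiny_hierarchy <- function() {
  indicator_hierarchy(data.frame(
    id = c("1", "1.1", "1.2", "1.1.1", "1.1.2", "1.2.1", "2", "2.1", "2.1.1"),
    name = c("A", "A1", "A2", "A11", "A12", "A21", "B", "B1", "B11"),
    stringsAsFactors = FALSE))
}

# random integer score panel under a fixed seed
rand_panel <- function(m, n, seed, values = 1:5) {
  set.seed(seed)
  s <- matrix(sample(values, m * n, replace = TRUE), m, n,
              dimnames = list(paste0("E", 1:m), paste0("I", 1:n)))
  score_panel(s)
}

# independent brute-force Kendall's W: count-based mid-ranks and explicit
# loops, sharing no code with the implementation under test
oracle_w <- function(scores) {
  m <- nrow(scores); n <- ncol(scores)
  ranks <- matrix(0, m, n)
  for (e in 1:m) {
    for (i in 1:n) {
      less <- sum(scores[e, ] < scores[e, i])
      eq <- sum(scores[e, ] == scores[e, i])
      ranks[e, i] <- less + (eq + 1) / 2
    }
  }
  rsum <- numeric(n)
  for (i in 1:n) rsum[i] <- sum(ranks[, i])
  S <- sum((rsum - mean(rsum))^2)
  Tsum <- 0
  for (e in 1:m) {
    for (v in unique(scores[e, ])) {
      t <- sum(scores[e, ] == v)
      Tsum <- Tsum + t^3 - t
    }
  }
  12 * S / (m^2 * (n^3 - n) - m * Tsum)
}

# published reference table for the packaged framework: per-indicator mean,
# population SD, CV and combination weight. CV for row 2.3 is stored as
# sd/mean (0.13); the source table prints 0.11 there, which is arithmetically
# inconsistent with its own mean and SD (see package notes).
reference_table <- function() {
  read.csv(text = 'id,mean,sd,cv,weight
1,5.00,0.00,0.00,0.4545
1.1,5.00,0.00,0.00,0.2453
1.1.1,5.00,0.00,0.00,0.1635
1.1.2,4.87,0.34,0.07,0.0818
1.2,4.87,0.34,0.07,0.1350
1.2.1,4.80,0.40,0.08,0.1350
1.3,4.80,0.40,0.08,0.0743
1.3.1,4.67,0.47,0.10,0.0743
2,5.00,0.00,0.00,0.4545
2.1,4.93,0.25,0.05,0.2121
2.1.1,4.40,0.61,0.14,0.1591
2.1.2,4.20,0.65,0.16,0.0530
2.2,4.93,0.25,0.05,0.2121
2.2.1,4.87,0.34,0.07,0.0530
2.2.2,4.93,0.25,0.05,0.1061
2.2.3,4.87,0.34,0.07,0.0530
2.3,4.00,0.52,0.13,0.0303
2.3.1,4.07,0.57,0.14,0.0202
2.3.2,4.00,0.52,0.13,0.0101
3,4.33,0.47,0.11,0.0909
3.1,4.13,0.81,0.19,0.0171
3.1.1,4.27,0.68,0.16,0.0085
3.1.2,4.20,0.40,0.10,0.0053
3.1.3,4.13,0.62,0.15,0.0034
3.2,3.80,0.65,0.17,0.0074
3.2.1,4.00,0.63,0.16,0.0055
3.2.2,3.80,0.54,0.14,0.0018
3.3,4.73,0.57,0.12,0.0664
3.3.1,4.60,0.49,0.11,0.0371
3.3.2,4.47,0.50,0.11,0.0212
3.3.3,4.20,0.40,0.10,0.0081',
    colClasses = c("character", rep("numeric", 4)))
}

# concordance of estimated ordering with the latent ordering, over pairs
# actually ordered in mu (tied mu pairs carry no ordering information)
ordering_tau <- function(mu, est) {
  d1 <- outer(mu, mu, "-")
  d2 <- outer(est, est, "-")
  keep <- upper.tri(d1) & d1 != 0
  mean(sign(d1[keep]) * sign(d2[keep]))
}

round2dp <- function(x) round(x + 1e-12, 2)
round4dp <- function(x) round(x + 1e-12, 4)
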