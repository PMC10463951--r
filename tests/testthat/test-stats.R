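# Statistics layer versus independent oracles: closed-form t, rank
# enumeration, brute-force BH, cell-means ANOVA sums of squares, and
# numerical integration for the Dunnett distribution.

test_that("pooled t-test matches the closed-form formula", {
  a <- c(1.1, 2.3, 3.7, 2.2)
  b <- c(4.9, 6.1, 5.0, 7.2, 5.5)
  r <- ttestUnpaired(a, b)
  # independent closed-form evaluation
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tOracle <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pOracle <- 2 * pt(-abs(tOracle), length(a) + length(b) - 2)
  expect_equal(r$t, tOracle, tolerance = 1e-12)
  expect_equal(r$p, pOracle, tolerance = 1e-12)

  same <- ttestUnpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- ttestUnpaired(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 1e-3)
  big <- ttestUnpaired(c(1, 2, 3) * 1e-3, 10 + c(1, 2, 3) * 1e-3)
  expect_lt(big$p, 1e-6)

  deg <- ttestUnpaired(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("Mann-Whitney exact p matches full enumeration", {
  # U = 0 case: P(U <= 0) by listing all 6 rank allocations
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_true(r$exact)
  expect_equal(r$p, 2 * 1 / 6)  # two-sided doubling of the 1/6 tail
  rLess <- mannWhitney(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(rLess$p, 1 / 6)

  # enumeration oracle at n = 5 + 5: exact distribution of U
  set.seed(33)
  a <- rnorm(5); b <- rnorm(5) + 0.8
  r2 <- mannWhitney(a, b)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  comb <- combn(10, 5)
  pool <- c(a, b)
  uObs <- uStat(a, b)
  uAll <- apply(comb, 2, function(idx) uStat(pool[idx], pool[-idx]))
  muU <- length(a) * length(b) / 2
  pEnum <- mean(abs(uAll - muU) >= abs(uObs - muU))
  expect_equal(r2$p, pEnum, tolerance = 1e-12)

  expect_equal(mannWhitney(c(3, 3, 3), c(3, 3))$p, 1)
})

test_that("exact and approximate Mann-Whitney agree at the size boundary", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6) + 0.5
    pExact <- mannWhitney(a, b)$p
    wApprox <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))$p.value
    expect_lt(abs(pExact - wApprox), 0.02)
  }
})

test_that("RM-ANOVA sums of squares match a cell-means oracle on a 2x2x3 design", {
  # 2 groups x 2 within-levels x 3 subjects/group, fixed values
  d <- data.frame(
    value = c(3.1, 4.0, 3.6, 4.4, 5.1, 4.7, 2.9, 3.5, 3.2, 5.6, 6.0, 6.4),
    group = rep(c("ctl", "trt"), each = 6),
    subject = rep(c("s1", "s2", "s3", "s4", "s5", "s6"), each = 2),
    within = rep(c("t1", "t2"), 6))
  tab <- anova2RM(d)

  # brute-force oracle from cell/marginal/subject means
  y <- d$value
  grand <- mean(y)
  subjMean <- tapply(y, d$subject, mean)
  groupMean <- tapply(y, d$group, mean)
  withinMean <- tapply(y, d$within, mean)
  cellMean <- tapply(y, list(d$group, d$within), mean)
  b <- 2  # within levels
  ssBetweenSubj <- b * sum((subjMean - grand)^2)
  ssA <- sum(6 * (groupMean - grand)^2)          # n_g * b = 6 values/group
  ssSubj <- ssBetweenSubj - ssA
  ssTotal <- sum((y - grand)^2)
  ssWithinTotal <- ssTotal - ssBetweenSubj
  ssB <- sum(6 * (withinMean - grand)^2)         # N_subj = 6 per level
  ssAB <- sum(3 * (cellMean - grand)^2) - ssA - ssB  # 3 obs per cell
  ssErr <- ssWithinTotal - ssB - ssAB

  expect_equal(tab$ss[tab$effect == "group"], ssA, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "subjects"], ssSubj, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "within"], ssB, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "group:within"], ssAB,
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "residuals"], ssErr, tolerance = 1e-10)

  # F and p from the same oracle quantities
  fA <- (ssA / 1) / (ssSubj / 4)
  expect_equal(tab$f[tab$effect == "group"], fA, tolerance = 1e-10)
  expect_equal(tab$p[tab$effect == "group"], pf(fA, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("all-equal data give zero F for every effect", {
  d <- expand.grid(subject = paste0("s", 1:6), within = c("t1", "t2", "t3"))
  d$group <- ifelse(d$subject %in% c("s1", "s2", "s3"), "a", "b")
  d$value <- 5
  tab <- anova2RM(d)
  # no variation anywhere: every effect sum of squares vanishes
  expect_true(all(tab$ss < 1e-20))
})

test_that("collapsing the within factor reproduces the between-groups F (= t^2)", {
  set.seed(55)
  d <- data.frame(value = rnorm(12), group = rep(c("a", "b"), each = 6),
                  subject = paste0("s", 1:12), within = "only")
  tab <- anova2RM(d)
  tt <- ttestUnpaired(d$value[d$group == "a"], d$value[d$group == "b"])
  expect_equal(tab$f[tab$effect == "group"], tt$t^2, tolerance = 1e-10)
  expect_equal(tab$p[tab$effect == "group"], tt$p, tolerance = 1e-10)
})

test_that("anova2RM rejects incomplete designs", {
  d <- data.frame(value = rnorm(5), group = "a",
                  subject = c("s1", "s1", "s2", "s2", "s3"),
                  within = c("t1", "t2", "t1", "t2", "t1"))
  expect_error(anova2RM(d), "complete")
})

test_that("Sidak adjustment follows the closed form", {
  expect_equal(sidakAdjust(0.05, 1), 0.05)
  expect_equal(sidakAdjust(0.05, 2), 1 - 0.95^2)
  expect_equal(sidakAdjust(0.5, 10), 1 - 0.5^10)
  expect_equal(sidakAdjust(0.9, 50), 1)
  p <- runif(20)
  expect_true(all(sidakAdjust(p, 5) >= p))
  expect_error(sidakAdjust(0.5, 0), "at least 1")
})

test_that("BH q-values match a brute-force step-up", {
  bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))  # enforce monotonicity
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(77)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bhFdr(p), bruteBH(p), tolerance = 1e-12)
  }
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(rep(0.2, 7)), rep(0.2, 7))
  expect_length(bhFdr(numeric(0)), 0)
})

test_that("Dunnett MC adjustment: k = 1 limit, monotonicity, determinism", {
  r1 <- dunnettAdjust(t = 2.2, df = 20, k = 1, nDraws = 2e5, seed = 3)
  expect_equal(r1$adj_p, r1$raw_p, tolerance = 0.01)

  rk <- dunnettAdjust(t = c(1.5, 2.5, 0.3), df = 15, k = 3, seed = 5)
  expect_true(all(rk$adj_p >= rk$raw_p))
  expect_true(all(rk$adj_p <= 1))

  again <- dunnettAdjust(t = c(1.5, 2.5, 0.3), df = 15, k = 3, seed = 5)
  expect_identical(rk$adj_p, again$adj_p)
})

test_that("Dunnett MC matches numerical integration of the bivariate-t case", {
  skip_if_not_installed("mvtnorm")
  tObs <- 2.0; df <- 10; rho <- 0.5
  # oracle: P(max(|T1|,|T2|) >= t) from the equicorrelated multivariate t
  pOracle <- 1 - mvtnorm::pmvt(lower = rep(-tObs, 2), upper = rep(tObs, 2),
                               df = df, corr = matrix(c(1, rho, rho, 1), 2),
                               type = "Kshirsagar")[1]
  r <- dunnettAdjust(t = tObs, df = df, k = 2, rho = rho, nDraws = 4e5,
                     seed = 9)
  expect_lt(abs(r$adj_p - pOracle), 0.005)
})

test_that("dunnettTest builds contrasts against the named control", {
  set.seed(91)
  values <- c(rnorm(8, 0), rnorm(8, 3), rnorm(8, 0.2))
  group <- rep(c("ctl", "hi", "lo"), each = 8)
  r <- dunnettTest(values, group, control = "ctl", nDraws = 5e4, seed = 1)
  expect_equal(nrow(r), 2)
  expect_true(all(r$adj_p >= r$raw_p))
  expect_lt(r$adj_p[r$comparison == "hi - ctl"], 0.05)
  expect_error(dunnettTest(values, group, control = "nope"), "control")
})

test_that("auto and range scaling normalize columns as defined", {
  set.seed(13)
  m <- cbind(a = rnorm(30, 5, 2), b = runif(30), c = rep(1, 30))
  as_ <- autoScale(m)
  expect_equal(unname(colMeans(as_[, 1:2])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(as_[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_true(all(is.na(as_[, "c"])))
  expect_equal(attr(as_, "flagged"), "c")

  rs <- rangeScale(m)
  expect_equal(unname(apply(rs[, 1:2], 2, function(x) diff(range(x)))),
               c(1, 1), tolerance = 1e-12)

  # affine invariance of auto scaling
  m2 <- m; m2[, "a"] <- 3 * m[, "a"] - 7
  expect_equal(autoScale(m2)[, "a"], as_[, "a"], tolerance = 1e-12)
})
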