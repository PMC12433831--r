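test_that("ANOVA branch reproduces the closed-form oracle to 1e-10", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6), c = c(10, 11, 12, 13, 14))
  d <- chooseAndRunOmnibus(g)
  ## textbook one-way ANOVA from sums of squares
  vals <- unlist(g)
  fac <- rep(1:3, each = 5L)
  grand <- mean(vals)
  ssb <- sum(5 * (tapply(vals, fac, mean) - grand)^2)
  ssw <- sum((vals - ave(vals, fac))^2)
  Fo <- (ssb / 2) / (ssw / 12)
  expect_identical(d$branch, "ANOVA_TUKEY")
  expect_equal(d$omnibus$statistic, Fo, tolerance = 1e-10)
  expect_equal(d$omnibus$p, pf(Fo, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Tukey adjusted p-values match TukeyHSD", {
  set.seed(3)
  g <- list(a = rnorm(8), b = rnorm(9) + 1, c = rnorm(10))
  d <- chooseAndRunOmnibus(g)
  expect_identical(d$branch, "ANOVA_TUKEY")
  df <- data.frame(
    v = unlist(g), f = factor(rep(names(g), lengths(g)))
  )
  ref <- TukeyHSD(aov(v ~ f, df))$f[, "p adj"]
  expect_equal(sort(d$pairwise$p_adjusted), sort(unname(ref)),
               tolerance = 1e-8)
})

test_that("the pooled-variance t oracle is reproduced to 1e-10", {
  a <- 1:6
  b <- 2:7
  pc <- pairwiseComparison(a, b)  # n < 8: treated as normal
  sp2 <- (5 * var(a) + 5 * var(b)) / 10
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  expect_identical(pc$test, "Student t")
  expect_equal(pc$statistic, tt, tolerance = 1e-10)
  expect_equal(pc$p, 2 * pt(-abs(tt), 10), tolerance = 1e-10)
})

test_that("identical samples give t = 0 and p = 1", {
  pc <- pairwiseComparison(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(pc$statistic, 0)
  expect_equal(pc$p, 1)
  expect_error(
    pairwiseComparison(rep(2, 5), rep(2, 6)),
    "degenerate"
  )
})

test_that("grossly unequal variances route to Welch", {
  set.seed(8)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 0, 5)
  pc <- pairwiseComparison(a, b)
  expect_identical(pc$test, "Welch t")
  expect_lt(pc$varianceP, 0.05)
})

test_that("Mann-Whitney p-values match exact enumeration at small n", {
  enumP <- function(a, b) {
    r <- rank(c(a, b))
    na <- length(a)
    uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    cmb <- combn(length(r), na)
    U <- apply(cmb, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    mid <- na * length(b) / 2
    mean(abs(U - mid) >= abs(uObs - mid) - 1e-9)
  }
  set.seed(31)
  for (i in 1:5) {
    a <- round(rnorm(4), 3)
    b <- round(rnorm(6) + 1, 3)
    mw <- xirplesion:::.mannWhitney(a, b)
    expect_true(mw$exact)
    expect_equal(mw$p, enumP(a, b), tolerance = 1e-10)
  }
  ## ties force the corrected normal approximation
  mwT <- xirplesion:::.mannWhitney(c(1, 2, 2, 3), c(2, 3, 4, 5))
  expect_false(mwT$exact)
})

test_that("non-normal data route to Kruskal-Wallis with Holm-adjusted Mann-Whitney", {
  hits <- 0L
  for (i in 1:60) {
    set.seed(400 + i)
    g <- list(a = rlnorm(12), b = rlnorm(12), c = rlnorm(12))
    d <- chooseAndRunOmnibus(g)
    if (d$branch == "KRUSKAL_HOLM_MW") {
      hits <- hits + 1L
      expect_identical(d$omnibus$test, "Kruskal-Wallis")
      expect_true(all(d$pairwise$p_adjusted >= d$pairwise$p_raw - 1e-12))
    }
  }
  expect_gte(hits / 60, 0.9)
})

test_that("normal data with unequal variances route to Welch ANOVA with Dunnett T3", {
  set.seed(55)
  g <- list(a = rnorm(12, 0, 1), b = rnorm(12, 0, 1), c = rnorm(12, 0, 6))
  d <- chooseAndRunOmnibus(g)
  expect_identical(d$branch, "WELCH_BF_DUNNETT_T3")
  w <- oneway.test(v ~ f, data.frame(
    v = unlist(g), f = factor(rep(names(g), lengths(g)))
  ), var.equal = FALSE)
  expect_equal(d$omnibus$p, w$p.value, tolerance = 1e-10)
  expect_true(all(d$pairwise$test == "Dunnett T3"))
  expect_true(all(d$pairwise$p_adjusted >= d$pairwise$p_raw - 1e-12))
  ## T3 with a single comparison collapses to the raw Welch p
  t3 <- dunnettT3(g[1:2])
  expect_equal(t3$p_adjusted, t3$p_raw, tolerance = 1e-12)
  expect_equal(t3$p_raw, t.test(g$a, g$b)$p.value, tolerance = 1e-10)
})

test_that("branch routing is a pure function of the recorded audit trail", {
  set.seed(17)
  for (i in 1:20) {
    g <- list(
      a = rlnorm(10, 0, runif(1, 0.1, 1)),
      b = rnorm(10), c = rnorm(10, 0, runif(1, 0.5, 3))
    )
    d <- chooseAndRunOmnibus(g)
    allNormal <- all(is.na(d$normality) | d$normality > d$alpha)
    varSimilar <- all(d$varianceTests > d$alpha)
    replay <- if (!allNormal) {
      "KRUSKAL_HOLM_MW"
    } else if (varSimilar) {
      "ANOVA_TUKEY"
    } else {
      "WELCH_BF_DUNNETT_T3"
    }
    expect_identical(d$branch, replay)
  }
})

test_that("Holm adjustment is monotone and never decreases a p-value", {
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(3:8, 1))
    h <- p.adjust(p, "holm")
    expect_true(all(h >= p - 1e-15))
    expect_true(all(diff(h[order(p)]) >= -1e-15))
  }
})

test_that("group-size and degeneracy guards name the offender", {
  expect_error(
    chooseAndRunOmnibus(list(ok = rnorm(5), tiny = rnorm(2), ok2 = rnorm(5))),
    "tiny"
  )
  expect_error(
    chooseAndRunOmnibus(list(a = rep(1, 5), b = rnorm(5), c = rnorm(5))),
    "constant"
  )
  expect_error(pairwiseComparison(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("identical readout tables give perfect concordance", {
  e1 <- syntheticReadouts(63L, seed = 5L)
  rep <- interobserverConcordance(e1, e1)
  for (m in rep) {
    expect_equal(m$r, 1.0)
    expect_equal(m$meanDifference, 0)
    expect_equal(m$p, 1)
    expect_identical(m$n, 63L)
  }
})

test_that("small operator jitter keeps r above 0.99", {
  e1 <- syntheticReadouts(63L, seed = 6L)
  e2 <- e1
  set.seed(7)
  for (m in c("lesion_density_per_mm2", "mean_lesion_size_um2",
              "macro_density_per_mm2")) {
    e2[[m]] <- e1[[m]] + rnorm(63, 0, 0.01 * sd(e1[[m]]))
  }
  rep <- interobserverConcordance(e1, e2)
  for (m in rep) expect_gte(m$r, 0.99)
})

test_that("shuffled readouts decorrelate", {
  e1 <- syntheticReadouts(63L, seed = 8L)
  small <- 0L
  nSeeds <- 40L
  for (s in seq_len(nSeeds)) {
    set.seed(s)
    e2 <- e1
    perm <- sample(63L)
    for (m in c("lesion_density_per_mm2", "mean_lesion_size_um2",
                "macro_density_per_mm2")) {
      e2[[m]] <- e1[[m]][perm]
    }
    rep <- interobserverConcordance(e1, e2)
    rs <- vapply(rep, `[[`, numeric(1), "r")
    if (all(abs(rs) <= 0.3)) small <- small + 1L
  }
  expect_gte(small / nSeeds, 0.9)
})

test_that("unmatched sample ids are reported", {
  e1 <- syntheticReadouts(10L)
  e2 <- e1
  e2$sample_id[3] <- "zz"
  expect_error(interobserverConcordance(e1, e2), "zz")
})

test_that("the study analysis needs all six groups", {
  sim <- generateCohort(baseSeed = 4L)
  cohort <- sim$cohort
  expect_s3_class(runStudyAnalysis(cohort)$table, "data.frame")
  expect_error(
    runStudyAnalysis(cohort[cohort$genotype != "HOM" |
                            cohort$condition != "run", ]),
    "HOM run"
  )
})

test_that("a fully null six-group cohort rarely yields significant contrasts", {
  ## each omnibus + post hoc family controls its error rate, so across
  ## seeds at least 90% of comparison families stay free of (adjusted)
  ## significant calls
  familiesClean <- 0L
  familiesTotal <- 0L
  for (s in 1:30) {
    set.seed(1000 + s)
    cohort <- data.frame(
      genotype = rep(rep(c("WT", "HET", "HOM"), each = 9L), 2L),
      condition = rep(c("no_run", "run"), each = 27L),
      lesion_density_per_mm2 = rlnorm(54, log(3000), 0.29),
      mean_lesion_size_um2 = rlnorm(54, log(0.9), 0.29),
      macro_density_per_mm2 = rlnorm(54, log(40), 0.29)
    )
    rep <- runStudyAnalysis(cohort)
    for (m in names(rep$omnibus)) {
      for (cond in names(rep$omnibus[[m]])) {
        pw <- rep$omnibus[[m]][[cond]]$pairwise
        familiesTotal <- familiesTotal + 1L
        if (!any(pw$p_adjusted < 0.05)) familiesClean <- familiesClean + 1L
      }
    }
  }
  expect_gte(familiesClean / familiesTotal, 0.9)
})
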