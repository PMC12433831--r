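## Normality/variance-guided group-comparison decision tree, pairwise
## routing, Dunnett T3, and interobserver concordance.

#' Anderson-Darling normality assessment
#'
#' Case-3 Anderson-Darling test (mean and variance estimated) via
#' \pkg{nortest}. The approximation requires n >= 8; smaller samples cannot
#' be assessed and are treated as consistent with normality (p = NA,
#' pass = TRUE), which routes them to the parametric branch.
#'
#' @param x numeric sample.
#' @param alpha significance level.
#' @return list with \code{p} and logical \code{pass}.
#' @export
adNormality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8L || sd(x) == 0) {
    return(list(p = NA_real_, pass = TRUE))
  }
  p <- nortest::ad.test(x)$p.value
  list(p = p, pass = p > alpha)
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA on the absolute deviations from the group medians
#' (Levene's test with median centering).
#'
#' @param groups list of numeric samples.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
brownForsytheVarTest <- function(groups) {
  z <- lapply(groups, function(g) abs(g - median(g)))
  k <- length(z)
  n <- lengths(z)
  N <- sum(n)
  mAll <- mean(unlist(z))
  mGrp <- vapply(z, mean, numeric(1))
  ssb <- sum(n * (mGrp - mAll)^2)
  ssw <- sum(unlist(lapply(z, function(g) (g - mean(g))^2)))
  stat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(
    statistic = stat, df = c(k - 1, N - k),
    p = pf(stat, k - 1, N - k, lower.tail = FALSE)
  )
}

#' Brown-Forsythe ANOVA for means (unequal variances)
#'
#' The variance-adjusted F statistic
#' \code{F* = sum n_i (m_i - m)^2 / sum (1 - n_i/N) s_i^2} with
#' Satterthwaite denominator degrees of freedom.
#'
#' @param groups list of numeric samples.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
brownForsytheAnova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  ci <- (1 - n / N) * v
  den <- sum(ci)
  stat <- num / den
  g <- ci / den
  df2 <- 1 / sum(g^2 / (n - 1))
  list(
    statistic = stat, df = c(k - 1, df2),
    p = pf(stat, k - 1, df2, lower.tail = FALSE)
  )
}

#' Dunnett's T3 all-pairs comparisons
#'
#' Pairwise Welch t statistics with Welch-Satterthwaite degrees of freedom;
#' adjusted p-values from the studentized maximum modulus distribution over
#' the number of comparisons (independence form
#' \code{1 - (2 F(|t|) - 1)^k}). Designed for unequal variances and small
#' unequal group sizes.
#'
#' @param groups named list of numeric samples.
#' @return data.frame with columns \code{pair}, \code{test},
#'   \code{statistic}, \code{df}, \code{p_raw}, \code{p_adjusted}.
#' @export
dunnettT3 <- function(groups) {
  nm <- names(groups)
  pairs <- combn(seq_along(groups), 2L)
  k <- ncol(pairs)
  res <- lapply(seq_len(k), function(j) {
    a <- groups[[pairs[1, j]]]
    b <- groups[[pairs[2, j]]]
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    tt <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    pr <- 2 * pt(-abs(tt), df)
    data.frame(
      pair = paste(nm[pairs[1, j]], "vs", nm[pairs[2, j]]),
      test = "Dunnett T3",
      statistic = tt, df = df, p_raw = pr,
      p_adjusted = min(1, 1 - (2 * pt(abs(tt), df) - 1)^k)
    )
  })
  do.call(rbind, res)
}

#' @keywords internal
.tukeyPairs <- function(groups) {
  nm <- names(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  mse <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2))) / (N - k)
  dfe <- N - k
  pairs <- combn(seq_len(k), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse * (1 / n[i1] + 1 / n[i2]))
    tt <- (m[i1] - m[i2]) / se
    data.frame(
      pair = paste(nm[i1], "vs", nm[i2]),
      test = "Tukey HSD",
      statistic = tt, df = dfe,
      p_raw = 2 * pt(-abs(tt), dfe),
      p_adjusted = ptukey(abs(tt) * sqrt(2), k, dfe, lower.tail = FALSE)
    )
  })
  do.call(rbind, res)
}

#' @keywords internal
.mannWhitney <- function(a, b) {
  ties <- any(duplicated(c(a, b)))
  exact <- (min(length(a), length(b)) <= 8L) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' @keywords internal
.checkGroups <- function(groups, minN) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  small <- names(groups)[lengths(groups) < minN]
  if (length(small) > 0L) {
    stop(
      "group(s) with fewer than ", minN, " observations: ",
      paste(small, collapse = ", ")
    )
  }
  groups
}

#' Run the omnibus decision tree over three or more groups
#'
#' Implements the study's statistical routing. Each group is tested for
#' normality (Anderson-Darling); equality of standard deviations is
#' assessed with both the Bartlett and the Brown-Forsythe tests.
#' \itemize{
#'   \item all groups normal and both variance tests non-significant:
#'     ordinary one-way ANOVA with post hoc Tukey multiple comparisons;
#'   \item all groups normal but either variance test significant:
#'     Brown-Forsythe and Welch ANOVA with Dunnett's T3 multiple
#'     comparisons (the Welch p is reported as the omnibus p);
#'   \item any group non-normal: Kruskal-Wallis with Bonferroni-Holm
#'     corrected pairwise Mann-Whitney tests.
#' }
#' The returned object carries the full audit trail (per-group normality
#' p-values, both variance-test p-values, branch, omnibus and pairwise
#' results), so the routing can be replayed from the recorded outcomes.
#'
#' @param groups named list of >= 3 numeric samples (each n >= 3).
#' @param alpha significance level (default 0.05).
#' @return object of class \code{"statDecision"}: list with elements
#'   \code{branch}, \code{normality}, \code{varianceTests}, \code{omnibus},
#'   \code{pairwise}, \code{alpha}.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(9), b = rnorm(9), c = rnorm(9) + 2)
#' chooseAndRunOmnibus(g)$branch
#' @export
chooseAndRunOmnibus <- function(groups, alpha = 0.05) {
  groups <- .checkGroups(groups, 3L)
  if (length(groups) < 3L) stop("need at least three groups")
  nm <- names(groups)
  norm <- lapply(groups, adNormality, alpha = alpha)
  normP <- vapply(norm, `[[`, numeric(1), "p")
  allNormal <- all(vapply(norm, `[[`, logical(1), "pass"))
  if (any(vapply(groups, function(g) sd(g) == 0, logical(1)))) {
    stop("constant group: variance tests and ANOVA are undefined")
  }
  bart <- bartlett.test(groups)
  bf <- brownForsytheVarTest(groups)
  varSimilar <- (bart$p.value > alpha) && (bf$p > alpha)
  values <- unlist(groups)
  fac <- factor(rep(nm, lengths(groups)), levels = nm)
  if (allNormal && varSimilar) {
    branch <- "ANOVA_TUKEY"
    fit <- anova(lm(values ~ fac))
    omnibus <- list(
      test = "one-way ANOVA", statistic = fit$`F value`[1],
      df = c(fit$Df[1], fit$Df[2]), p = fit$`Pr(>F)`[1]
    )
    pairwise <- .tukeyPairs(groups)
  } else if (allNormal) {
    branch <- "WELCH_BF_DUNNETT_T3"
    welch <- oneway.test(values ~ fac, var.equal = FALSE)
    bfA <- brownForsytheAnova(groups)
    omnibus <- list(
      test = "Welch ANOVA (with Brown-Forsythe ANOVA)",
      statistic = unname(welch$statistic),
      df = unname(welch$parameter), p = welch$p.value,
      brownForsythe = bfA
    )
    pairwise <- dunnettT3(groups)
  } else {
    branch <- "KRUSKAL_HOLM_MW"
    kw <- kruskal.test(groups)
    omnibus <- list(
      test = "Kruskal-Wallis", statistic = unname(kw$statistic),
      df = unname(kw$parameter), p = kw$p.value
    )
    pairs <- combn(seq_along(groups), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      mw <- .mannWhitney(groups[[pairs[1, j]]], groups[[pairs[2, j]]])
      data.frame(
        pair = paste(nm[pairs[1, j]], "vs", nm[pairs[2, j]]),
        test = if (mw$exact) "Mann-Whitney U (exact)" else "Mann-Whitney U",
        statistic = mw$statistic, df = NA_real_,
        p_raw = mw$p, p_adjusted = NA_real_
      )
    })
    pairwise <- do.call(rbind, rows)
    pairwise$p_adjusted <- p.adjust(pairwise$p_raw, method = "holm")
  }
  structure(
    list(
      branch = branch,
      normality = setNames(normP, nm),
      varianceTests = c(bartlett = bart$p.value, brown_forsythe = bf$p),
      omnibus = omnibus,
      pairwise = pairwise,
      alpha = alpha,
      groupSizes = setNames(lengths(groups), nm)
    ),
    class = "statDecision"
  )
}

#' @export
print.statDecision <- function(x, ...) {
  cat(sprintf(
    "Omnibus decision [%s]: %s p = %.4g (alpha = %g)\n",
    x$branch, x$omnibus$test, x$omnibus$p, x$alpha
  ))
  cat("  normality p:",
      paste(sprintf("%s=%.3g", names(x$normality), x$normality),
            collapse = ", "), "\n")
  cat(sprintf(
    "  variance tests: Bartlett p = %.3g, Brown-Forsythe p = %.3g\n",
    x$varianceTests["bartlett"], x$varianceTests["brown_forsythe"]
  ))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Two-sample comparison with normality- and variance-guided routing
#'
#' Both samples normal (Anderson-Darling) and variances similar (two-sided
#' F test): Student's t. Both normal but variances dissimilar: Welch's t.
#' Otherwise: Mann-Whitney U (exact when the smaller sample has at most 8
#' untied observations, normal approximation with tie correction
#' otherwise). All tests two-tailed.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param alpha significance level used for the routing tests.
#' @return list with \code{test}, \code{statistic}, \code{p}, plus the
#'   routing audit (\code{normalityP}, \code{varianceP}).
#' @export
pairwiseComparison <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each sample needs at least 3 observations")
  }
  if (sd(c(a, b)) == 0) {
    stop("degenerate comparison: all values identical in both samples")
  }
  na <- adNormality(a, alpha)
  nb <- adNormality(b, alpha)
  if (na$pass && nb$pass) {
    vp <- if (sd(a) == 0 || sd(b) == 0) 0 else var.test(a, b)$p.value
    if (vp > alpha) {
      tt <- t.test(a, b, var.equal = TRUE)
      test <- "Student t"
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      test <- "Welch t"
    }
    out <- list(
      test = test, statistic = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value
    )
  } else {
    mw <- .mannWhitney(a, b)
    out <- list(
      test = if (mw$exact) "Mann-Whitney U (exact)" else "Mann-Whitney U",
      statistic = mw$statistic, df = NA_real_, p = mw$p
    )
    vp <- NA_real_
  }
  out$normalityP <- c(a = na$p, b = nb$p)
  out$varianceP <- vp
  out$alpha <- alpha
  out
}

#' Significance stars at the study's thresholds
#'
#' @param p numeric p-values.
#' @return character vector: \code{****} p < 0.0001, \code{***} p < 0.001,
#'   \code{**} p < 0.01, \code{*} p < 0.05, \code{ns} otherwise.
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 1e-4, "****",
      ifelse(p < 1e-3, "***",
        ifelse(p < 1e-2, "**",
          ifelse(p < 0.05, "*", "ns")
        )
      )
    )
  )
}

.READOUT_METRICS <- c(
  "lesion_density_per_mm2", "mean_lesion_size_um2", "macro_density_per_mm2"
)

#' Interobserver concordance between two analysts
#'
#' Compares the readout tables produced by two investigators on the same
#' samples, per metric (lesion density, mean lesion size, macrolesion
#' density): Pearson correlation, slope/intercept of the least-squares line,
#' mean difference E1 - E2 with its paired t-test p-value, and
#' per-investigator distribution summaries. Because the detection pipeline
#' is deterministic once the ROI is fixed, identical inputs give r = 1 and
#' zero mean difference.
#'
#' @param e1,e2 readout data.frames (schema of [quantifySample()]), matched
#'   by \code{sample_id}.
#' @param metrics metric columns to compare.
#' @return object of class \code{"concordanceReport"}: per-metric list with
#'   \code{r}, \code{slope}, \code{intercept}, \code{meanDifference},
#'   \code{p}, \code{n}, and \code{summaries}.
#' @export
interobserverConcordance <- function(e1, e2, metrics = .READOUT_METRICS) {
  miss1 <- setdiff(e2$sample_id, e1$sample_id)
  miss2 <- setdiff(e1$sample_id, e2$sample_id)
  if (length(miss1) + length(miss2) > 0L) {
    stop(
      "unmatched sample_ids: ",
      paste(unique(c(miss1, miss2)), collapse = ", ")
    )
  }
  e2 <- e2[match(e1$sample_id, e2$sample_id), , drop = FALSE]
  perMetric <- lapply(metrics, function(m) {
    x <- e1[[m]]
    y <- e2[[m]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    d <- x - y
    if (sd(d) == 0) {
      p <- if (all(d == 0)) 1 else NA_real_
    } else {
      p <- t.test(d)$p.value
    }
    fit <- coef(lm(y ~ x))
    list(
      metric = m,
      n = length(x),
      r = if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y),
      intercept = unname(fit[1]),
      slope = unname(fit[2]),
      meanDifference = mean(d),
      p = p,
      summaries = rbind(
        E1 = c(mean = mean(x), sd = sd(x), median = median(x),
               q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75))),
        E2 = c(mean = mean(y), sd = sd(y), median = median(y),
               q25 = unname(quantile(y, 0.25)), q75 = unname(quantile(y, 0.75)))
      )
    )
  })
  names(perMetric) <- metrics
  structure(perMetric, class = "concordanceReport")
}

#' @export
print.concordanceReport <- function(x, ...) {
  cat("Interobserver concordance\n")
  for (m in x) {
    cat(sprintf(
      "  %-24s n = %d, r = %.4f, E1-E2 = %.4g (p = %.3g), slope = %.3f\n",
      m$metric, m$n, m$r, m$meanDifference, m$p, m$slope
    ))
  }
  invisible(x)
}

#' @keywords internal
.cohortGroups <- function(cohort, metric, condition) {
  sub <- cohort[cohort$condition == condition, , drop = FALSE]
  out <- lapply(c("WT", "HET", "HOM"), function(g) {
    v <- sub[[metric]][sub$genotype == g]
    v[is.finite(v)]
  })
  names(out) <- c("WT", "HET", "HOM")
  out
}

#' Run the full six-group study analysis
#'
#' For each metric (lesion density, mean lesion size, macrolesion density):
#' the three-genotype omnibus decision tree within each exercise condition,
#' plus the within-genotype no-run vs run pairwise contrasts (reported
#' unadjusted, as planned contrasts between two specific datasets of
#' interest). Significance stars use the usual thresholds.
#'
#' @param cohort readout data.frame carrying \code{genotype}
#'   (WT/HET/HOM), \code{condition} (no_run/run) and the metric columns.
#' @param alpha significance level.
#' @param metrics metric columns to analyse.
#' @return object of class \code{"studyReport"}: list with \code{omnibus}
#'   (nested decision objects), \code{contrasts} and a tidy \code{table} of
#'   every test performed.
#' @export
runStudyAnalysis <- function(cohort, alpha = 0.05,
                             metrics = .READOUT_METRICS) {
  need <- expand.grid(
    genotype = c("WT", "HET", "HOM"),
    condition = c("no_run", "run")
  )
  for (i in seq_len(nrow(need))) {
    n <- sum(cohort$genotype == need$genotype[i] &
             cohort$condition == need$condition[i])
    if (n < 2L) {
      stop(sprintf(
        "missing or underpopulated group: %s %s (n = %d)",
        need$genotype[i], need$condition[i], n
      ))
    }
  }
  omnibus <- list()
  contrasts <- list()
  rows <- list()
  for (m in metrics) {
    for (cond in c("no_run", "run")) {
      dec <- chooseAndRunOmnibus(.cohortGroups(cohort, m, cond), alpha)
      omnibus[[m]][[cond]] <- dec
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, comparison = paste("genotypes |", cond),
        branch = dec$branch, test = dec$omnibus$test,
        statistic = dec$omnibus$statistic, p_raw = dec$omnibus$p,
        p_adjusted = NA_real_, significant = dec$omnibus$p < alpha
      )
      pw <- dec$pairwise
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m,
        comparison = paste0(pw$pair, " | ", cond),
        branch = dec$branch, test = pw$test,
        statistic = pw$statistic, p_raw = pw$p_raw,
        p_adjusted = pw$p_adjusted,
        significant = pw$p_adjusted < alpha
      )
    }
    for (g in c("WT", "HET", "HOM")) {
      a <- cohort[[m]][cohort$genotype == g & cohort$condition == "no_run"]
      b <- cohort[[m]][cohort$genotype == g & cohort$condition == "run"]
      pc <- pairwiseComparison(a[is.finite(a)], b[is.finite(b)], alpha)
      contrasts[[m]][[g]] <- pc
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, comparison = paste(g, "no_run vs run"),
        branch = "PAIRWISE", test = pc$test,
        statistic = pc$statistic, p_raw = pc$p,
        p_adjusted = NA_real_, significant = pc$p < alpha
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$stars <- significanceStars(
    ifelse(is.na(tab$p_adjusted), tab$p_raw, tab$p_adjusted)
  )
  rownames(tab) <- NULL
  structure(
    list(omnibus = omnibus, contrasts = contrasts, table = tab,
         alpha = alpha),
    class = "studyReport"
  )
}

#' @export
print.studyReport <- function(x, ...) {
  cat("Six-group study analysis (alpha =", x$alpha, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
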