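.checkGroups <- function(values, groups, minPer = 2, minGroups = 2) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < minGroups)
    stop("need at least ", minGroups, " groups")
  n <- table(droplevels(groups))
  if (any(n < minPer))
    stop("every group needs at least ", minPer, " observations")
  droplevels(groups)
}

#' Variance-homogeneity screen routing the post-hoc procedure
#'
#' Groups are screened for unequal variances before multiple comparisons:
#' equal-variance data are routed to ANOVA with Tukey HSD, unequal-variance
#' data to the Steel-Dwass procedure. The gate is a Brown-Forsythe
#' (Levene-type) test on absolute deviations from the group medians.
#'
#' @param values numeric measurements.
#' @param groups group labels (coerced to factor).
#' @param alpha screen significance level.
#' @return list with `equalVariance` (logical), `route` (`"anova_tukey"` or
#'   `"steel_dwass"`), `p` and `statistic` of the screen.
#' @export
varianceScreen <- function(values, groups, alpha = 0.05) {
  groups <- .checkGroups(values, groups)
  med <- tapply(values, groups, median)
  z <- abs(values - med[groups])
  if (all(z == 0)) {                      # all groups constant: trivially equal
    return(list(equalVariance = TRUE, route = "anova_tukey",
                p = 1, statistic = 0))
  }
  a <- anova(lm(z ~ groups))
  p <- a[["Pr(>F)"]][1]
  list(equalVariance = p >= alpha,
       route = if (p >= alpha) "anova_tukey" else "steel_dwass",
       p = p, statistic = a[["F value"]][1])
}

#' Two-sample t test (pooled or Welch)
#'
#' Unpaired two-tailed comparison of two means; `welch = TRUE` uses the
#' Welch-Satterthwaite degrees of freedom, `FALSE` the pooled variance.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param welch logical.
#' @return list with `test`, `statistic`, `df`, `p`.
#' @export
twoSampleTest <- function(a, b, welch = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(test = "t", statistic = 0, df = NA_real_, p = 1))
    return(list(test = "t", statistic = sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p = 0))
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(test = if (welch) "welch_t" else "pooled_t",
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

## Insert-and-absorb compact letter display from an adjusted pairwise p
## matrix: groups NOT sharing a letter differ at alpha.
compactLetters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  dropAbsorbed <- function(cols) {
    if (length(cols) < 2) return(cols)
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(cols[[a]] <= cols[[b]]) &&
          (!identical(cols[[a]], cols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols[keep]
  }
  cols <- list(rep(TRUE, k))               # start: all groups in one letter
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    nxt <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        nxt <- c(nxt, list(c1, c2))
      } else nxt <- c(nxt, list(col))
    }
    cols <- dropAbsorbed(nxt)
  }
  letters_out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, `[`, TRUE, i))], collapse = ""),
    character(1))
  setNames(letters_out, g)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Omnibus F test followed by all pairwise Tukey honest significant
#' difference comparisons (studentized-range adjusted p), with a
#' compact-letter display at `alpha`: groups that do not share a letter
#' differ significantly.
#'
#' @inheritParams varianceScreen
#' @return list with `test`, `statistic` (F), `df`, `p` (omnibus),
#'   `pairwise` (symmetric matrix of adjusted p), `letters`, `alpha`.
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- .checkGroups(values, groups)
  lev <- levels(groups)
  k <- length(lev)
  if (sd(values) == 0) {                  # all observations identical
    pmat <- matrix(1, k, k, dimnames = list(lev, lev))
    return(list(test = "anova_tukey", statistic = NA_real_, df = NULL,
                p = NA_real_, pairwise = pmat,
                letters = setNames(rep("a", k), lev), alpha = alpha,
                degenerate = TRUE))
  }
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[r, "p adj"]
  }
  diag(pmat) <- 1
  list(test = "anova_tukey", statistic = s[["F value"]][1],
       df = s[["Df"]], p = s[["Pr(>F)"]][1], pairwise = pmat,
       letters = compactLetters(pmat, alpha), alpha = alpha,
       degenerate = FALSE)
}

## tie-corrected standardized pairwise rank-sum statistic (midranks)
.sdPairStat <- function(x, y) {
  ni <- length(x); nj <- length(y); N <- ni + nj
  r <- rank(c(x, y))
  W <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  ties <- table(c(x, y))
  tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
  V <- ni * nj / 12 * ((N + 1) - tieTerm)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric comparisons
#'
#' The Steel-Dwass(-Critchlow-Fligner) procedure: for every pair of groups,
#' a midrank Wilcoxon statistic on the pooled pair with tie-corrected
#' variance, referenced to the studentized range distribution
#' (`p = 1 - ptukey(sqrt(2) |t|, k, Inf)`) to control the familywise error
#' over all pairs. `method = "exact"` replaces the normal approximation of
#' each pairwise statistic with its exhaustive permutation distribution
#' (all reassignments of the pooled pair), mapping the exact tail
#' probability through the same studentized-range reference; it is
#' available for pairs with up to `maxExact` combinations.
#'
#' @inheritParams varianceScreen
#' @param method `"asymptotic"` or `"exact"`.
#' @param maxExact combination cap for the exact enumeration.
#' @return list with `test`, `pairwise` (adjusted p matrix), `statistics`
#'   (matrix of standardized statistics), `letters`, `alpha`.
#' @export
steelDwass <- function(values, groups, alpha = 0.05,
                       method = c("asymptotic", "exact"),
                       maxExact = 1e5) {
  method <- match.arg(method)
  groups <- .checkGroups(values, groups)
  lev <- levels(groups)
  k <- length(lev)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  tmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  diag(pmat) <- 1; diag(tmat) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- values[groups == lev[i]]; y <- values[groups == lev[j]]
    t0 <- .sdPairStat(x, y)
    if (method == "asymptotic") {
      p <- 1 - ptukey(sqrt(2) * abs(t0), k, Inf)
    } else {
      pooled <- c(x, y); N <- length(pooled); ni <- length(x)
      if (choose(N, ni) > maxExact)
        stop("pair too large for exact enumeration; use asymptotic")
      sel <- combn(N, ni)
      tAll <- apply(sel, 2, function(s)
        .sdPairStat(pooled[s], pooled[-s]))
      q <- mean(abs(tAll) >= abs(t0) - 1e-12)
      ## exact pairwise tail mapped through the studentized-range reference
      z <- qnorm(1 - min(q, 1) / 2)
      p <- 1 - ptukey(sqrt(2) * z, k, Inf)
    }
    tmat[i, j] <- tmat[j, i] <- t0
    pmat[i, j] <- pmat[j, i] <- p
  }
  list(test = paste0("steel_dwass_", method), pairwise = pmat,
       statistics = tmat, letters = compactLetters(pmat, alpha),
       alpha = alpha)
}
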