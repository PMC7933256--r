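## Cohort statistics: Spearman and Pearson correlations, Student's t,
## Wilcoxon tests, chi-square, and the low-voltage association analysis.
## All p-values are two-tailed; alpha = 0.05; no multiplicity correction by
## default (a Benjamini-Hochberg flag exists for reuse). Small samples get
## exact null distributions (full enumeration, valid under ties with
## average ranks); larger samples use the standard approximations. Base R's
## cor.test/t.test/wilcox.test/chisq.test back the tie-free paths and serve
## as independent cross-checks in the test suite.

.avgRank <- function(x) rank(x, ties.method = "average")

.checkPair <- function(x, y, minN = 3L, fun) {
  if (length(x) != length(y)) stop(fun, ": x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop(fun, ": missing values are not allowed")
  if (length(x) < minN) stop(fun, ": need at least ", minN, " observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(fun, ": constant vector, correlation undefined")
  invisible(TRUE)
}

## decode permutation number k (0-based) of 1..n via the factorial number
## system; vectorised over k, returns length(k) x n index matrix
.permFromIndex <- function(k, n) {
  m <- length(k)
  out <- matrix(0L, m, n)
  avail <- matrix(rep(seq_len(n), each = m), m, n)
  rem <- as.numeric(k)
  for (pos in seq_len(n)) {
    f <- factorial(n - pos)
    d <- floor(rem / f)          # 0-based choice among remaining values
    rem <- rem - d * f
    out[, pos] <- avail[cbind(seq_len(m), d + 1L)]
    if (pos < n) {               # drop the chosen column, shift the rest left
      navail <- n - pos + 1L
      newavail <- matrix(0L, m, navail - 1L)
      for (j in seq_len(navail - 1L)) {
        take <- ifelse(d + 1L > j, j, j + 1L)
        newavail[, j] <- avail[cbind(seq_len(m), take)]
      }
      avail <- newavail
    }
  }
  out
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' Average ranks under ties; the two-tailed p-value comes from full
#' enumeration of all n! rank permutations for n <= \code{exactMax}
#' (exact even under ties) and from the t approximation
#' t = r sqrt((n-2)/(1-r^2)) otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @param exactMax largest n for exact enumeration (default 10).
#' @return list with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
spearmanTest <- function(x, y, exactMax = 10L) {
  .checkPair(x, y, 3L, "spearmanTest")
  n <- length(x)
  rx <- .avgRank(x); ry <- .avgRank(y)
  r <- stats::cor(rx, ry)
  if (n <= exactMax) {
    tot <- factorial(n)
    chunk <- 50000
    sx <- (rx - mean(rx)) / stats::sd(rx)
    sy <- (ry - mean(ry)) / stats::sd(ry)
    hits <- 0
    start <- 0
    thr <- abs(r) - 1e-12
    while (start < tot) {
      len <- min(chunk, tot - start)
      P <- .permFromIndex(start + seq_len(len) - 1, n)
      rPerm <- matrix(sy[P], nrow = len) %*% sx / (n - 1)
      hits <- hits + sum(abs(rPerm) >= thr)
      start <- start + len
    }
    p <- hits / tot
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(r = r, p = min(p, 1), n = n, method = method)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), not constant.
#' @return list with \code{r}, \code{p} (two-tailed, t distribution),
#'   \code{n}.
#' @export
pearsonTest <- function(x, y) {
  .checkPair(x, y, 3L, "pearsonTest")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Student's t test (paired or two-sample)
#'
#' Classic equal-variance Student statistic by default, mirroring common
#' clinical usage; Welch's correction by flag. Paired data with identically
#' zero differences return t = 0, p = 1; a nonzero constant difference with
#' zero variance is degenerate and raises an error.
#'
#' @param a,b numeric samples.
#' @param paired paired test (requires equal lengths).
#' @param equalVariance pooled-variance Student (TRUE) or Welch (FALSE).
#' @return list with \code{t}, \code{df}, \code{p}, group means.
#' @export
tTest2 <- function(a, b, paired = FALSE, equalVariance = TRUE) {
  if (anyNA(a) || anyNA(b)) stop("tTest2: missing values are not allowed")
  if (paired) {
    if (length(a) != length(b)) stop("tTest2: paired samples differ in length")
    if (length(a) < 2L) stop("tTest2: need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(list(t = 0, df = length(d) - 1L, p = 1,
                    meanA = mean(a), meanB = mean(b)))
      stop("tTest2: degenerate paired data (constant nonzero difference)")
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2L || length(b) < 2L)
      stop("tTest2: need at least 2 observations per group")
    ht <- stats::t.test(a, b, var.equal = equalVariance)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       meanA = mean(a), meanB = mean(b))
}

#' Wilcoxon tests with exact small-sample enumeration
#'
#' \code{rank_sum}: two independent groups, statistic W = sum of pooled
#' ranks of \code{a}; exact conditional null by enumerating all
#' choose(n, n_a) group assignments for combined n <= \code{exactMax},
#' normal approximation with tie and continuity corrections otherwise.
#' \code{signed_rank}: paired; zero differences are dropped; statistic V =
#' sum of ranks of positive differences; exact by enumerating all 2^n sign
#' patterns for n <= \code{exactMax}.
#'
#' @param a,b numeric samples (\code{b} is the paired partner for
#'   \code{signed_rank}).
#' @param mode "rank_sum" or "signed_rank".
#' @param exactMax enumeration cutoff on the (combined/nonzero) n.
#' @return list with \code{statistic}, \code{p}, \code{n}, \code{method}.
#' @export
wilcoxonTest <- function(a, b, mode = c("rank_sum", "signed_rank"),
                         exactMax = 12L) {
  mode <- match.arg(mode)
  if (anyNA(a) || anyNA(b)) stop("wilcoxonTest: missing values not allowed")
  if (mode == "signed_rank") {
    if (length(a) != length(b))
      stop("wilcoxonTest: paired samples differ in length")
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0L)
      stop("wilcoxonTest: all paired differences are zero")
    n <- length(d)
    rk <- .avgRank(abs(d))
    V <- sum(rk[d > 0])
    if (n <= exactMax) {
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      Vall <- drop(signs %*% rk)
      p <- 2 * min(mean(Vall <= V + 1e-12), mean(Vall >= V - 1e-12))
      method <- "exact enumeration"
    } else {
      mu <- n * (n + 1) / 4
      ties <- table(rk)
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
      z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
      method <- "normal approximation"
    }
    return(list(statistic = V, p = min(p, 1), n = n, method = method))
  }
  ## rank_sum
  na <- length(a); nb <- length(b); n <- na + nb
  if (na < 1L || nb < 1L) stop("wilcoxonTest: empty group")
  rk <- .avgRank(c(a, b))
  W <- sum(rk[seq_len(na)])
  if (n <= exactMax) {
    combos <- utils::combn(n, na)
    Wall <- colSums(matrix(rk[combos], nrow = na))
    p <- 2 * min(mean(Wall <= W + 1e-12), mean(Wall >= W - 1e-12))
    method <- "exact enumeration"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(rk)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p = min(p, 1), n = n, method = method)
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' No continuity correction by default; Yates' correction by flag (2 x 2).
#'
#' @param table 2 x k matrix of nonnegative counts, no all-zero margin.
#' @param yates apply Yates' continuity correction.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
chiSquareTest <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("chiSquareTest: need a 2 x k table with k >= 2")
  if (any(tab < 0) || anyNA(tab)) stop("chiSquareTest: invalid counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chiSquareTest: degenerate margin (all-zero row or column)")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

## ---------------------------------------------------------------------------
## Low-voltage association analysis
## ---------------------------------------------------------------------------

.metricCols <- function() c(paste0("D_", segmentNames()), "LAV", "ASI", "LAS")

#' Validate a cohort metrics table
#'
#' @param table data.frame with one row per patient: \code{patient},
#'   volumes/indices, D and lva columns per segment, and
#'   \code{lva_segment_count}.
#' @return the table, invisibly; errors describe the violation.
#' @export
validateCohortTable <- function(table) {
  need <- c("patient", "LAV", "LA_A", "LA_P", "ASI", "AR", "S", "LAS",
            paste0("D_", segmentNames()), paste0("lva_", segmentNames()),
            "lva_segment_count")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$patient)) stop("duplicated patient ids")
  cnt <- rowSums(table[, paste0("lva_", segmentNames())])
  if (any(cnt != table$lva_segment_count))
    stop("lva_segment_count does not equal the per-segment label sum")
  invisible(table)
}

#' Association analysis of shape metrics with low-voltage extent
#'
#' Families, all two-tailed at alpha = 0.05:
#' \enumerate{
#'   \item \code{burden}: the headline association - Spearman of each
#'     patient's overall deformation burden (mean of the six |D| values)
#'     against the number of low-voltage segments;
#'   \item \code{countCorrelations}: Spearman of each segmental D, LAV, ASI
#'     and LAS against the number of low-voltage segments;
#'   \item \code{pairwiseCorrelations}: Spearman grid among segmental D
#'     values and of each D against LAV/ASI/LAS;
#'   \item \code{groupContrasts}: extended low-voltage (all 6 segments)
#'     versus limited extent (1-3 segments), Student's t on each segmental
#'     D with group means +/- SD.
#' }
#' Contrasts that cannot be computed (constant vector, group with < 2
#' patients) are reported with NA and a flag rather than raising.
#'
#' @param table a validated cohort table (see [validateCohortTable()]).
#' @param welch use Welch's t for the group contrast.
#' @param bhCorrect add Benjamini-Hochberg adjusted p-values per family.
#' @param alpha significance threshold for the flag column.
#' @return list of class \code{"associationReport"} with the three
#'   data.frames.
#' @export
lvaAssociation <- function(table, welch = FALSE, bhCorrect = FALSE,
                           alpha = 0.05) {
  validateCohortTable(table)
  cnt <- table$lva_segment_count
  mets <- .metricCols()

  one_cor <- function(x, y) {
    res <- tryCatch(spearmanTest(x, y),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = length(x)))
    res
  }
  cc <- do.call(rbind, lapply(mets, function(m) {
    r <- one_cor(table[[m]], cnt)
    data.frame(metric = m, r = r$r, p = r$p, n = r$n)
  }))
  cc$significant <- !is.na(cc$p) & cc$p < alpha

  pairs <- utils::combn(mets, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    r <- one_cor(table[[m1]], table[[m2]])
    data.frame(metric1 = m1, metric2 = m2, r = r$r, p = r$p, n = r$n)
  }))
  pw$significant <- !is.na(pw$p) & pw$p < alpha

  ## headline association: overall deformation burden (patient mean of the
  ## six |D| values) against the number of low-voltage segments
  burdenScore <- rowMeans(abs(table[, paste0("D_", segmentNames())]))
  burden <- one_cor(burdenScore, cnt)
  burden <- data.frame(metric = "mean_abs_D", r = burden$r, p = burden$p,
                       n = burden$n,
                       significant = !is.na(burden$p) & burden$p < alpha)

  ext <- cnt == 6L
  lim <- cnt >= 1L & cnt <= 3L
  gc <- do.call(rbind, lapply(paste0("D_", segmentNames()), function(m) {
    if (sum(ext) < 2L || sum(lim) < 2L)
      return(data.frame(metric = m, t = NA_real_, df = NA_real_,
                        p = NA_real_, meanExtended = NA_real_,
                        sdExtended = NA_real_, meanLimited = NA_real_,
                        sdLimited = NA_real_, nExtended = sum(ext),
                        nLimited = sum(lim), computable = FALSE))
    tt <- tryCatch(tTest2(table[[m]][ext], table[[m]][lim],
                          equalVariance = !welch),
                   error = function(e) NULL)
    if (is.null(tt))
      return(data.frame(metric = m, t = NA_real_, df = NA_real_,
                        p = NA_real_, meanExtended = mean(table[[m]][ext]),
                        sdExtended = stats::sd(table[[m]][ext]),
                        meanLimited = mean(table[[m]][lim]),
                        sdLimited = stats::sd(table[[m]][lim]),
                        nExtended = sum(ext), nLimited = sum(lim),
                        computable = FALSE))
    data.frame(metric = m, t = tt$t, df = tt$df, p = tt$p,
               meanExtended = mean(table[[m]][ext]),
               sdExtended = stats::sd(table[[m]][ext]),
               meanLimited = mean(table[[m]][lim]),
               sdLimited = stats::sd(table[[m]][lim]),
               nExtended = sum(ext), nLimited = sum(lim), computable = TRUE)
  }))
  gc$significant <- !is.na(gc$p) & gc$p < alpha

  if (bhCorrect) {
    cc$pAdjusted <- stats::p.adjust(cc$p, "BH")
    pw$pAdjusted <- stats::p.adjust(pw$p, "BH")
    gc$pAdjusted <- stats::p.adjust(gc$p, "BH")
  }
  structure(list(burden = burden, countCorrelations = cc,
                 pairwiseCorrelations = pw, groupContrasts = gc,
                 alpha = alpha),
            class = "associationReport")
}

#' @export
print.associationReport <- function(x, ...) {
  cat("Low-voltage association report (alpha =", x$alpha, ")\n")
  cat(sprintf("- deformation burden vs LVA count: r = %.3f, p = %.4g\n",
              x$burden$r, x$burden$p))
  cat("- count correlations:", sum(x$countCorrelations$significant),
      "of", nrow(x$countCorrelations), "significant\n")
  cat("- pairwise correlations:", sum(x$pairwiseCorrelations$significant),
      "of", nrow(x$pairwiseCorrelations), "significant\n")
  cat("- group contrasts (extended vs 1-3 segments):",
      sum(x$groupContrasts$significant), "of", nrow(x$groupContrasts),
      "significant\n")
  invisible(x)
}

#' Write an association report to disk
#'
#' @param report an \code{associationReport}.
#' @param dir output directory; writes \code{association_report.json} and
#'   one flat CSV per family.
#' @return \code{dir}, invisibly.
#' @export
writeAssociationReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(alpha = report$alpha,
         burden = report$burden,
         countCorrelations = report$countCorrelations,
         pairwiseCorrelations = report$pairwiseCorrelations,
         groupContrasts = report$groupContrasts),
    file.path(dir, "association_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$countCorrelations,
                   file.path(dir, "count_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairwiseCorrelations,
                   file.path(dir, "pairwise_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$groupContrasts,
                   file.path(dir, "group_contrasts.csv"), row.names = FALSE)
  invisible(dir)
}
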