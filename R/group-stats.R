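#' Map postnatal day to age bin
#'
#' Recording days pool into four age categories: 1 month (days 30-35),
#' 1.5 months (days 36-42), 2 months (days 44-58) and 3 months (days 64-103).
#' Days outside these ranges (including the gaps at 43 and 59-63) are
#' out-of-range and map to NA.
#'
#' @param postnatalDay integer day(s) p.n. (>= 1).
#' @return numeric vector with values in \{1, 1.5, 2, 3\} or NA.
#' @examples
#' ageBin(c(30, 35, 43, 70))
#' @export
ageBin <- function(postnatalDay) {
  stopifnot(all(postnatalDay >= 1))
  vapply(postnatalDay, function(d) {
    if (d >= 30 && d <= 35) 1
    else if (d >= 36 && d <= 42) 1.5
    else if (d >= 44 && d <= 58) 2
    else if (d >= 64 && d <= 103) 3
    else NA_real_
  }, numeric(1))
}

#' Summarize one session's calls
#'
#' Arithmetic means over calls, computed per session (the unit of all later
#' group statistics). \code{pct_voiced} is the percentage of calls classified
#' voiced among all classes; duration and level are averaged over all calls;
#' F0 and harmonic-ratio statistics are averaged over voiced calls only (they
#' are undefined elsewhere).
#'
#' @param features per-call feature table from [analyzeSession()].
#' @param sessionId,animalId identifiers.
#' @param group hearing-status group.
#' @param postnatalDay age in days; binned via [ageBin()].
#' @return one-row data.frame (a session summary).
#' @export
summarizeSession <- function(features, sessionId = "session-1",
                             animalId = "unknown", group = "hearing",
                             postnatalDay = 30L) {
  if (!is.data.frame(features) || nrow(features) == 0)
    stop("empty session: no calls to summarize", call. = FALSE)
  voicedCols <- c("f0_mean", "f0_max", "f0_sd", "t_f0max_s",
                  "hr_mean", "hr_sd", "hr_max", "t_hrmax_s", "hr_at_f0max")
  out <- data.frame(
    session_id = sessionId, animal_id = animalId, group = group,
    postnatal_day = postnatalDay, age_bin = ageBin(postnatalDay),
    n_calls = nrow(features),
    pct_voiced = 100 * mean(features$call_class == "voiced"),
    duration_s = mean(features$duration_s),
    level_db = mean(features$level_db),
    stringsAsFactors = FALSE)
  for (cl in voicedCols) out[[cl]] <- mean(features[[cl]], na.rm = TRUE)
  out
}

#' Grand means over pooled session summaries
#'
#' Pools session summaries irrespective of age and averages the session means
#' per group -- a mean of session means, not a call-weighted mean.
#'
#' @param summaries data.frame of rows from [summarizeSession()].
#' @return data.frame, one row per group, with the per-feature grand means.
#' @export
grandMeans <- function(summaries) {
  num <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  num <- setdiff(num, c("postnatal_day", "age_bin"))
  do.call(rbind, lapply(split(summaries, summaries$group), function(g) {
    row <- data.frame(group = g$group[1], n_sessions = nrow(g),
                      stringsAsFactors = FALSE)
    for (cl in num) row[[cl]] <- mean(g[[cl]], na.rm = TRUE)
    row
  }))
}

# Anderson-Darling A^2 for a sample against a normal with estimated
# mean/variance, with Stephens' small-sample modification.
.adStatistic <- function(x) {
  n <- length(x)
  x <- sort(x)
  p <- stats::pnorm((x - mean(x)) / sd(x))
  eps <- .Machine$double.xmin
  p <- pmin(pmax(p, eps), 1 - 1e-16)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  A2 * (1 + 0.75 / n + 2.25 / n^2)
}

# Upper-tail p-value for the modified statistic (Stephens' approximation,
# case: both parameters estimated).
.adPvalue <- function(AA) {
  if (AA < 0.2) 1 - exp(-13.436 + 101.14 * AA - 223.73 * AA^2)
  else if (AA < 0.34) 1 - exp(-8.318 + 42.796 * AA - 59.938 * AA^2)
  else if (AA < 0.6) exp(0.9177 - 4.279 * AA - 1.38 * AA^2)
  else if (AA < 153) exp(1.2937 - 5.709 * AA + 0.0186 * AA^2)
  else 0
}

#' Normality test (EDF statistic with small-sample modification)
#'
#' Anderson-Darling test of composite normality (mean and variance
#' estimated), using Stephens' small-sample modification of the statistic and
#' his p-value approximation; the pass decision is taken at
#' \code{alpha = 0.10}. A degenerate (zero-variance) sample fails. A Pearson
#' chi-square alternative over equiprobable bins is available via
#' \code{method = "chisq"}.
#'
#' @param x numeric sample (n >= 5).
#' @param alpha significance level for the pass decision (default 0.10).
#' @param method \code{"ad"} (default) or \code{"chisq"}.
#' @return list: \code{statistic}, \code{p_value}, \code{pass} (TRUE =
#'   normality not rejected), \code{method}, \code{n}.
#' @export
normalityTest <- function(x, alpha = 0.10, method = c("ad", "chisq")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  if (sd(x) == 0)
    return(list(statistic = Inf, p_value = 0, pass = FALSE,
                method = method, n = n))
  if (method == "ad") {
    AA <- .adStatistic(x)
    p <- .adPvalue(AA)
    list(statistic = AA, p_value = p, pass = p > alpha, method = "ad", n = n)
  } else {
    k <- max(4L, floor(1.88 * n^(2 / 5)))      # Moore's rule for bin count
    br <- stats::qnorm(seq(0, 1, length.out = k + 1), mean(x), sd(x))
    br[1] <- -Inf; br[k + 1] <- Inf
    obs <- table(cut(x, br))
    exp <- n / k
    stat <- sum((obs - exp)^2 / exp)
    df <- k - 3
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    list(statistic = stat, p_value = p, pass = p > alpha, method = "chisq",
         n = n)
  }
}

#' Compare two samples: variance (F) test and mean (t) test
#'
#' The F statistic is the larger sample variance over the smaller, with the
#' matching two-tailed p value. The t test (two-tailed, uncorrected) uses the
#' pooled-variance form when the F test does not reject equality of variances
#' at \code{alphaVar}, and the unequal-variance (Welch) form otherwise.
#' Normality of each sample is assessed with [normalityTest()] and reported
#' as a flag -- the t test is run regardless, with failures flagged rather
#' than the test switched.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param feature label carried into the output.
#' @param alphaVar significance level gating the pooled/Welch choice
#'   (default 0.05).
#' @return data.frame with two rows (\code{test = "f_var"} and
#'   \code{"t_two_tailed"}): \code{feature}, \code{statistic}, \code{df},
#'   \code{df2}, \code{p_value}, \code{n_a}, \code{n_b},
#'   \code{normality_pass_a}, \code{normality_pass_b}.
#' @export
compareGroups <- function(a, b, feature = "", alphaVar = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0)
    stop("zero variance in both samples", call. = FALSE)
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  pF <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  tt <- t.test(a, b, var.equal = pF > alphaVar)
  npass <- function(x) if (length(x) >= 5 && sd(x) > 0)
    normalityTest(x)$pass else NA
  na <- npass(a); nb <- npass(b)
  data.frame(
    feature = feature,
    test = c("f_var", "t_two_tailed"),
    statistic = c(f, unname(tt$statistic)),
    df = c(df1, unname(tt$parameter)),
    df2 = c(df2, NA_real_),
    p_value = c(pF, tt$p.value),
    n_a = length(a), n_b = length(b),
    normality_pass_a = na, normality_pass_b = nb,
    stringsAsFactors = FALSE)
}

#' Developmental comparison table
#'
#' For each feature: within-group across-age comparisons (consecutive age
#' bins) and within-age across-group comparisons (all group pairs), each an
#' F-test / t-test pair from [compareGroups()], assembled into one
#' long-format table. Comparisons with fewer than 2 sessions on either side
#' are skipped. No multiple-testing correction is applied.
#'
#' @param summaries session-summary data.frame (rows from
#'   [summarizeSession()]).
#' @param features character vector of summary columns to compare.
#' @return long-format data.frame: \code{feature}, \code{comparison}
#'   (\code{"age_within_group"} or \code{"group_within_age"}), \code{group_a},
#'   \code{group_b}, \code{age_a}, \code{age_b}, plus the [compareGroups()]
#'   columns.
#' @export
developmentalTable <- function(summaries,
                               features = c("duration_s", "level_db",
                                            "f0_mean", "f0_max", "f0_sd",
                                            "hr_mean", "hr_sd")) {
  summaries <- summaries[!is.na(summaries$age_bin), , drop = FALSE]
  ages <- sort(unique(summaries$age_bin))
  if (length(ages) < 2) stop("need at least 2 populated age bins",
                             call. = FALSE)
  groups <- unique(summaries$group)
  rows <- list()
  add <- function(cmp, comparison, ga, gb, aa, ab) {
    cmp$comparison <- comparison
    cmp$group_a <- ga; cmp$group_b <- gb
    cmp$age_a <- aa; cmp$age_b <- ab
    rows[[length(rows) + 1]] <<- cmp
  }
  for (feat in features) {
    for (g in groups) {
      sg <- summaries[summaries$group == g, ]
      for (i in seq_len(length(ages) - 1)) {
        x <- sg[[feat]][sg$age_bin == ages[i]]
        y <- sg[[feat]][sg$age_bin == ages[i + 1]]
        if (sum(is.finite(x)) >= 2 && sum(is.finite(y)) >= 2)
          add(compareGroups(x, y, feat), "age_within_group", g, g,
              ages[i], ages[i + 1])
      }
    }
    if (length(groups) >= 2) {
      gp <- utils::combn(groups, 2)
      for (a in ages) for (j in seq_len(ncol(gp))) {
        sa <- summaries[[feat]][summaries$age_bin == a &
                                summaries$group == gp[1, j]]
        sb <- summaries[[feat]][summaries$age_bin == a &
                                summaries$group == gp[2, j]]
        if (sum(is.finite(sa)) >= 2 && sum(is.finite(sb)) >= 2)
          add(compareGroups(sa, sb, feat), "group_within_age",
              gp[1, j], gp[2, j], a, a)
      }
    }
  }
  if (length(rows) == 0) {
    warning("no cell has >= 2 sessions on both sides; empty comparison table")
    return(data.frame(feature = character(0), test = character(0),
                      statistic = numeric(0), df = numeric(0),
                      df2 = numeric(0), p_value = numeric(0),
                      n_a = integer(0), n_b = integer(0),
                      normality_pass_a = logical(0),
                      normality_pass_b = logical(0),
                      comparison = character(0),
                      group_a = character(0), group_b = character(0),
                      age_a = numeric(0), age_b = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
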