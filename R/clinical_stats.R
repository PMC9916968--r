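# Clinical association toolkit: contingency tests, rank correlation,
# Kaplan-Meier estimation and the two-group log-rank test.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the observed margins, sums the hypergeometric point
#' probabilities of all tables no more probable than the observed one
#' (point-probability method, with a 1 + 1e-7 relative tolerance on the
#' comparison). A table with a zero margin carries no evidence and
#' returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `p.value` and `method`.
#' @examples
#' fisher_exact_2x2(matrix(c(1, 11, 9, 3), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- validate_contingency(tab, allow_empty = TRUE)
  if (nrow(tab) != 2L || ncol(tab) != 2L) {
    stop_taavet("fisher_exact_2x2 requires a 2x2 table")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p.value = 1, method = "Fisher's exact test (two-sided)"))
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  d <- stats::dhyper(lo:hi, r1, r2, c1)
  p <- sum(d[d <= d[tab[1, 1] - lo + 1] * (1 + 1e-7)])
  list(p.value = min(p, 1), method = "Fisher's exact test (two-sided)")
}

#' Pearson's chi-squared test of independence
#'
#' Without continuity correction: the statistic is the plain
#' sum((O - E)^2 / E) against the chi-squared tail on (r-1)(c-1) degrees
#' of freedom. Refuses tables with a zero expected count and advises the
#' exact test instead.
#'
#' @param tab r x c matrix of non-negative integer counts (r, c >= 2).
#' @return List with `statistic`, `p.value`, `df`.
#' @export
chi_squared_test <- function(tab) {
  tab <- validate_contingency(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop_taavet("zero expected count; use Fisher's exact test instead")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       df = unname(res$parameter))
}

validate_contingency <- function(tab, allow_empty = FALSE) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || anyNA(tab) || any(tab < 0) || !all(is_whole(tab))) {
    stop_taavet("contingency table must hold non-negative integer counts")
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_taavet("contingency table needs at least 2 rows and 2 columns")
  }
  if (!allow_empty && sum(tab) == 0) stop_taavet("contingency table is all zero")
  storage.mode(tab) <- "double"
  tab
}

#' Spearman rank correlation
#'
#' Computes rho as the Pearson correlation of average (midrank) ranks.
#' The p-value is exact by full permutation enumeration for n <= 8 and
#' uses the t approximation on rho otherwise (two-sided in both cases).
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @param exact_max Largest n for which the permutation-exact p-value is
#'   computed (default 8; n! permutations are enumerated).
#' @return List with `rho`, `p.value`, `method`.
#' @export
spearman_rho <- function(x, y, exact_max = 8) {
  if (length(x) != length(y)) stop_taavet("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2L) stop_taavet("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop_taavet("missing values are not supported")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_taavet("rho is undefined for constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    # exact two-sided p: fraction of rank permutations with |rho| at
    # least as extreme; rho is monotone in sum(rx * ry_perm), so permute
    # the (possibly tied) midranks of y directly
    perms <- permutations_of(n)
    s <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    mu <- n * mean(rx) * mean(ry)
    sc <- stats::sd(rx) * stats::sd(ry) * (n - 1)
    rho_perm <- (s - mu) / sc
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation p)"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "Spearman rank correlation (t approximation)"
  }
  list(rho = rho, p.value = min(max(p, 0), 1), method = method)
}

# all n! permutations of 1..n as a matrix (rows = permutations)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with the median
#' survival time defined as the smallest event time at which the
#' estimated survival drops to 0.5 or below (undefined — `NA` — when the
#' curve never reaches 0.5).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return Object of class `taa_km`: `time`, `surv`, `n_risk`, `n_event`
#'   at each distinct observed time, plus `median` and `n`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop_taavet("no survival times supplied")
  if (length(times) != length(events)) {
    stop_taavet("`times` and `events` must have equal length")
  }
  if (anyNA(times) || any(times < 0)) {
    stop_taavet("survival times must be non-negative and non-missing")
  }
  events <- as.logical(events)
  if (anyNA(events)) stop_taavet("event indicators must be TRUE/FALSE")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  surv <- fit$surv
  time <- fit$time
  med <- if (any(fit$n.event > 0 & surv <= 0.5 + 1e-12)) {
    min(time[fit$n.event > 0 & surv <= 0.5 + 1e-12])
  } else {
    NA_real_
  }
  structure(list(time = time, surv = surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(times)),
            class = "taa_km")
}

#' @export
print.taa_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic on 1 degree of freedom
#' comparing the survival experience of two groups.
#'
#' @param times Follow-up times.
#' @param events Event indicators (`TRUE` = event).
#' @param group Two-level grouping vector.
#' @return List with `statistic`, `p.value`, `df`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) {
    stop_taavet("logrank_test compares exactly two groups, got ",
                nlevels(group))
  }
  if (any(tabulate(group, 2L) == 0L)) stop_taavet("both groups must be non-empty")
  events <- as.logical(events)
  if (sum(events) == 0L) {
    warning("no events in either group: log-rank statistic is 0", call. = FALSE)
    return(list(statistic = 0, p.value = 1, df = 1L))
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(statistic = unname(fit$chisq),
       p.value = min(stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE), 1),
       df = 1L)
}

#' Clinical association battery for one antigen
#'
#' Crosses the two expression groupings (intensity dichotomy low/high
#' and Q-Score >= 150 yes/no) with the categorical clinical covariates
#' (Fisher's exact test for 2x2 tables, Pearson's chi-squared otherwise)
#' and with progression-free survival (log-rank test). Exploratory: no
#' multiplicity correction by default; `bonferroni = TRUE` appends an
#' adjusted p-value column over the battery.
#'
#' @param tma TMA data frame (see [read_tma()]); unassessable cores are
#'   dropped.
#' @param antigen Optional antigen id to subset on.
#' @param covariates Clinical columns to cross with the groupings.
#' @param test `"auto"` (Fisher for 2x2, chi-squared otherwise),
#'   `"fisher"` or `"chisq"`.
#' @param bonferroni Apply a Bonferroni correction across the battery.
#' @return Long data frame: `antigen`, `grouping`, `covariate`, `test`,
#'   `statistic`, `p` (and `p_adjusted` when requested).
#' @export
tma_association_battery <- function(tma, antigen = NULL,
                                    covariates = c("grade", "figo_stage",
                                                   "t_stage", "perit_carc",
                                                   "residual_tumor",
                                                   "platinum_response"),
                                    test = c("auto", "fisher", "chisq"),
                                    bonferroni = FALSE) {
  test <- match.arg(test)
  if (!is.null(antigen) && "antigen" %in% names(tma)) {
    tma <- tma[tma$antigen == antigen, , drop = FALSE]
  }
  if ("assessable" %in% names(tma)) {
    tma <- tma[as.logical(tma$assessable), , drop = FALSE]
  }
  if (!nrow(tma)) stop_taavet("no assessable TMA cores")
  ant <- if (is.null(antigen)) paste(unique(tma$antigen), collapse = "+") else antigen

  groupings <- list(
    intensity_dichotomy = dichotomize_intensity(tma$consensus_intensity),
    q_ge_150 = factor(
      ifelse(q_score(tma$consensus_intensity, tma$percent_positive) >= 150,
             "Q>=150", "Q<150"),
      levels = c("Q<150", "Q>=150")))

  rows <- list()
  for (gname in names(groupings)) {
    g <- groupings[[gname]]
    for (cov in intersect(covariates, names(tma))) {
      v <- tma[[cov]]
      keep <- !is.na(v) & v != "unknown" & !is.na(g)
      if (length(unique(v[keep])) < 2L || length(unique(g[keep])) < 2L) next
      tab <- table(droplevels(g[keep]), factor(v[keep]))
      use_fisher <- switch(test,
                           auto = all(dim(tab) == 2L),
                           fisher = TRUE,
                           chisq = FALSE)
      if (use_fisher && !all(dim(tab) == 2L)) {
        stop_taavet("Fisher's exact test requested for a non-2x2 table (",
                    cov, ")")
      }
      res <- if (use_fisher) {
        c(test = "fisher_exact", statistic = NA_real_,
          p = fisher_exact_2x2(tab)$p.value)
      } else {
        ct <- chi_squared_test(tab)
        c(test = "chi_squared", statistic = ct$statistic, p = ct$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        antigen = ant, grouping = gname, covariate = cov,
        test = res[["test"]], statistic = as.numeric(res[["statistic"]]),
        p = as.numeric(res[["p"]]), stringsAsFactors = FALSE)
    }
    if (all(c("pfs_months", "pfs_event") %in% names(tma)) &&
        length(unique(g)) == 2L) {
      lr <- logrank_test(tma$pfs_months, tma$pfs_event, g)
      rows[[length(rows) + 1L]] <- data.frame(
        antigen = ant, grouping = gname, covariate = "pfs",
        test = "logrank", statistic = lr$statistic, p = lr$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(antigen = character(), grouping = character(),
                      covariate = character(), test = character(),
                      statistic = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (bonferroni && nrow(out)) {
    out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  }
  rownames(out) <- NULL
  out
}
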