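# Tissue-microarray staining quantification: Q-Score, binning,
# intensity dichotomization and per-antigen summaries.

#' Q-Score of an immunohistochemistry core
#'
#' The Q-Score combines staining intensity (0 negative, 1 weak,
#' 2 moderate, 3 strong) with homogeneity (percentage of positively
#' stained tumor cells) as their product, ranging 0-300. A Q-Score of at
#' least 150 implies moderate-to-strong intensity in at least half of
#' the tumor cells.
#'
#' @param intensity Integer staining intensity in `0:3` (vectorized).
#' @param percent_positive Integer percentage of stained tumor cells in
#'   `0:100` (vectorized).
#' @return Integer Q-Score(s) in `[0, 300]`.
#' @examples
#' q_score(3, 100)  # 300
#' q_score(2, 75)   # 150
#' @export
q_score <- function(intensity, percent_positive) {
  check_intensity(intensity)
  if (!all(is_whole(percent_positive)) ||
      any(percent_positive < 0 | percent_positive > 100)) {
    stop_taavet("`percent_positive` must be whole numbers in 0..100")
  }
  as.integer(round(intensity) * round(percent_positive))
}

check_intensity <- function(intensity) {
  if (!all(is_whole(intensity)) || any(intensity < 0 | intensity > 3)) {
    stop_taavet("staining intensity must be whole numbers in 0..3")
  }
  invisible(intensity)
}

#' Bin a Q-Score
#'
#' Splits the 0-300 Q-Score range into the three analysis bins: exactly
#' 0 (`zero`), 1-149 (`low`), and 150-300 (`high`).
#'
#' @param q Integer Q-Score(s) in `[0, 300]`.
#' @return Factor with levels `zero`, `low`, `high`.
#' @export
bin_q_score <- function(q) {
  if (!all(is_whole(q)) || any(q < 0 | q > 300)) {
    stop_taavet("Q-Scores must be whole numbers in 0..300")
  }
  factor(ifelse(q == 0, "zero", ifelse(q < 150, "low", "high")),
         levels = c("zero", "low", "high"))
}

#' Dichotomize staining intensity
#'
#' Collapses the four-level intensity scale to `low` (negative to weak,
#' 0-1) versus `high` (moderate to strong, 2-3), the split used for the
#' survival comparisons.
#'
#' @param intensity Integer staining intensity in `0:3` (vectorized).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_intensity <- function(intensity) {
  check_intensity(intensity)
  factor(ifelse(intensity >= 2, "high", "low"), levels = c("low", "high"))
}

#' Summarize staining of one antigen across a TMA
#'
#' Produces the per-antigen staining portrait: counts per consensus
#' intensity level, the distribution of percent-positive cells, the
#' number of cores with Q-Score of at least 150, the Spearman
#' correlation between intensity and percent positive, the number of
#' cores on which the two raters disagreed, and the number of
#' unassessable cores (excluded from all statistics).
#'
#' @param tma Data frame of TMA cores (see [read_tma()] for the schema);
#'   must contain `consensus_intensity`, `percent_positive`,
#'   `assessable`, and optionally `intensity_r1`/`intensity_r2` and
#'   `antigen`.
#' @param antigen Optional antigen id to subset on.
#' @return A list of class `taa_staining_summary`.
#' @export
staining_summary <- function(tma, antigen = NULL) {
  if (!is.null(antigen) && "antigen" %in% names(tma)) {
    tma <- tma[tma$antigen == antigen, , drop = FALSE]
  }
  if (!nrow(tma)) stop_taavet("no TMA cores to summarize")
  assessable <- if ("assessable" %in% names(tma)) {
    as.logical(tma$assessable)
  } else {
    rep(TRUE, nrow(tma))
  }
  n_unassessable <- sum(!assessable)
  d <- tma[assessable, , drop = FALSE]
  if (!nrow(d)) stop_taavet("no assessable TMA cores")
  check_intensity(d$consensus_intensity)
  q <- q_score(d$consensus_intensity, d$percent_positive)

  rho <- NULL
  if (nrow(d) >= 2) {
    rho <- tryCatch(spearman_rho(d$consensus_intensity, d$percent_positive),
                    error = function(e) NULL)
    if (is.null(rho)) {
      warning("intensity/percent correlation not computable (constant input)",
              call. = FALSE)
    }
  } else {
    warning("fewer than 2 assessable cores: correlation omitted", call. = FALSE)
  }
  n_discordant <- if (all(c("intensity_r1", "intensity_r2") %in% names(d))) {
    sum(d$intensity_r1 != d$intensity_r2)
  } else {
    NA_integer_
  }
  structure(list(
    antigen = if (is.null(antigen)) unique(as.character(tma$antigen)) else antigen,
    n_total = nrow(tma),
    n = nrow(d),
    n_unassessable = n_unassessable,
    intensity_counts = table(factor(d$consensus_intensity, levels = 0:3)),
    percent_median = median(d$percent_positive),
    percent_quartiles = quantile(d$percent_positive, c(0.25, 0.75),
                                 names = FALSE),
    n_positive = sum(d$consensus_intensity > 0),
    n_q_ge_150 = sum(q >= 150),
    q_bins = table(bin_q_score(q)),
    spearman = rho,
    n_discordant = n_discordant),
    class = "taa_staining_summary")
}

#' @export
print.taa_staining_summary <- function(x, ...) {
  cat(sprintf("Staining summary%s: %d assessable of %d cores\n",
              if (length(x$antigen)) paste0(" for ", paste(x$antigen, collapse = ", ")) else "",
              x$n, x$n_total))
  cat("  intensity 0/1/2/3: ",
      paste(as.integer(x$intensity_counts), collapse = " / "), "\n", sep = "")
  cat(sprintf("  percent positive: median %s (IQR %s-%s)\n",
              x$percent_median, x$percent_quartiles[1], x$percent_quartiles[2]))
  cat(sprintf("  positive cores: %d; Q-Score >= 150: %d\n",
              x$n_positive, x$n_q_ge_150))
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman rho(intensity, percent) = %.3f (p = %.3g)\n",
                x$spearman$rho, x$spearman$p.value))
  }
  if (!is.na(x$n_discordant)) {
    cat(sprintf("  rater-discordant cores: %d\n", x$n_discordant))
  }
  invisible(x)
}
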