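# Weighted multi-criterion antigen rubric: construction, normalization,
# per-candidate scoring and competition ranking.

NOT_APPLICABLE <- "not applicable"
UNKNOWN <- "unknown"

#' Construct a scoring rubric
#'
#' A rubric is an ordered set of criteria; each criterion holds ordered
#' subcriteria with point values, the first subcriterion carrying the
#' criterion maximum, and every criterion implicitly offers a
#' "not applicable" selection worth 0 points.
#'
#' @param criteria Data frame with columns `criterion`, `label`, `points`
#'   and optionally `definition`, one row per subcriterion in rubric
#'   order. A "not applicable" row is appended to any criterion lacking
#'   one.
#' @return An object of class `taa_rubric` (a validated data frame).
#' @seealso [default_rubric()] for the rubric shipped with the package.
#' @export
rubric <- function(criteria) {
  if (!is.data.frame(criteria) ||
      !all(c("criterion", "label", "points") %in% names(criteria))) {
    stop_taavet("rubric needs columns `criterion`, `label`, `points`")
  }
  criteria$criterion <- as.character(criteria$criterion)
  criteria$label <- as.character(criteria$label)
  criteria$points <- as.numeric(criteria$points)
  if (!"definition" %in% names(criteria)) criteria$definition <- ""
  criteria <- criteria[c("criterion", "label", "points", "definition")]
  # ensure each criterion has a zero-point "not applicable" selection
  out <- do.call(rbind, lapply(unique(criteria$criterion), function(cr) {
    block <- criteria[criteria$criterion == cr, , drop = FALSE]
    if (!NOT_APPLICABLE %in% block$label) {
      block <- rbind(block, data.frame(
        criterion = cr, label = NOT_APPLICABLE, points = 0,
        definition = "", stringsAsFactors = FALSE))
    }
    block
  }))
  rownames(out) <- NULL
  class(out) <- c("taa_rubric", "data.frame")
  validate_rubric(out)
  out
}

validate_rubric <- function(r) {
  if (anyNA(r$points) || any(r$points < 0)) {
    stop_taavet("rubric points must be non-negative numbers")
  }
  for (cr in unique(r$criterion)) {
    block <- r[r$criterion == cr, , drop = FALSE]
    if (anyDuplicated(block$label)) {
      stop_taavet("duplicate subcriterion label in criterion '", cr, "'")
    }
    if (block$points[1L] < max(block$points)) {
      stop_taavet("first subcriterion of '", cr,
                  "' must carry the criterion maximum")
    }
  }
  invisible(r)
}

#' Criterion maxima of a rubric
#'
#' @param r A `taa_rubric`.
#' @return Named numeric vector: maximum attainable points per criterion,
#'   in rubric order.
#' @export
criterion_maxima <- function(r) {
  stopifnot(inherits(r, "taa_rubric"))
  crs <- unique(r$criterion)
  vapply(crs, function(cr) max(r$points[r$criterion == cr]), numeric(1))
}

#' The default antigen-vetting rubric
#'
#' Seven weighted criteria for ranking tumor-associated antigens as
#' T cell-therapy targets, adapted from the Cheever prioritization
#' criteria by dropping the clinical-efficacy and cellular-location
#' criteria and renormalizing so the criterion maxima sum to exactly 10
#' points: Immunogenicity (2.5), Oncogenicity (2.25), Specificity (2.25),
#' Level of Expression (1), Tumor Stem Cell Expression (0.8), Patients
#' with TAA-positive Tumors (0.6) and Number of Epitopes (0.6).
#'
#' @return A `taa_rubric` with the canonical point values.
#' @examples
#' sum(criterion_maxima(default_rubric()))  # 10
#' @export
default_rubric <- function() {
  tbl <- rbind(
    c("Immunogenicity", "HLA-restricted T cell-immunity verifiable", 2.5,
      "Experimental generation of HLA-restricted TAA-specific T cells is possible"),
    c("Immunogenicity", "T cell-immunity detectable in humans", 2,
      "Spontaneous T cell immunity against the TAA detectable in humans"),
    c("Immunogenicity", "Immunogenicity in animal models", 0.28,
      "Immunogenic in animal models with similar antigen expression"),
    c("Immunogenicity", "Antibodies detectable in humans", 0.25,
      "Humoral response against the TAA observed in humans"),
    c("Oncogenicity", "oncogenic self-protein", 2.25,
      "TAA is associated with an oncogenic process"),
    c("Oncogenicity", "persistent viral AG", 0.77,
      "Persistently expressed viral antigen"),
    c("Oncogenicity", "Correlation with unfavorable outcome", 0.56,
      "Function unknown but expression correlates with unfavorable prognosis"),
    c("Oncogenicity", "tissue-differentiation, not oncogenic", 0.27,
      "Not oncogenic, associated with tissue differentiation"),
    c("Oncogenicity", "stromal-Expression", 0.27,
      "Expressed on tumor-related stroma, not on malignant cells"),
    c("Specificity", "absolute Specificity", 2.25,
      "Absolutely tumor-specific (e.g. mutated oncogene, viral protein)"),
    c("Specificity", "oncofetal AG", 1.22,
      "Fetal expression with no or little expression in healthy adult tissue (e.g. cancer-testis antigens)"),
    c("Specificity", "overexpressed in Tumors", 0.79,
      "Overexpressed in cancer but expressed in some healthy tissues"),
    c("Specificity", "abnormal posttranslational modifications", 0.52,
      "Normal-tissue protein carrying cancer-unique posttranslational changes"),
    c("Specificity", "Tissue specific (expendable tissue)", 0.47,
      "Tissue-specific expression in tissue expendable for survival"),
    c("Specificity", "Tumor stroma AG", 0.23,
      "Normal antigen expressed on tumor stroma"),
    c("Level of Expression", "high, all cancer cells", 1,
      "Highly expressed on all cancer cells"),
    c("Level of Expression", "high, most cancer cells", 0.37,
      "Highly expressed on most cancer cells"),
    c("Level of Expression", "lower, all cancer cells", 0.23,
      "Lower level of expression on all cancer cells"),
    c("Level of Expression", "lower, most cancer cells", 0.08,
      "Lower level of expression on most cancer cells"),
    c("Tumor Stem Cell Expression", "Stem Cell Expression, presumptive", 0.8,
      "Evidence for expression on tumor stem cells"),
    c("Tumor Stem Cell Expression", "No info about SCs, but on all stages", 0.53,
      "Present at all tumor stages, stem-cell expression unknown"),
    c("Tumor Stem Cell Expression", "No info about SCs, but most cancer cells", 0.16,
      "Expressed on most cancer cells, stem-cell expression unknown"),
    c("Patients with TAA-pos. Tumors", "many Patients, high level", 0.6,
      "High expression in a high fraction of patients"),
    c("Patients with TAA-pos. Tumors", "many Patients, lower level", 0.1,
      "Lower expression in a high fraction of patients"),
    c("Patients with TAA-pos. Tumors", "fewer Patients, high level", 0.07,
      "High expression in a lower fraction of patients"),
    c("No. of Epitopes", "longer Antigen", 0.6,
      "Longer antigen with multiple (potential) immunogenic epitopes"),
    c("No. of Epitopes", "short antigenic segment", 0.08,
      "Short antigenic segment with fewer epitopes, restricted MHC binding"))
  rubric(data.frame(criterion = tbl[, 1], label = tbl[, 2],
                    points = as.numeric(tbl[, 3]), definition = tbl[, 4],
                    stringsAsFactors = FALSE))
}

#' Rescale a rubric to a target total
#'
#' Multiplies every subcriterion's points by
#' `target_total / sum(criterion maxima)` and rounds to 2 decimals (half
#' away from zero). Useful for bringing a user-supplied rubric onto the
#' 10-point scale of the default rubric. Warns when rounding leaves the
#' post-scaling maxima more than 0.05 points away from the target.
#'
#' @param r A `taa_rubric`.
#' @param target_total Desired sum of criterion maxima (default 10).
#' @return The rescaled `taa_rubric`.
#' @export
normalize_rubric <- function(r, target_total = 10) {
  stopifnot(inherits(r, "taa_rubric"))
  assert_scalar_number(target_total, "target_total")
  if (target_total <= 0) stop_taavet("`target_total` must be positive")
  tot <- sum(criterion_maxima(r))
  if (tot <= 0) stop_taavet("rubric criterion maxima sum to zero; cannot normalize")
  r$points <- round_half_up(r$points * target_total / tot, 2)
  new_tot <- sum(criterion_maxima(r))
  if (abs(new_tot - target_total) > 0.05) {
    warning(sprintf("normalized rubric maxima sum to %.2f, not %.2f (rounding drift)",
                    new_tot, target_total), call. = FALSE)
  }
  validate_rubric(r)
  r
}

#' Build a candidate annotation
#'
#' An annotation records, for one candidate, the subcriterion selected in
#' each rubric criterion: a subcriterion label, `"not applicable"`, or
#' `"unknown"` when the literature holds no evidence for that criterion
#' (both score 0). A candidate whose literature is insufficient for any
#' evaluation is flagged `insufficient_data` and is never scored.
#'
#' @param id Candidate identifier.
#' @param selections Named character vector or list, names = criterion
#'   names, values = selected subcriterion labels. Criteria missing from
#'   `selections` default to `"unknown"`.
#' @param insufficient_data Flag marking the candidate unscorable.
#' @return A list of class `taa_annotation`.
#' @export
candidate_annotation <- function(id, selections = character(),
                                 insufficient_data = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_taavet("`id` must be a single non-empty string")
  }
  assert_flag(insufficient_data, "insufficient_data")
  selections <- unlist(selections)
  if (length(selections) && is.null(names(selections))) {
    stop_taavet("`selections` must be named by criterion")
  }
  structure(list(id = id, selections = selections,
                 insufficient_data = insufficient_data),
            class = "taa_annotation")
}

#' Score one candidate against a rubric
#'
#' Looks up the selected subcriterion's points in every criterion
#' (`"unknown"` and `"not applicable"` score 0) and sums them. The total
#' is reported to 2 decimals. Candidates flagged `insufficient_data`
#' come back unscored with an `NA` total.
#'
#' @param annotation A `taa_annotation` (see [candidate_annotation()]).
#' @param rubric A `taa_rubric` (default [default_rubric()]).
#' @return A list of class `taa_score`: `id`, `scored` flag, `total`
#'   (2-decimal), `points` (named per-criterion vector), `selections`.
#' @examples
#' ann <- candidate_annotation("LY6K", c(
#'   "Immunogenicity" = "HLA-restricted T cell-immunity verifiable",
#'   "Oncogenicity" = "oncogenic self-protein",
#'   "Specificity" = "oncofetal AG",
#'   "Level of Expression" = "high, most cancer cells",
#'   "Tumor Stem Cell Expression" = "Stem Cell Expression, presumptive",
#'   "Patients with TAA-pos. Tumors" = "many Patients, high level",
#'   "No. of Epitopes" = "longer Antigen"))
#' score_candidate(ann)$total  # 8.34
#' @export
score_candidate <- function(annotation, rubric = default_rubric()) {
  stopifnot(inherits(annotation, "taa_annotation"),
            inherits(rubric, "taa_rubric"))
  crs <- unique(rubric$criterion)
  extra <- setdiff(names(annotation$selections), crs)
  if (length(extra)) {
    stop_taavet("annotation for '", annotation$id,
                "' names criteria absent from the rubric: ",
                paste(extra, collapse = ", "))
  }
  if (annotation$insufficient_data) {
    return(structure(list(id = annotation$id, scored = FALSE,
                          total = NA_real_,
                          points = setNames(rep(NA_real_, length(crs)), crs),
                          selections = annotation$selections),
                     class = "taa_score"))
  }
  pts <- vapply(crs, function(cr) {
    idx <- match(cr, names(annotation$selections))
    if (is.na(idx)) return(0)          # missing criterion defaults to unknown
    sel <- annotation$selections[[idx]]
    if (is.na(sel) || identical(sel, UNKNOWN)) return(0)
    block <- rubric[rubric$criterion == cr, , drop = FALSE]
    hit <- match(sel, block$label)
    if (is.na(hit)) {
      stop_taavet("candidate '", annotation$id, "', criterion '", cr,
                  "': unknown subcriterion label '", sel, "'")
    }
    block$points[hit]
  }, numeric(1))
  structure(list(id = annotation$id, scored = TRUE,
                 total = round_half_up(sum(pts), 2),
                 points = pts, selections = annotation$selections),
            class = "taa_score")
}

#' @export
print.taa_score <- function(x, ...) {
  if (!x$scored) {
    cat(sprintf("%s: not scored (insufficient data)\n", x$id))
  } else {
    cat(sprintf("%s: %.2f points\n", x$id, x$total))
    for (cr in names(x$points)) {
      cat(sprintf("  %-32s %5.2f\n", cr, x$points[[cr]]))
    }
  }
  invisible(x)
}

#' Score a list of candidates
#'
#' @param annotations List of `taa_annotation` objects.
#' @inheritParams score_candidate
#' @return List of `taa_score` objects, in input order.
#' @export
score_candidates <- function(annotations, rubric = default_rubric()) {
  lapply(annotations, score_candidate, rubric = rubric)
}

#' Rank scored candidates
#'
#' Orders candidates by descending total using competition ranking: equal
#' totals share a rank and the next distinct total skips the tied
#' positions. Ties are displayed alphabetically by id. Unscored
#' candidates (insufficient data) are appended at the bottom with rank
#' `NA`.
#'
#' @param scored List of `taa_score` objects (see [score_candidate()]),
#'   or a data frame with columns `id` and `total`.
#' @param tiers Optional named vector mapping id to healthy-expression
#'   tier, carried into the output.
#' @return Data frame with columns `rank`, `id`, `total` (and `tier` when
#'   supplied), scored candidates first.
#' @export
rank_candidates <- function(scored, tiers = NULL) {
  if (is.data.frame(scored)) {
    df <- data.frame(id = as.character(scored$id),
                     total = as.numeric(scored$total),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      id = vapply(scored, `[[`, character(1), "id"),
      total = vapply(scored, `[[`, numeric(1), "total"),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$id)) stop_taavet("duplicate candidate ids in ranking input")
  is_scored <- !is.na(df$total)
  sc <- df[is_scored, , drop = FALSE]
  un <- df[!is_scored, , drop = FALSE]
  sc <- sc[order(-sc$total, sc$id), , drop = FALSE]
  sc$rank <- if (nrow(sc)) rank(-sc$total, ties.method = "min") else integer()
  un <- un[order(un$id), , drop = FALSE]
  un$rank <- rep(NA_integer_, nrow(un))
  out <- rbind(sc, un)[c("rank", "id", "total")]
  rownames(out) <- NULL
  if (!is.null(tiers)) out$tier <- unname(tiers[out$id])
  out
}
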