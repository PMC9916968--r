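# Three-step expression-based candidate selection:
# neoantigen exclusion -> healthy-tissue tiering -> tumor-expression gate.

EXCLUSION_REASONS <- c("neoantigen", "high_healthy_expression",
                       "below_tumor_cutoff", "no_tumor_data")

#' Default tumor-gate cutoffs by healthy-expression tier
#'
#' Low-tier candidates count as expressed in the tumor cohort when median
#' FPKM exceeds 0.5 or mean FPKM exceeds 1 (a detection threshold);
#' medium-tier candidates must clear the stricter 5 / 10 pair, because
#' their background expression in healthy tissue demands robust tumor
#' expression to justify the on-target/off-tumor risk.
#'
#' @return A named list with elements `low` and `medium`, each a numeric
#'   vector `c(median = , mean = )`.
#' @export
default_gate_cutoffs <- function() {
  list(low = c(median = 0.5, mean = 1),
       medium = c(median = 5, mean = 10))
}

#' Assign a healthy-tissue expression tier
#'
#' Tiers a gene by its maximum median TPM across healthy tissues: `low`
#' when every tissue is below `low_cutoff`, `medium` when every tissue is
#' below `medium_cutoff`, `excluded` otherwise. Comparisons are strict, so
#' a gene sitting exactly on a cutoff lands in the next (more expressed)
#' tier.
#'
#' @param profile_row Named numeric vector of median TPM per tissue for
#'   one gene (all values must be non-negative).
#' @param low_cutoff,medium_cutoff TPM cutoffs, `0 < low < medium`.
#'   Defaults 40 and 400 TPM.
#' @return One of `"low"`, `"medium"`, `"excluded"`.
#' @examples
#' assign_tier(c(liver = 5, testis = 390))
#' @export
assign_tier <- function(profile_row, low_cutoff = 40, medium_cutoff = 400) {
  check_tier_cutoffs(low_cutoff, medium_cutoff)
  if (length(profile_row) == 0L) {
    stop_taavet("tissue profile is empty: at least one tissue is required")
  }
  if (!is.numeric(profile_row) || anyNA(profile_row)) {
    stop_taavet("tissue TPM values must be numeric and non-missing")
  }
  if (any(profile_row < 0)) {
    stop_taavet("negative TPM value in tissue profile")
  }
  m <- max(profile_row)
  if (m < low_cutoff) "low" else if (m < medium_cutoff) "medium" else "excluded"
}

check_tier_cutoffs <- function(low_cutoff, medium_cutoff) {
  assert_scalar_number(low_cutoff, "low_cutoff")
  assert_scalar_number(medium_cutoff, "medium_cutoff")
  if (!(0 < low_cutoff && low_cutoff < medium_cutoff)) {
    stop_taavet("cutoffs must satisfy 0 < low_cutoff < medium_cutoff")
  }
}

#' Tier every gene of a healthy-tissue expression profile
#'
#' @param profile Numeric matrix of median TPM, genes in rows (rownames),
#'   tissues in columns.
#' @inheritParams assign_tier
#' @return Named character vector of tiers, one per gene.
#' @export
assign_tiers <- function(profile, low_cutoff = 40, medium_cutoff = 400) {
  profile <- as_healthy_profile(profile)
  vapply(seq_len(nrow(profile)), function(i) {
    assign_tier(profile[i, ], low_cutoff, medium_cutoff)
  }, character(1), USE.NAMES = FALSE) |>
    setNames(rownames(profile))
}

as_healthy_profile <- function(profile) {
  if (is.data.frame(profile)) {
    if ("gene" %in% names(profile)) {
      rn <- as.character(profile$gene)
      profile <- as.matrix(profile[setdiff(names(profile), "gene")])
      rownames(profile) <- rn
    } else {
      profile <- as.matrix(profile)
    }
  }
  if (!is.matrix(profile) || !is.numeric(profile)) {
    stop_taavet("healthy profile must be a numeric gene x tissue matrix")
  }
  if (is.null(rownames(profile)) || ncol(profile) < 1L) {
    stop_taavet("healthy profile needs gene rownames and >= 1 tissue column")
  }
  if (anyNA(profile) || any(profile < 0)) {
    stop_taavet("healthy profile values must be non-negative and non-missing")
  }
  profile
}

#' Summarize a tumor FPKM matrix per gene
#'
#' @param fpkm Numeric matrix, genes in rows (rownames), samples in
#'   columns; values are FPKM.
#' @return Data frame with columns `gene`, `median_fpkm`, `mean_fpkm`,
#'   `n_samples`.
#' @export
summarize_tumor_matrix <- function(fpkm) {
  if (!is.matrix(fpkm) || !is.numeric(fpkm) || is.null(rownames(fpkm))) {
    stop_taavet("tumor matrix must be a numeric gene x sample matrix with rownames")
  }
  if (ncol(fpkm) < 1L) stop_taavet("tumor matrix has no samples")
  if (anyNA(fpkm) || any(fpkm < 0)) {
    stop_taavet("FPKM values must be non-negative and non-missing")
  }
  data.frame(gene = rownames(fpkm),
             median_fpkm = apply(fpkm, 1, median),
             mean_fpkm = rowMeans(fpkm),
             n_samples = ncol(fpkm),
             row.names = NULL, stringsAsFactors = FALSE)
}

as_tumor_summary <- function(tumor) {
  if (is.matrix(tumor)) return(summarize_tumor_matrix(tumor))
  if (is.data.frame(tumor)) {
    need <- c("gene", "median_fpkm", "mean_fpkm")
    if (!all(need %in% names(tumor))) {
      stop_taavet("tumor summary needs columns gene, median_fpkm, mean_fpkm")
    }
    if (!"n_samples" %in% names(tumor)) tumor$n_samples <- NA_integer_
    if (anyNA(tumor$median_fpkm) || anyNA(tumor$mean_fpkm) ||
        any(tumor$median_fpkm < 0) || any(tumor$mean_fpkm < 0)) {
      stop_taavet("tumor FPKM summaries must be non-negative and non-missing")
    }
    return(tumor[c("gene", "median_fpkm", "mean_fpkm", "n_samples")])
  }
  stop_taavet("tumor data must be an FPKM matrix or a per-gene summary table")
}

#' Gate a candidate on tumor-cohort expression
#'
#' A candidate counts as expressed in the tumor cohort when its median
#' FPKM strictly exceeds the tier's median cutoff OR its mean FPKM
#' strictly exceeds the tier's mean cutoff.
#'
#' @param median_fpkm,mean_fpkm Per-gene tumor-cohort summaries (either
#'   may be `NA` together to signal absent data).
#' @param tier `"low"` or `"medium"` (candidates tiered `"excluded"` never
#'   reach the gate).
#' @param cutoffs Cutoff list as returned by [default_gate_cutoffs()].
#' @return One of `"retained"`, `"omitted"`, `"no_data"`.
#' @examples
#' tumor_gate(0.6, 0.9, "low")     # retained via the median clause
#' tumor_gate(4, 9, "medium")      # omitted
#' @export
tumor_gate <- function(median_fpkm, mean_fpkm, tier,
                       cutoffs = default_gate_cutoffs()) {
  if (!tier %in% c("low", "medium")) {
    stop_taavet("tumor_gate applies only to low- or medium-tier candidates, got tier = ",
                tier)
  }
  if (is.null(median_fpkm) || (length(median_fpkm) == 1L && is.na(median_fpkm))) {
    return("no_data")
  }
  assert_scalar_number(median_fpkm, "median_fpkm", lower = 0)
  assert_scalar_number(mean_fpkm, "mean_fpkm", lower = 0)
  cut <- cutoffs[[tier]]
  if (is.null(cut) || !all(c("median", "mean") %in% names(cut))) {
    stop_taavet("gate cutoffs must provide `median` and `mean` for tier ", tier)
  }
  if (median_fpkm > cut[["median"]] || mean_fpkm > cut[["mean"]]) {
    "retained"
  } else {
    "omitted"
  }
}

#' Run the three-step candidate selection cascade
#'
#' Stages run in order: (1) exclusion of neoantigens and virus-associated
#' antigens, (2) healthy-tissue tiering with exclusion of the high tier,
#' (3) tumor-cohort expression gating with tier-specific cutoffs.
#' Candidates missing from the healthy profile are an error (tiering is
#' mandatory); candidates missing from the tumor table are softly
#' excluded with reason `no_tumor_data`.
#'
#' @param candidates Candidate roster (see [antigen_candidates()]); a bare
#'   character vector is treated as all self-antigens.
#' @param healthy_profile Gene x tissue matrix of median TPM (or a data
#'   frame with a `gene` column).
#' @param tumor Gene x sample FPKM matrix, or a pre-summarized data frame
#'   with columns `gene`, `median_fpkm`, `mean_fpkm` (optionally
#'   `n_samples`).
#' @param low_cutoff,medium_cutoff Healthy-tissue TPM cutoffs (default
#'   40 / 400).
#' @param gate_cutoffs Tumor-gate cutoffs (see [default_gate_cutoffs()]).
#' @return A `taa_filter_report`: a list with `stages` (per-stage counts),
#'   `exclusions` (per-candidate reasons), `retained` (data frame of
#'   retained ids with their tier) and `tiers` (all tier assignments).
#' @export
run_cascade <- function(candidates, healthy_profile, tumor,
                        low_cutoff = 40, medium_cutoff = 400,
                        gate_cutoffs = default_gate_cutoffs()) {
  candidates <- as_taa_candidates(candidates)
  healthy_profile <- as_healthy_profile(healthy_profile)
  tumor <- as_tumor_summary(tumor)
  check_tier_cutoffs(low_cutoff, medium_cutoff)

  exclusions <- data.frame(id = character(), stage = character(),
                           reason = character(), stringsAsFactors = FALSE)
  stage <- function(name, n_in, n_excluded) {
    data.frame(stage = name, n_in = n_in, n_excluded = n_excluded,
               n_out = n_in - n_excluded, stringsAsFactors = FALSE)
  }

  # stage 1: antigen-class exclusion
  s1 <- exclude_neoantigens(candidates)
  if (nrow(s1$excluded)) {
    exclusions <- rbind(exclusions, data.frame(
      id = s1$excluded$id, stage = "neoantigen_exclusion",
      reason = "neoantigen", stringsAsFactors = FALSE))
  }
  stages <- stage("neoantigen_exclusion", nrow(candidates), s1$n_excluded)
  ids <- s1$retained$id

  # stage 2: healthy-tissue tiering
  missing_healthy <- setdiff(ids, rownames(healthy_profile))
  if (length(missing_healthy)) {
    stop_taavet("candidate(s) absent from the healthy-tissue profile: ",
                paste(head(missing_healthy, 5), collapse = ", "),
                if (length(missing_healthy) > 5) ", ...")
  }
  tiers <- assign_tiers(healthy_profile[ids, , drop = FALSE],
                        low_cutoff, medium_cutoff)
  high <- names(tiers)[tiers == "excluded"]
  if (length(high)) {
    exclusions <- rbind(exclusions, data.frame(
      id = high, stage = "healthy_tissue_tiering",
      reason = "high_healthy_expression", stringsAsFactors = FALSE))
  }
  stages <- rbind(stages,
                  stage("healthy_tissue_tiering", length(ids), length(high)))
  ids <- names(tiers)[tiers != "excluded"]

  # stage 3: tumor-expression gate
  tum <- tumor[match(ids, tumor$gene), , drop = FALSE]
  status <- vapply(seq_along(ids), function(i) {
    if (is.na(tum$gene[i])) return("no_data")
    tumor_gate(tum$median_fpkm[i], tum$mean_fpkm[i], tiers[[ids[i]]],
               gate_cutoffs)
  }, character(1))
  dropped <- status != "retained"
  if (any(dropped)) {
    exclusions <- rbind(exclusions, data.frame(
      id = ids[dropped], stage = "tumor_expression_gate",
      reason = ifelse(status[dropped] == "no_data",
                      "no_tumor_data", "below_tumor_cutoff"),
      stringsAsFactors = FALSE))
  }
  stages <- rbind(stages,
                  stage("tumor_expression_gate", length(ids), sum(dropped)))

  retained <- data.frame(id = ids[!dropped],
                         tier = unname(tiers[ids[!dropped]]),
                         stringsAsFactors = FALSE)
  report <- structure(
    list(stages = stages, exclusions = exclusions, retained = retained,
         tiers = tiers,
         cutoffs = list(low_tpm = low_cutoff, medium_tpm = medium_cutoff,
                        gate = gate_cutoffs)),
    class = "taa_filter_report")
  validate_filter_report(report)
  report
}

validate_filter_report <- function(report) {
  st <- report$stages
  if (!all(st$n_in == st$n_excluded + st$n_out)) {
    stop_taavet("filter report violates count conservation (n_in != n_excluded + n_out)")
  }
  if (nrow(st) > 1L && !all(st$n_in[-1L] == st$n_out[-nrow(st)])) {
    stop_taavet("filter report stages are not chained (stage k+1 n_in != stage k n_out)")
  }
  if (anyDuplicated(report$exclusions$id)) {
    stop_taavet("a candidate carries more than one exclusion reason")
  }
  if (!all(report$exclusions$reason %in% EXCLUSION_REASONS)) {
    stop_taavet("unknown exclusion reason in filter report")
  }
  invisible(report)
}

#' @export
print.taa_filter_report <- function(x, ...) {
  cat("Candidate selection cascade\n")
  for (i in seq_len(nrow(x$stages))) {
    s <- x$stages[i, ]
    cat(sprintf("  %-24s in %4d  excluded %4d  out %4d\n",
                s$stage, s$n_in, s$n_excluded, s$n_out))
  }
  if (nrow(x$retained)) {
    tt <- table(factor(x$retained$tier, levels = c("low", "medium")))
    cat(sprintf("Retained: %d (low %d, medium %d)\n",
                nrow(x$retained), tt[["low"]], tt[["medium"]]))
  } else {
    cat("Retained: 0\n")
  }
  if (nrow(x$exclusions)) {
    rt <- table(x$exclusions$reason)
    cat("Exclusion reasons:",
        paste(sprintf("%s = %d", names(rt), rt), collapse = ", "), "\n")
  }
  invisible(x)
}
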