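# Synthetic-data generators with planted ground truth. Every generator
# takes an explicit seed, restores the caller's RNG state, and returns
# its truth alongside the data so recovery tests can compare pipeline
# output to the plant afterwards.

with_seed <- function(seed, code) {
  assert_scalar_number(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

default_tissues <- function() {
  c("adipose", "adrenal_gland", "brain", "breast", "colon", "heart",
    "liver", "lung", "ovary", "pancreas", "skin", "testis")
}

#' Simulate a healthy-tissue expression profile with planted tiers
#'
#' Generates a gene x tissue table of median TPM in which each gene's
#' maximum tissue value is planted strictly inside its tier band:
#' low < 40 TPM, medium in [40, 400), high >= 400 TPM. One tissue
#' carries the maximum; the remaining tissues scatter below it on the
#' log scale with spread `noise_sd`.
#'
#' @param n_genes_per_tier Named counts `c(low = , medium = , high = )`.
#' @param tissues Character vector of tissue names (>= 1).
#' @param noise_sd Log-scale spread of the non-maximal tissues (>= 0).
#' @param low_cutoff,medium_cutoff Tier cutoffs the plant respects.
#' @param seed Integer seed.
#' @return List with `profile` (gene x tissue matrix) and `truth`
#'   (list with `tiers`, a named vector, and `seed`).
#' @export
simulate_healthy_expression <- function(n_genes_per_tier = c(low = 60, medium = 47, high = 60),
                                        tissues = default_tissues(),
                                        noise_sd = 0.8,
                                        low_cutoff = 40, medium_cutoff = 400,
                                        seed = 1) {
  stopifnot(all(c("low", "medium", "high") %in% names(n_genes_per_tier)))
  if (any(n_genes_per_tier < 0)) stop_taavet("tier counts must be >= 0")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_tier_cutoffs(low_cutoff, medium_cutoff)
  if (length(tissues) < 1L) stop_taavet("at least one tissue is required")

  with_seed(seed, {
    tiers <- rep(c("low", "medium", "high"),
                 times = n_genes_per_tier[c("low", "medium", "high")])
    n <- length(tiers)
    genes <- sprintf("TAA%03d", seq_len(n))
    # strict interior of each band, log-uniform
    band <- list(low = c(0.2, 0.96 * low_cutoff),
                 medium = c(1.04 * low_cutoff, 0.96 * medium_cutoff),
                 high = c(1.04 * medium_cutoff, 10 * medium_cutoff))
    profile <- t(vapply(seq_len(n), function(i) {
      b <- band[[tiers[i]]]
      mx <- exp(runif(1, log(b[1]), log(b[2])))
      vals <- mx * exp(-abs(rnorm(length(tissues), 0, noise_sd)) - 0.05)
      vals[sample.int(length(tissues), 1)] <- mx
      vals
    }, numeric(length(tissues))))
    dimnames(profile) <- list(genes, tissues)
    list(profile = profile,
         truth = list(tiers = setNames(tiers, genes), seed = seed))
  })
}

#' Simulate a tumor FPKM cohort with planted gate status
#'
#' Draws log-normal per-sample FPKM for each gene so that genes planted
#' as expressed clear their tier's gate cutoffs (median or mean clause)
#' and silent genes fall below both; rows are deterministically rescaled
#' if a random draw lands on the wrong side. A configurable number of
#' genes per tier is omitted from the matrix entirely, emulating
#' candidates without tumor expression data.
#'
#' @param tiers Named character vector gene -> tier (as produced by
#'   [simulate_healthy_expression()]); only low- and medium-tier genes
#'   are gated, high-tier genes receive arbitrary expression.
#' @param n_samples Number of tumor samples (columns), default 373.
#' @param n_expressed_by_tier Named counts of genes planted as expressed
#'   (gate-retained) in the low and medium tiers.
#' @param n_missing_by_tier Named counts of genes omitted from the
#'   matrix per tier (planted `no_data`); drawn from the silent pool.
#' @param gate_cutoffs Gate cutoffs the plant respects.
#' @param seed Integer seed.
#' @return List with `fpkm` (gene x sample matrix) and `truth` (list
#'   with `gate_status`, a named vector over low/medium genes with
#'   values retained/omitted/no_data, `n_samples`, `seed`).
#' @export
simulate_tumor_cohort <- function(tiers, n_samples = 373,
                                  n_expressed_by_tier = c(low = 21, medium = 17),
                                  n_missing_by_tier = c(low = 2, medium = 1),
                                  gate_cutoffs = default_gate_cutoffs(),
                                  seed = 1) {
  if (is.null(names(tiers))) stop_taavet("`tiers` must be named by gene")
  if (n_samples < 2) stop_taavet("`n_samples` must be at least 2")

  with_seed(seed, {
    genes <- names(tiers)
    status <- setNames(rep(NA_character_, length(genes)), genes)
    # log-normal location per tier and planted status; silent genes sit
    # well below both cutoffs, expressed genes well above the median one
    loc <- list(
      low = c(expressed = log(4), silent = log(0.05)),
      medium = c(expressed = log(25), silent = log(1)))
    for (tier in c("low", "medium")) {
      pool <- genes[tiers == tier]
      n_exp <- n_expressed_by_tier[[tier]]
      n_mis <- n_missing_by_tier[[tier]]
      if (n_exp + n_mis > length(pool)) {
        stop_taavet("tier '", tier, "': expressed + missing exceeds pool size")
      }
      expressed <- sample(pool, n_exp)
      silent <- setdiff(pool, expressed)
      missing <- sample(silent, n_mis)
      status[expressed] <- "retained"
      status[setdiff(silent, missing)] <- "omitted"
      status[missing] <- "no_data"
    }
    present <- genes[is.na(status) | status != "no_data"]
    fpkm <- t(vapply(present, function(g) {
      tier <- tiers[[g]]
      mu <- if (is.na(status[[g]])) log(50) else
        loc[[tier]][[if (status[[g]] == "retained") "expressed" else "silent"]]
      rlnorm_row(n_samples, mu, 0.4)
    }, numeric(n_samples)))
    colnames(fpkm) <- sprintf("S%03d", seq_len(n_samples))

    # enforce the planted gate status exactly (random draws near a
    # cutoff are rescaled multiplicatively)
    for (g in present) {
      st <- status[[g]]
      if (is.na(st)) next
      cut <- gate_cutoffs[[tiers[[g]]]]
      row <- fpkm[g, ]
      if (st == "retained") {
        if (!(median(row) > cut[["median"]] || mean(row) > cut[["mean"]])) {
          fpkm[g, ] <- row * 2 * cut[["median"]] / median(row)
        }
      } else {
        while (median(row) > cut[["median"]] || mean(row) > cut[["mean"]]) {
          row <- row / 2
        }
        fpkm[g, ] <- row
      }
    }
    list(fpkm = fpkm,
         truth = list(gate_status = status[!is.na(status)],
                      n_samples = n_samples, seed = seed))
  })
}

rlnorm_row <- function(n, meanlog, sdlog) {
  exp(rnorm(n, meanlog, sdlog))
}

#' Simulate rubric annotations with independently computed totals
#'
#' Draws one valid subcriterion selection per criterion for each
#' candidate (including `"unknown"` and `"not applicable"`, which score
#' zero) and records the expected total via a summation that is
#' independent of [score_candidate()]. A configurable number of
#' candidates is flagged `insufficient_data`.
#'
#' @param n_candidates Number of candidates.
#' @param rubric Rubric to annotate against.
#' @param n_insufficient Number of candidates flagged unscorable.
#' @param unknown_prob Probability of drawing `"unknown"` per criterion.
#' @param seed Integer seed.
#' @return List with `annotations` (list of `taa_annotation`) and
#'   `truth` (data frame `id`, `expected_total` with `NA` for the
#'   insufficient-data candidates, plus `seed`).
#' @export
simulate_annotations <- function(n_candidates, rubric = default_rubric(),
                                 n_insufficient = 0, unknown_prob = 0.15,
                                 seed = 1) {
  stopifnot(inherits(rubric, "taa_rubric"))
  if (n_insufficient > n_candidates) {
    stop_taavet("`n_insufficient` cannot exceed `n_candidates`")
  }
  with_seed(seed, {
    ids <- sprintf("CAND%03d", seq_len(n_candidates))
    insufficient <- ids %in% sample(ids, n_insufficient)
    crs <- unique(rubric$criterion)
    anns <- vector("list", n_candidates)
    expected <- numeric(n_candidates)
    for (i in seq_len(n_candidates)) {
      sel <- character(0)
      total <- 0
      for (cr in crs) {
        block <- rubric[rubric$criterion == cr, , drop = FALSE]
        if (runif(1) < unknown_prob) {
          sel[cr] <- UNKNOWN
        } else {
          j <- sample.int(nrow(block), 1)
          sel[cr] <- block$label[j]
          total <- total + block$points[j]   # generator-side double sum
        }
      }
      anns[[i]] <- candidate_annotation(ids[i], sel,
                                        insufficient_data = insufficient[i])
      expected[i] <- if (insufficient[i]) NA_real_ else round_half_up(total, 2)
    }
    list(annotations = anns,
         truth = list(expected = data.frame(id = ids,
                                            expected_total = expected,
                                            stringsAsFactors = FALSE),
                      seed = seed))
  })
}

#' Worked-example annotations for the top-ranked cancer-testis antigens
#'
#' Three named annotation fixtures reproducing the scoring pattern of
#' the highest-ranked low-tier candidates: maximum points in every
#' criterion except Specificity ("oncofetal AG", the cancer-testis
#' pattern) and Level of Expression ("high, most cancer cells"), with
#' the Tumor Stem Cell Expression tier stepping down across the three
#' fixtures. Against [default_rubric()] they score 8.34, 8.07 and 7.70
#' points.
#'
#' @return Named list of three `taa_annotation` objects (`LY6K`,
#'   `CT45`, `MAGEA4`).
#' @export
worked_example_annotations <- function() {
  base <- c(
    "Immunogenicity" = "HLA-restricted T cell-immunity verifiable",
    "Oncogenicity" = "oncogenic self-protein",
    "Specificity" = "oncofetal AG",
    "Level of Expression" = "high, most cancer cells",
    "Tumor Stem Cell Expression" = "Stem Cell Expression, presumptive",
    "Patients with TAA-pos. Tumors" = "many Patients, high level",
    "No. of Epitopes" = "longer Antigen")
  mid <- base
  mid[["Tumor Stem Cell Expression"]] <- "No info about SCs, but on all stages"
  low <- base
  low[["Tumor Stem Cell Expression"]] <- "No info about SCs, but most cancer cells"
  list(LY6K = candidate_annotation("LY6K", base),
       CT45 = candidate_annotation("CT45", mid),
       MAGEA4 = candidate_annotation("MAGEA4", low))
}

#' Simulate a TMA cohort with planted clinical effects
#'
#' Emulates a serous ovarian-cancer tissue-microarray cohort: staining
#' intensity drawn categorically, percent-positive cells correlated
#' with intensity, progression-free survival exponential under
#' proportional hazards with the planted hazard ratio between the
#' high (moderate/strong) and low (negative/weak) intensity groups,
#' platinum response drawn with the planted odds ratio between the
#' Q-Score >= 150 group and the rest, and clinical covariates drawn to
#' approximate the marginal frequencies of a typical advanced serous
#' cohort (about 90% grade 3, 79% FIGO III, 88% peritoneal
#' carcinomatosis, 26% residual tumor, median age about 60 years).
#'
#' @param n_samples Number of cores (default 58).
#' @param antigen Antigen label for all cores.
#' @param hazard_ratio_high_vs_low Planted PFS hazard ratio of the
#'   high-intensity group relative to the low-intensity group (> 0;
#'   values below 1 mean high staining is protective).
#' @param platinum_or Planted odds ratio of platinum response for
#'   Q-Score >= 150 versus below.
#' @param censoring_rate Approximate fraction of PFS observations
#'   censored (in `[0, 1)`).
#' @param n_unassessable Number of cores flagged unassessable.
#' @param rater_discordance Probability that the second pathologist's
#'   intensity differs from the consensus by one level.
#' @param median_pfs_low Baseline median PFS (months) in the
#'   low-intensity group.
#' @param seed Integer seed.
#' @return List with `tma` (data frame in the TMA schema, see
#'   [read_tma()]) and `truth` (the planted parameters plus the
#'   per-core intensity group and Q-bin).
#' @export
simulate_tma_cohort <- function(n_samples = 58, antigen = "CT45",
                                hazard_ratio_high_vs_low = 1,
                                platinum_or = 1,
                                censoring_rate = 0.2,
                                n_unassessable = 0,
                                rater_discordance = 0.1,
                                median_pfs_low = 15,
                                seed = 1) {
  if (hazard_ratio_high_vs_low <= 0) stop_taavet("hazard ratio must be > 0")
  assert_scalar_number(censoring_rate, "censoring_rate", lower = 0, upper = 1 - 1e-9)
  if (n_unassessable >= n_samples) {
    stop_taavet("`n_unassessable` must leave at least one assessable core")
  }
  with_seed(seed, {
    intensity <- sample(0:3, n_samples, replace = TRUE,
                        prob = c(0.28, 0.22, 0.30, 0.20))
    percent <- ifelse(intensity == 0, 0L,
                      as.integer(pmin(100, pmax(1, round(
                        30 * intensity + rnorm(n_samples, 0, 15))))))
    shift <- sample(c(-1L, 1L), n_samples, replace = TRUE)
    r2 <- ifelse(runif(n_samples) < rater_discordance,
                 pmin(3L, pmax(0L, intensity + shift)), intensity)
    grp <- dichotomize_intensity(intensity)
    qbin_high <- q_score(intensity, percent) >= 150

    rate_low <- log(2) / median_pfs_low
    rate <- rate_low * ifelse(grp == "high", hazard_ratio_high_vs_low, 1)
    t_event <- rexp(n_samples, rate)
    if (censoring_rate > 0) {
      t_cens <- rexp(n_samples, rate_low * censoring_rate / (1 - censoring_rate))
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    pfs <- round(pmin(t_event, t_cens), 2)
    pfs_event <- t_event <= t_cens

    p_resp <- plogis(qlogis(0.5) + log(platinum_or) * qbin_high)
    platinum <- ifelse(runif(n_samples) < 0.02, "unknown",
                       ifelse(runif(n_samples) < p_resp, "yes", "no"))

    os_extra <- rexp(n_samples, log(2) / 20)
    tma <- data.frame(
      sample_id = sprintf("TMA%03d", seq_len(n_samples)),
      antigen = antigen,
      intensity_r1 = intensity,
      intensity_r2 = r2,
      consensus_intensity = intensity,
      percent_positive = percent,
      assessable = !(seq_len(n_samples) %in% sample.int(n_samples, n_unassessable)),
      grade = sample(c("2", "3"), n_samples, TRUE, prob = c(0.10, 0.90)),
      figo_stage = sample(c("II", "III", "IV"), n_samples, TRUE,
                          prob = c(0.05, 0.79, 0.16)),
      t_stage = sample(c("1", "2", "3"), n_samples, TRUE,
                       prob = c(0.15, 0.25, 0.60)),
      perit_carc = runif(n_samples) < 0.88,
      residual_tumor = runif(n_samples) < 0.26,
      platinum_response = platinum,
      age = round(rnorm(n_samples, 60.5, 10)),
      pfs_months = pfs,
      pfs_event = pfs_event,
      os_months = round(pfs + os_extra, 2),
      os_event = pfs_event & runif(n_samples) < 0.8,
      ttp_months = pfs,
      ttp_event = pfs_event,
      stringsAsFactors = FALSE)
    list(tma = tma,
         truth = list(hazard_ratio = hazard_ratio_high_vs_low,
                      platinum_or = platinum_or,
                      intensity_group = as.character(grp),
                      q_ge_150 = qbin_high, seed = seed))
  })
}

#' Simulate a molecular-subtype expression dataset with planted shifts
#'
#' Null genes are exchangeable across the four clusters (Gaussian
#' intensities around a common baseline); planted genes are shifted by
#' a multiple of the pooled standard deviation in one named cluster.
#' With `probes_per_gene > 1`, each gene gets one dominant high-mean
#' probe so probe-set selection is exercised.
#'
#' @param n_per_cluster Samples per cluster (c1, c2, c4, c5).
#' @param n_genes Total number of genes.
#' @param planted Data frame with columns `gene`, `cluster`, `shift`
#'   (shift in pooled-SD units), or `NULL` for a pure null dataset.
#'   Gene names must match the generated `GENE###` ids.
#' @param probes_per_gene Probes measuring each gene (>= 1).
#' @param baseline_mean,sd Normal baseline and SD of intensities.
#' @param seed Integer seed.
#' @return List with `dataset` (a `taa_subtype_dataset`) and `truth`
#'   (the planted table, dominant probe per gene, and seed).
#' @export
simulate_subtype_dataset <- function(n_per_cluster = 20, n_genes = 50,
                                     planted = NULL, probes_per_gene = 1,
                                     baseline_mean = 8, sd = 1, seed = 1) {
  if (n_per_cluster < 2) stop_taavet("`n_per_cluster` must be at least 2")
  if (probes_per_gene < 1) stop_taavet("`probes_per_gene` must be >= 1")
  with_seed(seed, {
    clusters <- rep(SUBTYPE_CLUSTERS, each = n_per_cluster)
    samples <- sprintf("GSM%03d", seq_along(clusters))
    names(clusters) <- samples
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    probe_ids <- unlist(lapply(genes, function(g) {
      paste0(sub("GENE", "", g), sprintf("_%02d_at", seq_len(probes_per_gene)))
    }))
    probe_map <- setNames(rep(genes, each = probes_per_gene), probe_ids)
    # probe 1 of each gene is dominant; extra probes sit 2 SD lower
    expr <- matrix(0, nrow = length(probe_ids), ncol = length(samples),
                   dimnames = list(probe_ids, samples))
    for (i in seq_along(probe_ids)) {
      k <- (i - 1L) %% probes_per_gene  # 0 = dominant probe
      expr[i, ] <- rnorm(length(samples), baseline_mean - 2 * sd * k, sd)
    }
    if (!is.null(planted) && nrow(planted)) {
      if (!all(planted$gene %in% genes)) {
        stop_taavet("planted genes must be among the generated gene ids")
      }
      if (!all(planted$cluster %in% SUBTYPE_CLUSTERS)) {
        stop_taavet("planted clusters must be among c1, c2, c4, c5")
      }
      for (j in seq_len(nrow(planted))) {
        rows <- which(probe_map == planted$gene[j])
        cols <- which(clusters == planted$cluster[j])
        expr[rows, cols] <- expr[rows, cols] + planted$shift[j] * sd
      }
    }
    expr <- pmax(expr, 0)
    dominant <- setNames(probe_ids[seq(1, length(probe_ids),
                                       by = probes_per_gene)], genes)
    list(dataset = subtype_dataset(expr, clusters, probe_map),
         truth = list(planted = planted, dominant_probe = dominant,
                      seed = seed))
  })
}
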