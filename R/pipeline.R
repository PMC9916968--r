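# End-to-end pipeline driver: configuration, input loading, stage
# orchestration and report writing.

#' Build a pipeline configuration
#'
#' Collects input file paths and tunable cutoffs for an end-to-end run.
#' Unknown arguments are rejected; every numeric cutoff is validated
#' and ordered. Any analysis input left `NULL` simply disables the
#' corresponding pipeline stage.
#'
#' @param candidates_path,healthy_path,tumor_path Candidate roster,
#'   healthy-tissue profile and tumor expression table (the filter
#'   cascade needs all three).
#' @param annotations_path Rubric annotations (enables scoring/ranking).
#' @param rubric_path Rubric TSV, or `"default"` for the built-in one.
#' @param tma_path TMA CSV (enables IHC summaries and the clinical
#'   association battery).
#' @param subtype_matrix_path,subtype_clusters_path,subtype_probe_map_path
#'   Subtype dataset files (enable the differential-expression scan).
#' @param low_tpm,medium_tpm Healthy-tissue tier cutoffs (TPM).
#' @param gate_low_median,gate_low_mean,gate_medium_median,gate_medium_mean
#'   Tumor-gate FPKM cutoffs by tier.
#' @param seed Integer seed recorded in the run manifest.
#' @param out_dir Output directory for [write_report()].
#' @return A list of class `taa_pipeline_config`.
#' @export
pipeline_config <- function(candidates_path = NULL, healthy_path = NULL,
                            tumor_path = NULL, annotations_path = NULL,
                            rubric_path = "default", tma_path = NULL,
                            subtype_matrix_path = NULL,
                            subtype_clusters_path = NULL,
                            subtype_probe_map_path = NULL,
                            low_tpm = 40, medium_tpm = 400,
                            gate_low_median = 0.5, gate_low_mean = 1,
                            gate_medium_median = 5, gate_medium_mean = 10,
                            seed = 1, out_dir = NULL) {
  check_tier_cutoffs(low_tpm, medium_tpm)
  for (v in c(gate_low_median, gate_low_mean, gate_medium_median,
              gate_medium_mean)) {
    assert_scalar_number(v, "gate cutoff", lower = 0)
  }
  structure(list(
    candidates_path = candidates_path, healthy_path = healthy_path,
    tumor_path = tumor_path, annotations_path = annotations_path,
    rubric_path = rubric_path, tma_path = tma_path,
    subtype_matrix_path = subtype_matrix_path,
    subtype_clusters_path = subtype_clusters_path,
    subtype_probe_map_path = subtype_probe_map_path,
    low_tpm = low_tpm, medium_tpm = medium_tpm,
    gate_cutoffs = list(low = c(median = gate_low_median,
                                mean = gate_low_mean),
                        medium = c(median = gate_medium_median,
                                   mean = gate_medium_mean)),
    seed = seed, out_dir = out_dir),
    class = "taa_pipeline_config")
}

#' Load and validate every configured input
#'
#' @param config A `taa_pipeline_config`.
#' @return List of typed inputs (`candidates`, `healthy`, `tumor`,
#'   `annotations`, `rubric`, `tma`, `subtype`), with `NULL` for
#'   unconfigured stages.
#' @export
read_tables <- function(config) {
  stopifnot(inherits(config, "taa_pipeline_config"))
  inputs <- list(candidates = NULL, healthy = NULL, tumor = NULL,
                 annotations = NULL, rubric = NULL, tma = NULL,
                 subtype = NULL)
  if (!is.null(config$candidates_path)) {
    inputs$candidates <- read_candidates(config$candidates_path)
  }
  if (!is.null(config$healthy_path)) {
    inputs$healthy <- read_healthy_profile(config$healthy_path)
  }
  if (!is.null(config$tumor_path)) {
    inputs$tumor <- read_tumor_table(config$tumor_path)
  }
  if (!is.null(config$annotations_path)) {
    inputs$annotations <- read_annotations(config$annotations_path)
  }
  inputs$rubric <- if (identical(config$rubric_path, "default")) {
    default_rubric()
  } else if (!is.null(config$rubric_path)) {
    read_rubric(config$rubric_path)
  }
  if (!is.null(config$tma_path)) inputs$tma <- read_tma(config$tma_path)
  if (!is.null(config$subtype_matrix_path)) {
    inputs$subtype <- read_subtype_dataset(config$subtype_matrix_path,
                                           config$subtype_clusters_path,
                                           config$subtype_probe_map_path)
  }
  inputs
}

#' Run the full antigen-vetting pipeline
#'
#' Executes, in order, every stage its inputs enable: the expression
#' filter cascade, rubric scoring and ranking, IHC staining summaries
#' with the clinical association battery, and the molecular-subtype
#' differential-expression scan. Each stage logs one line (input and
#' output counts) via `message()`.
#'
#' @param config A `taa_pipeline_config`.
#' @return List of class `taa_report_bundle` with elements
#'   `filter_report`, `ranking`, `ihc_summaries`, `associations`,
#'   `subtype_scan` (stages without inputs are `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  inputs <- read_tables(config)
  bundle <- list(filter_report = NULL, ranking = NULL,
                 ihc_summaries = NULL, associations = NULL,
                 subtype_scan = NULL)

  if (!is.null(inputs$candidates) && !is.null(inputs$healthy) &&
      !is.null(inputs$tumor)) {
    bundle$filter_report <- run_cascade(
      inputs$candidates, inputs$healthy, inputs$tumor,
      low_cutoff = config$low_tpm, medium_cutoff = config$medium_tpm,
      gate_cutoffs = config$gate_cutoffs)
    st <- bundle$filter_report$stages
    message(sprintf("[filter] %d candidates in -> %d retained",
                    st$n_in[1], st$n_out[nrow(st)]))
  }

  if (!is.null(inputs$annotations)) {
    scored <- score_candidates(inputs$annotations, inputs$rubric)
    tiers <- NULL
    if (!is.null(bundle$filter_report)) {
      tiers <- setNames(bundle$filter_report$retained$tier,
                        bundle$filter_report$retained$id)
    }
    bundle$ranking <- rank_candidates(scored, tiers = tiers)
    message(sprintf("[score] %d candidates scored, %d unscored",
                    sum(!is.na(bundle$ranking$total)),
                    sum(is.na(bundle$ranking$total))))
  }

  if (!is.null(inputs$tma)) {
    antigens <- unique(inputs$tma$antigen)
    bundle$ihc_summaries <- lapply(setNames(antigens, antigens), function(a) {
      staining_summary(inputs$tma, antigen = a)
    })
    bundle$associations <- do.call(rbind, lapply(antigens, function(a) {
      tma_association_battery(inputs$tma, antigen = a)
    }))
    message(sprintf("[ihc] %d antigen(s), %d association tests",
                    length(antigens), nrow(bundle$associations)))
  }

  if (!is.null(inputs$subtype)) {
    bundle$subtype_scan <- subtype_de_scan(inputs$subtype)
    message(sprintf("[subtype] %d genes tested",
                    nrow(bundle$subtype_scan$table)))
  }

  bundle$manifest <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("taavet")),
    schema_version = "1.0")
  structure(bundle, class = "taa_report_bundle")
}

#' Write a report bundle to disk
#'
#' `json` writes one machine-readable `report.json` (stable, versioned
#' schema; no timestamps, so identical runs produce byte-identical
#' files). `text` writes `report.txt` with the stage-count flow of the
#' filter cascade and the top-ranked candidates.
#'
#' @param bundle A `taa_report_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @param format `"json"`, `"text"`, or both.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(bundle, out_dir, format = c("json", "text")) {
  stopifnot(inherits(bundle, "taa_report_bundle"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_taavet("cannot create output directory: ", out_dir)
  }
  paths <- character()
  if ("json" %in% format) {
    p <- file.path(out_dir, "report.json")
    payload <- list(
      schema_version = bundle$manifest$schema_version,
      manifest = bundle$manifest,
      filter = if (!is.null(bundle$filter_report)) {
        list(stages = bundle$filter_report$stages,
             exclusions = bundle$filter_report$exclusions,
             retained = bundle$filter_report$retained)
      },
      ranking = bundle$ranking,
      ihc = if (!is.null(bundle$ihc_summaries)) {
        lapply(bundle$ihc_summaries, function(s) {
          list(n = s$n, n_unassessable = s$n_unassessable,
               intensity_counts = as.list(s$intensity_counts),
               percent_median = s$percent_median,
               n_q_ge_150 = s$n_q_ge_150,
               spearman = s$spearman, n_discordant = s$n_discordant)
        })
      },
      associations = bundle$associations,
      subtype = if (!is.null(bundle$subtype_scan)) {
        list(table = bundle$subtype_scan$table,
             posthoc = bundle$subtype_scan$posthoc)
      })
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
    paths <- c(paths, p)
  }
  if ("text" %in% format) {
    p <- file.path(out_dir, "report.txt")
    con <- file(p, open = "wt")
    on.exit(close(con), add = TRUE)
    sink(con)
    tryCatch({
      if (!is.null(bundle$filter_report)) print(bundle$filter_report)
      if (!is.null(bundle$ranking)) {
        cat("\nTop-ranked candidates\n")
        print(head(bundle$ranking, 10), row.names = FALSE)
      }
      if (!is.null(bundle$ihc_summaries)) {
        cat("\n")
        for (s in bundle$ihc_summaries) print(s)
      }
      if (!is.null(bundle$subtype_scan)) {
        cat("\n")
        print(bundle$subtype_scan)
      }
    }, finally = sink())
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Simulate a complete study directory
#'
#' Writes every input the pipeline consumes — candidate roster,
#' healthy-tissue profile, tumor cohort, annotations, TMA table and
#' subtype dataset — into `out_dir`, together with a `truth.json`
#' recording the planted ground truth. The default parameters reproduce
#' the marginal structure of the motivating study: 237 candidates with
#' 70 neoantigens, a 60/47/60 low/medium/high tier split, 3 candidates
#' without tumor data, 21 + 17 gate survivors, and a 58-core TMA.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; every generator derives from it.
#' @param n_neoantigens Number of non-self candidates in the roster.
#' @param ... Passed on to [simulate_tma_cohort()].
#' @return A `taa_pipeline_config` pointing at the written files,
#'   invisibly.
#' @export
simulate_study <- function(out_dir, seed = 1, n_neoantigens = 70, ...) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_taavet("cannot create output directory: ", out_dir)
  }
  healthy <- simulate_healthy_expression(seed = seed)
  tumor <- simulate_tumor_cohort(healthy$truth$tiers, seed = seed + 1)
  self_ids <- names(healthy$truth$tiers)
  roster <- antigen_candidates(
    c(self_ids, sprintf("NEO%03d", seq_len(n_neoantigens))),
    c(rep("self", length(self_ids)), rep("neoantigen", n_neoantigens)))
  ann <- simulate_annotations(38, n_insufficient = 5, seed = seed + 2)
  tma <- simulate_tma_cohort(seed = seed + 3, ...)
  sub <- simulate_subtype_dataset(
    planted = data.frame(gene = "GENE001", cluster = "c5", shift = 2,
                         stringsAsFactors = FALSE),
    seed = seed + 4)

  path <- function(f) file.path(out_dir, f)
  write_candidates(roster, path("candidates.tsv"))
  write_healthy_profile(healthy$profile, path("healthy_tpm.tsv"))
  write_tumor_table(tumor$fpkm, path("tumor_fpkm.tsv"))
  write_annotations(ann$annotations, path("annotations.tsv"))
  write_tma(tma$tma, path("tma.csv"))
  write_subtype_dataset(sub$dataset, path("subtype_matrix.tsv"),
                        path("subtype_clusters.tsv"),
                        path("subtype_probe_map.tsv"))
  jsonlite::write_json(
    list(seed = seed,
         tiers = as.list(healthy$truth$tiers),
         gate_status = as.list(tumor$truth$gate_status),
         expected_totals = ann$truth$expected,
         tma = tma$truth[c("hazard_ratio", "platinum_or")],
         subtype_planted = sub$truth$planted),
    path("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(pipeline_config(
    candidates_path = path("candidates.tsv"),
    healthy_path = path("healthy_tpm.tsv"),
    tumor_path = path("tumor_fpkm.tsv"),
    annotations_path = path("annotations.tsv"),
    tma_path = path("tma.csv"),
    subtype_matrix_path = path("subtype_matrix.tsv"),
    subtype_clusters_path = path("subtype_clusters.tsv"),
    subtype_probe_map_path = path("subtype_probe_map.tsv"),
    seed = seed, out_dir = out_dir))
}
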