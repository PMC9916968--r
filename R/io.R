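# Tabular readers and writers. All expression tables are tab-separated
# with a header row, UTF-8, "." decimal separator; the TMA table is CSV
# (the usual clinical-export dialect). Writers and readers round-trip
# every value exactly at the printed precision.

read_tsv_checked <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_taavet("file not found: ", path)
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_taavet("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read / write a healthy-tissue expression profile
#'
#' TSV with a `gene` column followed by one column per tissue holding
#' median TPM.
#'
#' @param path File path.
#' @return `read_healthy_profile()`: a gene x tissue matrix.
#' @export
read_healthy_profile <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, "gene", path)
  tissues <- setdiff(names(df), "gene")
  if (!length(tissues)) stop_taavet(path, ": no tissue columns")
  m <- as.matrix(df[tissues])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[tissues], 2, as.numeric))),
                 arr.ind = TRUE)
    stop_taavet(path, ": non-numeric TPM value (first at data row ",
                if (nrow(bad)) bad[1, 1] else "?", ")")
  }
  rownames(m) <- df$gene
  as_healthy_profile(m)
}

#' @param profile Gene x tissue matrix of median TPM.
#' @rdname read_healthy_profile
#' @export
write_healthy_profile <- function(profile, path) {
  profile <- as_healthy_profile(profile)
  df <- data.frame(gene = rownames(profile), profile, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a tumor expression table
#'
#' Either a gene x sample FPKM matrix (TSV, `gene` column then one
#' column per sample) or a pre-summarized table with columns `gene`,
#' `median_fpkm`, `mean_fpkm`, `n_samples`. The reader detects the form
#' from the header.
#'
#' @param path File path.
#' @return A matrix (full cohort) or summary data frame.
#' @export
read_tumor_table <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, "gene", path)
  if (all(c("median_fpkm", "mean_fpkm") %in% names(df))) {
    return(as_tumor_summary(df))
  }
  m <- as.matrix(df[setdiff(names(df), "gene")])
  if (!is.numeric(m) || anyNA(m)) {
    stop_taavet(path, ": non-numeric FPKM value in tumor matrix")
  }
  rownames(m) <- df$gene
  m
}

#' @param tumor Matrix or summary data frame (see above).
#' @rdname read_tumor_table
#' @export
write_tumor_table <- function(tumor, path) {
  if (is.matrix(tumor)) {
    df <- data.frame(gene = rownames(tumor), tumor, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- as_tumor_summary(tumor)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a candidate roster
#'
#' TSV with columns `id`, `antigen_class` and optionally `aliases`
#' (semicolon-separated).
#'
#' @param path File path.
#' @return A `taa_candidates` roster.
#' @export
read_candidates <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("id", "antigen_class"), path)
  antigen_candidates(df$id, df$antigen_class,
                     if ("aliases" %in% names(df)) df$aliases else NULL)
}

#' @param candidates A `taa_candidates` roster.
#' @rdname read_candidates
#' @export
write_candidates <- function(candidates, path) {
  candidates <- as_taa_candidates(candidates)
  df <- data.frame(id = candidates$id,
                   antigen_class = candidates$antigen_class,
                   aliases = vapply(candidates$aliases, paste,
                                    character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a rubric
#'
#' TSV with columns `criterion`, `label`, `points`, `definition`.
#'
#' @param path File path.
#' @return A `taa_rubric`.
#' @export
read_rubric <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("criterion", "label", "points"), path)
  rubric(df)
}

#' @param r A `taa_rubric`.
#' @rdname read_rubric
#' @export
write_rubric <- function(r, path) {
  stopifnot(inherits(r, "taa_rubric"))
  utils::write.table(as.data.frame(r), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write candidate annotations
#'
#' Long-format TSV with columns `candidate_id`, `criterion`,
#' `selection`, `insufficient_data` (logical, constant within a
#' candidate). Every candidate must select exactly one subcriterion
#' (or `unknown` / `not applicable`) per listed criterion.
#'
#' @param path File path.
#' @return A named list of `taa_annotation` objects.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("candidate_id", "criterion", "selection"), path)
  if (!"insufficient_data" %in% names(df)) df$insufficient_data <- FALSE
  out <- lapply(split(df, df$candidate_id), function(block) {
    if (anyDuplicated(block$criterion)) {
      stop_taavet(path, ": candidate '", block$candidate_id[1],
                  "' selects a criterion twice")
    }
    candidate_annotation(block$candidate_id[1],
                         setNames(block$selection, block$criterion),
                         insufficient_data = any(as.logical(block$insufficient_data)))
  })
  out[unique(df$candidate_id)]
}

#' @param annotations List of `taa_annotation` objects.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    if (!length(a$selections)) {
      return(data.frame(candidate_id = a$id, criterion = NA_character_,
                        selection = NA_character_,
                        insufficient_data = a$insufficient_data,
                        stringsAsFactors = FALSE))
    }
    data.frame(candidate_id = a$id, criterion = names(a$selections),
               selection = unname(a$selections),
               insufficient_data = a$insufficient_data,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

TMA_COLUMNS <- c("sample_id", "antigen", "intensity_r1", "intensity_r2",
                 "consensus_intensity", "percent_positive", "assessable",
                 "grade", "figo_stage", "t_stage", "perit_carc",
                 "residual_tumor", "platinum_response", "age",
                 "pfs_months", "pfs_event", "os_months", "os_event",
                 "ttp_months", "ttp_event")

#' Read / write a tissue-microarray table
#'
#' CSV with one row per stained core: per-rater intensities (0-3),
#' consensus intensity, percent positive cells (integer 0-100), an
#' assessable flag, and the clinical covariates (grade, FIGO stage,
#' T stage, peritoneal carcinomatosis, residual tumor, platinum
#' response yes/no/unknown, age, and PFS/OS/TTP times with event
#' flags). Range violations are rejected with the offending row number.
#'
#' @param path File path.
#' @return Validated data frame with the TMA schema.
#' @export
read_tma <- function(path) {
  df <- read_tsv_checked(path, sep = ",")
  require_columns(df, TMA_COLUMNS, path)
  validate_tma(df, path)
}

validate_tma <- function(df, where = "TMA table") {
  for (col in c("sample_id", "antigen", "grade", "figo_stage", "t_stage",
                "platinum_response")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("intensity_r1", "intensity_r2", "consensus_intensity")) {
    bad <- which(!is_whole(df[[col]]) | df[[col]] < 0 | df[[col]] > 3)
    if (length(bad)) {
      stop_taavet(where, ": ", col, " outside 0..3 at row ", bad[1])
    }
  }
  bad <- which(!is_whole(df$percent_positive) |
                 df$percent_positive < 0 | df$percent_positive > 100)
  if (length(bad)) {
    stop_taavet(where, ": percent_positive outside 0..100 at row ", bad[1])
  }
  for (col in c("pfs_months", "os_months", "ttp_months")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad)) stop_taavet(where, ": ", col, " negative or missing at row ", bad[1])
  }
  for (col in c("assessable", "pfs_event", "os_event", "ttp_event",
                "perit_carc", "residual_tumor")) {
    df[[col]] <- as.logical(df[[col]])
    if (anyNA(df[[col]])) stop_taavet(where, ": ", col, " must be logical")
  }
  bad <- which(!df$platinum_response %in% c("yes", "no", "unknown"))
  if (length(bad)) {
    stop_taavet(where, ": platinum_response must be yes/no/unknown at row ", bad[1])
  }
  df
}

#' @param tma TMA data frame.
#' @rdname read_tma
#' @export
write_tma <- function(tma, path) {
  tma <- validate_tma(tma)
  utils::write.table(tma[TMA_COLUMNS], path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a molecular-subtype dataset
#'
#' Three TSV files: the probe x sample matrix (`probe` column then one
#' column per sample), the cluster labels (`sample`, `cluster`), and
#' the probe map (`probe`, `gene`).
#'
#' @param matrix_path,clusters_path,probe_map_path File paths.
#' @return A `taa_subtype_dataset`.
#' @export
read_subtype_dataset <- function(matrix_path, clusters_path, probe_map_path) {
  m <- read_tsv_checked(matrix_path)
  require_columns(m, "probe", matrix_path)
  expr <- as.matrix(m[setdiff(names(m), "probe")])
  if (!is.numeric(expr) || anyNA(expr)) {
    stop_taavet(matrix_path, ": non-numeric expression value")
  }
  rownames(expr) <- m$probe
  cl <- read_tsv_checked(clusters_path)
  require_columns(cl, c("sample", "cluster"), clusters_path)
  pm <- read_tsv_checked(probe_map_path)
  require_columns(pm, c("probe", "gene"), probe_map_path)
  subtype_dataset(expr, setNames(cl$cluster, cl$sample),
                  setNames(pm$gene, pm$probe))
}

#' @param dataset A `taa_subtype_dataset`.
#' @rdname read_subtype_dataset
#' @export
write_subtype_dataset <- function(dataset, matrix_path, clusters_path,
                                  probe_map_path) {
  stopifnot(inherits(dataset, "taa_subtype_dataset"))
  m <- data.frame(probe = rownames(dataset$expr), dataset$expr,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(m, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(dataset$expr),
               cluster = as.character(dataset$clusters)),
    clusters_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe = names(dataset$probe_map),
               gene = unname(dataset$probe_map)),
    probe_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}
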