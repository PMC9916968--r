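# Molecular-subtype differential expression: probe-set selection,
# Kruskal-Wallis across clusters, Dunn-Bonferroni post-hoc.

SUBTYPE_CLUSTERS <- c("c1", "c2", "c4", "c5")

#' Assemble a molecular-subtype expression dataset
#'
#' Bundles a probe x sample matrix of pre-normalized expression
#' intensities with per-sample molecular-subtype labels and a
#' probe-to-gene map. Only the malignant ovarian-cancer clusters c1
#' (high stromal response), c2 (high immune signature), c4 (low stromal
#' response) and c5 (mesenchymal) are accepted. The matrix is expected
#' to be already normalized (e.g. model-based expression indices);
#' no preprocessing is applied here.
#'
#' @param expr Numeric probe x sample matrix, probes in rownames,
#'   samples in colnames; values non-negative.
#' @param clusters Named character vector or factor: sample -> cluster
#'   label in `c1, c2, c4, c5`; at least two clusters represented.
#' @param probe_map Named character vector: probe -> gene.
#' @return A list of class `taa_subtype_dataset`.
#' @export
subtype_dataset <- function(expr, clusters, probe_map) {
  if (!is.matrix(expr) || !is.numeric(expr) ||
      is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_taavet("`expr` must be a numeric probe x sample matrix with dimnames")
  }
  if (anyNA(expr) || any(expr < 0)) {
    stop_taavet("expression intensities must be non-negative and non-missing")
  }
  cl <- as.character(clusters)
  names(cl) <- names(clusters)
  if (is.null(names(cl))) stop_taavet("`clusters` must be named by sample")
  missing_cl <- setdiff(colnames(expr), names(cl))
  if (length(missing_cl)) {
    stop_taavet("samples without a cluster label: ",
                paste(head(missing_cl, 5), collapse = ", "))
  }
  cl <- cl[colnames(expr)]
  bad <- setdiff(unique(cl), SUBTYPE_CLUSTERS)
  if (length(bad)) {
    stop_taavet("unknown cluster label(s): ", paste(bad, collapse = ", "),
                " (only c1, c2, c4, c5 represent true malignant neoplasia)")
  }
  if (length(unique(cl)) < 2L) {
    stop_taavet("at least two clusters must be represented")
  }
  pm <- as.character(probe_map)
  names(pm) <- names(probe_map)
  missing_pm <- setdiff(rownames(expr), names(pm))
  if (length(missing_pm)) {
    stop_taavet("probes without a gene mapping: ",
                paste(head(missing_pm, 5), collapse = ", "))
  }
  structure(list(expr = expr,
                 clusters = factor(cl, levels = SUBTYPE_CLUSTERS),
                 probe_map = pm[rownames(expr)]),
            class = "taa_subtype_dataset")
}

#' Select the representative probe set for a gene
#'
#' When a gene is measured by several probe sets, the probe set with the
#' highest average expression across all samples represents the gene.
#' Ties break to the lexicographically smallest probe id.
#'
#' @param gene Gene symbol.
#' @param dataset A `taa_subtype_dataset`.
#' @return The selected probe id (character scalar).
#' @export
select_probe_set <- function(gene, dataset) {
  stopifnot(inherits(dataset, "taa_subtype_dataset"))
  probes <- names(dataset$probe_map)[dataset$probe_map == gene]
  if (!length(probes)) stop_taavet("gene '", gene, "' has no mapped probe set")
  means <- rowMeans(dataset$expr[probes, , drop = FALSE])
  cand <- probes[means == max(means)]
  sort(cand)[1L]
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction. The p-value comes from
#' the chi-squared approximation on k - 1 degrees of freedom, or — for
#' small samples (`exact = TRUE`, the default when the pooled n is at
#' most 10) — from exact enumeration of all assignments of the pooled
#' observations to groups of the observed sizes.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param exact `TRUE`, `FALSE`, or `NULL` (decide by pooled n <= 10).
#' @return List with `statistic` (H), `p.value`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, exact = NULL) {
  groups <- check_groups(groups)
  n <- lengths(groups)
  N <- sum(n)
  if (N < 3L) stop_taavet("need a pooled sample size of at least 3")
  pooled <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, p.value = 1, df = k - 1L,
                method = "Kruskal-Wallis (degenerate: constant data)"))
  }
  if (is.null(exact)) exact <- N <= 10L
  h_obs <- kw_h(rank(pooled), split_index(n), N)
  if (exact) {
    r <- rank(pooled)
    asg <- group_assignments(seq_len(N), n)
    h_all <- vapply(asg, function(idx) kw_h(r, idx, N), numeric(1))
    p <- mean(h_all >= h_obs - 1e-12)
    method <- "Kruskal-Wallis (exact enumeration p)"
  } else {
    p <- stats::pchisq(h_obs, df = k - 1L, lower.tail = FALSE)
    method <- "Kruskal-Wallis (chi-squared approximation)"
  }
  list(statistic = h_obs, p.value = min(max(p, 0), 1), df = k - 1L,
       method = method)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_taavet("`groups` must be a list of at least two numeric vectors")
  }
  if (any(lengths(groups) == 0L)) stop_taavet("every group must be non-empty")
  if (anyNA(unlist(groups))) stop_taavet("missing values are not supported")
  lapply(groups, as.numeric)
}

# H statistic with tie correction, given pooled ranks `r`, a list of
# per-group index vectors and pooled size N
kw_h <- function(r, idx, N) {
  rs <- vapply(idx, function(i) sum(r[i]), numeric(1))
  n <- lengths(idx)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
  ties <- table(r)
  cor_ties <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / cor_ties
}

split_index <- function(sizes) {
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq, starts, ends)
}

# all ways to partition `indices` into ordered groups of the given sizes
group_assignments <- function(indices, sizes) {
  if (length(sizes) == 1L) return(list(list(indices)))
  first <- combn(indices, sizes[1L], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- group_assignments(setdiff(indices, f), sizes[-1L])
    out <- c(out, lapply(rest, function(r) c(list(f), r)))
  }
  out
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics on pooled ranks with tie correction, following
#' a Kruskal-Wallis test. Two-sided raw p-values are Bonferroni-adjusted
#' by the number of pairwise comparisons.
#'
#' @param groups List of >= 2 non-empty numeric vectors; names label
#'   the groups.
#' @return Data frame: `group1`, `group2`, `z`, `p.value`, `p.adjusted`.
#' @export
dunn_bonferroni <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  idx <- split_index(n)
  rbar <- vapply(idx, function(i) mean(r[i]), numeric(1))
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[i1] + 1 / n[i2]))
    z <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = labels[i1], group2 = labels[i2], z = z,
               p.value = p, p.adjusted = min(1, m * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential-expression scan across molecular subtypes
#'
#' For every gene of a subtype dataset, selects its representative probe
#' set ([select_probe_set()]) and tests differential expression across
#' the clusters with the Kruskal-Wallis test; genes below `alpha` get a
#' Dunn-Bonferroni post-hoc table.
#'
#' @param dataset A `taa_subtype_dataset`.
#' @param genes Genes to test (default: all mapped genes).
#' @param alpha Threshold for running the post-hoc test (default 0.05).
#' @return List of class `taa_subtype_scan`: `table` (gene, probe, H,
#'   p.value) sorted by p, and `posthoc` (named list of Dunn tables).
#' @export
subtype_de_scan <- function(dataset, genes = NULL, alpha = 0.05) {
  stopifnot(inherits(dataset, "taa_subtype_dataset"))
  if (is.null(genes)) genes <- unique(dataset$probe_map)
  cl <- droplevels(dataset$clusters)
  rows <- lapply(genes, function(g) {
    probe <- select_probe_set(g, dataset)
    vals <- dataset$expr[probe, ]
    kw <- kruskal_wallis(split(vals, cl), exact = FALSE)
    data.frame(gene = g, probe = probe, H = kw$statistic,
               p.value = kw$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p.value, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  posthoc <- list()
  for (i in which(tab$p.value < alpha)) {
    vals <- dataset$expr[tab$probe[i], ]
    posthoc[[tab$gene[i]]] <- dunn_bonferroni(split(vals, cl))
  }
  structure(list(table = tab, posthoc = posthoc, alpha = alpha),
            class = "taa_subtype_scan")
}

#' @export
print.taa_subtype_scan <- function(x, ...) {
  cat(sprintf("Subtype differential expression: %d genes tested, %d with p < %g\n",
              nrow(x$table), sum(x$table$p.value < x$alpha), x$alpha))
  print(head(x$table, 10))
  invisible(x)
}
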