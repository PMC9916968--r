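# Candidate antigens entering the selection cascade.

ANTIGEN_CLASSES <- c("self", "neoantigen", "viral")

#' Construct a candidate antigen roster
#'
#' A candidate roster lists the antigens entering the selection cascade,
#' each with a class label. Only self-antigens survive the first cascade
#' stage: neoantigens are patient-specific and virus-associated antigens
#' have no role in epithelial ovarian cancer.
#'
#' @param id Character vector of gene-symbol-like identifiers (unique,
#'   non-empty).
#' @param antigen_class Character vector, one of `"self"`, `"neoantigen"`,
#'   `"viral"` per candidate (recycled if length 1).
#' @param aliases Optional list of character vectors of aliases per
#'   candidate, or a character vector of semicolon-separated aliases.
#' @return A data frame of class `taa_candidates` with columns `id`,
#'   `antigen_class`, `aliases` (list column).
#' @examples
#' antigen_candidates(c("KIF20A", "CT45", "LY6K"), "self")
#' @export
antigen_candidates <- function(id, antigen_class = "self", aliases = NULL) {
  id <- as.character(id)
  if (length(id) == 0L) {
    out <- data.frame(id = character(), antigen_class = character(),
                      stringsAsFactors = FALSE)
    out$aliases <- list()
    class(out) <- c("taa_candidates", "data.frame")
    return(out)
  }
  if (anyNA(id) || any(!nzchar(id))) {
    stop_taavet("candidate ids must be non-empty strings")
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop_taavet("duplicate candidate ids: ", paste(dup, collapse = ", "))
  }
  antigen_class <- as.character(antigen_class)
  if (length(antigen_class) == 1L) {
    antigen_class <- rep(antigen_class, length(id))
  }
  if (length(antigen_class) != length(id)) {
    stop_taavet("`antigen_class` must have length 1 or length(id)")
  }
  bad <- setdiff(unique(antigen_class), ANTIGEN_CLASSES)
  if (length(bad)) {
    stop_taavet("unknown antigen class(es): ", paste(bad, collapse = ", "),
                " (expected self, neoantigen or viral)")
  }
  if (is.null(aliases)) {
    aliases <- rep(list(character()), length(id))
  } else if (is.character(aliases)) {
    aliases <- lapply(strsplit(aliases, ";", fixed = TRUE), function(a) {
      a <- trimws(a)
      a[nzchar(a)]
    })
  }
  if (length(aliases) != length(id)) {
    stop_taavet("`aliases` must have one entry per candidate")
  }
  out <- data.frame(id = id, antigen_class = antigen_class,
                    stringsAsFactors = FALSE)
  out$aliases <- aliases
  class(out) <- c("taa_candidates", "data.frame")
  out
}

#' Exclude neoantigens and virus-associated antigens
#'
#' The first cascade stage retains only self-antigens, in input order.
#'
#' @param candidates A `taa_candidates` roster (see [antigen_candidates()]).
#' @return A list with `retained` (the self-antigen roster, order
#'   preserved), `excluded` (the dropped rows) and `n_excluded`.
#' @export
exclude_neoantigens <- function(candidates) {
  candidates <- as_taa_candidates(candidates)
  keep <- candidates$antigen_class == "self"
  list(retained = candidates[keep, , drop = FALSE],
       excluded = candidates[!keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

as_taa_candidates <- function(x) {
  if (inherits(x, "taa_candidates")) {
    dup <- unique(x$id[duplicated(x$id)])
    if (length(dup)) {
      stop_taavet("duplicate candidate ids: ", paste(dup, collapse = ", "))
    }
    return(x)
  }
  if (is.data.frame(x)) {
    if (!all(c("id", "antigen_class") %in% names(x))) {
      stop_taavet("candidate table needs columns `id` and `antigen_class`")
    }
    al <- if ("aliases" %in% names(x)) x$aliases else NULL
    if (is.list(al)) {
      out <- antigen_candidates(x$id, x$antigen_class)
      out$aliases <- al
      return(out)
    }
    return(antigen_candidates(x$id, x$antigen_class, al))
  }
  if (is.character(x)) return(antigen_candidates(x))
  stop_taavet("cannot interpret `candidates` as a candidate roster")
}
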