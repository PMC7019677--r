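# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, evaluates `code`, and restores the caller's `.Random.seed`,
#' so seeded package functions never perturb the user's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Deterministic substream seed from a master seed and a key
#'
#' Each (gene, group) or covariate draw uses its own substream so that adding
#' a gene to a configuration leaves the other genes' draws untouched.
#' @noRd
substream_seed <- function(master, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

#' Stable content hash for provenance records
#'
#' Polynomial hash over the version-2 serialization of `x`; changes whenever
#' the configuration or inputs change.
#' @noRd
provenance_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Coerce group labels to a case indicator
#'
#' Accepts logicals, 0/1 numerics, or character/factor labels containing
#' `case_label`. Errors unless both classes are present when `require_both`.
#' @noRd
as_case_labels <- function(labels, case_label = "case", require_both = TRUE) {
  if (is.logical(labels)) {
    is_case <- labels
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    is_case <- labels == 1
  } else {
    labels <- as.character(labels)
    if (!case_label %in% labels && require_both) {
      stop("no samples labelled '", case_label, "' found in `labels`",
           call. = FALSE)
    }
    is_case <- labels == case_label
  }
  if (anyNA(is_case)) stop("`labels` contains missing values", call. = FALSE)
  if (require_both && (!any(is_case) || all(is_case))) {
    stop("both classes must be present (got a single-class label vector)",
         call. = FALSE)
  }
  is_case
}

# Pull (expression data.frame, group labels) out of the containers the
# pipeline accepts: a saliva_cohort, or a wide data.frame plus labels.
resolve_expression <- function(x, groups = NULL) {
  if (inherits(x, "saliva_cohort")) {
    expr <- x$expression
    groups <- groups %||% x$metadata$group
  } else if (is.data.frame(x)) {
    expr <- x
  } else {
    stop("expected a `saliva_cohort` or a data.frame of expression values",
         call. = FALSE)
  }
  genes <- setdiff(names(expr), "sample_id")
  list(expression = expr, groups = groups, genes = genes)
}
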