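#' Average replicate Ct values
#'
#' Arithmetic mean of a well's technical replicates, on the cycle scale.
#' Undetermined replicates (`NA`) are dropped before averaging; replicates
#' outside the plausible Ct window raise a warning but are retained.
#'
#' @param cts Numeric vector of replicate cycle-threshold values.
#' @param ct_window Plausible Ct range in cycles (default 5-45).
#' @return Mean Ct in cycles.
#' @export
average_ct <- function(cts, ct_window = c(5, 45)) {
  cts <- cts[!is.na(cts)]
  if (length(cts) == 0L) {
    stop("no non-missing replicate Ct values to average", call. = FALSE)
  }
  out <- cts < ct_window[1] | cts > ct_window[2]
  if (any(out)) {
    warning(sum(out), " replicate Ct value(s) outside the plausible window [",
            ct_window[1], ", ", ct_window[2], "] cycles (kept)")
  }
  mean(cts)
}

#' Delta-Ct: target minus reference
#'
#' @param target_mean_ct,reference_mean_ct Mean Ct values in cycles.
#' @return `target_mean_ct - reference_mean_ct` (cycles).
#' @export
delta_ct <- function(target_mean_ct, reference_mean_ct) {
  if (!all(is.finite(target_mean_ct)) || !all(is.finite(reference_mean_ct))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  target_mean_ct - reference_mean_ct
}

#' Relative expression on the 2^-ddCt scale
#'
#' `2^-(delta_ct - calibrator_delta_ct)`; equals 1 exactly when the sample's
#' delta-Ct matches the calibrator's. Assumes perfect amplification
#' efficiency (a doubling per cycle).
#'
#' @param delta_ct Sample delta-Ct (cycles).
#' @param calibrator_delta_ct Calibrator delta-Ct (cycles, default 0).
#' @return Dimensionless relative expression, strictly positive.
#' @export
rel_expression <- function(delta_ct, calibrator_delta_ct = 0) {
  if (!all(is.finite(delta_ct)) || !all(is.finite(calibrator_delta_ct))) {
    stop("delta-Ct values must be finite", call. = FALSE)
  }
  2^-(delta_ct - calibrator_delta_ct)
}

#' Calibrator policies for ddCt quantification
#'
#' The ddCt calibrator fixes the point at which relative expression equals 1.
#' Fold changes between groups are calibrator-invariant, so the choice only
#' moves the reporting scale:
#'
#' * `calibrator_control_mean()` — per-gene mean delta-Ct of the control
#'   group (the default; makes the control group's mean relative expression
#'   interpretable as the baseline). Requires group labels at
#'   quantification time.
#' * `calibrator_sample(sample_id)` — a named reference sample's delta-Ct.
#' * `calibrator_fixed(values)` — explicit per-gene calibrator delta-Ct
#'   values (named numeric), as stored on plates built by
#'   [simulate_ct_plate()].
#' * `calibrator_none()` — no calibration; report `2^-dCt`.
#'
#' @param control_label Group label identifying controls.
#' @param sample_id Sample identifier.
#' @param values Named numeric vector of per-gene calibrator delta-Ct.
#' @return A `ddct_calibrator` policy object.
#' @name calibrators
NULL

#' @rdname calibrators
#' @export
calibrator_control_mean <- function(control_label = "control") {
  structure(list(policy = "control_mean", control_label = control_label),
            class = "ddct_calibrator")
}

#' @rdname calibrators
#' @export
calibrator_sample <- function(sample_id) {
  structure(list(policy = "sample", sample_id = as.character(sample_id)),
            class = "ddct_calibrator")
}

#' @rdname calibrators
#' @export
calibrator_fixed <- function(values) {
  if (is.null(names(values))) {
    stop("`values` must be a named (per-gene) numeric vector", call. = FALSE)
  }
  structure(list(policy = "fixed", values = values), class = "ddct_calibrator")
}

#' @rdname calibrators
#' @export
calibrator_none <- function() {
  structure(list(policy = "none"), class = "ddct_calibrator")
}

#' Quantify a plate of Ct measurements into relative expression
#'
#' Implements the full 2^-ddCt workflow: replicate Ct values are averaged per
#' (sample, gene); each sample's target genes are normalised to its
#' reference-gene (housekeeping) Ct to give delta-Ct; a calibrator delta-Ct
#' per gene (see [calibrators]) is subtracted; and relative expression
#' `2^-ddCt` is returned. Samples lacking the reference gene cannot be
#' normalised and are dropped with a message (their ids are recorded in the
#' `excluded_samples` attribute). Cells whose replicates are all `NA` stay
#' missing; downstream summaries use complete cases per gene.
#'
#' @param ct Long data.frame with columns `sample_id`, `gene`, `replicate`,
#'   `ct` (a `ct_plate` works directly).
#' @param reference_gene Housekeeping gene name (default `"GAPDH"`).
#' @param calibrator A `ddct_calibrator` policy (default
#'   [calibrator_control_mean()]).
#' @param groups Group labels needed by the control-mean policy: either a
#'   vector named by sample id, or a data.frame with `sample_id` and `group`
#'   columns.
#' @param ct_window Plausible Ct range passed to [average_ct()].
#' @return Wide data.frame (`sample_id` plus one column per target gene) of
#'   relative expression, with attributes `excluded_samples`,
#'   `calibrator_delta_ct` and `reference_gene`.
#' @export
quantify_table <- function(ct, reference_gene = "GAPDH",
                           calibrator = calibrator_control_mean(),
                           groups = NULL, ct_window = c(5, 45)) {
  need <- c("sample_id", "gene", "replicate", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("`ct` must have columns sample_id, gene, replicate, ct", call. = FALSE)
  }
  if (!inherits(calibrator, "ddct_calibrator")) {
    stop("`calibrator` must be one of the calibrator_*() policies", call. = FALSE)
  }
  dup <- duplicated(ct[c("sample_id", "gene", "replicate")])
  if (any(dup)) {
    stop("duplicate (sample_id, gene, replicate) rows in `ct`", call. = FALSE)
  }

  out_win <- !is.na(ct$ct) & (ct$ct < ct_window[1] | ct$ct > ct_window[2])
  if (any(out_win)) {
    warning(sum(out_win), " Ct value(s) outside the plausible window [",
            ct_window[1], ", ", ct_window[2], "] cycles (kept)")
  }

  samples <- unique(ct$sample_id)
  genes <- setdiff(unique(ct$gene), reference_gene)
  if (!reference_gene %in% ct$gene) {
    stop("reference gene '", reference_gene, "' absent from `ct`", call. = FALSE)
  }

  # mean Ct per (sample, gene), NA replicates dropped; all-NA cell -> NA
  mean_ct <- tapply(ct$ct, list(factor(ct$sample_id, samples),
                                factor(ct$gene, c(reference_gene, genes))),
                    function(v) {
                      v <- v[!is.na(v)]
                      if (length(v)) mean(v) else NA_real_
                    })

  ref_ct <- mean_ct[, reference_gene]
  keep <- !is.na(ref_ct)
  if (!all(keep)) {
    dropped <- samples[!keep]
    message("excluding ", length(dropped), " sample(s) lacking reference gene '",
            reference_gene, "': ", paste(dropped, collapse = ", "))
  }
  dct <- mean_ct[keep, genes, drop = FALSE] - ref_ct[keep]
  kept_samples <- samples[keep]

  calib <- switch(
    calibrator$policy,
    control_mean = {
      if (is.null(groups)) {
        stop("the control-mean calibrator needs `groups`", call. = FALSE)
      }
      if (is.data.frame(groups)) {
        groups <- stats::setNames(groups$group, groups$sample_id)
      }
      grp <- as.character(groups[kept_samples])
      is_ctrl <- grp == calibrator$control_label
      if (!any(is_ctrl)) {
        stop("no samples labelled '", calibrator$control_label,
             "' to calibrate against", call. = FALSE)
      }
      apply(dct[is_ctrl, , drop = FALSE], 2, mean, na.rm = TRUE)
    },
    sample = {
      if (!calibrator$sample_id %in% kept_samples) {
        stop("calibrator sample '", calibrator$sample_id,
             "' not present after exclusions", call. = FALSE)
      }
      dct[match(calibrator$sample_id, kept_samples), ]
    },
    fixed = {
      missing_g <- setdiff(genes, names(calibrator$values))
      if (length(missing_g)) {
        stop("fixed calibrator lacks gene(s): ",
             paste(missing_g, collapse = ", "), call. = FALSE)
      }
      calibrator$values[genes]
    },
    none = stats::setNames(rep(0, length(genes)), genes)
  )

  rel <- 2^-sweep(dct, 2, as.numeric(calib), `-`)
  out <- data.frame(sample_id = kept_samples, stringsAsFactors = FALSE)
  for (g in genes) out[[g]] <- unname(rel[, g])
  structure(out,
            excluded_samples = samples[!keep],
            calibrator_delta_ct = stats::setNames(as.numeric(calib), genes),
            reference_gene = reference_gene)
}

#' Read a long Ct table or a wide expression table from CSV
#'
#' @param path CSV/TSV path (delimiter inferred from the extension).
#' @param columns Optional named character vector remapping input column
#'   names to the expected `sample_id`, `gene`, `replicate`, `ct`.
#' @return A data.frame.
#' @export
read_ct_table <- function(path, columns = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columns)) {
    names(x)[match(columns, names(x))] <- names(columns)
  }
  x
}
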