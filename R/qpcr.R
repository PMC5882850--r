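# Relative qPCR quantification by the 2^-ddCt method.

#' A qPCR measurement for one sample
#'
#' Bundles target-gene and reference-gene (e.g. GAPDH) threshold-cycle
#' replicates for one sample.
#'
#' @param sample Sample label.
#' @param target_ct Numeric vector of target-gene Ct replicates.
#' @param reference_ct Numeric vector of reference-gene Ct replicates.
#' @return An object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(sample, target_ct, reference_ct) {
  if (length(target_ct) < 1 || length(reference_ct) < 1) {
    abort("each gene needs at least one Ct replicate",
      class = "optoxr_input_error"
    )
  }
  if (any(!is.finite(target_ct)) || any(!is.finite(reference_ct)) ||
      any(target_ct <= 0) || any(reference_ct <= 0)) {
    abort("Ct values must be positive finite numbers",
      class = "optoxr_input_error"
    )
  }
  structure(
    list(sample = sample, target_ct = as.numeric(target_ct),
         reference_ct = as.numeric(reference_ct)),
    class = "qpcr_measurement"
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` per measurement (arithmetic
#' mean over replicates, the standard aggregation for this method; no
#' efficiency correction), `ddCt = dCt_sample - dCt_calibrator`, fold change
#' `= 2^-ddCt`.
#'
#' @param sample,calibrator [qpcr_measurement()] objects.
#' @return Fold change (numeric scalar) with attribute `ddct`.
#' @export
ddct <- function(sample, calibrator) {
  stopifnot(inherits(sample, "qpcr_measurement"),
            inherits(calibrator, "qpcr_measurement"))
  d_s <- mean(sample$target_ct) - mean(sample$reference_ct)
  d_c <- mean(calibrator$target_ct) - mean(calibrator$reference_ct)
  dd <- d_s - d_c
  structure(2^(-dd), ddct = dd)
}

#' Relative expression for a tidy Ct table
#'
#' Takes the usual long-format qPCR export (one row per well) and returns
#' one fold change per sample, relative to the calibrator sample and
#' normalised to the reference gene.
#'
#' @param data A data frame with columns `sample`, `gene`, `ct`.
#' @param target_gene Target gene name.
#' @param reference_gene Reference gene name (e.g. `"GAPDH"`).
#' @param calibrator Calibrator sample label.
#' @return A tibble with columns `sample`, `dct`, `ddct`, `fold_change`.
#' @export
relative_expression <- function(data, target_gene = "target",
                                reference_gene = "reference",
                                calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(data)))
  if (!calibrator %in% data$sample) {
    abort("calibrator sample not present in the table",
      class = "optoxr_input_error"
    )
  }
  dct <- data |>
    filter(.data$gene %in% c(target_gene, reference_gene)) |>
    group_by(.data$sample, .data$gene) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mean_ct") |>
    mutate(dct = .data[[target_gene]] - .data[[reference_gene]])
  cal <- dct$dct[dct$sample == calibrator]
  dct |>
    mutate(ddct = .data$dct - cal, fold_change = 2^(-.data$ddct)) |>
    select("sample", "dct", "ddct", "fold_change")
}
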