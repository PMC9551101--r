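#' Relative quantification by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference` normalises the target to
#' the reference gene; `ddCt` subtracts the mean calibrator-condition `dCt`;
#' the relative quantity is `rq = 2^-ddCt` (amplification efficiency fixed
#' at 2). Per condition the point estimate is `2^-mean(ddCt)`, so the
#' calibrator condition is 1 by construction; the SEM is computed across
#' replicates on the rq scale (matching mean-plus-or-minus-SEM bar plots),
#' or on the ddCt scale in cycles with `log_scale = TRUE`.
#'
#' With dual reference genes, pass the per-replicate geometric-mean
#' reference Ct as `ct_reference` (i.e. the arithmetic mean of the two
#' reference Ct values), which is the standard multi-reference
#' normalisation on the Ct scale.
#'
#' @param ct data.frame with columns `sample_id`, `condition`,
#'   `target_gene`, `ct_target`, `ct_reference` (and optionally
#'   `replicate`). Ct values must lie in (0, 45).
#' @param calibrator condition level used as calibrator (rq = 1 by
#'   construction).
#' @param log_scale report the SEM on the ddCt scale (cycles) instead of
#'   the rq scale.
#' @return A data.frame of class `relative_quant`: one row per
#'   (target_gene, condition) with `mean_ddct`, `rq` and `sem`.
#' @examples
#' ct <- data.frame(sample_id = c("s1", "s2"),
#'                  condition = c("control", "treated"),
#'                  target_gene = "REST",
#'                  ct_target = c(20, 19), ct_reference = c(18, 18))
#' ddct(ct, calibrator = "control")  # treated rq = 2
#' @export
ddct <- function(ct, calibrator, log_scale = FALSE) {
  need <- c("sample_id", "condition", "target_gene", "ct_target",
            "ct_reference")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  bad <- is.na(ct$ct_reference) | is.na(ct$ct_target)
  if (any(bad))
    stop("missing Ct in record(s): ",
         paste(ct$sample_id[bad], ct$target_gene[bad], collapse = "; "))
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45 |
          ct$ct_reference <= 0 | ct$ct_reference >= 45))
    stop("Ct values must lie in (0, 45)")
  if (!calibrator %in% ct$condition)
    stop("calibrator condition '", calibrator, "' not present")
  ct$dct <- ct$ct_target - ct$ct_reference
  out <- do.call(rbind, lapply(split(ct, ct$target_gene), function(g) {
    cal <- mean(g$dct[g$condition == calibrator])
    if (is.nan(cal))
      stop("no calibrator replicate for target ", g$target_gene[1])
    g$ddct <- g$dct - cal
    g$rq <- 2^(-g$ddct)
    do.call(rbind, lapply(split(g, g$condition), function(h) {
      sem <- function(v) if (length(v) > 1)
        stats::sd(v) / sqrt(length(v)) else NA_real_
      m <- mean(h$ddct)
      data.frame(target_gene = h$target_gene[1],
                 condition = h$condition[1], n = nrow(h),
                 mean_ddct = m, rq = 2^(-m),
                 sem = if (log_scale) sem(h$ddct) else sem(h$rq))
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("relative_quant", "data.frame")
  attr(out, "calibrator") <- calibrator
  out
}

#' @export
print.relative_quant <- function(x, ...) {
  cat("2^-ddCt relative quantification (calibrator: ",
      attr(x, "calibrator"), ")\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Standard percent-of-input convention with dilution adjustment: the input
#' Ct is first shifted by `log2(1 / input_fraction)` to the scale of an
#' undiluted input, then
#' `%input = 100 * 2^(adjusted_input_Ct - Ct_IP)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_fraction fraction of chromatin the input represents, in
#'   `(0, 1]` (e.g. 0.01 for a 1\% input).
#' @return Percent of input (vectorised).
#' @examples
#' chip_enrichment(18, 22, 0.01)  # ~16.0
#' @export
chip_enrichment <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0 | input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
}
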