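# qPCR relative expression by the 2^-ddCt (Livak) method from replicated
# Ct tables with a reference gene, plus Welch-t significance flags.

#' Read a long-format Ct table
#'
#' Tab-separated with columns `sample`, `gene`, `replicate`, `ct`.
#'
#' @param path TSV file.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
}

#' Validate a Ct table
#'
#' Checks the column set, Ct range (0, 45) and that every
#' (sample, gene) cell has the same replicate count.
#'
#' @param ct Data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @return The table, invisibly validated.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  reps <- table(ct$sample, ct$gene)
  reps <- reps[reps > 0L]
  if (length(unique(reps)) > 1L)
    stop("replicate count differs across (sample, gene) cells")
  ct
}

.cell_ct <- function(ct, gene, sample) {
  x <- ct[ct$gene == gene & ct$sample == sample, ]
  if (nrow(x) == 0L) return(NULL)
  x$ct[order(x$replicate)]
}

# per-replicate delta Ct (target - reference), paired by replicate index
.replicate_dct <- function(ct, target, reference, sample) {
  t_ct <- .cell_ct(ct, target, sample)
  r_ct <- .cell_ct(ct, reference, sample)
  if (is.null(r_ct))
    stop("reference gene ", reference, " missing in sample ", sample)
  if (is.null(t_ct)) return(NULL)
  if (length(t_ct) != length(r_ct))
    stop("replicate count mismatch for ", target, " vs ", reference,
         " in sample ", sample)
  t_ct - r_ct
}

#' Welch-t significance of a sample against the calibrator
#'
#' Two-sided Welch t-test on the per-replicate delta-Ct values
#' (target minus reference) of `sample` versus `calibrator`; stars at
#' the raw thresholds 0.05 (`*`) and 0.01 (`**`).
#'
#' @param ct Ct table.
#' @param target,reference Gene labels.
#' @param sample,calibrator Sample labels.
#' @return List `(p_value, stars)`; `p_value` is NA (stars `""`) with
#'   fewer than two replicates or zero variance in both groups.
#' @export
significance <- function(ct, target, reference, sample, calibrator) {
  d_s <- .replicate_dct(ct, target, reference, sample)
  d_c <- .replicate_dct(ct, target, reference, calibrator)
  if (is.null(d_s) || is.null(d_c) || length(d_s) < 2L || length(d_c) < 2L)
    return(list(p_value = NA_real_, stars = ""))
  if (stats::sd(d_s) == 0 && stats::sd(d_c) == 0) {
    p <- if (isTRUE(all.equal(mean(d_s), mean(d_c)))) 1 else 0
  } else {
    p <- stats::t.test(d_s, d_c, var.equal = FALSE)$p.value
  }
  stars <- if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(p_value = p, stars = stars)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample: `dCt = mean Ct(target) - mean Ct(reference)`,
#' `ddCt = dCt(sample) - dCt(calibrator)`, `fold = 2^-ddCt`. The
#' replicate standard deviation of dCt is propagated as the asymmetric
#' range `2^-(ddCt +/- sd)`. Samples where the target was not detected
#' (no Ct rows) are reported with NA fold, not zero.
#'
#' @param ct Ct table (see [validate_ct_table()]).
#' @param target Target gene label.
#' @param reference Reference (housekeeping) gene label.
#' @param calibrator Calibrator sample label (fold = 1 by construction).
#' @return Data frame with one row per sample: `sample`, `gene`,
#'   `delta_ct`, `delta_delta_ct`, `fold`, `fold_lo`, `fold_hi`,
#'   `p_value`, `stars`.
#' @export
delta_delta_ct <- function(ct, target, reference, calibrator) {
  validate_ct_table(ct)
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample not in table")
  d_cal <- .replicate_dct(ct, target, reference, calibrator)
  if (is.null(d_cal)) stop("target ", target, " not measured in calibrator")
  rows <- lapply(samples, function(s) {
    d <- .replicate_dct(ct, target, reference, s)
    if (is.null(d))
      return(data.frame(sample = s, gene = target, delta_ct = NA_real_,
                        delta_delta_ct = NA_real_, fold = NA_real_,
                        fold_lo = NA_real_, fold_hi = NA_real_,
                        p_value = NA_real_, stars = ""))
    dct <- mean(d)
    ddct <- dct - mean(d_cal)
    sd_d <- stats::sd(d)
    sig <- significance(ct, target, reference, s, calibrator)
    data.frame(sample = s, gene = target, delta_ct = dct,
               delta_delta_ct = ddct, fold = 2^(-ddct),
               fold_lo = 2^(-(ddct + sd_d)), fold_hi = 2^(-(ddct - sd_d)),
               p_value = sig$p_value, stars = sig$stars)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
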