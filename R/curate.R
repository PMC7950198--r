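#' Batch-level extraction QC thresholds
#'
#' Defaults follow strict targeted-glycopeptide curation practice: mean mass
#' accuracy within -30 to +30 ppm, mean deviation from the theoretical
#' isotopic pattern (IPQ) below 0.25, and mean signal-to-noise above 15.
#'
#' @param ppm_range length-2 numeric, allowed mean ppm error range.
#' @param ipq_max maximum mean IPQ (fraction).
#' @param snr_min minimum mean signal-to-noise.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(ppm_range = c(-30, 30), ipq_max = 0.25, snr_min = 15) {
  stopifnot(length(ppm_range) == 2, ppm_range[1] < ppm_range[2],
            is.finite(ppm_range), is.finite(ipq_max), is.finite(snr_min))
  list(ppm_range = ppm_range, ipq_max = ipq_max, snr_min = snr_min)
}

#' Batch-level analyte quality control
#'
#' QC operates on the batch, not per sample: for every analyte x charge the
#' QC metrics are averaged across all samples in which the analyte was found
#' (flagged-missing records are excluded from the averages), and the analyte x
#' charge is retained only if all three averages pass the thresholds.
#'
#' @param records integration records from [extract_run()] (rows across all
#'   samples).
#' @param thresholds from [qc_thresholds()].
#' @return data.frame with one row per analyte x charge: `analyte_id`,
#'   `site_group`, `composition`, `charge`, mean `ppm_error`, `ipq`, `snr`,
#'   `n_samples` and logical `retained`. Analytes missing in every sample are
#'   dropped with a message.
#' @export
batch_qc <- function(records, thresholds = qc_thresholds()) {
  if (nrow(records) == 0) stop("no integration records")
  key <- paste(records$analyte_id, records$charge)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    ok <- !d$flag_missing
    data.frame(
      analyte_id = d$analyte_id[1], site_group = d$site_group[1],
      composition = d$composition[1], charge = d$charge[1],
      ppm_error = if (any(ok)) mean(d$ppm_error[ok]) else NA_real_,
      ipq = if (any(ok)) mean(d$ipq[ok]) else NA_real_,
      snr = if (any(ok)) mean(d$snr[ok]) else NA_real_,
      n_samples = sum(ok), stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  absent <- out$n_samples == 0
  if (any(absent)) {
    message(sum(absent), " analyte x charge combination(s) absent in all samples; dropped: ",
            paste(utils::head(paste(out$analyte_id[absent], out$charge[absent], sep = "/z"), 5),
                  collapse = ", "), if (sum(absent) > 5) " ...")
    out <- out[!absent, , drop = FALSE]
  }
  out$retained <- out$ppm_error >= thresholds$ppm_range[1] &
    out$ppm_error <= thresholds$ppm_range[2] &
    out$ipq < thresholds$ipq_max &
    out$snr > thresholds$snr_min
  out$retained[is.na(out$retained)] <- FALSE
  out
}

#' Sum retained charge states per analyte
#'
#' Signals of the retained charge states (typically 3+ and 4+) are summed per
#' sample and analyte. Analytes for which no charge state passed batch QC are
#' absent from the result.
#'
#' @param records integration records across samples.
#' @param qc batch QC table from [batch_qc()].
#' @return data.frame `sample`, `analyte_id`, `site_group`, `composition`,
#'   `area`.
#' @export
sum_charges <- function(records, qc) {
  kept <- qc[qc$retained, c("analyte_id", "charge")]
  if (nrow(kept) == 0) stop("no analyte x charge retained by QC")
  keep <- paste(records$analyte_id, records$charge) %in%
    paste(kept$analyte_id, kept$charge)
  d <- records[keep & !records$flag_missing, , drop = FALSE]
  key <- paste(d$sample, d$analyte_id, sep = "\r")
  out <- do.call(rbind, lapply(split(d, key), function(x) data.frame(
    sample = x$sample[1], analyte_id = x$analyte_id[1],
    site_group = x$site_group[1], composition = x$composition[1],
    area = sum(x$area), stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  out[order(out$sample, out$site_group, out$composition), , drop = FALSE]
}

#' Normalize glycoform areas to total area per glycosylation site
#'
#' Within each sample and site group, charge-summed areas are divided by the
#' site total so glycoform fractions sum to 1, removing between-sample signal
#' intensity variation.
#'
#' @param areas charge-summed areas from [sum_charges()].
#' @param batch optional named vector (sample -> plate/batch id) carried as an
#'   annotation.
#' @return an `abundance_table`: long data.frame `sample`, `site_group`,
#'   `composition`, `fraction`. Sample x site combinations with zero total
#'   area are marked missing (NA fractions) with a warning.
#' @export
normalize_per_site <- function(areas, batch = NULL) {
  key <- paste(areas$sample, areas$site_group, sep = "\r")
  out <- areas
  out$fraction <- NA_real_
  for (k in unique(key)) {
    i <- which(key == k)
    tot <- sum(areas$area[i])
    if (tot > 0) {
      out$fraction[i] <- areas$area[i] / tot
    } else {
      warning("zero total area for sample x site ", sub("\r", " / ", k),
              "; marked missing")
    }
  }
  out <- out[, c("sample", "site_group", "composition", "fraction")]
  structure(out, class = c("abundance_table", "data.frame"), batch = batch)
}
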