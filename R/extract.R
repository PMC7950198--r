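#' Construct an in-memory raw LC-MS run
#'
#' Container for centroided MS1 (and optionally MS2) scans. Scans are sorted
#' by retention time and each scan's m/z array is sorted ascending.
#'
#' @param run_id run identifier.
#' @param ms1 list of scans, each a list with `rt` (minutes), `mz` and
#'   `intensity` numeric vectors.
#' @param ms2 optional list of fragment scans, each with `rt`,
#'   `precursor_mz`, `mz`, `intensity`.
#' @return a `raw_run` object.
#' @export
raw_run <- function(run_id, ms1, ms2 = NULL) {
  rts <- vapply(ms1, `[[`, numeric(1), "rt")
  ms1 <- ms1[order(rts)]
  ms1 <- lapply(ms1, function(s) {
    o <- order(s$mz)
    list(rt = s$rt, mz = s$mz[o], intensity = s$intensity[o])
  })
  if (!is.null(ms2) && length(ms2) > 0) {
    ms2 <- ms2[order(vapply(ms2, `[[`, numeric(1), "rt"))]
  }
  structure(list(run_id = run_id, ms1 = ms1, ms2 = ms2), class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  rng <- range(vapply(x$ms1, `[[`, numeric(1), "rt"))
  cat("Raw run '", x$run_id, "': ", length(x$ms1), " MS1 scans (rt ",
      round(rng[1], 2), "-", round(rng[2], 2), " min), ",
      length(x$ms2), " MS2 scans\n", sep = "")
  invisible(x)
}

#' Glycan oxonium diagnostic fragment ions
#'
#' Singly protonated oxonium ions used to locate glycopeptide elution windows
#' in fragment spectra: HexNAc 204.087, NeuAc-H2O 274.092, NeuAc 292.103,
#' LacNAc (HexNAc+Hex) 366.140, sialylated LacNAc 657.235.
#' @export
diagnostic_ions <- function() {
  c(HexNAc = 204.087, NeuAc_H2O = 274.092, NeuAc = 292.103,
    LacNAc = 366.140, LacNAc_NeuAc = 657.235)
}

#' Screen MS2 scans for glycopeptide diagnostic ions
#'
#' Flags fragment scans in which at least one diagnostic oxonium ion exceeds a
#' relative-intensity floor, and merges flagged retention times into elution
#' windows.
#'
#' @param run a `raw_run` with MS2 scans.
#' @param ions named vector of singly charged diagnostic m/z values.
#' @param tol_ppm matching tolerance in ppm.
#' @param min_rel_intensity floor as a fraction of the scan base peak.
#' @param gap_min maximum rt gap (minutes) bridged within one window.
#' @return data.frame with columns `rt_start`, `rt_end` (empty, with a
#'   warning, if the run has no MS2 scans).
#' @export
screen_diagnostic_ions <- function(run, ions = diagnostic_ions(),
                                   tol_ppm = 20, min_rel_intensity = 0.05,
                                   gap_min = 0.5) {
  empty <- data.frame(rt_start = numeric(0), rt_end = numeric(0))
  if (is.null(run$ms2) || length(run$ms2) == 0) {
    warning("run '", run$run_id, "' has no MS2 scans; nothing to screen")
    return(empty)
  }
  hit_rt <- numeric(0)
  for (s in run$ms2) {
    if (length(s$mz) == 0) next
    floor_int <- min_rel_intensity * max(s$intensity)
    hit <- FALSE
    for (ion in ions) {
      d <- abs(s$mz - ion) / ion * 1e6
      if (any(d <= tol_ppm & s$intensity >= floor_int)) { hit <- TRUE; break }
    }
    if (hit) hit_rt <- c(hit_rt, s$rt)
  }
  if (length(hit_rt) == 0) return(empty)
  hit_rt <- sort(hit_rt)
  brk <- c(0, which(diff(hit_rt) > gap_min), length(hit_rt))
  do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    w <- hit_rt[(brk[i] + 1):brk[i + 1]]
    data.frame(rt_start = min(w), rt_end = max(w))
  }))
}

#' Align retention times against calibrant glycopeptides
#'
#' Detects the XIC apex of each calibrant in the run and fits a monotone
#' piecewise-linear mapping from observed to reference retention times.
#' Outside the calibrated range the end-segment slopes are extended.
#'
#' @param run a `raw_run`.
#' @param calibrants data.frame with columns `label`, `mz`, `ref_rt`.
#' @param tol_ppm m/z matching tolerance for the calibrant XICs.
#' @return an `rt_alignment` with elements `observed`, `reference`, `labels`
#'   and `warp` (the mapping function).
#' @export
align_rt <- function(run, calibrants, tol_ppm = 20) {
  stopifnot(all(c("label", "mz", "ref_rt") %in% names(calibrants)))
  rts <- vapply(run$ms1, `[[`, numeric(1), "rt")
  obs <- rep(NA_real_, nrow(calibrants))
  for (i in seq_len(nrow(calibrants))) {
    xic <- vapply(run$ms1, function(s) {
      m <- abs(s$mz - calibrants$mz[i]) / calibrants$mz[i] * 1e6 <= tol_ppm
      if (any(m)) sum(s$intensity[m]) else 0
    }, numeric(1))
    if (max(xic) > 0) obs[i] <- rts[which.max(xic)]
  }
  ok <- !is.na(obs)
  if (sum(ok) < 2) {
    stop("alignment failure: calibrant(s) not detected: ",
         paste(calibrants$label[!ok], collapse = ", "),
         " (", sum(ok), " of >= 2 required calibrants found)")
  }
  o <- obs[ok][order(obs[ok])]
  r <- calibrants$ref_rt[ok][order(obs[ok])]
  if (any(diff(r) <= 0)) {
    stop("alignment failure: calibrant order in run contradicts reference rts")
  }
  warp <- function(rt) {
    y <- stats::approx(o, r, xout = rt, rule = 1)$y
    lo <- rt < o[1]; hi <- rt > o[length(o)]
    n <- length(o)
    s1 <- (r[2] - r[1]) / (o[2] - o[1])
    s2 <- (r[n] - r[n - 1]) / (o[n] - o[n - 1])
    y[lo] <- r[1] + s1 * (rt[lo] - o[1])
    y[hi] <- r[n] + s2 * (rt[hi] - o[n])
    y
  }
  structure(list(observed = o, reference = r,
                 labels = calibrants$label[ok][order(obs[ok])],
                 residuals = r - o, warp = warp),
            class = "rt_alignment")
}

#' Select isotopologues covering the theoretical envelope
#'
#' Adds isotopologues in order of decreasing theoretical abundance until the
#' cumulative fraction reaches `coverage` (default 90% of the theoretical
#' isotopic pattern). When `cap` is set, only the first `cap` isotopologues
#' (offsets `0 .. cap-1`) are eligible regardless of coverage — used where a
#' coeluting near-isobaric peptide overlaps the higher isotopes.
#'
#' @param pattern an `isotope_pattern`.
#' @param coverage target cumulative fraction in (0, 1].
#' @param cap optional integer cap on the number of leading isotopologues.
#' @return sorted integer offsets.
#' @export
select_isotopologues <- function(pattern, coverage = 0.90, cap = NULL) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    stop("`coverage` must be in (0, 1]")
  }
  offsets <- pattern$offsets
  fr <- pattern$fractions
  if (!is.null(cap) && !is.na(cap)) {
    keep <- offsets < cap
    offsets <- offsets[keep]; fr <- fr[keep]
  }
  o <- order(fr, decreasing = TRUE)
  csum <- cumsum(fr[o])
  k <- which(csum >= coverage)
  n_take <- if (length(k) == 0) length(o) else k[1]
  sort(offsets[o[seq_len(n_take)]])
}

#' Targeted isotopologue integration of one analyte
#'
#' Builds per-isotopologue extracted ion chromatograms within a ppm tolerance,
#' integrates them over the retention-time window by the trapezoid rule, and
#' computes the three extraction QC metrics: `ppm_error` (intensity-weighted
#' mean apex mass error), `ipq` (L1 deviation of the observed from the
#' theoretical isotopologue envelope, normalized over the selected offsets)
#' and `snr` (apex intensity over a robust MAD-based noise estimate from
#' flanking m/z bands).
#'
#' @param run a `raw_run` (retention times already aligned if applicable).
#' @param target list with `analyte_id`, `site_group`, `composition`, `charge`,
#'   `mz0` (monoisotopic m/z), `offsets`, `fractions` (theoretical pattern over
#'   all modeled offsets), `tol_ppm`, `rt_window` (c(lo, hi) minutes).
#' @param flank_mz flanking noise band, Th outside the envelope (c(near, far)).
#' @return one-row data.frame (an integration record): `analyte_id`,
#'   `site_group`, `composition`, `charge`, `area`, `ppm_error`, `ipq`, `snr`,
#'   `flag_missing`.
#' @export
integrate_analyte <- function(run, target, flank_mz = c(0.5, 2)) {
  stopifnot(target$tol_ppm > 0)
  rts <- vapply(run$ms1, `[[`, numeric(1), "rt")
  sel <- which(rts >= target$rt_window[1] & rts <= target$rt_window[2])
  rec <- data.frame(
    analyte_id = target$analyte_id, site_group = target$site_group,
    composition = target$composition, charge = target$charge,
    area = 0, ppm_error = NA_real_, ipq = NA_real_, snr = NA_real_,
    flag_missing = TRUE, stringsAsFactors = FALSE
  )
  if (length(sel) < 2) return(rec)

  z <- target$charge
  iso_mz <- target$mz0 + target$offsets * .ISOTOPE_SPACING / z
  n_off <- length(iso_mz)
  xic <- matrix(0, nrow = length(sel), ncol = n_off)
  obs_mz <- matrix(NA_real_, nrow = length(sel), ncol = n_off)
  for (si in seq_along(sel)) {
    s <- run$ms1[[sel[si]]]
    for (k in seq_len(n_off)) {
      m <- abs(s$mz - iso_mz[k]) / iso_mz[k] * 1e6 <= target$tol_ppm
      if (any(m)) {
        xic[si, k] <- sum(s$intensity[m])
        obs_mz[si, k] <- sum(s$mz[m] * s$intensity[m]) / sum(s$intensity[m])
      }
    }
  }
  rt_w <- rts[sel]
  trapz <- function(y) sum(diff(rt_w) * (y[-1] + y[-length(y)]) / 2)
  areas <- apply(xic, 2, trapz)
  total <- sum(areas)
  if (total <= 0) return(rec)

  theo <- target$fractions[match(target$offsets, seq_along(target$fractions) - 1L)]
  theo <- theo / sum(theo)
  obs_fr <- areas / total
  ipq <- sum(abs(obs_fr - theo))

  # ppm error: weighted mean of apex mass errors across isotopologues
  apex_idx <- apply(xic, 2, which.max)
  apex_int <- xic[cbind(apex_idx, seq_len(n_off))]
  ppm_k <- (obs_mz[cbind(apex_idx, seq_len(n_off))] - iso_mz) / iso_mz * 1e6
  wok <- apex_int > 0 & !is.na(ppm_k)
  ppm <- if (any(wok)) sum(ppm_k[wok] * apex_int[wok]) / sum(apex_int[wok]) else NA_real_

  # S/N: apex peak height over a robust MAD noise estimate sampled in the
  # flanking m/z bands at half-integer positions of the isotopologue comb,
  # so that near-isobaric neighbour glycoforms (which sit on integer-Da
  # offsets of the same comb) do not masquerade as noise
  spacing <- .ISOTOPE_SPACING / z
  n_flank <- max(2L, ceiling(flank_mz[2] / spacing))
  flank_off <- c(seq(-n_flank, -1L), max(target$offsets) + seq(1L, n_flank)) + 0.5
  flank_pos <- target$mz0 + flank_off * spacing
  noise_int <- unlist(lapply(sel, function(j) {
    s <- run$ms1[[j]]
    unlist(lapply(flank_pos, function(fp) {
      m <- abs(s$mz - fp) / fp * 1e6 <= target$tol_ppm
      if (any(m)) sum(s$intensity[m]) else NULL
    }))
  }))
  peak_apex <- max(xic)
  noise <- if (length(noise_int) >= 3) stats::mad(noise_int) else 0
  snr <- if (noise > 0) peak_apex / noise else Inf

  rec$area <- total
  rec$ppm_error <- ppm
  rec$ipq <- ipq
  rec$snr <- snr
  rec$flag_missing <- FALSE
  rec
}

#' Build extraction targets from a glycopeptide library
#'
#' One target per analyte x charge state, with isotopologues chosen by
#' [select_isotopologues()] (>= `coverage` of the theoretical pattern, subject
#' to the per-analyte isotopologue cap) and a calibrant-anchored retention-time
#' window around the site's expected elution time.
#'
#' @param library a `glycopeptide_library`.
#' @param site_rt named numeric vector: expected (reference) apex rt in
#'   minutes per site group.
#' @param tol_ppm extraction m/z tolerance (ppm).
#' @param coverage theoretical-pattern coverage.
#' @param rt_halfwidth window half-width in minutes.
#' @param n_iso isotopologues modeled per analyte.
#' @return list of targets for [integrate_analyte()].
#' @export
make_extraction_targets <- function(library, site_rt, tol_ppm = 20,
                                    coverage = 0.90, rt_halfwidth = 0.5,
                                    n_iso = 10L) {
  missing_rt <- setdiff(unique(library$site_group), names(site_rt))
  if (length(missing_rt) > 0) {
    stop("no expected rt for site group(s): ", paste(missing_rt, collapse = ", "))
  }
  targets <- list()
  for (i in seq_len(nrow(library))) {
    pat <- analyte_isotope_pattern(library$peptide[i], library$composition[i],
                                   n_iso = n_iso)
    offs <- select_isotopologues(pat, coverage = coverage,
                                 cap = library$isotopologue_cap[i])
    rt0 <- site_rt[[library$site_group[i]]]
    for (z in library$charges[[i]]) {
      targets[[length(targets) + 1L]] <- list(
        analyte_id = paste0(library$site_group[i], " ", library$composition[i]),
        site_group = library$site_group[i],
        composition = library$composition[i],
        charge = z,
        mz0 = analyte_mz(library$analyte_mass[i], z),
        offsets = offs,
        fractions = pat$fractions,
        tol_ppm = tol_ppm,
        rt_window = c(rt0 - rt_halfwidth, rt0 + rt_halfwidth)
      )
    }
  }
  targets
}

#' Extract all targets from a run
#'
#' Optionally warps scan retention times through an [align_rt()] model, then
#' integrates every target.
#'
#' @param run a `raw_run`.
#' @param targets list from [make_extraction_targets()].
#' @param alignment optional `rt_alignment`.
#' @param sample_id sample identifier recorded on every integration record
#'   (default the run id).
#' @return data.frame of integration records (one row per analyte x charge).
#' @export
extract_run <- function(run, targets, alignment = NULL, sample_id = run$run_id) {
  if (!is.null(alignment)) {
    run$ms1 <- lapply(run$ms1, function(s) {
      s$rt <- alignment$warp(s$rt); s
    })
  }
  recs <- do.call(rbind, lapply(targets, function(t) integrate_analyte(run, t)))
  cbind(data.frame(sample = sample_id, stringsAsFactors = FALSE), recs)
}
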