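#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every Lys/Arg, including before proline
#' (the Trypsin/P dialect), and enumerates peptides with up to `max_missed`
#' missed cleavages.
#'
#' @param sequence uppercase amino-acid string (20-letter alphabet).
#' @param max_missed maximum number of missed cleavages (>= 0).
#' @return data.frame with columns `sequence`, `start`, `end` (1-based,
#'   inclusive) and `missed_cleavages`, ordered by start position then length.
#' @examples
#' digest("AKRCD", max_missed = 1)
#' @export
digest <- function(sequence, max_missed = 0L) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("`sequence` must be a non-empty amino-acid string")
  }
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), .AA_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  if (max_missed < 0) stop("`max_missed` must be >= 0")
  n <- length(aa)
  # cleavage boundaries: positions after which the backbone is cut
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  bounds <- c(0L, cuts, n)          # peptide i spans bounds[i]+1 .. bounds[i+1]
  n_pep <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_pep)) {
    for (mc in 0:min(max_missed, n_pep - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + 1L + mc]
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, start, end),
        start = start, end = end, missed_cleavages = mc,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Elemental composition of a (modified) tryptic peptide
#'
#' Residue formulas plus water, plus one carbamidomethyl group per cysteine
#' when `cam = TRUE` (iodoacetamide alkylation is a fixed modification in this
#' workflow) and minus ammonia when the N-terminal glutamine has cyclized to
#' pyroglutamate.
#'
#' @param sequence amino-acid string.
#' @param cam logical; carbamidomethylate all cysteines (default TRUE).
#' @param pyroglu logical; N-terminal pyroglutamate (loss of NH3).
#' @return named element-count vector.
#' @export
peptide_formula <- function(sequence, cam = TRUE, pyroglu = FALSE) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), .AA_ALPHABET)
  if (length(aa) == 0 || length(bad) > 0) {
    stop("invalid residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(aa, levels = .AA_ALPHABET))
  f <- .formula_zero()
  for (res in names(counts)[counts > 0]) {
    f <- .formula_add(f, counts[[res]] * .RESIDUE_FORMULA[[res]])
  }
  f <- .formula_add(f, .WATER_FORMULA)
  if (cam) f <- .formula_add(f, sum(aa == "C") * .CAM_FORMULA)
  if (pyroglu) {
    if (aa[1] != "Q") stop("pyroglutamate requires an N-terminal glutamine")
    f <- .formula_add(f, .PYROGLU_FORMULA)
  }
  f
}

#' Monoisotopic peptide mass
#'
#' @inheritParams peptide_formula
#' @return monoisotopic mass in Da.
#' @examples
#' peptide_mass("GK")
#' peptide_mass("QDQCIYNTTYLNVQR") # site-IV AGP1 peptide, CAM-Cys: 1914.889
#' @export
peptide_mass <- function(sequence, cam = TRUE, pyroglu = FALSE) {
  .formula_mass(peptide_formula(sequence, cam = cam, pyroglu = pyroglu))
}

#' Locate N-glycosylation sequons
#'
#' Finds all Asn-X-Ser/Thr/Cys motifs with X != Pro.
#'
#' @param sequence amino-acid string.
#' @return integer vector of 1-based Asn positions.
#' @export
find_sequons <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  pos <- which(aa == "N")
  pos <- pos[pos + 2 <= n]
  pos[aa[pos + 1] != "P" & aa[pos + 2] %in% c("S", "T", "C")]
}
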