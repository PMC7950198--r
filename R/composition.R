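#' Glycan compositions
#'
#' N-glycan compositions are written in the compact `N#H#S#[F#]` nomenclature:
#' counts of HexNAc (N), hexose (H), N-acetylneuraminic acid (S) and
#' deoxyhexose/fucose (F). `N5H6S3` is a triantennary glycan with three sialic
#' acids; a trailing `F1` marks a single fucose (`N4H5S2F1`).
#'
#' @param label a composition label such as `"N5H6S3"` or `"N4H5S2F1"`.
#' @return `parse_composition()` returns a `glycan_composition`: a list with
#'   integer counts `N`, `H`, `S`, `F`.
#' @examples
#' parse_composition("N5H6S3")
#' format_composition(glycan_composition(N = 4, H = 5, S = 2, F = 1))
#' @export
parse_composition <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  m <- regmatches(label, regexec("^N([0-9]+)H([0-9]+)S([0-9]+)(?:F([0-9]+))?$", label))[[1]]
  if (length(m) == 0) {
    # point at the first token that breaks the N..H..S..[F..] grammar
    bad <- regmatches(label, regexpr("[^NHSF0-9]|^[^N]", label))
    stop("malformed composition label '", label, "'",
         if (length(bad) > 0 && nzchar(bad)) paste0(" (offending token '", bad, "')"))
  }
  counts <- as.integer(m[2:5])
  counts[is.na(counts)] <- 0L
  glycan_composition(N = counts[1], H = counts[2], S = counts[3], F = counts[4])
}

#' @rdname parse_composition
#' @param N,H,S,F non-negative integer monosaccharide counts.
#' @export
glycan_composition <- function(N = 0L, H = 0L, S = 0L, F = 0L) {
  counts <- c(N = N, H = H, S = S, F = F)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("monosaccharide counts must be non-negative integers")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "glycan_composition")
}

#' @rdname parse_composition
#' @param comp a `glycan_composition`.
#' @export
format_composition <- function(comp) {
  comp <- as_composition(comp)
  paste0("N", comp$N, "H", comp$H, "S", comp$S,
         if (comp$F > 0) paste0("F", comp$F) else "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format_composition(x), "\n")
  invisible(x)
}

# Accept either a label or an already-parsed composition.
#' @keywords internal
as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  stop("expected a glycan_composition or a composition label")
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of dehydrated monosaccharide residue masses (HexNAc 203.07937,
#' Hex 162.05282, NeuAc 291.09542, dHex 146.05791 Da); this is the mass the
#' glycan adds to a peptide backbone.
#'
#' @param comp a `glycan_composition` or composition label.
#' @return monoisotopic residue mass in Da.
#' @examples
#' glycan_mass("N5H6S3")
#' @export
glycan_mass <- function(comp) {
  .formula_mass(glycan_formula(comp))
}

#' @rdname glycan_mass
#' @return `glycan_formula()` returns the elemental composition as a named
#'   count vector.
#' @export
glycan_formula <- function(comp) {
  comp <- as_composition(comp)
  .formula_add(
    comp$N * .GLYCAN_FORMULA$HexNAc,
    comp$H * .GLYCAN_FORMULA$Hex,
    comp$S * .GLYCAN_FORMULA$NeuAc,
    comp$F * .GLYCAN_FORMULA$dHex
  )
}
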