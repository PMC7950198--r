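#' Theoretical isotopic pattern of a molecule
#'
#' Computes the aggregated isotopologue distribution of a molecule by iterated
#' convolution of per-element isotope distributions. Isotopologues are
#' aggregated by neutron-number offset from the monoisotopic peak (nominal-mass
#' aggregation, i.e. no fine structure), which is the resolution regime of a
#' Q-TOF and the convention of targeted glycopeptide extraction tools.
#'
#' @param elements named integer vector of element counts (elements C, H, N, O,
#'   S), e.g. `c(C = 79, H = 123, N = 23, O = 27, S = 1)`.
#' @param n_iso number of isotopologues to keep (offsets `0 .. n_iso - 1`).
#'   The truncated pattern is renormalized to sum to 1.
#' @return An object of class `isotope_pattern`: a list with integer `offsets`
#'   and numeric `fractions` (non-negative, summing to 1), where offset 0 is
#'   the monoisotopic peak.
#' @examples
#' theoretical_isotope_pattern(c(C = 1), n_iso = 2)
#' @export
theoretical_isotope_pattern <- function(elements, n_iso = 10L) {
  if (!is.numeric(n_iso) || length(n_iso) != 1 || n_iso < 1) {
    stop("`n_iso` must be a single integer >= 1")
  }
  n_iso <- as.integer(n_iso)
  elements <- elements[elements != 0]
  if (any(elements < 0)) stop("element counts must be >= 0")
  unknown <- setdiff(names(elements), names(.ELEMENT_ISOTOPES))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }

  dist <- 1 # distribution of the empty molecule: all mass at offset 0
  for (el in names(elements)) {
    pow <- .dist_power(.ELEMENT_ISOTOPES[[el]], elements[[el]], n_iso)
    dist <- .dist_convolve(dist, pow, n_iso)
  }
  dist <- dist / sum(dist)
  structure(
    list(offsets = seq_along(dist) - 1L, fractions = unname(dist)),
    class = "isotope_pattern"
  )
}

# Convolution of two offset-indexed distributions, truncated to n_iso terms.
.dist_convolve <- function(a, b, n_iso) {
  n <- min(n_iso, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# dist^k by binary exponentiation (k atoms of one element), truncated.
.dist_power <- function(dist, k, n_iso) {
  result <- 1
  base <- dist
  while (k > 0) {
    if (k %% 2 == 1) result <- .dist_convolve(result, base, n_iso)
    k <- k %/% 2
    if (k > 0) base <- .dist_convolve(base, base, n_iso)
  }
  result
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("Isotope pattern (", length(x$offsets), " isotopologues)\n", sep = "")
  print(round(stats::setNames(x$fractions, paste0("+", x$offsets)), 5))
  invisible(x)
}
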