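#' Branching class of a complex N-glycan
#'
#' The number of antennae of a complex N-glycan is inferred from the HexNAc
#' count: two core HexNAc plus one per antenna, capped at four antennae.
#' HexNAc in excess of the tetraantennary count is attributed to
#' poly-N-acetyllactosamine (LacNAc) repeats, so N7H8S4 classifies as a
#' tetraantennary glycan with one LacNAc repeat.
#'
#' @param comp a `glycan_composition` or composition label.
#' @return list with `class` (`"BiAnt"`, `"TriAnt"` or `"TetraAnt"`),
#'   `antennae` (2-4) and `lacnac_repeats` (>= 0).
#' @examples
#' antennarity("N5H6S3") # triantennary
#' @export
antennarity <- function(comp) {
  comp <- as_composition(comp)
  if (comp$N < 4) {
    stop("composition ", format_composition(comp),
         " has fewer than 4 HexNAc; not a classifiable complex N-glycan")
  }
  antennae <- min(comp$N - 2L, 4L)
  list(
    class = c("BiAnt", "TriAnt", "TetraAnt")[min(antennae, 4L) - 1L],
    antennae = antennae,
    lacnac_repeats = max(0L, comp$N - 6L)
  )
}

#' Sialylation class (sialic acids per antennary galactose)
#'
#' Sialic acids attach to galactosylated antennae, so the degree of
#' sialylation is expressed as the ratio of NeuAc count to the number of
#' antennary galactoses, taken as the (capped) antenna count, and reduced to
#' lowest terms: N5H6S3 is fully sialylated (`S1/1`), N6H7S1 carries one of
#' four possible sialic acids (`S1/4`).
#'
#' @param comp a `glycan_composition` or composition label.
#' @return list with `label` (e.g. `"S3/4"`, or `"S0"` for asialo), `num`,
#'   `den` (reduced), and `value` (the ratio).
#' @examples
#' sialylation_class("N6H7S3") # S3/4
#' @export
sialylation_class <- function(comp) {
  comp <- as_composition(comp)
  den <- antennarity(comp)$antennae
  if (comp$S > den) {
    stop("composition ", format_composition(comp), " carries ", comp$S,
         " sialic acids on ", den, " antennae (oversialylated)")
  }
  if (comp$S == 0) {
    return(list(label = "S0", num = 0L, den = den, value = 0))
  }
  g <- .gcd(comp$S, den)
  num <- comp$S %/% g
  d <- den %/% g
  list(label = paste0("S", num, "/", d), num = num, den = d, value = num / d)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Enumerate derived glycosylation traits
#'
#' For each quantified glycosylation site group, traits are defined by
#' grouping the site's glycan compositions by shared structural features:
#' one branching trait per branching class present (`BiAnt`, `TriAnt`,
#' `TetraAnt`), one fucosylation trait `F` when any member glycoform is
#' fucosylated (members: all fucosylated compositions), and one sialylation
#' trait per distinct sialic-per-galactose class present (`S1/1`, `S3/4`, ...,
#' ordered by decreasing ratio). Trait labels combine site group and feature,
#' e.g. `"II_12 TriAnt"`. The bundled 96-glycoform AGP library yields 63
#' traits.
#'
#' @param library a `glycopeptide_library`.
#' @return A `trait_definitions` data.frame with columns `trait`,
#'   `site_group`, `kind` (`branching`/`fucosylation`/`sialylation`) and a
#'   list column `members` of composition labels.
#' @examples
#' defs <- enumerate_traits(agp_glycoform_library())
#' nrow(defs) # 63
#' @export
enumerate_traits <- function(library) {
  if (nrow(library) == 0) stop("empty library")
  out <- list()
  for (sg in unique(library$site_group)) {
    comps <- library$composition[library$site_group == sg]
    if (length(comps) == 0) stop("site group ", sg, " has no compositions")
    ant <- vapply(comps, function(x) antennarity(x)$class, "")
    for (cls in c("BiAnt", "TriAnt", "TetraAnt")) {
      if (any(ant == cls)) {
        out[[length(out) + 1L]] <- list(
          trait = paste(sg, cls), site_group = sg, kind = "branching",
          members = comps[ant == cls])
      }
    }
    fuc <- vapply(comps, function(x) as_composition(x)$F > 0, NA)
    if (any(fuc)) {
      out[[length(out) + 1L]] <- list(
        trait = paste(sg, "F"), site_group = sg, kind = "fucosylation",
        members = comps[fuc])
    }
    sia <- lapply(comps, sialylation_class)
    lab <- vapply(sia, `[[`, "", "label")
    val <- vapply(sia, `[[`, numeric(1), "value")
    for (sl in unique(lab[order(-val)])) {
      out[[length(out) + 1L]] <- list(
        trait = paste(sg, sl), site_group = sg, kind = "sialylation",
        members = comps[lab == sl])
    }
  }
  defs <- data.frame(
    trait = vapply(out, `[[`, "", "trait"),
    site_group = vapply(out, `[[`, "", "site_group"),
    kind = vapply(out, `[[`, "", "kind"),
    stringsAsFactors = FALSE
  )
  defs$members <- lapply(out, `[[`, "members")
  structure(defs, class = c("trait_definitions", "data.frame"),
            library_compositions = paste(library$site_group, library$composition))
}

#' Compute derived trait values
#'
#' A trait value is the sum of its member glycoform fractions within the
#' site, per sample. A sample missing any member fraction gets a missing
#' trait value (no zero-imputation).
#'
#' @param ab an `abundance_table` (long format: `sample`, `site_group`,
#'   `composition`, `fraction`), see [normalize_per_site()].
#' @param defs `trait_definitions` from [enumerate_traits()].
#' @return A `trait_table`: data.frame with a `sample` column and one column
#'   per trait (values in `[0, 1]` or `NA`). A member glycoform that belongs
#'   to the library but was removed from the table (e.g. by batch QC) makes
#'   its traits missing for every sample, with a message — the behaviour that
#'   shrinks a trait panel when fewer glycopeptides pass quantification QC. A
#'   definition referencing a composition outside the library is an error.
#' @export
compute_traits <- function(ab, defs) {
  samples <- unique(ab$sample)
  known <- unique(paste(ab$site_group, ab$composition))
  registry <- attr(defs, "library_compositions") %||% known
  res <- data.frame(sample = samples, stringsAsFactors = FALSE,
                    check.names = FALSE)
  dropped <- character(0)
  for (i in seq_len(nrow(defs))) {
    members <- defs$members[[i]]
    sg <- defs$site_group[i]
    keys <- paste(sg, members)
    unknown <- setdiff(keys, registry)
    if (length(unknown) > 0) {
      stop("trait '", defs$trait[i], "' references composition(s) absent ",
           "from the library: ", paste(unknown, collapse = ", "))
    }
    if (length(setdiff(keys, known)) > 0) {
      dropped <- c(dropped, defs$trait[i])
      res[[defs$trait[i]]] <- NA_real_
      next
    }
    sub <- ab[ab$site_group == sg & ab$composition %in% members, ]
    agg <- tapply(sub$fraction, factor(sub$sample, levels = samples),
                  function(x) if (length(x) < length(members) || anyNA(x)) NA_real_ else sum(x))
    res[[defs$trait[i]]] <- as.numeric(agg)
  }
  if (length(dropped) > 0) {
    message(length(dropped), " trait(s) missing because member glycoforms ",
            "were not quantified: ", paste(dropped, collapse = ", "))
  }
  structure(res, class = c("trait_table", "data.frame"), defs = defs)
}
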