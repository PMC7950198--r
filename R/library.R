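#' Read AGP protein isoforms from FASTA
#'
#' Headers carry `key=value` metadata: `protein` (AGP1/AGP2), `variant`
#' (F1/F2/S/A), `signal` (signal-peptide length) and `sites` (comma-separated
#' N-glycosylation positions in UniProt precursor coordinates, as
#' conventionally printed: Asn-33/-56/-72/-93/-103). Sequences are precursor
#' sequences; the signal peptide is stripped on import and site positions are
#' converted to mature coordinates, keeping the precursor numbers as labels.
#'
#' @param path FASTA file path.
#' @return list of isoforms, each a list with `name`, `protein`, `variant`,
#'   `mature_sequence`, `site_positions` (mature), `site_labels` (precursor
#'   numbering, e.g. "N93").
#' @export
read_isoform_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no FASTA records in ", path)
  ends <- c(idx[-1] - 1L, length(lines))
  isoforms <- lapply(seq_along(idx), function(i) {
    header <- sub("^>", "", lines[idx[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    name <- toks[1]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    meta <- stats::setNames(
      sub("^[^=]+=", "", kv),
      sub("=.*$", "", kv)
    )
    seq <- paste(lines[(idx[i] + 1):ends[i]], collapse = "")
    seq <- gsub("\\s", "", seq)
    signal_len <- as.integer(meta[["signal"]])
    sites_prec <- as.integer(strsplit(meta[["sites"]], ",")[[1]])
    mature <- substr(seq, signal_len + 1L, nchar(seq))
    sites_mat <- sites_prec - signal_len
    iso <- list(
      name = name,
      protein = meta[["protein"]],
      variant = meta[["variant"]],
      accession = if ("accession" %in% names(meta)) meta[["accession"]] else NA_character_,
      mature_sequence = mature,
      site_positions = sites_mat,
      site_labels = paste0("N", sites_prec)
    )
    # every declared site must carry an N-X-S/T/C sequon, X != P
    sequons <- find_sequons(mature)
    missing <- setdiff(sites_mat, sequons)
    if (length(missing) > 0) {
      stop("isoform ", name, ": declared site(s) without sequon at mature position(s) ",
           paste(missing, collapse = ", "))
    }
    iso
  })
  names(isoforms) <- vapply(isoforms, `[[`, "", "name")
  isoforms
}

#' Bundled AGP isoforms
#'
#' The AGP1 genetic variants (F1: Gln-38/Val-174, F2: Gln-38/Met-174,
#' S: Arg-38/Val-174, precursor numbering) and AGP2. The AGP2 entry is a
#' synthetic reconstruction: its five tryptic glycopeptide regions match the
#' reported AGP2 sequences, the backbone elsewhere follows AGP1 (see the
#' bundled FASTA header).
#'
#' @return list of isoforms (see [read_isoform_fasta()]).
#' @export
agp_isoforms <- function() {
  read_isoform_fasta(system.file("extdata", "agp_isoforms.fasta",
                                 package = "agpglyco", mustWork = TRUE))
}

# roman numeral per site rank (sites ordered along the backbone)
.SITE_ROMAN <- c("I", "II", "III", "IV", "V")

#' Enumerate sequon-bearing tryptic glycopeptide groups
#'
#' Digests each isoform (Trypsin/P, no missed cleavages), locates the tryptic
#' peptide covering each declared N-glycosylation site, and collapses identical
#' peptide sequences across isoforms. Groups are labelled by the site's roman
#' numeral plus a subscript for the protein(s) carrying the peptide: `_1` for
#' AGP1-only, `_2` for AGP2-only, `_12` for peptides shared by both (written
#' `I_1`, `I_12`, ... for file-format safety).
#'
#' Groups whose peptide mass falls inside the low isotopologues of a lighter
#' same-site peptide (mass difference below ~6 Da, causing envelope overlap of
#' coeluting analytes) are flagged `quantified = FALSE`; the lighter peptide is
#' kept with an isotopologue cap covering only the non-overlapping isotopes.
#' For AGP this excludes IV_2 (1919.858 Da, ~5 Da above IV_1 at 1914.889 Da)
#' and caps IV_1 at six isotopes, leaving 7 quantified groups out of 8.
#'
#' @param isoforms list of isoforms from [read_isoform_fasta()].
#' @return data.frame with one row per group: `site_group`, `site_label`,
#'   `peptide`, `start`, `end` (mature coordinates of one carrier), `proteins`,
#'   `cam_count`, `peptide_mass`, `quantified`, `isotopologue_cap`.
#' @export
enumerate_glycopeptide_groups <- function(isoforms) {
  rows <- list()
  for (iso in isoforms) {
    peps <- digest(iso$mature_sequence, max_missed = 0L)
    for (k in seq_along(iso$site_positions)) {
      pos <- iso$site_positions[k]
      hit <- peps[peps$start <= pos & peps$end >= pos, , drop = FALSE]
      if (nrow(hit) != 1) {
        stop("isoform ", iso$name, ": no unique tryptic peptide covers site ",
             iso$site_labels[k])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site_rank = k, site_label = iso$site_labels[k],
        peptide = hit$sequence, start = hit$start, end = hit$end,
        protein = iso$protein, stringsAsFactors = FALSE
      )
    }
  }
  all <- do.call(rbind, rows)
  key <- paste(all$site_rank, all$peptide)
  groups <- do.call(rbind, lapply(split(all, key), function(d) {
    prot <- sort(unique(d$protein))
    sub <- paste(ifelse(prot == "AGP1", "1", "2"), collapse = "")
    data.frame(
      site_group = paste0(.SITE_ROMAN[d$site_rank[1]], "_", sub),
      site_label = d$site_label[1],
      peptide = d$peptide[1], start = d$start[1], end = d$end[1],
      proteins = paste(prot, collapse = ";"),
      cam_count = sum(strsplit(d$peptide[1], "")[[1]] == "C"),
      peptide_mass = peptide_mass(d$peptide[1]),
      stringsAsFactors = FALSE
    )
  }))
  groups <- groups[order(match(sub("_.*", "", groups$site_group), .SITE_ROMAN),
                         groups$site_group), , drop = FALSE]
  rownames(groups) <- NULL

  groups$quantified <- TRUE
  groups$isotopologue_cap <- NA_integer_
  for (lab in unique(groups$site_label)) {
    i <- which(groups$site_label == lab)
    if (length(i) < 2) next
    for (a in i) for (b in i) {
      dm <- groups$peptide_mass[b] - groups$peptide_mass[a]
      if (a != b && dm > 0 && dm < 6) {
        # heavier peptide's monoisotopic peak lands near isotope round(dm)+1
        # of the lighter one: drop the heavier, cap the lighter below that
        groups$quantified[b] <- FALSE
        groups$isotopologue_cap[a] <- as.integer(round(dm) + 1L)
      }
    }
  }
  groups
}

#' Build the glycopeptide analyte library
#'
#' Combines the tryptic glycopeptide groups with per-site glycan composition
#' sets to produce one analyte per (site group, composition), with monoisotopic
#' masses, m/z per charge state and elemental compositions.
#'
#' @param isoforms isoform list, default the bundled AGP isoforms.
#' @param composition_tsv path to a TSV with columns `site_group`,
#'   `peptide_sequence`, `composition_label`, `charges` (e.g. `"3;4"`) and
#'   `isotopologue_cap`; default the bundled AGP glycoform set (96 glycoforms
#'   across the 7 quantified groups).
#' @return A `glycopeptide_library`: data.frame with one row per analyte and
#'   columns `site_group`, `site_label`, `peptide`, `composition`,
#'   `peptide_mass`, `glycan_mass`, `analyte_mass`, `charges` (list column of
#'   integer vectors), `isotopologue_cap`, plus attribute `groups` (the full
#'   8-group table including unquantified groups).
#' @examples
#' lib <- agp_glycoform_library()
#' nrow(lib)      # 96 glycoforms
#' table(lib$site_group)
#' @export
build_glycopeptide_library <- function(isoforms = agp_isoforms(),
                                       composition_tsv = NULL) {
  if (is.null(composition_tsv)) {
    composition_tsv <- system.file("extdata", "agp_glycoform_library.tsv",
                                   package = "agpglyco", mustWork = TRUE)
  }
  groups <- enumerate_glycopeptide_groups(isoforms)
  comp <- utils::read.delim(composition_tsv, stringsAsFactors = FALSE)
  need <- c("site_group", "peptide_sequence", "composition_label", "charges")
  miss <- setdiff(need, names(comp))
  if (length(miss) > 0) stop("library TSV lacks column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(comp$site_group, groups$site_group)
  if (length(unknown) > 0) {
    stop("library TSV references undefined site group(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  g <- groups[match(comp$site_group, groups$site_group), ]
  if (any(comp$peptide_sequence != g$peptide)) {
    bad <- comp$site_group[comp$peptide_sequence != g$peptide]
    stop("library TSV peptide differs from digested peptide for group(s): ",
         paste(unique(bad), collapse = ", "))
  }
  cap <- if ("isotopologue_cap" %in% names(comp)) {
    suppressWarnings(as.integer(comp$isotopologue_cap))
  } else {
    g$isotopologue_cap
  }
  lib <- data.frame(
    site_group = comp$site_group,
    site_label = g$site_label,
    peptide = comp$peptide_sequence,
    composition = comp$composition_label,
    stringsAsFactors = FALSE
  )
  lib$peptide_mass <- vapply(lib$peptide, peptide_mass, numeric(1))
  lib$glycan_mass <- vapply(lib$composition, glycan_mass, numeric(1))
  lib$analyte_mass <- lib$peptide_mass + lib$glycan_mass
  lib$charges <- lapply(strsplit(comp$charges, ";"), as.integer)
  lib$isotopologue_cap <- cap
  dup <- duplicated(paste(lib$site_group, lib$composition))
  if (any(dup)) {
    stop("duplicate (site group, composition) in library: ",
         paste(unique(paste(lib$site_group[dup], lib$composition[dup])), collapse = ", "))
  }
  structure(lib, class = c("glycopeptide_library", "data.frame"),
            groups = groups)
}

#' @rdname build_glycopeptide_library
#' @export
agp_glycoform_library <- function() {
  build_glycopeptide_library()
}

#' @export
print.glycopeptide_library <- function(x, ...) {
  grp <- attr(x, "groups")
  cat("Glycopeptide library: ", nrow(x), " analytes across ",
      length(unique(x$site_group)), " quantified site groups\n", sep = "")
  if (!is.null(grp)) {
    cat("Site groups (", nrow(grp), " total, ",
        sum(grp$quantified), " quantified):\n", sep = "")
    print(grp[, c("site_group", "site_label", "peptide", "peptide_mass", "quantified")])
  }
  invisible(x)
}

#' Mass-to-charge ratio of a protonated analyte
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param z positive integer charge (number of protons).
#' @return m/z.
#' @examples
#' analyte_mz(3000, 3)
#' @export
analyte_mz <- function(mass, z) {
  if (any(z <= 0) || any(z != round(z))) stop("`z` must be a positive integer")
  (mass + z * .PROTON_MASS) / z
}

#' Theoretical isotope pattern of a library analyte
#'
#' @param peptide peptide backbone sequence (CAM-Cys assumed fixed).
#' @param composition glycan composition (label or object).
#' @param n_iso isotopologues to model.
#' @param pyroglu N-terminal pyroglutamate flag.
#' @return an `isotope_pattern`.
#' @export
analyte_isotope_pattern <- function(peptide, composition, n_iso = 10L,
                                    pyroglu = FALSE) {
  f <- .formula_add(peptide_formula(peptide, cam = TRUE, pyroglu = pyroglu),
                    glycan_formula(composition))
  theoretical_isotope_pattern(f, n_iso = n_iso)
}
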