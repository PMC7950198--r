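.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full glycosylation profiling pipeline
#'
#' Orchestrates build-library -> extract -> curate -> traits and the
#' configured analyses (batch correction, stability CVs, association, ROC),
#' writing TSV outputs and a JSON run log (seed, versions, sample/analyte
#' counts entering and leaving each stage) to the output directory. Any stage
#' error aborts with a stage-tagged message; outputs of completed stages are
#' preserved.
#'
#' @param config a list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{output_dir}{directory for outputs (created if needed).}
#'     \item{seed}{integer seed for simulation.}
#'     \item{library}{optional list: `fasta`, `composition_tsv` (defaults:
#'       bundled AGP library).}
#'     \item{runs}{either a list of `raw_run` objects, or a character vector
#'       of mzML paths, or NULL to simulate.}
#'     \item{simulate}{when `runs` is NULL: list of [simulate_run()]
#'       arguments (`n_samples` plus any of `ppm_bias`, `noise_sd`, ...).}
#'     \item{extraction}{list: `site_rt` (named, minutes; default the
#'       simulator layout), `tol_ppm` (20), `coverage` (0.9),
#'       `rt_halfwidth` (0.5).}
#'     \item{qc}{list passed to [qc_thresholds()].}
#'     \item{metadata}{data.frame or TSV path with per-sample metadata.}
#'     \item{analysis}{list of flags: `batch_correct`, `stability`,
#'       `associate`, `roc` (+ `roc_traits`).}
#'   }
#' @return (invisibly) a list with the main tables (`library`, `records`,
#'   `qc`, `abundance`, `traits`, and any analysis results) plus `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package_version = as.character(utils::packageVersion("agpglyco")),
              r_version = R.version.string,
              seed = config$seed %||% NA, stages = list())
  res <- list()

  res$library <- .stage("build-library", {
    lib_cfg <- config$library %||% list()
    iso <- if (is.null(lib_cfg$fasta)) agp_isoforms() else read_isoform_fasta(lib_cfg$fasta)
    build_glycopeptide_library(iso, lib_cfg$composition_tsv)
  })
  log$stages$library <- list(analytes = nrow(res$library),
                             site_groups = length(unique(res$library$site_group)))

  ext <- config$extraction %||% list()
  site_rt <- ext$site_rt
  runs <- .stage("acquire", {
    if (!is.null(config$runs)) {
      if (is.character(config$runs)) {
        lapply(config$runs, read_mzml)
      } else config$runs
    } else {
      sim <- config$simulate %||% list()
      n_samples <- sim$n_samples %||% 4
      sim$n_samples <- NULL
      seed0 <- config$seed %||% 1L
      lapply(seq_len(n_samples), function(i) {
        args <- c(list(library = res$library, run_id = sprintf("S%03d", i),
                       seed = seed0 + i), sim)
        if (!is.null(site_rt)) args$site_rt <- unlist(site_rt)
        do.call(simulate_run, args)
      })
    }
  })
  if (is.null(site_rt)) {
    truth <- attr(runs[[1]], "truth")
    if (!is.null(truth)) site_rt <- truth$site_rt
  }
  if (is.null(site_rt)) stop("stage 'extract': extraction$site_rt is required for real runs")
  log$stages$acquire <- list(n_runs = length(runs))

  res$records <- .stage("extract", {
    targets <- make_extraction_targets(
      res$library, unlist(site_rt),
      tol_ppm = ext$tol_ppm %||% 20,
      coverage = ext$coverage %||% 0.90,
      rt_halfwidth = ext$rt_halfwidth %||% 0.5
    )
    recs <- do.call(rbind, lapply(runs, function(r) extract_run(r, targets)))
    .write_tsv(recs, file.path(out_dir, "integration_records.tsv"))
    recs
  })
  log$stages$extract <- list(records = nrow(res$records),
                             samples = length(unique(res$records$sample)))

  res$qc <- .stage("curate", {
    thr <- do.call(qc_thresholds, config$qc %||% list())
    qc <- batch_qc(res$records, thr)
    .write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
    qc
  })
  res$abundance <- .stage("curate", {
    areas <- sum_charges(res$records, res$qc)
    ab <- normalize_per_site(areas)
    .write_tsv(ab, file.path(out_dir, "abundance.tsv"))
    ab
  })
  log$stages$curate <- list(
    retained = sum(res$qc$retained), assessed = nrow(res$qc),
    samples = length(unique(res$abundance$sample))
  )
  if (length(unique(res$abundance$sample)) != length(runs)) {
    stop("stage 'curate': sample count changed during curation (",
         length(unique(res$abundance$sample)), " of ", length(runs), ")")
  }

  res$trait_definitions <- .stage("traits", enumerate_traits(res$library))
  res$traits <- .stage("traits", {
    tt <- compute_traits(res$abundance, res$trait_definitions)
    .write_tsv(tt, file.path(out_dir, "traits.tsv"))
    tt
  })
  log$stages$traits <- list(n_traits = ncol(res$traits) - 1L,
                            samples = nrow(res$traits))

  meta <- config$metadata
  if (is.character(meta)) meta <- .read_tsv(meta)
  an <- config$analysis %||% list()

  if (isTRUE(an$batch_correct)) {
    res$traits_corrected <- .stage("batch-correct", {
      if (is.null(meta) || !"plate" %in% names(meta)) {
        stop("metadata with a 'plate' column is required")
      }
      m <- meta[match(res$traits$sample, meta$sample), ]
      vals <- as.matrix(res$traits[, -1, drop = FALSE])
      corr <- batch_correct(vals, m$plate)
      out <- cbind(res$traits[, "sample", drop = FALSE], as.data.frame(corr))
      .write_tsv(out, file.path(out_dir, "traits_batch_corrected.tsv"))
      structure(out, class = class(res$traits))
    })
    log$stages$batch_correct <- list(samples = nrow(res$traits_corrected))
  }
  analysis_traits <- res$traits_corrected %||% res$traits

  if (isTRUE(an$stability)) {
    res$stability <- .stage("stability", {
      if (is.null(meta)) stop("metadata is required")
      s <- stability_summary(analysis_traits, meta)
      .write_tsv(s$per_trait, file.path(out_dir, "cv_summary.tsv"))
      s
    })
    log$stages$stability <- list(traits = nrow(res$stability$per_trait))
  }
  if (isTRUE(an$associate)) {
    res$association <- .stage("associate", {
      if (is.null(meta) || !"group" %in% names(meta)) {
        stop("metadata with a 'group' column is required")
      }
      a <- associate_traits(analysis_traits, meta,
                            covariates = an$covariates %||% c("age", "sex"))
      .write_tsv(a, file.path(out_dir, "association.tsv"))
      a
    })
    log$stages$associate <- list(tested = sum(res$association$converged))
  }
  if (isTRUE(an$roc)) {
    res$roc <- .stage("roc", {
      gly <- an$roc_traits
      if (is.null(gly) && !is.null(res$association)) {
        gly <- res$association$trait[which(res$association$p_adj < 0.05)]
      }
      if (length(gly) == 0) stop("no glycan traits selected for ROC models")
      r <- roc_models(analysis_traits, meta, gly)
      .write_tsv(r$summary, file.path(out_dir, "roc_auc.tsv"))
      r
    })
    log$stages$roc <- res$roc$summary$auc
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$log <- log
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
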