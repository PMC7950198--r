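#' Default ground-truth glycoform profile
#'
#' A fixed, deterministic per-site glycoform profile used as the simulators'
#' baseline: within each site, weights favour highly sialylated tri- and
#' tetraantennary structures (the regime reported for AGP), with fucosylated
#' and poly-LacNAc species present at lower abundance; weights are normalized
#' to fractions summing to 1 per site.
#'
#' @param library a `glycopeptide_library`.
#' @return named list: site group -> named numeric vector of fractions.
#' @export
default_site_fractions <- function(library = agp_glycoform_library()) {
  out <- list()
  for (sg in unique(library$site_group)) {
    comps <- library$composition[library$site_group == sg]
    w <- vapply(comps, function(cl) {
      comp <- as_composition(cl)
      ant <- antennarity(comp)
      sia <- sialylation_class(comp)
      exp(-(3 * abs(sia$value - 0.9) + 1.2 * comp$F +
              1.5 * ant$lacnac_repeats + 0.8 * abs(ant$antennae - 3)))
    }, numeric(1))
    out[[sg]] <- w / sum(w)
  }
  out
}

#' Simulate a raw LC-MS1 run of glycopeptides
#'
#' Generates centroided MS1 scans in which every library analyte elutes as a
#' Gaussian chromatographic peak at its site's retention time, with its
#' theoretical isotopic envelope at the library charge states (3+/4+ by
#' default). m/z values are perturbed by a systematic calibration bias plus
#' per-peak jitter (ppm); intensities carry multiplicative noise; random
#' decoy peaks with exponential intensities stress matching tolerances and
#' the S/N estimate. Optionally emits diagnostic-oxonium MS2 stub scans
#' within each elution window. The ground truth is attached as attributes.
#'
#' @param library a `glycopeptide_library` (or subset).
#' @param site_fractions named list (site group -> composition fractions
#'   summing to 1); default [default_site_fractions()].
#' @param site_rt named numeric, apex rt (min) per site group.
#' @param run_id run identifier.
#' @param base_intensity apex intensity of a fraction-1 analyte.
#' @param charge_weights named weights for the charge states.
#' @param rt_sd chromatographic peak sd (min).
#' @param scan_interval MS1 scan spacing (min).
#' @param ppm_bias systematic calibration error (ppm).
#' @param ppm_jitter per-peak m/z jitter sd (ppm).
#' @param noise_sd multiplicative intensity noise sd (fraction).
#' @param decoy_per_scan expected number of random decoy peaks per scan.
#' @param decoy_intensity mean of the exponential decoy intensity.
#' @param rt_shift global retention-time shift (min), for alignment tests.
#' @param n_iso isotopologues simulated per analyte.
#' @param ms2_stubs emit diagnostic-ion MS2 stub scans.
#' @param seed integer seed; fixed seed makes the run bit-reproducible.
#' @return a `raw_run` with attributes `truth` (list: `site_fractions`,
#'   `ppm_bias`, `rt_shift`, `site_rt`) attached.
#' @export
simulate_run <- function(library = agp_glycoform_library(),
                         site_fractions = default_site_fractions(library),
                         site_rt = NULL, run_id = "sim",
                         base_intensity = 1e5,
                         charge_weights = c("3" = 0.6, "4" = 0.4),
                         rt_sd = 0.08, scan_interval = 0.025,
                         ppm_bias = 0, ppm_jitter = 1,
                         noise_sd = 0.02, decoy_per_scan = 20,
                         decoy_intensity = 50, rt_shift = 0,
                         n_iso = 10L, ms2_stubs = FALSE, seed = 1L) {
  set.seed(seed)
  sites <- unique(library$site_group)
  if (is.null(site_rt)) {
    site_rt <- stats::setNames(seq(6, by = 0.9, length.out = length(sites)), sites)
  }
  for (sg in sites) {
    fr <- site_fractions[[sg]]
    if (is.null(fr)) stop("no simulated fractions for site group ", sg)
    if (abs(sum(fr) - 1) > 1e-6) {
      stop("fractions for site group ", sg, " sum to ", sum(fr), ", not 1")
    }
  }

  # precompute peak templates: one row per analyte x charge x isotopologue
  tmpl <- list()
  for (i in seq_len(nrow(library))) {
    sg <- library$site_group[i]
    frac <- site_fractions[[sg]][[library$composition[i]]]
    if (is.null(frac) || is.na(frac) || frac <= 0) next
    pat <- analyte_isotope_pattern(library$peptide[i], library$composition[i],
                                   n_iso = n_iso)
    for (z in library$charges[[i]]) {
      mz0 <- analyte_mz(library$analyte_mass[i], z)
      tmpl[[length(tmpl) + 1L]] <- data.frame(
        mz = mz0 + pat$offsets * .ISOTOPE_SPACING / z,
        amp = base_intensity * frac * charge_weights[[as.character(z)]] * pat$fractions,
        center = site_rt[[sg]] + rt_shift
      )
    }
  }
  tmpl <- do.call(rbind, tmpl)

  rt_grid <- seq(min(site_rt) + rt_shift - 1, max(site_rt) + rt_shift + 1,
                 by = scan_interval)
  min_int <- base_intensity * 1e-5
  ms1 <- vector("list", length(rt_grid))
  for (si in seq_along(rt_grid)) {
    rt <- rt_grid[si]
    g <- exp(-(rt - tmpl$center)^2 / (2 * rt_sd^2))
    on <- which(tmpl$amp * g > min_int)
    mz <- tmpl$mz[on] * (1 + (ppm_bias + stats::rnorm(length(on), 0, ppm_jitter)) / 1e6)
    int <- tmpl$amp[on] * g[on] * pmax(0, 1 + stats::rnorm(length(on), 0, noise_sd))
    n_dec <- stats::rpois(1, decoy_per_scan)
    if (n_dec > 0) {
      mz <- c(mz, stats::runif(n_dec, 800, 1600))
      int <- c(int, stats::rexp(n_dec, 1 / decoy_intensity))
    }
    ms1[[si]] <- list(rt = rt, mz = mz, intensity = int)
  }

  ms2 <- NULL
  if (ms2_stubs) {
    ions <- diagnostic_ions()
    ms2 <- lapply(sites, function(sg) {
      list(rt = site_rt[[sg]] + rt_shift, precursor_mz = 1000,
           mz = unname(ions), intensity = rep(1000, length(ions)))
    })
  }
  run <- raw_run(run_id, ms1, ms2)
  attr(run, "truth") <- list(site_fractions = site_fractions,
                             ppm_bias = ppm_bias, rt_shift = rt_shift,
                             site_rt = site_rt)
  run
}

#' Simulate a case/control cohort of derived traits
#'
#' Trait values are generated from a latent-Gaussian logistic model: every
#' trait is standard normal on the latent scale in controls, and case status
#' shifts the latent mean of each effect trait by its per-SD log odds ratio
#' (the retrospective-sampling equivalence for a unit-variance Gaussian
#' exposure), so the log OR recovered by rank-INT logistic regression is
#' controlled exactly. Latent values map to the positive trait scale
#' monotonically (`mu * exp(sigma * z)`), plate shifts act multiplicatively
#' (additively in log space), and covariates (age, sex, BMI, family history)
#' are drawn independently of the traits.
#'
#' @param trait_names character vector of trait labels.
#' @param n_case,n_control group sizes (defaults 59/49, a two-plate pilot
#'   cohort layout).
#' @param effects named numeric: per-SD log odds ratio for a subset of traits
#'   (unnamed traits are null).
#' @param trait_means baseline trait means (recycled; default 0.2).
#' @param sigma_log log-scale trait dispersion (default 0.25).
#' @param n_plates number of 96-well plates samples are randomized across.
#' @param plate_shift_sd sd of the per-plate log-scale shift (0.3 simulates a
#'   clear batch effect; 0 disables it).
#' @param seed integer seed.
#' @return list with `traits` (a `trait_table`), `meta` (sample metadata:
#'   `sample`, `group`, `age`, `sex`, `bmi`, `family_history`, `plate`) and
#'   `truth` (effects and plate shifts).
#' @export
simulate_cohort <- function(trait_names, n_case = 59, n_control = 49,
                            effects = numeric(0), trait_means = 0.2,
                            sigma_log = 0.25, n_plates = 2,
                            plate_shift_sd = 0, seed = 1L) {
  set.seed(seed)
  unknown <- setdiff(names(effects), trait_names)
  if (length(unknown) > 0) {
    stop("effect(s) on unknown trait(s): ", paste(unknown, collapse = ", "))
  }
  n <- n_case + n_control
  group <- c(rep("case", n_case), rep("control", n_control))
  mu <- rep_len(trait_means, length(trait_names))
  plate <- sample(rep_len(paste0("plate", seq_len(n_plates)), n))
  shift <- stats::setNames(stats::rnorm(n_plates, 0, plate_shift_sd),
                           paste0("plate", seq_len(n_plates)))
  traits <- data.frame(sample = sprintf("S%03d", seq_len(n)),
                       stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(trait_names)) {
    beta <- if (trait_names[j] %in% names(effects)) effects[[trait_names[j]]] else 0
    z <- stats::rnorm(n) + beta * (group == "case")
    traits[[trait_names[j]]] <- mu[j] * exp(sigma_log * z + shift[plate])
  }
  meta <- data.frame(
    sample = traits$sample, group = group,
    age = round(stats::runif(n, 18, 79)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    bmi = round(stats::rnorm(n, 27, 4), 1),
    family_history = stats::rbinom(n, 1, 0.3),
    plate = plate, stringsAsFactors = FALSE
  )
  list(
    traits = structure(traits, class = c("trait_table", "data.frame")),
    meta = meta,
    truth = list(effects = effects, plate_shift = shift)
  )
}

#' Simulate a longitudinal stability design
#'
#' Emulates a cohort of healthy subjects sampled at several time points with
#' a subset of technical duplicate pairs (the 14-subject x 3-time-point
#' layout by default). On the log scale each measurement is
#' `subject effect (inter_sd) + visit effect (intra_sd) + technical noise
#' (tech_sd)`, so the three CV categories of [stability_summary()] are
#' directly controlled (for small sds, CV in percent is about 100 x sd).
#'
#' @param trait_names character vector of trait labels.
#' @param n_subjects,n_time_points design size (defaults 14 x 3).
#' @param inter_sd,intra_sd,tech_sd log-scale sds of the subject, visit and
#'   technical components.
#' @param n_duplicates number of random technical duplicate pairs (default 8).
#' @param trait_means baseline trait means (recycled).
#' @param seed integer seed.
#' @return list with `traits` (a `trait_table`), `meta` (`sample`, `subject`,
#'   `time_point`, `replicate`) and `truth`.
#' @export
simulate_stability <- function(trait_names, n_subjects = 14, n_time_points = 3,
                               inter_sd = 0.10, intra_sd = 0.04,
                               tech_sd = 0.02, n_duplicates = 8,
                               trait_means = 0.2, seed = 1L) {
  if (n_subjects < 2 || n_time_points < 2) {
    stop("design requires at least 2 subjects and 2 time points")
  }
  if (any(c(inter_sd, intra_sd, tech_sd) < 0)) stop("sds must be >= 0")
  set.seed(seed)
  mu <- rep_len(trait_means, length(trait_names))
  design <- expand.grid(subject = sprintf("subj%02d", seq_len(n_subjects)),
                        time_point = seq_len(n_time_points),
                        stringsAsFactors = FALSE)
  design$replicate <- 1L
  if (n_duplicates > 0) {
    dup <- design[sample(nrow(design), min(n_duplicates, nrow(design))), ]
    dup$replicate <- 2L
    design <- rbind(design, dup)
  }
  design <- design[order(design$subject, design$time_point, design$replicate), ]
  design$sample <- sprintf("T%03d", seq_len(nrow(design)))
  traits <- data.frame(sample = design$sample, stringsAsFactors = FALSE,
                       check.names = FALSE)
  subj_lev <- unique(design$subject)
  for (j in seq_along(trait_names)) {
    b_subj <- stats::setNames(stats::rnorm(length(subj_lev), 0, inter_sd), subj_lev)
    # visit effect is shared by technical duplicates of the same visit
    visit_key <- paste(design$subject, design$time_point)
    b_visit <- stats::setNames(stats::rnorm(length(unique(visit_key)), 0, intra_sd),
                               unique(visit_key))[visit_key]
    b_tech <- stats::rnorm(nrow(design), 0, tech_sd)
    traits[[trait_names[j]]] <- mu[j] * exp(b_subj[design$subject] + b_visit + b_tech)
  }
  meta <- design[, c("sample", "subject", "time_point", "replicate")]
  rownames(meta) <- rownames(traits) <- NULL
  list(
    traits = structure(traits, class = c("trait_table", "data.frame")),
    meta = meta,
    truth = list(inter_sd = inter_sd, intra_sd = intra_sd, tech_sd = tech_sd)
  )
}
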