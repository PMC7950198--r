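#' Empirical-Bayes batch (plate) correction
#'
#' Measurements are log-transformed and plate effects are removed by the
#' ComBat empirical-Bayes location/scale adjustment (via the sva package):
#' features are standardized, per-batch effects estimated, shrunk toward
#' common priors, and the estimated batch effect is subtracted from the
#' log-transformed measurements. With a single batch the adjustment is the
#' identity (the log-transformed data are returned unchanged).
#'
#' @param x numeric matrix or data.frame, samples in rows, features
#'   (glycoforms or traits) in columns; strictly positive values.
#' @param batch batch/plate label per sample (length `nrow(x)`).
#' @param log_transform log-transform before correction (default TRUE; set
#'   FALSE if `x` is already in log space).
#' @param back_transform exponentiate the corrected values back to the
#'   original scale (default TRUE).
#' @return matrix of corrected values, same dimensions and dimnames as `x`.
#' @export
batch_correct <- function(x, batch, log_transform = TRUE, back_transform = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (length(batch) != nrow(x)) stop("`batch` must have one label per sample (row)")
  if (log_transform) {
    if (any(!is.na(x) & x <= 0)) {
      stop("values must be strictly positive before log transformation")
    }
    x <- log(x)
  }
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (length(tab) > 1) {
    suppressMessages(invisible(utils::capture.output(
      corrected <- t(sva::ComBat(dat = t(x), batch = as.factor(batch),
                                 par.prior = TRUE, prior.plots = FALSE))
    )))
    dimnames(corrected) <- dimnames(x)
    x <- corrected
  }
  if (back_transform && log_transform) exp(x) else x
}

#' Coefficient of variation
#'
#' @param values numeric vector, `n >= 2`, non-zero mean.
#' @return CV in percent: `100 * sd / mean`.
#' @examples
#' cv(c(9, 11)) # 14.14%
#' @export
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

.cv_safe <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

.med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Temporal stability summary (three CV categories)
#'
#' For a longitudinal design (subjects sampled at several time points, with a
#' subset of technical duplicate pairs) this computes, per derived trait:
#' the duplicate CV (method baseline, from replicate pairs), the
#' intraindividual CV (per subject across time points, summarized across
#' subjects) and the interindividual CV (per time point across subjects,
#' summarized across time points), each reported as median and IQR, plus an
#' overall median/IQR across traits for each category.
#'
#' @param traits a `trait_table` (column `sample` + one column per trait).
#' @param meta data.frame with columns `sample`, `subject`, `time_point` and
#'   `replicate` (1 for the primary measurement, 2+ for technical duplicates
#'   of the same subject x time point).
#' @return a `cv_summary`: list with `per_trait` (data.frame of medians and
#'   quartiles per category) and `overall` (data.frame, one row per category).
#' @export
stability_summary <- function(traits, meta) {
  need <- c("sample", "subject", "time_point", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta <- meta[match(traits$sample, meta$sample), ]
  if (anyNA(meta$sample)) stop("metadata missing for some samples in the trait table")
  absent <- c(
    if (length(unique(meta$subject)) < 2) "at least 2 subjects",
    if (length(unique(meta$time_point)) < 2) "at least 2 time points",
    if (!any(table(paste(meta$subject, meta$time_point)) >= 2)) "technical duplicate pairs"
  )
  if (length(absent) > 0) {
    stop("stability design incomplete; needs: ", paste(absent, collapse = "; "))
  }

  trait_names <- setdiff(names(traits), "sample")
  st_key <- paste(meta$subject, meta$time_point, sep = "\r")
  dup_groups <- names(which(table(st_key) >= 2))
  per_trait <- list()
  for (tn in trait_names) {
    v <- traits[[tn]]
    dup_cvs <- vapply(dup_groups, function(k) .cv_safe(v[st_key == k]), numeric(1))
    # collapse technical replicates before biological CVs
    coll <- tapply(v, st_key, mean, na.rm = TRUE)
    subj <- sub("\r.*", "", names(coll))
    tp <- sub(".*\r", "", names(coll))
    intra_cvs <- vapply(unique(subj), function(s) .cv_safe(coll[subj == s]), numeric(1))
    inter_cvs <- vapply(unique(tp), function(t) .cv_safe(coll[tp == t]), numeric(1))
    per_trait[[tn]] <- c(.med_iqr(dup_cvs), .med_iqr(intra_cvs), .med_iqr(inter_cvs))
  }
  pt <- as.data.frame(do.call(rbind, per_trait))
  names(pt) <- c("dup_median", "dup_q1", "dup_q3",
                 "intra_median", "intra_q1", "intra_q3",
                 "inter_median", "inter_q1", "inter_q3")
  pt <- cbind(data.frame(trait = trait_names, stringsAsFactors = FALSE), pt)
  rownames(pt) <- NULL
  overall <- data.frame(
    category = c("duplicates", "intraindividual", "interindividual"),
    rbind(.med_iqr(pt$dup_median), .med_iqr(pt$intra_median), .med_iqr(pt$inter_median))
  )
  structure(list(per_trait = pt, overall = overall), class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("CV summary across", nrow(x$per_trait), "derived traits (%):\n")
  o <- x$overall
  for (i in seq_len(nrow(o))) {
    cat(sprintf("  %-16s median %.1f (IQR %.1f-%.1f)\n",
                o$category[i], o$median[i], o$q1[i], o$q3[i]))
  }
  invisible(x)
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their (average-tied) ranks:
#' `z_i = qnorm((rank_i - offset) / (n - 2*offset + 1))`. The default
#' `offset = 0.5` gives `qnorm((rank - 0.5)/n)`, the GenABEL `rntransform`
#' convention; `offset = 3/8` gives the Blom variant. After transformation
#' every variable has the same standardized variance, so per-SD effect sizes
#' are comparable across traits.
#'
#' @param x numeric vector, `n >= 3`, not all values identical; NAs preserved.
#' @param offset rank offset (default 0.5).
#' @return numeric vector of z-scores.
#' @examples
#' rank_int(c(5, 1, 9))
#' @export
rank_int <- function(x, offset = 0.5) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("rank-based INT requires at least 3 non-missing values")
  if (length(unique(x[ok])) < 2) stop("all values identical; no ordering to transform")
  r <- rank(x[ok], ties.method = "average")
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  out
}

#' Per-trait logistic association with a binary outcome
#'
#' Each derived trait is rank-inverse-normal transformed and entered as the
#' exposure in a logistic regression of the binary outcome with the given
#' covariates: `outcome ~ rank_int(trait) + age + sex`. The reported
#' coefficient B is the natural-log odds ratio per 1 SD of the transformed
#' trait; p-values are Wald tests, adjusted across all testable traits by
#' Benjamini-Hochberg.
#'
#' @param traits a `trait_table`.
#' @param meta data.frame with `sample`, `group` (`"case"`/`"control"`) and
#'   covariate columns.
#' @param covariates covariate column names in `meta` (default age and sex).
#' @param int_offset rank offset passed to [rank_int()].
#' @return an `association_result` data.frame: `trait`, `B`, `p`, `p_adj`,
#'   `n`, `converged`. Traits whose fit fails or separates are flagged
#'   `converged = FALSE`, excluded from FDR adjustment, and reported with NA
#'   p-values (with a warning).
#' @export
associate_traits <- function(traits, meta, covariates = c("age", "sex"),
                             int_offset = 0.5) {
  stopifnot("sample" %in% names(meta), "group" %in% names(meta))
  miss <- setdiff(covariates, names(meta))
  if (length(miss) > 0) stop("metadata lacks covariate(s): ", paste(miss, collapse = ", "))
  m <- meta[match(traits$sample, meta$sample), ]
  if (!all(m$group %in% c("case", "control"))) {
    stop("`group` must be 'case' or 'control' for every sample")
  }
  y <- as.integer(m$group == "case")
  if (anyNA(m[covariates])) stop("missing covariate values")
  trait_names <- setdiff(names(traits), "sample")
  res <- data.frame(trait = trait_names, B = NA_real_, p = NA_real_,
                    p_adj = NA_real_, n = NA_integer_, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(trait_names)) {
    v <- traits[[trait_names[i]]]
    ok <- !is.na(v)
    if (sum(ok) < 3 || length(unique(v[ok])) < 2) next
    dat <- data.frame(y = y[ok], z = rank_int(v[ok], offset = int_offset),
                      m[ok, covariates, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    sm <- summary(fit)$coefficients
    if (!"z" %in% rownames(sm)) next
    # very large SE flags (quasi-)complete separation
    if (sm["z", "Std. Error"] > 50) next
    res$B[i] <- sm["z", "Estimate"]
    res$p[i] <- sm["z", "Pr(>|z|)"]
    res$n[i] <- sum(ok)
    res$converged[i] <- TRUE
  }
  if (any(!res$converged)) {
    warning(sum(!res$converged), " trait(s) excluded (non-convergence or separation): ",
            paste(utils::head(res$trait[!res$converged], 5), collapse = ", "))
  }
  res$p_adj[res$converged] <- stats::p.adjust(res$p[res$converged], method = "BH")
  structure(res, class = c("association_result", "data.frame"))
}

#' AUC by the Mann-Whitney rank statistic
#'
#' @param score numeric predictor/fitted probability.
#' @param label binary outcome (0/1 or logical).
#' @return area under the ROC curve.
#' @export
auc_rank <- function(score, label) {
  label <- as.integer(label)
  stopifnot(all(label %in% c(0, 1)))
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.roc_points <- function(score, label) {
  label <- as.integer(label)
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(label[o] == 1); fp <- cumsum(label[o] == 0)
  data.frame(fpr = c(0, fp / sum(label == 0)), tpr = c(0, tp / sum(label == 1)))
}

#' Compare predictive logistic models by ROC/AUC
#'
#' Builds and compares predictive logistic regressions for the binary
#' outcome: a base clinical model (age and sex), an extended clinical model
#' (age, sex, BMI, family history), and both again with the selected glycan
#' traits added. AUC is computed from the fitted probabilities by the
#' Mann-Whitney rank statistic.
#'
#' @param traits a `trait_table`.
#' @param meta data.frame with `sample`, `group` and the clinical predictor
#'   columns.
#' @param glycan_traits character vector of trait columns to add (e.g. the
#'   FDR-significant set).
#' @param base_covariates predictors of the base model.
#' @param extended_covariates predictors of the extended clinical model.
#' @return a `model_comparison`: list with `summary` (data.frame `model`,
#'   `auc`, `n_predictors`) and `roc` (named list of fpr/tpr data.frames).
#' @export
roc_models <- function(traits, meta, glycan_traits,
                       base_covariates = c("age", "sex"),
                       extended_covariates = c("age", "sex", "bmi", "family_history")) {
  m <- meta[match(traits$sample, meta$sample), ]
  y <- as.integer(m$group == "case")
  unknown <- setdiff(glycan_traits, names(traits))
  if (length(unknown) > 0) stop("unknown trait(s): ", paste(unknown, collapse = ", "))
  models <- list(
    clinical_base = list(cov = base_covariates, gly = character(0)),
    clinical_extended = list(cov = extended_covariates, gly = character(0)),
    clinical_base_glycans = list(cov = base_covariates, gly = glycan_traits),
    clinical_extended_glycans = list(cov = extended_covariates, gly = glycan_traits)
  )
  summ <- list(); rocs <- list()
  for (nm in names(models)) {
    sp <- models[[nm]]
    dat <- cbind(m[, sp$cov, drop = FALSE],
                 traits[, sp$gly, drop = FALSE])
    const <- vapply(dat, function(col) length(unique(col[!is.na(col)])) < 2, NA)
    if (any(const)) {
      warning("model '", nm, "': dropping constant predictor(s): ",
              paste(names(dat)[const], collapse = ", "))
      dat <- dat[, !const, drop = FALSE]
    }
    ok <- stats::complete.cases(dat)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(data.frame(y = y), dat)[ok, ],
                 family = stats::binomial())
    )
    prob <- stats::fitted(fit)
    summ[[nm]] <- data.frame(model = nm, auc = auc_rank(prob, y[ok]),
                             n_predictors = ncol(dat), stringsAsFactors = FALSE)
    rocs[[nm]] <- .roc_points(prob, y[ok])
  }
  structure(list(summary = do.call(rbind, summ), roc = rocs),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Predictive model comparison (AUC):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-26s AUC = %.3f (%d predictors)\n",
                s$model[i], s$auc[i], s$n_predictors[i]))
  }
  invisible(x)
}
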