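test_that("coefficient of variation matches its definition", {
  expect_equal(cv(c(10, 10, 10)), 0)
  expect_equal(cv(c(9, 11)), 14.14214, tolerance = 1e-5)
  expect_error(cv(c(5)), "at least 2")
  expect_error(cv(c(0, 0)), "zero mean")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("rank-INT maps ranks to normal scores", {
  z <- rank_int(c(5, 1, 9))
  expect_equal(z, qnorm(c(0.5, 1 / 6, 5 / 6)), tolerance = 1e-12)
  # monotone in the input, mean zero for odd n without ties
  x <- c(0.3, 2, -5, 7, 0.1)
  z2 <- rank_int(x)
  expect_equal(order(z2), order(x))
  expect_equal(mean(z2), 0, tolerance = 1e-9)
  # invariant under strictly monotone transformation
  expect_equal(rank_int(exp(x)), z2, tolerance = 1e-12)
  expect_equal(rank_int(rank(x)), z2, tolerance = 1e-12)
  # Blom offset variant
  expect_equal(rank_int(c(5, 1, 9), offset = 3 / 8),
               qnorm((c(2, 1, 3) - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_error(rank_int(c(1, 2)), "at least 3")
  expect_error(rank_int(rep(2, 5)), "identical")
})

test_that("BH adjustment matches the closed form with monotonicity", {
  p <- c(0.001, 0.02, 0.04, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.004, 0.04, 0.04 * 4 / 3, 0.5),
               tolerance = 1e-12)
  # BH at level alpha never rejects more than unadjusted alpha-level testing
  set.seed(8)
  for (i in 1:20) {
    pp <- runif(50)^2
    expect_lte(sum(p.adjust(pp, "BH") < 0.05), sum(pp < 0.05))
    expect_true(all(p.adjust(pp, "BH") >= pp))
  }
})

test_that("AUC equals brute-force pairwise concordance", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + y
    brute <- {
      pos <- s[y == 1]; neg <- s[y == 0]
      g <- outer(pos, neg, ">"); e <- outer(pos, neg, "==")
      (sum(g) + 0.5 * sum(e)) / (length(pos) * length(neg))
    }
    expect_equal(auc_rank(s, y), brute, tolerance = 1e-12)
  }
  expect_equal(auc_rank(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1) # perfect separation
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(15)
  y <- rbinom(150, 1, 0.45)
  s <- rnorm(150) + 0.8 * y
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("logistic fit matches an independent Newton solver on toy data", {
  set.seed(16)
  x <- rnorm(80); y <- rbinom(80, 1, plogis(-0.4 + 0.9 * x))
  newton <- function(x, y, iter = 50) {
    X <- cbind(1, x); b <- c(0, 0)
    for (i in seq_len(iter)) {
      p <- plogis(X %*% b)
      W <- as.numeric(p * (1 - p))
      b <- b + solve(t(X) %*% (X * W), t(X) %*% (y - p))
    }
    as.numeric(b)
  }
  fit <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(fit)), newton(x, y), tolerance = 1e-6)
})

test_that("association analysis is calibrated under the null", {
  set.seed(17)
  n <- 100
  pvals <- replicate(300, {
    tr <- data.frame(sample = paste0("s", 1:n), t1 = rlnorm(n),
                     check.names = FALSE)
    meta <- data.frame(sample = tr$sample,
                       group = rep(c("case", "control"), length.out = n),
                       age = runif(n, 20, 70), sex = sample(c("M", "F"), n, TRUE))
    associate_traits(tr, meta)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("association recovers a known per-SD log odds ratio", {
  set.seed(18)
  B <- replicate(60, {
    sim <- simulate_cohort(paste0("t", 1:3), effects = c(t1 = 0.8),
                           seed = sample.int(1e6, 1))
    associate_traits(sim$traits, sim$meta)$B[1]
  })
  expect_gt(median(B), 0.5)
  expect_lt(median(B), 1.1)
})

test_that("flagged traits are excluded from FDR with a warning", {
  set.seed(19)
  n <- 40
  tr <- data.frame(sample = paste0("s", 1:n),
                   good = rnorm(n), flat = rep(1, n), check.names = FALSE)
  meta <- data.frame(sample = tr$sample,
                     group = rep(c("case", "control"), each = n / 2),
                     age = runif(n, 20, 70), sex = sample(c("M", "F"), n, TRUE))
  expect_warning(res <- associate_traits(tr, meta), "excluded")
  expect_false(res$converged[res$trait == "flat"])
  expect_true(is.na(res$p_adj[res$trait == "flat"]))
  expect_true(res$converged[res$trait == "good"])
})

test_that("batch correction removes a simulated plate shift", {
  set.seed(20)
  n <- 60; n_feat <- 12
  base <- matrix(rlnorm(n * n_feat, 0, 0.2), n, n_feat,
                 dimnames = list(paste0("s", 1:n), paste0("f", 1:n_feat)))
  plate <- rep(c("p1", "p2"), each = n / 2)
  shifted <- base * exp(0.3 * (plate == "p2"))
  corr <- batch_correct(shifted, plate)
  # the systematic plate component is removed to < 0.02 log-units
  resid <- mean(colMeans(log(corr[plate == "p2", ])) -
                  colMeans(log(corr[plate == "p1", ])))
  expect_lt(abs(resid), 0.02)
  # and per-feature residual shifts stay well below the injected 0.3
  per_feat <- abs(colMeans(log(corr[plate == "p2", ])) -
                    colMeans(log(corr[plate == "p1", ])))
  expect_lt(max(per_feat), 0.1)
  # single batch: identity adjustment (log then back-transform)
  expect_equal(batch_correct(base, rep("p1", n)), base, tolerance = 1e-12)
  expect_equal(batch_correct(base, rep("p1", n), back_transform = FALSE),
               log(base), tolerance = 1e-12)
  expect_error(batch_correct(base, c("solo", plate[-1])), "fewer than 2")
  neg <- base; neg[1, 1] <- -1
  expect_error(batch_correct(neg, plate), "strictly positive")
})

test_that("batch correction reduces interplate CV of duplicates", {
  set.seed(22)
  n_pairs <- 10; n_feat <- 8
  truth <- matrix(rlnorm(n_pairs * n_feat, 0, 0.15), n_pairs, n_feat)
  make_plate <- function(shift) truth * exp(shift) *
    matrix(rlnorm(n_pairs * n_feat, 0, 0.05), n_pairs, n_feat)
  x <- rbind(make_plate(0), make_plate(0.3))
  colnames(x) <- paste0("f", 1:n_feat)
  plate <- rep(c("p1", "p2"), each = n_pairs)
  interplate_cv <- function(m) {
    median(vapply(seq_len(n_pairs), function(i)
      mean(vapply(seq_len(n_feat), function(j)
        cv(c(m[i, j], m[n_pairs + i, j])), numeric(1))), numeric(1)))
  }
  corr <- batch_correct(x, plate)
  expect_lt(interplate_cv(corr), interplate_cv(x))
})

test_that("stability summary reproduces the designed CV ordering", {
  sim <- simulate_stability(paste0("t", 1:12), inter_sd = 0.12,
                            intra_sd = 0.04, tech_sd = 0.02, seed = 23)
  s <- stability_summary(sim$traits, sim$meta)
  pt <- s$per_trait
  expect_true(all(pt$inter_median > pt$intra_median))
  expect_true(median(pt$intra_median) > median(pt$dup_median))
  # zero noise everywhere: all CVs are 0
  sim0 <- simulate_stability(paste0("t", 1:3), inter_sd = 0, intra_sd = 0,
                             tech_sd = 0, seed = 24)
  s0 <- stability_summary(sim0$traits, sim0$meta)
  expect_equal(max(abs(as.matrix(s0$per_trait[, -1]))), 0, tolerance = 1e-9)
  # incomplete designs are rejected with a description of what is absent
  bad_meta <- sim$meta; bad_meta$time_point <- 1
  expect_error(stability_summary(sim$traits, bad_meta), "time points")
  expect_error(stability_summary(sim$traits, sim$meta[, 1:3]), "replicate")
})

test_that("technical duplicate noise is recovered from duplicate pairs", {
  sim <- simulate_stability(paste0("t", 1:10), inter_sd = 0.1, intra_sd = 0.03,
                            tech_sd = 0.02, n_duplicates = 30, seed = 25)
  key <- paste(sim$meta$subject, sim$meta$time_point)
  dup_keys <- names(which(table(key) >= 2))
  # root-mean-square duplicate CV estimates the technical noise (~2%)
  cvs <- unlist(lapply(paste0("t", 1:10), function(tn)
    vapply(dup_keys, function(k) cv(sim$traits[[tn]][key == k]), numeric(1))))
  expect_equal(sqrt(mean(cvs^2)), 2, tolerance = 0.25)
})

test_that("ROC model comparison ranks informative models higher", {
  set.seed(26)
  sim <- simulate_cohort(paste0("t", 1:6),
                         effects = c(t1 = 0.9, t2 = 0.8, t3 = 0.7), seed = 27)
  r <- roc_models(sim$traits, sim$meta, c("t1", "t2", "t3"))
  s <- r$summary
  expect_true(all(s$auc >= 0 & s$auc <= 1))
  expect_gt(s$auc[s$model == "clinical_base_glycans"],
            s$auc[s$model == "clinical_base"])
  # ROC curves end at (1, 1)
  for (rc in r$roc) expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  # labels independent of score: AUC near 0.5
  null_auc <- replicate(50, auc_rank(rnorm(200), rbinom(200, 1, 0.5)))
  expect_equal(mean(null_auc), 0.5, tolerance = 0.03)
  # constant predictors are dropped with a warning (both extended models)
  sim$meta$bmi <- 25
  w <- capture_warnings(roc_models(sim$traits, sim$meta, "t1"))
  expect_true(any(grepl("constant", w)))
})
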