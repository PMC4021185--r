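test_that("classification metrics match their closed forms and a recount oracle", {
  perfect <- classification_stats(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(unlist(perfect[, c("tpr", "tnr", "prc", "mcc", "f1")]),
               c(tpr = 1, tnr = 1, prc = 1, mcc = 1, f1 = 1))

  st <- classification_stats(tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(st$mcc, 10 / sqrt(600))
  expect_equal(st$f1, 2 * 0.75 * 0.6 / 1.35)

  # all-negative prediction on mixed truth: degenerate precision flagged
  deg <- classification_stats_from_predictions(
    truth = c(TRUE, TRUE, FALSE), prediction = c(FALSE, FALSE, FALSE))
  expect_equal(deg$tpr, 0)
  expect_equal(deg$tnr, 1)
  expect_equal(deg$mcc, 0)
  expect_true(deg$degenerate)

  # brute-force recount on random prediction vectors
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (truth[j] && pred[j]) tp <- tp + 1
      if (!truth[j] && !pred[j]) tn <- tn + 1
      if (!truth[j] && pred[j]) fp <- fp + 1
      if (truth[j] && !pred[j]) fn <- fn + 1
    }
    got <- classification_stats_from_predictions(truth, pred)
    want <- classification_stats(tp = tp, tn = tn, fp = fp, fn = fn)
    expect_equal(got, want)
  }

  # MCC is symmetric under simultaneous class swap
  a <- classification_stats(tp = 7, tn = 3, fp = 2, fn = 5)
  b <- classification_stats(tp = 3, tn = 7, fp = 5, fn = 2)
  expect_equal(a$mcc, b$mcc)
})

test_that("cross-validation leaves out whole proteins with no leakage", {
  pl <- make_planted_instances(planted_signal_config(n_proteins = 3,
                                                     residues_per_protein = 20))
  # a marker feature unique to each protein; the probe learner refuses to
  # score a protein whose marker it saw during training
  pl$marker <- as.numeric(factor(pl$protein_id))
  probe <- list(
    name = "probe",
    fit = function(instances, features = NULL) unique(instances$marker),
    margin = function(model, instances) {
      if (any(instances$marker %in% model)) {
        stop("test protein leaked into its own training fold")
      }
      rep(1, nrow(instances))
    })
  cv <- lopo_cv(pl, probe)
  expect_equal(nrow(cv), 3) # one fold per protein
  expect_setequal(cv$protein_id, unique(pl$protein_id))
  # constant positive prediction: TPr 1, TNr 0
  expect_equal(cv$tpr, rep(1, 3))
  expect_equal(cv$tnr, rep(0, 3))
})

test_that("planted-signal data is recovered well above chance", {
  pl <- make_planted_instances(planted_signal_config(seed = 2))
  cv <- lopo_cv(pl, adtree_learner(10), target_positive_fraction = 0.5)
  expect_gt(attr(cv, "mean_mcc"), 0.5)
  expect_equal(glance(cv)$mean_mcc, attr(cv, "mean_mcc"))
})

test_that("the signed-rank test matches hand enumeration and the exact law", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  # differences (+1, +2, +3, -4): W = 1 + 2 + 3 - 4 = 2
  w <- wilcoxon_signed_rank(c(1, 2, 3, 0), c(0, 0, 0, 4))
  expect_equal(w$w, 2)
  expect_equal(w$n, 4)

  # normal approximation vs exact enumeration at n = 10
  a <- c(5, 6, 7, 8, 9, 10, 11, 12, 1.5, 2.1)
  b <- c(1, 1, 1, 1, 1, 1, 1, 1, 2.0, 2.5)
  p_exact <- wilcoxon_signed_rank(a, b, exact = TRUE)$p
  p_norm <- wilcoxon_signed_rank(a, b, exact = FALSE)$p
  expect_lt(abs(p_exact - p_norm), 0.02)
})

test_that("point-biserial correlation hits analytic limits and values", {
  lab <- rep(c(TRUE, FALSE), 50)
  expect_equal(pearson_feature_correlation(as.numeric(lab), lab)$r, 1)
  expect_equal(pearson_feature_correlation(1 - as.numeric(lab), lab)$r, -1)
  expect_error(pearson_feature_correlation(rep(1, 10), rep(c(TRUE, FALSE), 5)),
               "zero variance")
  # planted mixture, equal classes, means 0 vs 1, SD 1:
  # closed form r = d / sqrt(d^2 + 4) with d = 1 -> 0.4472
  set.seed(21)
  n <- 1000
  lab2 <- rep(c(TRUE, FALSE), each = n / 2)
  x <- rnorm(n, mean = as.numeric(lab2))
  r <- pearson_feature_correlation(x, lab2)$r
  expect_equal(r, 1 / sqrt(5), tolerance = 0.12)
  expect_lt(abs(r - 1 / sqrt(5)), 0.05)
})

test_that("metric-table aggregation reproduces summary arithmetic", {
  tbl <- tibble::tibble(
    method = c("NEW", "M1", "M2", "M3", "M4", "M5"),
    mcc = c(0.264, 0.147, 0.166, 0.151, 0.136, 0.230))
  s <- summarise_metrics(tbl, exclude = "NEW")
  expect_equal(s$mean[s$metric == "mcc"], 0.166)
  expect_equal(s$median[s$metric == "mcc"], 0.151)

  cmp <- compare_to_baseline(tbl, "NEW")
  expect_equal(cmp$delta[cmp$method == "M1"], 0.264 - 0.147)
  sc <- summarise_comparison(cmp)
  expect_equal(sc$mean_delta, mean(0.264 - c(0.147, 0.166, 0.151, 0.136, 0.230)))

  # single reportee equal to the baseline: zero deltas
  same <- tibble::tibble(method = c("NEW", "M1"), mcc = c(0.2, 0.2))
  c2 <- compare_to_baseline(same, "NEW")
  expect_equal(c2$delta, 0)
  expect_equal(c2$pct_delta, 0)
  expect_error(compare_to_baseline(same, "missing"), "absent")
})

test_that("the distribution sweep trades TPr against TNr monotonically", {
  pl <- make_planted_instances(planted_signal_config(
    n_proteins = 8, residues_per_protein = 30, n_informative = 1,
    n_noise = 2, positive_fraction = 0.5, seed = 4))
  sw <- distribution_sweep(pl, fractions = c(0.3, 0.5, 0.7),
                           learner = logistic_learner(), seed = 2)
  expect_equal(nrow(sw), 3)
  # ascending TPr, descending TNr, tolerating one inversion from sampling
  expect_lte(sum(diff(sw$tpr) < -1e-9), 1)
  expect_lte(sum(diff(sw$tnr) > 1e-9), 1)
  expect_true(attr(sw, "crossing") >= 0.3 && attr(sw, "crossing") <= 0.7)

  one <- distribution_sweep(pl, fractions = 0.5, learner = logistic_learner())
  expect_equal(nrow(one), 1)
})

test_that("iterative removal drops the noisiest protein first", {
  pl <- make_planted_instances(planted_signal_config(
    n_proteins = 6, residues_per_protein = 30, n_informative = 1,
    n_noise = 1, effect_size = 2.5, positive_fraction = 0.4, seed = 8))
  # protein P03: pure label noise
  noisy <- pl$protein_id == "P03"
  set.seed(99)
  pl$label[noisy] <- sample(pl$label[noisy])
  pl$inf1[noisy] <- rnorm(sum(noisy))
  tr <- iterative_removal(pl, logistic_learner(), steps = 3,
                          tracked = c("P01", "P02"))
  expect_equal(nrow(tr), 3)
  expect_equal(anyDuplicated(tr$removed), 0)
  expect_equal(tr$removed[1], "P03")
  tracked <- attr(tr, "tracked")
  # tracked proteins have one entry per step while still present
  expect_equal(nrow(tracked), 2 * 3)
  expect_setequal(unique(tracked$protein_id), c("P01", "P02"))
})
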