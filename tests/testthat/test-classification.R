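test_that("NSA binarization is total, idempotent in effect, and validated", {
  lab <- binarize_nsa(1:6)
  expect_identical(as.character(lab),
                   c("non_observable", "non_observable", rep("observable", 4)))
  expect_identical(levels(lab), c("non_observable", "observable"))
  expect_error(binarize_nsa(0), "\\[1, 6\\]")
  expect_error(binarize_nsa(7), "\\[1, 6\\]")
  expect_error(binarize_nsa(2.5), "\\[1, 6\\]")
})

test_that("CFS merit evaluates its closed form", {
  r_cf <- c(a = 0.6, b = 0.5, c = 0.5)
  r_ff <- matrix(0, 3, 3, dimnames = list(names(r_cf), names(r_cf)))
  expect_equal(cfs_merit("a", r_cf, r_ff), 0.6)

  r_ff_all1 <- r_ff; r_ff_all1[] <- 1
  expect_equal(cfs_merit(c("b", "c"), r_cf, r_ff_all1), 0.5)
  expect_equal(cfs_merit(c("b", "c"), r_cf, r_ff), 1 / sqrt(2) * 0.5 * 2,
               tolerance = 1e-9)
  expect_error(cfs_merit(character(0), r_cf, r_ff), "non-empty")
})

test_that("CFS merit matches brute-force evaluation on random structures", {
  set.seed(31)
  for (rep in 1:100) {
    p <- 6
    nm <- letters[1:p]
    r_cf <- stats::setNames(stats::runif(p), nm)
    m <- matrix(stats::runif(p * p), p, p, dimnames = list(nm, nm))
    r_ff <- (m + t(m)) / 2
    diag(r_ff) <- 1
    for (k in 1:4) {
      subs <- utils::combn(nm, k, simplify = FALSE)
      for (s in subs[sample(length(subs), min(5, length(subs)))]) {
        # independent literal evaluation
        rcf_bar <- sum(r_cf[s]) / k
        rff_sum <- 0; n_pairs <- 0
        if (k > 1) {
          for (i in 1:(k - 1)) for (j in (i + 1):k) {
            rff_sum <- rff_sum + r_ff[s[i], s[j]]
            n_pairs <- n_pairs + 1
          }
        }
        rff_bar <- if (n_pairs > 0) rff_sum / n_pairs else 0
        want <- k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
        expect_equal(cfs_merit(s, r_cf, r_ff), want, tolerance = 1e-12)
      }
    }
  }
})

test_that("CFS search prefers informative, non-redundant features", {
  set.seed(41)
  n <- 60
  y <- factor(rep(c("no", "yes"), each = n / 2))
  signal <- as.numeric(y) + stats::rnorm(n, 0, 0.1)
  X <- data.frame(signal = signal,
                  dup = signal + stats::rnorm(n, 0, 0.01),
                  n1 = stats::rnorm(n), n2 = stats::rnorm(n),
                  n3 = stats::rnorm(n))
  sel <- cfs_select(X, y)
  expect_true("signal" %in% sel$selected || "dup" %in% sel$selected)
  # near-duplicates are not both kept
  expect_false(all(c("signal", "dup") %in% sel$selected))
  expect_false(any(c("n1", "n2", "n3") %in% sel$selected))

  expect_error(cfs_select(X, factor(rep("yes", n))), "constant")
  expect_error(cfs_select(data.frame(a = rep(1, n), b = rep(2, n)), y),
               "constant")
})

test_that("correlation ranking sorts by |r| with deterministic ties", {
  set.seed(51)
  n <- 50
  y <- factor(rep(c("no", "yes"), each = n / 2))
  X <- data.frame(exact = as.numeric(y),
                  weak = as.numeric(y) + stats::rnorm(n, 0, 3),
                  noise = stats::rnorm(n))
  sel <- correlation_rank_select(X, y, k = 1)
  expect_identical(sel$selected, "exact")
  expect_equal(unname(sel$merit), 1)

  sel_all <- correlation_rank_select(X, y, k = 3)
  y01 <- as.numeric(y) - 1
  want <- names(sort(-abs(sapply(X, function(v) stats::cor(v, y01)))))
  expect_identical(sel_all$selected, want)
  expect_warning(correlation_rank_select(X, y, k = 10), "clipping")
  expect_error(correlation_rank_select(X, y, k = 0), "k must be")
})

test_that("confusion-matrix metrics reproduce published arithmetic", {
  # patient-vs-healthy rows: accuracy %, precision/recall/F to 2 decimals
  mlp <- matrix(c(44, 10, 5, 21), 2, 2, byrow = TRUE)
  m <- metrics_from_confusion(mlp)
  expect_lt(abs(m$accuracy - 81.3), 0.1)
  expect_lt(abs(m$precision - 0.90), 0.01)
  expect_lt(abs(m$recall - 0.82), 0.01)
  expect_lt(abs(m$f_score - 0.85), 0.01)

  # symptom-item row (non-observable vs observable)
  expect_lt(abs(metrics_from_confusion(matrix(c(33, 4, 7, 10), 2, 2,
                                              byrow = TRUE))$accuracy - 79.6),
            0.1)

  perfect <- metrics_from_confusion(diag(c(10, 10)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "all zero")
  expect_error(metrics_from_confusion(matrix(1, 3, 3)), "2x2")
  deg <- metrics_from_confusion(matrix(c(0, 0, 0, 5), 2, 2))
  expect_true(is.na(deg$precision))
})

test_that("LOOCV separates separable data and stays at chance on null data", {
  set.seed(61)
  n <- 40
  y <- factor(rep(c("ctrl", "case"), each = n / 2),
              levels = c("ctrl", "case"))
  X <- data.frame(f1 = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 6)),
                  f2 = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 6)))
  rep_sep <- loocv(X, y, classifier = "svm", selection = "none")
  expect_equal(rep_sep$accuracy, 100)
  expect_equal(rep_sep$auc, 1.0)

  accs <- vapply(1:20, function(s) {
    set.seed(800 + s)
    yp <- sample(y)
    loocv(X, yp, classifier = "svm", selection = "none", seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 35)
  expect_lte(mean(accs), 65)

  # constant features: majority-class behaviour, chance-level AUC
  y_imb <- factor(c(rep("ctrl", 25), rep("case", 15)),
                  levels = c("ctrl", "case"))
  Xc <- data.frame(f1 = rep(1, 40), f2 = rep(-2, 40))
  rep_c <- loocv(Xc, y_imb, classifier = "svm", selection = "none")
  expect_equal(rep_c$accuracy, 100 * 25 / 40)
  expect_equal(rep_c$auc, 0.5, tolerance = 0.05)
})

test_that("fold-nested selection does not leak the held-out subject", {
  set.seed(71)
  n <- 30
  y <- factor(rep(c("ctrl", "case"), n / 2), levels = c("ctrl", "case"))
  X <- as.data.frame(matrix(stats::rnorm(n * 10), n, 10))
  # a probe column informative only at one subject, noise elsewhere
  probe <- stats::rnorm(n, 0, 0.1)
  probe[7] <- if (y[7] == "case") 10 else -10
  X$probe <- probe
  rep_pr <- loocv(X, y, classifier = "svm", selection = "correlation", k = 3)
  expect_lte(rep_pr$accuracy, 65)
  # report metrics recompute exactly from the report's own confusion matrix
  m <- metrics_from_confusion(rep_pr$confusion)
  expect_equal(rep_pr$accuracy, m$accuracy)
  expect_equal(unname(rep_pr$precision[rep_pr$positive]), m$precision)
  expect_equal(unname(rep_pr$recall[rep_pr$positive]), m$recall)
})

test_that("all four classifier backends run and report coherently", {
  set.seed(81)
  n <- 24
  y <- factor(rep(c("ctrl", "case"), each = n / 2),
              levels = c("ctrl", "case"))
  X <- data.frame(f1 = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 4)),
                  f2 = stats::rnorm(n))
  for (clf in c("svm", "rf", "mlp", "bagging")) {
    r <- loocv(X, y, classifier = clf, selection = "none", seed = 3)
    expect_identical(sum(r$confusion), as.integer(n))
    expect_gte(r$accuracy, 75)
    expect_gte(r$auc, 0.8)
  }
  # determinism of the stochastic backends under a fixed seed
  r1 <- loocv(X, y, classifier = "rf", selection = "none", seed = 5)
  r2 <- loocv(X, y, classifier = "rf", selection = "none", seed = 5)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$auc, r2$auc)
})
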