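#' NSA-16 rating record columns
#'
#' Canonical column names for a ratings table: items 1-16 (6-point Likert,
#' higher = more severe), the global rating, the total (sum of items 1-16)
#' and the five domain sums: communication (items 1-4), emotion/affect (5-7),
#' social involvement (8-10), motivation (11-14), retardation (15-16).
#'
#' @return Character vector of rating column names.
#' @export
nsa_columns <- function() {
  c(paste0("nsa_", 1:16), "nsa_global", "nsa_total",
    "communication", "emotion_affect", "social_involvement",
    "motivation", "retardation")
}

#' Validate a ratings table
#'
#' Checks item ranges and the arithmetic identities between items, total and
#' domain sums.
#'
#' @param ratings Data frame with \code{subject_id}, \code{group} and the
#'   \code{\link{nsa_columns}}.
#' @return The ratings, invisibly; errors describe the first violation.
#' @export
validate_ratings <- function(ratings) {
  items <- as.matrix(ratings[paste0("nsa_", 1:16)])
  if (any(items < 1 | items > 6)) stop("NSA items must lie in [1, 6]")
  chk <- function(col, idx) {
    if (any(ratings[[col]] != rowSums(items[, idx, drop = FALSE]))) {
      stop(col, " must equal the sum of items ",
           paste(range(idx), collapse = "-"))
    }
  }
  chk("nsa_total", 1:16)
  chk("communication", 1:4)
  chk("emotion_affect", 5:7)
  chk("social_involvement", 8:10)
  chk("motivation", 11:14)
  chk("retardation", 15:16)
  invisible(ratings)
}

#' Pearson correlations between speech cues and NSA ratings
#'
#' One (r, p) pair per feature x rating item, using pairwise-complete
#' observations; p-values come from the t transform with n - 2 degrees of
#' freedom. Ordinal items are treated as numeric. Cells with a constant
#' feature or rating (or fewer than 3 complete pairs) are \code{NA}, never 0.
#' No multiplicity correction is applied by default; set
#' \code{adjust = "BH"} for Benjamini-Hochberg within the table.
#'
#' @param features Data frame with \code{subject_id} plus numeric feature
#'   columns.
#' @param ratings Data frame with \code{subject_id} plus rating columns.
#' @param rating_cols Rating columns to use (default \code{\link{nsa_columns}}
#'   intersected with what is present).
#' @param adjust "none" (default) or a \code{\link[stats]{p.adjust}} method.
#' @return A \code{cue_correlations} list with matrices \code{r} and \code{p}
#'   (features x items) and \code{n} subjects shared.
#' @export
correlation_table <- function(features, ratings,
                              rating_cols = NULL, adjust = "none") {
  merged <- merge(features, ratings, by = "subject_id")
  if (nrow(merged) < 3L) stop("need at least 3 shared subjects")
  feat_cols <- setdiff(names(features), "subject_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  if (is.null(rating_cols)) {
    rating_cols <- intersect(nsa_columns(), names(ratings))
  }
  r <- p <- matrix(NA_real_, length(feat_cols), length(rating_cols),
                   dimnames = list(feat_cols, rating_cols))
  for (f in feat_cols) {
    for (it in rating_cols) {
      x <- merged[[f]]; y <- merged[[it]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[f, it] <- unname(ct$estimate)
      p[f, it] <- ct$p.value
    }
  }
  if (adjust != "none") {
    p[] <- stats::p.adjust(p, method = adjust)
  }
  structure(list(r = r, p = p, n = nrow(merged)), class = "cue_correlations")
}

#' @export
print.cue_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("<cue_correlations> %d features x %d rating items (n = %d)\n",
              nrow(x$r), ncol(x$r), x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' Threshold a correlation table at a significance level
#'
#' @param table A \code{\link{correlation_table}} result.
#' @param alpha Significance level; a cell is flagged iff \code{p < alpha}
#'   (strict, default 0.05). Missing cells are \code{FALSE}.
#' @return Logical matrix of the same shape as \code{table$p}.
#' @export
significance_mask <- function(table, alpha = 0.05) {
  m <- table$p < alpha
  m[is.na(m)] <- FALSE
  m
}

#' Kruskal-Wallis comparison of one feature between groups
#'
#' Rank-based H with tie correction (via \code{\link[stats]{kruskal.test}})
#' and a chi-square p-value.
#'
#' @param values Numeric feature values.
#' @param groups Group labels (two groups for the patient-vs-control use).
#' @return A list with \code{H}, \code{p} and \code{df}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("each group needs at least 2 values")
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Kruskal-Wallis tests over a feature table
#'
#' Tests each feature for a group difference and, for features significant at
#' \code{alpha}, records five-number boxplot summaries per group (the
#' features one would plot).
#'
#' @param features Data frame with \code{subject_id} and numeric features.
#' @param groups Group label per row of \code{features}.
#' @param alpha Threshold for retaining boxplot summaries (default 0.01).
#' @return A \code{group_tests} list: data frame \code{tests}
#'   (feature, H, p) and list \code{boxplots} keyed by significant feature.
#' @export
kruskal_wallis_table <- function(features, groups, alpha = 0.01) {
  feat_cols <- setdiff(names(features), "subject_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  rows <- lapply(feat_cols, function(f) {
    res <- tryCatch(kruskal_wallis(features[[f]], groups),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(feature = f, H = NA_real_, p = NA_real_)
    } else {
      data.frame(feature = f, H = res$H, p = res$p)
    }
  })
  tests <- do.call(rbind, rows)
  sig <- tests$feature[!is.na(tests$p) & tests$p < alpha]
  boxplots <- lapply(stats::setNames(sig, sig), function(f) {
    tapply(features[[f]], as.factor(groups), function(v) {
      stats::fivenum(v[is.finite(v)])
    })
  })
  structure(list(tests = tests, boxplots = boxplots, alpha = alpha),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf("<group_tests> %d features; %d significant at p < %g\n",
              nrow(x$tests), length(x$boxplots), x$alpha))
  print(x$tests[order(x$tests$p), ], row.names = FALSE)
  invisible(x)
}

#' @export
plot.group_tests <- function(x, features, groups, ...) {
  sig <- names(x$boxplots)
  if (length(sig) == 0L) {
    message("no features significant at p < ", x$alpha)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(ceiling(length(sig) / 3), min(3, length(sig))))
  on.exit(graphics::par(old))
  for (f in sig) {
    graphics::boxplot(features[[f]] ~ as.factor(groups), main = f,
                      xlab = "", ylab = f, ...)
  }
  invisible(x)
}
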