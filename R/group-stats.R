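# Univariate pre/post change statistics: pooled z-scoring, two-group OLS
# change regressions with Bonferroni family control, concurrent-validity OLS.

#' Compute the standardized change table
#'
#' Each measure is z-scored with the mean and SD pooled over all
#' participants and both sessions (pre and post together), and the change is
#' z(post) - z(pre) per participant. Measures with (near) zero pooled SD are
#' dropped with a warning.
#'
#' @param cohort a `cohort_table` ([generate_cohort()]) or any list with
#'   `participants` (participant_id, condition) and aligned `pre`/`post`
#'   matrices.
#' @return data.frame of class `change_table`: `participant_id`,
#'   `condition`, one column per retained measure.
#' @export
compute_change_table <- function(cohort) {
  pre <- as.matrix(cohort$pre)
  post <- as.matrix(cohort$post)
  stopifnot(identical(dim(pre), dim(post)),
            identical(colnames(pre), colnames(post)))
  keep <- character(0)
  changes <- list()
  for (m in colnames(pre)) {
    pooled <- c(pre[, m], post[, m])
    s <- sd(pooled)
    if (!is.finite(s) || s < 1e-12) {
      warning("dropping measure '", m, "' (zero pooled SD)")
      next
    }
    mu <- mean(pooled)
    changes[[m]] <- (post[, m] - mu) / s - (pre[, m] - mu) / s
    keep <- c(keep, m)
  }
  out <- data.frame(
    participant_id = cohort$participants$participant_id,
    condition = cohort$participants$condition,
    stringsAsFactors = FALSE
  )
  for (m in keep) out[[m]] <- changes[[m]]
  class(out) <- c("change_table", "data.frame")
  attr(out, "measures") <- keep
  out
}

#' Two-group change regression for one measure
#'
#' Ordinary least squares of the change score on an intercept and the
#' dummy-coded intervention condition (positive arm = 1). The intercept
#' estimates the mean change in the negative arm; intercept + coefficient
#' estimates the mean change in the positive arm. Two-sided t-test p-values.
#'
#' @param change numeric change scores.
#' @param condition 0/1 intervention indicator (both levels required).
#' @return one-row data.frame: `intercept`, `intercept_p`,
#'   `intervention_coef`, `intervention_p`, `n`.
#' @export
fit_change_regression <- function(change, condition) {
  stopifnot(length(change) == length(condition))
  ok <- is.finite(change) & is.finite(condition)
  change <- change[ok]; condition <- condition[ok]
  if (length(unique(condition)) < 2) {
    stop("both intervention conditions must be represented")
  }
  fit <- lm(change ~ condition)
  s <- summary(fit)$coefficients
  data.frame(
    intercept = s[1, 1], intercept_p = s[1, 4],
    intervention_coef = s[2, 1], intervention_p = s[2, 4],
    n = length(change)
  )
}

#' Bonferroni-adjusted per-test alpha
#'
#' @param family_size number of tests in the family (>= 1).
#' @param familywise familywise error rate (default 0.05).
#' @return adjusted alpha = familywise / family_size. With the study's
#'   families: 18 cognitive measures give 0.0028 and 14 self-report
#'   measures give 0.0036 (4 dp).
#' @export
bonferroni_alpha <- function(family_size, familywise = 0.05) {
  if (length(family_size) != 1 || family_size < 1) {
    stop("family_size must be a single value >= 1")
  }
  familywise / family_size
}

#' Change regressions for a measure family
#'
#' Runs [fit_change_regression()] for every measure column of a change
#' table and attaches the Bonferroni-adjusted alpha for the family (family
#' size = number of measures unless overridden).
#'
#' @param change_table a [compute_change_table()] result (or any data.frame
#'   with `condition` plus measure columns).
#' @param measures measure columns to analyse (default: all).
#' @param family family label recorded in the output.
#' @param family_size Bonferroni family size (default `length(measures)`).
#' @param familywise familywise error rate (default 0.05).
#' @return data.frame of class `change_regression`: one row per measure
#'   with estimates, p-values, `alpha_adjusted` and `significant` flag.
#' @export
change_regressions <- function(change_table, measures = NULL,
                               family = "measures", family_size = NULL,
                               familywise = 0.05) {
  if (is.null(measures)) {
    measures <- attr(change_table, "measures") %||%
      setdiff(names(change_table), c("participant_id", "condition"))
  }
  family_size <- family_size %||% length(measures)
  alpha <- bonferroni_alpha(family_size, familywise)
  rows <- lapply(measures, function(m) {
    r <- fit_change_regression(change_table[[m]], change_table$condition)
    cbind(data.frame(measure = m, family = family,
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$alpha_adjusted <- alpha
  out$significant <- out$intervention_p < alpha
  class(out) <- c("change_regression", "data.frame")
  out
}

#' @export
print.change_regression <- function(x, digits = 3, ...) {
  cat("Change regressions (", nrow(x), " measures, family '",
      x$family[1], "', adjusted alpha ",
      format(x$alpha_adjusted[1], digits = 2), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Concurrent-validity regressions
#'
#' One OLS model per dependent variable: the self-report change score
#' regressed on the full feature set (all columns of `features`). Reports
#' the overall F test, R-squared, and per-coefficient t-tests; the
#' significance flag uses the Bonferroni-adjusted alpha for the DV family
#' (0.05 / 14 with the study's 14 self-report measures).
#'
#' @param dv_table data.frame holding the DV columns (rows aligned with
#'   `features`).
#' @param features data.frame/matrix of independent variables.
#' @param dv_names DV columns to model (default: all non-id columns of
#'   `dv_table`).
#' @param family_size Bonferroni family size for the DV family (default 14).
#' @param familywise familywise error rate (default 0.05).
#' @return list of class `concurrent_validity`: `summary` (one row per DV:
#'   F, df, p, r_squared, significant) and `coefficients` (named list of
#'   per-DV coefficient tables).
#' @export
concurrent_validity <- function(dv_table, features, dv_names = NULL,
                                family_size = 14, familywise = 0.05) {
  X <- as.data.frame(features)
  if (is.null(dv_names)) {
    dv_names <- setdiff(names(dv_table), c("participant_id", "condition"))
  }
  stopifnot(nrow(dv_table) == nrow(X))
  if (nrow(X) <= ncol(X) + 1) {
    stop("need more observations than IVs + 1")
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  alpha <- bonferroni_alpha(family_size, familywise)
  coefs <- list()
  rows <- lapply(dv_names, function(dv) {
    dat <- cbind(.dv = dv_table[[dv]], X)
    fit <- lm(.dv ~ ., data = dat)
    s <- summary(fit)
    f <- s$fstatistic
    p <- pf(f[1], f[2], f[3], lower.tail = FALSE)
    coefs[[dv]] <<- as.data.frame(s$coefficients)
    data.frame(dv = dv, f_statistic = unname(f[1]),
               df1 = unname(f[2]), df2 = unname(f[3]),
               p = unname(p), r_squared = s$r.squared,
               significant = unname(p) < alpha,
               stringsAsFactors = FALSE)
  })
  structure(
    list(summary = do.call(rbind, rows), coefficients = coefs,
         alpha_adjusted = alpha),
    class = "concurrent_validity"
  )
}

#' @export
print.concurrent_validity <- function(x, digits = 3, ...) {
  cat("Concurrent-validity OLS models (adjusted alpha ",
      format(x$alpha_adjusted, digits = 2), "):\n", sep = "")
  print(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}
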