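#' @export
print.pyloric_stat <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s: %s = %.4f, df = %s, p = %.4g (n = %s)\n",
              x$test, x$statistic_name, x$statistic, dfs, x$p,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

stat_result <- function(test, statistic_name, statistic, df, p, n, estimate = NULL) {
  structure(list(test = test, statistic_name = statistic_name,
                 statistic = statistic, df = df, p = min(max(p, 0), 1),
                 n = n, estimate = estimate),
            class = "pyloric_stat")
}

#' Pearson correlation with a t-based two-sided p value
#'
#' Sample Pearson R; significance from `t = R * sqrt((n - 2) / (1 - R^2))`
#' against a t distribution with `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite, non-constant).
#' @return `pyloric_stat` with `statistic` = R, `df = n - 2`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  stat_result("Pearson correlation", "R", r, n - 2L, p, n)
}

#' Paired t test
#'
#' `t = mean(d) / (SD(d) / sqrt(n))` on the paired differences `d = a - b`,
#' with `n - 1` degrees of freedom, two-sided.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @return `pyloric_stat` with `estimate` = mean difference.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) != 0) stop("all differences identical and nonzero: t undefined")
    return(stat_result("paired t", "t", 0, n - 1L, 1, n, estimate = 0))
  }
  tt <- mean(d) / (s / sqrt(n))
  stat_result("paired t", "t", tt, n - 1L, 2 * stats::pt(-abs(tt), n - 1),
              n, estimate = mean(d))
}

#' Unpaired two-sample t test
#'
#' Pooled-variance t by default (groups with similar n and variances);
#' `equal_var = FALSE` gives the Welch form with Satterthwaite degrees of
#' freedom.
#'
#' @param a,b numeric vectors.
#' @param equal_var logical, pooled variance (default `TRUE`).
#' @return `pyloric_stat` with `estimate` = mean difference.
#' @export
unpaired_t <- function(a, b, equal_var = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) stop("both groups have zero variance: t undefined")
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (mean(a) - mean(b)) / se
  stat_result(if (equal_var) "unpaired t (pooled)" else "unpaired t (Welch)",
              "t", tt, df, 2 * stats::pt(-abs(tt), df), c(n1, n2),
              estimate = mean(a) - mean(b))
}

#' Mood's median test
#'
#' Appropriate for comparing groups of very different sizes and variances:
#' counts observations above vs at-or-below the grand median of the pooled
#' data in a 2x2 table per group and applies the Pearson chi-square test
#' (1 df, no continuity correction). Ties at the grand median count in the
#' "at or below" cell.
#'
#' @param a,b numeric vectors.
#' @return `pyloric_stat` with `statistic` = chi-square, `df = 1`; the 2x2
#'   table is in `estimate`.
#' @examples
#' moods_median(c(1, 2, 3, 4), c(5, 6, 7, 8))  # chi-square = 8
#' @export
moods_median <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  gm <- stats::median(c(a, b))
  tab <- rbind(a = c(above = sum(a > gm), at_or_below = sum(a <= gm)),
               b = c(above = sum(b > gm), at_or_below = sum(b <= gm)))
  if (any(colSums(tab) == 0L))
    stop("degenerate table: all values on one side of the grand median")
  chisq <- pearson_chisq_2x2(tab)
  stat_result("Mood's median test", "chi-square", chisq, 1L,
              stats::pchisq(chisq, 1, lower.tail = FALSE),
              c(length(a), length(b)), estimate = tab)
}

# Pearson chi-square for a 2x2 table, no continuity correction
pearson_chisq_2x2 <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

#' Split-plot (two-way mixed) ANOVA
#'
#' Classical univariate split-plot decomposition for one between-subjects
#' factor (e.g. decentralization state) crossed with one within-subjects
#' factor (e.g. day). Sums of squares: group; subjects-within-groups
#' (between-subjects error); within factor; group x within interaction; and
#' the within x subjects-within-groups residual (within-subjects error).
#' `F_group = MS_group / MS_subj_within`;
#' `F_within = MS_within / MS_resid`;
#' `F_interaction = MS_interaction / MS_resid`. Unequal group sizes are
#' handled by the standard cell-mean formulas weighted by per-group n (the
#' design has proportional cell frequencies, so the decomposition is
#' orthogonal). No sphericity correction is applied by default;
#' `gg_correct = TRUE` applies the Greenhouse-Geisser epsilon to the
#' within-subjects and interaction tests.
#'
#' @param values numeric matrix, one row per subject and one column per
#'   within-factor level; every subject must be complete (rows with NAs are
#'   dropped with a message).
#' @param groups factor or vector of between-subjects group labels, one per
#'   row of `values`; every group needs >= 2 subjects.
#' @param gg_correct logical, apply Greenhouse-Geisser correction.
#' @return an object of class `pyloric_anova`: `table` (data.frame of SS,
#'   df, MS, F, p per stratum), `F_between`, `p_between`, `F_within`,
#'   `p_within`, `F_interaction`, `p_interaction`, `epsilon` (when
#'   corrected).
#' @export
mixed_anova <- function(values, groups, gg_correct = FALSE) {
  values <- as.matrix(values)
  groups <- as.factor(groups)
  stopifnot(nrow(values) == length(groups))
  complete <- stats::complete.cases(values)
  if (!all(complete)) {
    message(sprintf("dropping %d subject(s) with missing within-factor levels",
                    sum(!complete)))
    values <- values[complete, , drop = FALSE]
    groups <- droplevels(groups[complete])
  }
  ng <- table(groups)
  if (any(ng < 2L)) stop("every group needs at least 2 complete subjects")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  Tn <- ncol(values)
  if (Tn < 2L) stop("need at least 2 within-factor levels")
  N <- nrow(values)

  grand <- mean(values)
  subj_mean <- rowMeans(values)
  time_mean <- colMeans(values)                     # balanced over subjects
  group_mean <- tapply(subj_mean, groups, mean)
  cell_mean <- apply(values, 2, function(col) tapply(col, groups, mean))
  # cell_mean: groups x levels

  ss_total <- sum((values - grand)^2)
  ss_between_subj <- Tn * sum((subj_mean - grand)^2)
  ss_group <- Tn * sum(ng * (group_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_within_subj <- sum((values - subj_mean)^2)     # recycles by column
  ss_time <- N * sum((time_mean - grand)^2)
  ss_cells <- Tn_cells_ss(cell_mean, ng, grand)
  ss_inter <- ss_cells - ss_group - ss_time
  ss_resid <- ss_within_subj - ss_time - ss_inter

  df_group <- nlevels(groups) - 1L
  df_subj <- N - nlevels(groups)
  df_time <- Tn - 1L
  df_inter <- df_group * df_time
  df_resid <- df_subj * df_time

  ms <- c(ss_group / df_group, ss_subj_within / df_subj, ss_time / df_time,
          ss_inter / df_inter, ss_resid / df_resid)
  if (ms[2] <= 0 || ms[5] <= 0) stop("zero error mean square: F undefined")
  F_between <- ms[1] / ms[2]
  F_within <- ms[3] / ms[5]
  F_inter <- ms[4] / ms[5]

  eps <- NA_real_
  df_time_eff <- df_time; df_inter_eff <- df_inter; df_resid_eff <- df_resid
  if (gg_correct) {
    eps <- gg_epsilon(values, groups)
    df_time_eff <- eps * df_time
    df_inter_eff <- eps * df_inter
    df_resid_eff <- eps * df_resid
  }
  p_between <- stats::pf(F_between, df_group, df_subj, lower.tail = FALSE)
  p_within <- stats::pf(F_within, df_time_eff, df_resid_eff, lower.tail = FALSE)
  p_inter <- stats::pf(F_inter, df_inter_eff, df_resid_eff, lower.tail = FALSE)

  tab <- data.frame(
    term = c("group", "subjects_within_groups", "within", "group_x_within",
             "within_x_subjects", "total"),
    SS = c(ss_group, ss_subj_within, ss_time, ss_inter, ss_resid, ss_total),
    df = c(df_group, df_subj, df_time, df_inter, df_resid, N * Tn - 1L),
    MS = c(ms, NA),
    F = c(F_between, NA, F_within, F_inter, NA, NA),
    p = c(p_between, NA, p_within, p_inter, NA, NA))
  structure(list(table = tab,
                 F_between = F_between, p_between = p_between,
                 F_within = F_within, p_within = p_within,
                 F_interaction = F_inter, p_interaction = p_inter,
                 epsilon = eps, n_per_group = as.integer(ng),
                 n_levels = Tn),
            class = "pyloric_anova")
}

# weighted SS of the group x level cell means about the grand mean
Tn_cells_ss <- function(cell_mean, ng, grand) {
  sum(sweep((cell_mean - grand)^2, 1, as.numeric(ng), `*`))
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures
gg_epsilon <- function(values, groups) {
  Tn <- ncol(values)
  centered <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g, , drop = FALSE]
    sweep(v, 2, colMeans(v))
  }))
  S <- crossprod(centered) / (nrow(values) - nlevels(groups))
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (Tn * (dbar - sbar))^2
  den <- (Tn - 1) * (sum(S^2) - 2 * Tn * sum(rowMeans(S)^2) + Tn^2 * sbar^2)
  max(1 / (Tn - 1), min(1, num / den))
}

#' @export
print.pyloric_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Split-plot mixed ANOVA (%s subjects per group, %d within levels)\n",
              paste(x$n_per_group, collapse = "/"), x$n_levels))
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$F <- signif(tab$F, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  if (!is.na(x$epsilon))
    cat(sprintf("Greenhouse-Geisser epsilon = %.4f\n", x$epsilon))
  invisible(x)
}
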