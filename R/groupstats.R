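# Nonparametric case-control statistics: Lilliefors normality screen,
# Kruskal-Wallis omnibus, exact/approximate Mann-Whitney post-hoc tests,
# Benjamini-Hochberg FDR, and the per-electrode group-comparison table.

#' Round half away from zero
#'
#' `base::round()` rounds half to even; result tables use conventional
#' half-up rounding so printed values match clinical-paper formatting.
#'
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal with mean and SD estimated
#' from the data; the p-value uses the Dallal-Wilkinson (1986)
#' approximation for the Lilliefors null distribution (accurate in the
#' decision-relevant region p < ~0.1; larger p-values are conservative
#' and capped at 1).
#'
#' @param values numeric vector, n >= 5, non-constant
#' @param alpha decision level for `is_normal` (default 0.05)
#' @return list with `statistic` (sup-distance D), `p`, `is_normal`
#' @export
ks_normality <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 5) stop("ks_normality requires n >= 5", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate (constant) input: normality is undefined",
         call. = FALSE)
  }
  x <- sort(values)
  z <- stats::pnorm((x - mean(x)) / s)
  D <- max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
  if (n > 100) {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- D
    nd <- n
  }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) -
             0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  p <- min(1, max(0, p))
  list(statistic = D, p = p, is_normal = p >= alpha)
}

# Exact null distribution of the Mann-Whitney U statistic: counts of rank
# configurations with U = 0..m*n, by the standard recurrence
# N(u | m, n) = N(u - n | m - 1, n) + N(u | m, n - 1).
mwu_exact_counts <- function(m, n) {
  arr <- array(0, dim = c(m + 1, n + 1, m * n + 1))
  arr[1, , 1] <- 1
  arr[, 1, 1] <- 1
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      for (u in 0:(i * j)) {
        v <- arr[i + 1, j, u + 1]
        if (u - j >= 0) v <- v + arr[i, j + 1, u - j + 1]
        arr[i + 1, j + 1, u + 1] <- v
      }
    }
  }
  arr[m + 1, n + 1, ]
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' `U` counts the pairs in which the first sample exceeds the second,
#' plus half the tied pairs. The two-sided p-value is exact (from the
#' full permutation distribution of U) for tie-free samples with
#' `length(x) + length(y) <= exact_max`, otherwise a normal approximation
#' with tie correction and (optionally) continuity correction is used.
#'
#' @param x,y numeric samples, each non-empty
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact branch;
#'   `NULL` (default) decides automatically
#' @param correct apply the continuity correction in the approximation
#' @param exact_max largest total n for the automatic exact branch
#' @return list with `U`, `p` (two-sided), `method`
#' @export
mann_whitney <- function(x, y, exact = NULL, correct = TRUE,
                         exact_max = 12) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty", call. = FALSE)
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  N <- nx + ny
  has_ties <- anyDuplicated(all_v) > 0
  use_exact <- if (is.null(exact)) (N <= exact_max && !has_ties) else exact
  if (use_exact && !has_ties) {
    cnt <- mwu_exact_counts(nx, ny)
    tot <- sum(cnt)
    p_le <- sum(cnt[seq_len(U + 1)]) / tot
    p_ge <- sum(cnt[(U + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tab <- table(all_v)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, p = 1, method = "normal_approx"))
  }
  z <- U - mu
  if (correct) z <- sign(z) * max(0, abs(z) - 0.5)
  p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  list(U = U, p = p, method = "normal_approx")
}

#' Kruskal-Wallis rank-sum test
#'
#' H from mid-rank sums with the usual tie correction; p from the
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   total n >= 5)
#' @return list with `H`, `p`, `df`
#' @export
kruskal_wallis <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  if (k < 2 || any(ns < 1)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  all_v <- unlist(groups, use.names = FALSE)
  N <- length(all_v)
  if (diff(range(all_v)) == 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  r <- rank(all_v)
  idx <- rep(seq_len(k), ns)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  tab <- table(all_v)
  C <- 1 - sum(tab^3 - tab) / (N^3 - N)
  if (C > 0) H <- H / C
  list(H = H, p = stats::pchisq(H, k - 1, lower.tail = FALSE), df = k - 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, q_i = p_i * n / i, enforce
#' monotonicity from the largest rank down by cumulative minimum, cap at
#' 1, return in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order as the input
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

iqr_linear <- function(v) {
  qs <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  qs[2] - qs[1]
}

metric_columns <- function(metric_table, prefix, electrodes) {
  cols <- paste0(prefix, "_", electrodes)
  missing <- setdiff(cols, names(metric_table))
  if (length(missing) > 0) {
    stop("metric table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols
}

#' Per-electrode case-control comparison of alpha-band PSD
#'
#' For every region-of-interest electrode: group medians and IQRs
#' (linear-interpolation quartiles), a two-sided Mann-Whitney test, and
#' Benjamini-Hochberg adjustment across exactly the ROI electrodes. The
#' omnibus gatekeeper is a Kruskal-Wallis test on each subject's mean
#' alpha PSD over the ROI; post-hoc results are reported regardless and
#' flagged non-confirmatory when the omnibus p >= `alpha_level`.
#'
#' Rows with a missing value in any tested column are excluded (with a
#' message naming the subjects).
#'
#' @param metric_table data frame with a `group` column (values `"case"`
#'   and `"control"`) and one `alpha_<electrode>` column per electrode
#' @param roi electrodes tested (and the FDR family), default
#'   [roi_electrodes()]
#' @param alpha_level significance level (default 0.05)
#' @return an object of class `group_comparison`: `$table` (electrode,
#'   median_case, median_control, iqr_case, iqr_control, U, p_raw,
#'   p_fdr), `$omnibus_H`, `$omnibus_p`, `$nonconfirmatory`,
#'   `$alpha_level`, `$n_case`, `$n_control`
#' @export
compare_groups <- function(metric_table, roi = roi_electrodes(),
                           alpha_level = 0.05) {
  cols <- metric_columns(metric_table, "alpha", roi)
  keep <- stats::complete.cases(metric_table[, cols])
  if (any(!keep)) {
    message("excluding ", sum(!keep), " subject(s) with missing electrodes: ",
            paste(metric_table$subject_id[!keep], collapse = ", "))
    metric_table <- metric_table[keep, , drop = FALSE]
  }
  is_case <- metric_table$group == "case"
  if (sum(is_case) == 0 || sum(!is_case) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  rows <- lapply(roi, function(el) {
    v <- metric_table[[paste0("alpha_", el)]]
    xc <- v[is_case]; xk <- v[!is_case]
    mw <- mann_whitney(xc, xk)
    data.frame(
      electrode = el,
      median_case = stats::median(xc), median_control = stats::median(xk),
      iqr_case = iqr_linear(xc), iqr_control = iqr_linear(xk),
      U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- bh_fdr(tab$p_raw)
  roi_mean <- rowMeans(metric_table[, cols])
  kw <- kruskal_wallis(list(roi_mean[is_case], roi_mean[!is_case]))
  structure(
    list(table = tab, omnibus_H = kw$H, omnibus_p = kw$p,
         nonconfirmatory = kw$p >= alpha_level, alpha_level = alpha_level,
         n_case = sum(is_case), n_control = sum(!is_case)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d cases vs %d controls; omnibus H = %.3f, p = %.3f%s\n",
              x$n_case, x$n_control, x$omnibus_H, x$omnibus_p,
              if (x$nonconfirmatory) " (post-hoc non-confirmatory)" else ""))
  print(format(x))
  invisible(x)
}

#' @export
format.group_comparison <- function(x, digits = 3, ...) {
  t <- x$table
  data.frame(
    Electrode = t$electrode,
    `Median case` = round_half_up(t$median_case, digits),
    `Median control` = round_half_up(t$median_control, digits),
    `IQR case` = round_half_up(t$iqr_case, digits),
    `IQR control` = round_half_up(t$iqr_control, digits),
    p = round_half_up(t$p_raw, digits),
    p_FDR = round_half_up(t$p_fdr, digits),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Write a group comparison to disk
#'
#' @param comparison a `group_comparison`
#' @param path output path; `.json` gets the full unrounded object,
#'   anything else a tab-separated table rounded to 3 decimals
#' @return `path`, invisibly
#' @export
write_comparison <- function(comparison, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(table = comparison$table, omnibus_H = comparison$omnibus_H,
           omnibus_p = comparison$omnibus_p,
           nonconfirmatory = comparison$nonconfirmatory,
           alpha_level = comparison$alpha_level),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(format(comparison), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Occipital IAF comparison, optionally stratified by migraine
#'
#' Per electrode, compares the individual alpha peak frequency between
#' the groups. With stratification the omnibus Kruskal-Wallis runs across
#' the group x migraine cells; per-stratum Mann-Whitney post-hoc tests
#' are computed only when the omnibus is significant (otherwise no
#' further statistical analyses are carried out). Strata with fewer than
#' 2 subjects on either side are flagged and skipped.
#'
#' @param metric_table data frame with `group`, `migraine` and
#'   `iaf_<electrode>` columns
#' @param electrodes electrodes examined (default O1, O2)
#' @param stratify_by_migraine stratify by the migraine flag (default
#'   TRUE)
#' @param alpha_level omnibus significance gate
#' @return list with `summaries` (per electrode x stratum x group: n,
#'   median, min, max, IQR), `omnibus` (per electrode: H, p, strata
#'   used), `posthoc` (possibly empty), `flags` (skipped strata)
#' @export
iaf_comparison <- function(metric_table, electrodes = c("O1", "O2"),
                           stratify_by_migraine = TRUE,
                           alpha_level = 0.05) {
  metric_columns(metric_table, "iaf", electrodes)
  strata <- if (stratify_by_migraine) {
    ifelse(metric_table$migraine, "migraine", "no_migraine")
  } else {
    rep("all", nrow(metric_table))
  }
  summaries <- NULL
  omnibus <- NULL
  posthoc <- NULL
  flags <- character(0)
  for (el in electrodes) {
    v <- metric_table[[paste0("iaf_", el)]]
    cells <- split(v, interaction(metric_table$group, strata, drop = TRUE))
    for (nm in names(cells)) {
      cv <- cells[[nm]]
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      summaries <- rbind(summaries, data.frame(
        electrode = el, group = parts[1], stratum = parts[2],
        n = length(cv), median = stats::median(cv), min = min(cv),
        max = max(cv), iqr = iqr_linear(cv), stringsAsFactors = FALSE
      ))
    }
    ok <- vapply(cells, length, integer(1)) >= 2
    if (any(!ok)) {
      flags <- c(flags, paste0(el, ": stratum cell(s) ",
                               paste(names(cells)[!ok], collapse = ", "),
                               " have n < 2; tests skipped"))
    }
    usable <- cells[ok]
    if (length(usable) < 2) {
      omnibus <- rbind(omnibus, data.frame(
        electrode = el, H = NA_real_, p = NA_real_,
        n_strata = length(usable), stringsAsFactors = FALSE))
      next
    }
    kw <- tryCatch(kruskal_wallis(usable), error = function(e) NULL)
    if (is.null(kw)) {
      omnibus <- rbind(omnibus, data.frame(
        electrode = el, H = NA_real_, p = NA_real_,
        n_strata = length(usable), stringsAsFactors = FALSE))
      next
    }
    omnibus <- rbind(omnibus, data.frame(
      electrode = el, H = kw$H, p = kw$p, n_strata = length(usable),
      stringsAsFactors = FALSE))
    if (kw$p < alpha_level) {
      for (st in unique(strata)) {
        xc <- v[metric_table$group == "case" & strata == st]
        xk <- v[metric_table$group == "control" & strata == st]
        if (length(xc) < 2 || length(xk) < 2) next
        mw <- mann_whitney(xc, xk)
        posthoc <- rbind(posthoc, data.frame(
          electrode = el, stratum = st, U = mw$U, p = mw$p,
          median_case = stats::median(xc), median_control = stats::median(xk),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(posthoc)) {
    posthoc <- data.frame(electrode = character(0), stratum = character(0),
                          U = numeric(0), p = numeric(0),
                          median_case = numeric(0),
                          median_control = numeric(0))
  }
  list(summaries = summaries, omnibus = omnibus, posthoc = posthoc,
       flags = flags)
}

#' Cohort demographics table
#'
#' Group counts, sex and migraine percentages, mean +/- SD age, and a
#' pooled-variance two-sample t-test on age with 95% CI.
#'
#' @param manifest cohort manifest (columns `group`, `age`, `sex`,
#'   `migraine`)
#' @param percent `"half_up"` (14/21 prints 66.7) or `"truncate"` (66.6)
#' @return list with `table` (one row per characteristic) and `age_test`
#'   (t, p, 95% CI, df)
#' @export
cohort_demographics <- function(manifest, percent = c("half_up", "truncate")) {
  percent <- match.arg(percent)
  pct <- function(k, n) {
    v <- 100 * k / n
    if (percent == "half_up") round_half_up(v, 1) else floor(v * 10) / 10
  }
  groups <- c("case", "control")
  row_of <- function(label, stat) {
    data.frame(characteristic = label,
               case = stat("case"), control = stat("control"),
               stringsAsFactors = FALSE)
  }
  g <- function(grp) manifest[manifest$group == grp, , drop = FALSE]
  tab <- rbind(
    row_of("n", function(grp) sprintf("%d", nrow(g(grp)))),
    row_of("Male sex - no. (%)", function(grp) {
      k <- sum(g(grp)$sex == "M"); n <- nrow(g(grp))
      sprintf("%d (%s)", k, format(pct(k, n), nsmall = 1))
    }),
    row_of("Migraine - no. (%)", function(grp) {
      k <- sum(g(grp)$migraine); n <- nrow(g(grp))
      sprintf("%d (%s)", k, format(pct(k, n), nsmall = 1))
    }),
    row_of("Age - mean +/- SD [yr]", function(grp) {
      sprintf("%.0f +/- %.1f", mean(g(grp)$age), stats::sd(g(grp)$age))
    })
  )
  a1 <- g("case")$age; a2 <- g("control")$age
  tt <- stats::t.test(a1, a2, var.equal = TRUE)
  list(table = tab,
       age_test = list(t = unname(tt$statistic), p = tt$p.value,
                       ci = unname(tt$conf.int), df = unname(tt$parameter)))
}
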