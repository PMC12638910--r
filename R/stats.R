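#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided rank-sum test with the Mann-Whitney U statistic. When both
#' groups have at most 10 observations and the pooled data are tie-free the
#' exact null distribution of U is used; otherwise the normal approximation
#' with tie correction and continuity correction. Degenerate data (all
#' pooled values identical) give p = 1.
#'
#' Cohen's d (pooled SD) and the post-hoc power of the corresponding
#' two-sample t test are attached when group sizes permit, along with the
#' rank-biserial correlation as a rank-native effect size.
#'
#' @param x,y numeric samples (n1, n2 >= 1).
#' @param alpha significance level used for the power computation.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   mode.
#' @param continuity apply the continuity correction on the normal path.
#' @return a one-row tibble: `U`, `p`, `n1`, `n2`, `effect_size` (Cohen's
#'   d), `power`, `rank_biserial`, `method`.
#' @export
ranksum <- function(x, y, alpha = 0.05, exact = NULL, continuity = TRUE) {
  n1 <- length(x)
  n2 <- length(y)
  stop_if_not(n1 >= 1 && n2 >= 1, "both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- exact %||% (n1 <= 10 && n2 <= 10 && !ties)
  if (use_exact && ties)
    warning("exact mode requested with ties; p-values are approximate")
  if (use_exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      if (continuity) z <- z - sign(z) * 0.5
      z <- z / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  es <- if (n1 >= 2 && n2 >= 2) posthoc_power(x, y, alpha = alpha)
        else list(effect_size = NA_real_, power = NA_real_)
  tibble::tibble(U = U, p = p, n1 = n1, n2 = n2,
                 effect_size = es$effect_size, power = es$power,
                 rank_biserial = 1 - 2 * U / (n1 * n2), method = method)
}

#' Post-hoc effect size and power
#'
#' Cohen's d with pooled SD and the achieved power of the two-sided
#' two-sample t test at the observed d and group sizes, computed from the
#' noncentral t distribution (the convention of standard power software).
#' At d = 0 the power equals alpha up to approximation tolerance.
#'
#' @param x,y numeric samples (n1, n2 >= 2), or omit them and give `d`,
#'   `n1`, `n2` directly.
#' @param d standardized mean difference (computed from `x`, `y` when
#'   omitted).
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @return list with `effect_size` and `power`; zero pooled SD gives `NA`
#'   effect size with a warning.
#' @export
posthoc_power <- function(x = NULL, y = NULL, d = NULL,
                          n1 = length(x), n2 = length(y), alpha = 0.05) {
  if (is.null(d)) {
    stop_if_not(n1 >= 2 && n2 >= 2, "need n1, n2 >= 2 for an effect size")
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    if (sp == 0) {
      warning("zero pooled SD: effect size undefined")
      return(list(effect_size = NA_real_, power = NA_real_))
    }
    d <- (mean(x) - mean(y)) / sp
  }
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tc <- stats::qt(1 - alpha / 2, df)
  # pt() warns about its last digit at extreme noncentrality; irrelevant here
  power <- suppressWarnings(1 - stats::pt(tc, df, ncp) +
                              stats::pt(-tc, df, ncp))
  list(effect_size = d, power = power)
}

#' Comparison plan
#'
#' Enumerates the pairwise contrasts of the study design: the three stage
#' pairs within each task (`"stages_within_task"`) or the three task pairs
#' within each stage (`"tasks_within_stage"`), for each measure and scalp
#' region.
#'
#' @param grouping contrast family.
#' @param measures band names (mean relative power over the region),
#'   `"amplitude"` (mean of the per-channel average amplitudes) or the name
#'   of any existing column of the feature table.
#' @param regions any of `"whole"`, `"left"`, `"right"`.
#' @param alpha significance level for stars and power.
#' @param adjust `"none"` (the study convention: uncorrected stars) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values.
#' @return a `comparison_plan` list.
#' @export
comparison_plan <- function(grouping = c("stages_within_task",
                                         "tasks_within_stage"),
                            measures = c("alpha", "low_beta", "high_beta"),
                            regions = "whole", alpha = 0.05,
                            adjust = c("none", "BH")) {
  grouping <- match.arg(grouping)
  adjust <- match.arg(adjust)
  structure(list(grouping = grouping, measures = measures, regions = regions,
                 alpha = alpha, adjust = adjust),
            class = "comparison_plan")
}

#' @keywords internal
region_measure <- function(features, measure, region,
                           montage = emotiv_montage()) {
  ch <- hemisphere_channels(region, montage)
  if (measure %in% names(features)) return(features[[measure]])
  suffix <- if (measure == "amplitude") "_amp" else paste0("_", measure)
  cols <- paste0(ch, suffix)
  stop_if_not(all(cols %in% names(features)),
              paste("feature table lacks columns for measure", measure))
  rowMeans(as.matrix(features[, cols]))
}

#' Run the pairwise comparison harness
#'
#' For each level of the fixed factor (task or stage), each measure and
#' each region, performs the rank-sum test for every pair of the varying
#' factor, with effect size, post-hoc power and significance stars
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Contrasts with an empty
#' group are skipped with a message.
#'
#' @param features tidy feature table from [extract_features()] (columns
#'   `stage`, `task`, features).
#' @param plan a [comparison_plan()].
#' @param montage montage tibble.
#' @return tibble with one row per executed contrast.
#' @export
run_comparisons <- function(features, plan = comparison_plan(),
                            montage = emotiv_montage()) {
  stop_if_not(inherits(plan, "comparison_plan"), "plan must be a comparison_plan")
  if (plan$grouping == "stages_within_task") {
    fixed <- "task"; varying <- "stage"
  } else {
    fixed <- "stage"; varying <- "task"
  }
  out <- list()
  for (fx in unique(features[[fixed]])) {
    sub <- features[features[[fixed]] == fx, ]
    lev <- sort(unique(sub[[varying]]))
    all_lev <- if (varying == "stage") 1:3 else c("lecture", "lab", "quiz")
    pairs <- utils::combn(all_lev, 2L, simplify = FALSE)
    for (ms in plan$measures) {
      for (rg in plan$regions) {
        vals <- region_measure(sub, ms, rg, montage)
        for (pr in pairs) {
          a <- vals[sub[[varying]] == pr[1]]
          b <- vals[sub[[varying]] == pr[2]]
          if (!length(a) || !length(b)) {
            message("skipping ", fixed, " ", fx, ", ", ms, ", ", rg, ": ",
                    pr[1], " vs ", pr[2], " (empty group)")
            next
          }
          rs <- ranksum(a, b, alpha = plan$alpha)
          row <- tibble::tibble(contrast = paste(pr[1], "vs", pr[2]),
                                measure = ms, region = rg, rs)
          row <- tibble::add_column(row, "{fixed}" := fx, .before = 1L)
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  stop_if_not(length(out) > 0, "no contrasts could be run")
  res <- do.call(rbind, out)
  if (plan$adjust == "BH") res$p <- stats::p.adjust(res$p, "BH")
  res$stars <- cut(res$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  res
}
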