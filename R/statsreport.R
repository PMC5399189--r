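#' Two-group comparison
#'
#' Unpaired two-sided Student's t test (pooled variance) or Mann-Whitney
#' (Wilcoxon rank-sum) test, with per-group mean +/- SEM and the effect
#' direction (sign of mean(B) - mean(A)).
#'
#' @param a,b numeric vectors, >= 2 values each.
#' @param method `"t_unpaired"` or `"mann_whitney"`.
#' @param metric name of the quantity compared.
#' @param labels length-2 character, group names.
#' @return an object of class `group_comparison`.
#' @examples
#' compare_two(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.021
#' @export
compare_two <- function(a, b, method = c("t_unpaired", "mann_whitney"),
                        metric = "metric", labels = c("A", "B")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop_param("each group needs >= 2 values")
  if (method == "t_unpaired") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop_param("zero variance in both groups; t-test degenerate")
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_name <- "Student's t (unpaired)"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test_name <- "Mann-Whitney"
  }
  diff <- mean(b) - mean(a)
  structure(list(
    metric = metric,
    groups = labels,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sem = c(sem(a), sem(b)),
    test = test_name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    adjusted_p = NA_real_,
    effect_direction = if (diff > 0) "up" else if (diff < 0) "down" else "none"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]\n", x$metric, x$test))
  for (i in 1:2)
    cat(sprintf("  %s: %.4g +/- %.3g (n = %d)\n",
                x$groups[i], x$mean[i], x$sem[i], x$n[i]))
  cat(sprintf("  statistic %.4g, p = %.4g%s; direction (%s vs %s): %s\n",
              x$statistic, x$p_value,
              if (!is.na(x$adjusted_p)) sprintf(" (adj. %.4g)", x$adjusted_p) else "",
              x$groups[2], x$groups[1], x$effect_direction))
  invisible(x)
}

#' Compare I-V relations between two groups of cells
#'
#' Per-cell current-density tables on a shared voltage grid are compared by
#' a two-way ANOVA (factors: group and voltage) in a repeated-measures
#' design — each cell contributes its whole curve, so the group effect is
#' tested against between-cell variability, not against the pseudo-
#' replicated cell x voltage residual — with per-voltage Welch-t contrasts
#' (Bonferroni-adjusted), or by a Friedman test over the voltage-matched
#' group mean curves (voltages as blocks). Both methods are offered because
#' both are in routine use for I-V families; the ANOVA gives the
#' per-voltage stars. Cells with non-matching grids are intersected with a
#' warning.
#'
#' @param tables list of per-cell `iv_result` (or data frames with
#'   `voltage_mV` and the response column).
#' @param groups factor/character, group membership of each table.
#' @param method `"two_way_anova"` or `"friedman"`.
#' @param response column to compare (default `density_pA_pF`).
#' @return list with `main` (`group_comparison` for the group effect; the
#'   comparison means are per-cell curve averages), `per_voltage` (data
#'   frame: voltage, per-group means, difference, t, raw and adjusted p),
#'   and `method`.
#' @export
compare_iv <- function(tables, groups,
                       method = c("two_way_anova", "friedman"),
                       response = "density_pA_pF") {
  method <- match.arg(method)
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2) stop_param("compare_iv expects exactly 2 groups")
  if (length(tables) != length(groups)) stop_param("one group label per table")

  grids <- lapply(tables, function(tb) tb$voltage_mV)
  shared <- Reduce(intersect, grids)
  if (!all(vapply(grids, function(g) length(g) == length(shared), logical(1))))
    warning("unbalanced voltage grids; intersecting", call. = FALSE)
  if (length(shared) == 0) stop_param("no shared voltages between cells")

  long <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    keep <- tb$voltage_mV %in% shared
    data.frame(cell = i, group = groups[i], voltage = tb$voltage_mV[keep],
               y = tb[[response]][keep])
  }))
  lv <- levels(groups)

  # per-cell curve averages summarize each cell for the group-level means
  cell_means <- tapply(long$y, long$cell, mean)
  cell_group <- groups[as.integer(names(cell_means))]

  if (method == "two_way_anova") {
    long$fvolt <- factor(long$voltage)
    long$fcell <- factor(long$cell)
    if (length(shared) > 1) {
      # per-cell curves share one conductance scale, so cells (not
      # cell x voltage points) are the replicates: the group effect is
      # tested in the between-cell error stratum (repeated-measures design)
      fit <- stats::aov(y ~ group * fvolt + Error(fcell), data = long)
      s <- summary(fit)
      tabc <- s[["Error: fcell"]][[1]]
      rn <- trimws(rownames(tabc))
      fstat <- tabc[match("group", rn), "F value"]
      pval <- tabc[match("group", rn), "Pr(>F)"]
      test_name <- "two-way ANOVA, cells as replicates (group main effect)"
    } else {
      # single shared voltage: the design degenerates to one-way
      fit <- stats::aov(y ~ group, data = long)
      tab <- summary(fit)[[1]]
      rn <- trimws(rownames(tab))
      fstat <- tab[match("group", rn), "F value"]
      pval <- tab[match("group", rn), "Pr(>F)"]
      test_name <- "one-way ANOVA (single voltage)"
    }
    # per-voltage stars: Welch t between groups at each voltage, Bonferroni
    per_v <- lapply(shared, function(v) {
      ya <- long$y[long$voltage == v & long$group == lv[1]]
      yb <- long$y[long$voltage == v & long$group == lv[2]]
      ht <- stats::t.test(yb, ya)
      data.frame(voltage_mV = v, mean_a = mean(ya), mean_b = mean(yb),
                 diff = mean(yb) - mean(ya), t = unname(ht$statistic),
                 p_value = ht$p.value)
    })
    per_v <- do.call(rbind, per_v)
    per_v$adjusted_p <- pmin(1, per_v$p_value * nrow(per_v))
    stat <- fstat
  } else {
    mean_curves <- vapply(lv, function(g) {
      vapply(shared, function(v)
        mean(long$y[long$voltage == v & long$group == g]), numeric(1))
    }, numeric(length(shared)))
    ht <- stats::friedman.test(mean_curves)
    stat <- unname(ht$statistic)
    pval <- ht$p.value
    test_name <- "Friedman (voltage-blocked group curves)"
    per_v <- data.frame(
      voltage_mV = shared,
      mean_a = mean_curves[, 1], mean_b = mean_curves[, 2],
      diff = mean_curves[, 2] - mean_curves[, 1],
      t = NA_real_, p_value = NA_real_, adjusted_p = NA_real_)
  }

  ma <- cell_means[cell_group == lv[1]]
  mb <- cell_means[cell_group == lv[2]]
  diff <- mean(mb) - mean(ma)
  main <- structure(list(
    metric = response,
    groups = lv,
    n = c(length(ma), length(mb)),
    mean = c(mean(ma), mean(mb)),
    sem = c(sem(ma), sem(mb)),
    test = test_name,
    statistic = stat,
    p_value = pval,
    adjusted_p = NA_real_,
    effect_direction = if (diff > 0) "up" else if (diff < 0) "down" else "none"
  ), class = "group_comparison")

  list(main = main, per_voltage = per_v, method = method)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' For three or more groups: overall F test, then all pairwise unpaired t
#' tests on the pooled residual variance with Bonferroni adjustment
#' `adjusted_p = min(1, m * p)` over the m pairs.
#'
#' @param values named list of numeric vectors (>= 3 groups, >= 2 values
#'   each).
#' @return list with `anova` (`F`, `p_value`, `df`) and `pairwise` (data
#'   frame of `group_comparison`-style rows with `adjusted_p`).
#' @export
anova_bonferroni <- function(values) {
  if (length(values) < 3)
    stop_param("fewer than 3 groups; use compare_two()")
  if (any(vapply(values, length, integer(1)) < 2))
    stop_param("each group needs >= 2 values")
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  long <- data.frame(
    y = unlist(values, use.names = FALSE),
    g = factor(rep(names(values), vapply(values, length, integer(1))),
               levels = names(values)))
  fit <- stats::aov(y ~ g, data = long)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  mse <- tab[match("Residuals", rn), "Mean Sq"]
  dfres <- tab[match("Residuals", rn), "Df"]

  pairs <- utils::combn(names(values), 2, simplify = FALSE)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    ya <- values[[pr[1]]]; yb <- values[[pr[2]]]
    se <- sqrt(mse * (1 / length(ya) + 1 / length(yb)))
    tstat <- (mean(yb) - mean(ya)) / se
    p <- 2 * stats::pt(-abs(tstat), dfres)
    data.frame(group_a = pr[1], group_b = pr[2],
               mean_a = mean(ya), mean_b = mean(yb),
               diff = mean(yb) - mean(ya), t = tstat,
               p_value = p, adjusted_p = min(1, m * p),
               direction = if (mean(yb) > mean(ya)) "up"
                           else if (mean(yb) < mean(ya)) "down" else "none")
  }))
  list(
    anova = list(F = tab[match("g", rn), "F value"],
                 p_value = tab[match("g", rn), "Pr(>F)"],
                 df = c(tab[match("g", rn), "Df"], dfres)),
    pairwise = pw
  )
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) pmin(1, m * p)
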