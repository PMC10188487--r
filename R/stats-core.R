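#' @title Shared statistical procedures
#' @description Two-sample tests used across the pipeline (variance-gated t
#'   test on embryo means, F variance test, two-proportion Z) and the qPCR
#'   delta-delta-Ct quantification.
#' @name stats_core
NULL

.two_sample_result <- function(statistic, df, p, method, extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_two_sided = min(max(unname(p), 0), 1), method = method),
              extra),
            class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, two-sided p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$df) || all(is.na(x$df))) "NA"
              else paste(signif(x$df, 4), collapse = ", "),
              x$p_two_sided))
  invisible(x)
}

#' F test for equality of variances
#'
#' Ratio of sample variances with the larger variance in the numerator and a
#' two-sided p value from the F distribution. Used to gate the pooled/Welch
#' choice in [t_test_means()].
#'
#' @param xs,ys numeric samples with at least 2 values each.
#' @return `two_sample_result` with `method = "f_var"`; `df` is
#'   `c(df_num, df_den)`.
#' @export
f_variance_test <- function(xs, ys) {
  .assert(is.numeric(xs) && length(xs) >= 2, "xs needs >= 2 values")
  .assert(is.numeric(ys) && length(ys) >= 2, "ys needs >= 2 values")
  v1 <- stats::var(xs); v2 <- stats::var(ys)
  .assert(v1 > 0 || v2 > 0, "both samples have zero variance")
  swap <- v2 > v1
  ft <- if (swap) stats::var.test(ys, xs) else stats::var.test(xs, ys)
  .two_sample_result(ft$statistic, ft$parameter, ft$p.value, "f_var",
                     list(swapped = swap))
}

#' Two-sided t test on group means, variance-test gated
#'
#' Runs [f_variance_test()] first; when its p value is at least `f_alpha`
#' the classical pooled (Student) t test is used, otherwise the Welch test.
#' Intended for embryo-level means (two or three embryos per group in the
#' typical design).
#'
#' @param xs,ys numeric vectors of per-embryo means (>= 2 each).
#' @param f_alpha significance level of the variance gate (default 0.05).
#' @return `two_sample_result` with `method` `"pooled_t"` or `"welch_t"`;
#'   the gate's result is attached as `$f_test`.
#' @export
t_test_means <- function(xs, ys, f_alpha = 0.05) {
  .assert(is.numeric(xs) && length(xs) >= 2, "xs needs >= 2 values")
  .assert(is.numeric(ys) && length(ys) >= 2, "ys needs >= 2 values")
  if (stats::var(xs) == 0 && stats::var(ys) == 0 && mean(xs) == mean(ys)) {
    # identical constant samples: no spread, no difference
    return(.two_sample_result(0, length(xs) + length(ys) - 2, 1, "pooled_t",
                              list(f_test = NULL, mean_diff = 0)))
  }
  ft <- f_variance_test(xs, ys)
  pooled <- ft$p_two_sided >= f_alpha
  tt <- stats::t.test(xs, ys, var.equal = pooled)
  .two_sample_result(tt$statistic, tt$parameter, tt$p.value,
                     if (pooled) "pooled_t" else "welch_t",
                     list(f_test = ft,
                          mean_diff = unname(tt$estimate[1] - tt$estimate[2])))
}

#' Two-proportion Z test (pooled)
#'
#' Tests `x1/n1` against `x2/n2` with the pooled standard error
#' `sqrt(p*(1-p)*(1/n1 + 1/n2))`, `p = (x1 + x2)/(n1 + n2)`, and a
#' two-sided normal p value. Degenerate pooled proportions (0 or 1) return
#' `z = 0` with a warning.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @param pooled use the pooled variance (default); otherwise the unpooled
#'   standard error `sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`.
#' @return `two_sample_result` with `method = "two_prop_z"` and fields `p1`,
#'   `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2, pooled = TRUE) {
  .assert(.is_num(x1) && .is_num(n1) && .is_num(x2) && .is_num(n2),
          "counts must be finite scalars")
  .assert(n1 >= 1 && n2 >= 1 && x1 >= 0 && x2 >= 0 && x1 <= n1 && x2 <= n2,
          "need 0 <= x <= n and n >= 1")
  p1 <- x1 / n1; p2 <- x2 / n2
  ph <- (x1 + x2) / (n1 + n2)
  se <- if (pooled) {
    sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
  } else {
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  if (se == 0) {
    warning("degenerate proportions (pooled p is 0 or 1); returning z = 0")
    return(.two_sample_result(0, NA_real_, 1, "two_prop_z",
                              list(p1 = p1, p2 = p2)))
  }
  z <- (p1 - p2) / se
  .two_sample_result(z, NA_real_, 2 * stats::pnorm(-abs(z)), "two_prop_z",
                     list(p1 = p1, p2 = p2))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes each target-gene Ct by the housekeeping reference within the
#' same group and replicate (`dCt = Ct_target - Ct_ref`), subtracts the mean
#' control-group dCt per gene (`ddCt`), and reports per-replicate fold
#' changes `2^-ddCt` with their mean and SD. Amplification efficiency is
#' taken as exactly 2.
#'
#' @param ct_table data.frame with columns `sample_group`, `gene`,
#'   `replicate`, `ct`.
#' @param reference_gene housekeeping gene (default `"ef1a"`); must be
#'   measured in every group and replicate.
#' @param control_group name of the control condition.
#' @return list with `replicates` (per-replicate fold changes) and `summary`
#'   (per group x gene: `fold_mean`, `fold_sd`, `n`).
#' @export
delta_delta_ct <- function(ct_table, reference_gene = "ef1a", control_group) {
  need <- c("sample_group", "gene", "replicate", "ct")
  .assert(all(need %in% names(ct_table)), "ct_table needs sample_group/gene/replicate/ct")
  .assert(all(is.finite(ct_table$ct)), "ct values must be finite")
  .assert(control_group %in% ct_table$sample_group, "control group not present")
  ref <- ct_table[ct_table$gene == reference_gene, ]
  .assert(nrow(ref) > 0, "reference gene not present")
  groups <- unique(ct_table$sample_group)
  .assert(all(groups %in% ref$sample_group),
          "reference gene must be measured in every group")
  tg <- ct_table[ct_table$gene != reference_gene, ]
  key <- function(g, r) paste(g, r, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref$sample_group, ref$replicate))
  rk <- key(tg$sample_group, tg$replicate)
  .assert(all(rk %in% names(ref_ct)),
          "every target replicate needs a matching reference replicate")
  tg$dct <- tg$ct - ref_ct[rk]
  ctrl_mean <- tapply(tg$dct[tg$sample_group == control_group],
                      tg$gene[tg$sample_group == control_group], mean)
  .assert(all(unique(tg$gene) %in% names(ctrl_mean)),
          "every target gene needs control-group measurements")
  tg$ddct <- tg$dct - ctrl_mean[tg$gene]
  tg$fold <- 2^(-tg$ddct)
  agg <- do.call(rbind, lapply(split(tg, list(tg$sample_group, tg$gene), drop = TRUE),
    function(d) data.frame(sample_group = d$sample_group[1], gene = d$gene[1],
                           fold_mean = mean(d$fold), fold_sd = stats::sd(d$fold),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(replicates = tg[, c("sample_group", "gene", "replicate", "ct", "dct",
                           "ddct", "fold")],
       summary = agg[order(agg$gene, agg$sample_group), ])
}
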