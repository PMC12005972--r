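#' Per-nucleus mean intensity for one antigen
#'
#' Mean voxel intensity over each undilated nucleus mask — quantifying
#' per-mask rather than per-voxel eliminates local staining imbalances.
#'
#' @param intensity 3D numeric array, same dimensions as the label volume.
#' @param labels A [label_volume()].
#' @param antigen Antigen name recorded in the output.
#' @return Data frame: cell, antigen, mean_intensity (empty for an empty
#'   label set).
#' @export
quantify_masks <- function(intensity, labels, antigen = "antigen") {
  stopifnot(inherits(labels, "label_volume"))
  if (!identical(dim(intensity), dim(labels$data))) {
    stop("intensity and label volumes have different dimensions", call. = FALSE)
  }
  a <- labels$data
  idx <- which(a > 0L)
  if (length(idx) == 0L) {
    return(data.frame(cell = integer(0), antigen = character(0),
                      mean_intensity = numeric(0), stringsAsFactors = FALSE))
  }
  m <- tapply(intensity[idx], a[idx], mean)
  data.frame(cell = as.integer(names(m)), antigen = antigen,
             mean_intensity = as.numeric(m), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Normalize antigen intensities to an inactive-chromatin reference
#'
#' Per-cell ratio of each target antigen's mean nuclear intensity to the
#' reference antigen's (default H3K27me3, inactive chromatin) in the same
#' nucleus. Ratios are scale-invariant: a global intensity rescaling of both
#' channels cancels. Cells with zero or missing reference intensity are
#' excluded and flagged.
#'
#' @param table Protein table: columns cell, antigen, mean_intensity.
#' @param reference Reference antigen name (default `"H3K27me3"`).
#' @return List: `ratios` (data.frame cell, antigen, ratio), `excluded`
#'   (cells lacking a positive reference), `reference`.
#' @export
normalize_to_reference <- function(table, reference = "H3K27me3") {
  stopifnot(all(c("cell", "antigen", "mean_intensity") %in% names(table)))
  ref <- table[table$antigen == reference, ]
  if (nrow(ref) == 0L) {
    stop("reference antigen '", reference, "' absent from the table",
         call. = FALSE)
  }
  ref_val <- ref$mean_intensity[match(table$cell, ref$cell)]
  tgt <- table$antigen != reference
  bad_ref <- is.na(ref_val) | ref_val <= 0
  excluded <- sort(unique(table$cell[tgt & bad_ref]))
  keep <- tgt & !bad_ref
  ratios <- data.frame(cell = table$cell[keep],
                       antigen = table$antigen[keep],
                       ratio = table$mean_intensity[keep] / ref_val[keep],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(ratios = ratios, excluded = excluded, reference = reference)
}

#' Compare grouped values with ANOVA and Bonferroni pairwise tests
#'
#' One-way ANOVA F-test across all groups, followed by pairwise Welch
#' two-sample t-tests of each group against the reference group, with raw
#' p-values multiplied by the number of comparisons (Bonferroni) and capped
#' at 1. Significance codes follow the boxplot-legend convention:
#' `n.s.` for p > 0.05, `*` for p < 0.05, `**` for p < 0.01, `****` for
#' p < 0.0001. Degenerate pairs (both groups constant) get p = 1 when means
#' are equal and p = 0 otherwise.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @param reference_group The reference (e.g. cluster C1).
#' @return List: `anova_p`, `anova_F`, `pairwise` (data.frame group, p_raw,
#'   p_adjusted, code), `n_comparisons`, `boxplot_stats` (10/25/50/75/90
#'   percentiles and mean per group).
#' @export
compare_groups <- function(values, groups, reference_group) {
  groups <- as.character(groups)
  if (!reference_group %in% groups) {
    stop("reference group not present", call. = FALSE)
  }
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }

  anova_p <- NA_real_; anova_F <- NA_real_
  if (stats::sd(values) > 0) {
    fit <- stats::aov(values ~ factor(groups))
    s <- summary(fit)[[1]]
    anova_F <- s[["F value"]][1]
    anova_p <- s[["Pr(>F)"]][1]
  } else {
    anova_p <- 1                               # all values identical
  }

  others <- setdiff(names(tab), reference_group)
  m <- length(others)
  ref_vals <- values[groups == reference_group]
  pw <- data.frame(group = others, p_raw = NA_real_, p_adjusted = NA_real_,
                   code = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(others)) {
    gv <- values[groups == others[i]]
    if (stats::sd(gv) == 0 && stats::sd(ref_vals) == 0) {
      p <- if (isTRUE(all.equal(mean(gv), mean(ref_vals)))) 1 else 0
    } else {
      p <- stats::t.test(gv, ref_vals)$p.value   # Welch
    }
    pw$p_raw[i] <- p
    pw$p_adjusted[i] <- min(1, p * m)
  }
  pw$code <- vapply(pw$p_adjusted, significance_code, "")

  bs <- do.call(rbind, lapply(names(tab), function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    data.frame(group = g, p10 = q[1], p25 = q[2], median = q[3], p75 = q[4],
               p90 = q[5], mean = mean(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  list(anova_p = anova_p, anova_F = anova_F, pairwise = pw,
       n_comparisons = m, boxplot_stats = bs)
}

significance_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}
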