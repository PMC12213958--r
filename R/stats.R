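# Group-level ROI statistics: paired condition contrasts on mean CDR
# scores with Benjamini-Hochberg FDR control applied separately per
# correction family (hemisphere x mask family x component).

#' Paired t-test with degenerate-variance guard
#'
#' Classical paired t on per-subject values, two-sided p from the Student t
#' distribution with df = n - 1. When the differences have exactly zero
#' variance the result is flagged degenerate (t is 0 for identical vectors,
#' signed infinite otherwise, p is NA).
#'
#' @param a,b Per-subject values under the two conditions (same order).
#' @return List: `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stopf("paired samples differ in length")
  n <- length(a)
  if (n < 3L) stopf("at least 3 paired observations are required")
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (md == 0) 0 else sign(md) * Inf, df = n - 1L,
                p = NA_real_, mean_diff = md, n = n, degenerate = TRUE))
  }
  tval <- md / (s / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1L),
       mean_diff = md, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg q-values within correction families
#'
#' Standard BH step-up applied independently within each family label;
#' q-value monotonicity within a family is enforced by the step-up itself.
#'
#' @param p_values Numeric p-values in `[0, 1]` (NA allowed, propagated).
#' @param family_labels Vector assigning each p to a correction family;
#'   a single family when omitted.
#' @return Numeric q-values aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, family_labels = NULL) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stopf("p-values must lie in [0, 1]")
  if (is.null(family_labels)) family_labels <- rep("all", length(p_values))
  q <- rep(NA_real_, length(p_values))
  for (fam in unique(family_labels)) {
    i <- which(family_labels == fam)
    q[i] <- stats::p.adjust(p_values[i], method = "BH")
  }
  q
}

#' Group condition contrasts per ROI with family-wise FDR control
#'
#' Runs a paired t-test (source correct minus source incorrect) on every
#' ROI's per-subject mean CDR score, separately per component, and adjusts
#' p-values with BH within correction families: hemisphere x mask family x
#' component for the bilateral atlas family, mask family x component for
#' the fMRI-constrained set.
#'
#' @param roi_cdr Long data.frame with columns `subject`, `component`,
#'   `mask`, `roi`, `hemisphere`, `family`, `condition`, `mean_cdr`
#'   (as produced by the pipeline's inverse stage).
#' @param fdr_level Significance level on q (default 0.05).
#' @return `smeloc_stat_report`: data.frame `table` with one row per
#'   (component, mask): `n`, `mean_diff`, `t`, `df`, `p`, `q`,
#'   `correction_family`, `significant`; plus `fdr_level`.
#' @export
build_stat_report <- function(roi_cdr, fdr_level = 0.05) {
  req <- c("subject", "component", "mask", "roi", "hemisphere", "family",
           "condition", "mean_cdr")
  if (!all(req %in% names(roi_cdr))) stopf("missing columns in ROI CDR table")
  combos <- unique(roi_cdr[, c("component", "mask", "roi", "hemisphere",
                               "family")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    sub <- roi_cdr[roi_cdr$component == cb$component & roi_cdr$mask == cb$mask, ]
    wide <- stats::reshape(sub[, c("subject", "condition", "mean_cdr")],
                           idvar = "subject", timevar = "condition",
                           direction = "wide")
    ca <- wide[["mean_cdr.source_correct"]]
    cb2 <- wide[["mean_cdr.source_incorrect"]]
    if (anyNA(ca) || anyNA(cb2) || is.null(ca) || is.null(cb2))
      stopf("subject sets differ between conditions for mask '%s'", cb$mask)
    tt <- paired_t(ca, cb2)
    fam_id <- if (cb$family == "MTL_atlas")
      paste(cb$component, cb$family, cb$hemisphere, sep = "|")
    else paste(cb$component, cb$family, sep = "|")
    data.frame(component = cb$component, family = cb$family,
               hemisphere = cb$hemisphere, mask = cb$mask, roi = cb$roi,
               n = tt$n, mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
               p = tt$p, correction_family = fam_id,
               degenerate = tt$degenerate)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p, tab$correction_family)
  tab$significant <- !is.na(tab$q) & tab$q < fdr_level
  structure(list(table = tab, fdr_level = fdr_level),
            class = "smeloc_stat_report")
}

#' @export
print.smeloc_stat_report <- function(x, ...) {
  sig <- x$table[x$table$significant, ]
  cat(sprintf("<smeloc_stat_report> %d tests, %d significant at q < %g\n",
              nrow(x$table), nrow(sig), x$fdr_level))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s %s: diff = %.3g, t(%d) = %.2f, q = %.3g\n",
                  sig$component[i], sig$mask[i], sig$mean_diff[i],
                  sig$df[i], sig$t[i], sig$q[i]))
  }
  invisible(x)
}

#' Render a stat report as Markdown
#'
#' @param report A [build_stat_report()] result.
#' @param truth Optional [make_ground_truth()] record; when present, the
#'   report lists each planted ROI and whether it was recovered.
#' @return Character vector of Markdown lines.
#' @export
format_stat_report <- function(report, truth = NULL) {
  tab <- report$table
  lines <- c("# ROI condition contrasts (source correct - source incorrect)", "")
  for (comp in unique(tab$component)) {
    lines <- c(lines, sprintf("## %s", comp), "",
               "| family | hemisphere | ROI | n | mean diff | t | df | p | q | sig |",
               "|---|---|---|---|---|---|---|---|---|---|")
    sub <- tab[tab$component == comp, ]
    for (i in seq_len(nrow(sub)))
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %d | %.4g | %.3f | %d | %.4g | %.4g | %s |",
        sub$family[i], sub$hemisphere[i], sub$mask[i], sub$n[i],
        sub$mean_diff[i], sub$t[i], sub$df[i], sub$p[i], sub$q[i],
        if (sub$significant[i]) "*" else ""))
    lines <- c(lines, "")
  }
  if (!is.null(truth)) {
    lines <- c(lines, "## Planted-effect recovery", "")
    for (comp in names(truth$effect_rois)) {
      for (key in truth$effect_rois[[comp]]) {
        hit <- any(tab$component == comp & tab$mask == key & tab$significant)
        lines <- c(lines, sprintf("- %s / %s: %s", comp, key,
                                  if (hit) "recovered" else "not recovered"))
      }
    }
    lines <- c(lines, "")
  }
  lines
}
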