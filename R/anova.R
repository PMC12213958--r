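# Within-subject 2 x 3 x 3 ANOVA on cluster mean amplitudes, computed from
# the balanced cell-mean decomposition (each effect tested against its
# interaction with subjects), plus Tukey-corrected estimated-marginal-mean
# condition contrasts.

#' Stack per-subject cluster means into a long amplitude table
#'
#' @param cluster_means_list Named list (names = subject ids) of
#'   [cluster_means()] data frames.
#' @return Long data.frame with `subject`, `condition`, `coronal`,
#'   `sagittal`, `amplitude`.
#' @export
amplitude_table <- function(cluster_means_list) {
  ids <- names(cluster_means_list) %||% sprintf("S%02d", seq_along(cluster_means_list))
  do.call(rbind, lapply(seq_along(cluster_means_list), function(i)
    cbind(subject = ids[i], cluster_means_list[[i]])))
}

# Expand a marginal mean array over kept dims back to the full array shape.
expand_margin <- function(m, keep, full_dim) {
  if (!length(keep)) return(array(m, full_dim))
  rest <- setdiff(seq_along(full_dim), keep)
  a <- array(m, c(full_dim[keep], full_dim[rest]))
  aperm(a, order(c(keep, rest)))
}

# Interaction-effect array for the factor subset `eff` (Moebius sum of
# marginal means over all subsets).
effect_array <- function(Y, eff) {
  fd <- dim(Y)
  total <- array(0, fd)
  subsets <- list(integer(0))
  for (d in eff) subsets <- c(subsets, lapply(subsets, function(s) c(s, d)))
  for (s in subsets) {
    m <- if (length(s)) apply(Y, s, mean) else mean(Y)
    total <- total + (-1)^(length(eff) - length(s)) * expand_margin(m, s, fd)
  }
  total
}

#' Repeated-measures 2 x 3 x 3 ANOVA
#'
#' Univariate within-subject ANOVA of cluster amplitudes with factors
#' Condition (2), Coronal plane (3) and Sagittal plane (3), all within
#' subjects. Sums of squares come from the balanced cell-mean
#' decomposition; every Condition-involving effect is tested against its
#' interaction with subjects. Only Condition-involving effects are
#' reported. No sphericity correction is applied by default;
#' `gg_correct = TRUE` applies Greenhouse-Geisser adjusted dfs.
#'
#' @param amplitudes Long data.frame from [amplitude_table()] (complete,
#'   balanced crossing; >= 3 subjects).
#' @param gg_correct Apply Greenhouse-Geisser correction (default FALSE).
#' @return `smeloc_anova`: data.frame `effects` with `effect`, `F`,
#'   `df_num`, `df_den`, `p` (and `eps_gg` when corrected), plus the cell
#'   array and factor levels for downstream contrasts.
#' @export
rm_anova_2x3x3 <- function(amplitudes, gg_correct = FALSE) {
  req <- c("subject", "condition", "coronal", "sagittal", "amplitude")
  if (!all(req %in% names(amplitudes))) stopf("missing columns in amplitude table")
  subj <- sort(unique(amplitudes$subject))
  cond <- sort(unique(amplitudes$condition))
  corl <- c("frontal", "central", "posterior")
  sagl <- c("left", "middle", "right")
  corl <- corl[corl %in% amplitudes$coronal]
  sagl <- sagl[sagl %in% amplitudes$sagittal]
  n <- length(subj)
  if (n < 3L) stopf("at least 3 subjects are required")
  if (length(cond) != 2L || length(corl) != 3L || length(sagl) != 3L)
    stopf("design must be 2 conditions x 3 coronal x 3 sagittal")
  Y <- array(NA_real_, c(n, 2L, 3L, 3L),
             dimnames = list(subj, cond, corl, sagl))
  idx <- cbind(match(amplitudes$subject, subj),
               match(amplitudes$condition, cond),
               match(amplitudes$coronal, corl),
               match(amplitudes$sagittal, sagl))
  Y[idx] <- amplitudes$amplitude
  if (anyNA(Y)) stopf("unbalanced design: missing cells")

  # dims: 1 subject, 2 condition, 3 coronal, 4 sagittal
  ss <- function(eff) sum(effect_array(Y, eff)^2)
  terms <- list(
    Condition = list(eff = 2L, err = c(1L, 2L), df = 1L),
    `Condition:Coronal` = list(eff = c(2L, 3L), err = c(1L, 2L, 3L), df = 2L),
    `Condition:Sagittal` = list(eff = c(2L, 4L), err = c(1L, 2L, 4L), df = 2L),
    `Condition:Coronal:Sagittal` = list(eff = c(2L, 3L, 4L),
                                        err = c(1L, 2L, 3L, 4L), df = 4L))
  rows <- lapply(names(terms), function(nm) {
    tm <- terms[[nm]]
    ss_eff <- ss(tm$eff)
    ss_err <- ss(tm$err)
    df1 <- tm$df
    df2 <- tm$df * (n - 1L)
    eps <- 1
    if (gg_correct && df1 > 1L) {
      eps <- gg_epsilon(Y, tm$eff)
      df1 <- eps * df1
      df2 <- eps * df2
    }
    if (ss_eff == 0) {
      f <- 0; p <- 1
    } else {
      f <- (ss_eff / df1) / (ss_err / df2)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    data.frame(effect = nm, ss = ss_eff, ss_error = ss_err, F = f,
               df_num = df1, df_den = df2, p = p, eps_gg = eps)
  })
  structure(list(effects = do.call(rbind, rows), cells = Y,
                 conditions = cond, coronal = corl, sagittal = sagl,
                 n_subjects = n, gg_correct = gg_correct),
            class = "smeloc_anova")
}

# Greenhouse-Geisser epsilon for a within-subject effect: collapse the cell
# array to subject x contrast-cell means for the effect's factors and apply
# the standard covariance-based formula.
gg_epsilon <- function(Y, eff) {
  n <- dim(Y)[1]
  collapse <- apply(Y, c(1L, eff), mean)
  Z <- matrix(collapse, nrow = n)
  S <- stats::cov(Z)
  k <- ncol(Z)
  mdiag <- mean(diag(S)); mall <- mean(S); rowm <- rowMeans(S)
  num <- (k * (mdiag - mall))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mall^2)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.smeloc_anova <- function(x, ...) {
  cat(sprintf("<smeloc_anova> %d subjects, 2 x 3 x 3 within-subject design\n",
              x$n_subjects))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-28s F(%g, %g) = %.3f, p = %.4g\n",
                e$effect[i], e$df_num[i], e$df_den[i], e$F[i], e$p[i]))
  invisible(x)
}

#' Tukey-corrected estimated-marginal-means condition contrasts
#'
#' Contrasts the two conditions within each cell of the chosen slice
#' (coronal x sagittal cells, or sagittal-only after averaging over the
#' coronal plane). Each contrast uses the per-subject condition difference
#' in that cell; the standard error pools the difference variance across
#' cells (df = cells x (n - 1)). Adjusted p-values come from the
#' studentized-range distribution with the total number of estimated
#' marginal means in the slice family as `nmeans`.
#'
#' @param anova A [rm_anova_2x3x3()] result.
#' @param by `c("coronal", "sagittal")` (default) or `"sagittal"`.
#' @return data.frame: one row per cell with `estimate` (correct minus
#'   incorrect in condition sort order), `se`, `t`, `df`, `p_unadj`,
#'   `p_tukey`.
#' @export
emm_tukey_posthoc <- function(anova, by = c("coronal", "sagittal")) {
  stopifnot(inherits(anova, "smeloc_anova"))
  Y <- anova$cells
  n <- dim(Y)[1]
  D <- Y[, 1, , ] - Y[, 2, , ]               # subject x coronal x sagittal
  if (identical(by, "sagittal")) {
    D <- apply(D, c(1, 3), mean)             # average over coronal
    cells <- data.frame(sagittal = anova$sagittal)
    dmat <- matrix(D, n)
  } else if (identical(sort(by), c("coronal", "sagittal"))) {
    cells <- expand.grid(coronal = anova$coronal, sagittal = anova$sagittal,
                         stringsAsFactors = FALSE)
    dmat <- matrix(D, n)                      # columns follow expand.grid order
  } else stopf("unsupported slice: %s", paste(by, collapse = ", "))
  ncell <- ncol(dmat)
  dbar <- colMeans(dmat)
  s2_pool <- sum(sweep(dmat, 2, dbar)^2) / (ncell * (n - 1))
  df <- ncell * (n - 1)
  se <- sqrt(s2_pool / n)
  tval <- if (se > 0) dbar / se else ifelse(dbar == 0, 0, sign(dbar) * Inf)
  k_means <- 2L * ncell
  p_tukey <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k_means, df = df,
                           lower.tail = FALSE)
  p_unadj <- 2 * stats::pt(-abs(tval), df)
  cbind(cells,
        data.frame(estimate = dbar, se = se, t = tval, df = df,
                   p_unadj = p_unadj, p_tukey = p_tukey,
                   contrast = paste(anova$conditions[1], "-",
                                    anova$conditions[2])))
}
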