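test_that("the paired t matches its closed form and stats::t.test", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)       # differences 1, 2, 3
  r <- paired_t(a, b)
  expect_equal(r$mean_diff, 2)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_identical(r$df, 2L)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate differences are flagged and antisymmetry holds", {
  x <- c(1.5, 2.5, 3.5, 4)
  r0 <- paired_t(x, x)
  expect_true(r0$degenerate)
  expect_identical(r0$t, 0)
  expect_true(is.na(r0$p))

  set.seed(21)
  a <- rnorm(8); b <- rnorm(8)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_error(paired_t(a, b[1:3]), "length")
  expect_error(paired_t(1:2, 2:3), "at least 3")
})

test_that("BH q-values follow the step-up construction per family", {
  expect_equal(bh_fdr(0.03), 0.03)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), rep(0.04, 4))
  # hand step-up on an uneven vector
  p2 <- c(0.001, 0.04, 0.03, 0.6)
  hand <- {
    o <- order(p2); m <- 4
    q <- p2[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m); out[o] <- q; out
  }
  expect_equal(bh_fdr(p2), hand, tolerance = 1e-15)
  expect_equal(bh_fdr(p2), p.adjust(p2, "BH"), tolerance = 1e-15)

  # identical p-vectors in two families correct independently
  q2 <- bh_fdr(c(p, p), rep(c("L", "R"), each = 4))
  expect_equal(q2[1:4], q2[5:8])
  expect_equal(q2[1:4], bh_fdr(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(bh_fdr(p) >= p))
})

make_roi_cdr <- function(n_sub, effect_masks = character(0), d = 1.5,
                         seed = 1) {
  set.seed(seed)
  masks <- fix_masks_coarse()
  rows <- list()
  for (key in names(masks$masks)) {
    m <- masks$masks[[key]]
    base <- abs(rnorm(n_sub, 10, 1))
    eff <- if (key %in% effect_masks) rnorm(n_sub, d, 1) else rnorm(n_sub, 0, 1)
    for (comp in c("P2", "LSW")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", seq_len(n_sub)), component = comp,
        mask = key, roi = m$roi, hemisphere = m$hemisphere,
        family = m$family,
        condition = "source_correct",
        mean_cdr = base + if (comp == "LSW") eff else 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", seq_len(n_sub)), component = comp,
        mask = key, roi = m$roi, hemisphere = m$hemisphere,
        family = m$family,
        condition = "source_incorrect", mean_cdr = base)
    }
  }
  do.call(rbind, rows)
}

test_that("the stat report tests every mask with df = n - 1 and separate correction families", {
  cdr <- make_roi_cdr(12, effect_masks = "left EC", d = 2)
  rep <- build_stat_report(cdr)
  tab <- rep$table
  expect_equal(nrow(tab), 36)                      # 18 masks x 2 components
  expect_true(all(tab$df == 11))
  expect_true(all(tab$n == 12))
  # hemisphere x family x component for the atlas family
  mtl <- tab[tab$family == "MTL_atlas", ]
  expect_setequal(unique(mtl$correction_family),
                  c("P2|MTL_atlas|left", "P2|MTL_atlas|right",
                    "LSW|MTL_atlas|left", "LSW|MTL_atlas|right"))
  fmri <- tab[tab$family == "fMRI_constrained", ]
  expect_length(unique(fmri$correction_family), 2)
  expect_true(all(tab$q >= tab$p - 1e-15, na.rm = TRUE))
  # the planted LSW effect is detected in the left EC mask
  hit <- tab[tab$component == "LSW" & tab$mask == "left EC", ]
  expect_true(hit$significant)
  p2row <- tab[tab$component == "P2" & tab$mask == "left EC", ]
  expect_false(p2row$significant)
})

test_that("mismatched subject sets across conditions are an error", {
  cdr <- make_roi_cdr(6)
  drop_row <- which(cdr$mask == "left EC" & cdr$component == "P2" &
                      cdr$condition == "source_correct" &
                      cdr$subject == "S01")
  expect_error(build_stat_report(cdr[-drop_row, ]), "differ between conditions")
})

test_that("the Markdown report lists planted ROIs and their recovery", {
  cdr <- make_roi_cdr(12, effect_masks = c("left EC", "left rostral PhG"),
                      d = 2)
  rep <- build_stat_report(cdr)
  truth <- make_ground_truth(fix_masks_coarse())
  md <- format_stat_report(rep, truth)
  expect_true(any(grepl("Planted-effect recovery", md)))
  expect_true(any(grepl("LSW / left EC: recovered", md)))
  expect_true(any(grepl("^## P2$", md)))
})
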