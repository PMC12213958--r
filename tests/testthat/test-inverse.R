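# Small dedicated grid so the weight iteration stays fast.
fix_inverse_setup <- function() fixture("inv_setup", function() {
  head <- fix_head()
  mon <- make_montage(head, 32)
  ss <- make_source_space(head, spacing = 0.02)
  lf <- compute_leadfield(head, ss, mon)
  w <- eloreta_weights(lf, alpha = 0)
  list(head = head, montage = mon, ss = ss, lf = lf, w = w,
       inv = make_inverse_operator(lf, w))
})

test_that("eLORETA weight blocks are symmetric positive definite", {
  s <- fix_inverse_setup()
  expect_true(s$w$converged)
  eig <- sapply(s$w$W, function(Wj) {
    expect_equal(Wj, t(Wj), tolerance = 1e-10)
    min(eigen(Wj, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_true(all(eig > 0))
})

test_that("weights are invariant to lead-field scaling and the operator compensates", {
  s <- fix_inverse_setup()
  lf2 <- s$lf
  lf2$gain <- 5 * s$lf$gain
  w2 <- eloreta_weights(lf2, alpha = 0)
  rel <- mapply(function(a, b) norm(a - b, "F") / norm(a, "F"), s$w$W, w2$W)
  expect_lt(max(rel), 1e-8)
  inv2 <- make_inverse_operator(lf2, w2)
  expect_equal(inv2$operator, s$inv$operator / 5, tolerance = 1e-8)
})

test_that("duplicated grid points get identical weight blocks", {
  s <- fix_inverse_setup()
  lf <- s$lf
  lf$gain <- cbind(lf$gain[, 1:30], lf$gain[, 1:6])   # duplicate points 1, 2
  lf$n_sources <- 12L
  w <- eloreta_weights(lf, alpha = 0)
  expect_equal(w$W[[1]], w$W[[11]], tolerance = 1e-8)
  expect_equal(w$W[[2]], w$W[[12]], tolerance = 1e-8)
})

test_that("noiseless point sources are localized exactly at their grid point", {
  s <- fix_inverse_setup()
  g <- s$ss$grid_positions
  rad <- sqrt(rowSums(g^2))
  interior <- which(rad > (s$ss$band[1] + 0.05) * s$ss$r_inner &
                      rad < (s$ss$band[2] - 0.05) * s$ss$r_inner)
  set.seed(13)
  picks <- sample(interior, 40, replace = TRUE)
  hits <- 0L
  M <- s$inv$n_sources
  for (j in picks) {
    q <- rnorm(3); q <- q / sqrt(sum(q^2)) * 20
    phi <- s$lf$gain[, (3 * j - 2):(3 * j)] %*% q
    mom <- s$inv$operator %*% phi
    arr <- array(0, c(M, 3, 1))
    for (a in 1:3) arr[, a, 1] <- mom[seq(a, 3 * M, 3)]
    if (which.max(cdr_scores(arr)) == j) hits <- hits + 1L
  }
  expect_gte(hits / length(picks), 0.95)
})

test_that("the inverse operator is linear and maps silence to silence", {
  s <- fix_inverse_setup()
  set.seed(14)
  ne <- nrow(s$lf$gain)
  H <- diag(ne) - 1 / ne
  phi1 <- drop(H %*% rnorm(ne)); phi2 <- drop(H %*% rnorm(ne))
  T <- s$inv$operator
  expect_identical(drop(T %*% rep(0, ne)), rep(0, 3 * s$inv$n_sources))
  expect_equal(drop(T %*% (2 * phi1 - 3 * phi2)),
               drop(2 * T %*% phi1 - 3 * T %*% phi2), tolerance = 1e-12)
})

test_that("inverting the trial average equals averaging single-trial inversions", {
  s <- fix_inverse_setup()
  set.seed(15)
  n_tr <- 6; ne <- 32; n_samp <- 100
  data <- array(rnorm(n_tr * ne * n_samp), c(n_tr, ne, n_samp))
  ep <- epochs_set(data, rep("source_correct", n_tr), 512, -100,
                   s$montage$labels)
  w <- component_window("P2", 60, window_ms = 20, epoch_ms = c(-100, 93))
  avg_first <- apply_inverse_window(s$inv, ep, w, "source_correct")
  per_trial <- lapply(seq_len(n_tr), function(i) {
    epi <- epochs_set(data[i, , , drop = FALSE], "source_correct", 512, -100,
                      s$montage$labels)
    apply_inverse_window(s$inv, epi, w, "source_correct")$moments
  })
  expect_equal(avg_first$moments, Reduce(`+`, per_trial) / n_tr,
               tolerance = 1e-9)
  expect_error(apply_inverse_window(s$inv, ep, w, "source_incorrect"),
               "not present")
})

test_that("CDR is the mean over samples of the moment-vector norm", {
  arr <- array(0, c(1, 3, 4))
  arr[1, , ] <- c(3, 4, 0)
  expect_equal(cdr_scores(arr), 5)
  arr2 <- array(0, c(1, 3, 2))
  arr2[1, , 1] <- c(3, 4, 0)
  expect_equal(cdr_scores(arr2), 2.5)
  set.seed(16)
  arr3 <- array(rnorm(5 * 3 * 7), c(5, 3, 7))
  oracle <- sapply(1:5, function(j)
    mean(sapply(1:7, function(s) sqrt(sum(arr3[j, , s]^2)))))
  expect_equal(cdr_scores(arr3), oracle, tolerance = 1e-12)
})

test_that("CDR scales with the data magnitude and stays non-negative", {
  s <- fix_inverse_setup()
  set.seed(17)
  ne <- 32
  phi <- drop((diag(ne) - 1 / ne) %*% rnorm(ne))
  M <- s$inv$n_sources
  to_cdr <- function(v) {
    arr <- array(0, c(M, 3, 1))
    mom <- s$inv$operator %*% v
    for (a in 1:3) arr[, a, 1] <- mom[seq(a, 3 * M, 3)]
    cdr_scores(arr)
  }
  c1 <- to_cdr(phi); c2 <- to_cdr(-2.5 * phi)
  expect_true(all(c1 >= 0))
  expect_equal(c2, 2.5 * c1, tolerance = 1e-10)
})

test_that("ROI aggregation averages member grid points", {
  masks <- fix_masks_coarse()
  M <- masks$n_grid
  cdr <- rep(1.5, M)
  agg <- roi_aggregate(cdr, masks)
  expect_true(all(agg$mean_cdr == 1.5))
  expect_equal(nrow(agg), 18)

  key <- names(masks$masks)[1]
  idx <- masks$masks[[key]]$indices[1:3]
  cdr2 <- numeric(M); cdr2[idx] <- c(1, 2, 6)
  m1 <- masks
  m1$masks <- list(a = list(indices = idx, roi = "a", hemisphere = "left",
                            family = "MTL_atlas"),
                   b = list(indices = masks$masks[[key]]$indices[4], roi = "b",
                            hemisphere = "left", family = "MTL_atlas"))
  agg2 <- roi_aggregate(cdr2, m1)
  expect_equal(agg2$mean_cdr[agg2$mask == "a"], 3)
  expect_equal(agg2$mean_cdr[agg2$mask == "b"], 0)  # singleton ROI
})

test_that("non-convergence is surfaced as a warning, not an error", {
  s <- fix_inverse_setup()
  expect_warning(w <- eloreta_weights(s$lf, alpha = 0, tol = 1e-14,
                                      max_iter = 2L),
                 "did not converge")
  expect_false(w$converged)
  expect_length(w$W, s$inv$n_sources)
})
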