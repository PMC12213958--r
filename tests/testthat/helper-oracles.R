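# Independent brute-force oracles used by the unit and acceptance tests.

# Textbook SS-by-summation for the 2 x 3 x 3 within-subject design.
anova_ss_oracle <- function(Y) {
  n <- dim(Y)[1]
  m <- mean(Y)
  m_i <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean); m_c <- apply(Y, 4, mean)
  m_ia <- apply(Y, c(1, 2), mean); m_ib <- apply(Y, c(1, 3), mean)
  m_ic <- apply(Y, c(1, 4), mean)
  m_ab <- apply(Y, c(2, 3), mean); m_ac <- apply(Y, c(2, 4), mean)
  m_iab <- apply(Y, c(1, 2, 3), mean); m_iac <- apply(Y, c(1, 2, 4), mean)
  m_abc <- apply(Y, c(2, 3, 4), mean)
  m_bc <- apply(Y, c(3, 4), mean); m_ibc <- apply(Y, c(1, 3, 4), mean)
  ss <- list(A = 0, AS = 0, AB = 0, ABS = 0, AC = 0, ACS = 0, ABC = 0,
             ABCS = 0)
  for (i in 1:n) for (a in 1:2) for (b in 1:3) for (cc in 1:3) {
    ss$A <- ss$A + (m_a[a] - m)^2
    ss$AS <- ss$AS + (m_ia[i, a] - m_i[i] - m_a[a] + m)^2
    ss$AB <- ss$AB + (m_ab[a, b] - m_a[a] - m_b[b] + m)^2
    ss$ABS <- ss$ABS + (m_iab[i, a, b] - m_ia[i, a] - m_ib[i, b] -
                          m_ab[a, b] + m_i[i] + m_a[a] + m_b[b] - m)^2
    ss$AC <- ss$AC + (m_ac[a, cc] - m_a[a] - m_c[cc] + m)^2
    ss$ACS <- ss$ACS + (m_iac[i, a, cc] - m_ia[i, a] - m_ic[i, cc] -
                          m_ac[a, cc] + m_i[i] + m_a[a] + m_c[cc] - m)^2
    ss$ABC <- ss$ABC + (m_abc[a, b, cc] - m_ab[a, b] - m_ac[a, cc] -
                          m_bc[b, cc] + m_a[a] + m_b[b] + m_c[cc] - m)^2
    ss$ABCS <- ss$ABCS + (Y[i, a, b, cc] - m_iab[i, a, b] - m_iac[i, a, cc] -
                            m_ibc[i, b, cc] - m_abc[a, b, cc] + m_ia[i, a] +
                            m_ib[i, b] + m_ic[i, cc] + m_ab[a, b] +
                            m_ac[a, cc] + m_bc[b, cc] - m_i[i] - m_a[a] -
                            m_b[b] - m_c[cc] + m)^2
  }
  lapply(ss, unname)
}

random_amplitudes <- function(n_sub, seed = 1, effect = 0) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("S%02d", seq_len(n_sub)),
                      condition = c("source_correct", "source_incorrect"),
                      coronal = c("frontal", "central", "posterior"),
                      sagittal = c("left", "middle", "right"),
                      stringsAsFactors = FALSE)
  grid$amplitude <- rnorm(nrow(grid)) +
    effect * (grid$condition == "source_correct")
  grid
}

# Upper tail of the studentized range distribution by direct double
# integration (independent of stats::ptukey).
tukey_p_oracle <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  dens <- function(s) 2 * s * df * stats::dchisq(df * s^2, df) * inner(s)
  1 - stats::integrate(dens, 0, Inf, rel.tol = 1e-8)$value
}

# Hand BH step-up.
bh_oracle <- function(p) {
  o <- order(p); m <- length(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}
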