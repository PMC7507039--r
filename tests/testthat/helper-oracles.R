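# Independent oracles used across tests. These deliberately take the
# slow/brute-force route so they never share code with the implementation.

# Fisher's exact two-sided p by full hypergeometric enumeration over all
# tables with the observed margins.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled two-sample t p-value from first principles (no stats:: test call).
pooled_t_p <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), df)
}

# Exact Wilcoxon rank-sum two-sided p by enumeration of all group
# assignments (combined n must be small).
wilcox_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Spearman rho by explicit rank formula.
spearman_enum_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# Closed-form extended Tofts solution for a constant input from t = 0:
# Ct(t) = vp c + ve c (1 - exp(-kep t)).
tofts_const_input <- function(ktrans, ve, vp, conc, times_s) {
  kep_s <- (ktrans / ve) / 60
  vp * conc + ve * conc * (1 - exp(-kep_s * times_s))
}

# Shared small protocol for speed (full 7-angle VFA, fewer voxels).
default_times <- function() (0:44) * 8

# One-region noisy recovery run used by several tests: full chain from
# SPGR synthesis through the linear Tofts fit; returns the fitted table.
recover_ktrans <- function(seed, ktrans, n_voxels = 200, snr = 50,
                           ve = 0.2, vp = 0.02, t1_ms = 1200) {
  tr <- phantom_truth(region_label = 1, t1_ms = t1_ms, ktrans = ktrans,
                      ve = ve, vp = vp)
  shape <- c(n_voxels, 1, 1)
  ph <- generate_phantom(seed, truth = tr, grid_shape = shape,
                         labels = array(1L, shape), snr = snr)
  maps <- fit_t1_vfa(ph$vfa, ph$protocol$flip_angles, ph$protocol$tr)
  cs <- signal_to_concentration(ph$dyn, maps, ph$protocol)
  fit_tofts_map(cs, population_aif(ph$times))
}
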