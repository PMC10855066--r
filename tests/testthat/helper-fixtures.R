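# shared fixtures and independent oracles

# a tiny long-layout CSV with a base block and two titration points
write_toy_long_csv <- function(path, concs = c(1e-6, 2e-6),
                               wl = c(600, 603, 606),
                               base = c(80, 100, 90),
                               scale = c(0.9, 0.8),
                               shuffle = FALSE) {
  rows <- do.call(rbind, c(
    list(data.frame(titrant_conc = 0, wavelength = wl, intensity = base)),
    lapply(seq_along(concs), function(i) {
      data.frame(titrant_conc = concs[i], wavelength = wl,
                 intensity = base * scale[i])
    })
  ))
  if (shuffle) rows <- rows[sample(nrow(rows)), ]
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# brute-force oracle for the apparent association constant: grid-search
# nonlinear least squares of the 1:1 isotherm A(c) = (1-a)A0 + a*Ac,
# a = Kc/(1+Kc), over a (K, Ac) grid -- independent of the linearized fit
bh_grid_oracle <- function(conc, a_obs, a0,
                           k_grid = exp(seq(log(1e2), log(1e5), length.out = 4001)),
                           refine = TRUE) {
  sse_for <- function(K) {
    alpha <- K * conc / (1 + K * conc)
    # Ac solved in closed form for fixed K (linear in Ac)
    ac <- sum(alpha * (a_obs - (1 - alpha) * a0)) / sum(alpha^2)
    sum((a_obs - ((1 - alpha) * a0 + alpha * ac))^2)
  }
  sse <- vapply(k_grid, sse_for, numeric(1))
  k_best <- k_grid[which.min(sse)]
  if (refine) {
    k_fine <- seq(k_best * 0.98, k_best * 1.02, length.out = 2001)
    k_best <- k_fine[which.min(vapply(k_fine, sse_for, numeric(1)))]
  }
  k_best
}

# closed-form two-temperature van't Hoff solution
vant_hoff_two_point <- function(t1, k1, t2, k2, R = 8.314) {
  slope <- (log(k1) - log(k2)) / (1 / t1 - 1 / t2)
  intercept <- log(k1) - slope / t1
  list(dh = -R * slope, ds = R * intercept)
}
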