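# Independent oracles used across tests. These deliberately avoid the
# package's grid machinery: closed forms and hand-rolled arithmetic only.

# Closed-form posterior mode in the near-delta surface limit: behind the
# surface the log-posterior is the sum of two quadratics, so the mode is the
# precision-weighted mean of the surface position and the disparity mean;
# at or in front of the surface the prior is flat and the mode is mu_disp.
closed_form_match <- function(mu_disp, sigma_disp, x_surf, sigma_opacity) {
  if (mu_disp <= x_surf) {
    mu_disp
  } else {
    (x_surf / sigma_opacity^2 + mu_disp / sigma_disp^2) /
      (1 / sigma_opacity^2 + 1 / sigma_disp^2)
  }
}

# Hand-executed Cousineau-Morey computation for a subject x cell matrix
# (rows = subjects, columns = cells), written out step by step with base
# arithmetic.
cousineau_morey_oracle <- function(mat, level = 0.95) {
  n <- nrow(mat)
  C <- ncol(mat)
  grand <- sum(mat) / length(mat)
  norm <- mat - rowMeans(mat) + grand
  half <- numeric(C)
  for (j in seq_len(C)) {
    v <- norm[, j]
    s <- sqrt(sum((v - mean(v))^2) / (n - 1))
    s_corr <- s * sqrt(C / (C - 1))
    half[j] <- qt((1 + level) / 2, df = n - 1) * s_corr / sqrt(n)
  }
  half
}

# Small panel used by several fitting/analysis tests (3 observers keeps the
# per-test fit cost low; the full 12-observer design is exercised in the
# acceptance suite).
small_panel <- function(seed = 7, n_observers = 3, ...) {
  simulate_panel(n_observers = n_observers, design = make_design("exp1"),
                 seed = seed, ...)
}
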