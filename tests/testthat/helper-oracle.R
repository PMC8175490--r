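# Independent high-accuracy integration oracle (lsoda, piecewise around the
# enzyme lag) used to check the explicit-Euler scheme. Returns the state at
# the sampling times as a matrix with columns P, A, B, Q, R, E.
ode_oracle <- function(params, conditions, rtol = 1e-10, atol = 1e-12) {
  pv <- setNames(as.numeric(params),
                 c("V_p", "K_b", "h", "K_ma", "V_q", "V_r",
                   "k_d1", "k_d2", "k_a", "t_lag"))
  rhs <- function(t, y, parms, lag_active) {
    A <- max(y[2], 0); B <- max(y[3], 0); Q <- y[4]; E <- y[6]
    kb <- if (B > 0) pv[["K_b"]] * B^pv[["h"]] else 0
    dP <- pv[["V_p"]] * kb / (1 + kb) * A / (pv[["K_ma"]] + A) * E
    dQ <- pv[["V_q"]] * A * E - pv[["V_r"]] * A * Q * E
    dR <- pv[["V_r"]] * A * Q * E
    dE <- if (lag_active) {
      -(pv[["k_d1"]] + pv[["k_d2"]] * B) * E + pv[["k_a"]] * conditions$Ph_b
    } else 0
    list(c(dP, -dP - dQ - 2 * dR, -dP, dQ, dR, dE))
  }
  y0 <- setNames(as.numeric(conditions$initial),
                 c("P", "A", "B", "Q", "R", "E"))
  tl <- pv[["t_lag"]]
  y1 <- y0
  if (tl > 0) {
    s1 <- deSolve::ode(y0, c(0, tl), rhs, parms = NULL, lag_active = FALSE,
                       method = "lsoda", rtol = rtol, atol = atol)
    y1 <- s1[nrow(s1), -1]
  }
  times <- c(tl, seq(conditions$sampling_interval, conditions$t_end,
                     by = conditions$sampling_interval))
  s2 <- deSolve::ode(y1, times, rhs, parms = NULL, lag_active = TRUE,
                     method = "lsoda", rtol = rtol, atol = atol)
  out <- rbind(y0, s2[-1, -1])
  dimnames(out) <- list(NULL, c("P", "A", "B", "Q", "R", "E"))
  out
}

# sampled simulation as a matrix in canonical species order
sampled_matrix <- function(traj) {
  s <- sampled_states(traj)
  m <- as.matrix(s[, c("pac_mM", "pyruvate_mM", "benzaldehyde_mM",
                       "acetaldehyde_mM", "acetoin_mM", "enzyme_pct")])
  dimnames(m) <- list(NULL, c("P", "A", "B", "Q", "R", "E"))
  m
}

# worst relative deviation between two sampled state matrices, skipping the
# shared initial row
max_rel_dev <- function(a, b) {
  rel <- abs(a - b) / pmax(abs(b), 1e-12)
  max(rel[-1, ])
}

study_pairs <- c("30/36", "50/60", "100/120")
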