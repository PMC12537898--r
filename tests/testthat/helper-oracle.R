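# Independent, deliberately naive re-implementation of the hybrid-model
# likelihood, kept free of any package internals: explicit probability
# normalisation (no log-sum-exp), explicit loops, values tracked in named
# lists. Used as the oracle the package's compiled recursion is checked
# against.
oracle_nll <- function(par, trials, p_common = 0.7) {
  qmf <- c(0, 0)
  q2 <- matrix(0, 2, 2) # state x action
  nll <- 0
  prev_a1 <- NA
  for (t in seq_len(nrow(trials))) {
    row <- trials[t, ]
    # model-based values: expectation of the best second-stage action
    qmb <- c(
      p_common * max(q2[1, ]) + (1 - p_common) * max(q2[2, ]),
      p_common * max(q2[2, ]) + (1 - p_common) * max(q2[1, ])
    )
    qnet <- par$omega * qmb + (1 - par$omega) * qmf
    pref <- par$beta1 * qnet
    if (!is.na(prev_a1)) pref[prev_a1 + 1] <- pref[prev_a1 + 1] + par$rep
    p1 <- exp(pref - max(pref))
    p1 <- p1 / sum(p1)
    nll <- nll - log(p1[row$a1 + 1])

    pref2 <- par$beta2 * q2[row$s2 + 1, ]
    p2 <- exp(pref2 - max(pref2))
    p2 <- p2 / sum(p2)
    nll <- nll - log(p2[row$a2 + 1])

    d1 <- q2[row$s2 + 1, row$a2 + 1] - qmf[row$a1 + 1]
    qmf[row$a1 + 1] <- qmf[row$a1 + 1] + par$alpha1 * d1
    d2 <- row$points - q2[row$s2 + 1, row$a2 + 1]
    q2[row$s2 + 1, row$a2 + 1] <- q2[row$s2 + 1, row$a2 + 1] +
      par$alpha2 * d2
    qmf[row$a1 + 1] <- qmf[row$a1 + 1] + par$alpha1 * par$lam * d2
    prev_a1 <- row$a1
  }
  nll
}

# random parameter draw for oracle comparisons
random_oracle_params <- function() {
  list(alpha1 = runif(1), alpha2 = runif(1), lam = runif(1),
       beta1 = runif(1, 0, 3), beta2 = runif(1, 0, 3),
       omega = runif(1), rep = rnorm(1, 0, 0.5))
}
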