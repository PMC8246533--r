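# shared fixtures, built in code

design94 <- function(seed = 1) generate_design(9, 9, 4, seed = seed)

# small pooled-DGP panel for quick structural tests
toy_panel <- function(N = 20, beta = c(1, 0.5, 0, -0.5, rep(0, 5)),
                      seed = 42, design = design94()) {
  simulate_panel(dgp_spec("pooled", design, N = N,
                          parameters = list(beta = beta), seed = seed))
}

# independent enumeration oracle for maxdiff pair probabilities:
# plain loops, no shared code with the implementation
enumerate_pair_probs <- function(beta, shown) {
  num <- c()
  lab <- list()
  for (i in shown) for (j in shown) if (i != j) {
    num <- c(num, exp(beta[i] - beta[j]))
    lab[[length(lab) + 1]] <- c(i, j)
  }
  list(pairs = do.call(rbind, lab), prob = num / sum(num))
}
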