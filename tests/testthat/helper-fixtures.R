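# Shared fixtures, all generated in code.

# A small fully-observed stack with two deterministic continuous layers and
# one categorical layer.
tiny_stack <- function(n = 10, period_tag = "current") {
  g <- grid_def(0, n, 1, n, n)
  a <- matrix(seq_len(n * n), n, n)                 # gradient
  b <- matrix(rev(seq_len(n * n)) / 2, n, n)        # reversed gradient
  k <- matrix(rep(c(1, 2), length.out = n * n), n, n)
  env_stack(list(env_layer("alpha", a, "continuous"),
                 env_layer("beta", b, "continuous"),
                 env_layer("kat", k, "categorical")),
            g, period_tag)
}

# Random presence/absence table with a planted linear signal.
signal_table <- function(n = 200, p = 3, strength = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    eta <- strength * X[, 1]
    lab <- rbinom(n, 1, plogis(eta))
    tibble::tibble(label = lab, cell = seq_len(n) - 1L,
                   !!!as.data.frame(X))
  })
}

# Labels independent of features.
noise_table <- function(n = 120, p = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    tibble::tibble(label = rep(c(0L, 1L), length.out = n),
                   cell = seq_len(n) - 1L, !!!as.data.frame(X))
  })
}

rowcol_cell_for_test <- function(g, row, col) as.integer(row * g$n_cols + col)

# Independent brute-force AUC: exhaustive pair counting.
pair_count_auc <- function(labels, predictions) {
  pos <- predictions[labels == 1]
  neg <- predictions[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
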