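# Independent brute-force oracle: explicit O(n^2) enumeration of
# positive/negative pairs with half credit for ties. Kept free of any
# package internals so it can certify the rank-based implementation.
pf_oracle <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) for (n in neg_scores) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# brute-force marginal ranking loss by pair enumeration
hinge_oracle <- function(x_p, x_n, margin) {
  tot <- 0
  for (p in x_p) for (n in x_n) tot <- tot + max(0, -p + n + margin)
  tot / (length(x_p) * length(x_n))
}

# random scored set with groups, guaranteed both classes present
random_scored_set <- function(n, n_groups = 2, tie_prob = 0.3) {
  scores <- round(runif(n), if (runif(1) < tie_prob) 1 else 6)
  labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
  groups <- sample(LETTERS[seq_len(n_groups)], n, replace = TRUE)
  scored_set(scores, labels, groups)
}

# feature-payload records for trainer tests: one informative dim + noise
toy_records <- function(n, d = 2, prevalence = 0.5, n_noise = 3, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, prevalence)
  X <- cbind(d * y + rnorm(n), matrix(rnorm(n * n_noise), n))
  colnames(X) <- paste0("f", seq_len(ncol(X)) - 1)
  tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)),
                 patient_id = sprintf("p%04d", seq_len(n)),
                 label = y, grp = sample(c("A", "B"), n, replace = TRUE)) |>
    cbind(as.data.frame(X)) |> tibble::as_tibble()
}
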