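# Shared helpers: small config factories and brute-force oracles kept
# independent of the package implementation paths they check.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_cases = 40, n_controls = 40, n_genera = 16,
                   n_blocks = 3, block_sizes = c(5, 4, 3),
                   n_pathways = 18, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Strip non-structural attributes (e.g. orientation/group) for comparisons.
bare <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# All permutations of 1..n, independent of the package internal.
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exhaustive minimum-total-distance one-to-one matching (n x m, n <= m).
brute_force_match <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 7)
  best <- Inf
  for (r in seq_len(nrow(p <- perms_oracle(m)))) {
    cols <- p[r, seq_len(n)]
    tot <- sum(cost[cbind(seq_len(n), cols)])
    if (tot < best) best <- tot
  }
  best
}

# AUC by direct pair enumeration.
auc_oracle <- function(pos, neg) {
  wins <- outer(pos, neg, ">")
  ties <- outer(pos, neg, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(pos) * length(neg))
}

# BH step-up by hand (sort, adjust, cumulative min from the largest rank,
# unsort) — the textbook procedure, written independently of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
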