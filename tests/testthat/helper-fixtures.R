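# Shared fixtures, built in code. Small by design: heavyweight end-to-end
# runs live in test-acceptance.R only.

# tiny deterministic two-cloud classification problem
toy_separable <- function(n = 60) {
  set.seed(42)
  X <- rbind(matrix(rnorm(n, -3, 0.5), n / 2, 2),
             matrix(rnorm(n, 3, 0.5), n / 2, 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

# small nonseparable problem with one strong and one weak signal
toy_signal <- function(n = 800, seed = 9) {
  set.seed(seed)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] - 0.7 * X[, 2]))
  list(X = X, y = y)
}

# brute-force Shapley of the marginal-expectation game by full enumeration,
# independent of shap_exact's internals (direct permutation average)
shapley_bruteforce <- function(predict_fn, x, background) {
  d <- length(x)
  perms <- gtools_permutations(d)
  vfun <- function(S) {
    H <- background
    if (length(S)) H[, S] <- matrix(x[S], nrow(background), length(S),
                                    byrow = TRUE)
    mean(predict_fn(H))
  }
  phi <- numeric(d)
  for (p in seq_len(nrow(perms))) {
    S <- integer(0)
    vprev <- vfun(S)
    for (j in perms[p, ]) {
      S <- c(S, j)
      v <- vfun(S)
      phi[j] <- phi[j] + (v - vprev)
      vprev <- v
    }
  }
  phi / nrow(perms)
}

# all permutations of 1:d without external packages
gtools_permutations <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(d - 1)
  out <- NULL
  for (j in seq_len(d)) {
    rest <- setdiff(seq_len(d), j)
    out <- rbind(out, cbind(j, matrix(rest[sub], nrow(sub), d - 1)))
  }
  unname(out)
}

# adjusted Rand index for planted-partition recovery checks
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# exhaustive-grid MCC oracle for threshold selection
best_mcc_exhaustive <- function(scores, y) {
  cands <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                         min(scores) - 1, max(scores) + 1)))
  best <- -Inf
  for (t in cands) {
    pred <- as.numeric(scores >= t)
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    best <- max(best, dentshap::mcc(tp, fp, fn, tn))
  }
  best
}
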