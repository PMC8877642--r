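# Independent oracles used across the suite.

# Run code under a fixed seed without disturbing the session RNG.
with_seed_test <- function(seed, code) deidverify:::with_seed(seed, code)

# O(n^2) pairwise-comparison count of distinct rows.
brute_distinct_groups <- function(df) {
  n <- nrow(df)
  first_of_group <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!first_of_group[i]) next
    for (j in seq_len(n)) {
      if (j > i && all(df[i, ] == df[j, ])) first_of_group[j] <- FALSE
    }
  }
  sum(first_of_group)
}

# Draw one uniformly random masking policy from the current RNG stream.
random_policy <- function() {
  masking_policy(
    name_level = sample(0:3, 1),
    age_level = sample(0:2, 1),
    phone_level = sample(c("none", "partial", "full"), 1),
    blood_mask = sample(c(FALSE, TRUE), 1),
    region_mask = sample(c(FALSE, TRUE), 1),
    illness_mask = sample(c(FALSE, TRUE), 1),
    smoking_mask = sample(c(FALSE, TRUE), 1))
}

# A policy masking at least as much as `base` on every field.
escalate_policy <- function(base) {
  lv <- c("none", "partial", "full")
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 v
  masking_policy(
    name_level = pick(base$name_level:3),
    age_level = pick(base$age_level:2),
    phone_level = lv[pick(match(base$phone_level, lv):3)],
    blood_mask = base$blood_mask || sample(c(FALSE, TRUE), 1),
    region_mask = base$region_mask || sample(c(FALSE, TRUE), 1),
    illness_mask = base$illness_mask || sample(c(FALSE, TRUE), 1),
    smoking_mask = base$smoking_mask || sample(c(FALSE, TRUE), 1))
}

# Brute-force Shapley values for a boosted surrogate at instance x
# (named numeric vector): enumerate all 2^p coalitions of the model's
# features, with the coalition value v(S) the cover-weighted
# conditional expectation over the trees (features outside S averaged
# by training cover). Exponential; for p <= 4 only.
brute_shap <- function(surrogate, x) {
  if (inherits(surrogate, "deid_tuned")) surrogate <- surrogate$model
  arr <- deidverify:::xgb_tree_arrays(surrogate$model, surrogate$features)
  p <- length(surrogate$features)
  stopifnot(p <= 4)
  x <- as.numeric(x[surrogate$features])

  expvalue <- function(node, S) {  # node is a 0-based array index
    i <- node + 1L
    if (arr$feat[i] < 0L) return(arr$val[i])
    f <- arr$feat[i] + 1L
    l <- arr$left[i]; r <- arr$right[i]
    if (f %in% S) {
      if (x[f] < arr$thr[i]) expvalue(l, S) else expvalue(r, S)
    } else {
      (arr$cover[l + 1L] * expvalue(l, S) +
         arr$cover[r + 1L] * expvalue(r, S)) / arr$cover[i]
    }
  }
  v <- function(S) {
    arr$base_score + sum(vapply(arr$roots, expvalue, numeric(1), S = S))
  }

  subsets <- function(set) {
    if (length(set) == 0L) return(list(integer(0)))
    rest <- subsets(set[-1])
    c(rest, lapply(rest, function(s) c(set[1], s)))
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (S in subsets(setdiff(seq_len(p), j))) {
      w <- factorial(length(S)) * factorial(p - length(S) - 1L) / factorial(p)
      phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  list(phi = phi, base = v(integer(0)))
}

# Tiny deterministic training frame for surrogate/SHAP unit tests.
toy_regression <- function(n = 120, p = 3, seed = 5,
                           fun = function(X) X[, 1] + 2 * X[, 2]) {
  set.seed(seed)
  X <- matrix(sample(0:5, n * p, replace = TRUE), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  df <- as.data.frame(X)
  df$final_score <- fun(X)
  df
}
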