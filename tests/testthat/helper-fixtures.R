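# Shared fixtures: mid-range hyperparameter settings and small separable
# datasets, all built in code at test time.

mid_hyperparams <- function(learner) {
  sp <- learner_space(learner)
  hp <- lapply(sp, function(s) {
    switch(s$kind,
      categorical = s$categories[[1]],
      integer = round(mean(s$range)),
      log_uniform = 10^mean(log10(s$range)),
      continuous = mean(s$range))
  })
  names(hp) <- names(sp)
  hp
}

# Linearly separable two-feature data: class 1 iff x1 + x2 > 0, with a wide
# margin so any sane linear fit separates it.
separable_data <- function(n = 60, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- rnorm(n) + ifelse(y == 1, 3, -3)
  x2 <- rnorm(n) + ifelse(y == 1, 3, -3)
  data.frame(x1 = x1, x2 = x2, noise = rnorm(n), caf = y)
}

# Exhaustive pairwise Mann-Whitney concordance: the independent ROC-AUC
# oracle.
auc_pairwise <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Brute-force step integration of the precision-recall curve at every
# unique descending threshold.
prauc_bruteforce <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in thr) {
    tp <- sum(y == 1 & s >= t); fp <- sum(y == 0 & s >= t)
    r <- tp / sum(y == 1)
    ap <- ap + (r - r_prev) * tp / (tp + fp)
    r_prev <- r
  }
  ap
}
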