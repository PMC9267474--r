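# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# symmetric (reflective) padding by b pixels on every side; assumes b < dim
oracle_pad_sym <- function(m, b) {
  ri <- c(b:1, seq_len(nrow(m)), nrow(m):(nrow(m) - b + 1L))
  ci <- c(b:1, seq_len(ncol(m)), ncol(m):(ncol(m) - b + 1L))
  if (b == 0L) return(m)
  m[ri, ci, drop = FALSE]
}

# per-pixel local mean over a block x block window
oracle_local_mean <- function(m, block) {
  b <- block %/% 2L
  p <- oracle_pad_sym(m, b)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- mean(p[i:(i + 2L * b), j:(j + 2L * b)])
    }
  }
  out
}

oracle_threshold_mask <- function(m, block, offset, dark = TRUE) {
  thr <- oracle_local_mean(m, block)
  if (dark) m < thr - offset else m > thr + offset
}

oracle_median_filter <- function(m, k) {
  b <- k %/% 2L
  p <- oracle_pad_sym(m, b)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- median(p[i:(i + 2L * b), j:(j + 2L * b)])
    }
  }
  out
}

# AUC by exhaustive positive/negative pair counting (win 1, tie 0.5)
oracle_auc_pairwise <- function(scores, labels, positive = 1) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) {
    for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos) * length(neg))
}

# pooled-variance two-sided Student's t from the textbook formula
oracle_students_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# small noise-free cube built directly from a scene's true reflectance
truth_cube <- function(scene) scene_reflectance(scene)

# the full-size 21 + 21 default cohort is expensive; compute it once and
# share it across the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.acceptance_cache$res)) {
    .acceptance_cache$res <- run_cohort(n_per_group = 21L, seed = 1L)
  }
  .acceptance_cache$res
}
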