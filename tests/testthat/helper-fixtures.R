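# small deterministic fixtures shared across test files

# metadata for `n_rep` samples per (region, age, sex) cell
tiny_meta <- function(regions = c("cortex", "pons"), ages = c(3, 12, 21),
                      sexes = "M", n_rep = 2, reads = 5e6) {
  g <- expand.grid(rep = seq_len(n_rep), sex = sexes, age_months = ages,
                   region = regions, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%03d", seq_len(nrow(g))),
             region = g$region, age_months = g$age_months, sex = g$sex,
             individual = sprintf("i%s%02g%d", g$sex, g$age_months, g$rep),
             aligned_reads = reads, stringsAsFactors = FALSE)
}

# expression matrix with given dimnames filled from a generator function
tiny_matrix <- function(meta, n_features = 10, fill = function(n) seq_len(n)) {
  m <- matrix(fill(n_features * nrow(meta)), nrow = n_features,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              meta$sample_id))
  m
}

# independent brute-force Benjamini-Hochberg (step-up, min over the tail)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent Welch t-test p from the textbook formula
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# z-scored cluster templates over an age grid (monotone up/down, peak, step)
trajectory_templates <- function(n_ages = 7) {
  zrow <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  rbind(up = zrow(seq_len(n_ages)),
        down = zrow(rev(seq_len(n_ages))),
        peak = zrow(c(rep(0, n_ages %/% 2), 1, rep(0, n_ages - n_ages %/% 2 - 1))),
        step = zrow(c(rep(0, n_ages %/% 2), rep(1, n_ages - n_ages %/% 2))))
}

# draw noisy trajectories from templates; returns matrix + true labels
sample_trajectories <- function(per_template = 40, sigma = 0.3, n_ages = 7,
                                seed = 1) {
  set.seed(seed)
  tpl <- trajectory_templates(n_ages)
  lab <- rep(seq_len(nrow(tpl)), each = per_template)
  x <- tpl[lab, ] + matrix(rnorm(length(lab) * n_ages, sd = sigma),
                           ncol = n_ages)
  x <- t(apply(x, 1, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))))
  rownames(x) <- sprintf("f%03d|r%02d", seq_along(lab), lab)
  list(x = x, labels = lab)
}

# adjusted Rand index between two labelings (closed-form pair counting)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
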