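# Shared fixtures and independent oracles.

recist_scale <- function() rating_scale(c("PR", "SD", "PD"))

fixture_counts <- list(
  testing_r1      = matrix(c(1, 0, 2, 4, 3, 3, 1, 1, 16), 3, byrow = TRUE),
  testing_r2      = matrix(c(1, 0, 3, 3, 3, 5, 2, 1, 13), 3, byrow = TRUE),
  testing_auto    = matrix(c(2, 0, 2, 3, 3, 1, 1, 1, 18), 3, byrow = TRUE),
  validation_r1   = matrix(c(3, 2, 0, 3, 2, 1, 1, 0, 19), 3, byrow = TRUE),
  validation_r2   = matrix(c(2, 2, 2, 4, 2, 2, 1, 0, 16), 3, byrow = TRUE),
  validation_auto = matrix(c(4, 2, 0, 1, 2, 3, 2, 0, 17), 3, byrow = TRUE)
)

fixture_table <- function(id) {
  m <- fixture_counts[[id]]
  dimnames(m) <- list(c("PR", "SD", "PD"), c("PR", "SD", "PD"))
  contingency_table(m, scale = recist_scale(), id = id)
}

# Reference kappa point estimates and non-null SEs for the six fixtures,
# frozen from an independent implementation of the same estimator family
# (statsmodels cohens_kappa, Fleiss-Cohen-Everitt variance), 10 dp.
# Columns: kc, se_c, klw, se_lw, kqw, se_qw.
frozen_reference <- rbind(
  testing_r1      = c(0.3504761905, 0.1252449725, 0.3764367816,
                      0.1352880115, 0.4026974952, 0.1654899157),
  testing_r2      = c(0.2208258528, 0.1265966835, 0.2008141113,
                      0.1426543006, 0.1804922516, 0.1769249270),
  testing_auto    = c(0.4928425358, 0.1340381823, 0.5079365079,
                      0.1431748620, 0.5213442325, 0.1678238133),
  validation_r1   = c(0.5677290837, 0.1168021610, 0.6657681941,
                      0.1041375970, 0.7463175123, 0.1039510050),
  validation_r2   = c(0.3765996344, 0.1184461545, 0.4478371501,
                      0.1245384733, 0.5094936709, 0.1445753475),
  validation_auto = c(0.5184466019, 0.1309652460, 0.5963541667,
                      0.1280514973, 0.6593406593, 0.1358355670)
)
colnames(frozen_reference) <- c("kc", "se_c", "klw", "se_lw", "kqw",
                                "se_qw")

# Published 2-dp point estimates and 95% CI bounds for the same six
# comparisons (kc/lw/qw per row block).
published_points <- rbind(
  testing_r1      = c(0.35, 0.38, 0.40),
  testing_r2      = c(0.22, 0.20, 0.18),
  testing_auto    = c(0.49, 0.51, 0.52),
  validation_r1   = c(0.57, 0.67, 0.75),
  validation_r2   = c(0.38, 0.45, 0.51),
  validation_auto = c(0.52, 0.60, 0.66)
)
published_ci <- list(
  testing_r1      = list(c(0.11, 0.60), c(0.11, 0.66), c(0.08, 0.73)),
  testing_r2      = list(c(-0.03, 0.47), c(-0.08, 0.48), c(-0.17, 0.53)),
  testing_auto    = list(c(0.23, 0.76), c(0.23, 0.79), c(0.19, 0.85)),
  validation_r1   = list(c(0.34, 0.80), c(0.46, 0.87), c(0.54, 0.95)),
  validation_r2   = list(c(0.14, 0.61), c(0.20, 0.69), c(0.23, 0.79)),
  validation_auto = list(c(0.26, 0.78), c(0.35, 0.85), c(0.39, 0.93))
)

# Brute-force per-subject oracle for weighted kappa: observed agreement
# tallies w over subjects directly; chance agreement tallies w over all
# ordered subject pairs (s, t), i.e. the empirical marginal product.
brute_force_kappa <- function(a, b, labels, w) {
  ia <- match(a, labels)
  ib <- match(b, labels)
  n <- length(ia)
  po <- mean(w[cbind(ia, ib)])
  pe <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) pe <- pe + w[ia[s], ib[t]]
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# Random paired ratings over k categories with some diagonal pull.
random_ratings <- function(n, k, diag_boost = 2) {
  labels <- LETTERS[seq_len(k)]
  p <- matrix(1, k, k) + diag(rep(diag_boost, k))
  p <- p / sum(p)
  cell <- sample.int(k * k, n, replace = TRUE, prob = as.vector(p))
  i <- ((cell - 1L) %% k) + 1L
  j <- ((cell - 1L) %/% k) + 1L
  paired_ratings(labels[i], labels[j])
}

expand_to_ratings <- function(tab) {
  idx <- which(tab$counts > 0, arr.ind = TRUE)
  a <- rep(tab$scale$labels[idx[, 1]], tab$counts[idx])
  b <- rep(tab$scale$labels[idx[, 2]], tab$counts[idx])
  paired_ratings(a, b)
}
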