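# Independent oracles used across the suite. These deliberately share no
# code with the package: morphology by repeated neighborhood max, exact
# tests by direct enumeration, approximate tests by permutation.

# Dilation by `steps` applications of a 3x3 square structuring element,
# computed as a pixelwise neighborhood maximum with zero padding.
brute_dilate <- function(mask, steps) {
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(steps)) {
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    out <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1)
      out <- pmax(out, p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
    m <- out
  }
  m
}

# Ring pixel set of object k by brute-force set operations.
brute_ring <- function(labels, k, inner, outer) {
  douter <- brute_dilate(labels == k, outer) > 0
  union_inner <- brute_dilate(labels > 0, inner) > 0
  which(douter & !union_inner)
}

# Two-sided Fisher p by full hypergeometric enumeration over the margins
# (probability-mass definition, 1e-7 relative tolerance for float ties).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  p <- exp(logp)
  p_obs <- p[xs == tab[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# One-sided (enrichment) hypergeometric tail by enumeration:
# P(X >= k) drawing n from N with K successes.
hyper_tail_p <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(n, K)
  p <- exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n))
  sum(p[xs >= k])
}

# Permutation p-value for the (tie-corrected) Kruskal-Wallis statistic.
perm_kruskal_p <- function(groups, B = 1e5) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  sizes <- lengths(groups)
  g <- rep(seq_along(groups), sizes)
  r <- rank(x)
  tie <- table(r)
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  h_of <- function(rr) {
    S <- as.numeric(rowsum(rr, g))
    ((12 / (n * (n + 1))) * sum(S^2 / sizes) - 3 * (n + 1)) / corr
  }
  h_obs <- h_of(r)
  idx <- replicate(B, sample.int(n))
  P <- matrix(r[idx], n, B)
  S <- rowsum(P, g)
  H <- ((12 / (n * (n + 1))) * colSums(S^2 / sizes) - 3 * (n + 1)) / corr
  mean(H >= h_obs - 1e-12)
}

# Two-sided permutation p-value for the rank-sum statistic of sample x.
perm_wilcox_p <- function(x, y, B = 1e5) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  idx <- replicate(B, sample.int(n, n1))
  W <- colSums(matrix(r[idx], n1, B))
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-12)
}

# Wrap a consecutive-integer label matrix as the package's mask container.
as_label_mask <- function(labels, channel_role = "marker") {
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  structure(list(labels = labels, channel_role = channel_role,
                 threshold = NA_real_,
                 border_ids = sort(border[border > 0]), note = NULL),
            class = "label_mask")
}

# Small flat noise-free scene parameters used by several tests.
quiet_params <- function(...) {
  defaults <- list(shape = c(256L, 256L), n_cells = 10L,
                   background_gradient = c(0, 0), psf_sigma = 0,
                   shot_noise = FALSE, read_noise_sd = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}
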