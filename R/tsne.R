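# Exact (quadratic) t-SNE. Written for the library sizes this package
# screens (hundreds to a few thousand molecules), where the O(n^2)
# gradient is cheap and reproducibility matters more than asymptotics.

# Per-point conditional probabilities at a fixed perplexity via binary
# search on the Gaussian precision beta.
pk_tsne_p <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    d <- D2[i, -i]
    for (try in seq_len(max_tries)) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
        p <- w
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

# X: numeric matrix (rows = points). Returns an n x 2 coordinate matrix.
pk_tsne <- function(X, perplexity = 30, seed = 42, max_iter = 500,
                    eta = 100, early_exaggeration = 12,
                    exaggeration_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) abort("t-SNE needs at least 5 points", class = "probekit_data_error")
  if (n - 1 < 3 * perplexity) {
    perplexity <- max(2, floor((n - 1) / 3))
    warn(paste0("perplexity reduced to ", perplexity,
                " for n = ", n, " points"))
  }
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  P <- pk_tsne_p(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  pk_with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    momentum <- 0.5
    for (iter in seq_len(max_iter)) {
      Pit <- if (iter <= exaggeration_iter) P * early_exaggeration else P
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      if (iter == floor(max_iter / 2)) momentum <- 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

# Mean silhouette width of a labeling on a coordinate matrix (Euclidean).
pk_silhouette <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  labels <- as.character(labels)
  sq <- rowSums(coords^2)
  D <- sqrt(pmax(outer(sq, sq, "+") - 2 * tcrossprod(coords), 0))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    same[i] <- FALSE
    a <- if (any(same)) mean(D[i, same]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
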