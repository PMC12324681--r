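# 2D projection of pocket embedding vectors and the binned label-entropy
# map. PCA uses base R; t-SNE (exact, O(n^2)) and FastICA are implemented
# here since the cohort sizes handled per projection (thousands of
# pockets) make the dense formulations tractable.

# Conditional-probability matrix for t-SNE: per-row binary search of the
# Gaussian bandwidth to hit the target perplexity.
tsne_input_probs <- function(d2, perplexity, tol = 1e-5) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - log_u) < tol) break
      if (h > log_u) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sw
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, .Machine$double.eps)
}

# Exact t-SNE by momentum gradient descent with early exaggeration.
tsne_exact <- function(x, perplexity = 50, n_iter = 1000L, seed = 1L,
                       learning_rate = NULL) {
  n <- nrow(x)
  if (perplexity >= n) stop("perplexity must be smaller than the number of points",
                            call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_input_probs(d2, perplexity)
  if (is.null(learning_rate)) learning_rate <- max(n / 12, 50)  # "auto" rule
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2)
  update <- matrix(0, n, 2)
  exaggeration <- 12
  stop_lying <- 250L
  for (iter in seq_len(n_iter)) {
    pe <- if (iter <= stop_lying) p * exaggeration else p
    momentum <- if (iter <= stop_lying) 0.5 else 0.8
    yd2 <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    q <- pmax(num / sum(num), .Machine$double.eps)
    l <- (pe - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    gain <- ifelse(sign(grad) != sign(update), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    update <- momentum * update - learning_rate * gain * grad
    y <- y + update
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

# FastICA with symmetric decorrelation and the logcosh contrast.
fast_ica <- function(x, n_components = 2L, seed = 1L, max_iter = 200L,
                     tol = 1e-6) {
  x <- scale(x, scale = FALSE)
  cv <- stats::cov(x)
  eig <- eigen(cv, symmetric = TRUE)
  keep <- which(eig$values > 1e-12)[seq_len(n_components)]
  whitening <- eig$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eig$values[keep]), length(keep))
  z <- x %*% whitening  # n x k, identity covariance
  set.seed(seed)
  w <- matrix(stats::rnorm(n_components^2), n_components)
  sym_decorr <- function(w) {
    s <- eigen(w %*% t(w), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% w
  }
  w <- sym_decorr(w)
  for (iter in seq_len(max_iter)) {
    wz <- z %*% t(w)
    g <- tanh(wz)
    g_prime <- 1 - g^2
    w_new <- t(g) %*% z / nrow(z) - diag(colMeans(g_prime)) %*% w
    w_new <- sym_decorr(w_new)
    if (max(abs(abs(diag(w_new %*% t(w))) - 1)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  z %*% t(w)
}

#' Project pocket embeddings to 2D
#'
#' @param emb an [embedding_set()].
#' @param method `"pca"`, `"ica"`, or `"tsne"`.
#' @param seed RNG seed (initialisation of t-SNE and ICA).
#' @param perplexity t-SNE perplexity (must be < number of pockets).
#' @param n_iter t-SNE gradient-descent iterations.
#' @return list of class `projection2d` with `method`, `coords`
#'   (pockets x 2, rownames = pocket ids), `params` and `seed`.
#' @export
project_embeddings <- function(emb, method = c("tsne", "pca", "ica"),
                               seed = 1L, perplexity = 50, n_iter = 1000L) {
  method <- match.arg(method)
  x <- emb$vectors
  if (nrow(x) < 2L) stop("at least 2 pockets are required", call. = FALSE)
  coords <- switch(
    method,
    pca = stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE],
    ica = fast_ica(x, 2L, seed = seed),
    tsne = tsne_exact(x, perplexity = perplexity, n_iter = n_iter, seed = seed)
  )
  coords <- as.matrix(coords)
  dimnames(coords) <- list(emb$pocket_ids, c("dim1", "dim2"))
  structure(
    list(method = method, coords = coords, seed = seed,
         params = if (method == "tsne") list(perplexity = perplexity,
                                             n_iter = n_iter) else list()),
    class = "projection2d"
  )
}

#' Binned label entropy over a 2D projection
#'
#' Overlays a regular grid on the projection bounding box and computes,
#' per bin, the Shannon entropy (natural log) of the label distribution:
#' `S = -sum_i p_i ln(p_i)` with `p_i` the fraction of the bin's pockets
#' carrying label `i` among the `N` categories present in the dataset.
#' Bins holding fewer than `min_count` pockets are masked (`NA`), as no
#' robust entropy estimate exists there.
#'
#' @param proj a [project_embeddings()] result.
#' @param labels character vector aligned with the projected pockets.
#' @param n_bins_x,n_bins_y grid resolution.
#' @param min_count masking threshold.
#' @return list of class `entropy_grid` with `entropy` and `count`
#'   matrices (x-bin rows, y-bin columns), bin edges, `n_categories` and
#'   `min_count`.
#' @export
binned_entropy <- function(proj, labels, n_bins_x = 50L, n_bins_y = 50L,
                           min_count = 20L) {
  if (n_bins_x < 1L || n_bins_y < 1L) stop("need at least one bin", call. = FALSE)
  coords <- proj$coords
  if (length(labels) != nrow(coords)) {
    stop("every pocket needs a label", call. = FALSE)
  }
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  labels <- as.character(labels)
  cats <- sort(unique(labels))
  xe <- seq(min(coords[, 1]), max(coords[, 1]), length.out = n_bins_x + 1L)
  ye <- seq(min(coords[, 2]), max(coords[, 2]), length.out = n_bins_y + 1L)
  bx <- pmin(findInterval(coords[, 1], xe, rightmost.closed = TRUE), n_bins_x)
  by <- pmin(findInterval(coords[, 2], ye, rightmost.closed = TRUE), n_bins_y)
  count <- matrix(0L, n_bins_x, n_bins_y)
  entropy <- matrix(NA_real_, n_bins_x, n_bins_y)
  bin_key <- paste(bx, by)
  for (key in unique(bin_key)) {
    members <- bin_key == key
    ij <- as.integer(strsplit(key, " ")[[1]])
    count[ij[1], ij[2]] <- sum(members)
    if (sum(members) >= min_count) {
      p <- table(factor(labels[members], levels = cats)) / sum(members)
      p <- p[p > 0]
      entropy[ij[1], ij[2]] <- -sum(p * log(p))
    }
  }
  structure(
    list(entropy = entropy, count = count, x_edges = xe, y_edges = ye,
         n_categories = length(cats), min_count = min_count),
    class = "entropy_grid"
  )
}
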