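# Feature embedding for cluster maps: high-dimensional per-annotation
# feature vectors are reduced to two dimensions before grid layout.

#' Reduce per-annotation feature vectors to two dimensions
#'
#' `pca` projects onto the first two principal components (closed form, via
#' [stats::prcomp()]). `tsne` runs an exact (non-approximated) t-SNE,
#' implemented in the package, suitable for the hundreds-to-thousands of
#' annotations a validation map holds. `umap` delegates to the Python
#' `umap-learn` library through an on-disk bridge and requires a `python`
#' with that library on the PATH; the two native methods have no such
#' requirement. All methods are deterministic for a fixed `seed`.
#'
#' Degenerate input — all feature vectors identical — yields all-zero
#' coordinates rather than an error.
#'
#' @param features A tibble with an `annotation_id` column plus numeric
#'   feature columns (e.g. from [generate_feature_table()]), or a numeric
#'   matrix with annotation ids as row names.
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param seed Integer seed for the stochastic methods.
#' @param perplexity t-SNE perplexity (default `min(30, (n - 1) / 3)`).
#' @param n_iter t-SNE gradient-descent iterations.
#' @return A tibble of class `slide_embedding`: `annotation_id`, `u`, `v`
#'   (finite 2-D coordinates).
#' @export
reduce_features <- function(features, method = c("pca", "tsne", "umap"), seed = 1L,
                            perplexity = NULL, n_iter = 500L) {
  method <- match.arg(method)
  parsed <- parse_feature_table(features)
  X <- parsed$X
  n <- nrow(X)
  if (n < 2L) abort("need at least 2 feature vectors")
  degenerate <- all(abs(sweep(X, 2, X[1L, ])) < 1e-12)
  Y <- if (degenerate) {
    matrix(0, n, 2)
  } else {
    switch(method,
      pca = embed_pca(X),
      tsne = embed_tsne(X, seed = seed, perplexity = perplexity, n_iter = n_iter),
      umap = embed_umap(X, seed = seed)
    )
  }
  if (any(!is.finite(Y))) abort("embedding produced non-finite coordinates")
  out <- tibble(annotation_id = parsed$ids, u = Y[, 1], v = Y[, 2])
  class(out) <- c("slide_embedding", class(out))
  out
}

parse_feature_table <- function(features) {
  if (is.matrix(features)) {
    ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
    return(list(ids = ids, X = unname(features)))
  }
  if (!is.data.frame(features)) abort("`features` must be a data frame or matrix")
  ids <- if ("annotation_id" %in% names(features)) as.character(features$annotation_id)
         else as.character(seq_len(nrow(features)))
  num <- features[vapply(features, is.numeric, logical(1))]
  if (!ncol(num)) abort("`features` has no numeric columns")
  list(ids = ids, X = unname(as.matrix(num)))
}

embed_pca <- function(X) {
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- ncol(p$x)
  Y <- matrix(0, nrow(X), 2)
  Y[, seq_len(min(2L, k))] <- p$x[, seq_len(min(2L, k)), drop = FALSE]
  Y
}

# Exact t-SNE (quadratic in n): conditional Gaussians with per-point
# precision tuned by bisection to the target perplexity, Student-t
# low-dimensional affinities, gradient descent with momentum and early
# exaggeration. Deterministic: the only randomness is the seeded init.
embed_tsne <- function(X, seed = 1L, perplexity = NULL, n_iter = 500L) {
  n <- nrow(X)
  perplexity <- perplexity %||% max(2, min(30, (n - 1) / 3))
  if (3 * perplexity > n - 1) perplexity <- max(1.5, (n - 1) / 3)
  D <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP < 1e-300) sumP <- 1e-300
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- withr::with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 200; exaggeration <- 12
  P_run <- P * exaggeration
  for (it in seq_len(n_iter)) {
    if (it == 101L) P_run <- P
    momentum <- if (it <= 250L) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) == sign(dY), gains * 0.8, gains + 0.2))
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# UMAP through the pre-installed Python library: features out as CSV, a
# short script in, coordinates back as CSV.
embed_umap <- function(X, seed = 1L) {
  python <- Sys.which("python")
  if (python == "") abort("umap needs a `python` with umap-learn on the PATH; use pca or tsne otherwise")
  td <- tempfile("umap"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fin <- file.path(td, "x.csv"); fout <- file.path(td, "y.csv")
  utils::write.table(X, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy, umap, warnings; warnings.filterwarnings('ignore')\n",
    "x = numpy.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "y = umap.UMAP(n_components=2, random_state=%d).fit_transform(x)\n",
    "numpy.savetxt(%s, y, delimiter=',')\n"),
    deparse(fin), as.integer(seed), deparse(fout))
  status <- system2(python, "-", input = script, stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) abort("the python umap bridge failed")
  as.matrix(utils::read.table(fout, sep = ","))
}
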