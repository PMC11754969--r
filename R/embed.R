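#' 2-D t-SNE embedding for scaling QA
#'
#' Exact t-distributed stochastic neighbour embedding of the feature rows,
#' used to inspect visually (and score) how well the stress and relaxation
#' classes separate before versus after longitudinal scaling. Deterministic
#' given `seed`; all randomness (the initial layout) is drawn from R's RNG.
#'
#' @param data feature table or numeric matrix.
#' @param features feature columns when `data` is a data.frame.
#' @param labels optional class labels (e.g. task); when given, the mean
#'   silhouette width of the labels in the embedded space is attached as the
#'   `"silhouette"` attribute — the separation score reported alongside.
#' @param perplexity t-SNE perplexity (default 50); at least `3 * perplexity`
#'   samples are required.
#' @param max_iter gradient-descent iterations (default 5000).
#' @param seed integer seed.
#' @return n x 2 matrix of coordinates (columns `tsne1`, `tsne2`), with a
#'   `"silhouette"` attribute when labels were supplied.
#' @export
embed_2d <- function(data, features = hrv_feature_names(), labels = NULL,
                     perplexity = 50, max_iter = 5000L, seed = 1L) {
  X <- if (is.matrix(data)) data else as.matrix(data[, features, drop = FALSE])
  n <- nrow(X)
  if (n < 3 * perplexity) {
    stop(sprintf("t-SNE needs at least 3 x perplexity = %d samples (have %d); lower the perplexity",
                 ceiling(3 * perplexity), n), call. = FALSE)
  }
  Y0 <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  Y <- .tsne_exact(X, Y0, perplexity, as.integer(max_iter))
  colnames(Y) <- c("tsne1", "tsne2")
  if (!is.null(labels)) {
    attr(Y, "silhouette") <- silhouette_score(Y, labels)
  }
  Y
}

#' Mean silhouette width of labelled points
#'
#' @param coords numeric matrix of coordinates.
#' @param labels class labels (>= 2 classes).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(coords, labels) {
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) stop("need at least two classes", call. = FALSE)
  sil <- cluster::silhouette(cl, stats::dist(coords))
  mean(sil[, "sil_width"])
}
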