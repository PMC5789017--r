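#' Spectral 4-vectors from per-plane signals
#'
#' Converts per-channel fitted signals into the normalized 4-component
#' vector used for dye classification: each component is the relative
#' signal received in that color channel. Localizations with all-zero or
#' negative channel signals are flagged `rejected` rather than dropped.
#'
#' @param signals A localization table (or any data frame) with columns
#'   `signal_1..signal_4`, or a numeric matrix with 4 columns.
#'
#' @return A tibble with `v1..v4` (components, rows summing to 1) and
#'   `rejected` (logical).
#' @examples
#' channel_vector(matrix(c(10, 10, 10, 10), 1))
#' @export
channel_vector <- function(signals) {
  m <- if (is.matrix(signals)) {
    signals
  } else {
    cols <- signal_columns(signals)
    if (length(cols) != 4L) {
      stop("need 4 signal columns (signal_1..signal_4)", call. = FALSE)
    }
    as.matrix(as.data.frame(signals)[, cols])
  }
  if (ncol(m) != 4L) stop("signals must have 4 channels", call. = FALSE)
  tot <- rowSums(m)
  bad <- tot <= 0 | apply(m < 0, 1, any) | !is.finite(tot)
  v <- m / ifelse(tot > 0, tot, 1)
  v[bad, ] <- NA_real_
  tibble::tibble(v1 = v[, 1], v2 = v[, 2], v3 = v[, 3], v4 = v[, 4],
                 rejected = bad)
}

vectors_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  as.matrix(as.data.frame(vectors)[, c("v1", "v2", "v3", "v4")])
}

#' First spectral moment of a 4-vector
#'
#' `sum_i i * v_i` with channels indexed 0..3 in wavelength order: a
#' scalar in [0, 3] locating the emission centroid along the channel
#' axis. Invariant to overall signal scaling.
#'
#' @param vectors Output of [channel_vector()] (or a 4-column matrix of
#'   normalized vectors).
#' @return Numeric vector of moments.
#' @examples
#' first_moment(matrix(c(0.25, 0.25, 0.25, 0.25), 1))  # 1.5
#' @export
first_moment <- function(vectors) {
  v <- vectors_matrix(vectors)
  drop(v %*% (0:3))
}

#' First-moment dye classification
#'
#' Classifies by thresholding the first spectral moment; cut points are
#' the midpoints between per-dye moment medians estimated from labelled
#' training data.
#'
#' @param moments Moments of the localizations to classify.
#' @param train_moments,train_labels Labelled training moments.
#' @return Integer labels (sorted by increasing training median moment,
#'   relabelled to the training label set).
#' @export
classify_first_moment <- function(moments, train_moments, train_labels) {
  meds <- tapply(train_moments, train_labels, stats::median)
  ord <- order(meds)
  cuts <- (meds[ord][-1] + meds[ord][-length(meds)]) / 2
  idx <- findInterval(moments, cuts) + 1L
  as.integer(names(meds)[ord][idx])
}

# k-means++ style seeding
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Train a k-means cluster model on spectral vectors
#'
#' Lloyd k-means with k-means++-style seeded initialization. If a cluster
#' empties during training the fit restarts with a new seeded
#' initialization (at most 10 restarts).
#'
#' @param vectors Output of [channel_vector()] (rejected rows are
#'   excluded) or a 4-column matrix.
#' @param k Number of dyes, >= 2.
#' @param seed RNG seed (mandatory; identical data + seed give an
#'   identical model).
#'
#' @return A `cluster_model` with `means` (k x 4), `k`, `seed`, `n`.
#' @export
train_clusters <- function(vectors, k, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(k >= 2)
  X <- vectors_matrix(vectors)
  if (is.data.frame(vectors) && "rejected" %in% names(vectors)) {
    X <- X[!vectors$rejected, , drop = FALSE]
  }
  if (nrow(X) < k) stop("need at least k vectors", call. = FALSE)
  fit <- with_seed(seed, {
    res <- NULL
    for (try in seq_len(10L)) {
      init <- kmeanspp_init(X, k)
      res <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = init, iter.max = 100,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(res) && all(res$size > 0)) break
      res <- NULL
    }
    res
  })
  if (is.null(fit)) {
    stop("k-means failed: empty cluster after 10 seeded restarts",
         call. = FALSE)
  }
  structure(list(means = fit$centers, k = as.integer(k),
                 seed = as.integer(seed), n = nrow(X)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, trained on %d vectors (seed %d)\n",
              x$k, x$n, x$seed))
  print(round(x$means, 3))
  invisible(x)
}

#' Classify spectral vectors with fractional rejection
#'
#' Assigns each vector to the nearest cluster mean (Euclidean distance,
#' ties to the lower cluster index), then discards the
#' `rejection_fraction` of assigned localizations with the largest
#' distance to their nearest mean — a global quantile over all
#' localizations, not per cluster. Discarded and invalid vectors get
#' label `NA` and `rejected = TRUE`.
#'
#' @param model A [train_clusters()] model.
#' @param vectors Output of [channel_vector()] or a 4-column matrix.
#' @param rejection_fraction Fraction to discard, in [0, 1).
#'
#' @return A tibble with `label` (integer or `NA`), `dist`, `rejected`.
#' @examples
#' # 10 vectors at rejection 0.2 -> exactly 2 discarded
#' @export
classify <- function(model, vectors, rejection_fraction = 0.20) {
  stopifnot(rejection_fraction >= 0, rejection_fraction < 1)
  X <- vectors_matrix(vectors)
  invalid <- apply(!is.finite(X), 1, any)
  if (is.data.frame(vectors) && "rejected" %in% names(vectors)) {
    invalid <- invalid | vectors$rejected
  }
  d2 <- outer(rowSums(X^2, na.rm = TRUE), rep(1, model$k)) +
    outer(rep(1, nrow(X)), rowSums(model$means^2)) -
    2 * ifelse(is.na(X), 0, X) %*% t(model$means)
  label <- apply(d2, 1, which.min)           # ties -> lower index
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(X)), label)], 0))
  label[invalid] <- NA_integer_
  dist[invalid] <- NA_real_

  assigned <- which(!invalid)
  n_drop <- floor(rejection_fraction * length(assigned))
  rejected <- invalid
  if (n_drop > 0L) {
    ord <- assigned[order(-dist[assigned], assigned)]
    drop_idx <- ord[seq_len(n_drop)]
    rejected[drop_idx] <- TRUE
    label[drop_idx] <- NA_integer_
  }
  tibble::tibble(label = as.integer(label), dist = dist,
                 rejected = rejected)
}

#' Cross-talk matrix between true and assigned dye labels
#'
#' Entry (i, j) is the fraction of true-class-i localizations assigned to
#' class j; rows sum to 1. Rejected (NA-labelled) localizations are
#' excluded before counting. An empty true class yields an NA row and a
#' warning.
#'
#' @param true_labels,assigned_labels Aligned label vectors.
#' @param k Number of classes.
#' @return List with `matrix` (k x k) and `max_offdiag`.
#' @export
crosstalk_matrix <- function(true_labels, assigned_labels, k) {
  keep <- !is.na(assigned_labels)
  tl <- true_labels[keep]
  al <- assigned_labels[keep]
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    n_i <- sum(tl == i)
    if (n_i == 0L) {
      warning("true class ", i, " is empty; row undefined", call. = FALSE)
      m[i, ] <- NA_real_
      next
    }
    for (j in seq_len(k)) m[i, j] <- sum(tl == i & al == j) / n_i
  }
  off <- m
  diag(off) <- NA
  list(matrix = m, max_offdiag = max(off, na.rm = TRUE))
}
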