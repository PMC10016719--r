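#' Condense voltage-clamp responses into fixed-length vectors
#'
#' For one protocol, each model's per-voltage-step current trace is linearly
#' resampled onto a fixed time grid of `grid_points` points, the steps are
#' concatenated in ascending step-voltage order, and the resulting vector is
#' normalized by its maximum absolute value (so the representation captures
#' kinetic shape, not magnitude). All models must share identical voltage
#' steps.
#'
#' @param responses Response tibble from [generate_channel_response_set()]
#'   (columns `model_id`, `protocol`, `step_mv`, `time_ms`, `current`).
#' @param protocol Protocol kind to condense (`"activation"`, ...).
#' @param grid_points Resampling grid length per voltage step.
#' @param value Response column to condense (default `"current"`).
#' @return Numeric matrix, one row per model (rownames = `model_id`).
#' @export
condense_responses <- function(responses, protocol, grid_points = 512,
                               value = "current") {
  df <- responses[responses$protocol == protocol, , drop = FALSE]
  stop_if_not(nrow(df) > 0, paste0("no responses for protocol ", protocol))
  ids <- unique(df$model_id)
  step_sets <- tapply(df$step_mv, df$model_id, function(s) sort(unique(s)))
  ref_steps <- step_sets[[1]]
  same <- vapply(step_sets, function(s) identical(s, ref_steps), logical(1))
  stop_if_not(all(same), "inconsistent voltage steps across models")

  rows <- vapply(ids, function(id) {
    sub <- df[df$model_id == id, ]
    unlist(lapply(ref_steps, function(sv) {
      tr <- sub[sub$step_mv == sv, ]
      grid <- seq(min(tr$time_ms), max(tr$time_ms), length.out = grid_points)
      approx(tr$time_ms, tr[[value]], xout = grid)$y
    }))
  }, numeric(grid_points * length(ref_steps)))
  m <- t(rows)
  rownames(m) <- ids
  scale_row <- apply(abs(m), 1, max)
  scale_row[scale_row == 0] <- 1
  m / scale_row
}

# marginal log-likelihood of each row under a probabilistic-PCA model fitted
# at `variance_threshold` explained variance. The residual variance is the
# mean of the discarded *observed* (nonzero) eigenvalues: with fewer samples
# than dimensions the sample spectrum has at most n-1 nonzero values, and
# averaging the residual over all d-q directions would drive sigma^2 toward
# zero and make the likelihood degenerate.
ppca_loglik <- function(x, variance_threshold = 0.99) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  stop_if_not(n >= 2, "need >= 2 models to fit a PCA model")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- ev / sum(ev)
  q <- which(cumsum(frac) >= variance_threshold - 1e-12)[1]
  q <- min(q, max(1L, n - 2L))  # keep at least one discarded direction
  lam <- ev[seq_len(q)]
  rank <- sum(ev > max(ev) * 1e-12)
  sigma2 <- max((sum(ev) - sum(lam)) / max(rank - q, 1L),
                1e-9 * mean(ev), 1e-12)
  z <- p$x[, seq_len(q), drop = FALSE]
  xc <- sweep(x, 2, p$center)
  # residual by direct reconstruction (no catastrophic cancellation)
  recon <- z %*% t(p$rotation[, seq_len(q), drop = FALSE])
  resid2 <- rowSums((xc - recon)^2)
  -0.5 * (d * log(2 * pi) + sum(log(lam)) + (d - q) * log(sigma2) +
            rowSums(sweep(z^2, 2, lam, "/")) + resid2 / sigma2)
}

#' Score channel models under per-protocol PCA models
#'
#' For each of the three protocols, a probabilistic-PCA model is fitted to
#' the condensed response matrix at 99% explained variance, and each channel
#' model is scored by its log-likelihood under that fitted model. Every
#' model thus receives a three-dimensional score vector — its channel family
#' score.
#'
#' @param condensed Named list of three condensed matrices (names
#'   `activation`, `deactivation`, `inactivation`; identical rownames).
#' @param variance_threshold Explained-variance threshold for each
#'   per-protocol PCA (default 0.99).
#' @return Tibble: `model_id`, `ll_activation`, `ll_deactivation`,
#'   `ll_inactivation`.
#' @export
compute_family_scores <- function(condensed, variance_threshold = 0.99) {
  need <- c("activation", "deactivation", "inactivation")
  missing <- setdiff(need, names(condensed))
  stop_if_not(length(missing) == 0,
              paste0("missing protocol: ", paste(missing, collapse = ", ")))
  ids <- rownames(condensed[[need[1]]])
  for (nm in need) {
    stop_if_not(identical(rownames(condensed[[nm]]), ids),
                "condensed matrices must share identical model rows")
  }
  scores <- lapply(need, function(nm) {
    ppca_loglik(condensed[[nm]], variance_threshold)
  })
  tibble(model_id = ids,
         ll_activation = scores[[1]],
         ll_deactivation = scores[[2]],
         ll_inactivation = scores[[3]])
}

# adaptive tree cut of an hclust dendrogram, singletons allowed. A merge is
# "cut" (treated as a real cluster boundary) when its height exceeds
# `cut_ratio` times the tallest internal merge height of its child subtrees
# (floored at the median merge height, so early merges of nearby point pairs
# inside one diffuse cluster are not cut). Clusters are
# the maximal subtrees containing no cut; a subtree holding a cut below it
# is implicitly split as well. All-identical data (zero heights) yields a
# single cluster.
dynamic_tree_cut <- function(hc, cut_ratio = 3) {
  n <- length(hc$height) + 1L
  if (n == 1L) return(1L)
  h <- hc$height
  eps <- max(h) * 1e-9
  if (max(h) <= 0) return(rep(1L, n))
  med <- stats::median(h)

  internal <- function(node) if (node < 0) 0 else h[node]
  n_merge <- nrow(hc$merge)
  cut <- logical(n_merge)
  for (k in seq_len(n_merge)) {
    # a leaf child has no internal scale; the typical merge height stands in
    ref <- max(internal(hc$merge[k, 1]), internal(hc$merge[k, 2]), med, eps)
    cut[k] <- h[k] > cut_ratio * ref && h[k] > 1e-6 * max(h)
  }
  # propagate upward: a node above a cut cannot be a single cluster
  has_cut <- cut
  for (k in seq_len(n_merge)) {   # children always have smaller indices
    for (ch in hc$merge[k, ]) {
      if (ch > 0 && has_cut[ch]) has_cut[k] <- TRUE
    }
  }
  labels <- integer(n)
  next_label <- 0L
  members <- function(node) {
    if (node < 0) return(-node)
    unlist(lapply(hc$merge[node, ], members))
  }
  assign_cluster <- function(node) {
    next_label <<- next_label + 1L
    labels[members(node)] <<- next_label
  }
  walk <- function(node) {
    if (node < 0 || !has_cut[node]) {
      assign_cluster(node)
    } else {
      walk(hc$merge[node, 1])
      walk(hc$merge[node, 2])
    }
  }
  walk(n_merge)
  labels
}

#' Cluster channel models from their family scores
#'
#' The score matrix is reduced by PCA (99% explained variance), clustered by
#' agglomerative hierarchical clustering with Ward's minimal-variance
#' linkage, and cut with an adaptive (dynamic) tree cut in which singleton
#' clusters are allowed. Labels are canonicalized by each cluster's smallest
#' member id, so permuting the input rows permutes labels consistently.
#'
#' @param scores Tibble from [compute_family_scores()] (or any data frame
#'   with `model_id` plus numeric score columns).
#' @param variance_threshold Explained-variance threshold for the PCA.
#' @param cut_ratio Sensitivity of the adaptive tree cut (larger = fewer,
#'   coarser clusters).
#' @return A `channel_cluster_set`: `$labels` tibble (`model_id`,
#'   `cluster`), `$linkage` (the `hclust` tree), `$cut_params`.
#' @export
cluster_channels <- function(scores, variance_threshold = 0.99,
                             cut_ratio = 3) {
  stop_if_not(is.data.frame(scores) && "model_id" %in% names(scores),
              "scores must contain a model_id column")
  stop_if_not(nrow(scores) >= 2, "need >= 2 models")
  ord <- order(scores$model_id)
  scores <- scores[ord, , drop = FALSE]
  x <- as.matrix(scores[vapply(scores, is.numeric, logical(1))])
  if (nrow(unique(x)) == 1L) {
    labels <- rep(1L, nrow(x))
    hc <- NULL
  } else {
    red <- pca_reduce(x, variance_threshold)
    sc <- as.matrix(score_columns(red$scores))
    hc <- hclust(dist(sc), method = "ward.D2")
    labels <- dynamic_tree_cut(hc, cut_ratio = cut_ratio)
  }
  # canonical numbering: clusters ordered by their smallest model_id
  first_id <- tapply(scores$model_id, labels, min)
  canon <- match(labels, as.integer(names(sort(first_id))))
  structure(
    list(labels = tibble(model_id = scores$model_id, cluster = canon),
         linkage = hc,
         cut_params = list(cut_ratio = cut_ratio,
                           variance_threshold = variance_threshold)),
    class = "channel_cluster_set")
}

#' @export
print.channel_cluster_set <- function(x, ...) {
  k <- length(unique(x$labels$cluster))
  cat("Channel cluster set:", k, "clusters over", nrow(x$labels),
      "models\n")
  print(table(x$labels$cluster))
  invisible(x)
}

#' End-to-end channel characterization for one family
#'
#' Convenience wrapper: condense all three protocols, compute family scores,
#' and cluster.
#'
#' @param responses Response tibble from [generate_channel_response_set()].
#' @param grid_points Condensation grid length per voltage step.
#' @param ... Passed to [cluster_channels()].
#' @return List: `condensed`, `scores`, `clusters`.
#' @export
characterize_channels <- function(responses, grid_points = 512, ...) {
  condensed <- lapply(
    setNames(nm = c("activation", "deactivation", "inactivation")),
    function(p) condense_responses(responses, p, grid_points = grid_points))
  scores <- compute_family_scores(condensed)
  list(condensed = condensed, scores = scores,
       clusters = cluster_channels(scores, ...))
}
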