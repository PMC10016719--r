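#' Default per-feature missing-value fill policies
#'
#' Each feature gets one of three fill policies applied by [fill_missing()]:
#' `"min"` / `"max"` (the observed column extremum) or `"mean"` (the
#' cross-model column mean). Count-like features that are absent because the
#' model never spiked fill with the column minimum; latency-like features
#' that are absent because no spike occurred fill with the column maximum
#' (an unobserved spike is "later than any observed one"); everything else
#' defaults to the cross-model mean.
#'
#' @return Tibble with columns `feature`, `policy`.
#' @export
default_fill_policies <- function() {
  feats <- feature_names()
  policy <- rep("mean", length(feats))
  policy[grepl("^spike_count|^resting_ap_count", feats)] <- "min"
  policy[grepl("^delay_|^time_to_first_ramp", feats)] <- "max"
  tibble(feature = feats, policy = policy)
}

#' Fill missing feature values by declared per-feature policy
#'
#' @param matrix A feature tibble (e.g. from [compute_feature_matrix()]);
#'   non-numeric columns and identifier columns are passed through.
#' @param policies Tibble `feature`, `policy` (`"min"`, `"max"`, `"mean"`);
#'   defaults to [default_fill_policies()]. A numeric column with missing
#'   entries but no declared policy is an error.
#' @return The tibble with no remaining `NA` entries in policy-covered
#'   columns.
#' @export
fill_missing <- function(matrix, policies = default_fill_policies()) {
  stop_if_not(is.data.frame(matrix), "matrix must be a data frame")
  out <- matrix
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  for (col in num_cols) {
    x <- out[[col]]
    if (!anyNA(x)) next
    pol <- policies$policy[policies$feature == col]
    stop_if_not(length(pol) == 1L,
                paste0("feature '", col, "' has missing entries but no ",
                       "declared fill policy"))
    obs <- x[!is.na(x)]
    stop_if_not(length(obs) > 0,
                paste0("feature '", col, "': undefined ", pol,
                       " (entire column missing)"))
    fill <- switch(pol, min = min(obs), max = max(obs), mean = mean(obs),
                   abort(paste0("unknown fill policy '", pol, "'")))
    x[is.na(x)] <- fill
    out[[col]] <- x
  }
  out
}

#' Bi-symmetric log transformation
#'
#' An odd, strictly increasing, smooth-through-zero transform defined for all
#' reals, `y = sign(x) * log10(1 + |x| / C)`, that compresses large
#' magnitudes logarithmically without exaggerating values between -1 and 1.
#' Used to tame skewed property distributions before PCA. The default scale
#' constant `C = 1 / ln(10)` makes the slope at the origin equal to 1.
#'
#' @param x Numeric vector.
#' @param C Positive scale constant.
#' @return Transformed vector of the same length.
#' @examples
#' bilog_transform(c(-1000, 0, 1000))
#' @export
bilog_transform <- function(x, C = 1 / log(10)) {
  stop_if_not(is_number(C) && C > 0, "C must be a positive number")
  sign(x) * log10(1 + abs(x) / C)
}

#' Z-score the columns of a feature matrix
#'
#' Each numeric column is centered and scaled to unit variance using the
#' population (1/n) standard deviation. Zero-variance columns are mapped to
#' zeros with a warning.
#'
#' @param matrix A complete (no `NA`) data frame; non-numeric columns pass
#'   through untouched.
#' @return The standardized tibble.
#' @export
standardize <- function(matrix) {
  stop_if_not(is.data.frame(matrix), "matrix must be a data frame")
  out <- as_tibble(matrix)
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  for (col in num_cols) {
    x <- out[[col]]
    stop_if_not(!anyNA(x), paste0("column '", col, "' contains missing values; ",
                                  "run fill_missing() first"))
    s <- sd_pop(x)
    if (is.na(s) || s == 0) {
      warn(paste0("zero-variance column '", col, "' mapped to 0"))
      out[[col]] <- rep(0, length(x))
    } else {
      out[[col]] <- (x - mean(x)) / s
    }
  }
  out
}

#' Prepare a raw feature matrix for clustering
#'
#' Applies, in order: missing-value filling, the bi-symmetric log transform
#' and column z-scoring. The order matters — fills must happen on the raw
#' scale, and z-scores must be computed on the transformed values.
#'
#' @inheritParams fill_missing
#' @inheritParams bilog_transform
#' @param id_cols Columns excluded from transformation (identifiers, flags).
#' @return Standardized tibble ready for [pca_reduce()].
#' @export
prepare_feature_matrix <- function(matrix, policies = default_fill_policies(),
                                   C = 1 / log(10),
                                   id_cols = c("model_id", "rheobase_na",
                                               "non_positive_rheobase")) {
  keep <- intersect(id_cols, names(matrix))
  feats <- setdiff(names(matrix), keep)
  filled <- fill_missing(matrix[feats], policies)
  transformed <- dplyr::mutate(filled, dplyr::across(
    dplyr::where(is.numeric), function(x) bilog_transform(x, C = C)))
  dplyr::bind_cols(matrix[keep], standardize(transformed))
}
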