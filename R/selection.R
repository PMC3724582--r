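# Mutual-information estimation and feature ranking.
#
# MI is estimated with an equal-width histogram: each variable is
# discretized into `bins` bins over its own range and
# MI(A;B) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) ) over non-empty cells,
# in bits. The normalized variant divides by sqrt(H(A) H(B)) so that a
# variable's MI with itself is 1; the raw variant feeds the mRMR criterion.

bin_indices <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  idx <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(idx, bins)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_from_indices <- function(ia, ib) {
  joint <- table(ia, ib) / length(ia)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  outer_p <- outer(pa, pb)
  mi <- sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
  list(mi = mi, ha = entropy_bits(pa), hb = entropy_bits(pb))
}

#' Histogram mutual information between two sample vectors
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @param bins Number of equal-width bins per variable (>= 2).
#' @param normalized If `TRUE`, divide by `sqrt(H(A) H(B))`; a variable then
#'   has MI 1 with itself. A constant vector (zero entropy) yields 1 for a
#'   self-pair and 0 otherwise, with a warning.
#' @return Mutual information in bits (or the unitless normalized value).
#' @export
#' @examples
#' x <- rep(c(0, 1), 50)
#' mutual_information(x, x)                     # 1 bit
#' mutual_information(x, x, normalized = TRUE)  # 1
mutual_information <- function(a, b, bins = 10, normalized = FALSE) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  stopifnot(length(a) >= 2, bins >= 2)
  res <- mi_from_indices(bin_indices(a, bins), bin_indices(b, bins))
  if (!normalized) return(res$mi)
  if (res$ha == 0 || res$hb == 0) {
    warning("zero-entropy (constant) input to normalized MI")
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  }
  res$mi / sqrt(res$ha * res$hb)
}

#' Mutual information between a feature and the class label
#'
#' The feature is histogram-discretized; the label is treated as a
#' categorical variable (no binning).
#'
#' @param x Numeric feature vector.
#' @param labels Class label per element of `x`.
#' @param bins Histogram bin count for `x`.
#' @return Raw MI in bits.
#' @export
class_mutual_information <- function(x, labels, bins = 10) {
  if (length(x) != length(labels)) stop("x and labels must have equal length")
  mi_from_indices(bin_indices(x, bins), as.integer(factor(labels)))$mi
}

# Flatten a feature set to one vector per feature: channels concatenated
# column-major, with the matching label vector.
flatten_feature <- function(fset) {
  list(values = as.vector(fset$matrix),
       labels = rep(fset$row_labels, times = ncol(fset$matrix)))
}

#' Pairwise feature MI matrix
#'
#' Per subject, each feature's channels are concatenated into one vector and
#' all pairwise MI values are computed; matrices are averaged across
#' subjects.
#'
#' @param single_sets Either a named list of `emg_feature_set` (one subject)
#'   or a list of such lists (one element per subject, identical feature
#'   names).
#' @param bins Histogram bin count.
#' @param normalized Use normalized MI (default; diagonal is 1).
#' @return An `emg_mi_matrix`: list with `values` (symmetric matrix),
#'   `normalized`, `bins`, `subjects_averaged`.
#' @export
mi_matrix <- function(single_sets, bins = 10, normalized = TRUE) {
  if (inherits(single_sets[[1]], "emg_feature_set")) {
    single_sets <- list(single_sets)
  }
  feats <- names(single_sets[[1]])
  if (length(feats) < 2) stop("need at least two feature sets")
  acc <- matrix(0, length(feats), length(feats),
                dimnames = list(feats, feats))
  for (subj_sets in single_sets) {
    vecs <- lapply(subj_sets[feats], function(s) flatten_feature(s)$values)
    n <- vapply(vecs, length, 1L)
    if (length(unique(n)) != 1) stop("feature sets have mismatched rows")
    m <- matrix(0, length(feats), length(feats))
    for (i in seq_along(feats)) {
      for (j in i:length(feats)) {
        m[i, j] <- m[j, i] <- mutual_information(vecs[[i]], vecs[[j]],
                                                 bins = bins,
                                                 normalized = normalized)
      }
    }
    acc <- acc + m
  }
  structure(list(values = acc / length(single_sets),
                 normalized = normalized, bins = bins,
                 subjects_averaged = length(single_sets)),
            class = "emg_mi_matrix")
}

#' Per-feature class relevance
#'
#' Raw MI between each feature (channels concatenated) and the gesture
#' label, averaged across subjects.
#'
#' @inheritParams mi_matrix
#' @return Named numeric vector of MI values in bits.
#' @export
class_relevance <- function(single_sets, bins = 10) {
  if (inherits(single_sets[[1]], "emg_feature_set")) {
    single_sets <- list(single_sets)
  }
  feats <- names(single_sets[[1]])
  acc <- stats::setNames(numeric(length(feats)), feats)
  for (subj_sets in single_sets) {
    for (f in feats) {
      fl <- flatten_feature(subj_sets[[f]])
      acc[f] <- acc[f] + class_mutual_information(fl$values, fl$labels, bins)
    }
  }
  acc / length(single_sets)
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy-maximum-relevance ordering: the first feature
#' maximizes relevance MI(f;C); each subsequent feature maximizes
#' `MI(f;C) - mean(MI(f;s), s in selected)`. For every prefix set A the
#' reported scores are the set-level relevance
#' `D = mean(MI(f;C), f in A)`, redundancy
#' `R = (1/|A|^2) sum_{f,g in A} MI(f;g)` (diagonal included), and `D - R`.
#' Ties break alphabetically.
#'
#' @param relevance Named vector of raw MI between each feature and the
#'   class.
#' @param redundancy Symmetric raw-MI matrix over the same features (an
#'   `emg_mi_matrix` or plain matrix).
#' @return An `emg_ranking`: list with `order`, `scores` (data frame with
#'   columns feature, D, R, criterion), `criterion = "MRMR"`.
#' @export
mrmr_rank <- function(relevance, redundancy) {
  if (inherits(redundancy, "emg_mi_matrix")) redundancy <- redundancy$values
  feats <- sort(names(relevance))
  if (length(feats) == 0) stop("empty candidate set")
  if (!all(feats %in% rownames(redundancy))) {
    stop("redundancy matrix does not cover all features")
  }
  selected <- character(0)
  remaining <- feats
  while (length(remaining) > 0) {
    gain <- vapply(remaining, function(f) {
      red <- if (length(selected) == 0) 0
             else mean(redundancy[f, selected])
      relevance[[f]] - red
    }, 1)
    pick <- remaining[which.max(gain)]  # remaining is alphabetical: ties resolve alphabetically
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  scores <- do.call(rbind, lapply(seq_along(selected), function(k) {
    s <- selected[seq_len(k)]
    D <- mean(relevance[s])
    R <- mean(redundancy[s, s, drop = FALSE])
    data.frame(feature = selected[k], D = D, R = R, criterion = D - R)
  }))
  structure(list(order = selected, scores = scores, criterion = "MRMR"),
            class = "emg_ranking")
}

#' Recognition-accuracy feature ranking
#'
#' Orders features by their individual mean test accuracy, descending; ties
#' break alphabetically.
#'
#' @param per_feature_accuracies Named vector of mean test accuracies (%).
#' @return An `emg_ranking` with `criterion = "RA"`.
#' @export
#' @examples
#' ra_rank(c(MPV = 87.1, MAV = 86.0))$order
ra_rank <- function(per_feature_accuracies) {
  if (length(per_feature_accuracies) == 0) stop("empty accuracy map")
  ord <- order(-per_feature_accuracies, names(per_feature_accuracies))
  selected <- names(per_feature_accuracies)[ord]
  structure(list(order = selected,
                 scores = data.frame(feature = selected,
                                     accuracy = unname(per_feature_accuracies[ord])),
                 criterion = "RA"),
            class = "emg_ranking")
}

#' @export
print.emg_ranking <- function(x, ...) {
  cat(sprintf("<emg_ranking> %s: %s\n", x$criterion,
              paste(x$order, collapse = " > ")))
  invisible(x)
}

#' @export
print.emg_mi_matrix <- function(x, ...) {
  cat(sprintf("<emg_mi_matrix> %s, %d bins, averaged over %d subject(s)\n",
              if (x$normalized) "normalized" else "raw (bits)",
              x$bins, x$subjects_averaged))
  print(round(x$values, 3))
  invisible(x)
}
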