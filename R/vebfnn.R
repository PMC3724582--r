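# Versatile elliptic basis function (VEBF) network.
#
# Hidden units are hyperellipsoids Omega_k = (C, S, N, A, d): center C,
# covariance S of the absorbed samples, sample count N, per-axis widths A
# and class label d. The ellipsoid axes are the eigenvectors of S, so a
# neuron rotates to cover nearby data without translating or growing. The
# activation
#   psi(x) = sum_i ((x - C)' u_i)^2 / a_i^2  -  1
# is <= 0 exactly when x lies inside the ellipsoid ("the neuron covers x").
# Training is one-pass: each sample updates the nearest same-class neuron's
# sufficient statistics recursively; the update is kept only if the updated
# neuron covers the sample, otherwise a fresh neuron is created at the
# sample. Samples are discarded after use.

#' VEBF training configuration
#'
#' @param initial_width Radius of the initial (spherical) width vector
#'   `A0`; 0.5 pairs with min-max normalized inputs in `[0, 1]`.
#' @param merge_enabled Merge close same-class neurons after each insertion.
#' @param merge_gamma Merge gate multiplier: two neurons are merged when
#'   their center distance is at most
#'   `merge_gamma * (mean(A_i) + mean(A_j))`.
#' @param seed Recorded for provenance; training itself is deterministic.
#' @return List of class `vebf_config`.
#' @export
vebf_config <- function(initial_width = 0.5, merge_enabled = TRUE,
                        merge_gamma = 1.0, seed = NULL) {
  stopifnot(initial_width > 0, merge_gamma >= 0)
  structure(list(initial_width = initial_width,
                 merge_enabled = isTRUE(merge_enabled),
                 merge_gamma = merge_gamma, seed = seed),
            class = "vebf_config")
}

#' Elliptic basis activation
#'
#' `psi(x) = sum_i ((x - C)' u_i)^2 / a_i^2 - 1`; `psi <= 0` means the
#' neuron covers `x`. At the center `psi = -1`; on the ellipsoid surface
#' `psi = 0`.
#'
#' @param x Input vector.
#' @param neuron A VEBF neuron (see [vebf_train()]).
#' @return Scalar activation.
#' @export
vebf_activation <- function(x, neuron) {
  if (length(x) != length(neuron$center)) stop("dimension mismatch")
  proj <- as.numeric(crossprod(neuron$basis, x - neuron$center))
  sum((proj / neuron$widths)^2) - 1
}

#' Recursive mean update
#'
#' `mu_new = n/(n+1) mu_old + x/(n+1)` — the batch mean of the n+1 samples
#' seen so far.
#'
#' @param mu_old Current mean of n samples.
#' @param n Samples absorbed so far (>= 1).
#' @param x_new New sample.
#' @return Updated mean vector.
#' @export
update_mean <- function(mu_old, n, x_new) {
  stopifnot(n >= 1)
  (n / (n + 1)) * mu_old + x_new / (n + 1)
}

#' Recursive covariance update
#'
#' `tau_new = n/(n+1) tau_old + theta` with
#' `theta = x x'/(n+1) - mu_new mu_new' + mu_old mu_old' - mu_old mu_old'/(n+1)`.
#' Equals the batch population covariance (1/m normalization) of all
#' `m = n + 1` samples seen.
#'
#' @param tau_old Current population covariance of n samples.
#' @param mu_old Mean before the update.
#' @param mu_new Mean after the update ([update_mean()]).
#' @param n Samples absorbed so far (>= 1).
#' @param x_new New sample.
#' @return Updated covariance matrix.
#' @export
update_covariance <- function(tau_old, mu_old, mu_new, n, x_new) {
  stopifnot(n >= 1)
  if (max(abs(tau_old - t(tau_old))) > 1e-8) {
    stop("tau_old is not symmetric")
  }
  theta <- tcrossprod(x_new) / (n + 1) - tcrossprod(mu_new) +
    tcrossprod(mu_old) - tcrossprod(mu_old) / (n + 1)
  (n / (n + 1)) * tau_old + theta
}

#' Orthonormal eigenbasis of a covariance matrix
#'
#' Eigenvalues sorted descending; each eigenvector's sign is fixed so its
#' largest-magnitude component is positive (deterministic orientation). A
#' zero matrix returns the standard basis.
#'
#' @param S Symmetric positive semi-definite matrix.
#' @return List with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
orthonormal_basis <- function(S) {
  if (any(!is.finite(S))) stop("non-finite entries in covariance")
  if (max(abs(S - t(S))) > 1e-8) stop("covariance is not symmetric")
  d <- nrow(S)
  if (all(S == 0)) {
    return(list(values = numeric(d), vectors = diag(d)))
  }
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- e$vectors
  for (j in seq_len(d)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) v[, j] <- -v[, j]
  }
  list(values = e$values, vectors = v)
}

new_neuron <- function(x, label, width, created) {
  d <- length(x)
  list(center = as.numeric(x), cov = matrix(0, d, d), n = 1L,
       widths = rep(width, d), class = label,
       basis = diag(d), eigenvalues = numeric(d),
       created = as.integer(created))
}

#' Merge two same-class neurons
#'
#' Pools the sufficient statistics: `N = N_i + N_j`, weighted mean center,
#' pooled population covariance of the union of absorbed samples. Widths
#' reset to the initial radius and the eigenbasis is recomputed.
#'
#' @param ni,nj Neurons of the same class and dimension.
#' @param initial_width Width radius assigned to the merged neuron.
#' @return The merged neuron (creation index = the smaller of the two).
#' @export
merge_neurons <- function(ni, nj, initial_width = 0.5) {
  if (!identical(ni$class, nj$class)) stop("cannot merge different classes")
  if (length(ni$center) != length(nj$center)) stop("dimension mismatch")
  n <- ni$n + nj$n
  mu <- (ni$n * ni$center + nj$n * nj$center) / n
  S <- (ni$n * (ni$cov + tcrossprod(ni$center)) +
        nj$n * (nj$cov + tcrossprod(nj$center))) / n - tcrossprod(mu)
  S <- (S + t(S)) / 2
  eb <- orthonormal_basis(S)
  list(center = mu, cov = S, n = n,
       widths = rep(initial_width, length(mu)), class = ni$class,
       basis = eb$vectors, eigenvalues = eb$values,
       created = min(ni$created, nj$created))
}

# Merge the neuron at position idx with eligible same-class neighbours,
# repeating until no pair qualifies. The merged neuron occupies the
# earlier-created slot so the list stays in creation order.
merge_pass <- function(neurons, idx, config) {
  repeat {
    cur <- neurons[[idx]]
    others <- setdiff(seq_along(neurons), idx)
    others <- others[vapply(neurons[others],
                            function(nb) identical(nb$class, cur$class),
                            TRUE)]
    if (length(others) == 0) break
    dists <- vapply(neurons[others],
                    function(nb) sqrt(sum((nb$center - cur$center)^2)), 1)
    gates <- vapply(neurons[others],
                    function(nb) config$merge_gamma *
                      (mean(cur$widths) + mean(nb$widths)), 1)
    ok <- dists <= gates
    if (!any(ok)) break
    j <- others[ok][which.min(dists[ok])]
    merged <- merge_neurons(neurons[[idx]], neurons[[j]],
                            config$initial_width)
    keep <- min(idx, j); drop <- max(idx, j)
    neurons[[keep]] <- merged
    neurons[[drop]] <- NULL
    idx <- keep
  }
  neurons
}

#' One-epoch VEBF training
#'
#' Consumes each (sample, label) pair exactly once, in order. A sample with
#' no same-class neuron creates one (center = sample, zero covariance,
#' spherical width `A0`). Otherwise the nearest same-class neuron (Euclidean
#' center distance) is tentatively updated — recursive mean/covariance,
#' eigenbasis refresh — and the update is committed only if the updated
#' neuron covers the sample (`psi <= 0`); if not, a fresh neuron is created.
#' Same-class neurons closer than the merge gate are pooled after each
#' insertion. The result is deterministic for a fixed input order.
#'
#' @param samples Numeric matrix, one sample per row.
#' @param labels Class label per row.
#' @param config A [vebf_config()].
#' @param on_consume Optional function called with the row index as each
#'   sample is absorbed (single-consumption instrumentation hook).
#' @return A `vebf_network`: list with `neurons` (creation order),
#'   `classes`, `dim`, `config`.
#' @export
#' @examples
#' net <- vebf_train(matrix(c(0, 0, 1, 1), 2, byrow = TRUE), c("a", "b"),
#'                   vebf_config())
#' length(net$neurons)
vebf_train <- function(samples, labels, config = vebf_config(),
                       on_consume = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(labels)) {
    stop("samples and labels must have equal length")
  }
  if (nrow(samples) == 0) stop("no training data")
  neurons <- list()
  n_created <- 0L
  for (j in seq_len(nrow(samples))) {
    x <- samples[j, ]
    t_j <- labels[j]
    same <- which(vapply(neurons, function(nb) identical(nb$class, t_j), TRUE))
    inserted <- FALSE
    if (length(same) == 0) {
      n_created <- n_created + 1L
      neurons[[length(neurons) + 1L]] <-
        new_neuron(x, t_j, config$initial_width, n_created)
      inserted <- TRUE
      idx <- length(neurons)
    } else {
      dists <- vapply(same, function(k) {
        sqrt(sum((neurons[[k]]$center - x)^2))
      }, 1)
      k <- same[which.min(dists)]
      nk <- neurons[[k]]
      mu_new <- update_mean(nk$center, nk$n, x)
      tau_new <- update_covariance(nk$cov, nk$center, mu_new, nk$n, x)
      tau_new <- (tau_new + t(tau_new)) / 2
      eb <- orthonormal_basis(tau_new)
      cand <- nk
      cand$center <- mu_new; cand$cov <- tau_new
      cand$basis <- eb$vectors; cand$eigenvalues <- eb$values
      if (vebf_activation(x, cand) <= 0) {
        cand$n <- nk$n + 1L
        neurons[[k]] <- cand
      } else {
        n_created <- n_created + 1L
        neurons[[length(neurons) + 1L]] <-
          new_neuron(x, t_j, config$initial_width, n_created)
        inserted <- TRUE
        idx <- length(neurons)
      }
    }
    if (inserted && config$merge_enabled) {
      neurons <- merge_pass(neurons, idx, config)
    }
    if (!is.null(on_consume)) on_consume(j)
  }
  structure(list(neurons = neurons,
                 classes = sort(unique(as.character(labels))),
                 dim = ncol(samples), config = config),
            class = "vebf_network")
}

#' Predict class labels
#'
#' Assigns each input the class of the neuron minimizing `psi(x)` (ties:
#' earliest-created neuron). `rule = "nearest_center"` uses plain Euclidean
#' center distance instead.
#'
#' @param object A `vebf_network`.
#' @param newdata Numeric matrix (rows = inputs) or a single vector.
#' @param rule Decision rule.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.vebf_network <- function(object, newdata,
                                 rule = c("min_psi", "nearest_center"), ...) {
  rule <- match.arg(rule)
  if (length(object$neurons) == 0) stop("empty network")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) stop("dimension mismatch")
  apply(newdata, 1, function(x) {
    score <- vapply(object$neurons, function(nb) {
      if (rule == "min_psi") vebf_activation(x, nb)
      else sqrt(sum((x - nb$center)^2))
    }, 1)
    as.character(object$neurons[[which.min(score)]]$class)
  })
}

#' @export
print.vebf_network <- function(x, ...) {
  per_class <- table(vapply(x$neurons, function(nb) as.character(nb$class), ""))
  cat(sprintf("<vebf_network> %d neurons over %d classes (input dim %d)\n",
              length(x$neurons), length(x$classes), x$dim))
  print(per_class)
  invisible(x)
}

#' Serialize a network to JSON
#'
#' Per neuron: center, covariance (row-major), count, widths, class and
#' creation index. Deterministic output for identical networks.
#'
#' @param network A `vebf_network`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
vebf_to_json <- function(network, path = NULL) {
  payload <- list(
    dim = network$dim,
    classes = network$classes,
    config = unclass(network$config),
    neurons = lapply(network$neurons, function(nb) {
      list(center = nb$center, cov = as.vector(t(nb$cov)), n = nb$n,
           widths = nb$widths, class = as.character(nb$class),
           created = nb$created)
    }))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Deserialize a network written by [vebf_to_json()]
#'
#' @param x JSON string or file path.
#' @return A `vebf_network` (eigenbases recomputed from the stored
#'   covariances).
#' @export
vebf_from_json <- function(x) {
  payload <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  d <- payload$dim
  neurons <- lapply(payload$neurons, function(nb) {
    S <- matrix(unlist(nb$cov), d, d, byrow = TRUE)
    eb <- orthonormal_basis(S)
    list(center = unlist(nb$center), cov = S, n = as.integer(nb$n),
         widths = unlist(nb$widths), class = nb$class,
         basis = eb$vectors, eigenvalues = eb$values,
         created = as.integer(nb$created))
  })
  cfg <- payload$config
  structure(list(neurons = neurons,
                 classes = unlist(payload$classes),
                 dim = d,
                 config = vebf_config(cfg$initial_width %||% 0.5,
                                      cfg$merge_enabled %||% TRUE,
                                      cfg$merge_gamma %||% 1.0,
                                      cfg$seed)),
            class = "vebf_network")
}
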