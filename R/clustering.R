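#' Label farms as High or Low antimicrobial users
#'
#' The observed and the model-predicted transformed TIDDDvet values are each
#' min-max normalised to \[0, 1\]; farms above 0.5 are "High" users, the
#' rest "Low". Labels are therefore invariant to affine rescaling of the
#' inputs. A constant vector cannot be normalised; all its farms are
#' labelled Low with a warning.
#'
#' @param y_real_t observed transformed TIDDDvet.
#' @param y_pred_t predicted transformed TIDDDvet.
#' @param farm_id optional farm identifiers.
#' @return `data.frame` with `farm_id`, `real_label`, `predicted_label`
#'   (factors with levels Low, High).
#' @export
label_users <- function(y_real_t, y_pred_t, farm_id = seq_along(y_real_t)) {
  if (!length(y_real_t)) stop("label_users: empty input")
  stopifnot(length(y_real_t) == length(y_pred_t))
  lab <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning("label_users: constant vector, normalisation degenerate; all labelled Low")
      z <- rep(0, length(v))
    } else {
      z <- (v - rng[1]) / (rng[2] - rng[1])
    }
    factor(ifelse(z > 0.5, "High", "Low"), levels = c("Low", "High"))
  }
  data.frame(farm_id = farm_id, real_label = lab(y_real_t),
             predicted_label = lab(y_pred_t), stringsAsFactors = FALSE)
}

#' Embed the proximity matrix by classical MDS
#'
#' Converts forest proximities P to dissimilarities D = 1 - P and projects
#' the farms onto the first `dims` principal coordinates (classical metric
#' multidimensional scaling). Identical farms (proximity 1) map to
#' coincident points. Dimensions beyond the available positive eigenvalues
#' are zero-padded.
#'
#' @param proximity symmetric proximity matrix with unit diagonal.
#' @param dims number of coordinates (default 3, as displayed in the usual
#'   3-D farm-similarity plot).
#' @return n x `dims` coordinate matrix.
#' @export
embed_proximity <- function(proximity, dims = 3) {
  P <- unclass(proximity)
  if (!is.matrix(P) || nrow(P) != ncol(P) || !isSymmetric(unname(P))) {
    stop("embed_proximity: proximity must be a symmetric square matrix")
  }
  D <- 1 - P
  coords <- stats::cmdscale(stats::as.dist(D), k = dims)
  if (ncol(coords) < dims) {   # degenerate spectra give fewer coordinates
    coords <- cbind(coords,
                    matrix(0, nrow(coords), dims - ncol(coords)))
  }
  coords
}

#' MDS stress of an embedding
#'
#' Kruskal-type raw stress: sqrt of the sum of squared differences between
#' embedded and target distances over the sum of squared target distances.
#' Used as a diagnostic that the chosen dimensionality preserves the
#' forest's dissimilarity structure.
#'
#' @param coords embedding coordinates.
#' @param D target dissimilarity matrix.
#' @return Non-negative stress value.
#' @export
mds_stress <- function(coords, D) {
  d_emb <- as.matrix(stats::dist(coords))
  D <- as.matrix(D)
  sqrt(sum((d_emb - D)^2) / sum(D^2))
}

# BIC of a k-means solution under a spherical equal-variance Gaussian
# mixture (the x-means formulation). Larger is better here; callers minimise
# -BIC or compare directly.
kmeans_bic <- function(km, coords) {
  n <- nrow(coords)
  d <- ncol(coords)
  k <- nrow(km$centers)
  wss <- km$tot.withinss
  sigma2 <- wss / (d * max(n - k, 1))
  sigma2 <- max(sigma2, 1e-12)
  nj <- km$size
  loglik <- sum(nj * log(nj / n)) -
    n * d / 2 * log(2 * pi * sigma2) -
    d * (n - k) / 2
  n_par <- (k - 1) + k * d + 1
  loglik - n_par / 2 * log(n)
}

#' Cluster farms on the MDS embedding
#'
#' Runs k-means (25 random restarts) for each candidate number of clusters
#' and selects k by the Bayesian information criterion computed under a
#' spherical equal-variance Gaussian formulation of the k-means objective.
#'
#' @param coords MDS coordinates from [embed_proximity()].
#' @param k_min,k_max candidate range for the number of clusters (defaults
#'   2 and 10).
#' @param seed integer seed (restarts are reproducible).
#' @param nstart random restarts per k (default 25).
#' @return An object of class `cluster_model`: `embedding`, selected `k`,
#'   `assignments`, `bic_by_k`, `wss_by_k` (total within-cluster sum of
#'   squares per candidate k) and the chosen `kmeans` fit.
#' @export
cluster_farms <- function(coords, k_min = 2, k_max = 10, seed = 1L,
                          nstart = 25) {
  n <- nrow(coords)
  if (n < k_max + 1) stop("cluster_farms: need at least k_max + 1 farms")
  ks <- seq.int(k_min, k_max)
  bic <- stats::setNames(rep(NA_real_, length(ks)), ks)
  wss <- stats::setNames(rep(NA_real_, length(ks)), ks)
  fits <- vector("list", length(ks))
  set.seed(seed)
  for (i in seq_along(ks)) {
    km <- stats::kmeans(coords, centers = ks[i], nstart = nstart,
                        iter.max = 50)
    fits[[i]] <- km
    bic[i] <- kmeans_bic(km, coords)
    wss[i] <- km$tot.withinss
  }
  best <- which.max(bic)
  structure(list(
    embedding = coords,
    k = ks[best],
    assignments = fits[[best]]$cluster,
    bic_by_k = bic,
    wss_by_k = wss,
    kmeans = fits[[best]]
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Farm proximity clustering\n")
  cat(sprintf("  k = %d clusters selected by BIC over k = %s..%s\n",
              x$k, names(x$bic_by_k)[1],
              names(x$bic_by_k)[length(x$bic_by_k)]))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Cluster-class prototypes
#'
#' For every (cluster, predicted user class) cell, the representative farm
#' profile: the median for numeric fields and the most frequent level (with
#' its frequency) for categorical/binary fields. A cell with no members
#' (e.g. a cluster containing only Low users) is marked not applicable.
#' Modal ties are broken toward level 1 ("measure applied") and flagged.
#'
#' @param farms farm table aligned with `assignments`.
#' @param assignments cluster id per farm.
#' @param labels labels from [label_users()] (the `predicted_label` column
#'   defines the classes).
#' @param fields columns of `farms` to summarise; defaults to the three
#'   size/productivity covariates plus all biosecurity measures.
#' @return `data.frame`, one row per cluster x class x field, with columns
#'   `cluster`, `class`, `n_members`, `field`, `prototype`, `frequency`
#'   (modal share for categorical fields, `NA` for medians) and `tie`.
#' @export
prototypes <- function(farms, assignments, labels,
                       fields = c("broilers_per_round", "rounds_per_year",
                                  "n_workers", feature_cols(farms))) {
  stopifnot(nrow(farms) == length(assignments),
            nrow(farms) == nrow(labels))
  numeric_fields <- c("broilers_per_round", "rounds_per_year", "n_workers")
  out <- list()
  for (cl in sort(unique(assignments))) {
    for (class in c("Low", "High")) {
      members <- which(assignments == cl & labels$predicted_label == class)
      if (!length(members)) {
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, class = class, n_members = 0L, field = NA_character_,
          prototype = NA_real_, frequency = NA_real_, tie = NA,
          stringsAsFactors = FALSE)
        next
      }
      for (f in fields) {
        v <- farms[[f]][members]
        if (f %in% numeric_fields) {
          proto <- stats::median(v, na.rm = TRUE)
          freq <- NA_real_
          tie <- FALSE
        } else {
          tab <- table(factor(v[!is.na(v)]))
          if (!length(tab)) next
          top <- which(tab == max(tab))
          tie <- length(top) > 1L
          lev <- if (tie && "1" %in% names(tab)[top]) "1" else
            names(tab)[top[1L]]
          proto <- suppressWarnings(as.numeric(lev))
          freq <- as.numeric(tab[lev] / sum(tab))
        }
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, class = class, n_members = length(members),
          field = f, prototype = proto, frequency = freq, tie = tie,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
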