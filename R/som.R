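#' Train a self-organizing map
#'
#' Classic online Kohonen training on a rectangular grid: for each
#' presented sample the best-matching unit (BMU, smallest Euclidean
#' distance) and its Gaussian neighbourhood move toward the sample.
#' Training runs in two phases: an ordering phase in which the
#' neighbourhood radius shrinks from half the grid diagonal to 1 and the
#' learning rate from `lr[1]` to `lr[2]`, then a fine-tuning phase at
#' radius 1 with the learning rate decaying to `lr[3]`.  The codebook is
#' initialised from randomly sampled data points (slightly jittered),
#' which keeps every unit inside the data cloud; the whole procedure is
#' deterministic given `seed`.
#'
#' @param x Numeric matrix, samples x features (standardise features
#'   first; see [som_features()]).  No missing values.
#' @param grid `c(nx, ny)` rectangular grid dimensions.
#' @param epochs Total passes through the data (split evenly between the
#'   two phases).
#' @param lr Learning-rate schedule `c(start, mid, end)`.
#' @param seed Integer seed.
#'
#' @return An object of class `som_fit`: list with `codebook` (units x
#'   features), `grid_coords` (units x 2), `grid`, `assignments` (BMU
#'   index per sample) and `quant_error` (mean distance to BMU).
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' fit <- som_train(x, grid = c(4, 3), epochs = 50, seed = 1)
#' table(fit$assignments)
#' @export
som_train <- function(x, grid = c(8, 6), epochs = 1000,
                      lr = c(0.5, 0.05, 0.01), seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two samples", call. = FALSE)
  if (anyNA(x)) stop("features must not contain missing values",
                     call. = FALSE)
  n_units <- prod(grid)
  coords <- as.matrix(expand.grid(gx = seq_len(grid[1]),
                                  gy = seq_len(grid[2])))
  # squared grid distances between all unit pairs, fixed for the run
  gd2 <- as.matrix(stats::dist(coords))^2
  r0 <- sqrt(sum((grid - 1)^2)) / 2
  n_feat <- ncol(x)
  half <- floor(epochs / 2)
  with_seed(seed, {
    jitter_sd <- 0.05 * mean(apply(x, 2, stats::sd))
    codebook <- x[sample.int(nrow(x), n_units, replace = TRUE), ,
                  drop = FALSE] +
      matrix(stats::rnorm(n_units * n_feat, 0, jitter_sd), n_units, n_feat)
    for (e in seq_len(epochs)) {
      if (e <= half) {
        frac <- (e - 1) / max(half - 1, 1)
        radius <- r0 + (1 - r0) * frac
        alpha <- lr[1] + (lr[2] - lr[1]) * frac
      } else {
        frac <- (e - half - 1) / max(epochs - half - 1, 1)
        radius <- 1
        alpha <- lr[2] + (lr[3] - lr[2]) * frac
      }
      for (i in sample.int(nrow(x))) {
        xi <- x[i, ]
        d2 <- rowSums((codebook - rep(xi, each = n_units))^2)
        bmu <- which.min(d2)
        h <- alpha * exp(-gd2[, bmu] / (2 * radius^2))
        active <- h > 1e-4
        codebook[active, ] <- codebook[active, ] +
          h[active] * (rep(xi, each = sum(active)) - codebook[active, ])
      }
    }
    assignments <- som_assign(codebook, x)
    qe <- mean(sqrt(rowSums((x - codebook[assignments, , drop = FALSE])^2)))
    structure(list(codebook = codebook, grid_coords = coords, grid = grid,
                   assignments = assignments, quant_error = qe),
              class = "som_fit")
  })
}

# Best-matching unit per sample by Euclidean distance.
som_assign <- function(codebook, x) {
  cs <- rowSums(codebook^2)
  d2 <- matrix(cs, nrow(x), nrow(codebook), byrow = TRUE) -
    2 * x %*% t(codebook)
  max.col(-d2, ties.method = "first")
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %dx%d grid, %d features, quantisation error %.4f\n",
              x$grid[1], x$grid[2], ncol(x$codebook), x$quant_error))
  invisible(x)
}

#' Z-scored hourly feature matrix for SOM training
#'
#' Each hourly timepoint is one sample; the features are the five
#' metabolic parameters, z-scored per parameter across the series.
#'
#' @param profile Output of [metabolic_profile()].
#' @return List with `x` (samples x 5 matrix), `phase` (factor) and
#'   `time_h`.
#' @export
som_features <- function(profile) {
  params <- c("OR", "CR", "AE", "RQ", "AQ")
  x <- scale(as.matrix(profile[params]))
  keep <- stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE], phase = profile$phase[keep],
       time_h = profile$time_h[keep])
}

#' Ward clustering of SOM codebook vectors
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`stats::hclust`, method `"ward.D2"`) applied to the codebook, the
#' standard practice for summarising ecological SOMs.
#'
#' @param codebook Units x features matrix (or a `som_fit`).
#' @param k Number of clusters.
#' @return Integer cluster label per unit.
#' @export
ward_clusters <- function(codebook, k = 6) {
  if (inherits(codebook, "som_fit")) codebook <- codebook$codebook
  if (k > nrow(codebook)) stop("k exceeds the number of units",
                               call. = FALSE)
  hc <- stats::hclust(stats::dist(codebook), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Phase association of SOM/Ward clusters
#'
#' Crosses sample cluster membership (via each sample's BMU) with the
#' photoperiod phase flags.  Each cluster is tagged with its majority
#' phase and purity (majority fraction).  Cluster IDs are relabelled by
#' descending scotophase fraction, so cluster 1 is the most nocturnal.
#'
#' @param assignments BMU index per sample (from a `som_fit`).
#' @param unit_clusters Cluster label per unit (from [ward_clusters()]).
#' @param phases Phase factor per sample.
#'
#' @return List with `table` (cluster x phase contingency), `majority`
#'   (factor per cluster), `purity` (numeric per cluster),
#'   `sample_cluster` (relabelled cluster per sample) and `unit_cluster`
#'   (relabelled cluster per unit).
#' @export
cluster_phase_association <- function(assignments, unit_clusters, phases) {
  stopifnot(length(assignments) == length(phases))
  sample_cluster <- unit_clusters[assignments]
  k <- max(unit_clusters)
  tab <- table(cluster = factor(sample_cluster, levels = seq_len(k)),
               phase = phases)
  if (any(rowSums(tab) == 0)) {
    stop("every cluster must contain at least one sample", call. = FALSE)
  }
  scoto_frac <- tab[, "scotophase"] / rowSums(tab)
  relabel <- order(scoto_frac, decreasing = TRUE)
  new_id <- match(seq_len(k), relabel)
  tab <- tab[relabel, , drop = FALSE]
  rownames(tab) <- seq_len(k)
  purity <- apply(tab, 1, max) / rowSums(tab)
  majority <- factor(colnames(tab)[apply(tab, 1, which.max)],
                     levels = levels(phases))
  list(table = tab, majority = majority, purity = as.numeric(purity),
       sample_cluster = new_id[sample_cluster],
       unit_cluster = new_id[unit_clusters])
}

#' End-to-end SOM phase analysis of a dataset
#'
#' Convenience wrapper: hourly feature matrix, SOM training, Ward
#' clustering of the codebook and phase association.  Ward clustering is
#' run on the codebook vectors of *used* units (those that are the BMU
#' of at least one sample), so every cluster is guaranteed to contain
#' samples; dead units -- topological bridges between data clouds that
#' attract no samples -- inherit the cluster of their nearest used unit.
#'
#' @param rs A `rate_series`.
#' @param grid,epochs,seed Passed to [som_train()].
#' @param k Number of Ward clusters.
#' @return List with `fit`, `clusters` ([cluster_phase_association()]
#'   output) and `features`.
#' @export
som_phase_analysis <- function(rs, grid = c(8, 6), epochs = 1000, k = 6,
                               seed = 1) {
  feats <- som_features(metabolic_profile(rs))
  fit <- som_train(feats$x, grid = grid, epochs = epochs, seed = seed)
  used <- sort(unique(fit$assignments))
  cl_used <- ward_clusters(fit$codebook[used, , drop = FALSE], k = k)
  cl <- integer(nrow(fit$codebook))
  cl[used] <- cl_used
  dead <- setdiff(seq_len(nrow(fit$codebook)), used)
  if (length(dead)) {
    nearest <- som_assign(fit$codebook[used, , drop = FALSE],
                          fit$codebook[dead, , drop = FALSE])
    cl[dead] <- cl_used[nearest]
  }
  assoc <- cluster_phase_association(fit$assignments, cl, feats$phase)
  list(fit = fit, clusters = assoc, features = feats)
}
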