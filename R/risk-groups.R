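## Risk grouping: spectral clustering of post-EPP risk-score trajectories,
## bootstrap Jaccard stability, KNN label transfer to test encounters, and
## per-group PPV/EWT reporting.

TRAJECTORY_POINTS <- 73L  # 0 to 6 h inclusive at 5-minute steps

#' Extract post-EPP risk trajectories
#'
#' For every positive-predicted encounter, the risk scores on the 5-minute
#' grid over \[EPP, EPP + 6 h\] (73 points). Encounters whose series ends
#' (preparation or discharge) before the 6-hour horizon are excluded from
#' the clustering matrix but returned separately with their available prefix
#' padded by the last value, so they can still receive a transferred label.
#'
#' @param series risk-score series (data.table `encounter_id`, `time`,
#'   `score`) covering the scored span.
#' @param epps named vector of EPP times (minutes) for positive-predicted
#'   encounters (`NA` entries are dropped).
#' @return list: `trajectories` (matrix, rownames = encounter ids),
#'   `padded` (matrix of short trajectories padded to 73 points),
#'   `excluded` (data.table of encounter_id, available_minutes).
#' @export
extract_trajectories <- function(series, epps) {
  epps <- epps[!is.na(epps)]
  if (!length(epps)) stop("no positive predictions: no trajectories to extract")
  full <- list(); padded <- list(); excl <- list()
  for (e in names(epps)) {
    s <- series[encounter_id == e][order(time)]
    t0 <- epps[[e]]
    want <- t0 + seq(0L, by = 5L, length.out = TRAJECTORY_POINTS)
    idx <- match(want, s$time)
    avail <- sum(!is.na(idx))
    v <- s$score[idx]
    if (avail == TRAJECTORY_POINTS) {
      full[[e]] <- v
    } else {
      v[is.na(v)] <- v[avail]  # pad by last available value
      padded[[e]] <- v
      excl[[e]] <- data.table::data.table(encounter_id = e,
                                          available_minutes = (avail - 1L) * 5L)
    }
  }
  list(trajectories = do.call(rbind, full),
       padded = do.call(rbind, padded),
       excluded = if (length(excl)) data.table::rbindlist(excl)
                  else data.table::data.table(encounter_id = character(),
                                              available_minutes = integer()))
}

## symmetric KNN adjacency: edge iff either point is in the other's
## K-neighborhood (Euclidean distance). Edges are weighted by a
## locally-scaled Gaussian kernel w_ij = exp(-d_ij^2 / (sigma_i sigma_j)),
## sigma_i = distance to the 7th neighbor, so that the clustering is
## insensitive to K exceeding the natural cluster size; `weighted = FALSE`
## gives the plain 0/1 graph.
knn_adjacency <- function(x, K, weighted = TRUE) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  A <- matrix(0, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    A[i, ord[2:(K + 1L)]] <- 1
    sigma[i] <- d[i, ord[min(8L, n)]]
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  if (weighted) {
    sigma <- pmax(sigma, 1e-8)
    A <- A * exp(-d^2 / outer(sigma, sigma))
  }
  A
}

graph_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n); c <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    c <- c + 1L
    frontier <- s
    comp[s] <- c
    while (length(frontier)) {
      nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- c
      frontier <- nb
    }
  }
  comp
}

#' Spectral clustering of risk trajectories
#'
#' Normalized spectral clustering on a symmetric K-nearest-neighbor
#' adjacency graph: eigenvectors of the symmetric normalized Laplacian,
#' number of clusters chosen by the maximum eigengap over `2..k_max`
#' (unless `k` is given), rows of the row-normalized embedding clustered by
#' seeded k-means.
#'
#' @param trajectories numeric matrix (rows = trajectories).
#' @param K neighborhood size (default 200, silently capped at n - 1).
#' @param k number of clusters; `NULL` = eigengap selection.
#' @param k_max upper bound of the eigengap search.
#' @param seed integer seed for k-means.
#' @param weighted use locally-scaled Gaussian edge weights on the KNN graph
#'   (default) rather than the plain 0/1 adjacency.
#' @return list: `labels`, `k`, `K_used`, `eigenvalues`.
#' @export
spectral_cluster <- function(trajectories, K = 200L, k = NULL, k_max = 8L,
                             seed = 1L, weighted = TRUE) {
  n <- nrow(trajectories)
  if (is.null(n) || n < 3L) stop("need at least 3 trajectories")
  if (all(stats::dist(trajectories) < 1e-12)) {
    warning("all trajectories identical; returning a single cluster")
    return(list(labels = rep(1L, n), k = 1L, K_used = NA_integer_,
                eigenvalues = numeric(0)))
  }
  K_used <- as.integer(min(K, n - 1L))
  if (K_used < K) message(sprintf("K capped at n - 1 = %d", K_used))
  A <- knn_adjacency(trajectories, K_used, weighted = weighted)
  k_max <- min(k_max, n - 1L)
  comp <- graph_components(A)
  if (max(comp) > k_max)
    stop(sprintf(paste0("KNN graph has %d connected components (> k_max = %d); ",
                        "increase K"), max(comp), k_max))
  deg <- rowSums(A)
  dinv <- 1 / sqrt(pmax(deg, 1e-12))
  L <- diag(n) - (dinv * A) %*% diag(dinv)  # symmetric normalized Laplacian
  L <- (L + t(L)) / 2
  ev <- eigen(L, symmetric = TRUE)
  lambda <- rev(ev$values)  # ascending
  if (is.null(k)) {
    gaps <- lambda[3:(k_max + 1L)] - lambda[2:k_max]  # gap after k = 2..k_max
    k <- which.max(gaps) + 1L
  }
  U <- ev$vectors[, n:(n - k + 1L), drop = FALSE]  # k smallest
  rn <- sqrt(rowSums(U^2)); rn[rn < 1e-12] <- 1
  U <- U / rn
  labels <- with_seed(seed, embed_kmeans(U, k))
  list(labels = labels, k = k, K_used = K_used, eigenvalues = lambda)
}

## k-means on the spectral embedding, robust to (near-)duplicate rows: fall
## back to kmeans++ seeding with Lloyd iterations when Hartigan-Wong aborts
## on empty clusters, and to exact row matching when there are fewer
## distinct rows than centers
embed_kmeans <- function(U, k) {
  uu <- unique(round(U, 10))
  if (nrow(uu) <= k)
    return(match(data.frame(t(round(U, 10))), data.frame(t(uu))))
  km <- tryCatch(
    suppressWarnings(stats::kmeans(U, centers = k, nstart = 10, iter.max = 100)),
    error = function(e) NULL)
  if (is.null(km)) {
    centers <- U[kmeanspp_idx(U, k), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(U, centers = centers, iter.max = 200,
                                         algorithm = "Lloyd"))
  }
  km$cluster
}

kmeanspp_idx <- function(U, k) {
  n <- nrow(U)
  idx <- sample.int(n, 1L)
  d2 <- rowSums((U - matrix(U[idx, ], n, ncol(U), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    nxt <- sample.int(n, 1L, prob = p)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums((U - matrix(U[nxt, ], n, ncol(U), byrow = TRUE))^2))
  }
  idx
}

jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Bootstrap cluster-stability assessment (max-Jaccard)
#'
#' Repeatedly subsamples the trajectories without replacement, reclusters
#' each subsample (same K, cluster count fixed at the reference k), and for
#' each reference cluster records the maximum Jaccard index between its
#' membership (restricted to the subsample) and any subsample cluster. The
#' per-cluster stability is the mean of these maxima over subsamples.
#'
#' @param trajectories numeric matrix.
#' @param n_boot number of subsamples (default 50).
#' @param subsample_fraction fraction kept per draw, without replacement.
#' @param K,k_max,seed as in [spectral_cluster()].
#' @param reference optional precomputed reference clustering.
#' @return list: `per_cluster` (mean max-Jaccard per reference cluster),
#'   `mean` (their mean), `reference` (the reference clustering).
#' @export
stability_jaccard <- function(trajectories, n_boot = 50L,
                              subsample_fraction = 0.8, K = 200L, k_max = 8L,
                              seed = 1L, reference = NULL) {
  check_fraction(subsample_fraction, "subsample_fraction")
  if (is.null(reference))
    reference <- spectral_cluster(trajectories, K = K, k_max = k_max, seed = seed)
  n <- nrow(trajectories)
  k <- reference$k
  jac <- matrix(NA_real_, n_boot, k)
  with_seed(derive_seed(seed, "boot"), {
    for (b in seq_len(n_boot)) {
      keep <- sort(sample.int(n, floor(subsample_fraction * n)))
      if (length(keep) < k) { message("subsample smaller than k; skipped"); next }
      sub <- try(spectral_cluster(trajectories[keep, , drop = FALSE], K = K,
                                  k = k, k_max = k_max, seed = seed + b),
                 silent = TRUE)
      if (inherits(sub, "try-error")) next
      for (r in seq_len(k)) {
        ref_members <- intersect(which(reference$labels == r), keep)
        if (!length(ref_members)) next  # cluster absent from this draw
        jac[b, r] <- max(vapply(seq_len(max(sub$labels)), function(cl)
          jaccard_index(ref_members, keep[sub$labels == cl]), 0))
      }
    }
  })
  per_cluster <- colMeans(jac, na.rm = TRUE)
  list(per_cluster = per_cluster, mean = mean(per_cluster),
       reference = reference)
}

#' Order clusters into named risk groups
#'
#' Groups are ordered by their average risk score, ascending: low < medium <
#' high for k = 3, generic ordered names otherwise. The ordering statistic
#' is the mean over the full post-EPP window (`stat = "window"`, default):
#' at the EPP itself every trajectory sits just above the alert threshold by
#' construction of the first crossing, so when the threshold is high the
#' at-EPP means of all clusters coincide and cannot order them; the window
#' mean coincides with the at-EPP ordering whenever the at-EPP means do
#' separate. `stat = "epp"` selects the at-EPP mean.
#'
#' @param trajectories clustering matrix.
#' @param labels cluster labels from [spectral_cluster()].
#' @param stat ordering statistic: mean over the window or mean at EPP.
#' @return list: `order` (old label -> rank), `names` (rank -> group name),
#'   `group` (per-row ordered group index), `mean_risk` (ordering statistic
#'   by rank), `mean_at_epp` (at-EPP mean by rank).
#' @export
order_risk_groups <- function(trajectories, labels, stat = c("window", "epp")) {
  stat <- match.arg(stat)
  k <- max(labels)
  m_epp <- vapply(seq_len(k), function(cl) mean(trajectories[labels == cl, 1]), 0)
  m_win <- vapply(seq_len(k), function(cl) mean(trajectories[labels == cl, ]), 0)
  m <- if (stat == "window") m_win else m_epp
  rank_of <- match(seq_len(k), order(m))  # old label -> ascending rank
  nm <- if (k == 3L) c("low", "medium", "high")
        else paste0("group", seq_len(k))
  list(order = rank_of, names = nm, group = rank_of[labels],
       mean_risk = m[order(m)], mean_at_epp = m_epp[order(m)])
}

#' Fit a risk-group model
#'
#' Clusters training trajectories, orders the clusters by mean risk at EPP,
#' and stores what is needed to transfer labels to new encounters.
#'
#' @param trajectories training trajectory matrix.
#' @param K,k_max,seed passed to [spectral_cluster()].
#' @param k_nn neighbors for test-label transfer.
#' @return object of class `risk_group_model`.
#' @export
fit_risk_groups <- function(trajectories, K = 200L, k_max = 8L, seed = 1L,
                            k_nn = 15L) {
  cl <- spectral_cluster(trajectories, K = K, k_max = k_max, seed = seed)
  ord <- order_risk_groups(trajectories, cl$labels)
  structure(list(trajectories = trajectories, labels = ord$group,
                 k = cl$k, K_used = cl$K_used, k_nn = k_nn,
                 group_names = ord$names, mean_risk = ord$mean_risk,
                 mean_at_epp = ord$mean_at_epp,
                 eigenvalues = cl$eigenvalues),
            class = "risk_group_model")
}

#' @export
print.risk_group_model <- function(x, ...) {
  cat(sprintf("Risk-group model: k = %d groups over %d trajectories (K = %d)\n",
              x$k, nrow(x$trajectories), x$K_used))
  for (g in seq_len(x$k))
    cat(sprintf("  %s: n = %d, mean risk = %.3f\n", x$group_names[g],
                sum(x$labels == g), x$mean_risk[g]))
  invisible(x)
}

#' Transfer risk-group labels by K-nearest neighbors
#'
#' Majority vote among the `k_nn` nearest training trajectories (Euclidean
#' distance); ties break toward the higher-risk group.
#'
#' @param model a [fit_risk_groups()] model.
#' @param test_trajectories matrix of test trajectories (73 points each).
#' @param k_nn neighbors (defaults to the model's setting).
#' @return integer vector of ordered group indices (named by rownames).
#' @export
transfer_labels <- function(model, test_trajectories, k_nn = model$k_nn) {
  if (is.null(test_trajectories) || !nrow(test_trajectories))
    return(setNames(integer(0), character(0)))
  tr <- model$trajectories
  k_nn <- min(k_nn, nrow(tr))
  d2 <- outer(rowSums(test_trajectories^2), rep(1, nrow(tr))) -
    2 * test_trajectories %*% t(tr) +
    outer(rep(1, nrow(test_trajectories)), rowSums(tr^2))
  out <- apply(d2, 1, function(row) {
    nb <- model$labels[order(row)[seq_len(k_nn)]]
    tab <- tabulate(nb, nbins = model$k)
    max(which(tab == max(tab)))  # tie -> higher-risk group
  })
  setNames(as.integer(out), rownames(test_trajectories))
}

#' Per-group positive-prediction metrics
#'
#' For each risk group among positive-predicted encounters: the number of
#' positive predictions, PPV (fraction that truly received MV), and the EWT
#' median \[IQR\] over the group's true positives. Groups partition the
#' positive predictions.
#'
#' @param groups ordered group index per positive-predicted encounter.
#' @param outcomes MV outcome per encounter (logical).
#' @param ewt EWT in hours per encounter (`NA` for false positives).
#' @param group_names names by ordered index.
#' @return data.table with one row per group.
#' @export
group_metrics <- function(groups, outcomes, ewt,
                          group_names = c("low", "medium", "high")) {
  k <- length(group_names)
  rows <- lapply(seq_len(k), function(g) {
    in_g <- groups == g
    n <- sum(in_g)
    tp_ewt <- ewt[in_g & outcomes]
    tp_ewt <- tp_ewt[!is.na(tp_ewt)]
    mi <- median_iqr(tp_ewt)
    data.table::data.table(group = group_names[g], n_positive_predictions = n,
                           ppv = if (n > 0) mean(outcomes[in_g]) else NA_real_,
                           ewt_median = mi["median"], ewt_q1 = mi["q1"],
                           ewt_q3 = mi["q3"])
  })
  data.table::rbindlist(rows)
}
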