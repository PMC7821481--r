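#' Cluster samples
#'
#' Adds a categorical `cluster` column per sample.
#'
#' * **kmeans** — native k-means++ seeding followed by Lloyd iterations to
#'   convergence, 10 random restarts, best within-cluster sum of squares
#'   kept; runs on the reduced dimensions (`Dim*` columns) when present,
#'   otherwise on the log-CPM expression matrix.
#' * **SNN** — shared-nearest-neighbour graph on the embedding (computing a
#'   PCA if no `Dim*` columns are present): k-nearest-neighbour sets
#'   (Euclidean, self included), edge weight = Jaccard overlap of the
#'   neighbour sets, edges below `prune` removed, then native Louvain
#'   modularity optimization at the given `resolution` with a seeded node
#'   order.
#'
#' Labels are contiguous integers from 1 in order of first appearance.
#'
#' @param x A `tidy_expression_table`.
#' @param method `"kmeans"` or `"SNN"`.
#' @param centers Number of clusters k (kmeans).
#' @param knn Neighbourhood size for the SNN graph (default 20, capped at
#'   n - 1).
#' @param resolution Louvain resolution parameter (default 0.8).
#' @param prune Jaccard weight below which SNN edges are removed
#'   (default 1/15).
#' @param seed Integer seed (restarts and node order).
#' @param action Action mode (element role: sample).
#' @param ... Unused; reserved for backend options.
#' @export
cluster_elements <- function(x, method = c("kmeans", "SNN"), centers = NULL,
                             knn = 20, resolution = 0.8, prune = 1 / 15,
                             seed = NULL, action = "add", ...) {
  stopifnot(is_tidy_expression_table(x))
  method <- match.arg(method)
  keys <- te_keys(x)
  emb <- sample_embedding(x, need_dims = (method == "SNN"))
  n <- nrow(emb)
  if (method == "kmeans") {
    if (is.null(centers)) stop("usage error: centers (k) is required",
                               call. = FALSE)
    if (centers > n) stop("usage error: k exceeds the number of samples",
                          call. = FALSE)
    labels <- kmeans_pp(emb, centers, nstart = 10, seed = seed)$cluster
  } else {
    labels <- snn_louvain(emb, knn = min(knn, n - 1), resolution = resolution,
                          prune = prune, seed = seed)
  }
  labels <- as.integer(factor(labels, levels = unique(labels)))
  new_cols <- tibble::tibble(!!keys$sample := rownames(emb),
                             cluster = factor(labels))
  out <- apply_action(x, new_cols, "sample", "add")
  out <- log_method(out, if (method == "kmeans") "kmeans" else "snn")
  if (action == "add") out else apply_action(x, new_cols, "sample", action)
}

# samples x dims matrix: existing Dim* columns, else expression (log-CPM),
# optionally forcing a PCA embedding
sample_embedding <- function(x, need_dims = FALSE) {
  keys <- te_keys(x)
  sframe <- element_frame(x, "sample")
  dim_cols <- grep("^Dim[0-9]+$", names(sframe), value = TRUE)
  if (length(dim_cols) > 0) {
    emb <- as.matrix(sframe[, dim_cols, drop = FALSE])
    rownames(emb) <- as.character(sframe[[keys$sample]])
    return(emb)
  }
  if (need_dims) {
    n <- dplyr::n_distinct(x[[keys$sample]])
    x <- reduce_dimensions(x, "PCA", n_dims = min(10, n - 1))
    return(sample_embedding(x))
  }
  m <- te_assay(x)
  m[is.na(m)] <- 0
  t(log_cpm(m))
}

#' Native k-means with k-means++ seeding
#'
#' Lloyd iterations from k-means++ initial centers; `nstart` seeded restarts,
#' solution with the smallest total within-cluster sum of squares returned.
#'
#' @param x Numeric matrix (observations in rows).
#' @param k Number of clusters.
#' @param nstart Number of restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 100).
#' @param seed Integer seed.
#' @return List with `cluster`, `centers`, `tot_withinss`.
#' @export
kmeans_pp <- function(x, k, nstart = 10, max_iter = 100, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- kmeans_once(x, k, max_iter)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  best
}

kmeans_once <- function(x, k, max_iter) {
  n <- nrow(x)
  # k-means++ seeding
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  assign <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d <- point_center_dist2(x, centers)
    new_assign <- max.col(-d, ties.method = "first")
    if (all(new_assign == assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      idx <- assign == j
      if (any(idx)) {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      } else {  # empty cluster: reseed at the farthest point
        d_min <- apply(point_center_dist2(x, centers), 1, min)
        centers[j, ] <- x[which.max(d_min), ]
      }
    }
  }
  d <- point_center_dist2(x, centers)
  assign <- max.col(-d, ties.method = "first")
  tot <- sum(d[cbind(seq_len(n), assign)])
  list(cluster = assign, centers = centers, tot_withinss = tot)
}

point_center_dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

#' Shared-nearest-neighbour graph + Louvain clustering
#'
#' Builds the kNN graph (Euclidean, each point's neighbour set includes
#' itself), weights edges by the Jaccard overlap of neighbour sets, prunes
#' weights below `prune`, and optimizes modularity (with a resolution
#' parameter) by a native Louvain algorithm with a seeded node order.
#'
#' @param emb Numeric matrix (observations in rows).
#' @param knn Neighbourhood size.
#' @param resolution Modularity resolution.
#' @param prune Jaccard pruning threshold.
#' @param seed Integer seed.
#' @return Integer cluster labels.
#' @export
snn_louvain <- function(emb, knn = 20, resolution = 0.8, prune = 1 / 15,
                        seed = NULL) {
  w <- snn_graph(emb, knn, prune)
  louvain_communities(w, resolution = resolution, seed = seed)
}

#' @rdname snn_louvain
#' @export
snn_graph <- function(emb, knn = 20, prune = 1 / 15) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  knn <- min(knn, n - 1)
  d <- as.matrix(stats::dist(emb))
  # neighbour set = self + knn nearest others (ties by index for determinism)
  nbr <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, -i], seq_len(n)[-i])[seq_len(knn)]
    c(i, (seq_len(n)[-i])[ord])
  })
  w <- matrix(0, n, n, dimnames = list(rownames(emb), rownames(emb)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(nbr[[i]], nbr[[j]]))
      if (inter > 0) {
        jac <- inter / length(union(nbr[[i]], nbr[[j]]))
        if (jac >= prune) w[i, j] <- w[j, i] <- jac
      }
    }
  }
  w
}

#' Louvain community detection on a weighted adjacency matrix
#'
#' Two-phase modularity optimization: local moving of nodes in a seeded
#' random order, then aggregation of communities into super-nodes, repeated
#' until modularity stops improving. The resolution parameter scales the
#' null-model term.
#'
#' @param w Symmetric non-negative weight matrix, zero diagonal.
#' @param resolution Resolution parameter (default 1).
#' @param seed Integer seed for the node order.
#' @return Integer community labels, contiguous from 1.
#' @export
louvain_communities <- function(w, resolution = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- nrow(w)
  membership <- seq_len(n0)        # community of each original node
  w_cur <- w
  node_of <- seq_len(n0)           # super-node of each original node
  repeat {
    res <- louvain_one_level(w_cur, resolution)
    if (!res$improved) break
    membership <- res$community[node_of]
    node_of <- res$community[node_of]
    # aggregate
    comm <- res$community
    k <- max(comm)
    agg <- matrix(0, k, k)
    for (i in seq_len(nrow(w_cur))) {
      for (j in seq_len(nrow(w_cur))) {
        agg[comm[i], comm[j]] <- agg[comm[i], comm[j]] + w_cur[i, j]
      }
    }
    if (k == nrow(w_cur)) break
    w_cur <- agg
  }
  as.integer(factor(membership, levels = unique(membership)))
}

louvain_one_level <- function(w, resolution) {
  n <- nrow(w)
  deg <- rowSums(w) + diag(w)      # self-loops count once in strength
  m2 <- sum(deg)                   # 2m
  if (m2 == 0) return(list(community = seq_len(n), improved = FALSE))
  comm <- seq_len(n)
  tot <- deg                       # total strength per community
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      # links from i to each community; the self-loop moves with i and
      # contributes equally everywhere, so it is excluded
      wi <- w[i, ]; wi[i] <- 0
      links <- tapply(wi, comm, sum)
      tot[ci] <- tot[ci] - deg[i]
      comm[i] <- 0L
      best_gain <- 0; best_c <- ci
      cand <- unique(c(ci, comm[wi > 0]))
      cand <- cand[cand != 0]
      for (cc in cand) {
        l_ic <- if (as.character(cc) %in% names(links)) links[[as.character(cc)]] else 0
        gain <- l_ic - resolution * tot[cc] * deg[i] / m2
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_c <- cc }
      }
      comm[i] <- best_c
      tot[best_c] <- tot[best_c] + deg[i]
      if (best_c != ci) { moved <- TRUE; improved_any <- TRUE }
    }
    if (!moved) break
  }
  list(community = as.integer(factor(comm, levels = unique(comm))),
       improved = improved_any)
}

#' Remove redundant samples or transcripts
#'
#' Greedy elimination of near-duplicates. In `correlation` mode the Pearson
#' correlation matrix of log-CPM over the `top` most-variable transcripts is
#' computed between elements; while the largest off-diagonal correlation
#' exceeds `threshold`, the member of that pair with the larger mean
#' correlation to all remaining elements is removed (ties broken by removing
#' the lexicographically larger id). In `reduced_dimensions` mode the same
#' greedy loop runs on pairwise Euclidean distance in the first two `Dim`
#' columns, treating a distance below `threshold` as redundant and removing
#' the member with the smaller mean distance to the others. The removal
#' order is logged in the internals slot `"redundancy_removed"`.
#'
#' @param x A `tidy_expression_table`.
#' @param method `"correlation"` or `"reduced_dimensions"`.
#' @param threshold Correlation above / distance below which a pair is
#'   redundant (default 0.9).
#' @param top Number of most-variable transcripts for the correlation
#'   (default 1000).
#' @param of `"samples"` or `"features"`.
#' @export
remove_redundancy <- function(x, method = c("correlation", "reduced_dimensions"),
                              threshold = 0.9, top = 1000,
                              of = c("samples", "features")) {
  stopifnot(is_tidy_expression_table(x))
  method <- match.arg(method)
  of <- match.arg(of)
  keys <- te_keys(x)
  if (method == "correlation") {
    if (threshold <= 0 || threshold >= 1) {
      stop("usage error: correlation threshold must be in (0, 1)",
           call. = FALSE)
    }
    sub <- keep_variable(x, top = top)
    m <- te_assay(sub)
    m[is.na(m)] <- 0
    lm_ <- log_cpm(m)
    mat <- if (of == "samples") lm_ else t(lm_)
    if (ncol(mat) < 2) stop("usage error: need >= 2 elements", call. = FALSE)
    sim <- suppressWarnings(stats::cor(mat))
    sim[is.na(sim)] <- 0
    removed <- greedy_redundancy(sim, threshold)
  } else {
    sframe <- element_frame(x, "sample")
    dim_cols <- grep("^Dim[0-9]+$", names(sframe), value = TRUE)
    if (length(dim_cols) < 2) {
      stop("usage error: reduced_dimensions mode needs Dim columns; run reduce_dimensions first",
           call. = FALSE)
    }
    emb <- as.matrix(sframe[, dim_cols[1:2]])
    rownames(emb) <- as.character(sframe[[keys$sample]])
    sim <- -as.matrix(stats::dist(emb))
    removed <- greedy_redundancy(sim, -threshold)
  }
  id_col <- if (of == "samples") keys$sample else keys$transcript
  keep <- !(as.character(x[[id_col]]) %in% removed)
  out <- restore_te_attributes(tibble::as_tibble(x)[keep, , drop = FALSE], x)
  out <- set_internal_slot(out, "redundancy_removed", removed)
  log_method(out, "redundancy")
}

# shared greedy loop on a similarity matrix: while max off-diagonal
# similarity > cut, drop from the maximal pair the element with the larger
# mean similarity to all others (tie -> lexicographically larger id)
greedy_redundancy <- function(sim, cut) {
  removed <- character()
  diag(sim) <- -Inf
  while (nrow(sim) > 1 && max(sim) > cut) {
    idx <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    pair <- rownames(sim)[idx]
    mean_sim <- vapply(idx, function(i) {
      mean(sim[i, -i][is.finite(sim[i, -i])])
    }, numeric(1))
    drop_id <- if (abs(mean_sim[1] - mean_sim[2]) > 1e-12) {
      pair[which.max(mean_sim)]
    } else {
      max(pair)
    }
    removed <- c(removed, drop_id)
    keep <- rownames(sim) != drop_id
    sim <- sim[keep, keep, drop = FALSE]
  }
  removed
}
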