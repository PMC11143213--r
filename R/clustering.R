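#' Choose the number of read bins from community diversity
#'
#' The bin count scales linearly with the Shannon diversity of the community,
#' `k = round(a * diversity)` with `a = 8` (calibrated so k = 30 on real
#' metagenomes; 15 for a low-complexity mock, 37 for a high-complexity one),
#' floored at 2. Rounding is half-up. Shannon diversity is an input — compute
#' it with a taxonomic profiler or from known composition
#' ([shannon_diversity()]).
#'
#' @param diversity Positive Shannon diversity (natural log).
#' @param a Linear coefficient (default 8).
#'
#' @return Integer k >= 2.
#' @export
#'
#' @examples
#' choose_k(3.75)  # 30
#' choose_k(4.625) # 37
choose_k <- function(diversity, a = 8) {
  if (!is.numeric(diversity) || any(diversity <= 0)) {
    abort("`diversity` must be positive")
  }
  as.integer(pmax(2, floor(a * diversity + 0.5)))
}

#' Shannon diversity of a composition
#'
#' @param abundances Positive relative abundances (normalised internally).
#' @return Shannon entropy in nats.
#' @export
shannon_diversity <- function(abundances) {
  p <- abundances / sum(abundances)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Clustering configuration
#'
#' @param a_coefficient Diversity-to-k coefficient (default 8).
#' @param n_projections Random projections per hashing level; default
#'   `ceiling(log2(k)) + 4`, set at fit time when `NULL`.
#' @param hash_levels Levels of recursive re-hashing of oversized buckets
#'   (default 2).
#' @param init `"rph"` (random-projection-hash seeding, robust to uneven bin
#'   sizes) or `"kmeanspp"` (k-means++ fallback).
#' @param n_start Independent seeding/refinement restarts; the partition with
#'   the lowest within-cluster sum of squares wins (default 8).
#' @param max_iter Lloyd iteration cap (default 100).
#' @param seed Integer seed.
#'
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(a_coefficient = 8, n_projections = NULL,
                              hash_levels = 2, init = c("rph", "kmeanspp"),
                              n_start = 8, max_iter = 100, seed = 1L) {
  structure(
    list(a_coefficient = a_coefficient, n_projections = n_projections,
         hash_levels = as.integer(hash_levels), init = match.arg(init),
         n_start = as.integer(n_start), max_iter = as.integer(max_iter),
         seed = as.integer(seed)),
    class = "clustering_config"
  )
}

pairwise_sqdist <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# Random-projection-hash seeding: points are hashed by the signs of centred
# random projections; oversized buckets are re-hashed with fresh projections
# up to `levels` times; bucket centroids (weighted by bucket mass) are then
# reduced to k seeds with weighted k-means++.
rph_seeds <- function(x, k, n_proj, levels) {
  n <- nrow(x)
  centre <- colMeans(x)
  xc <- sweep(x, 2, centre)
  hash <- rep("", n)
  bucket_of <- rep(1L, n)
  for (lev in seq_len(levels)) {
    sizes <- table(bucket_of)
    big <- as.integer(names(sizes)[sizes > max(2 * n / max(k, 1), 1)])
    if (lev == 1) big <- 1L
    if (length(big) == 0) break
    proj <- matrix(rnorm(ncol(x) * n_proj), ncol(x), n_proj)
    signs <- (xc %*% proj) > 0
    code <- apply(signs, 1, function(b) paste(as.integer(b), collapse = ""))
    in_big <- bucket_of %in% big
    hash[in_big] <- paste0(hash[in_big], "|", code[in_big])
    bucket_of <- as.integer(factor(hash))
  }
  buckets <- sort(unique(bucket_of))
  cent <- do.call(rbind, lapply(buckets, function(b) {
    colMeans(x[bucket_of == b, , drop = FALSE])
  }))
  mass <- as.numeric(table(factor(bucket_of, levels = buckets)))
  if (nrow(cent) <= k) {
    # too few buckets: top up with the points farthest from existing seeds
    seeds <- cent
    while (nrow(seeds) < k) {
      d <- apply(pairwise_sqdist(x, seeds), 1, min)
      seeds <- rbind(seeds, x[which.max(d), ])
    }
    return(seeds)
  }
  kmeanspp_seeds(cent, k, weight = mass)
}

kmeanspp_seeds <- function(x, k, weight = rep(1, nrow(x))) {
  n <- nrow(x)
  seeds <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1, prob = weight)
  seeds[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, seeds[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 * weight
    if (sum(p) == 0) p <- weight
    i <- sample.int(n, 1, prob = p)
    seeds[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, seeds[j, ])^2))
  }
  seeds
}

lloyd_iterate <- function(x, centers, max_iter) {
  n <- nrow(x)
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- pairwise_sqdist(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed with the point farthest from its centroid
    empty <- setdiff(seq_len(nrow(centers)), unique(assign))
    if (length(empty)) {
      resid <- d2[cbind(seq_len(n), assign)]
      for (e in empty) {
        far <- which.max(resid)
        centers[e, ] <- x[far, ]
        assign[far] <- e
        resid[far] <- 0
      }
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (j in unique(assign)) {
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    }
  }
  list(assignment = assign, centers = centers,
       wcss = sum(pairwise_sqdist(x, centers)[cbind(seq_len(n), assign)]),
       iterations = it)
}

#' Cluster barcode embeddings into read bins
#'
#' k-means refinement seeded by random-projection hashing: points are hashed
#' into buckets by the signs of random projections, bucket centroids (weighted
#' by bucket mass) seed Lloyd iterations, and empty clusters are repaired by
#' re-seeding at the point farthest from its centroid. RPH seeding keeps
#' small, low-abundance bins from being absorbed by large ones. Deterministic
#' under the seed; bin labels are arbitrary (0-based).
#'
#' @param embeddings Numeric matrix (records x latent_dim) with barcode
#'   rownames, e.g. from [embed_barcodes()].
#' @param k Number of bins (>= 2), e.g. from [choose_k()].
#' @param config A [clustering_config()].
#'
#' @return A `bin_assignment` tibble: `barcode`, `bin` (in `[0, k)`), with the
#'   centers, WCSS and k as attributes.
#' @export
cluster_latent <- function(embeddings, k, config = clustering_config()) {
  x <- as.matrix(embeddings)
  if (nrow(x) < k) {
    abort(paste0("fewer points (", nrow(x), ") than clusters (", k,
                 "); choose a smaller k"))
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  n_proj <- config$n_projections %||% (ceiling(log2(k)) + 4)
  with_seed(config$seed, {
    fit <- NULL
    for (s in seq_len(max(1L, config$n_start))) {
      centers <- if (config$init == "rph") {
        rph_seeds(x, k, n_proj, config$hash_levels)
      } else {
        kmeanspp_seeds(x, k)
      }
      cand <- lloyd_iterate(x, centers, config$max_iter)
      if (is.null(fit) || cand$wcss < fit$wcss) fit <- cand
    }
    out <- tibble(barcode = rownames(x), bin = fit$assignment - 1L)
    attr(out, "centers") <- fit$centers
    attr(out, "wcss") <- fit$wcss
    attr(out, "k") <- as.integer(k)
    class(out) <- c("bin_assignment", class(out))
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a binning against ground truth
#'
#' Precision is the weighted purity of bins (each bin votes for its dominant
#' genome), recall the weighted completeness of genomes (each genome votes for
#' its dominant bin), and ARI the adjusted Rand index.
#'
#' @param assignment Tibble with `barcode`, `bin` (from [cluster_latent()]).
#' @param truth Tibble with `barcode`, `genome`.
#'
#' @return One-row tibble: `precision`, `recall`, `ari`, `n`.
#' @export
evaluate_binning <- function(assignment, truth) {
  joined <- dplyr::inner_join(assignment, truth, by = "barcode")
  if (nrow(joined) == 0) abort("assignment and truth share no barcodes")
  tab <- table(joined$bin, joined$genome)
  n <- sum(tab)
  tibble(
    precision = sum(apply(tab, 1, max)) / n,
    recall = sum(apply(tab, 2, max)) / n,
    ari = mclust::adjustedRandIndex(joined$bin, joined$genome),
    n = n
  )
}

#' Plot a 2-D view of clustered embeddings
#'
#' Principal-component projection of the latent space coloured by bin (or any
#' label joined on barcode).
#'
#' @param embeddings Matrix from [embed_barcodes()].
#' @param labels Optional tibble with `barcode` and a label column (e.g. a
#'   `bin_assignment` or truth table); the second column is used.
#' @return A ggplot.
#' @export
plot_latent <- function(embeddings, labels = NULL) {
  pc <- prcomp(embeddings, rank. = 2)
  df <- tibble(barcode = rownames(embeddings),
               pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  if (!is.null(labels)) {
    lab <- labels[, 1:2]
    names(lab) <- c("barcode", "label")
    df <- dplyr::left_join(df, lab, by = "barcode")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                          colour = factor(.data$label)))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2))
  }
  p + ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = NULL) +
    ggplot2::theme_minimal()
}
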