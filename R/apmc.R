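#' Select anchor subjects
#'
#' Anchors are subjects observed in both modalities; their per-modality
#' coordinates act as shared landmarks linking the two bipartite
#' subject-to-anchor graphs. Strategy `"random"` samples uniformly without
#' replacement; `"kmeans-medoid"` clusters the common subjects' concatenated
#' z-scored views into K groups and takes the subject nearest each centroid.
#'
#' @param dataset a [partial_mm_dataset()].
#' @param K number of anchors; must not exceed the common-subject count.
#' @param seed RNG seed.
#' @param strategy `"random"` or `"kmeans-medoid"`.
#' @return object of class `anchor_set`: `anchor_subject_ids`, `u_imaging`
#'   (K x imaging features), `u_genomic` (K x genes).
#' @export
select_anchors <- function(dataset, K, seed = 1L,
                           strategy = c("random", "kmeans-medoid")) {
  strategy <- match.arg(strategy)
  common <- which(dataset$has_imaging & dataset$has_genomic)
  if (!length(common))
    stop("no subjects with both modalities: anchor-based fusion inapplicable")
  if (K > length(common))
    stop("K = ", K, " exceeds the ", length(common), " common subjects")
  set.seed(seed)
  if (strategy == "random") {
    idx <- sort(sample(common, K))
  } else {
    V <- cbind(safe_zscore(dataset$imaging[common, , drop = FALSE]),
               safe_zscore(dataset$genomic[common, , drop = FALSE]))
    km <- stats::kmeans(V, centers = K, nstart = 10, iter.max = 50)
    idx <- sort(common[vapply(seq_len(K), function(cl) {
      members <- which(km$cluster == cl)
      d2 <- rowSums((V[members, , drop = FALSE] -
                       matrix(km$centers[cl, ], length(members),
                              ncol(V), byrow = TRUE))^2)
      members[which.min(d2)]
    }, integer(1))])
  }
  structure(list(
    anchor_subject_ids = dataset$subject_ids[idx],
    u_imaging = dataset$imaging[idx, , drop = FALSE],
    u_genomic = dataset$genomic[idx, , drop = FALSE]
  ), class = "anchor_set")
}

# z-score tolerant of constant columns (left at zero after centering)
safe_zscore <- function(x) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  sds <- apply(x, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  sweep(x, 2, sds, "/")
}

#' Gaussian subject-to-anchor similarities
#'
#' For each subject row: Euclidean distances to all K anchors; keep the `s`
#' nearest; on those, Z_ij = exp(-d_ij^2 / (2 sigma^2)); zero elsewhere;
#' rows normalized to sum to 1, so each Z row is the subject's one-step
#' transition distribution over anchors.
#'
#' @param view_matrix subjects x features matrix for one modality (present
#'   subjects only).
#' @param anchor_matrix K x features anchor coordinates in the same modality.
#' @param s neighbors kept per subject (capped at K).
#' @param bandwidth kernel scale sigma; `NULL` applies the default rule, the
#'   mean over subjects of the distance to the s-th nearest anchor.
#' @return object of class `anchor_similarity`: `Z` (subjects x K,
#'   row-stochastic, s nonzeros per row), `s`, `bandwidth`.
#' @export
anchor_similarity <- function(view_matrix, anchor_matrix, s = 15L,
                              bandwidth = NULL) {
  V <- as.matrix(view_matrix); U <- as.matrix(anchor_matrix)
  if (ncol(V) != ncol(U)) stop("view and anchors differ in feature dimension")
  K <- nrow(U)
  s <- min(as.integer(s), K)
  # squared distances via the expansion ||v||^2 + ||u||^2 - 2 v.u
  d2 <- outer(rowSums(V^2), rowSums(U^2), "+") - 2 * tcrossprod(V, U)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  snn <- apply(d, 1, function(r) sort(r, partial = s)[s])
  if (is.null(bandwidth)) bandwidth <- mean(snn)
  if (bandwidth <= 0)
    stop("zero kernel bandwidth: all subjects coincide with their anchors")
  Z <- matrix(0, nrow(V), K, dimnames = list(rownames(V), NULL))
  for (i in seq_len(nrow(V))) {
    keep <- order(d[i, ])[seq_len(s)]
    w <- exp(-d[i, keep]^2 / (2 * bandwidth^2))
    Z[i, keep] <- w / sum(w)
  }
  structure(list(Z = Z, s = s, bandwidth = bandwidth),
            class = "anchor_similarity")
}

#' Fuse the per-modality anchor graphs
#'
#' The two anchor graphs share the same anchors, so their rows are aligned:
#' a subject observed in one modality contributes that modality's row; a
#' subject observed in both contributes the average of its two rows. The
#' result stays row-stochastic.
#'
#' @param Z_imaging,Z_genomic `anchor_similarity` objects (or bare matrices)
#'   over the imaging-present and genomic-present subjects respectively.
#' @param dataset the [partial_mm_dataset()] the graphs were built from.
#' @return N x K row-stochastic matrix over all subjects.
#' @export
fuse_anchor_graphs <- function(Z_imaging, Z_genomic, dataset) {
  Zi <- if (inherits(Z_imaging, "anchor_similarity")) Z_imaging$Z else Z_imaging
  Zg <- if (inherits(Z_genomic, "anchor_similarity")) Z_genomic$Z else Z_genomic
  if (ncol(Zi) != ncol(Zg)) stop("anchor graphs reference different anchor sets")
  n <- length(dataset$subject_ids)
  fused <- matrix(0, n, ncol(Zi), dimnames = list(dataset$subject_ids, NULL))
  fused[dataset$has_imaging, ] <- Zi
  gi <- which(dataset$has_genomic)
  both <- dataset$has_imaging[gi]
  fused[gi[both], ] <- (fused[gi[both], , drop = FALSE] +
                          Zg[both, , drop = FALSE]) / 2
  fused[gi[!both], ] <- Zg[!both, , drop = FALSE]
  fused
}

#' Two-step random-walk similarity over the fused anchor graph
#'
#' The subject-subject similarity is the two-step transition probability of a
#' stationary Markov walk subject -> anchor -> subject on the bipartite graph:
#' S_ij = sum_k Z_ik Z_jk / (sum_i' Z_i'k), i.e. S = Z Lambda^-1 Z' with
#' Lambda the diagonal of Z's column sums. S is symmetric, row-stochastic and
#' positive semidefinite by construction.
#'
#' @param fused_Z N x K row-stochastic matrix; all-zero anchor columns are
#'   dropped with a warning.
#' @return object of class `fused_similarity`: `S` (N x N), `fused_Z`.
#' @export
two_step_similarity <- function(fused_Z) {
  Z <- as.matrix(fused_Z)
  colsum <- colSums(Z)
  if (any(colsum == 0)) {
    warning("dropping ", sum(colsum == 0), " empty anchor column(s)")
    Z <- Z[, colsum > 0, drop = FALSE]
    colsum <- colsum[colsum > 0]
  }
  if (!ncol(Z)) stop("no anchors left after dropping empty columns")
  S <- tcrossprod(sweep(Z, 2, sqrt(colsum), "/"))
  structure(list(S = S, fused_Z = Z), class = "fused_similarity")
}

#' Spectral clustering of a fused similarity matrix
#'
#' Symmetric-normalized Laplacian L = I - D^(-1/2) S D^(-1/2); the rows of
#' the matrix of the k smallest-eigenvalue eigenvectors are normalized to
#' unit length and clustered by k-means (20 seeded restarts). Cluster labels
#' are relabeled by decreasing cluster size so the output is deterministic.
#'
#' @param S symmetric nonnegative N x N similarity (matrix or
#'   `fused_similarity`).
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for the k-means restarts.
#' @return integer labels in 1..k (largest cluster = 1), with the spectral
#'   embedding in attribute `"embedding"`.
#' @export
spectral_cluster <- function(S, k, seed = 1L) {
  if (inherits(S, "fused_similarity")) S <- S$S
  S <- as.matrix(S)
  n <- nrow(S)
  if (k > n) stop("k exceeds the number of subjects")
  if (k < 2) stop("spectral clustering needs k >= 2")
  E <- spectral_embedding(S, k)
  set.seed(seed)
  km <- stats::kmeans(E, centers = k, nstart = 20, iter.max = 100)
  labels <- relabel_by_size(km$cluster)
  attr(labels, "embedding") <- E
  labels
}

# eigenvectors of the k smallest eigenvalues of
# L_sym = I - D^(-1/2) S D^(-1/2) (equivalently k largest of the normalized S).
# scale = "row" gives the row-normalized coordinates used for cluster
# assignment; scale = "eigenvalue" gives diffusion-style coordinates
# (eigenvectors damped by their eigenvalues) used for gap-statistic model
# selection, where the noise directions must not carry full weight.
spectral_embedding <- function(S, k, scale = c("row", "eigenvalue")) {
  scale <- match.arg(scale)
  deg <- rowSums(S)
  if (any(deg <= 0)) stop("similarity matrix has an all-zero row")
  dinv <- 1 / sqrt(deg)
  M <- S * tcrossprod(dinv)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  if (scale == "row") {
    rn <- sqrt(rowSums(E^2))
    rn[rn < 1e-12] <- 1
    E <- E / rn
  } else {
    E <- E * rep(pmax(eg$values[seq_len(k)], 0), each = nrow(E))
  }
  E
}

relabel_by_size <- function(cl) {
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[ord]] <- seq_along(ord)
  map[cl]
}

#' Gap statistic for the number of clusters
#'
#' Works in the spectral embedding of `max(k_candidates)` dimensions of the
#' two-step similarity built from `fused_Z`, with each eigenvector damped by
#' its eigenvalue (diffusion scaling) so that low-eigenvalue noise
#' directions do not mimic cluster structure. For each candidate k the pooled
#' within-cluster dispersion W_k comes from k-means; B reference datasets are
#' drawn uniformly over the embedding's bounding box; Gap(k) = mean_b log
#' W_k(ref_b) - log W_k. The chosen k* is the smallest k with Gap(k) >=
#' Gap(k+1) - SE(k+1) (the one-standard-error rule), falling back to the
#' argmax of the gap curve if no k qualifies.
#'
#' @param fused_Z N x K row-stochastic fused anchor graph.
#' @param k_candidates candidate cluster numbers (default 1:6).
#' @param B number of reference datasets (>= 10).
#' @param seed RNG seed.
#' @return list with `k` (chosen), `gap_curve` (data.frame: k, log_w, gap,
#'   se).
#' @export
gap_statistic_k <- function(fused_Z, k_candidates = 1:6, B = 25L, seed = 1L) {
  if (B < 10) stop("B must be at least 10")
  ks <- sort(unique(as.integer(k_candidates)))
  S <- two_step_similarity(fused_Z)$S
  kmax <- max(ks)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  rank_s <- sum(ev > max(ev) * 1e-10)
  if (rank_s < kmax) {
    warning("embedding rank ", rank_s, " below max candidate k; truncating")
    ks <- ks[ks <= rank_s]
    kmax <- max(ks)
  }
  E <- spectral_embedding(S, kmax, scale = "eigenvalue")
  set.seed(seed)
  log_w <- vapply(ks, function(k) log(wk_dispersion(E, k)), numeric(1))
  lo <- apply(E, 2, min); hi <- apply(E, 2, max)
  log_w_ref <- matrix(0, B, length(ks))
  for (b in seq_len(B)) {
    R <- sapply(seq_along(lo), function(j) stats::runif(nrow(E), lo[j], hi[j]))
    log_w_ref[b, ] <- vapply(ks, function(k) log(wk_dispersion(R, k)),
                             numeric(1))
  }
  gap <- colMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 2, stats::sd) * sqrt(1 + 1 / B)
  k_star <- NA_integer_
  for (i in seq_along(ks)[-length(ks)]) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) { k_star <- ks[i]; break }
  }
  if (is.na(k_star)) k_star <- ks[which.max(gap)]
  list(k = k_star,
       gap_curve = data.frame(k = ks, log_w = log_w, gap = gap, se = se))
}

# pooled within-cluster sum of squares (k = 1: total dispersion)
wk_dispersion <- function(E, k) {
  if (k == 1) {
    ctr <- colMeans(E)
    return(sum(sweep(E, 2, ctr)^2) + 1e-300)
  }
  km <- stats::kmeans(E, centers = k, nstart = 10, iter.max = 100)
  km$tot.withinss + 1e-300
}

#' APMC configuration
#'
#' @param K anchor count; `NULL` -> min(50, floor(common/2)).
#' @param anchor_strategy `"random"` or `"kmeans-medoid"`.
#' @param s nearest anchors kept per subject.
#' @param k number of subtypes; `NULL` -> chosen by [gap_statistic_k()].
#' @param k_candidates candidates for the gap statistic.
#' @param gap_B reference datasets for the gap statistic.
#' @param seed RNG seed for anchors, gap references and k-means.
#' @return list of class `apmc_config`.
#' @export
apmc_config <- function(K = NULL, anchor_strategy = "random", s = 15L,
                        k = NULL, k_candidates = 1:6, gap_B = 25L,
                        seed = 1L) {
  structure(list(K = K, anchor_strategy = anchor_strategy, s = as.integer(s),
                 k = k, k_candidates = k_candidates, gap_B = gap_B,
                 seed = as.integer(seed)),
            class = "apmc_config")
}

#' Anchor-based partial multi-modal clustering
#'
#' Full chain: anchor selection among both-modality subjects, Gaussian
#' subject-to-anchor graphs per modality, row-averaged fusion, two-step
#' random-walk similarity, gap-statistic choice of the cluster number (unless
#' fixed in the config), and spectral clustering. Transductive: all subjects
#' (both cohort splits) are clustered jointly.
#'
#' @param dataset a preprocessed [partial_mm_dataset()] (imaging reduced to
#'   the selected features; genomic restricted to the pathway gene panel as
#'   desired).
#' @param config an [apmc_config()].
#' @return object of class `subtype_assignment`: `labels` (named integer
#'   vector over all subjects), `k`, `embedding`, `gap_curve` (NULL when k
#'   was fixed), `similarity` (`fused_similarity`), `anchors`.
#' @export
run_apmc <- function(dataset, config = apmc_config()) {
  common <- sum(dataset$has_imaging & dataset$has_genomic)
  K <- if (is.null(config$K)) max(2L, min(50L, common %/% 2L)) else config$K
  anchors <- select_anchors(dataset, K, seed = config$seed,
                            strategy = config$anchor_strategy)
  Zi <- anchor_similarity(dataset$imaging[dataset$has_imaging, , drop = FALSE],
                          anchors$u_imaging, s = config$s)
  Zg <- anchor_similarity(dataset$genomic[dataset$has_genomic, , drop = FALSE],
                          anchors$u_genomic, s = config$s)
  fused <- fuse_anchor_graphs(Zi, Zg, dataset)
  sim <- two_step_similarity(fused)
  gap <- NULL
  k <- config$k
  if (is.null(k)) {
    gap <- gap_statistic_k(sim$fused_Z, config$k_candidates, config$gap_B,
                           seed = config$seed)
    k <- gap$k
  }
  if (k == 1) {
    labels <- rep(1L, length(dataset$subject_ids))
    emb <- spectral_embedding(sim$S, 1L)
  } else {
    labels <- spectral_cluster(sim, k, seed = config$seed)
    emb <- attr(labels, "embedding")
  }
  attributes(labels) <- NULL
  names(labels) <- dataset$subject_ids
  structure(list(labels = labels, k = k, embedding = emb, gap_curve = gap,
                 similarity = sim, anchors = anchors),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("subtype_assignment: %d subjects in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}
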