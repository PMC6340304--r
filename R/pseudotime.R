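#' Cosine normalization of cell expression vectors
#'
#' Scales each unit's expression vector (a column) to Euclidean norm 1, so
#' that Euclidean distances between cells become a monotone function of the
#' cosine of the angle between their expression profiles.
#'
#' @param values genes x units matrix.
#' @return matrix of the same shape with unit columns of norm 1.
#' @export
cosine_normalize <- function(values) {
  norms <- sqrt(colSums(values^2))
  zero <- norms == 0
  if (any(zero))
    stop("degenerate-unit: all-zero expression for: ",
         paste(colnames(values)[zero], collapse = ", "))
  sweep(values, 2, norms, "/")
}

#' Diffusion-map parameters
#'
#' @param k_neighbors neighborhood size for the kNN graph, default 21.
#' @param n_components number of non-trivial diffusion components to return,
#'   default 3.
#' @param kernel_scale `"local"` (per-cell bandwidth, the distance to the
#'   `ceiling(k/2)`-th neighbor) or `"global"` (one bandwidth, the median of
#'   the local ones).
#' @return a `diffusion_params` list.
#' @export
diffusion_params <- function(k_neighbors = 21, n_components = 3,
                             kernel_scale = c("local", "global")) {
  kernel_scale <- match.arg(kernel_scale)
  stopifnot(k_neighbors >= 2, n_components >= 1)
  structure(list(k_neighbors = k_neighbors, n_components = n_components,
                 kernel_scale = kernel_scale), class = "diffusion_params")
}

#' Diffusion map over cells
#'
#' Spectral embedding of the cell-cell random walk: (1) a symmetric k-nearest
#' neighbor graph on Euclidean distances of the cosine-normalized expression
#' vectors; (2) a Gaussian kernel with per-cell local bandwidth (the distance
#' to the `ceiling(k/2)`-th neighbor); (3) density normalization by the
#' product of kernel row sums (the anisotropic alpha = 1 correction, removing
#' sampling-density bias); (4) row normalization to a stochastic transition
#' matrix; (5) eigendecomposition. The trivial constant eigenvector
#' (eigenvalue 1) is dropped and the next `n_components` eigenvector /
#' eigenvalue pairs are returned, each component scaled by its eigenvalue.
#' The first diffusion component (DC1) serves as pseudotime.
#'
#' If the graph is disconnected, components are computed on the largest
#' connected component; other cells are labeled unassigned (NA components,
#' state 0) with a warning.
#'
#' @param values genes x units matrix, typically cosine-normalized log2
#'   expression over the HVGs (see [cosine_normalize()]).
#' @param params a [diffusion_params()].
#' @return object of class `trajectory_result`: `components` (units x
#'   n_components, NA for unassigned), `eigenvalues` (descending, in (-1, 1)),
#'   `pseudotime` (= DC1), `assigned` (logical), `unit_ids`.
#' @export
diffusion_map <- function(values, params = diffusion_params()) {
  n <- ncol(values)
  k <- params$k_neighbors
  if (n <= k) stop("need more units (", n, ") than k_neighbors (", k, ")")
  dm <- as.matrix(stats::dist(t(values)))
  unit_ids <- colnames(values)

  # kNN (excluding self), symmetrized by union
  nn_idx <- apply(dm, 1, function(row) order(row)[2:(k + 1)])  # k x n
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, nn_idx[, i]] <- TRUE
  adj <- adj | t(adj)

  # local bandwidth: distance to the ceiling(k/2)-th neighbor
  kk <- ceiling(k / 2)
  sigma <- vapply(seq_len(n), function(i) dm[i, nn_idx[kk, i]], numeric(1))
  eps <- max(dm) * 1e-12
  sigma <- pmax(sigma, eps)
  if (params$kernel_scale == "global") sigma[] <- stats::median(sigma)

  W <- matrix(0, n, n)
  sc <- outer(sigma, sigma)
  W[adj] <- exp(-dm[adj]^2 / (2 * sc[adj]))
  diag(W) <- 1

  # connected components of the kernel graph
  comp <- connected_components(W > 0)
  main <- which(comp == which.max(tabulate(comp)))
  assigned <- seq_len(n) %in% main
  if (length(main) < n)
    warning("disconnected kNN graph: ", n - length(main),
            " cell(s) outside the largest component left unassigned")
  Wm <- W[main, main, drop = FALSE]

  # anisotropic density normalization (alpha = 1), then row-stochastic
  q <- rowSums(Wm)
  Wt <- Wm / outer(q, q)
  dd <- rowSums(Wt)
  # symmetric conjugate of the transition matrix for a stable eigensolve
  S <- Wt / sqrt(outer(dd, dd))
  es <- eigen(S, symmetric = TRUE)
  phi <- es$vectors / sqrt(dd)          # right eigenvectors of P
  lam <- es$values

  ncomp <- min(params$n_components, length(main) - 1)
  comps <- matrix(NA_real_, n, ncomp,
                  dimnames = list(unit_ids, paste0("DC", seq_len(ncomp))))
  evals <- numeric(ncomp)
  for (j in seq_len(ncomp)) {
    v <- phi[, j + 1]                   # skip trivial eigenvector
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v   # deterministic sign
    comps[main, j] <- lam[j + 1] * v
    evals[j] <- lam[j + 1]
  }
  structure(list(components = comps, eigenvalues = evals,
                 pseudotime = comps[, 1], assigned = assigned,
                 unit_ids = unit_ids, params = params),
            class = "trajectory_result")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[i, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Meta-stable states by exact one-dimensional k-means
#'
#' Partitions per-cell pseudotime values (the first diffusion component) into
#' `n_states` groups minimizing the within-cluster sum of squares. In one
#' dimension the optimal partition is contiguous in sorted order, so it is
#' found exactly by dynamic programming -- deterministic, no seed. Ties are
#' broken toward segments of equal size, so degenerate inputs (all values
#' equal) yield the canonical contiguous equal-size split.
#'
#' State labels are ordered along the axis: state 1 has the lowest mean.
#' Unassigned cells (NA pseudotime) carry label 0 and are excluded from state
#' statistics.
#'
#' @param pseudotime numeric vector (NA allowed = unassigned).
#' @param n_states number of states, default 4.
#' @return list of class `metastable_states`: `labels` (integer per input,
#'   0 = unassigned), `centers` (within-state means, ascending), `wcss`.
#' @export
assign_metastable_states <- function(pseudotime, n_states = 4) {
  ok <- which(!is.na(pseudotime))
  x <- pseudotime[ok]
  n <- length(x)
  if (n_states > n) stop("n_states (", n_states, ") exceeds assigned units (", n, ")")
  ord <- order(x)
  xs <- x[ord]
  cs <- c(0, cumsum(xs)); cs2 <- c(0, cumsum(xs^2))
  cost <- function(i, j) { # SSQ of xs[i..j]
    s <- cs[j + 1] - cs[i]; s2 <- cs2[j + 1] - cs2[i]
    max(0, s2 - s^2 / (j - i + 1))
  }
  K <- n_states
  D <- matrix(Inf, K, n)
  B <- matrix(0L, K, n)   # start index of last segment
  for (j in seq_len(n)) { D[1, j] <- cost(1, j); B[1, j] <- 1L }
  for (k in seq_len(K)[-1]) {
    for (j in k:n) {
      best <- Inf; besti <- k; target <- j / k  # preferred segment length
      for (i in k:j) {
        val <- D[k - 1, i - 1] + cost(i, j)
        if (val < best - 1e-12 ||
            (val < best + 1e-12 &&
             abs((j - i + 1) - target) < abs((j - besti + 1) - target))) {
          best <- val; besti <- i
        }
      }
      D[k, j] <- best; B[k, j] <- besti
    }
  }
  seg <- integer(n)
  j <- n
  for (k in K:1) {
    i <- B[k, j]
    seg[i:j] <- k
    j <- i - 1L
  }
  labels_sorted <- seg
  labels <- integer(length(pseudotime))
  labels[ok[ord]] <- labels_sorted
  centers <- vapply(seq_len(K), function(k) mean(xs[labels_sorted == k]), numeric(1))
  wcss <- sum(vapply(seq_len(K), function(k) {
    xi <- xs[labels_sorted == k]; sum((xi - mean(xi))^2)
  }, numeric(1)))
  structure(list(labels = labels, centers = centers, wcss = wcss,
                 n_states = K), class = "metastable_states")
}

#' Orient pseudotime by anchor markers and summarize expression by state
#'
#' Flips the sign of DC1 (and hence pseudotime) if needed so that the mean
#' anchor-gene expression (maturation markers such as CCR7/CCL19-like genes)
#' increases along pseudotime, then recomputes meta-stable states so state 1
#' is earliest. Also returns per-state mean expression for any requested
#' genes, the table behind transient-program summaries along the trajectory.
#'
#' @param traj a `trajectory_result` from [diffusion_map()].
#' @param anchors a [gene_set()] of maturation markers.
#' @param normed a `normalized_matrix` covering the same units.
#' @param n_states meta-stable state count, default 4.
#' @param report_genes character vector of genes to tabulate by state
#'   (defaults to the anchors).
#' @return the `trajectory_result` augmented with `states`
#'   (a `metastable_states`), `state_means` (genes x states mean expression),
#'   and `flipped` (logical).
#' @export
orient_and_annotate <- function(traj, anchors, normed, n_states = 4,
                                report_genes = NULL) {
  present <- intersect(anchors$ids, rownames(normed$values))
  flipped <- FALSE
  if (length(present) == 0) {
    warning("no anchor genes found; orientation left as computed")
  } else {
    anchor_expr <- colMeans(normed$values[present, traj$unit_ids, drop = FALSE])
    ok <- traj$assigned
    if (stats::cor(traj$pseudotime[ok], anchor_expr[ok]) < 0) {
      traj$components <- -traj$components
      traj$pseudotime <- -traj$pseudotime
      flipped <- TRUE
    }
  }
  states <- assign_metastable_states(traj$pseudotime, n_states)
  report_genes <- report_genes %||% anchors$ids
  report_genes <- intersect(report_genes, rownames(normed$values))
  sm <- NULL
  if (length(report_genes) > 0) {
    sm <- vapply(seq_len(states$n_states), function(k) {
      cells <- traj$unit_ids[states$labels == k]
      rowMeans(normed$values[report_genes, cells, drop = FALSE])
    }, numeric(length(report_genes)))
    sm <- matrix(sm, nrow = length(report_genes),
                 dimnames = list(report_genes,
                                 paste0("state", seq_len(states$n_states))))
  }
  traj$states <- states
  traj$state_means <- sm
  traj$flipped <- flipped
  traj
}

#' Descriptive branch assignment from DC2
#'
#' Cells are split into two branches by the sign of DC2 relative to the
#' midpoint of the DC2 values at the two DC1 extremes; reported descriptively
#' (the meta-stable partition itself uses DC1 only).
#'
#' @param traj a `trajectory_result` with at least 2 components.
#' @return integer vector per unit: 1 or 2, 0 for unassigned cells.
#' @export
assign_branches <- function(traj) {
  if (ncol(traj$components) < 2) stop("branch assignment needs 2 components")
  dc1 <- traj$components[, 1]; dc2 <- traj$components[, 2]
  ok <- traj$assigned
  lo <- which.min(replace(dc1, !ok, Inf))
  hi <- which.max(replace(dc1, !ok, -Inf))
  mid <- mean(c(dc2[lo], dc2[hi]))
  br <- integer(length(dc1))
  br[ok] <- ifelse(dc2[ok] >= mid, 1L, 2L)
  br
}
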