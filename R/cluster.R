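#' Spearman correlation dissimilarity between cells
#'
#' `1 - rho` over the supplied genes (typically the highly variable genes),
#' with midranks for ties. Zero-variance units carry no rank information:
#' their dissimilarities are set to the maximum (2) with a warning.
#'
#' @param values genes x units numeric matrix (log2 normalized expression).
#' @return symmetric units x units dissimilarity matrix, zero diagonal,
#'   entries in \[0, 2\].
#' @export
spearman_dissimilarity <- function(values) {
  if (ncol(values) < 2) stop("need at least 2 units")
  if (nrow(values) < 3) stop("need at least 3 genes")
  sds <- apply(values, 2, stats::sd)
  flat <- sds == 0
  d <- matrix(2, ncol(values), ncol(values),
              dimnames = list(colnames(values), colnames(values)))
  if (any(flat))
    warning("zero-variance unit(s) set to maximum dissimilarity: ",
            paste(colnames(values)[flat], collapse = ", "))
  ok <- which(!flat)
  if (length(ok) >= 2)
    d[ok, ok] <- 1 - stats::cor(values[, ok, drop = FALSE], method = "spearman")
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @return an `hclust` tree.
#' @export
average_linkage_tree <- function(d) {
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Dynamic tree cut ("tree" variant)
#'
#' Adaptive cluster definition on a dendrogram: splits are examined from the
#' top of the tree downward and accepted only when both resulting branches
#' hold at least `min_module_size` leaves. An undersized branch encountered on
#' the way down is set aside and finally merged into the accepted cluster
#' nearest to it by average dissimilarity. If no admissible split exists the
#' result is a single cluster.
#'
#' Labels are canonical: clusters are numbered 1, 2, ... by decreasing size
#' (ties broken by smallest member id), so the labeling is invariant to unit
#' input order.
#'
#' @param tree an `hclust` dendrogram.
#' @param d the dissimilarity matrix the tree was built from (used for the
#'   small-branch merge rule).
#' @param min_module_size minimum cluster size, default 30.
#' @return list of class `cluster_assignment`: `unit_ids`, `labels` (positive
#'   integers), `merged_small` (data.frame logging small-branch merges),
#'   `tree`.
#' @export
dynamic_tree_cut <- function(tree, d, min_module_size = 30) {
  stopifnot(min_module_size >= 1)
  labels_all <- tree$labels
  n <- length(labels_all)
  accepted <- list()   # list of integer leaf-index vectors
  pending <- list()

  leaves_of <- function(node) {
    # node: row in merge; negative entries are leaves
    if (node < 0) return(-node)
    row <- tree$merge[node, ]
    c(leaves_of(row[1]), leaves_of(row[2]))
  }

  descend <- function(node) {
    lv <- leaves_of(node)
    if (length(lv) < min_module_size) {
      pending[[length(pending) + 1]] <<- lv
      return(invisible())
    }
    if (node < 0) { # single leaf, min_module_size == 1
      accepted[[length(accepted) + 1]] <<- lv
      return(invisible())
    }
    row <- tree$merge[node, ]
    sizes <- c(length(leaves_of(row[1])), length(leaves_of(row[2])))
    if (all(sizes >= min_module_size)) {
      descend(row[1]); descend(row[2])
    } else if (any(sizes >= min_module_size)) {
      big <- which.max(sizes); small <- 3 - big
      pending[[length(pending) + 1]] <<- leaves_of(row[small])
      descend(row[big])
    } else {
      accepted[[length(accepted) + 1]] <<- lv
    }
  }

  if (n == 1) {
    accepted <- list(1L)
  } else {
    descend(nrow(tree$merge))
  }
  merged_log <- data.frame(unit_id = character(0), into = integer(0),
                           stringsAsFactors = FALSE)
  if (length(accepted) == 0) {
    accepted <- list(unlist(pending))
    pending <- list()
  }
  labels <- integer(n)
  for (i in seq_along(accepted)) labels[accepted[[i]]] <- i
  for (blk in pending) {
    avg <- vapply(accepted, function(cl)
      mean(d[labels_all[blk], labels_all[cl], drop = FALSE]), numeric(1))
    tgt <- which.min(avg)
    labels[blk] <- tgt
    merged_log <- rbind(merged_log,
                        data.frame(unit_id = labels_all[blk], into = tgt,
                                   stringsAsFactors = FALSE))
  }
  # canonical relabeling: by decreasing size, ties by smallest member unit id,
  # so labels do not depend on unit input order
  sizes <- table(labels)
  firsts <- vapply(as.integer(names(sizes)),
                   function(l) min(labels_all[labels == l]), character(1))
  ord <- order(-as.integer(sizes), firsts)
  relab <- integer(max(labels))
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relab[labels]
  if (nrow(merged_log) > 0) merged_log$into <- relab[merged_log$into]
  structure(list(unit_ids = labels_all, labels = labels,
                 merged_small = merged_log, tree = tree,
                 min_module_size = min_module_size),
            class = "cluster_assignment")
}

#' Two-dimensional t-SNE embedding
#'
#' Barnes-Hut t-distributed stochastic neighbor embedding of units on the
#' supplied genes (typically HVGs), deterministic given the seed.
#'
#' @param values genes x units matrix (log2 normalized expression).
#' @param perplexity default 50; must satisfy `perplexity < (n_units - 1) / 3`.
#' @param seed RNG seed recorded in the output, default 42.
#' @return units x 2 coordinate matrix with attribute `seed`.
#' @export
tsne_embed <- function(values, perplexity = 50, seed = 42) {
  n <- ncol(values)
  if (perplexity >= (n - 1) / 3)
    stop("parameter error: perplexity ", perplexity,
         " too large for ", n, " units (needs perplexity < (n-1)/3)")
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("tsne_embed requires the Rtsne package")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(t(values), dims = 2, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE)
  coords <- fit$Y
  dimnames(coords) <- list(colnames(values), c("tsne1", "tsne2"))
  attr(coords, "seed") <- seed
  coords
}
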