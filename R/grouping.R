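## Ward minimum-variance clustering of genotypes into tolerance groups.
##
## Genotypes are clustered on the seven yield features (GYc, GYs, YSI,
## SSI, STI, TOL, GMP), z-standardized so scale-mixed features weigh
## equally, using Euclidean distance and Ward's minimum-variance linkage.
## The tree is cut into k = 3 groups and groups are labelled by their
## feature means: the group highest in mean GYc and STI is salt-tolerant;
## of the remaining two, the one with higher YSI and lower SSI is
## moderately salt-tolerant and the other salt-sensitive.

GROUP_FEATURES <- c("gyc", "gys", "ysi", "ssi", "sti", "tol", "gmp")

TOLERANCE_LABELS <- c(
  "salt-tolerant", "salt-sensitive", "moderately salt-tolerant"
)

#' Z-standardize a feature matrix
#'
#' Centers each column to mean 0 and scales to unit population standard
#' deviation (denominator n, not n - 1). Constant columns are an error,
#' named in the message.
#'
#' @param x numeric matrix or data.frame of features (rows = genotypes).
#' @return numeric matrix with attributes `"center"` and `"scale"`.
#' @export
#' @examples
#' standardize_features(cbind(f = c(1, 2, 3)))
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    halo_abort("need at least two genotypes", "halotype_bad_features")
  }
  if (any(is.na(x))) {
    halo_abort("feature matrix has missing cells", "halotype_bad_features")
  }
  ctr <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, ctr)^2)) # population sd
  if (any(sdp == 0)) {
    bad <- colnames(x)[sdp == 0] %||% which(sdp == 0)
    halo_abort(
      paste("constant feature(s):", paste(bad, collapse = ", ")),
      "halotype_constant_feature"
    )
  }
  out <- sweep(sweep(x, 2, ctr), 2, sdp, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdp
  out
}

#' Ward's minimum-variance clustering
#'
#' Agglomerative clustering of (already standardized) feature rows with
#' Euclidean distance and the Ward criterion -- each merge minimizes the
#' increase in total within-cluster variance -- cut into `k` groups.
#'
#' @param x numeric matrix of features, rows named by genotype.
#' @param k number of groups (default 3).
#' @param standardize z-standardize columns first (default `TRUE`).
#' @return object of class `tolerance_grouping`: list with `tree` (an
#'   [stats::hclust] object), `k`, `membership` (named integer vector),
#'   `group_means` (k x features matrix of unstandardized means) and
#'   `labels` (`NULL` until [label_groups()] is applied).
#' @export
ward_cluster <- function(x, k = 3, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (k < 1 || k > nrow(x)) {
    halo_abort("k must be between 1 and the number of genotypes",
               "halotype_bad_k")
  }
  z <- if (standardize) standardize_features(x) else x
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "ward.D2")
  membership <- stats::cutree(tree, k = k)
  gm <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(x[membership == g, , drop = FALSE])
  }))
  rownames(gm) <- paste0("group", seq_len(k))
  structure(
    list(
      tree = tree, k = k, membership = membership,
      group_means = gm, labels = NULL
    ),
    class = "tolerance_grouping"
  )
}

#' @export
print.tolerance_grouping <- function(x, ...) {
  cat(sprintf(
    "<tolerance_grouping> %d genotypes in %d groups (%s)\n",
    length(x$membership), x$k,
    paste(tabulate(x$membership, x$k), collapse = "/")
  ))
  if (!is.null(x$labels)) {
    lab <- x$labels[x$membership]
    print(table(lab))
  }
  invisible(x)
}

#' Attach tolerance labels to a 3-group clustering
#'
#' Labels the three groups from their feature means: the group with the
#' highest mean GYc *and* highest mean STI is `salt-tolerant`; of the
#' remaining two, the group with the higher YSI and lower SSI is
#' `moderately salt-tolerant`; the last is `salt-sensitive`. If the
#' deciding statistics disagree or tie, an error asks for manual labels.
#'
#' @param grouping a [ward_cluster()] result with `k = 3`.
#' @param group_means optional k x features matrix overriding the means
#'   stored in `grouping` (columns must include `gyc`, `ysi`, `ssi`,
#'   `sti`).
#' @return the grouping with `labels` set (character vector indexed by
#'   group number) and `genotype_labels` (named by genotype).
#' @export
label_groups <- function(grouping, group_means = NULL) {
  stopifnot(inherits(grouping, "tolerance_grouping"))
  if (grouping$k != 3L) {
    halo_abort("tolerance labels are defined for k = 3", "halotype_bad_k")
  }
  gm <- group_means %||% grouping$group_means
  gm <- as.data.frame(gm)
  need <- c("gyc", "ysi", "ssi", "sti")
  if (!all(need %in% names(gm))) {
    halo_abort(
      paste("group means must include", paste(need, collapse = ", ")),
      "halotype_bad_features"
    )
  }
  top_gyc <- which(gm$gyc == max(gm$gyc))
  top_sti <- which(gm$sti == max(gm$sti))
  if (length(top_gyc) != 1L || length(top_sti) != 1L ||
    top_gyc != top_sti) {
    halo_abort(
      "cannot decide the salt-tolerant group (GYc and STI disagree or tie); label manually",
      "halotype_label_tie"
    )
  }
  rest <- setdiff(seq_len(3L), top_gyc)
  hi_ysi <- rest[which(gm$ysi[rest] == max(gm$ysi[rest]))]
  lo_ssi <- rest[which(gm$ssi[rest] == min(gm$ssi[rest]))]
  if (length(hi_ysi) != 1L || length(lo_ssi) != 1L || hi_ysi != lo_ssi) {
    halo_abort(
      "cannot separate moderately salt-tolerant from salt-sensitive (YSI and SSI disagree or tie); label manually",
      "halotype_label_tie"
    )
  }
  labels <- character(3)
  labels[top_gyc] <- "salt-tolerant"
  labels[hi_ysi] <- "moderately salt-tolerant"
  labels[setdiff(rest, hi_ysi)] <- "salt-sensitive"
  grouping$labels <- labels
  grouping$genotype_labels <- stats::setNames(
    labels[grouping$membership], names(grouping$membership)
  )
  grouping
}

#' Cluster and label genotypes from a stress tolerance table
#'
#' Convenience wrapper: takes an [sti_table()] result, clusters on the
#' seven yield features and labels the groups.
#'
#' @param sti an [sti_table()] data.frame.
#' @param k number of groups (labelling requires 3).
#' @return a labelled `tolerance_grouping`.
#' @export
tolerance_groups <- function(sti, k = 3) {
  x <- as.matrix(sti[GROUP_FEATURES])
  rownames(x) <- sti$genotype
  grouping <- ward_cluster(x, k = k)
  if (k == 3) grouping <- label_groups(grouping) else grouping
}

#' Export a clustering dendrogram as Newick
#'
#' Serializes the Ward linkage tree for plotting in standard phylogenetic
#' tools.
#'
#' @param grouping a `tolerance_grouping`.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
export_newick <- function(grouping, path = NULL) {
  stopifnot(inherits(grouping, "tolerance_grouping"))
  phy <- ape::as.phylo(grouping$tree)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
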