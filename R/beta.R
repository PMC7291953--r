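#' Bray-Curtis dissimilarity between all samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over taxa; 0 for identical
#' samples and 1 for samples with disjoint taxon support.
#'
#' @param table a [zotu_table()] (columns are samples).
#' @return A `dist` object labelled by sample id, values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "zotu_table"))
  m <- t(unclass(table))
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "),
         call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

# Edge x tip incidence of a phylo tree: inc[e, t] is TRUE when tip t descends
# from edge e. Edges are processed child-before-parent (postorder).
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  E <- nrow(tree$edge)
  inc <- matrix(FALSE, E, nt)
  ord <- ape::postorder(tree)
  for (e in ord) {
    ch <- tree$edge[e, 2L]
    if (ch <= nt) {
      inc[e, ch] <- TRUE
    } else {
      kids <- which(tree$edge[, 1L] == ch)
      inc[e, ] <- colSums(inc[kids, , drop = FALSE]) > 0
    }
  }
  inc
}

#' Unweighted UniFrac distance between all samples
#'
#' Presence/absence phylogenetic dissimilarity: the branch length leading
#' exclusively to taxa of one of the two samples, divided by the branch
#' length leading to taxa of either sample.
#'
#' @param table a [zotu_table()].
#' @param tree rooted `phylo` with branch lengths containing all table taxa.
#' @return A `dist` object labelled by sample id, values in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "zotu_table"))
  al <- align_table_tree(table, tree, strict = TRUE)
  tree <- al$tree
  m <- unclass(al$table)
  if (any(colSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  # B[e, s]: edge e lies on the path to >= 1 taxon present in sample s
  pres <- (m > 0)[tree$tip.label, , drop = FALSE]
  B <- (inc %*% pres) > 0
  storage.mode(B) <- "double"
  shared <- crossprod(B * len, B)            # sum of len over edges in both
  per_sample <- colSums(B * len)
  union <- outer(per_sample, per_sample, "+") - shared
  d <- 1 - shared / union
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues, so Euclidean-embeddable inputs are reconstructed exactly.
#' Negative eigenvalues are dropped from the coordinates and reported.
#'
#' @param dm a `dist` or symmetric zero-diagonal matrix.
#' @param k maximum number of axes to retain (default all positive axes).
#' @return An object of class `ordination` with `method = "pcoa"`,
#'   `points` (samples x axes), `eigenvalues` (positive, non-increasing),
#'   `negative_eigenvalues` and `relative_eig` (share of the positive total).
#' @export
pcoa <- function(dm, k = NULL) {
  d <- as_dist_checked(dm)
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = n - 1L, eig = TRUE, list. = TRUE)
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-12)
  npos <- length(pos)
  keep <- if (is.null(k)) npos else min(k, npos)
  pts <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(keep))
  rownames(pts) <- attr(d, "Labels") %||% rownames(as.matrix(d))
  out <- list(method = "pcoa", points = pts,
              eigenvalues = eig[pos],
              negative_eigenvalues = eig[eig < 0],
              relative_eig = eig[pos] / sum(eig[pos]))
  class(out) <- "ordination"
  out
}

#' Non-metric multidimensional scaling (nMDS)
#'
#' Minimises Kruskal stress-1 with monotone (pool-adjacent-violators)
#' regression via [vegan::monoMDS()], taking the best solution of a PCoA
#' start plus `n_starts` random starts. Ties are handled by Kruskal's primary
#' approach.
#'
#' @param dm a `dist` or symmetric zero-diagonal matrix.
#' @param k number of ordination dimensions.
#' @param seed integer seed (reproducible starts).
#' @param n_starts number of random starts in addition to the PCoA start.
#' @param max_iter maximum iterations per start.
#' @param tol stress convergence tolerance per start.
#' @return An object of class `ordination` with `method = "nmds"`, `points`,
#'   `stress` (in `[0, 1]`) and `converged` (best start converged?).
#' @export
nmds <- function(dm, k = 2, seed = 1, n_starts = 20, max_iter = 500,
                 tol = 1e-7) {
  d <- as_dist_checked(dm)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- attr(d, "Size")
  best <- with_seed(derive_seed(seed, 307L), {
    init_pcoa <- stats::cmdscale(d, k = k)
    if (ncol(init_pcoa) < k)
      init_pcoa <- cbind(init_pcoa,
                         matrix(stats::rnorm(n * (k - ncol(init_pcoa)),
                                             0, 1e-4),
                                n, k - ncol(init_pcoa)))
    best <- NULL
    for (s in seq_len(n_starts + 1L)) {
      init <- if (s == 1L) init_pcoa else
        matrix(stats::runif(n * k, -1, 1), n, k)
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                            maxit = max_iter, sratmax = 1 - tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    best
  })
  if (best$icause == 1L)
    warning("nMDS reached max_iter before convergence; ",
            "returning best configuration found")
  pts <- best$points
  dimnames(pts) <- list(attr(d, "Labels"), paste0("NMDS", seq_len(k)))
  out <- list(method = "nmds", points = pts, stress = best$stress,
              converged = best$icause != 1L, n_starts = n_starts)
  class(out) <- "ordination"
  out
}

#' @export
print.ordination <- function(x, ...) {
  cat(toupper(x$method), "ordination:", nrow(x$points), "samples,",
      ncol(x$points), "axes\n")
  if (x$method == "nmds")
    cat("  Kruskal stress-1:", format(x$stress, digits = 4), "\n")
  if (x$method == "pcoa")
    cat("  relative eigenvalues:",
        paste(format(utils::head(x$relative_eig, 3L), digits = 3),
              collapse = ", "), "...\n")
  invisible(x)
}

#' @export
plot.ordination <- function(x, groups = NULL, axes = c(1L, 2L), ...) {
  pts <- x$points[, axes, drop = FALSE]
  col <- 1L
  pch <- 19L
  if (!is.null(groups)) {
    g <- as.factor(groups)
    col <- as.integer(g) + 1L
    pch <- 14L + as.integer(g)
  }
  graphics::plot(pts, col = col, pch = pch,
                 xlab = colnames(pts)[1L], ylab = colnames(pts)[2L], ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(as.factor(groups)),
                     col = seq_along(levels(as.factor(groups))) + 1L,
                     pch = 14L + seq_along(levels(as.factor(groups))))
  if (x$method == "nmds")
    graphics::mtext(paste("stress =", format(x$stress, digits = 3)), side = 3)
  invisible(x)
}
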