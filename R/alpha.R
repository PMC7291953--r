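#' Alpha diversity estimators
#'
#' Per-sample diversity indices computed from a vector of taxon counts:
#' observed richness (number of taxa with count > 0), the Shannon index
#' `H = -sum(p_i * log(p_i))` (natural log by default), the bias-corrected
#' Chao1 estimator `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1`/`F2`
#' the numbers of singleton/doubleton taxa, and Faith phylogenetic diversity
#' (PD) — the total branch length of the subtree spanning the present taxa.
#'
#' @param counts named non-negative count vector for one sample.
#' @return A single number.
#' @name alpha_diversity
NULL

#' @rdname alpha_diversity
#' @export
richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' @rdname alpha_diversity
#' @param base logarithm base for Shannon; `exp(1)` (nats, the default) or
#'   2 (bits).
#' @export
shannon <- function(counts, base = exp(1)) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero sample: Shannon undefined", call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' @rdname alpha_diversity
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) return(0)
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("Chao1 requires integer counts", call. = FALSE)
  as.numeric(vegan::estimateR(as.integer(round(counts)))["S.chao1"])
}

#' @rdname alpha_diversity
#' @param tree rooted `phylo` with branch lengths covering all present taxa.
#' @param include_root include the branch path connecting the subtree to the
#'   tree root (the dominant convention); `FALSE` measures only the subtree
#'   spanned by the present tips.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  validate_tree(tree)
  stopifnot(all(counts >= 0))
  if (is.null(names(counts)))
    stop("counts must be named by taxon id for faith_pd", call. = FALSE)
  present <- names(counts)[counts > 0]
  if (length(present) == 0L) return(0)
  miss <- setdiff(present, tree$tip.label)
  if (length(miss))
    stop("taxa present in sample but missing from tree: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  comm <- matrix(as.numeric(counts), nrow = 1L,
                 dimnames = list("s", names(counts)))
  comm <- comm[, tree$tip.label[tree$tip.label %in% colnames(comm)],
               drop = FALSE]
  as.numeric(picante::pd(comm, tree, include.root = include_root)[1L, "PD"])
}

#' Alpha-diversity table for every sample
#'
#' @param table a [zotu_table()].
#' @param tree optional rooted `phylo`; when supplied, Faith PD is added.
#' @param shannon_base,include_root see [alpha_diversity].
#' @return A data.frame with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `chao1` and (with a tree) `faith_pd`.
#' @export
alpha_table <- function(table, tree = NULL, shannon_base = exp(1),
                        include_root = TRUE) {
  stopifnot(inherits(table, "zotu_table"))
  m <- unclass(table)
  out <- data.frame(
    sample_id = colnames(m),
    richness = as.integer(colSums(m > 0)),
    shannon = apply(m, 2L, shannon, base = shannon_base),
    chao1 = apply(m, 2L, chao1),
    stringsAsFactors = FALSE
  )
  if (!is.null(tree)) {
    al <- align_table_tree(table, tree)
    pdres <- picante::pd(t(unclass(al$table)), al$tree,
                         include.root = include_root)
    out$faith_pd <- pdres[match(out$sample_id, rownames(pdres)), "PD"]
  }
  rownames(out) <- NULL
  out
}

#' Rarefaction curves of expected richness
#'
#' Mean observed richness over `reps` independent rarefaction draws at each
#' depth, per sample. Depths exceeding a sample's total are omitted for that
#' sample.
#'
#' @param table a [zotu_table()].
#' @param depths increasing vector of rarefaction depths.
#' @param reps draws per depth.
#' @param seed integer seed.
#' @return Long-format data.frame (`sample_id`, `depth`, `mean_richness`) of
#'   class `rarefaction_curve`.
#' @export
rarefaction_curve <- function(table, depths, reps = 10, seed = 1) {
  stopifnot(inherits(table, "zotu_table"), reps >= 1)
  if (is.unsorted(depths, strictly = TRUE))
    stop("depths must be strictly increasing", call. = FALSE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  m <- unclass(table)
  tot <- colSums(m)
  rows <- list()
  with_seed(derive_seed(seed, 211L), for (d in depths) {
    ok <- which(tot >= d)
    if (!length(ok)) next
    acc <- matrix(0, nrow = reps, ncol = length(ok))
    for (r in seq_len(reps))
      acc[r, ] <- rowSums(vegan::rrarefy(t(m[, ok, drop = FALSE]), d) > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = colnames(m)[ok], depth = d,
      mean_richness = colMeans(acc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  ids <- unique(x$sample_id)
  cols <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")
  graphics::plot(range(x$depth), range(x$mean_richness), type = "n",
                 xlab = "rarefaction depth", ylab = "mean observed richness",
                 ...)
  for (i in seq_along(ids)) {
    sub <- x[x$sample_id == ids[i], ]
    graphics::lines(sub$depth, sub$mean_richness, col = cols[i])
  }
  invisible(x)
}

#' Compact-letter display for group differences in a diversity index
#'
#' Pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests between groups;
#' groups that are not significantly different at `alpha` share a letter
#' (greedy assignment), as used to annotate alpha-diversity box plots.
#'
#' @param values numeric vector (e.g. a column of [alpha_table()]).
#' @param groups factor/character of the same length.
#' @param alpha significance level.
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()].
#' @return Named character vector of letters, one per group level.
#' @export
alpha_group_letters <- function(values, groups, alpha = 0.05,
                                p_adjust = "holm") {
  groups <- as.factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(k, 2L)
  p <- apply(pairs, 2L, function(ix) {
    stats::wilcox.test(values[groups == lev[ix[1L]]],
                       values[groups == lev[ix[2L]]], exact = FALSE)$p.value
  })
  p <- stats::p.adjust(p, method = p_adjust)
  same <- diag(TRUE, k)
  for (j in seq_len(ncol(pairs)))
    same[pairs[1L, j], pairs[2L, j]] <- same[pairs[2L, j], pairs[1L, j]] <-
      p[j] >= alpha
  letters_out <- rep("", k)
  letter_idx <- 0L
  remaining <- seq_len(k)
  while (length(remaining)) {
    letter_idx <- letter_idx + 1L
    seed_grp <- remaining[1L]
    member <- seed_grp
    for (g in setdiff(seq_len(k), seed_grp))
      if (all(same[g, member])) member <- c(member, g)
    letters_out[member] <- paste0(letters_out[member], letters[letter_idx])
    remaining <- setdiff(remaining, seed_grp)
  }
  stats::setNames(letters_out, lev)
}
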