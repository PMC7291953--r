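#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean rank between groups - mean rank within groups) / (M / 2)` with
#' `M = n(n-1)/2` the number of sample pairs. `R` is near 0 when grouping is
#' random and 1 when all between-group dissimilarities exceed all
#' within-group ones. Significance is assessed by permuting group labels;
#' with `exact = TRUE` all `n!` label permutations are enumerated and the
#' p-value is the exact tail probability, otherwise `n_permutations` random
#' permutations are drawn and `p = (count(R_perm >= R_obs) + 1) /
#' (n_permutations + 1)`.
#'
#' @param dm a `dist` or symmetric zero-diagonal matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_permutations number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exact enumerate all label permutations (requires <= 8 samples).
#' @return A list of class `group_test` with `statistic` (R), `p_value`,
#'   `n_permutations` and `method`.
#' @export
anosim <- function(dm, groups, n_permutations = 9999, seed = 1,
                   exact = FALSE) {
  d <- as_dist_checked(dm)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("groups must have one label per sample", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least two samples", call. = FALSE)
  r <- rank(as.vector(d))
  pr <- sample_pairs(n)
  denom <- length(r) / 2
  r_stat <- function(g) {
    within <- g[pr[, 1L]] == g[pr[, 2L]]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  g0 <- as.integer(groups)
  r_obs <- r_stat(g0)
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, function(ix) r_stat(g0[ix]))
    p <- mean(r_perm >= r_obs - 1e-12)
    np <- nrow(perms)
  } else {
    r_perm <- with_seed(derive_seed(seed, 401L),
                        replicate(n_permutations, r_stat(g0[sample.int(n)])))
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_permutations + 1)
    np <- n_permutations
  }
  structure(list(method = "ANOSIM", statistic = r_obs, p_value = p,
                 n_permutations = np, exact = exact),
            class = "group_test")
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson by default, Spearman optionally) between the
#' lower-triangle vectors of two distance matrices over the same samples;
#' significance by jointly permuting the rows and columns of the second
#' matrix. With `exact = TRUE` all `n!` sample permutations are enumerated.
#'
#' @param dm1,dm2 `dist` objects or symmetric matrices over the same samples
#'   (matched by label when both are labelled).
#' @param method correlation type.
#' @param n_permutations,seed,exact as in [anosim()].
#' @return A list of class `group_test` with `statistic` (r), `r_squared`,
#'   `p_value` and `n_permutations`.
#' @export
mantel <- function(dm1, dm2, method = c("pearson", "spearman"),
                   n_permutations = 9999, seed = 1, exact = FALSE) {
  method <- match.arg(method)
  d1 <- as_dist_checked(dm1, "dm1")
  d2 <- as_dist_checked(dm2, "dm2")
  n <- attr(d1, "Size")
  if (attr(d2, "Size") != n)
    stop("dm1 and dm2 differ in size", call. = FALSE)
  l1 <- attr(d1, "Labels")
  l2 <- attr(d2, "Labels")
  m2 <- as.matrix(d2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2))
      stop("dm1 and dm2 cover different samples", call. = FALSE)
    m2 <- m2[l1, l1]
  }
  v1 <- as.matrix(d1)[lower.tri(m2)]
  lw <- lower.tri(m2)
  r_of <- function(perm) {
    stats::cor(v1, m2[perm, perm][lw], method = method)
  }
  r_obs <- r_of(seq_len(n))
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, r_of)
    p <- mean(r_perm >= r_obs - 1e-12)
    np <- nrow(perms)
  } else {
    r_perm <- with_seed(derive_seed(seed, 409L),
                        replicate(n_permutations, r_of(sample.int(n))))
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_permutations + 1)
    np <- n_permutations
  }
  structure(list(method = paste0("Mantel (", method, ")"), statistic = r_obs,
                 r_squared = r_obs^2, p_value = p, n_permutations = np,
                 exact = exact),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4), sep = "")
  if (!is.null(x$r_squared))
    cat(", r^2 = ", format(x$r_squared, digits = 4), sep = "")
  cat(", p = ", format.pval(x$p_value, digits = 4),
      " (", x$n_permutations, if (isTRUE(x$exact)) " exhaustive" else " random",
      " permutations)\n", sep = "")
  invisible(x)
}

#' SIMPER: similarity-percentage decomposition
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions. For each between-group sample pair `(j, k)` the
#' contribution of taxon *i* is `|x_ij - x_ik| / sum_s(x_sj + x_sk)`;
#' contributions are averaged over all between-group pairs, so they sum
#' exactly to the average between-group Bray-Curtis dissimilarity.
#'
#' @param table a [zotu_table()] on the scale the Bray-Curtis matrix was
#'   computed from (typically rarefied counts).
#' @param groups label per sample; exactly two distinct labels.
#' @return A data.frame of class `simper_table`, sorted by decreasing
#'   contribution, with columns `taxon_id`, `average` (mean contribution to
#'   the pairwise dissimilarity), `percent`, `cumulative_percent` and the
#'   mean abundance in each group. The overall average between-group
#'   dissimilarity is in `attr(, "overall")`.
#' @export
simper <- function(table, groups) {
  stopifnot(inherits(table, "zotu_table"))
  m <- unclass(table)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("groups must have one label per sample", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("simper compares exactly two groups (got ",
         length(lev), ")", call. = FALSE)
  ja <- which(groups == lev[1L])
  jb <- which(groups == lev[2L])
  if (!length(ja) || !length(jb))
    stop("each group needs at least one sample", call. = FALSE)
  acc <- numeric(nrow(m))
  npair <- 0L
  for (j in ja) for (k in jb) {
    denom <- sum(m[, j]) + sum(m[, k])
    acc <- acc + abs(m[, j] - m[, k]) / denom
    npair <- npair + 1L
  }
  avg <- acc / npair
  ord <- order(avg, decreasing = TRUE)
  out <- data.frame(taxon_id = rownames(m)[ord], average = avg[ord],
                    percent = 100 * avg[ord] / sum(avg),
                    cumulative_percent = cumsum(100 * avg[ord] / sum(avg)),
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", lev[1L])]] <- rowMeans(m[, ja, drop = FALSE])[ord]
  out[[paste0("mean_", lev[2L])]] <- rowMeans(m[, jb, drop = FALSE])[ord]
  rownames(out) <- NULL
  attr(out, "overall") <- sum(avg)
  attr(out, "groups") <- lev
  class(out) <- c("simper_table", "data.frame")
  out
}

#' @export
print.simper_table <- function(x, n = 10L, ...) {
  g <- attr(x, "groups")
  cat("SIMPER ", g[1L], " vs ", g[2L], ": average between-group ",
      "dissimilarity = ", format(attr(x, "overall"), digits = 4), "\n",
      sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more taxa)\n", sep = "")
  invisible(x)
}

#' Shared and exclusive taxa between sample groups
#'
#' A taxon belongs to a group when it has a positive count in at least one of
#' the group's samples (Venn-diagram counting on post-normalisation
#' presence).
#'
#' @param table a [zotu_table()].
#' @param groups label per sample.
#' @return A list with `exclusive` (named count per group), `shared` (present
#'   in more than one group), `total` (taxa observed in any sample) and
#'   `membership` (logical taxa x group matrix).
#' @export
shared_taxa <- function(table, groups) {
  stopifnot(inherits(table, "zotu_table"))
  m <- unclass(table)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("groups must have one label per sample", call. = FALSE)
  lev <- unique(groups)
  member <- vapply(lev, function(g)
    rowSums(m[, groups == g, drop = FALSE]) > 0, logical(nrow(m)))
  observed <- rowSums(member) > 0
  ngroups <- rowSums(member)
  exclusive <- vapply(seq_along(lev), function(i)
    sum(member[, i] & ngroups == 1L), integer(1L))
  names(exclusive) <- lev
  list(exclusive = exclusive, shared = sum(ngroups > 1L),
       total = sum(observed), membership = member)
}
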