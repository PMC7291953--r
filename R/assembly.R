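#' Patristic (tip-to-tip) distances of a phylogeny
#'
#' The sum of branch lengths along the unique path between every pair of
#' tips.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return Symmetric numeric matrix (taxa x taxa) with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  ape::cophenetic.phylo(tree)
}

#' Weighted beta mean nearest taxon distance (betaMNTD) of one sample pair
#'
#' For communities A and B with relative abundances `f`,
#' `betaMNTD = 0.5 * (sum_{i in A} f_iA * min_{j in B} d(i, j) +
#'                    sum_{j in B} f_jB * min_{i in A} d(i, j))`.
#' A taxon present in both communities has nearest-taxon distance 0
#' (conspecifics are included), so identical communities score 0.
#'
#' @param rel_abund_a,rel_abund_b named relative-abundance vectors (each
#'   summing to 1 over its present taxa).
#' @param patristic patristic distance matrix covering all present taxa (see
#'   [patristic_distances()]).
#' @return The betaMNTD value (non-negative scalar).
#' @export
beta_mntd <- function(rel_abund_a, rel_abund_b, patristic) {
  a <- rel_abund_a[rel_abund_a > 0]
  b <- rel_abund_b[rel_abund_b > 0]
  if (!length(a) || !length(b))
    stop("empty community: betaMNTD undefined", call. = FALSE)
  miss <- setdiff(c(names(a), names(b)), rownames(patristic))
  if (length(miss))
    stop("taxa missing from patristic matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  sub <- patristic[names(a), names(b), drop = FALSE]
  0.5 * (sum(a * apply(sub, 1L, min)) + sum(b * apply(sub, 2L, min)))
}

#' Beta nearest taxon index (betaNTI) for all sample pairs
#'
#' Standardised effect size of the observed betaMNTD against a null
#' distribution obtained by shuffling taxon identities across the tips of the
#' whole metacommunity phylogeny (one joint permutation of the patristic
#' matrix's rows and columns per randomisation, shared by every pair within
#' that randomisation):
#' `betaNTI = (betaMNTD_obs - mean(null)) / sd(null)`.
#' `|betaNTI| > 2` is conventionally read as deterministic selection
#' (positive: heterogeneous, negative: homogeneous). Pairs whose null
#' distribution is degenerate (`sd = 0`, e.g. all taxa equidistant) get
#' `NA` with a warning.
#'
#' @param table a [zotu_table()] (typically rarefied).
#' @param tree rooted `phylo` covering the table taxa; alternatively pass a
#'   pre-computed `patristic` matrix.
#' @param patristic optional patristic matrix (overrides `tree`).
#' @param n_null number of randomisations (default 999).
#' @param seed integer seed; the same seed reproduces the identical null
#'   stream.
#' @param pairs optional 2-column matrix of sample index pairs to evaluate
#'   (default: all pairs).
#' @return A data.frame of class `assembly_pair_stats` with columns
#'   `sample_a`, `sample_b`, `beta_mntd`, `null_mean`, `null_sd`, `beta_nti`,
#'   `n_null`.
#' @export
beta_nti <- function(table, tree = NULL, patristic = NULL, n_null = 999,
                     seed = 1, pairs = NULL) {
  stopifnot(inherits(table, "zotu_table"), n_null >= 1)
  if (is.null(patristic)) {
    if (is.null(tree)) stop("supply a tree or a patristic matrix", call. = FALSE)
    al <- align_table_tree(table, tree, strict = TRUE)
    table <- al$table
    patristic <- patristic_distances(al$tree)
  }
  m <- unclass(table)
  if (!all(rownames(m) %in% rownames(patristic)))
    stop("patristic matrix does not cover all table taxa", call. = FALSE)
  patristic <- patristic[rownames(m), rownames(m)]
  n_taxa <- nrow(m)
  n_samp <- ncol(m)
  W <- t(m) / colSums(m)                       # samples x taxa, rows sum to 1
  if (is.null(pairs)) pairs <- sample_pairs(n_samp)
  perms <- with_seed(derive_seed(seed, 701L), {
    p <- matrix(0L, n_null, n_taxa)
    for (r in seq_len(n_null)) p[r, ] <- sample.int(n_taxa)
    p
  })
  res <- bmntd_engine(patristic, W, pairs, perms)
  null_mean <- colMeans(res$nulls)
  null_sd <- apply(res$nulls, 2L, stats::sd)
  bnti <- ifelse(null_sd > 1e-12,
                 (res$observed - null_mean) / null_sd, NA_real_)
  if (anyNA(bnti))
    warning(sum(is.na(bnti)), " pair(s) with degenerate null distribution ",
            "(sd = 0): betaNTI undefined, recorded as NA")
  out <- data.frame(sample_a = colnames(m)[pairs[, 1L]],
                    sample_b = colnames(m)[pairs[, 2L]],
                    beta_mntd = res$observed, null_mean = null_mean,
                    null_sd = null_sd, beta_nti = bnti, n_null = n_null,
                    stringsAsFactors = FALSE)
  class(out) <- c("assembly_pair_stats", "data.frame")
  out
}

#' Bray-Curtis based Raup-Crick metric (RC-bray) for all sample pairs
#'
#' Compares the observed Bray-Curtis dissimilarity of each pair against a
#' null distribution in which both communities are probabilistically
#' reassembled from the metacommunity: each null community draws its observed
#' richness as distinct taxa with probability proportional to occurrence
#' frequency (number of samples containing the taxon), then distributes its
#' observed read total among the drawn taxa multinomially with probability
#' proportional to metacommunity relative abundance. With `n_null`
#' replicates,
#' `RC = 2 * ((count(null < obs) + 0.5 * count(null == obs)) / n_null) - 1`,
#' so RC is in `[-1, 1]`; values near +1 mean more turnover than expected by
#' chance (dispersal limitation), near -1 less (homogenizing dispersal).
#' Exact ties use an absolute tolerance of `1e-12`.
#'
#' Each unordered pair gets its own RNG stream derived from `seed`, so
#' results do not depend on pair iteration order.
#'
#' @param table a [zotu_table()] of rarefied integer counts (equal depths
#'   make richness and total-read conditioning comparable across samples).
#' @param n_null number of null replicates (default 999).
#' @param seed integer master seed.
#' @param pairs optional 2-column matrix of sample index pairs.
#' @return A data.frame of class `assembly_pair_stats` with columns
#'   `sample_a`, `sample_b`, `bray_curtis`, `rc_bray`, `n_null`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1, pairs = NULL) {
  stopifnot(inherits(table, "zotu_table"), n_null >= 1)
  m <- unclass(table)
  if (any(colSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  occ <- as.numeric(rowSums(m > 0))
  relab <- as.numeric(rowSums(m)) / sum(m)
  rich <- colSums(m > 0)
  tot <- colSums(m)
  pool <- sum(occ > 0)
  if (any(rich > pool))
    stop("sample richness exceeds metacommunity pool size", call. = FALSE)
  n_samp <- ncol(m)
  if (is.null(pairs)) pairs <- sample_pairs(n_samp)
  tol <- 1e-12
  rc <- numeric(nrow(pairs))
  obs <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1L]; b <- pairs[p, 2L]
    lo <- min(a, b); hi <- max(a, b)          # order-invariant stream key
    obs[p] <- sum(abs(m[, a] - m[, b])) / sum(m[, a] + m[, b])
    nulls <- with_seed(
      derive_seed(seed, 100003L + (lo - 1L) * n_samp + hi),
      rc_null_bc(as.integer(n_null), occ, relab,
                 as.integer(rich[lo]), as.integer(tot[lo]),
                 as.integer(rich[hi]), as.integer(tot[hi])))
    rc[p] <- 2 * ((sum(nulls < obs[p] - tol) +
                     0.5 * sum(abs(nulls - obs[p]) <= tol)) / n_null) - 1
  }
  out <- data.frame(sample_a = colnames(m)[pairs[, 1L]],
                    sample_b = colnames(m)[pairs[, 2L]],
                    bray_curtis = obs, rc_bray = rc, n_null = n_null,
                    stringsAsFactors = FALSE)
  class(out) <- c("assembly_pair_stats", "data.frame")
  out
}

#' Five-way partition of community assembly processes
#'
#' Classifies every sample pair by its betaNTI and RC-bray values:
#' \itemize{
#'   \item `beta_nti >  bnti_threshold` — heterogeneous selection
#'   \item `beta_nti < -bnti_threshold` — homogeneous selection
#'   \item otherwise, `rc_bray >  rc_threshold` — dispersal limitation
#'   \item otherwise, `rc_bray < -rc_threshold` — homogenizing dispersal
#'   \item otherwise — (ecological) drift
#' }
#' and reports the fraction of pairs in each class per comparison group.
#' Pairs with missing betaNTI are excluded and counted.
#'
#' @param pair_stats data.frame with columns `sample_a`, `sample_b`,
#'   `beta_nti`, `rc_bray` (e.g. merged output of [beta_nti()] and
#'   [raup_crick_bray()]).
#' @param groups optional named group label per sample (names = sample ids).
#'   When given, pairs are split by `comparison`.
#' @param comparison `"within"` partitions within-group pairs per group,
#'   `"between"` partitions pairs whose samples belong to different groups,
#'   `"all"` pools everything.
#' @param bnti_threshold,rc_threshold classification thresholds (defaults 2
#'   and 0.95, the conventional cutoffs for this framework).
#' @return A data.frame of class `assembly_partition`: one row per comparison
#'   group with the five fractions (summing to 1), `n_pairs`, `n_excluded`
#'   and the thresholds used.
#' @export
partition_processes <- function(pair_stats, groups = NULL,
                                comparison = c("within", "between", "all"),
                                bnti_threshold = 2, rc_threshold = 0.95) {
  comparison <- match.arg(comparison)
  if (bnti_threshold <= 0 || rc_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  need <- c("sample_a", "sample_b", "beta_nti", "rc_bray")
  miss <- setdiff(need, colnames(pair_stats))
  if (length(miss))
    stop("pair_stats lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  classify <- function(bnti, rc) {
    ifelse(bnti > bnti_threshold, "heterogeneous_selection",
    ifelse(bnti < -bnti_threshold, "homogeneous_selection",
    ifelse(rc > rc_threshold, "dispersal_limitation",
    ifelse(rc < -rc_threshold, "homogenizing_dispersal", "drift"))))
  }
  split_sets <- list()
  if (is.null(groups) || comparison == "all") {
    split_sets[["all"]] <- seq_len(nrow(pair_stats))
  } else {
    ga <- groups[pair_stats$sample_a]
    gb <- groups[pair_stats$sample_b]
    if (anyNA(ga) || anyNA(gb))
      stop("groups must be named by sample id and cover every pair",
           call. = FALSE)
    if (comparison == "within") {
      for (g in unique(groups))
        split_sets[[g]] <- which(ga == g & gb == g)
    } else {
      idx <- which(ga != gb)
      if (length(idx)) {
        key <- apply(cbind(ga[idx], gb[idx]), 1L,
                     function(x) paste(sort(x), collapse = "_vs_"))
        for (k in unique(key)) split_sets[[k]] <- idx[key == k]
      }
    }
  }
  classes <- c("heterogeneous_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal", "drift")
  rows <- list()
  for (g in names(split_sets)) {
    idx <- split_sets[[g]]
    if (!length(idx)) next
    bnti <- pair_stats$beta_nti[idx]
    rc <- pair_stats$rc_bray[idx]
    ok <- !is.na(bnti) & !is.na(rc)
    cl <- factor(classify(bnti[ok], rc[ok]), levels = classes)
    frac <- as.numeric(table(cl)) / max(sum(ok), 1L)
    row <- as.data.frame(as.list(stats::setNames(frac, classes)))
    row <- cbind(data.frame(group = g, stringsAsFactors = FALSE), row)
    row$n_pairs <- sum(ok)
    row$n_excluded <- sum(!ok)
    rows[[g]] <- row
  }
  if (!length(rows))
    stop("no sample pairs to classify for comparison '", comparison, "'",
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bnti_threshold") <- bnti_threshold
  attr(out, "rc_threshold") <- rc_threshold
  class(out) <- c("assembly_partition", "data.frame")
  out
}

#' Fit the null-model partition of community assembly processes
#'
#' The package's core estimator. Runs the two-stage null-model framework on a
#' rarefied count table and phylogeny: (1) phylogenetic turnover — weighted
#' betaMNTD with a taxon-shuffling null ([beta_nti()]) — detects
#' selection; (2) for pairs without a selection signal, compositional
#' turnover against a probabilistic-assembly null ([raup_crick_bray()])
#' separates dispersal limitation, homogenizing dispersal and drift. Pair
#' classifications are aggregated into per-group process fractions
#' ([partition_processes()]).
#'
#' @param table a [zotu_table()] of rarefied integer counts.
#' @param tree rooted `phylo` with branch lengths covering the table taxa.
#' @param groups optional group label per sample (named by sample id, or in
#'   table column order).
#' @param comparison see [partition_processes()].
#' @param n_null randomisations for both null models.
#' @param bnti_threshold,rc_threshold classification cutoffs.
#' @param seed master seed.
#' @return An object of class `community_assembly`: list with `pair_stats`
#'   (per-pair betaMNTD, null mean/sd, betaNTI, Bray-Curtis, RC-bray),
#'   `partition` (per-group fractions), `thresholds`, `n_null`, `call`.
#' @examples
#' \donttest{
#' sim <- assemble_samples(scenario_config(n_taxa = 30,
#'   n_samples_per_group = 3, regime = "neutral_drift", depth_mean = 500,
#'   seed = 42))
#' fit <- community_assembly(sim$table, sim$tree,
#'   groups = setNames(sim$metadata$habitat, sim$metadata$sample_id),
#'   n_null = 99, seed = 1)
#' summary(fit)
#' }
#' @export
community_assembly <- function(table, tree, groups = NULL,
                               comparison = c("within", "between", "all"),
                               n_null = 999, bnti_threshold = 2,
                               rc_threshold = 0.95, seed = 1) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(table, "zotu_table"))
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != ncol(table))
        stop("groups must be named by sample id or match column order",
             call. = FALSE)
      groups <- stats::setNames(as.character(groups), colnames(table))
    } else {
      groups <- stats::setNames(as.character(groups), names(groups))
    }
  }
  al <- align_table_tree(table, tree, strict = TRUE)
  # only the pairs the requested comparison classifies are evaluated
  pr <- sample_pairs(ncol(al$table))
  if (!is.null(groups) && comparison != "all") {
    ga <- groups[colnames(al$table)[pr[, 1L]]]
    gb <- groups[colnames(al$table)[pr[, 2L]]]
    keep <- if (comparison == "within") ga == gb else ga != gb
    pr <- pr[keep, , drop = FALSE]
    if (!nrow(pr)) stop("no sample pairs match comparison '", comparison,
                        "'", call. = FALSE)
  }
  bn <- beta_nti(al$table, patristic = patristic_distances(al$tree),
                 n_null = n_null, seed = derive_seed(seed, 1L), pairs = pr)
  rc <- raup_crick_bray(al$table, n_null = n_null,
                        seed = derive_seed(seed, 2L), pairs = pr)
  stats_df <- merge(bn, rc[, c("sample_a", "sample_b", "bray_curtis",
                               "rc_bray")],
                    by = c("sample_a", "sample_b"), sort = FALSE)
  class(stats_df) <- c("assembly_pair_stats", "data.frame")
  part <- partition_processes(stats_df, groups = groups,
                              comparison = comparison,
                              bnti_threshold = bnti_threshold,
                              rc_threshold = rc_threshold)
  out <- list(pair_stats = stats_df, partition = part, groups = groups,
              comparison = comparison, n_null = n_null,
              thresholds = c(bnti = bnti_threshold, rc = rc_threshold),
              seed = seed, call = match.call())
  class(out) <- "community_assembly"
  out
}

#' @export
print.community_assembly <- function(x, ...) {
  cat("Community assembly partition (", nrow(x$pair_stats), " sample pairs, ",
      x$n_null, " randomisations, |betaNTI| > ", x$thresholds[["bnti"]],
      ", |RC| > ", x$thresholds[["rc"]], ")\n", sep = "")
  print.data.frame(x$partition, digits = 3)
  invisible(x)
}

#' @export
summary.community_assembly <- function(object, ...) {
  ps <- object$pair_stats
  cat("Pairs:", nrow(ps), " (", sum(is.na(ps$beta_nti)),
      "with undefined betaNTI )\n")
  cat("betaNTI:  ", paste(format(stats::quantile(ps$beta_nti, c(0, .5, 1),
                                                 na.rm = TRUE), digits = 3),
                          collapse = " / "), " (min/median/max)\n", sep = "")
  cat("RC-bray:  ", paste(format(stats::quantile(ps$rc_bray, c(0, .5, 1)),
                                 digits = 3), collapse = " / "),
      " (min/median/max)\n", sep = "")
  print(object)
  invisible(object)
}

#' @export
coef.community_assembly <- function(object, ...) {
  p <- object$partition
  m <- as.matrix(p[, c("heterogeneous_selection", "homogeneous_selection",
                       "dispersal_limitation", "homogenizing_dispersal",
                       "drift")])
  rownames(m) <- p$group
  m
}

#' @export
plot.community_assembly <- function(x, ...) {
  m <- t(coef(x))
  cols <- grDevices::hcl.colors(5L, "Temps")
  graphics::barplot(m, col = cols, ylab = "fraction of sample pairs",
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", cex = 0.7, bg = "white"),
                    ...)
  invisible(x)
}
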