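#' Run the full community analysis pipeline
#'
#' End-to-end orchestration: validate inputs, min-count filter, rarefy to a
#' common depth, alpha diversity, Bray-Curtis + nMDS, unweighted UniFrac +
#' PCoA, ANOSIM on habitat and size fraction, SIMPER between habitats, Mantel
#' tests of every (or selected) environmental covariate against community
#' dissimilarity, shared-taxon (Venn) counts, and the betaNTI / RC-bray
#' assembly partition within each habitat and between habitats. Every stage
#' is seeded from one master seed, so two runs with identical inputs and seed
#' produce identical numbers (and byte-identical TSV artifacts when
#' `output_dir` is set).
#'
#' @param table a [zotu_table()] of raw counts.
#' @param tree rooted `phylo` with branch lengths. Required: Faith PD,
#'   UniFrac and betaNTI are computed unconditionally; pass them up-front or
#'   use the individual stage functions instead.
#' @param metadata sample metadata (see [sample_metadata]).
#' @param output_dir optional directory; when set, every stage result is
#'   written as TSV plus a `manifest.json` recording package version, seed,
#'   resolved parameters, input checksums and collected warnings.
#' @param min_total_count minimum taxon total (default 4; see
#'   [filter_min_count()]).
#' @param depth rarefaction depth; default `NULL` uses the minimum sample
#'   total after filtering ("lowest number of sequences" policy).
#' @param n_null randomisations for the null models (default 999).
#' @param n_permutations permutations for ANOSIM/Mantel (default 9999).
#' @param bnti_threshold,rc_threshold partition cutoffs.
#' @param covariates covariate columns for the Mantel tests (default: all
#'   numeric metadata columns).
#' @param nmds_starts random starts for the nMDS.
#' @param seed master seed.
#' @param verbose print stage progress with wall time.
#' @return An object of class `pond_analysis`: list with elements `table`
#'   (rarefied), `depth`, `alpha`, `bray`, `unifrac`, `nmds`, `pcoa`,
#'   `anosim_habitat`, `anosim_fraction`, `simper`, `mantel` (one
#'   [group_test][anosim()] per covariate), `shared`, `assembly` (one
#'   [community_assembly()] fit per habitat, each using the habitat's own
#'   metacommunity as null pool), `assembly_within` / `assembly_between`
#'   (per-habitat and cross-habitat partitions), `assembly_pair_stats`
#'   (combined per-pair table), `metadata`, `manifest`.
#' @export
run_analysis <- function(table, tree, metadata, output_dir = NULL,
                         min_total_count = 4, depth = NULL, n_null = 999,
                         n_permutations = 9999, bnti_threshold = 2,
                         rc_threshold = 0.95, covariates = NULL,
                         nmds_starts = 20, seed = 1, verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  warn_log <- character()
  note <- function(stage) {
    if (verbose)
      message(sprintf("[%7.1fs] %s", proc.time()[["elapsed"]] - t0, stage))
  }
  with_warnings <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  stage <- "validate"
  run <- function(stage_name, expr) {
    stage <<- stage_name
    note(stage_name)
    tryCatch(with_warnings(stage_name, expr), error = function(e)
      stop("stage '", stage_name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  run("validate", {
    stopifnot(inherits(table, "zotu_table"))
    if (is.null(tree))
      stop("a rooted tree with branch lengths is required ",
           "(Faith PD, UniFrac and betaNTI are part of this pipeline)")
    validate_tree(tree)
    metadata <- validate_metadata(metadata, table)
  })
  for (p in c(min_total_count, n_null, n_permutations, bnti_threshold,
              rc_threshold, nmds_starts, seed))
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
      stop("stage 'validate' failed: non-numeric pipeline parameter",
           call. = FALSE)

  filtered <- run("filter_min_count", filter_min_count(table, min_total_count))
  depth_used <- if (is.null(depth)) min(colSums(filtered)) else as.integer(depth)
  rar <- run("rarefy", rarefy(filtered, depth_used, seed = derive_seed(seed, 1L)))
  metadata <- metadata[match(colnames(rar), metadata$sample_id), , drop = FALSE]
  al <- run("align_table_tree", align_table_tree(rar, tree, strict = FALSE))
  rar <- al$table
  tree_al <- al$tree

  habitat <- stats::setNames(metadata$habitat, metadata$sample_id)
  fraction <- stats::setNames(metadata$size_fraction, metadata$sample_id)

  alpha <- run("alpha_diversity", alpha_table(rar, tree_al))
  bray <- run("bray_curtis", bray_curtis(rar))
  unif <- run("unweighted_unifrac", unweighted_unifrac(rar, tree_al))
  ord_nmds <- run("nmds", nmds(bray, k = 2, seed = derive_seed(seed, 2L),
                               n_starts = nmds_starts))
  ord_pcoa <- run("pcoa", pcoa(unif))
  an_hab <- run("anosim_habitat",
                anosim(bray, habitat[colnames(rar)],
                       n_permutations = n_permutations,
                       seed = derive_seed(seed, 3L)))
  an_frac <- run("anosim_size_fraction",
                 anosim(bray, fraction[colnames(rar)],
                        n_permutations = n_permutations,
                        seed = derive_seed(seed, 4L)))
  simp <- run("simper", simper(rar, habitat[colnames(rar)]))
  covariates <- covariates %||% covariate_names(metadata)
  mantel_res <- run("mantel", {
    res <- list()
    for (i in seq_along(covariates)) {
      v <- metadata[[covariates[i]]]
      dcov <- stats::dist(stats::setNames(v, metadata$sample_id))
      res[[covariates[i]]] <- mantel(bray, dcov,
                                     n_permutations = n_permutations,
                                     seed = derive_seed(seed, 10L + i))
    }
    res
  })
  shared <- run("shared_taxa", shared_taxa(rar, habitat[colnames(rar)]))
  # within-habitat partitions use each habitat's own metacommunity as the
  # null pool; the cross-habitat partition uses the pooled metacommunity
  assembly <- run("assembly_within", {
    fits <- list()
    for (h in unique(habitat)) {
      ids <- names(habitat)[habitat == h]
      if (length(ids) < 2L) next
      sub <- unclass(rar)[, ids, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      class(sub) <- c("zotu_table", "matrix")
      fits[[h]] <- community_assembly(sub, tree_al, n_null = n_null,
                                      bnti_threshold = bnti_threshold,
                                      rc_threshold = rc_threshold,
                                      seed = derive_seed(seed, 5L +
                                                           match(h, .habitats)))
      fits[[h]]$partition$group <- h
    }
    fits
  })
  assembly_between <- run("assembly_between",
                          community_assembly(rar, tree_al, groups = habitat,
                                             comparison = "between",
                                             n_null = n_null,
                                             bnti_threshold = bnti_threshold,
                                             rc_threshold = rc_threshold,
                                             seed = derive_seed(seed, 9L)))
  assembly_within <- do.call(rbind, lapply(assembly, `[[`, "partition"))
  rownames(assembly_within) <- NULL
  class(assembly_within) <- c("assembly_partition", "data.frame")

  manifest <- list(
    package = "pondassembly",
    version = as.character(utils::packageVersion("pondassembly")),
    seed = seed, min_total_count = min_total_count, depth = depth_used,
    n_null = n_null, n_permutations = n_permutations,
    bnti_threshold = bnti_threshold, rc_threshold = rc_threshold,
    n_taxa_input = nrow(table), n_taxa_rarefied = nrow(rar),
    n_samples = ncol(rar), covariates = covariates,
    dropped_taxa_not_in_tree = al$dropped_taxa,
    warnings = warn_log,
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2)
  )
  out <- list(table = rar, depth = depth_used, alpha = alpha, bray = bray,
              unifrac = unif, nmds = ord_nmds, pcoa = ord_pcoa,
              anosim_habitat = an_hab, anosim_fraction = an_frac,
              simper = simp, mantel = mantel_res, shared = shared,
              assembly = assembly,
              assembly_within = assembly_within,
              assembly_between = assembly_between$partition,
              assembly_pair_stats = rbind(
                cbind(comparison = rep(names(assembly),
                                       vapply(assembly, function(f)
                                         nrow(f$pair_stats), integer(1L))),
                      do.call(rbind, lapply(assembly, `[[`, "pair_stats"))),
                cbind(comparison = "between",
                      assembly_between$pair_stats)),
              metadata = metadata, manifest = manifest)
  class(out) <- "pond_analysis"
  if (!is.null(output_dir)) {
    run("write_artifacts", write_analysis(out, output_dir))
    out$manifest$input_checksums <-
      as.list(tools::md5sum(file.path(output_dir,
                                      c("rarefied_table.tsv", "metadata.tsv"))))
    jsonlite::write_json(out$manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# Write every stage result of a pond_analysis as TSV artifacts.
write_analysis <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name, rn = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
  write_zotu_table(x$table, file.path(dir, "rarefied_table.tsv"))
  write_metadata(x$metadata, file.path(dir, "metadata.tsv"))
  w(x$alpha, "alpha_diversity.tsv")
  w(as.matrix(x$bray), "bray_curtis.tsv", rn = TRUE)
  w(as.matrix(x$unifrac), "unweighted_unifrac.tsv", rn = TRUE)
  w(data.frame(sample_id = rownames(x$nmds$points), x$nmds$points,
               stringsAsFactors = FALSE), "nmds_coordinates.tsv")
  w(data.frame(sample_id = rownames(x$pcoa$points), x$pcoa$points,
               stringsAsFactors = FALSE), "pcoa_coordinates.tsv")
  stats_df <- data.frame(
    test = c("anosim_habitat", "anosim_size_fraction",
             paste0("mantel_", names(x$mantel))),
    statistic = c(x$anosim_habitat$statistic, x$anosim_fraction$statistic,
                  vapply(x$mantel, `[[`, numeric(1L), "statistic")),
    r_squared = c(NA, NA, vapply(x$mantel, `[[`, numeric(1L), "r_squared")),
    p_value = c(x$anosim_habitat$p_value, x$anosim_fraction$p_value,
                vapply(x$mantel, `[[`, numeric(1L), "p_value")),
    nmds_stress = x$nmds$stress,
    stringsAsFactors = FALSE)
  w(stats_df, "group_tests.tsv")
  w(as.data.frame(x$simper), "simper.tsv")
  w(x$assembly_pair_stats, "assembly_pair_stats.tsv")
  w(rbind(x$assembly_within, x$assembly_between), "assembly_partition.tsv")
  venn <- data.frame(region = c(names(x$shared$exclusive), "shared", "total"),
                     n_taxa = c(as.integer(x$shared$exclusive),
                                x$shared$shared, x$shared$total),
                     stringsAsFactors = FALSE)
  w(venn, "shared_taxa.tsv")
  invisible(dir)
}

#' @export
print.pond_analysis <- function(x, ...) {
  cat("pondassembly analysis: ", nrow(x$table), " taxa x ", ncol(x$table),
      " samples (rarefied to ", x$depth, " reads)\n", sep = "")
  cat("  ANOSIM habitat: R = ", format(x$anosim_habitat$statistic, digits = 4),
      ", p = ", format.pval(x$anosim_habitat$p_value, digits = 3), "\n",
      sep = "")
  cat("  nMDS stress: ", format(x$nmds$stress, digits = 3), "\n", sep = "")
  if (length(x$mantel)) {
    r2 <- vapply(x$mantel, `[[`, numeric(1L), "r_squared")
    top <- names(which.max(r2))
    cat("  Mantel: strongest covariate ", top, " (r^2 = ",
        format(max(r2), digits = 3), ")\n", sep = "")
  }
  cat("  Shared taxa: ", x$shared$shared, " of ", x$shared$total, "\n",
      sep = "")
  cat("  Assembly partition (within groups):\n")
  print.data.frame(x$assembly_within, digits = 3)
  invisible(x)
}
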