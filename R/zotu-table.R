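#' Construct a ZOTU count table
#'
#' A `zotu_table` is a non-negative integer matrix of read counts with taxa
#' (ZOTUs — zero-radius operational taxonomic units, i.e. exact denoised
#' amplicon variants) as rows and samples as columns. Row and column names
#' are mandatory and must be unique.
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples.
#' @param taxon_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An integer matrix of class `zotu_table`.
#' @examples
#' zt <- zotu_table(matrix(c(5, 0, 2, 1, 3, 4), 3, 2,
#'   dimnames = list(c("Z1", "Z2", "Z3"), c("s1", "s2"))))
#' zt
#' @export
zotu_table <- function(counts, taxon_ids = rownames(counts),
                       sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids))
    stop("counts must carry taxon (row) and sample (column) identifiers",
         call. = FALSE)
  storage <- counts
  if (!is.numeric(storage)) stop("counts must be numeric", call. = FALSE)
  if (any(!is.finite(storage))) stop("counts must be finite", call. = FALSE)
  if (any(storage < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(storage - round(storage)) > 1e-9))
    stop("counts must be integral read counts", call. = FALSE)
  mode(storage) <- "integer"
  dimnames(storage) <- list(as.character(taxon_ids), as.character(sample_ids))
  dup <- unique(rownames(storage)[duplicated(rownames(storage))])
  if (length(dup))
    stop("duplicated taxon id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(colnames(storage)[duplicated(colnames(storage))])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  class(storage) <- c("zotu_table", "matrix")
  storage
}

#' @export
print.zotu_table <- function(x, ...) {
  cat("ZOTU count table: ", nrow(x), " taxa x ", ncol(x), " samples\n", sep = "")
  tot <- colSums(unclass(x))
  cat("  sample totals: ", min(tot), "-", max(tot),
      "; non-zero taxa: ", sum(rowSums(unclass(x)) > 0), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.zotu_table <- function(x, ...) {
  y <- unclass(x)
  attr(y, "class") <- NULL
  y
}

#' Read a ZOTU count table from a tab-separated file
#'
#' Expects taxa as rows: the first column holds taxon identifiers (header
#' field conventionally `#ZOTU_ID`) and the remaining header fields are
#' sample identifiers. All cells must be non-negative integers.
#'
#' @param path path to a TSV file.
#' @param auto_transpose if `TRUE` and the file has many more columns than
#'   rows (samples apparently as rows), the matrix is transposed with a
#'   warning. Off by default; the on-disk convention is taxa-as-rows.
#' @return A [zotu_table()].
#' @seealso [write_zotu_table()]
#' @export
read_zotu_table <- function(path, auto_transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (ncol(raw) < 2L) stop("expected a taxon-id column plus >=1 sample column",
                           call. = FALSE)
  ids <- as.character(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated taxon id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  samp <- colnames(raw)[-1L]
  dup <- unique(samp[duplicated(samp)])
  if (length(dup))
    stop("duplicated sample id(s) in header of ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- which(!is.finite(suppressWarnings(as.numeric(m))) |
                 abs(as.numeric(m) - round(as.numeric(m))) > 1e-9 |
                 as.numeric(m) < 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop("non-integer count at row ", rc[1L], " (", ids[rc[1L]], "), column ",
         rc[2L], " (", samp[rc[2L]], ") of ", path, call. = FALSE)
  }
  rownames(m) <- ids
  if (auto_transpose && ncol(m) > 3L * nrow(m)) {
    warning("more columns than taxa rows; transposing (auto_transpose = TRUE)")
    m <- t(m)
  }
  zotu_table(m)
}

#' Write a ZOTU count table to a tab-separated file
#'
#' @param table a [zotu_table()].
#' @param path output path; first header field is `#ZOTU_ID`.
#' @return `path`, invisibly.
#' @export
write_zotu_table <- function(table, path) {
  stopifnot(inherits(table, "zotu_table"))
  df <- data.frame(`#ZOTU_ID` = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove low-count taxa
#'
#' Drops every taxon whose total read count over all samples falls below
#' `min_total`. The default of 4 removes ZOTUs supported by fewer than four
#' reads, the usual guard against denoising artefacts.
#'
#' @param table a [zotu_table()].
#' @param min_total minimum total count a taxon must reach to be retained.
#' @return A filtered [zotu_table()] (possibly with zero rows).
#' @export
filter_min_count <- function(table, min_total = 4) {
  stopifnot(inherits(table, "zotu_table"), min_total >= 0)
  keep <- rowSums(unclass(table)) >= min_total
  out <- unclass(table)[keep, , drop = FALSE]
  class(out) <- c("zotu_table", "matrix")
  out
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`, normalising sampling effort across
#' samples. A single draw is taken per sample. Samples whose total is below
#' `depth` are dropped with a warning. Taxa left with zero reads everywhere
#' are removed.
#'
#' @param table a [zotu_table()].
#' @param depth target reads per sample; defaults to the minimum sample total
#'   ("lowest number of sequences" policy).
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return A rarefied [zotu_table()] whose column sums all equal `depth`.
#' @export
rarefy <- function(table, depth = min(colSums(table)), seed = 1) {
  stopifnot(inherits(table, "zotu_table"))
  if (length(depth) != 1L || !is.finite(depth) || depth <= 0)
    stop("depth must be a single positive integer", call. = FALSE)
  depth <- as.integer(round(depth))
  tot <- colSums(unclass(table))
  low <- tot < depth
  if (any(low)) {
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[low], collapse = ", "))
    table <- unclass(table)[, !low, drop = FALSE]
  } else {
    table <- unclass(table)
  }
  if (ncol(table) == 0L) stop("no samples at or above depth ", depth, call. = FALSE)
  # rrarefy heuristically warns when the smallest count exceeds 1; raw counts
  # here are genuine reads, so that advisory is noise
  rar <- with_seed(derive_seed(seed, 101L), withCallingHandlers(
    t(vegan::rrarefy(t(table), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  keep <- rowSums(rar) > 0
  zotu_table(rar[keep, , drop = FALSE])
}

#' Reconcile a count table with a phylogeny
#'
#' Prunes the tree to the taxa present in the table and (in non-strict mode)
#' drops table taxa that are absent from the tree.
#'
#' @param table a [zotu_table()].
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param strict if `TRUE` (default) any table taxon missing from the tree is
#'   an error; if `FALSE`, such taxa are dropped with a warning.
#' @return A list with elements `table`, `tree`, and `dropped_taxa`.
#' @export
align_table_tree <- function(table, tree, strict = TRUE) {
  stopifnot(inherits(table, "zotu_table"), inherits(tree, "phylo"))
  common <- intersect(rownames(table), tree$tip.label)
  if (length(common) == 0L)
    stop("table taxa and tree tips are disjoint", call. = FALSE)
  missing_tips <- setdiff(rownames(table), tree$tip.label)
  if (length(missing_tips)) {
    if (strict)
      stop(length(missing_tips), " table taxon/taxa missing from tree: ",
           paste(utils::head(missing_tips, 5L), collapse = ", "),
           if (length(missing_tips) > 5L) ", ..." else "", call. = FALSE)
    warning("dropping ", length(missing_tips), " table taxon/taxa absent from tree")
  }
  tab <- unclass(table)[common, , drop = FALSE]
  class(tab) <- c("zotu_table", "matrix")
  drop <- setdiff(tree$tip.label, common)
  tr <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  list(table = tab, tree = tr, dropped_taxa = missing_tips)
}
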