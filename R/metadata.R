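#' @name sample_metadata
#' @title Sample metadata
#'
#' @description Sample metadata is a plain `data.frame` with one row per
#' sample and mandatory columns `sample_id`, `habitat` (one of `"MP"` — melt
#' pond — or `"SW"` — sea water) and `size_fraction` (one of `"micro"`,
#' `"nano"`, `"pico"`). Any additional numeric columns are treated as
#' environmental covariates (salinity, temperature, nutrients, ...).
NULL

.habitats <- c("MP", "SW")
.size_fractions <- c("micro", "nano", "pico")

#' Validate sample metadata, optionally against a count table
#'
#' @param metadata a data.frame; see [sample_metadata].
#' @param table optional [zotu_table()]; every sample of the table must have
#'   exactly one metadata row.
#' @return The metadata, with rows ordered to match `table` when given.
#' @export
validate_metadata <- function(metadata, table = NULL) {
  req <- c("sample_id", "habitat", "size_fraction")
  miss <- setdiff(req, colnames(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  metadata$sample_id <- as.character(metadata$sample_id)
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup))
    stop("duplicated sample_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.character(metadata$habitat)), .habitats)
  if (length(bad))
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.habitats, collapse = ", "), ")", call. = FALSE)
  bad <- setdiff(unique(as.character(metadata$size_fraction)), .size_fractions)
  if (length(bad))
    stop("unknown size_fraction label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.size_fractions, collapse = ", "), ")",
         call. = FALSE)
  if (!is.null(table)) {
    miss <- setdiff(colnames(table), metadata$sample_id)
    if (length(miss))
      stop("sample(s) in table without metadata: ",
           paste(miss, collapse = ", "), call. = FALSE)
    metadata <- metadata[match(colnames(table), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  metadata
}

#' Read sample metadata from a tab-separated file
#'
#' @param path TSV with columns `sample_id`, `habitat`, `size_fraction` and
#'   optional numeric covariates.
#' @return A validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(md) == 0L) stop("no data rows in ", path, call. = FALSE)
  validate_metadata(md)
}

#' Write sample metadata to a tab-separated file
#' @param metadata validated metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Numeric covariate columns of a metadata table
#' @param metadata validated metadata data.frame.
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(metadata) {
  cand <- setdiff(colnames(metadata), c("sample_id", "habitat", "size_fraction"))
  cand[vapply(metadata[cand], is.numeric, logical(1L))]
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the downstream
#' phylogenetic statistics (Faith PD, unweighted UniFrac, betaMNTD) require:
#' a rooted tree, unique tip labels, and non-negative branch lengths on every
#' edge.
#'
#' @param path newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path, call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree a `phylo` object to validate in place.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; PD, UniFrac and betaMNTD are undefined",
         call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicated tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  tree
}

#' Write a phylogeny as newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
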