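test_that("TSV round trip preserves a count table cell for cell", {
  zt <- zotu_table(matrix(c(5L, 0L, 2L, 1L, 3L, 4L), 3, 2,
                          dimnames = list(c("Z1", "Z2", "Z3"),
                                          c("s1", "s2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_zotu_table(zt, path)
  back <- read_zotu_table(path)
  expect_identical(unclass(back), unclass(zt))
  expect_identical(readLines(path)[1], "#ZOTU_ID\ts1\ts2")
})

test_that("reader rejects malformed tables with informative errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#ZOTU_ID\ts1\ts2", p)
  expect_error(read_zotu_table(p), "no data rows")

  writeLines(c("#ZOTU_ID\ts1\ts1", "Z1\t1\t2"), p)
  expect_error(read_zotu_table(p), "s1")

  writeLines(c("#ZOTU_ID\ts1", "Z1\t1", "Z1\t2"), p)
  expect_error(read_zotu_table(p), "Z1")

  writeLines(c("#ZOTU_ID\ts1\ts2", "Z1\t1\t2", "Z2\t1.5\t2"), p)
  expect_error(read_zotu_table(p), "row 2.*Z2.*column 1.*s1")

  expect_error(read_zotu_table(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("zotu_table constructor enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(zotu_table(m), "zotu_table")
  expect_error(zotu_table(matrix(1:4, 2, 2)), "identifiers")
  m2 <- m; m2[1, 1] <- -1
  expect_error(zotu_table(m2), "non-negative")
  m3 <- m; m3[1, 1] <- 1.5
  expect_error(zotu_table(m3), "integral")
})

test_that("min-count filter keeps exactly the taxa at or above the threshold", {
  zt <- zotu_table(matrix(c(1L, 2L, 2L, 2L, 5L, 5L), 3, 2, byrow = TRUE,
                          dimnames = list(c("lo", "mid", "hi"),
                                          c("s1", "s2"))))
  # taxon totals 3, 4, 10: "fewer than four reads" removed at the default
  kept <- filter_min_count(zt)
  expect_identical(rownames(kept), c("mid", "hi"))
  expect_identical(unclass(filter_min_count(zt, 0)), unclass(zt))
  empty <- filter_min_count(zt, 100)
  expect_identical(nrow(empty), 0L)
})

test_that("rarefaction hits the target depth exactly and preserves support", {
  set.seed(11)
  zt <- random_table(25, 6, max_count = 50)
  depth <- min(colSums(zt))
  rar <- rarefy(zt, depth, seed = 3)
  expect_true(all(colSums(rar) == depth))
  # support preservation: zeros stay zeros
  common <- intersect(rownames(rar), rownames(zt))
  expect_true(all(unclass(zt)[common, ][unclass(rar)[common, ] > 0] > 0))
  # exhaustive draw leaves the minimum-depth sample unchanged
  jmin <- which.min(colSums(zt))
  expect_identical(unclass(rar)[common, colnames(zt)[jmin]],
                   unclass(zt)[common, jmin])
})

test_that("rarefaction is reproducible under a fixed seed and varies across seeds", {
  set.seed(2)
  zt <- random_table(30, 4, max_count = 60)
  depth <- floor(min(colSums(zt)) / 2)
  r1 <- rarefy(zt, depth, seed = 7)
  r2 <- rarefy(zt, depth, seed = 7)
  expect_identical(r1, r2)
  r3 <- rarefy(zt, depth, seed = 8)
  expect_false(identical(unclass(r1), unclass(r3)))
  expect_error(rarefy(zt, 0), "positive")
  # samples below depth are dropped with a warning
  expect_warning(rr <- rarefy(zt, min(colSums(zt)) + 1, seed = 1), "dropping")
  expect_false(colnames(zt)[which.min(colSums(zt))] %in% colnames(rr))
})

test_that("expected rarefied counts track depth * proportion", {
  counts <- c(A = 500L, B = 300L, C = 150L, D = 50L)
  zt <- zotu_table(matrix(counts, ncol = 1,
                          dimnames = list(names(counts), "s1")))
  depth <- 200L
  reps <- 400L
  acc <- matrix(0, reps, length(counts))
  for (r in seq_len(reps)) {
    rr <- rarefy(zt, depth, seed = r)
    v <- stats::setNames(rep(0L, length(counts)), names(counts))
    v[rownames(rr)] <- unclass(rr)[, 1]
    acc[r, ] <- v
  }
  expected <- depth * counts / sum(counts)
  se <- apply(acc, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(acc) - expected) < 3 * se + 1e-9))
})

test_that("table/tree reconciliation prunes, reports and errors as specified", {
  zt <- random_table(2, 2)
  tr <- ape::read.tree(text = "((Z1:1,Z2:1):1,Z3:2);")
  al <- align_table_tree(zt, tr)
  expect_setequal(al$tree$tip.label, c("Z1", "Z2"))
  expect_length(al$dropped_taxa, 0)

  al2 <- align_table_tree(zotu_table(unclass(zt)[1:2, ]), tr)
  expect_identical(sort(rownames(al2$table)), c("Z1", "Z2"))

  zt_extra <- random_table(4, 2)  # Z4 not in tree
  expect_error(align_table_tree(zt_extra, tr, strict = TRUE), "Z4")
  expect_warning(al3 <- align_table_tree(zt_extra, tr, strict = FALSE),
                 "dropping")
  expect_identical(al3$dropped_taxa, "Z4")

  tr_disjoint <- ape::read.tree(text = "((X1:1,X2:1):1,X3:2);")
  expect_error(align_table_tree(zt, tr_disjoint), "disjoint")
})

test_that("newick reader validates what the phylogenetic statistics need", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", p)
  tr <- read_tree(p)
  expect_identical(ape::Ntip(tr), 3L)
  expect_equal(sum(tr$edge.length), 5)

  writeLines("((A,B),C);", p)
  expect_error(read_tree(p), "branch lengths")

  # write-then-read round trip preserves topology and lengths
  set.seed(5)
  tr20 <- random_tree(20)
  write_tree(tr20, p)
  back <- read_tree(p)
  expect_true(ape::all.equal.phylo(tr20, back, tolerance = 1e-8))
})

test_that("metadata validation enforces the closed vocabularies", {
  md <- data.frame(sample_id = c("a", "b"), habitat = c("MP", "SW"),
                   size_fraction = c("micro", "pico"), salinity = c(2, 29))
  expect_silent(validate_metadata(md))
  expect_identical(covariate_names(md), "salinity")

  bad <- md; bad$habitat[1] <- "lake"
  expect_error(validate_metadata(bad), "lake")
  bad2 <- md; bad2$size_fraction[2] <- "huge"
  expect_error(validate_metadata(bad2), "huge")

  zt <- random_table(3, 3)
  expect_error(validate_metadata(md, zt), "s1")

  p <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, p)
  expect_identical(read_metadata(p)$habitat, md$habitat)
})
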