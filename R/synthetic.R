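#' Configure a synthetic metacommunity scenario
#'
#' Defines the generative conditions for a two-habitat (melt pond `MP` vs.
#' sea water `SW`), three-size-fraction metacommunity with a known assembly
#' regime, so that the downstream statistics can be tested against ground
#' truth. Abundances in the regional species pool are lognormal; habitat
#' preference is a phylogenetically conserved trait evolved by Brownian
#' motion on a Yule tree; selection acts through a Gaussian niche filter.
#'
#' Regimes:
#' \describe{
#'   \item{`selection`}{sampling weight of taxon *i* in sample *s* is
#'     proportional to `m_i * exp(-(trait_i - env_s)^2 / (2 * filter_width^2))`
#'     where `m_i` is the lognormal pool abundance and `env_s` the habitat
#'     optimum; the two habitats get distinct optima, so between-habitat
#'     comparisons experience heterogeneous selection.}
#'   \item{`dispersal_limited`}{samples fall into spatial clusters of
#'     `cluster_size`; each cluster draws neutrally from its own random
#'     subset of the pool (`subset_fraction` of all taxa), emulating
#'     restricted exchange between localities. With `cluster_size = 1` every
#'     sample has an independent subset — note that independent uniform
#'     subsets coincide with the Raup-Crick null itself, so turnover is then
#'     *not* expected to exceed the null.}
#'   \item{`neutral_drift`}{every sample is an independent multinomial draw
#'     from the one shared pool; with `drift_sigma > 0` each sample's
#'     expected relative abundances first receive independent lognormal
#'     wobble — the "stochastic changes in relative abundance" that
#'     constitute ecological drift. (With `drift_sigma = 0` samples are exact
#'     multinomial replicates, which the Raup-Crick null reads as
#'     *homogenizing dispersal*: observed turnover is then systematically
#'     below the richness-conditioned null.)}
#'   \item{`mixed`}{SW samples are generated under `dispersal_limited`, MP
#'     samples under `neutral_drift` — the qualitative contrast expected
#'     between open sea water and isolated melt ponds.}
#' }
#'
#' Sample depths are Poisson(`depth_mean`). The salinity covariate is the
#' habitat mean (SW around 29, closed melt ponds around 2.5) plus Gaussian
#' noise, and a habitat-linked temperature covariate is also emitted.
#'
#' @param n_taxa number of taxa in the regional pool (>= 4).
#' @param n_samples_per_group samples per habitat (>= 2).
#' @param regime one of `"selection"`, `"dispersal_limited"`,
#'   `"neutral_drift"`, `"mixed"`.
#' @param trait_sigma Brownian-motion rate (trait sd per unit branch length).
#' @param filter_width Gaussian niche breadth of the selection filter.
#' @param env_by_habitat named numeric, environmental optimum per habitat.
#' @param lognormal_mu,lognormal_sigma log-scale mean and sd of pool
#'   abundances.
#' @param depth_mean mean sequencing depth per sample.
#' @param subset_fraction fraction of the pool available to each cluster under
#'   dispersal limitation.
#' @param cluster_size samples per spatial cluster under dispersal limitation
#'   (clusters are formed within habitats).
#' @param drift_sigma sd of the per-sample lognormal wobble applied to the
#'   expected relative abundances in every regime (ecological drift; 0
#'   disables it).
#' @param habitat_pool_fraction named numeric in (0, 1]; fraction of the pool
#'   accessible to each habitat (1 = whole pool). Values below 1 emulate a
#'   species-poor habitat (e.g. fewer melt-pond source taxa).
#' @param salinity_by_habitat,salinity_sd salinity means per habitat and
#'   noise sd.
#' @param seed master seed for the whole scenario.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 100,
                            n_samples_per_group = 8,
                            regime = c("selection", "dispersal_limited",
                                       "neutral_drift", "mixed"),
                            trait_sigma = 1,
                            filter_width = 0.5,
                            env_by_habitat = c(MP = -2, SW = 2),
                            lognormal_mu = 0,
                            lognormal_sigma = 1.5,
                            depth_mean = 5000,
                            subset_fraction = 0.25,
                            cluster_size = 2,
                            drift_sigma = 0.15,
                            habitat_pool_fraction = c(MP = 1, SW = 1),
                            salinity_by_habitat = c(MP = 2.5, SW = 29),
                            salinity_sd = 1.5,
                            seed = 1) {
  regime <- match.arg(regime)
  cfg <- list(n_taxa = as.integer(n_taxa),
              n_samples_per_group = as.integer(n_samples_per_group),
              regime = regime, trait_sigma = trait_sigma,
              filter_width = filter_width, env_by_habitat = env_by_habitat,
              lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
              depth_mean = as.integer(depth_mean),
              subset_fraction = subset_fraction,
              cluster_size = as.integer(cluster_size),
              drift_sigma = drift_sigma,
              habitat_pool_fraction = habitat_pool_fraction,
              salinity_by_habitat = salinity_by_habitat,
              salinity_sd = salinity_sd, seed = as.integer(seed))
  if (cfg$n_taxa < 4L) stop("n_taxa must be >= 4", call. = FALSE)
  if (cfg$n_samples_per_group < 2L)
    stop("n_samples_per_group must be >= 2", call. = FALSE)
  for (p in c("trait_sigma", "filter_width", "lognormal_sigma",
              "subset_fraction", "salinity_sd", "drift_sigma"))
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 0)
      stop(p, " must be a non-negative number", call. = FALSE)
  if (cfg$subset_fraction <= 0 || cfg$subset_fraction > 1)
    stop("subset_fraction must be in (0, 1]", call. = FALSE)
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive", call. = FALSE)
  if (cfg$cluster_size < 1L) stop("cluster_size must be >= 1", call. = FALSE)
  if (!all(.habitats %in% names(cfg$env_by_habitat)))
    stop("env_by_habitat must name every habitat: ",
         paste(.habitats, collapse = ", "), call. = FALSE)
  if (!all(.habitats %in% names(cfg$habitat_pool_fraction)))
    stop("habitat_pool_fraction must name every habitat", call. = FALSE)
  if (any(cfg$habitat_pool_fraction <= 0 | cfg$habitat_pool_fraction > 1))
    stop("habitat_pool_fraction values must be in (0, 1]", call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return A rooted `phylo` with `n_taxa` tips labelled `Z1..Zn` and strictly
#'   positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2", call. = FALSE)
  tree <- with_seed(derive_seed(seed, 11L),
                    ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- paste0("Z", seq_len(n_taxa))
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  validate_tree(tree)
}

#' Evolve a continuous trait by Brownian motion
#'
#' Simulates a trait from a root value of 0 along the tree; the variance of a
#' tip value equals `trait_sigma^2` times its root-to-tip path length, and
#' the covariance of two tips equals `trait_sigma^2` times their shared path.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param trait_sigma Brownian rate; 0 yields all-zero traits.
#' @param seed integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
evolve_trait_bm <- function(tree, trait_sigma = 1, seed = 1) {
  validate_tree(tree)
  if (trait_sigma < 0) stop("trait_sigma must be >= 0", call. = FALSE)
  if (trait_sigma == 0 || sum(tree$edge.length) == 0) {
    tr <- rep(0, length(tree$tip.label))
    names(tr) <- tree$tip.label
    return(tr)
  }
  with_seed(derive_seed(seed, 13L),
            ape::rTraitCont(tree, model = "BM", sigma = trait_sigma,
                            root.value = 0))
}

#' Assemble synthetic samples under a known regime
#'
#' Draws the regional pool abundances, builds per-sample sampling weights
#' according to the configured regime (see [scenario_config()]), and samples
#' each community multinomially at a Poisson depth.
#'
#' @param config a [scenario_config()].
#' @param tree optional pre-built phylogeny (one is simulated from the
#'   config seed when omitted).
#' @param traits optional named trait vector (evolved on `tree` when omitted).
#' @return A list of class `synthetic_community` with elements `table`
#'   ([zotu_table()]), `metadata` (see [sample_metadata]), `tree`, `traits`,
#'   `pool` (pool relative abundances) and `truth` (per-sample regime label
#'   and environment value).
#' @export
assemble_samples <- function(config, tree = NULL, traits = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n_taxa <- config$n_taxa
  if (is.null(tree)) tree <- simulate_tree(n_taxa, seed = config$seed)
  validate_tree(tree)
  if (length(tree$tip.label) != n_taxa)
    stop("tree tip count does not match n_taxa", call. = FALSE)
  if (is.null(traits))
    traits <- evolve_trait_bm(tree, config$trait_sigma, seed = config$seed)
  if (!all(tree$tip.label %in% names(traits)))
    stop("traits must be defined for every tip", call. = FALSE)
  traits <- traits[tree$tip.label]
  taxa <- tree$tip.label

  with_seed(derive_seed(config$seed, 17L), {
  pool <- stats::rlnorm(n_taxa, config$lognormal_mu, config$lognormal_sigma)
  pool <- pool / sum(pool)
  names(pool) <- taxa

  nps <- config$n_samples_per_group
  habitat <- rep(.habitats, each = nps)
  sample_ids <- paste0(habitat, rep(seq_len(nps), times = 2L))
  size_fraction <- rep_len(.size_fractions, 2L * nps)
  n_samp <- length(sample_ids)

  # per-habitat pool restriction (optional species-poor habitat)
  hab_mask <- sapply(.habitats, function(h) {
    f <- config$habitat_pool_fraction[[h]]
    if (f >= 1) return(rep(TRUE, n_taxa))
    m <- rep(FALSE, n_taxa)
    m[sample.int(n_taxa, max(4L, round(f * n_taxa)))] <- TRUE
    m
  })

  regime_of <- function(h) {
    if (config$regime != "mixed") return(config$regime)
    if (h == "SW") "dispersal_limited" else "neutral_drift"
  }

  # spatial clusters (dispersal limitation): consecutive samples within a
  # habitat share one pool subset. Subsets are "dealt" from random
  # permutations of the pool so that different clusters harbor maximally
  # complementary taxon sets (allopatric structure); overlap only arises
  # where the deal wraps around the pool.
  within_idx <- stats::ave(seq_len(n_samp), habitat, FUN = seq_along)
  cluster_id <- paste0(habitat, "_c", ceiling(within_idx / config$cluster_size))
  n_subset <- max(2L, round(config$subset_fraction * n_taxa))
  clusters <- unique(cluster_id)
  deck <- integer(0)
  while (length(deck) < length(clusters) * n_subset)
    deck <- c(deck, sample.int(n_taxa))
  cluster_subset <- stats::setNames(lapply(seq_along(clusters), function(c)
    unique(deck[seq((c - 1L) * n_subset + 1L, c * n_subset)])), clusters)

  counts <- matrix(0L, n_taxa, n_samp, dimnames = list(taxa, sample_ids))
  env <- numeric(n_samp)
  regime_lab <- character(n_samp)
  for (s in seq_len(n_samp)) {
    h <- habitat[s]
    reg <- regime_of(h)
    regime_lab[s] <- reg
    env[s] <- config$env_by_habitat[[h]]
    w <- pool
    w[!hab_mask[, h]] <- 0
    if (reg == "selection") {
      w <- w * exp(-(traits - env[s])^2 / (2 * config$filter_width^2))
    } else if (reg == "dispersal_limited") {
      mask <- rep(FALSE, n_taxa)
      mask[cluster_subset[[cluster_id[s]]]] <- TRUE
      w[!mask] <- 0
    }
    if (sum(w) <= 0)
      stop("sampling weights degenerate for sample ", sample_ids[s],
           " (filter too narrow for the trait range?)", call. = FALSE)
    # ecological drift: per-sample stochastic wobble of relative abundances
    if (config$drift_sigma > 0)
      w <- w * exp(stats::rnorm(n_taxa, 0, config$drift_sigma))
    depth <- stats::rpois(1L, config$depth_mean)
    counts[, s] <- stats::rmultinom(1L, depth, w / sum(w))
  }

  salinity <- config$salinity_by_habitat[habitat] +
    stats::rnorm(n_samp, 0, config$salinity_sd)
  temperature <- ifelse(habitat == "SW", 2.5, -0.3) +
    stats::rnorm(n_samp, 0, ifelse(habitat == "SW", 2, 0.5))
  })  # end of the scenario's seeded block

  metadata <- data.frame(sample_id = sample_ids, habitat = habitat,
                         size_fraction = size_fraction,
                         salinity = as.numeric(salinity),
                         temperature = as.numeric(temperature),
                         stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_ids, regime = regime_lab,
                      environment = env, cluster = cluster_id,
                      stringsAsFactors = FALSE)
  out <- list(table = zotu_table(counts), metadata = validate_metadata(metadata),
              tree = tree, traits = traits, pool = pool, truth = truth,
              config = config)
  class(out) <- "synthetic_community"
  out
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("Synthetic metacommunity (regime: ", x$config$regime, ", seed ",
      x$config$seed, ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Generate a synthetic scenario and write it to disk
#'
#' Writes `zotu_table.tsv`, `tree.nwk`, `metadata.tsv`, `ground_truth.tsv`
#' and a `manifest.json` (seed, config, file list) into `dir`; the files are
#' readable back through [read_zotu_table()], [read_tree()] and
#' [read_metadata()].
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if missing).
#' @return The [assemble_samples()] bundle, invisibly, with a `paths`
#'   attribute naming the written files.
#' @export
run_synthetic <- function(config, dir) {
  stopifnot(inherits(config, "scenario_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- assemble_samples(config)
  paths <- c(table = file.path(dir, "zotu_table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_zotu_table(sim$table, paths[["table"]])
  write_tree(sim$tree, paths[["tree"]])
  write_metadata(sim$metadata, paths[["metadata"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(generator = "pondassembly::run_synthetic",
                   version = as.character(utils::packageVersion("pondassembly")),
                   seed = config$seed,
                   config = unclass(config),
                   files = as.list(basename(paths[-5L])))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(sim, "paths") <- paths
  invisible(sim)
}
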