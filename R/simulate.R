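# synthetic_data: generator for phylogenies, community tables and
# metadata with controllable assembly regimes, spatial gradients and
# planted co-occurrence modules. Every analysis stage gets a
# ground-truth oracle without any external data.
#
# The emulated design: ~24 sites along a single large river (position =
# distance to mouth, km), two seasons, thousands-to-hundreds of taxa
# with lognormal regional abundances, phylogenetically conserved niches
# (Brownian motion on the tree), an along-river environmental gradient,
# and optional dispersal limitation via per-taxon home sites.

#' Simulation configuration
#'
#' Defaults describe a mixed, realistic regime at desk scale (300 taxa,
#' 24 sites x 2 seasons, 20,000 reads/sample). The `regime` presets pin
#' the four canonical assembly scenarios used for ground-truth
#' validation:
#' \describe{
#'   \item{heterogeneous_selection}{strong phylogenetically conserved
#'     selection (`selection_strength = 20`) along a site-varying
#'     environmental gradient; no dispersal limitation.}
#'   \item{homogeneous_selection}{strong selection under an identical
#'     environment at every site and season, with the shared optimum
#'     displaced off the trait-distribution centre
#'     (`selection_env_offset = 1.5`): a uniformly harsh filter
#'     selecting a derived tolerant clade, which is what concentrates
#'     the filter phylogenetically. Demographic drift within the
#'     filtered pool (`drift_sdlog = 2`) and a finite local community
#'     (`local_community_size = 150`) supply the taxonomic turnover
#'     without which homogeneous selection is undetectable: taxa shared
#'     by two samples contribute zero to betaMNTD under every tip
#'     shuffle, so near-identical communities carry no signal. The
#'     filter also flattens regional abundances (`lognormal_sdlog =
#'     1`).}
#'   \item{dispersal_limitation}{no selection; taxa have home sites and
#'     an exponential dispersal kernel (`dispersal_decay = 0.01`/km).}
#'   \item{neutral}{no selection, well-mixed pool: every sample is a
#'     multinomial draw from the shared regional distribution.}
#' }
#'
#' @param n_sites Number of sites along the river (default 24).
#' @param n_seasons 1 or 2 (spring, autumn).
#' @param replicates_per_site Samples per site x season (1-4).
#' @param n_taxa Number of taxa (tree tips).
#' @param depth Reads per sample.
#' @param lognormal_meanlog,lognormal_sdlog Regional log-abundance
#'   distribution; `sdlog = 2` gives the heavy rare-biosphere tail.
#' @param selection_strength Niche selection strength `alpha >= 0`.
#' @param niche_breadth Niche width `sigma` (on the z-scored
#'   environment axis).
#' @param niche_conservatism `"brownian"` (phylogenetically conserved
#'   optima) or `"shuffled"` (signal destroyed).
#' @param dispersal_decay Exponential dispersal decay `lambda` per km
#'   (0 = well mixed).
#' @param selection_gradient Scale of the between-site environmental
#'   gradient on the selection axis (0 = identical environments).
#' @param selection_env_offset Constant displacement of the selection
#'   axis from the trait-distribution centre (default 0).
#' @param drift_sdlog sdlog of independent per-sample, per-taxon
#'   lognormal multipliers on the sampling weights: ecological drift /
#'   compositional overdispersion beyond multinomial noise (default 0,
#'   the pure well-mixed case).
#' @param local_community_size Finite number of individuals in the
#'   local community (Hubbell-style): the site's community is first
#'   assembled as a multinomial draw of this many individuals from the
#'   sampling weights, and reads are then sequenced from that local
#'   composition. `Inf` (default) sequences the weights directly.
#'   Finite values create realistic presence/absence turnover that no
#'   sequencing depth can undo.
#' @param season_env_shift Seasonal offset on the selection axis.
#' @param river_length_km River length (default 4300).
#' @param n_modules,module_size,module_correlation Planted
#'   co-occurrence modules; `module_correlation` is the sdlog of the
#'   shared lognormal latent factor (0 disables).
#' @param env_gradient Data frame describing the nine measured factors
#'   (see [default_env_gradient()]).
#' @param regime Optional preset name (see above).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 24, n_seasons = 2,
                       replicates_per_site = 1, n_taxa = 300,
                       depth = 20000, lognormal_meanlog = 0,
                       lognormal_sdlog = 2, selection_strength = 8,
                       niche_breadth = 1,
                       niche_conservatism = c("brownian", "shuffled"),
                       dispersal_decay = 0, selection_gradient = 1,
                       selection_env_offset = 0, drift_sdlog = 0,
                       local_community_size = Inf,
                       season_env_shift = 0.25, river_length_km = 4300,
                       n_modules = 0, module_size = 10,
                       module_correlation = 0,
                       env_gradient = default_env_gradient(),
                       regime = NULL, seed = 1) {
  niche_conservatism <- match.arg(niche_conservatism)
  cfg <- list(n_sites = n_sites, n_seasons = n_seasons,
              replicates_per_site = replicates_per_site,
              n_taxa = n_taxa, depth = depth,
              lognormal_meanlog = lognormal_meanlog,
              lognormal_sdlog = lognormal_sdlog,
              selection_strength = selection_strength,
              niche_breadth = niche_breadth,
              niche_conservatism = niche_conservatism,
              dispersal_decay = dispersal_decay,
              selection_gradient = selection_gradient,
              selection_env_offset = selection_env_offset,
              drift_sdlog = drift_sdlog,
              local_community_size = local_community_size,
              season_env_shift = season_env_shift,
              river_length_km = river_length_km,
              n_modules = n_modules, module_size = module_size,
              module_correlation = module_correlation,
              env_gradient = env_gradient,
              regime = regime %||% "custom", seed = seed)
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("heterogeneous_selection",
                                  "homogeneous_selection",
                                  "dispersal_limitation", "neutral"))
    cfg$regime <- regime
    preset <- switch(regime,
      heterogeneous_selection = list(selection_strength = 20,
                                     dispersal_decay = 0,
                                     selection_gradient = 1),
      homogeneous_selection = list(selection_strength = 20,
                                   niche_breadth = 1,
                                   dispersal_decay = 0,
                                   selection_gradient = 0,
                                   selection_env_offset = 1.5,
                                   season_env_shift = 0,
                                   drift_sdlog = 2,
                                   lognormal_sdlog = 1,
                                   local_community_size = 150),
      dispersal_limitation = list(selection_strength = 0,
                                  dispersal_decay = 0.01),
      neutral = list(selection_strength = 0, dispersal_decay = 0))
    cfg[names(preset)] <- preset
  }
  stopifnot(cfg$n_sites >= 2, cfg$n_taxa >= 2, cfg$depth >= 1,
            cfg$n_seasons %in% 1:2,
            cfg$replicates_per_site %in% 1:4,
            cfg$selection_strength >= 0, cfg$dispersal_decay >= 0,
            cfg$niche_breadth > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Default along-river trends for the nine environmental factors
#'
#' Each factor is generated as
#' `base + trend * downstream + autumn_offset * I(autumn) + noise`,
#' with `downstream` the 0-1 position from source to mouth, plus an
#' extra independent component for TOC (`indep_sd`) so a TOC-specific
#' association can be planted and detected. Magnitudes are plausible
#' for a large temperate river (WT degC, nutrients mg/L, TOC g/kg,
#' flow m3/s, slope permille).
#'
#' @return Data frame, one row per factor.
#' @export
default_env_gradient <- function() {
  data.frame(
    factor = env_factors(),
    base = c(12, 8.0, 0.15, 1.2, 1.8, 12, 0.6, 2000, 2.5),
    trend = c(8, 0.3, 0.10, 0.5, 0.6, 3, 0.2, 28000, -2.3),
    autumn_offset = c(6, -0.1, 0.02, 0.1, 0.15, 1, 0.05, 3000, 0),
    noise_sd = c(1.5, 0.15, 0.05, 0.2, 0.25, 2, 0.1, 1500, 0.2),
    indep_sd = c(0, 0, 0, 0, 0, 2, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' @param n_taxa Number of tips (labelled `ASV1..ASVn`).
#' @param seed Optional seed.
#' @param birth Speciation rate (default 1; only rescales depth).
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, birth = 1) {
  stopifnot(n_taxa >= 2)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = 0))
  tr$tip.label <- paste0("ASV", seq_len(n_taxa))
  tr
}

#' Simulate per-taxon environmental optima
#'
#' Brownian motion along the tree (variance proportional to branch
#' length) gives phylogenetically conserved niches — the signal the
#' betaNTI framework assumes. `"shuffled"` reassigns the same values
#' randomly across tips, destroying the signal while keeping the trait
#' distribution.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param mode `"brownian"` or `"shuffled"`.
#' @param seed Optional seed.
#' @return Named numeric vector of optima, z-scored across taxa.
#' @export
simulate_niches <- function(tree, mode = c("brownian", "shuffled"),
                            seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    mu <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    if (sd(mu) > 0) mu <- (mu - mean(mu)) / sd(mu)
    if (mode == "shuffled") mu <- setNames(sample(mu), names(mu))
    mu
  })
}

# Per-sample design: site positions, seasons, replicates, landforms.
sample_frame <- function(cfg) {
  pos <- seq(cfg$river_length_km, 0, length.out = cfg$n_sites)
  seasons <- c("spring", "autumn")[seq_len(cfg$n_seasons)]
  df <- expand.grid(rep = seq_len(cfg$replicates_per_site),
                    site = seq_len(cfg$n_sites), season = seasons,
                    stringsAsFactors = FALSE)
  df$dist_to_mouth_km <- pos[df$site]
  downstream <- 1 - df$dist_to_mouth_km / cfg$river_length_km
  df$landform <- landform_levels()[pmin(5L, 1L + floor(downstream * 5))]
  suffix <- if (cfg$replicates_per_site > 1) paste0("r", df$rep) else ""
  df$sample_id <- sprintf("S%02d%s%s", df$site,
                          substr(df$season, 1, 2), suffix)
  df
}

#' Assemble community count tables under a configured regime
#'
#' Sampling weight of taxon i at sample s:
#' `w_i(s) = A_i * exp(-alpha (mu_i - E_s)^2 / (2 sigma^2)) * K_i(s)`
#' with `A_i` the regional lognormal abundance, `E_s` the sample's
#' position on the selection axis, and `K_i(s) = exp(-lambda |x_s -
#' home_i|)` the dispersal kernel (1 when well-mixed). Counts are one
#' multinomial draw of `depth` reads per sample.
#'
#' @param cfg A [sim_config()].
#' @param tree Optional pre-built tree (built from `cfg` otherwise).
#' @param niches Optional pre-built optima.
#' @return Object of class `synthetic_dataset`: `counts`, `tree`,
#'   `metadata`, `weights` (expected weights, samples x taxa) and
#'   `truth` (per-taxon optimum, regional abundance, home site, module;
#'   regime label).
#' @export
sample_communities <- function(cfg, tree = NULL, niches = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tree))
    tree <- simulate_tree(cfg$n_taxa, seed = derive_seed(cfg$seed, 1))
  if (is.null(niches))
    niches <- simulate_niches(tree, cfg$niche_conservatism,
                              seed = derive_seed(cfg$seed, 2))
  taxa <- tree$tip.label
  nt <- length(taxa)
  A <- with_seed(derive_seed(cfg$seed, 3),
                 rlnorm(nt, cfg$lognormal_meanlog, cfg$lognormal_sdlog))
  home <- with_seed(derive_seed(cfg$seed, 4), {
    pos <- seq(cfg$river_length_km, 0, length.out = cfg$n_sites)
    pos[sample.int(cfg$n_sites, nt, replace = TRUE)]
  })
  sf <- sample_frame(cfg)
  ns <- nrow(sf)
  downstream <- 1 - sf$dist_to_mouth_km / cfg$river_length_km
  zpos <- if (sd(downstream) > 0)
    (downstream - mean(downstream)) / sd(downstream) else downstream * 0
  E <- cfg$selection_env_offset + cfg$selection_gradient * zpos +
    cfg$season_env_shift * (sf$season == "autumn")

  W <- matrix(0, nrow = ns, ncol = nt,
              dimnames = list(sf$sample_id, taxa))
  mu <- niches[taxa]
  for (s in seq_len(ns)) {
    sel <- if (cfg$selection_strength > 0)
      exp(-cfg$selection_strength * (mu - E[s])^2 /
            (2 * cfg$niche_breadth^2)) else 1
    K <- if (cfg$dispersal_decay > 0)
      exp(-cfg$dispersal_decay * abs(sf$dist_to_mouth_km[s] - home)) else 1
    w <- A * sel * K
    if (all(w == 0)) stop("degenerate sampling weights at sample ",
                          sf$sample_id[s], call. = FALSE)
    W[s, ] <- w
  }
  if (cfg$drift_sdlog > 0) {
    W <- W * with_seed(derive_seed(cfg$seed, 9),
                       matrix(rlnorm(ns * nt, 0, cfg$drift_sdlog), ns, nt))
  }
  Wreads <- W
  if (is.finite(cfg$local_community_size)) {
    Wreads <- draw_counts(W, cfg$local_community_size,
                          derive_seed(cfg$seed, 10))
    Wreads <- Wreads + 0.0
  }
  counts <- draw_counts(Wreads, cfg$depth, derive_seed(cfg$seed, 6))
  md <- make_metadata(cfg, sf, E)
  truth <- data.frame(asv_id = taxa, niche_optimum = unname(mu),
                      regional_abundance = A, home_site_km = home,
                      module = NA_integer_, stringsAsFactors = FALSE)
  out <- list(counts = counts, tree = tree, metadata = md,
              weights = W, truth = truth, regime = cfg$regime,
              config = cfg)
  class(out) <- "synthetic_dataset"
  if (cfg$n_modules > 0 && cfg$module_correlation > 0)
    out <- plant_modules(out, cfg$n_modules, cfg$module_size,
                         cfg$module_correlation,
                         seed = derive_seed(cfg$seed, 7))
  out
}

draw_counts <- function(W, depth, seed) {
  with_seed(seed, {
    counts <- matrix(0L, nrow = nrow(W), ncol = ncol(W),
                     dimnames = dimnames(W))
    for (s in seq_len(nrow(W)))
      counts[s, ] <- rmultinom(1, depth, prob = W[s, ])[, 1]
    counts
  })
}

# Nine measured factors: linear trend in downstream position + seasonal
# offset + noise; the selection axis E is attached as attribute.
make_metadata <- function(cfg, sf, E) {
  eg <- cfg$env_gradient
  downstream <- 1 - sf$dist_to_mouth_km / cfg$river_length_km
  md <- data.frame(sample_id = sf$sample_id, season = sf$season,
                   landform = sf$landform,
                   dist_to_mouth_km = sf$dist_to_mouth_km,
                   stringsAsFactors = FALSE)
  env <- with_seed(derive_seed(cfg$seed, 5), {
    vapply(seq_len(nrow(eg)), function(k) {
      v <- eg$base[k] + eg$trend[k] * downstream +
        eg$autumn_offset[k] * (sf$season == "autumn") +
        rnorm(nrow(sf), 0, eg$noise_sd[k]) +
        rnorm(nrow(sf), 0, eg$indep_sd[k])
      pmax(v, 0.001)
    }, numeric(nrow(sf)))
  })
  colnames(env) <- eg$factor
  md <- cbind(md, as.data.frame(env))
  rownames(md) <- md$sample_id
  attr(md, "selection_env") <- setNames(E, md$sample_id)
  md
}

#' Plant correlated co-occurrence modules
#'
#' Members of each module share a latent per-sample lognormal factor
#' multiplying their expected abundance before the multinomial draw,
#' inducing positive cross-sample rank correlation within the module.
#' Members are taken from the highest regional abundances (disjoint
#' across modules) so the planted signal survives the prevalence filter
#' and sampling noise. `module_correlation = 0` is the identity.
#'
#' @param dataset A `synthetic_dataset`.
#' @param n_modules,module_size Number and size of modules.
#' @param module_correlation sdlog of the shared latent factor.
#' @param seed Optional seed.
#' @return The dataset with re-drawn counts and module membership
#'   recorded in `truth$module`.
#' @export
plant_modules <- function(dataset, n_modules, module_size,
                          module_correlation, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (module_correlation == 0 || n_modules == 0) return(dataset)
  nt <- ncol(dataset$weights)
  if (n_modules * module_size > nt)
    stop("modules would overlap: too many member taxa", call. = FALSE)
  ord <- order(dataset$truth$regional_abundance, decreasing = TRUE)
  members <- ord[seq_len(n_modules * module_size)]
  modu <- rep(seq_len(n_modules), each = module_size)
  W <- dataset$weights
  W2 <- with_seed(seed, {
    for (m in seq_len(n_modules)) {
      f <- rlnorm(nrow(W), 0, module_correlation)
      cols <- members[modu == m]
      W[, cols] <- W[, cols] * f
    }
    W
  })
  dataset$weights <- W2
  dataset$truth$module <- NA_integer_
  dataset$truth$module[members] <- modu
  dataset$counts <- draw_counts(W2, dataset$config$depth,
                                derive_seed(dataset$config$seed, 8))
  dataset
}

#' Simulate a complete dataset from a configuration
#'
#' Tree, niches, communities, metadata and truth tables in one call;
#' bit-reproducible for a fixed configuration.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_dataset`.
#' @export
simulate_dataset <- function(cfg) sample_communities(cfg)

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d samples x %d taxa, regime '%s', depth %d\n",
    nrow(x$counts), ncol(x$counts), x$regime, x$config$depth))
  invisible(x)
}

#' Expected modal assembly process for a regime preset
#'
#' The four presets correspond to the four decisive classes of the
#' five-way (betaNTI, RCbray) framework. In particular the
#' neutral/well-mixed world maps to *homogenizing dispersal*:
#' unconstrained dispersal from one shared pool produces communities
#' more similar than the richness- and abundance-constrained
#' stochastic-assembly null, which is precisely what RCbray < -0.95
#' flags. "Undominated" is the signature of intermediate dispersal plus
#' drift, a scenario the presets deliberately do not include.
#'
#' @param regime Preset name.
#' @return The expected process label.
#' @export
expected_process <- function(regime) {
  switch(match.arg(regime, c("heterogeneous_selection",
                             "homogeneous_selection",
                             "dispersal_limitation", "neutral")),
         heterogeneous_selection = "heterogeneous_selection",
         homogeneous_selection = "homogeneous_selection",
         dispersal_limitation = "dispersal_limitation",
         neutral = "homogenizing_dispersal")
}

#' Deterministic table with planted abundance categories
#'
#' Builds an exact integer count table in which designated taxa follow
#' each of the six abundance-class dynamics (AAT, CAT, CRAT, MT, CRT,
#' ART) by construction, plus one filler taxon absorbing the remaining
#' reads (itself AAT). Used as the bookkeeping oracle for the
#' classifier: `classify_asvs()` must recover `truth` exactly.
#'
#' @param n_per_class Taxa per category (default 3).
#' @param n_samples Number of samples (default 6, >= 2).
#' @param depth Reads per sample (default 1e6; must keep the class
#'   proportions representable as integers).
#' @return List with `counts` and `truth` (named category vector).
#' @export
simulate_category_mix <- function(n_per_class = 3, n_samples = 6,
                                  depth = 1e6) {
  stopifnot(n_samples >= 2, depth >= 1e5)
  # per-sample relative abundances: (low, high) alternating patterns
  profiles <- list(
    AAT  = c(0.02,   0.03),    # always >= 1%
    CAT  = c(5e-4,   0.015),   # >= 0.01% everywhere, >= 1% somewhere
    CRAT = c(5e-5,   0.015),   # < 0.01% somewhere, >= 1% somewhere
    MT   = c(5e-4,   5e-3),    # within [0.01%, 1%) everywhere
    CRT  = c(5e-5,   1e-3),    # < 1% everywhere, < 0.01% somewhere
    ART  = c(5e-5,   8e-5))    # < 0.01% everywhere
  cats <- names(profiles)
  taxa <- paste0(rep(cats, each = n_per_class), "_",
                 sequence(rep(n_per_class, length(cats))))
  counts <- matrix(0L, nrow = n_samples, ncol = length(taxa) + 1,
                   dimnames = list(paste0("S", seq_len(n_samples)),
                                   c(taxa, "filler")))
  for (k in seq_along(taxa)) {
    pr <- profiles[[sub("_.*", "", taxa[k])]]
    # alternate low/high across samples, offset per taxon
    pat <- rep(pr, length.out = n_samples + k %% 2)[
      seq_len(n_samples) + k %% 2]
    counts[, k] <- as.integer(round(pat * depth))
  }
  fill <- depth - rowSums(counts)
  stopifnot(all(fill / depth >= 0.01))
  counts[, "filler"] <- as.integer(fill)
  truth <- setNames(c(rep(cats, each = n_per_class), "AAT"),
                    colnames(counts))
  list(counts = counts, truth = truth)
}
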