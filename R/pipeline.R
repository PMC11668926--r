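# pipeline_cli: end-to-end orchestration from a single configuration,
# producing a results bundle that mirrors the standard figure/table set
# (alpha diversity, partition summary, beta/decay/ANOSIM, network +
# keystones + O/R, assembly process fractions, Mantel/VPA) plus a
# manifest sufficient to reproduce every number.

#' Pipeline configuration
#'
#' Either `input` (paths to a count TSV, newick tree, metadata CSV and
#' optionally a taxonomy TSV) or `simulation` (arguments for
#' [sim_config()]) must be supplied. All randomness derives from
#' `seed` via fixed per-stage offsets, so independent stage re-runs are
#' reproducible.
#'
#' @param input Optional list: `table`, `tree`, `metadata`, `taxonomy`.
#' @param simulation Optional list of [sim_config()] arguments.
#' @param rarefy_depth Rarefaction depth (`NULL` = minimum sample
#'   total).
#' @param rare_cut,abundant_cut Partition thresholds.
#' @param rho_min,alpha,prevalence Network thresholds.
#' @param degree_min,betweenness_max Keystone criteria.
#' @param nti_cut,rc_cut Assembly process thresholds.
#' @param n_null Null replicates for betaNTI and RCbray.
#' @param er_reps Erdos-Renyi ensemble size for O/R.
#' @param n_perm Permutations for ANOSIM/Mantel/decay.
#' @param out_dir Output directory (`NULL` = return bundle only).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            rarefy_depth = NULL, rare_cut = 1e-4,
                            abundant_cut = 1e-2, rho_min = 0.8,
                            alpha = 0.01, prevalence = 0.2,
                            degree_min = 100, betweenness_max = 5000,
                            nti_cut = 2, rc_cut = 0.95, n_null = 999,
                            er_reps = 999, n_perm = 999,
                            out_dir = NULL, seed = 1) {
  if (is.null(input) && is.null(simulation))
    stop("supply either input paths or a simulation block", call. = FALSE)
  stopifnot(rare_cut > 0, rare_cut < abundant_cut, abundant_cut < 1,
            rho_min > 0, rho_min < 1, alpha > 0, alpha < 1,
            prevalence >= 0, prevalence <= 1, nti_cut > 0,
            rc_cut > 0, rc_cut < 1, n_null >= 2, n_perm >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose top-level keys are arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Sequences rarefaction, coverage, abundance-class partition, alpha
#' and beta diversity, distance-decay and ANOSIM, the co-occurrence
#' network with keystones and O/R ratios, betaNTI/RCbray process
#' classification per subcommunity, and Mantel/partial-Mantel/VPA
#' environmental attribution. Writes TSV outputs and a JSON manifest
#' when `out_dir` is set.
#'
#' @param cfg A `pipeline_config` (or path to its JSON form).
#' @return A `results_bundle` list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    tt <- system.time(res <- force(expr))["elapsed"]
    timings[[name]] <<- unname(tt)
    res
  }

  # ---- inputs -------------------------------------------------------
  taxonomy <- NULL
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- sim_args$seed %||% derive_seed(cfg$seed, 11)
    ds <- tick("simulate", simulate_dataset(do.call(sim_config, sim_args)))
    counts <- ds$counts; tree <- ds$tree; meta <- ds$metadata
  } else {
    inp <- cfg$input
    counts <- read_asv_table(inp$table)
    tree <- read_tree(inp$tree)
    meta <- read_sample_metadata(inp$metadata)
    if (!is.null(inp$taxonomy)) {
      tx <- read.delim(inp$taxonomy, stringsAsFactors = FALSE)
      taxonomy <- setNames(tx[[2]], tx[[1]])
    }
    ds <- NULL
  }
  if (!all(rownames(counts) %in% rownames(meta)))
    stop("metadata does not cover all samples", call. = FALSE)
  meta <- meta[rownames(counts), , drop = FALSE]

  # ---- core ---------------------------------------------------------
  rare <- tick("rarefy", rarefy(counts, depth = cfg$rarefy_depth,
                                seed = derive_seed(cfg$seed, 1)))
  meta <- meta[rownames(rare), , drop = FALSE]
  coverage <- goods_coverage(rare)
  part <- tick("partition", classify_asvs(rare, cfg$rare_cut,
                                          cfg$abundant_cut))
  part_sum <- partition_summary(part, taxonomy)
  alpha_tab <- tick("alpha", alpha_diversity(rare, tree))
  season <- setNames(meta$season, rownames(meta))
  alpha_season <- NULL
  if (length(unique(season)) == 2) {
    sp <- split(seq_len(nrow(alpha_tab)), season[alpha_tab$sample_id])
    alpha_season <- do.call(rbind, lapply(
      c("chao1", "shannon", if ("faith_pd" %in% names(alpha_tab))
        "faith_pd"), function(ix) {
        wt <- wilcoxon_rank_sum(alpha_tab[[ix]][sp[[1]]],
                                alpha_tab[[ix]][sp[[2]]])
        data.frame(index = ix, statistic = wt$statistic,
                   p_value = wt$p_value, stringsAsFactors = FALSE)
      }))
  }

  # ---- beta / spatial ----------------------------------------------
  beta <- tick("beta", list(bray = bray_curtis(rare),
                            unifrac = unweighted_unifrac(rare, tree)))
  x_mouth <- setNames(meta$dist_to_mouth_km, rownames(meta))
  anosim_res <- list(
    season = if (length(unique(season)) >= 2)
      anosim(beta$bray, season, n_perm = cfg$n_perm,
             seed = derive_seed(cfg$seed, 2)) else NULL,
    landform = if (length(unique(meta$landform)) >= 2)
      anosim(beta$bray, setNames(meta$landform, rownames(meta)),
             n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 3))
      else NULL)
  subcats <- list(ART = "ART", CRT = "CRT", CRAT = "CRAT")
  decay <- tick("decay", lapply(subcats, function(w) {
    sub <- subcommunity(rare, part, w)
    if (ncol(sub) < 2) return(NULL)
    keep <- rowSums(sub) > 0
    if (sum(keep) < 4) return(NULL)
    distance_decay(bray_curtis(sub[keep, , drop = FALSE]),
                   x_mouth[keep], n_perm = cfg$n_perm,
                   seed = derive_seed(cfg$seed, 4))
  }))

  # ---- network ------------------------------------------------------
  net <- tick("network", {
    filt <- prevalence_filter(rare, cfg$prevalence)
    if (ncol(filt) >= 2 && nrow(filt) >= 4)
      spearman_edges(filt, cfg$rho_min, cfg$alpha) else NULL
  })
  topo <- keyst <- orr <- degfits <- NULL
  if (!is.null(net) && igraph::ecount(net) > 0) {
    topo <- topology(net)
    keyst <- keystones(topo, cfg$degree_min, cfg$betweenness_max)
    node_cat <- setNames(as.character(part$table$category),
                         part$table$asv_id)
    orr <- tick("o_r", o_r_ratios(net, node_cat, reps = cfg$er_reps,
                                  seed = derive_seed(cfg$seed, 5)))
    degfits <- if (sum(igraph::degree(net) >= 1) >= 10)
      list(power_law = fit_degree_distribution(net, "power_law"),
           gaussian = fit_degree_distribution(net, "gaussian"))
  }

  # ---- assembly -----------------------------------------------------
  assembly <- tick("assembly", lapply(subcats, function(w) {
    sub <- subcommunity(rare, part, w)
    keep <- rowSums(sub) > 0
    sub <- sub[keep, , drop = FALSE]
    if (ncol(sub) < 3 || nrow(sub) < 3) return(NULL)
    bnti <- beta_nti(sub, tree, n_null = cfg$n_null,
                     seed = derive_seed(cfg$seed, 6))
    rc <- raup_crick_bray(sub, n_null = cfg$n_null,
                          seed = derive_seed(cfg$seed, 7))
    cls <- classify_processes(bnti, rc, cfg$nti_cut, cfg$rc_cut)
    list(classification = cls,
         fractions = process_fractions(cls, strata = season))
  }))

  # ---- environmental attribution -----------------------------------
  envres <- tick("env", {
    geo <- abs(outer(x_mouth, x_mouth, "-"))
    dimnames(geo) <- list(names(x_mouth), names(x_mouth))
    facs <- intersect(env_factors(), names(meta))
    mt <- do.call(rbind, lapply(facs, function(f) {
      ed <- env_distance(meta, f)
      if (sd(lower_vec(ed)) == 0) return(NULL)
      m1 <- mantel(beta$bray, ed, n_perm = cfg$n_perm,
                   seed = derive_seed(cfg$seed, 8))
      m2 <- partial_mantel(beta$bray, ed, geo, n_perm = cfg$n_perm,
                           seed = derive_seed(cfg$seed, 9))
      data.frame(factor = f, mantel_r = m1$r, mantel_p = m1$p_value,
                 partial_r = m2$r, partial_p = m2$p_value,
                 stringsAsFactors = FALSE)
    }))
    natural <- intersect(c("WT", "pH", "river_flow", "channel_slope"),
                         names(meta))
    nutrient <- intersect(c("NH3_N", "NO3_N", "TN", "TOC", "TP"),
                          names(meta))
    vpa <- if (length(natural) && length(nutrient) &&
               nrow(rare) > length(natural) + length(nutrient) + 1)
      vpa_two_sets(rare, meta[, natural, drop = FALSE],
                   meta[, nutrient, drop = FALSE]) else NULL
    list(mantel = mt, vpa = vpa)
  })

  manifest <- list(
    package_version = as.character(packageVersion("riversed")),
    seed = cfg$seed,
    thresholds = cfg[c("rare_cut", "abundant_cut", "rho_min", "alpha",
                       "prevalence", "degree_min", "betweenness_max",
                       "nti_cut", "rc_cut")],
    replicates = cfg[c("n_null", "er_reps", "n_perm")],
    rarefy_depth = min(rowSums(counts)),
    n_samples = nrow(rare), n_asvs = ncol(rare),
    timings = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  bundle <- list(counts_rarefied = rare, metadata = meta,
                 coverage = coverage, partition = part,
                 partition_summary = part_sum, alpha = alpha_tab,
                 alpha_season_tests = alpha_season, beta = beta,
                 anosim = anosim_res, decay = decay, network = net,
                 topology = topo, keystones = keyst, o_r = orr,
                 degree_fits = degfits, assembly = assembly,
                 env = envres, manifest = manifest,
                 dataset = ds)
  class(bundle) <- "results_bundle"
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

# TSV/JSON writers for the bundle; filenames are stable so stages can
# be re-consumed downstream.
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write_asv_table(bundle$counts_rarefied,
                  file.path(dir, "counts_rarefied.tsv"))
  w(data.frame(sample_id = names(bundle$coverage),
               goods_coverage = bundle$coverage), "coverage.tsv")
  w(bundle$partition$table, "partition.tsv")
  w(bundle$partition_summary, "partition_summary.tsv")
  w(bundle$alpha, "alpha_diversity.tsv")
  wm <- function(m, name) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    w(df, name)
  }
  wm(bundle$beta$bray, "beta_bray.tsv")
  wm(bundle$beta$unifrac, "beta_unifrac.tsv")
  if (!is.null(bundle$network)) {
    el <- igraph::as_data_frame(bundle$network, what = "edges")
    w(el, "network_edges.tsv")
    w(bundle$topology, "network_topology.tsv")
    if (!is.null(bundle$o_r)) w(bundle$o_r, "network_o_r.tsv")
  }
  for (nm in names(bundle$assembly)) {
    a <- bundle$assembly[[nm]]
    if (is.null(a)) next
    w(as.data.frame(a$classification),
      paste0("assembly_", nm, "_pairs.tsv"))
    w(a$fractions, paste0("assembly_", nm, "_fractions.tsv"))
  }
  if (!is.null(bundle$env$mantel)) w(bundle$env$mantel, "mantel.tsv")
  if (!is.null(bundle$env$vpa))
    w(data.frame(fraction = names(bundle$env$vpa$raw),
                 raw = bundle$env$vpa$raw,
                 reported = bundle$env$vpa$fractions), "vpa.tsv")
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
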