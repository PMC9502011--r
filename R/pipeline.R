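# End-to-end orchestration: simulate -> community -> ordination ->
# network -> association -> agronomy, seeded and logged.

#' Pipeline configuration
#'
#' Assembles and validates every stage parameter with the conventional
#' defaults of the analysis chain: rarefaction depth 20,000, genus-level
#' aggregation, 1% mean-abundance filter (union over treatment groups),
#' Benjamini-Hochberg FDR with edge cutoff 0.001, RMT threshold grid
#' 0.30-0.95, ANOSIM with 999 and Mantel tests with 9999 permutations,
#' Manhattan significance level 0.05.
#'
#' @param seed integer master seed; stage streams are derived from it.
#' @param simulation arguments forwarded to [simulation_config()] (the
#'   simulation inherits `seed` unless overridden).
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "community", "ordination", "network", "association",
#'   "agronomy")`.
#' @param inputs optional named list of input paths (`counts`,
#'   `taxonomy`, `metadata`, `environment`, `agronomy`, `guild_map`)
#'   used when `"simulate"` is not enabled.
#' @param depth rarefaction depth.
#' @param aggregate_rank rank for the network node table.
#' @param abundance_threshold mean relative-abundance filter.
#' @param filter_rule `"union"`, `"intersection"` or `"global"`.
#' @param fdr_method,fdr_cut FDR procedure and edge q cutoff.
#' @param rmt_grid candidate thresholds for [rmt_threshold()].
#' @param fallback_threshold correlation cutoff used (with a logged
#'   warning) when the RMT scan finds no Poisson-consistent candidate;
#'   0.72 is a typical value for genus-level soil networks.
#' @param per_treatment_networks also build one network per treatment
#'   (same threshold) for linkage comparisons.
#' @param anosim_permutations,mantel_permutations permutation counts.
#' @param manhattan_alpha FDR level for enrichment calls.
#' @param differential_groups length-2 character vector: the two
#'   treatments contrasted by the enrichment caller (focal first).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            simulation = list(),
                            stages = c("simulate", "community", "ordination",
                                       "network", "association", "agronomy"),
                            inputs = list(),
                            depth = 20000,
                            aggregate_rank = "genus",
                            abundance_threshold = 0.01,
                            filter_rule = "union",
                            fdr_method = "BH",
                            fdr_cut = 0.001,
                            rmt_grid = seq(0.30, 0.95, by = 0.01),
                            fallback_threshold = 0.72,
                            per_treatment_networks = FALSE,
                            anosim_permutations = 999,
                            mantel_permutations = 9999,
                            manhattan_alpha = 0.05,
                            differential_groups = c("CRU+FA", "CRU")) {
  all_stages <- c("simulate", "community", "ordination", "network",
                  "association", "agronomy")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!"seed" %in% names(simulation)) simulation$seed <- seed
  sim_cfg <- do.call(simulation_config, simulation)
  cfg <- list(seed = seed, simulation = sim_cfg, stages = stages,
              inputs = inputs, depth = depth,
              aggregate_rank = aggregate_rank,
              abundance_threshold = abundance_threshold,
              filter_rule = filter_rule, fdr_method = fdr_method,
              fdr_cut = fdr_cut, rmt_grid = rmt_grid,
              fallback_threshold = fallback_threshold,
              per_treatment_networks = per_treatment_networks,
              anosim_permutations = anosim_permutations,
              mantel_permutations = mantel_permutations,
              manhattan_alpha = manhattan_alpha,
              differential_groups = differential_groups)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; keys not present keep their
#' [pipeline_config()] defaults. The `simulation` block maps onto
#' [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

.pipeline_inputs <- function(config) {
  if ("simulate" %in% config$stages) {
    sim <- simulate_community(config$simulation)
    env <- simulate_environment(sim$truth, sim$counts, config$simulation)
    agro <- simulate_agronomy(config$simulation)
    list(counts = sim$counts, taxonomy = sim$taxonomy,
         metadata = sim$metadata, environment = env, agronomy = agro,
         guild_map = default_guild_map(), truth = sim$truth)
  } else {
    need <- c("counts", "taxonomy", "metadata")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      stop("simulation disabled and no input path for: ",
           paste(missing, collapse = ", "))
    inp <- config$inputs
    list(
      counts = read_count_table(inp$counts),
      taxonomy = read_taxonomy(inp$taxonomy),
      metadata = read_table_tsv(inp$metadata),
      environment = if (!is.null(inp$environment))
        as.matrix(read_table_tsv(inp$environment, rownames_col = "sample")),
      agronomy = if (!is.null(inp$agronomy)) read_table_tsv(inp$agronomy),
      guild_map = if (!is.null(inp$guild_map)) read_guild_map(inp$guild_map)
        else default_guild_map(),
      truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load inputs),
#' count-table processing, ordination, co-occurrence network,
#' module/guild-environment association, agronomic statistics — and,
#' when `outdir` is given, writes every intermediate artifact plus a
#' JSON manifest recording package and R versions, the seed, all
#' parameter values and the MD5 checksum of every written file.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list of class `pipeline_run` with one element per executed
#'   stage plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  res <- list(config = config)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  dat <- .pipeline_inputs(config)
  res$data <- dat
  note("inputs ready: %d taxa x %d samples", nrow(dat$counts), ncol(dat$counts))

  meta <- dat$metadata
  groups <- setNames(meta$treatment, meta$sample)

  if ("community" %in% stages) {
    rare <- rarefy_counts(dat$counts, depth = config$depth,
                          seed = config$seed + 10L)
    coverage <- goods_coverage(rare)
    rel_otu <- relative_abundance(rare)
    agg <- aggregate_taxa(rare, dat$taxonomy, rank = config$aggregate_rank)
    rel_rank <- relative_abundance(agg)
    nodes_tab <- filter_mean_abundance(rel_rank, groups[colnames(rel_rank)],
                                       threshold = config$abundance_threshold,
                                       rule = config$filter_rule)
    res$community <- list(rarefied = rare, coverage = coverage,
                          rel_otu = rel_otu, rel_rank = rel_rank,
                          nodes_tab = nodes_tab)
    note("community: mean Good's coverage %.4f; %d/%d %s-level taxa pass the %.2g filter",
         mean(coverage), nrow(nodes_tab), nrow(rel_rank),
         config$aggregate_rank, config$abundance_threshold)
  }

  if ("ordination" %in% stages) {
    if (is.null(res$community)) stop("ordination stage requires the community stage")
    d <- bray_curtis(res$community$rel_otu)
    pc <- pcoa_ord(d)
    an_t <- anosim_test(d, groups[rownames(d)],
                        n_perm = config$anosim_permutations,
                        seed = config$seed + 20L)
    an_d <- anosim_test(d, setNames(meta$day, meta$sample)[rownames(d)],
                        n_perm = config$anosim_permutations,
                        seed = config$seed + 21L)
    res$ordination <- list(distance = d, pcoa = pc, anosim_treatment = an_t,
                           anosim_day = an_d)
    note("ordination: PC1 %.2f%%, PC2 %.2f%%; ANOSIM(treatment) R = %.2f p = %.3g",
         100 * pc$proportion_explained[1], 100 * pc$proportion_explained[2],
         an_t$statistic, an_t$p_value)
  }

  if ("network" %in% stages) {
    if (is.null(res$community)) stop("network stage requires the community stage")
    tab <- res$community$nodes_tab
    corr <- spearman_matrix(tab, fdr_method = config$fdr_method)
    scan <- tryCatch(rmt_threshold(corr, grid = config$rmt_grid),
                     error = function(e) e)
    if (inherits(scan, "error")) {
      threshold <- config$fallback_threshold
      note("network: RMT scan failed (%s); falling back to threshold %.2f",
           conditionMessage(scan), threshold)
      scan <- NULL
    } else {
      threshold <- scan$threshold
      note("network: RMT-selected threshold %.2f", threshold)
    }
    net <- build_network(corr, threshold, q_cut = config$fdr_cut,
                         node_abundance = rowMeans(tab))
    part <- detect_modules(net, seed = config$seed + 30L)
    modab <- module_abundance(part, tab)
    stats <- network_stats(net, part)
    per_trt <- NULL
    if (config$per_treatment_networks) {
      per_trt <- lapply(split(meta$sample, meta$treatment), function(ss) {
        ct <- spearman_matrix(tab[, ss, drop = FALSE],
                              fdr_method = config$fdr_method)
        nt <- build_network(ct, threshold, q_cut = config$fdr_cut,
                            node_abundance = rowMeans(tab[, ss, drop = FALSE]))
        list(network = nt, stats = network_stats(nt))
      })
    }
    res$network <- list(correlation = corr, rmt = scan, threshold = threshold,
                        network = net, partition = part,
                        module_abundance = modab, stats = stats,
                        per_treatment = per_trt)
    note("network: %d nodes, %d edges, %d modules, Q = %.3f",
         stats$n_nodes, stats$n_edges, stats$n_modules, stats$modularity)
  }

  if ("association" %in% stages) {
    if (is.null(res$network)) stop("association stage requires the network stage")
    if (is.null(dat$environment)) stop("association stage needs an environmental matrix")
    mec <- module_env_correlation(res$network$module_abundance,
                                  dat$environment)
    focal <- focal_module(mec)
    fm_id <- match(focal, res$network$partition$module_names)
    fm_taxa <- names(res$network$partition$module_of)[
      res$network$partition$module_of == fm_id]
    ga <- meta$sample[meta$treatment == config$differential_groups[1]]
    gb <- meta$sample[meta$treatment == config$differential_groups[2]]
    diff <- NULL
    if (length(ga) >= 2 && length(gb) >= 2) {
      # phylum lookup for rows of the aggregated node table
      map <- unique(dat$taxonomy[, c(config$aggregate_rank, "phylum")])
      phy <- setNames(map$phylum, map[[config$aggregate_rank]])
      tax_df <- data.frame(phylum = unname(phy[fm_taxa]),
                           row.names = fm_taxa, stringsAsFactors = FALSE)
      diff <- differential_otus(res$community$nodes_tab, fm_taxa, ga, gb,
                                alpha = config$manhattan_alpha,
                                taxonomy = tax_df, module = focal)
    }
    guilds <- sort(setdiff(unique(dat$guild_map$guild), "none"))
    set.seed(config$seed + 40L)
    mantel <- do.call(rbind, lapply(guilds, function(gl) {
      gd <- tryCatch(suppressWarnings(
        guild_distances(res$community$rarefied, dat$taxonomy,
                        dat$guild_map, gl)), error = function(e) NULL)
      if (is.null(gd)) return(NULL)
      day_d <- abs(outer(meta$day, meta$day, "-"))
      dimnames(day_d) <- list(meta$sample, meta$sample)
      do.call(rbind, lapply(colnames(dat$environment), function(f) {
        ed <- env_factor_distance(dat$environment[rownames(gd), , drop = FALSE], f)
        mt <- partial_mantel_test(gd, ed, day_d[rownames(gd), rownames(gd)],
                                  n_perm = config$mantel_permutations,
                                  label = "day difference")
        data.frame(guild = gl, factor = f, r = mt$r, p = mt$p_value,
                   stars = significance_stars(mt$p_value),
                   stringsAsFactors = FALSE)
      }))
    }))
    res$association <- list(module_env = mec, focal_module = focal,
                            differential = diff, mantel = mantel)
    note("association: focal module %s; %d enrichment calls; %d guild-factor Mantel tests",
         focal, if (is.null(diff)) 0L else sum(diff$status != "ns"),
         if (is.null(mantel)) 0L else nrow(mantel))
  }

  if ("agronomy" %in% stages) {
    if (is.null(dat$agronomy)) stop("agronomy stage needs an agronomic table")
    agro <- dat$agronomy
    eff <- nitrogen_efficiency(agro)
    duncan <- lapply(setNames(c("grain_yield", "biomass", "thousand_grain"),
                              c("grain_yield", "biomass", "thousand_grain")),
                     function(v) anova_duncan(agro[[v]], agro$treatment))
    yield_means <- tapply(agro$grain_yield, agro$treatment, mean)
    res$agronomy <- list(efficiency = eff, duncan = duncan,
                         yield_means = yield_means)
    note("agronomy: CRU+FA vs CRU yield change %.1f%%",
         percent_change(yield_means[["CRU+FA"]], yield_means[["CRU"]]))
  }

  res$log <- log
  res$manifest <- list(
    package = as.character(packageVersion("micronet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = stages,
    parameters = .manifest_params(config),
    log = log)
  if (!is.null(outdir)) res$manifest$files <- .write_pipeline(res, outdir)
  class(res) <- "pipeline_run"
  res
}

.manifest_params <- function(config) {
  p <- unclass(config)
  p$simulation <- unclass(p$simulation)
  p$rmt_grid <- range(p$rmt_grid)
  p
}

.write_pipeline <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    paths <<- c(paths, setNames(path, name))
  }
  dat <- res$data
  put("counts.tsv", function(p) write_count_table(dat$counts, p))
  put("taxonomy.tsv", function(p) write_taxonomy(dat$taxonomy, p))
  put("metadata.tsv", function(p) write_table_tsv(dat$metadata, p))
  if (!is.null(dat$environment))
    put("environment.tsv", function(p)
      write_table_tsv(dat$environment, p, rownames_col = "sample"))
  if (!is.null(dat$agronomy))
    put("agronomy.tsv", function(p) write_table_tsv(dat$agronomy, p))
  if (!is.null(dat$guild_map))
    put("guild_map.tsv", function(p) write_table_tsv(dat$guild_map, p))
  if (!is.null(res$community)) {
    put("rarefied.tsv", function(p) write_count_table(res$community$rarefied, p))
    put("coverage.tsv", function(p)
      write_table_tsv(data.frame(sample = names(res$community$coverage),
                                 coverage = res$community$coverage), p))
    put("network_nodes_abundance.tsv", function(p)
      write_count_table(res$community$nodes_tab, p))
  }
  if (!is.null(res$ordination)) {
    put("bray_curtis.tsv", function(p)
      write_table_tsv(res$ordination$distance, p, rownames_col = "sample"))
    put("pcoa.tsv", function(p) {
      co <- res$ordination$pcoa$coordinates
      write_table_tsv(co, p, rownames_col = "sample")
    })
    put("anosim.json", function(p)
      jsonlite::write_json(list(
        treatment = res$ordination$anosim_treatment[c("statistic", "p_value", "n_permutations")],
        day = res$ordination$anosim_day[c("statistic", "p_value", "n_permutations")]),
        p, auto_unbox = TRUE, digits = NA))
  }
  if (!is.null(res$network)) {
    put("network.graphml", function(p) write_network_graphml(res$network$network, p))
    put("network.gexf", function(p) write_network_gexf(res$network$network, p))
    put("edges.csv", function(p) write_edge_list(res$network$network, p))
    put("modules.tsv", function(p) write_partition(res$network$partition, p))
    put("module_abundance.tsv", function(p)
      write_table_tsv(res$network$module_abundance, p, rownames_col = "module"))
    put("network_stats.tsv", function(p) write_table_tsv(res$network$stats, p))
    if (!is.null(res$network$rmt))
      put("rmt_diagnostics.tsv", function(p)
        write_table_tsv(res$network$rmt$diagnostics, p))
  }
  if (!is.null(res$association)) {
    put("module_env_correlation.tsv", function(p)
      write_table_tsv(res$association$module_env, p))
    if (!is.null(res$association$differential))
      put("differential.tsv", function(p)
        write_table_tsv(res$association$differential, p))
    if (!is.null(res$association$mantel))
      put("mantel.tsv", function(p) write_table_tsv(res$association$mantel, p))
  }
  if (!is.null(res$agronomy)) {
    put("efficiency.tsv", function(p)
      write_table_tsv(res$agronomy$efficiency$summary, p))
    put("duncan_grain_yield.tsv", function(p)
      write_table_tsv(res$agronomy$duncan$grain_yield$groups, p))
  }
  sums <- md5sum(paths)
  files <- data.frame(name = names(paths), path = unname(paths),
                      md5 = unname(sums), stringsAsFactors = FALSE)
  manifest <- res$manifest
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("micronet pipeline run\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
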