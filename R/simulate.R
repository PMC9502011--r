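# Synthetic-data generator: OTU tables with planted module structure,
# taxonomy, environmental covariates coupled to module abundances,
# guild maps and agronomic records with known ground truth.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic community
#' generator. The defaults mirror a soil incubation study: 3 treatments
#' (zero-N control, controlled-release urea, CRU plus fulvic acid) x 4
#' destructive-sampling days x 3 replicates = 36 samples sequenced to
#' 20,000 reads, with taxa organised into 5 correlated modules whose
#' abundances shift with treatment and day.
#'
#' @param n_taxa number of taxa (OTUs).
#' @param n_modules number of planted co-occurrence modules.
#' @param n_treatments number of treatments (2-4), drawn in order from
#'   control, CRU, CRU+FA, FA.
#' @param days sampling days, strictly increasing.
#' @param n_replicates replicates per treatment x day.
#' @param depth reads per sample.
#' @param module_effect treatment x day shift applied to responsive
#'   modules, on the natural-log abundance scale (dimensionless).
#' @param module_cor latent within-module correlation in \[0, 1).
#' @param env_noise_sd environmental noise-to-signal ratio: factors are
#'   standardized module-abundance combinations plus Gaussian noise of
#'   this SD (dimensionless).
#' @param dispersion Dirichlet concentration closing the compositional
#'   draw (> 0); smaller values give more count overdispersion.
#' @param seed integer seed; all stages derive their streams from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 300, n_modules = 5, n_treatments = 3,
                              days = c(1, 7, 30, 60), n_replicates = 3,
                              depth = 20000, module_effect = 2,
                              module_cor = 0.8, env_noise_sd = 0.5,
                              dispersion = 5000, seed = 1) {
  cfg <- list(n_taxa = n_taxa, n_modules = n_modules,
              n_treatments = n_treatments, days = days,
              n_replicates = n_replicates, depth = depth,
              module_effect = module_effect, module_cor = module_cor,
              env_noise_sd = env_noise_sd, dispersion = dispersion,
              seed = seed)
  counts <- c("n_taxa", "n_modules", "n_treatments", "n_replicates", "depth")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("`", f, "` must be a positive integer")
  if (n_modules > n_taxa) stop("`n_modules` cannot exceed `n_taxa`")
  if (n_treatments > 4) stop("at most 4 treatments are defined")
  if (length(days) < 1 || is.unsorted(days, strictly = TRUE))
    stop("`days` must be strictly increasing")
  if (module_cor < 0 || module_cor >= 1)
    stop("`module_cor` must lie in [0, 1)")
  if (dispersion <= 0) stop("`dispersion` must be positive")
  if (env_noise_sd < 0) stop("`env_noise_sd` must be nonnegative")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation: %d taxa in %d modules; %d treatments x %d days x %d reps = %d samples at depth %d\n",
              x$n_taxa, x$n_modules, x$n_treatments, length(x$days),
              x$n_replicates,
              x$n_treatments * length(x$days) * x$n_replicates, x$depth))
  invisible(x)
}

.TREATMENTS <- c("control", "CRU", "CRU+FA", "FA")

.ENV_FACTORS <- c("NO3_L", "NH4_L", "HCO3_L", "pH_L",
                  "NO3_S", "NH4_S", "pH_S",
                  "NO3_P", "NH4_P", "pH_P", "NUE", "Yield")

#' Reference catalogue of soil bacterial genera
#'
#' Six-rank lineages for 45 genera commonly reported from agricultural
#' soils, including the nitrogen-cycle genera used by the default guild
#' map; the synthetic taxonomy draws from this catalogue.
#'
#' @return data frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
genus_catalog <- function() {
  raw <- c(
    "Sphingomonas|Proteobacteria|Alphaproteobacteria|Sphingomonadales|Sphingomonadaceae",
    "Lysobacter|Proteobacteria|Gammaproteobacteria|Lysobacterales|Lysobacteraceae",
    "Nitrospira|Nitrospirota|Nitrospiria|Nitrospirales|Nitrospiraceae",
    "Nocardioides|Actinobacteriota|Actinobacteria|Propionibacteriales|Nocardioidaceae",
    "Gaiella|Actinobacteriota|Thermoleophilia|Gaiellales|Gaiellaceae",
    "Ensifer|Proteobacteria|Alphaproteobacteria|Rhizobiales|Rhizobiaceae",
    "Blastococcus|Actinobacteriota|Actinobacteria|Geodermatophilales|Geodermatophilaceae",
    "Pseudolabrys|Proteobacteria|Alphaproteobacteria|Rhizobiales|Xanthobacteraceae",
    "Nitrosospira|Proteobacteria|Gammaproteobacteria|Nitrosomonadales|Nitrosomonadaceae",
    "Arthrobacter|Actinobacteriota|Actinobacteria|Micrococcales|Micrococcaceae",
    "Pseudarthrobacter|Actinobacteriota|Actinobacteria|Micrococcales|Micrococcaceae",
    "Streptomyces|Actinobacteriota|Actinobacteria|Streptomycetales|Streptomycetaceae",
    "Mycobacterium|Actinobacteriota|Actinobacteria|Corynebacteriales|Mycobacteriaceae",
    "Agromyces|Actinobacteriota|Actinobacteria|Micrococcales|Microbacteriaceae",
    "Kribbella|Actinobacteriota|Actinobacteria|Propionibacteriales|Nocardioidaceae",
    "Marmoricola|Actinobacteriota|Actinobacteria|Propionibacteriales|Nocardioidaceae",
    "Aeromicrobium|Actinobacteriota|Actinobacteria|Propionibacteriales|Nocardioidaceae",
    "Terrabacter|Actinobacteriota|Actinobacteria|Micrococcales|Intrasporangiaceae",
    "Solirubrobacter|Actinobacteriota|Thermoleophilia|Solirubrobacterales|Solirubrobacteraceae",
    "Conexibacter|Actinobacteriota|Thermoleophilia|Solirubrobacterales|Conexibacteraceae",
    "Rubrobacter|Actinobacteriota|Rubrobacteria|Rubrobacterales|Rubrobacteraceae",
    "Iamia|Actinobacteriota|Acidimicrobiia|Microtrichales|Iamiaceae",
    "Bacillus|Firmicutes|Bacilli|Bacillales|Bacillaceae",
    "Paenibacillus|Firmicutes|Bacilli|Paenibacillales|Paenibacillaceae",
    "Gemmatimonas|Gemmatimonadota|Gemmatimonadetes|Gemmatimonadales|Gemmatimonadaceae",
    "Flavobacterium|Bacteroidota|Bacteroidia|Flavobacteriales|Flavobacteriaceae",
    "Massilia|Proteobacteria|Gammaproteobacteria|Burkholderiales|Oxalobacteraceae",
    "Ramlibacter|Proteobacteria|Gammaproteobacteria|Burkholderiales|Comamonadaceae",
    "Variovorax|Proteobacteria|Gammaproteobacteria|Burkholderiales|Comamonadaceae",
    "Luteimonas|Proteobacteria|Gammaproteobacteria|Lysobacterales|Lysobacteraceae",
    "Steroidobacter|Proteobacteria|Gammaproteobacteria|Steroidobacterales|Steroidobacteraceae",
    "Povalibacter|Proteobacteria|Gammaproteobacteria|Steroidobacterales|Steroidobacteraceae",
    "Haliangium|Myxococcota|Polyangia|Haliangiales|Haliangiaceae",
    "Rhodoplanes|Proteobacteria|Alphaproteobacteria|Rhizobiales|Xanthobacteraceae",
    "Bradyrhizobium|Proteobacteria|Alphaproteobacteria|Rhizobiales|Xanthobacteraceae",
    "Microvirga|Proteobacteria|Alphaproteobacteria|Rhizobiales|Beijerinckiaceae",
    "Devosia|Proteobacteria|Alphaproteobacteria|Rhizobiales|Devosiaceae",
    "Hyphomicrobium|Proteobacteria|Alphaproteobacteria|Rhizobiales|Hyphomicrobiaceae",
    "Pedomicrobium|Proteobacteria|Alphaproteobacteria|Rhizobiales|Hyphomicrobiaceae",
    "Phenylobacterium|Proteobacteria|Alphaproteobacteria|Caulobacterales|Caulobacteraceae",
    "Skermanella|Proteobacteria|Alphaproteobacteria|Rhodospirillales|Azospirillaceae",
    "Dongia|Proteobacteria|Alphaproteobacteria|Dongiales|Dongiaceae",
    "Altererythrobacter|Proteobacteria|Alphaproteobacteria|Sphingomonadales|Sphingomonadaceae",
    "Chthoniobacter|Verrucomicrobiota|Verrucomicrobiae|Chthoniobacterales|Chthoniobacteraceae",
    "Opitutus|Verrucomicrobiota|Opitutae|Opitutales|Opitutaceae")
  parts <- do.call(rbind, strsplit(raw, "|", fixed = TRUE))
  data.frame(domain = "Bacteria", phylum = parts[, 2], class = parts[, 3],
             order = parts[, 4], family = parts[, 5], genus = parts[, 1],
             stringsAsFactors = FALSE)
}

#' Default genus-to-guild map for the soil nitrogen cycle
#'
#' Example mapping of well-known nitrogen-cycle genera to functional
#' guilds: ammonia oxidation, nitrification, denitrification and N
#' fixation. Guild membership of environmental taxa is contested;
#' treat this as a starting point and supply your own map for real
#' analyses (see also the copy in `inst/extdata/nitrogen_guilds.tsv`).
#'
#' @return data frame with columns `genus` and `guild`.
#' @export
default_guild_map <- function() {
  data.frame(
    genus = c("Nitrosospira", "Sphingomonas", "Lysobacter", "Nitrospira",
              "Nocardioides", "Gaiella",
              "Ensifer", "Blastococcus", "Pseudolabrys"),
    guild = c("ammonia-oxidizer", "nitrifier", "nitrifier", "nitrifier",
              "denitrifier", "denitrifier",
              "N-fixer", "N-fixer", "N-fixer"),
    stringsAsFactors = FALSE)
}

# responsive modules per treatment: treatment j (j >= 2) raises one
# module and suppresses the next, cycling over modules
.module_delta <- function(n_modules, n_treatments) {
  delta <- matrix(0, n_modules, n_treatments)
  for (j in seq_len(n_treatments)[-1]) {
    up <- ((j - 2) * 2) %% n_modules + 1
    down <- ((j - 2) * 2 + 1) %% n_modules + 1
    delta[up, j] <- delta[up, j] + 1
    delta[down, j] <- delta[down, j] - 1
  }
  delta
}

#' Simulate a module-structured bacterial community
#'
#' Log-normal module-factor model: each taxon's latent log abundance is
#' an idiosyncratic baseline plus its module's shared per-sample factor
#' (weighted so the latent within-module correlation equals
#' `module_cor`) plus a treatment x day shift for responsive modules.
#' Per sample the latents are closed to proportions, perturbed by a
#' Dirichlet draw with concentration `dispersion`, and counted with a
#' multinomial of size `depth` — so every sample total equals `depth`
#' exactly. Taxonomy nests genera inside modules, drawing names from
#' [genus_catalog()].
#'
#' @param config a [simulation_config()].
#' @return list of class `community_simulation`: `counts` (taxa x
#'   samples), `taxonomy` (data frame), `metadata` (sample, treatment,
#'   day, replicate), `truth` (ground truth: `module_of`, `differential`,
#'   `delta`, `day_weight`, `env_loadings`, `guild_of`, `latent`).
#' @export
simulate_community <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  K <- config$n_modules
  n <- config$n_taxa
  treatments <- .TREATMENTS[seq_len(config$n_treatments)]
  metadata <- expand.grid(replicate = seq_len(config$n_replicates),
                          day = config$days, treatment = treatments,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  metadata <- metadata[, c("treatment", "day", "replicate")]
  metadata$sample <- sprintf("%s_d%02d_r%d", gsub("[^A-Za-z0-9]", "", metadata$treatment),
                             metadata$day, metadata$replicate)
  S <- nrow(metadata)
  taxa <- sprintf("OTU%04d", seq_len(n))
  module_of <- setNames(sort(rep_len(seq_len(K), n)), taxa)

  # taxonomy: genera nested in modules so genus-level tables keep the
  # planted structure
  cat <- genus_catalog()
  genus_module <- (seq_len(nrow(cat)) - 1) %% K + 1
  taxonomy <- do.call(rbind, lapply(seq_len(n), function(i) {
    pool <- which(genus_module == module_of[i])
    if (!length(pool)) pool <- seq_len(nrow(cat))
    cat[pool[(sum(module_of[seq_len(i)] == module_of[i]) - 1) %% length(pool) + 1], ]
  }))
  rownames(taxonomy) <- taxa

  # latent log abundances
  mu <- rnorm(n, 0, 1.5)
  day_weight <- setNames(seq(0.5, 1, length.out = length(config$days)),
                         config$days)
  delta <- .module_delta(K, config$n_treatments)
  colnames(delta) <- treatments
  rownames(delta) <- seq_len(K)
  fac <- matrix(rnorm(K * S), K, S)
  eps <- matrix(rnorm(n * S), n, S)
  shift <- config$module_effect *
    delta[, metadata$treatment, drop = FALSE] *
    rep(day_weight[as.character(metadata$day)], each = K)
  latent <- mu +
    sqrt(config$module_cor) * fac[module_of, ] +
    sqrt(1 - config$module_cor) * eps +
    shift[module_of, ]
  dimnames(latent) <- list(taxa, metadata$sample)

  counts <- matrix(0L, n, S, dimnames = dimnames(latent))
  for (s in seq_len(S)) {
    w <- exp(latent[, s])
    p <- w / sum(w)
    gam <- rgamma(n, shape = config$dispersion * p)
    if (sum(gam) == 0) gam <- p
    counts[, s] <- rmultinom(1, config$depth, gam / sum(gam))[, 1]
  }

  # differential ground truth: taxa of responsive modules, per
  # treatment and day, with the signed log-scale effect actually applied
  diffs <- expand.grid(treatment = treatments[-1], day = config$days,
                       module = seq_len(K), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  diffs$effect <- config$module_effect *
    delta[cbind(diffs$module, match(diffs$treatment, treatments))] *
    day_weight[as.character(diffs$day)]
  diffs <- diffs[diffs$effect != 0, , drop = FALSE]
  differential <- do.call(rbind, lapply(seq_len(nrow(diffs)), function(i) {
    tx <- names(module_of)[module_of == diffs$module[i]]
    data.frame(taxon = tx, module = diffs$module[i],
               treatment = diffs$treatment[i], day = diffs$day[i],
               effect = diffs$effect[i], stringsAsFactors = FALSE)
  }))
  if (is.null(differential))
    differential <- data.frame(taxon = character(), module = integer(),
                               treatment = character(), day = numeric(),
                               effect = numeric())

  # environmental loadings: each factor tracks one module positively and
  # the next negatively
  L <- matrix(0, length(.ENV_FACTORS), K,
              dimnames = list(.ENV_FACTORS, seq_len(K)))
  for (f in seq_along(.ENV_FACTORS)) {
    L[f, (f - 1) %% K + 1] <- 1
    L[f, f %% K + 1] <- -0.5
  }

  guild_map <- default_guild_map()
  guild_of <- setNames(rep("none", nrow(cat)), cat$genus)
  guild_of[guild_map$genus] <- guild_map$guild

  truth <- structure(list(module_of = module_of, differential = differential,
                          delta = delta, day_weight = day_weight,
                          env_loadings = L, guild_of = guild_of,
                          latent = latent), class = "ground_truth")
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 truth = truth, config = config),
            class = "community_simulation")
}

#' @export
print.community_simulation <- function(x, ...) {
  cat(sprintf("Synthetic community: %d taxa x %d samples (depth %d), %d modules\n",
              nrow(x$counts), ncol(x$counts), x$config$depth,
              x$config$n_modules))
  invisible(x)
}

#' Simulate environmental covariates coupled to module abundances
#'
#' Each factor is a linear combination of per-sample module relative
#' abundances (weights from the ground truth's `env_loadings`),
#' standardized across samples, plus Gaussian noise with SD
#' `env_noise_sd` — so `env_noise_sd` is a noise-to-signal ratio and a
#' factor with all-zero loadings is pure noise. Factor names follow the
#' leachate / incubation / pot vocabulary (`NO3_L`, `NH4_L`, `HCO3_L`,
#' `pH_L`, `NO3_S`, `NH4_S`, `pH_S`, `NO3_P`, `NH4_P`, `pH_P`, `NUE`,
#' `Yield`).
#'
#' @param truth `ground_truth` from [simulate_community()].
#' @param counts the simulated count table.
#' @param config the [simulation_config()] used.
#' @return samples x factors numeric matrix.
#' @export
simulate_environment <- function(truth, counts, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  L <- truth$env_loadings
  if (!all(colnames(L) %in% as.character(unique(truth$module_of))))
    stop("env loadings refer to unknown module ids")
  set.seed(config$seed + 1L)
  rel <- relative_abundance(counts)
  modab <- rowsum(rel, truth$module_of[rownames(rel)])
  signal <- t(L %*% modab[colnames(L), , drop = FALSE])
  z <- apply(signal, 2, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  env <- z + matrix(rnorm(length(z), sd = config$env_noise_sd),
                    nrow(z), ncol(z))
  dimnames(env) <- list(colnames(counts), rownames(L))
  env
}

#' Simulate an agronomic record table
#'
#' Per-replicate grain yield, aboveground biomass, 1000-grain weight,
#' plant N uptake and fertiliser N dose for a zero-N control, CRU and
#' CRU+FA pot experiment. Default treatment means follow typical wheat
#' pot-trial magnitudes (grain yield 37.6 / 81.6 / 99.6 g pot^-1) with a
#' 3.18 g pot^-1 fertiliser N dose (450 kg N ha^-1 scaled to a 30
#' cm-diameter pot); replicate noise is Gaussian with coefficient of
#' variation `residual_cv`.
#'
#' @param config a [simulation_config()] (supplies the seed).
#' @param n_replicates replicates per treatment (default 4, the usual
#'   pot-trial layout).
#' @param means named list of per-treatment mean vectors (`grain_yield`,
#'   `biomass`, `thousand_grain`, `n_uptake`), each of length 3 for
#'   control, CRU, CRU+FA.
#' @param n_dose fertiliser N dose per treatment (g pot^-1); the control
#'   must be 0.
#' @param residual_cv replicate coefficient of variation (0 gives every
#'   replicate its treatment mean exactly).
#' @return data frame of class `agronomic_table`: one row per replicate.
#' @export
simulate_agronomy <- function(config = simulation_config(),
                              n_replicates = 4,
                              means = list(
                                grain_yield = c(37.6, 81.6, 99.6),
                                biomass = c(82.6, 168.8, 196.2),
                                thousand_grain = c(53.6, 47.1, 59.3),
                                n_uptake = c(0.5, 1.626, 2.09)),
                              n_dose = c(0, 3.18, 3.18),
                              residual_cv = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  treatments <- c("control", "CRU", "CRU+FA")
  if (n_dose[1] != 0) stop("the zero-N control must have `n_dose` 0")
  if (any(n_dose[-1] <= 0)) stop("fertilised treatments need a positive dose")
  if (n_replicates < 2) stop("need at least 2 replicates")
  set.seed(config$seed + 2L)
  out <- do.call(rbind, lapply(seq_along(treatments), function(j) {
    draw <- function(m) rnorm(n_replicates, m, residual_cv * m)
    data.frame(treatment = treatments[j], replicate = seq_len(n_replicates),
               grain_yield = draw(means$grain_yield[j]),
               biomass = draw(means$biomass[j]),
               thousand_grain = draw(means$thousand_grain[j]),
               n_uptake = draw(means$n_uptake[j]),
               n_dose = n_dose[j], stringsAsFactors = FALSE)
  }))
  class(out) <- c("agronomic_table", "data.frame")
  out
}
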