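# Multi-study paired rhizosphere/bulk community generator with known ground
# truth. The generative model is a stand-in for observational survey data:
# log-normal base composition, taxon-level compartment log-fold effects with
# a study-level random effect on the log scale (variance tau2), block-
# correlated latent abundances to induce co-occurrence structure, and
# multinomial read sampling at a negative-binomial depth.

#' Build and validate a synthetic study-set configuration
#'
#' @param n_studies Number of paired studies.
#' @param n_per_group Samples per compartment per study.
#' @param n_taxa Number of taxa (ASVs).
#' @param depth_mean,depth_dispersion Mean and negative-binomial size of the
#'   per-sample sequencing depth.
#' @param frac_differential Fraction of taxa given a compartment effect.
#' @param frac_enriched Of the differential taxa, fraction enriched in the
#'   rhizosphere (the rest are depleted).
#' @param effect_range Range (log-ratio units, natural log) of the absolute
#'   compartment log-fold effects.
#' @param tau2 Between-study variance of the compartment effect
#'   (squared log-ratio units).
#' @param n_blocks Number of latent correlation blocks.
#' @param block_rho Within-block latent correlation, in [0, 1).
#' @param sigma_base SD of the log-normal base composition.
#' @param sigma_sample SD of the per-sample latent abundance noise.
#' @param operon_lambda_base,operon_lambda_enriched Poisson means (above the
#'   floor of 1 copy) for rRNA operon copies of background vs
#'   rhizosphere-enriched taxa; enriched taxa model copiotrophs.
#' @param ta_lambda_base,ta_lambda_enriched Poisson means for
#'   toxin-antitoxin gene counts of background vs enriched taxa.
#' @param sporulation_lambda Poisson mean for sporulation gene counts.
#' @param n_functions Number of functions in the generated function map.
#' @param seed Integer seed controlling all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_studies = 20, n_per_group = 5, n_taxa = 300,
                         depth_mean = 20000, depth_dispersion = 20,
                         frac_differential = 0.1, frac_enriched = 0.5,
                         effect_range = c(0.5, 1.5), tau2 = 0.05,
                         n_blocks = 6, block_rho = 0.6,
                         sigma_base = 1.5, sigma_sample = 0.7,
                         operon_lambda_base = 1.3, operon_lambda_enriched = 4.5,
                         ta_lambda_base = 1, ta_lambda_enriched = 4,
                         sporulation_lambda = 2,
                         n_functions = 5, seed = 1L) {
  cfg <- list(n_studies = n_studies, n_per_group = n_per_group,
              n_taxa = n_taxa, depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              frac_differential = frac_differential,
              frac_enriched = frac_enriched,
              effect_range = effect_range, tau2 = tau2,
              n_blocks = n_blocks, block_rho = block_rho,
              sigma_base = sigma_base, sigma_sample = sigma_sample,
              operon_lambda_base = operon_lambda_base,
              operon_lambda_enriched = operon_lambda_enriched,
              ta_lambda_base = ta_lambda_base,
              ta_lambda_enriched = ta_lambda_enriched,
              sporulation_lambda = sporulation_lambda,
              n_functions = n_functions, seed = as.integer(seed))
  with(cfg, {
    if (n_studies < 1 || n_per_group < 1 || n_taxa < 2 || depth_mean <= 0 ||
        depth_dispersion <= 0 || n_blocks < 1 || n_functions < 0) {
      abort("synth_config: counts and sizes must be strictly positive.")
    }
    if (frac_differential < 0 || frac_differential > 1 ||
        frac_enriched < 0 || frac_enriched > 1) {
      abort("synth_config: fractions must lie in [0, 1].")
    }
    if (block_rho < 0 || block_rho >= 1) {
      abort("synth_config: block_rho must lie in [0, 1).")
    }
    if (tau2 < 0) abort("synth_config: tau2 must be >= 0.")
    if (length(effect_range) != 2 || any(effect_range < 0) ||
        effect_range[1] > effect_range[2]) {
      abort("synth_config: effect_range must be an ascending non-negative pair.")
    }
  })
  structure(cfg, class = "synth_config")
}

# Soil phyla used to label synthetic taxa (labels only; no reference data).
SOIL_PHYLA <- c("Proteobacteria", "Actinobacteriota", "Acidobacteriota",
                "Bacteroidota", "Chloroflexi", "Firmicutes",
                "Verrucomicrobiota", "Planctomycetota")

SYNTH_FUNCTIONS <- c("cellulolysis", "ligninolysis", "nitrification",
                     "nitrogen_fixation", "chitinolysis", "methylotrophy",
                     "sulfate_respiration", "aromatic_degradation")

#' Generate a complete multi-study paired dataset with ground truth
#'
#' Draws counts, metadata, taxonomy, a random coalescent phylogeny, a trait
#' table coupled to the compartment effects (rhizosphere-enriched taxa
#' receive copiotroph-like operon counts and higher toxin-antitoxin gene
#' loads), a taxonomy-rule function map, and the ground truth needed to
#' validate every downstream stage.
#'
#' @param config A [synth_config()].
#' @return A list of class `rhizo_study_set` with elements `counts`,
#'   `metadata`, `taxonomy`, `tree`, `traits`, `function_map`, `truth`,
#'   `config`.
#' @export
generate_study_set <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  set.seed(config$seed)
  n_taxa <- config$n_taxa
  taxa <- sprintf("ASV_%04d", seq_len(n_taxa))

  # --- ground-truth effects -------------------------------------------------
  mu <- rnorm(n_taxa, 0, config$sigma_base)
  n_diff <- round(config$frac_differential * n_taxa)
  diff_idx <- if (n_diff > 0) sample.int(n_taxa, n_diff) else integer()
  n_up <- round(config$frac_enriched * n_diff)
  delta <- numeric(n_taxa)
  if (n_diff > 0) {
    mag <- runif(n_diff, config$effect_range[1], config$effect_range[2])
    sgn <- c(rep(1, n_up), rep(-1, n_diff - n_up))
    delta[diff_idx] <- mag * sgn
  }
  blocks <- rep_len(seq_len(config$n_blocks), n_taxa)[sample.int(n_taxa)]
  u_study <- rnorm(config$n_studies, 0, sqrt(config$tau2))

  # --- taxonomy -------------------------------------------------------------
  phylum <- sample(SOIL_PHYLA, n_taxa, replace = TRUE,
                   prob = c(30, 20, 13, 10, 9, 8, 6, 4))
  n_genera <- max(10L, n_taxa %/% 5L)
  genus_id <- sample.int(n_genera, n_taxa, replace = TRUE)
  taxonomy <- tibble(
    taxon_id = taxa,
    Kingdom = "Bacteria",
    Phylum = phylum,
    Class = paste0(substr(phylum, 1, 4), "_class_", (genus_id %% 3L) + 1L),
    Order = paste0(substr(phylum, 1, 4), "_order_", (genus_id %% 5L) + 1L),
    Family = sprintf("Family_%03d", (genus_id %% 40L) + 1L),
    Genus = sprintf("Genus_%03d", genus_id),
    Species = ""
  )

  # --- tree -----------------------------------------------------------------
  tree <- ape::rcoal(n_taxa, tip.label = sample(taxa))

  # --- traits (coupled to enrichment: copiotroph signature) -----------------
  enriched <- delta > 0
  operon <- 1 + rpois(n_taxa, ifelse(enriched, config$operon_lambda_enriched,
                                     config$operon_lambda_base))
  ta <- rpois(n_taxa, ifelse(enriched, config$ta_lambda_enriched,
                             config$ta_lambda_base))
  spor <- rpois(n_taxa, config$sporulation_lambda)
  nsti <- rlnorm(n_taxa, log(0.3), 0.8)
  traits <- tibble(taxon_id = taxa, operon_copies = operon,
                   toxin_antitoxin_genes = ta, sporulation_genes = spor,
                   nsti = nsti)

  # --- function map: taxonomy rules over genera -----------------------------
  fmap <- list()
  n_fun <- min(config$n_functions, length(SYNTH_FUNCTIONS))
  for (f in seq_len(n_fun)) {
    genera <- sprintf("Genus_%03d", sample.int(n_genera, min(3L, n_genera)))
    fmap[[SYNTH_FUNCTIONS[f]]] <- tibble(rank = "Genus", value = genera,
                                         exclude = FALSE)
  }
  fmap <- structure(fmap, class = "function_map")

  # --- counts + metadata ----------------------------------------------------
  n_samp <- config$n_studies * 2L * config$n_per_group
  count_mat <- matrix(0, n_samp, n_taxa, dimnames = list(NULL, taxa))
  meta <- vector("list", config$n_studies)
  sample_ids <- character(n_samp)
  row <- 0L
  ecosystems <- c("cropland", "forest", "grassland")
  for (s in seq_len(config$n_studies)) {
    eff_s <- delta + sign(delta) * u_study[s]   # study-level shift on log scale
    eco <- sample(ecosystems, 1)
    lat <- runif(1, -50, 60); lon <- runif(1, -160, 160)
    ph <- rnorm(1, 6.5, 0.8); soc <- rlnorm(1, log(15), 0.5)
    tn <- rlnorm(1, log(1.5), 0.4)
    for (comp in c("rhizosphere", "bulk")) {
      shift <- if (comp == "rhizosphere") eff_s else numeric(n_taxa)
      for (i in seq_len(config$n_per_group)) {
        row <- row + 1L
        f_block <- rnorm(config$n_blocks)
        z <- sqrt(config$block_rho) * f_block[blocks] +
          sqrt(1 - config$block_rho) * rnorm(n_taxa)
        loga <- mu + shift + config$sigma_sample * z
        p <- exp(loga - max(loga)); p <- p / sum(p)
        depth <- max(1L, rnbinom(1, mu = config$depth_mean,
                                 size = config$depth_dispersion))
        count_mat[row, ] <- rmultinom(1, depth, p)[, 1]
        sample_ids[row] <- sprintf("S%02d_%s%02d", s,
                                   if (comp == "rhizosphere") "R" else "B", i)
      }
    }
    meta[[s]] <- tibble(
      sample_id = sprintf("S%02d_%s%02d", s,
                          rep(c("R", "B"), each = config$n_per_group),
                          rep(seq_len(config$n_per_group), 2)),
      study_id = sprintf("study_%02d", s),
      compartment = rep(c("rhizosphere", "bulk"), each = config$n_per_group),
      pair_id = sprintf("S%02d_P%02d", s, rep(seq_len(config$n_per_group), 2)),
      ecosystem = eco, latitude = lat, longitude = lon,
      ph = ph, soc = soc, total_n = tn
    )
  }
  rownames(count_mat) <- sample_ids
  counts <- as_count_tbl(count_mat)
  metadata <- bind_rows(meta)

  # --- study-level variable truth at the latent-median composition ----------
  truth_rows <- list()
  for (s in seq_len(config$n_studies)) {
    eff_s <- delta + sign(delta) * u_study[s]
    p_b <- exp(mu - max(mu)); p_b <- p_b / sum(p_b)
    la_r <- mu + eff_s
    p_r <- exp(la_r - max(la_r)); p_r <- p_r / sum(p_r)
    vars_b <- latent_variables(p_b, operon, ta, spor)
    vars_r <- latent_variables(p_r, operon, ta, spor)
    truth_rows[[s]] <- tibble(
      study_id = sprintf("study_%02d", s),
      variable = names(vars_b),
      true_lnrr = log(vars_r / vars_b)
    )
  }
  truth <- list(
    taxon_effects = tibble(taxon_id = taxa, log_fold = delta,
                           differential = delta != 0, block = blocks),
    study_effects = tibble(study_id = sprintf("study_%02d",
                                              seq_len(config$n_studies)),
                           u = u_study),
    study_lnrr = bind_rows(truth_rows),
    tau2_true = config$tau2,
    min_effect = if (n_diff > 0) config$effect_range[1] else 0
  )

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                 tree = tree, traits = traits, function_map = fmap,
                 truth = truth, config = config),
            class = "rhizo_study_set")
}

# Community variables evaluated on a noise-free composition vector; used
# only to define the generator's study-level truth.
latent_variables <- function(p, operon, ta, spor) {
  H <- -sum(p * log(p))
  c(richness = sum(p > 0), shannon = H, pielou = H / log(sum(p > 0)),
    operon = sum(p * operon), toxin_antitoxin = sum(p * ta),
    sporulation = sum(p * spor))
}

#' Simulate study-level effect records for a single variable
#'
#' Draws `k` paired studies whose true log response ratios are normal with
#' mean `true_lnrr` and between-study variance `tau2`, generates per-sample
#' values in both compartments, and summarises each study into an effect
#' record. Used for calibration/coverage simulations of the meta-analysis
#' engine at known truth.
#'
#' @param k Number of studies.
#' @param true_lnrr Mean true log response ratio.
#' @param tau2 Between-study variance of the true effect.
#' @param n_per_group Samples per compartment per study.
#' @param cv Within-group coefficient of variation of the measured variable.
#' @param seed Integer seed.
#' @return A tibble of effect records (one row per study), as produced by
#'   [effect_from_groups()].
#' @export
simulate_lnrr_studies <- function(k, true_lnrr = 0, tau2 = 0,
                                  n_per_group = 5, cv = 0.2, seed = 1L) {
  set.seed(seed)
  base <- 100
  out <- vector("list", k)
  for (i in seq_len(k)) {
    theta <- rnorm(1, true_lnrr, sqrt(tau2))
    mu_c <- base * rlnorm(1, 0, 0.3)           # studies measure on their own scale
    mu_t <- mu_c * exp(theta)
    bulk <- abs(rnorm(n_per_group, mu_c, cv * mu_c))
    rhizo <- abs(rnorm(n_per_group, mu_t, cv * mu_t))
    out[[i]] <- effect_from_groups(rhizo, bulk,
                                   study_id = sprintf("study_%03d", i),
                                   variable = "variable")
  }
  bind_rows(out)
}

#' Write a generated study set to a fixture directory
#'
#' Emits the counts, metadata, taxonomy, traits (TSV), tree (newick),
#' function map (text) and ground truth (JSON), plus a manifest.
#'
#' @param dir_path Writable directory (created if absent).
#' @param bundle A `rhizo_study_set` from [generate_study_set()].
#' @return The manifest as a list (invisibly written to `manifest.json`).
#' @export
write_fixture <- function(dir_path, bundle) {
  stopifnot(inherits(bundle, "rhizo_study_set"))
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'.", dir_path))
  }
  files <- list(
    counts = "counts.tsv", metadata = "metadata.tsv",
    taxonomy = "taxonomy.tsv", tree = "tree.nwk", traits = "traits.tsv",
    function_map = "function_map.txt", ground_truth = "ground_truth.json"
  )
  p <- function(f) file.path(dir_path, f)
  write_count_table(bundle$counts, p(files$counts))
  write_metadata(bundle$metadata, p(files$metadata))
  write_taxonomy(bundle$taxonomy, p(files$taxonomy))
  write_tree(bundle$tree, p(files$tree))
  write_traits(bundle$traits, p(files$traits))
  write_function_map(bundle$function_map, p(files$function_map))
  truth <- bundle$truth
  jsonlite::write_json(
    list(taxon_effects = truth$taxon_effects,
         study_effects = truth$study_effects,
         study_lnrr = truth$study_lnrr,
         tau2_true = truth$tau2_true,
         min_effect = truth$min_effect),
    p(files$ground_truth), dataframe = "columns", auto_unbox = TRUE,
    digits = NA)
  manifest <- list(files = files, seed = bundle$config$seed,
                   n_studies = bundle$config$n_studies,
                   n_taxa = bundle$config$n_taxa)
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture directory back into a study-set bundle
#'
#' @param dir_path Directory written by [write_fixture()].
#' @return A list with `counts`, `metadata`, `taxonomy`, `tree`, `traits`,
#'   `function_map`, `truth`, `manifest`.
#' @export
read_fixture <- function(dir_path) {
  manifest <- jsonlite::read_json(file.path(dir_path, "manifest.json"),
                                  simplifyVector = TRUE)
  p <- function(f) file.path(dir_path, f)
  truth <- jsonlite::read_json(p(manifest$files$ground_truth),
                               simplifyVector = TRUE)
  list(counts = read_count_table(p(manifest$files$counts)),
       metadata = read_metadata(p(manifest$files$metadata)),
       taxonomy = read_taxonomy(p(manifest$files$taxonomy)),
       tree = read_tree(p(manifest$files$tree)),
       traits = read_traits(p(manifest$files$traits)),
       function_map = read_function_map(p(manifest$files$function_map)),
       truth = truth, manifest = manifest)
}
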