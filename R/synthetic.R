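# Synthetic multi-dataset expression generator with planted module
# structure, shared hub genes, directional differential expression and a
# druggable-gene subset. Emulates a multi-cohort irradiated-vs-control
# transcriptomics study closely enough that every downstream stage of the
# pipeline has recoverable ground truth.

#' Synthetic study configuration
#'
#' Defines the study conditions the generator emulates: several datasets
#' over a shared gene universe, module-correlated expression driven by an
#' irradiation response, planted hub genes shared across datasets,
#' condition-wise differential expression, and a druggable-gene subset.
#'
#' The expression model for a gene g of module m in dataset d is
#' `x_g = mu_g + s_g * |u_g| * e_m + eps`, with `eps ~ N(0, noise_sd^2)`
#' per sample. `|u_g|` is drawn from `loading_range_hub` for planted hubs
#' and `loading_range_nonhub` otherwise; the sign `s_g` and the loadings
#' are re-drawn per dataset, while hub status and module membership are
#' shared across datasets. The module eigengene `e_m` is the standardized
#' sum of (i) a saturating monotone dose effect with exponential time
#' decay, `dose_amplitude * dose/(dose + dose_half_gray) *
#' exp(-time/time_decay_hours)`, (ii) a condition-level random effect
#' shared by both arms of a condition (`condition_effect_sd`), and (iii)
#' sample-level noise (`eigengene_noise_sd`). Background genes are pure
#' noise. Planted differential expression adds `+/- de_effect_log2` to the
#' irradiated samples of the gene's planted conditions.
#'
#' @param n_genes Total genes in the shared universe.
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector (length `n_modules`) of module
#'   sizes; the remainder of the universe is background noise genes.
#' @param n_datasets Number of datasets (one network each).
#' @param samples_per_dataset Integer vector of sample counts.
#' @param conditions_per_dataset Integer vector of irradiation conditions
#'   per dataset; the total across datasets is the number of
#'   irradiated-vs-control comparisons (32 with the defaults).
#' @param hub_fraction_per_module Fraction of each module planted as hubs.
#' @param loading_range_hub,loading_range_nonhub Absolute-loading
#'   intervals within (0, 1); the hub interval must sit strictly above the
#'   non-hub one.
#' @param noise_sd Per-sample residual standard deviation (log2 scale).
#' @param de_effect_log2 Planted log2 shift for differential expression
#'   (default 1.5, clearing the 2-fold rule with margin).
#' @param frac_de Fraction of non-hub genes planted with a
#'   differential-expression direction.
#' @param de_hub_prob Probability that a planted hub gene also carries
#'   planted differential expression (default 0.9): hubs of
#'   radiation-responsive modules are typically themselves strongly
#'   radiation-responsive.
#' @param de_conditions_range Range of the number of conditions a planted
#'   gene is shifted in (drawn uniformly; the default 12..16 keeps planted
#'   genes above the 25% significance gate).
#' @param de_majority_prob Probability that an individual planted
#'   (gene, condition) shift follows the gene's majority direction; the
#'   remainder go the opposite way (default 0.75). Values below 1 emulate
#'   heterogeneous responses across doses/times and keep planted response
#'   patterns from forming their own correlation structure.
#' @param frac_druggable Fraction of genes present in the drug-target
#'   catalog.
#' @param condition_effect_sd Standard deviation of the condition-level
#'   random effect on module eigengenes (shared by both arms, so it
#'   cancels in fold-change contrasts).
#' @param eigengene_noise_sd Sample-level eigengene noise.
#' @param dose_amplitude,dose_half_gray,time_decay_hours Parameters of the
#'   irradiation dose-response component of the eigengenes.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   abundance `mu_g` (log2 scale).
#' @param seed Integer seed; the whole collection is deterministic
#'   given it.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1200,
                             n_modules = 5,
                             module_sizes = rep(150L, 5),
                             n_datasets = 5,
                             samples_per_dataset = c(168L, 168L, 144L, 144L, 144L),
                             conditions_per_dataset = c(7L, 7L, 6L, 6L, 6L),
                             hub_fraction_per_module = 0.07,
                             loading_range_hub = c(0.88, 0.96),
                             loading_range_nonhub = c(0.40, 0.60),
                             noise_sd = 1,
                             de_effect_log2 = 1.5,
                             frac_de = 0.25,
                             de_hub_prob = 0.9,
                             de_conditions_range = c(12L, 16L),
                             de_majority_prob = 0.75,
                             frac_druggable = 0.5,
                             condition_effect_sd = 0.5,
                             eigengene_noise_sd = 0.9,
                             dose_amplitude = 0.4,
                             dose_half_gray = 2,
                             time_decay_hours = 36,
                             baseline_mean = 7,
                             baseline_sd = 1.5,
                             seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_modules <- assert_count(n_modules, "n_modules")
  n_datasets <- assert_count(n_datasets, "n_datasets")
  if (length(module_sizes) != n_modules) {
    stop_coexhub("length(module_sizes) must equal n_modules",
                 "coexhub_bad_config")
  }
  if (length(samples_per_dataset) != n_datasets ||
      length(conditions_per_dataset) != n_datasets) {
    stop_coexhub("samples_per_dataset and conditions_per_dataset must have length n_datasets",
                 "coexhub_bad_config")
  }
  if (any(module_sizes < 2) || sum(module_sizes) > n_genes) {
    stop_coexhub("module_sizes must be >= 2 and sum to at most n_genes",
                 "coexhub_bad_config")
  }
  if (any(samples_per_dataset < 4)) {
    stop_coexhub("every dataset needs at least 4 samples", "coexhub_bad_config")
  }
  if (any(samples_per_dataset < 4 * conditions_per_dataset)) {
    stop_coexhub("every condition needs >= 2 control and >= 2 irradiated samples",
                 "coexhub_bad_config")
  }
  assert_fraction(hub_fraction_per_module, "hub_fraction_per_module")
  assert_fraction(de_majority_prob, "de_majority_prob", closed_right = TRUE)
  if (de_majority_prob <= 0.5) {
    stop_coexhub("`de_majority_prob` must exceed 0.5 so a majority direction exists",
                 "coexhub_bad_config")
  }
  assert_fraction(frac_de, "frac_de", closed_right = TRUE)
  assert_fraction(de_hub_prob, "de_hub_prob", closed_right = TRUE)
  assert_fraction(frac_druggable, "frac_druggable", closed_right = TRUE)
  for (rng in list(loading_range_hub, loading_range_nonhub)) {
    if (length(rng) != 2 || any(rng <= 0) || any(rng >= 1) || rng[1] > rng[2]) {
      stop_coexhub("loading ranges must be ordered intervals within (0, 1)",
                   "coexhub_bad_config")
    }
  }
  if (loading_range_hub[1] <= loading_range_nonhub[2]) {
    stop_coexhub("loading_range_hub must sit strictly above loading_range_nonhub",
                 "coexhub_bad_config")
  }
  if (noise_sd < 0 || de_effect_log2 <= 0) {
    stop_coexhub("noise_sd must be >= 0 and de_effect_log2 > 0",
                 "coexhub_bad_config")
  }
  structure(
    list(n_genes = n_genes, n_modules = n_modules,
         module_sizes = as.integer(module_sizes),
         n_datasets = n_datasets,
         samples_per_dataset = as.integer(samples_per_dataset),
         conditions_per_dataset = as.integer(conditions_per_dataset),
         hub_fraction_per_module = hub_fraction_per_module,
         loading_range_hub = loading_range_hub,
         loading_range_nonhub = loading_range_nonhub,
         noise_sd = noise_sd, de_effect_log2 = de_effect_log2,
         frac_de = frac_de,
         de_hub_prob = de_hub_prob,
         de_conditions_range = as.integer(de_conditions_range),
         de_majority_prob = de_majority_prob,
         frac_druggable = frac_druggable,
         condition_effect_sd = condition_effect_sd,
         eigengene_noise_sd = eigengene_noise_sd,
         dose_amplitude = dose_amplitude,
         dose_half_gray = dose_half_gray,
         time_decay_hours = time_decay_hours,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Allocate samples of one dataset to conditions and arms. Every condition
# gets an (as even as possible) share of samples, split half control /
# half irradiated.
design_dataset <- function(dataset_id, n_samples, condition_ids,
                           doses, times) {
  n_cond <- length(condition_ids)
  base <- n_samples %/% n_cond
  extra <- n_samples %% n_cond
  per_cond <- rep(base, n_cond) + c(rep(1L, extra), rep(0L, n_cond - extra))
  rows <- list()
  s <- 0L
  for (ci in seq_len(n_cond)) {
    n_c <- per_cond[ci]
    n_ctrl <- n_c %/% 2L
    arms <- c(rep("control", n_ctrl), rep("irradiated", n_c - n_ctrl))
    rows[[ci]] <- data.frame(
      sample_id = sprintf("%s_S%03d", dataset_id, s + seq_len(n_c)),
      condition_id = condition_ids[ci],
      arm = arms,
      dose_gray = ifelse(arms == "irradiated", doses[ci], 0),
      time_hours = times[ci],
      stringsAsFactors = FALSE
    )
    s <- s + n_c
  }
  do.call(rbind, rows)
}

#' Generate a synthetic multi-dataset expression collection
#'
#' Produces one `expression_dataset` per configured dataset, the ground
#' truth used to validate every downstream stage, and a drug-target
#' catalog covering the druggable genes. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#'
#' @return A list of class `synthetic_collection` with elements
#'   `datasets` (list of `expression_dataset`), `truth` (see Details) and
#'   `catalog` (a `drug_target_catalog`).
#'
#' @details `truth` is a list with: `module_of_gene` (named integer, 0 =
#'   background), `hub_genes`, `druggable_genes`, `de_direction` (data
#'   frame gene_id/condition_id/direction of the planted shifts),
#'   `consistent_direction` (named vector up/down/none, derived from the
#'   planted shifts by the same majority rule the pipeline applies: at
#'   least 25% of all conditions shifted, strict majority of directions),
#'   `conditions` (condition design table) and `eigengenes` (list per
#'   dataset of the planted module factors, for factor-recovery checks).
#' @export
generate_collection <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cf <- config
  genes <- sprintf("G%05d", seq_len(cf$n_genes))
  n_mod_genes <- sum(cf$module_sizes)

  # module membership: contiguous blocks over a random gene order, so
  # module labels are not confounded with lexicographic gene order
  shuffled <- sample(genes)
  module_of_gene <- stats::setNames(rep(UNASSIGNED, cf$n_genes), genes)
  offset <- 0L
  for (m in seq_len(cf$n_modules)) {
    members <- shuffled[offset + seq_len(cf$module_sizes[m])]
    module_of_gene[members] <- m
    offset <- offset + cf$module_sizes[m]
  }

  # hubs: a fixed subset of each module, shared across datasets
  hub_genes <- unlist(lapply(seq_len(cf$n_modules), function(m) {
    members <- names(module_of_gene)[module_of_gene == m]
    sample(members, max(1L, ceiling(cf$hub_fraction_per_module * length(members))))
  }))
  hub_genes <- sort(hub_genes)

  druggable_genes <- sort(sample(genes, round(cf$frac_druggable * cf$n_genes)))

  # condition design: globally unique condition ids with dataset-specific
  # dose (Gy) and time post-irradiation (h)
  dataset_ids <- sprintf("DS%d", seq_len(cf$n_datasets))
  cond_list <- list()
  for (d in seq_len(cf$n_datasets)) {
    n_cond <- cf$conditions_per_dataset[d]
    cond_list[[d]] <- data.frame(
      condition_id = sprintf("%s_C%02d", dataset_ids[d], seq_len(n_cond)),
      dataset_id = dataset_ids[d],
      dose_gray = sample(c(1, 2, 4, 6, 8, 10), n_cond, replace = TRUE),
      time_hours = sample(c(4, 8, 24, 48), n_cond, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  conditions <- do.call(rbind, cond_list)
  n_conditions <- nrow(conditions)

  # planted differential expression: each planted gene gets one direction
  # and a random subset of conditions
  non_hubs <- setdiff(genes, hub_genes)
  de_genes <- sort(c(
    hub_genes[stats::runif(length(hub_genes)) < cf$de_hub_prob],
    sample(non_hubs, round(cf$frac_de * length(non_hubs)))
  ))
  de_rows <- list()
  for (g in de_genes) {
    major <- sample(c("up", "down"), 1)
    minor <- setdiff(c("up", "down"), major)
    lo <- min(cf$de_conditions_range[1], n_conditions)
    hi <- min(cf$de_conditions_range[2], n_conditions)
    n_de <- if (lo == hi) lo else sample(seq(lo, hi), 1)
    conds <- sample(conditions$condition_id, n_de)
    dirs <- sample(c(major, minor), n_de, replace = TRUE,
                   prob = c(cf$de_majority_prob, 1 - cf$de_majority_prob))
    de_rows[[g]] <- data.frame(gene_id = g, condition_id = conds,
                               direction = dirs, stringsAsFactors = FALSE)
  }
  de_direction <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(gene_id = character(0), condition_id = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(de_direction) <- NULL

  # truth consistency by the majority rule over ALL conditions
  min_sig <- ceiling(0.25 * n_conditions)
  consistent_direction <- stats::setNames(rep("none", cf$n_genes), genes)
  if (nrow(de_direction) > 0) {
    for (g in unique(de_direction$gene_id)) {
      sub <- de_direction[de_direction$gene_id == g, ]
      n_up <- sum(sub$direction == "up")
      n_down <- sum(sub$direction == "down")
      if (n_up + n_down >= min_sig && n_up != n_down) {
        consistent_direction[g] <- if (n_up > n_down) "up" else "down"
      }
    }
  }

  baseline <- stats::rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)
  names(baseline) <- genes

  # per-module dose-response parameters (shared across datasets: the same
  # biology drives every cohort)
  d50 <- stats::runif(cf$n_modules, 0.5, 1.5) * cf$dose_half_gray
  tau <- stats::runif(cf$n_modules, 0.75, 1.25) * cf$time_decay_hours

  datasets <- list()
  planted_eigengenes <- list()
  for (d in seq_len(cf$n_datasets)) {
    did <- dataset_ids[d]
    cond_d <- conditions[conditions$dataset_id == did, , drop = FALSE]
    md <- design_dataset(did, cf$samples_per_dataset[d],
                         cond_d$condition_id, cond_d$dose_gray,
                         cond_d$time_hours)
    n_s <- nrow(md)

    # module eigengenes over this dataset's samples
    eig <- matrix(0, cf$n_modules, n_s,
                  dimnames = list(sprintf("M%d", seq_len(cf$n_modules)),
                                  md$sample_id))
    for (m in seq_len(cf$n_modules)) {
      b_cond <- stats::rnorm(nrow(cond_d), 0, cf$condition_effect_sd)
      names(b_cond) <- cond_d$condition_id
      f <- cf$dose_amplitude * md$dose_gray / (md$dose_gray + d50[m]) *
        exp(-md$time_hours / tau[m])
      e_raw <- f + b_cond[md$condition_id] +
        stats::rnorm(n_s, 0, cf$eigengene_noise_sd)
      eig[m, ] <- as.numeric(scale(e_raw))
    }
    planted_eigengenes[[did]] <- eig

    # per-dataset loadings: re-drawn magnitude and sign
    u <- numeric(cf$n_genes)
    names(u) <- genes
    is_hub <- genes %in% hub_genes
    in_module <- module_of_gene != UNASSIGNED
    u[in_module & is_hub] <- stats::runif(sum(in_module & is_hub),
                                          cf$loading_range_hub[1],
                                          cf$loading_range_hub[2])
    u[in_module & !is_hub] <- stats::runif(sum(in_module & !is_hub),
                                           cf$loading_range_nonhub[1],
                                           cf$loading_range_nonhub[2])
    s_sign <- sample(c(-1, 1), cf$n_genes, replace = TRUE)

    x <- matrix(stats::rnorm(cf$n_genes * n_s, 0, cf$noise_sd),
                cf$n_genes, n_s, dimnames = list(genes, md$sample_id))
    x <- x + baseline
    for (m in seq_len(cf$n_modules)) {
      idx <- which(module_of_gene == m)
      x[idx, ] <- x[idx, ] +
        (s_sign[idx] * u[idx]) %o% eig[m, ]
    }

    # planted DE shifts on irradiated samples of the planted conditions
    de_d <- de_direction[de_direction$condition_id %in% cond_d$condition_id, ,
                         drop = FALSE]
    if (nrow(de_d) > 0) {
      irr_of_cond <- split(md$sample_id[md$arm == "irradiated"],
                           md$condition_id[md$arm == "irradiated"])
      for (i in seq_len(nrow(de_d))) {
        cols <- irr_of_cond[[de_d$condition_id[i]]]
        shift <- if (de_d$direction[i] == "up") cf$de_effect_log2 else
          -cf$de_effect_log2
        x[de_d$gene_id[i], cols] <- x[de_d$gene_id[i], cols] + shift
      }
    }

    datasets[[did]] <- structure(
      list(dataset_id = did, values = x, metadata = md),
      class = "expression_dataset"
    )
  }

  # drug-target catalog: 1-3 drugs per druggable gene
  n_drugs <- sample(1:3, length(druggable_genes), replace = TRUE)
  catalog <- data.frame(
    gene_id = rep(druggable_genes, n_drugs),
    stringsAsFactors = FALSE
  )
  catalog$drug_name <- sprintf("CPD-%04d", seq_len(nrow(catalog)))
  catalog$status <- sample(CATALOG_STATUSES, nrow(catalog), replace = TRUE)
  catalog <- as_drug_target_catalog(catalog)

  truth <- list(module_of_gene = module_of_gene,
                hub_genes = hub_genes,
                druggable_genes = druggable_genes,
                de_direction = de_direction,
                consistent_direction = consistent_direction,
                conditions = conditions,
                eigengenes = planted_eigengenes,
                min_sig = min_sig)

  structure(list(datasets = datasets, truth = truth, catalog = catalog,
                 config = config),
            class = "synthetic_collection")
}

#' Synthetic annotation collection aligned with the planted modules
#'
#' Builds a GMT-style term collection over the synthetic gene universe:
#' for each planted module a few "signal" terms (random subsets of the
#' module's genes) plus random background terms, so enrichment of
#' module-derived gene sets is detectable by construction.
#'
#' @param truth The `truth` element of a [generate_collection()] result.
#' @param n_background_terms Number of random terms (default 20).
#' @param terms_per_module Signal terms per module (default 2).
#' @param seed Integer seed.
#'
#' @return An `annotation_collection` over the full synthetic universe.
#' @export
synthetic_annotations <- function(truth, n_background_terms = 20,
                                  terms_per_module = 2, seed = 1) {
  set.seed(seed)
  genes <- names(truth$module_of_gene)
  terms <- list()
  for (m in setdiff(sort(unique(truth$module_of_gene)), UNASSIGNED)) {
    members <- genes[truth$module_of_gene == m]
    for (j in seq_len(terms_per_module)) {
      size <- sample(seq(10, max(11, length(members) %/% 2)), 1)
      terms[[sprintf("MODTERM_M%d_%d", m, j)]] <- sample(members, min(size, length(members)))
    }
  }
  for (j in seq_len(n_background_terms)) {
    terms[[sprintf("RNDTERM_%02d", j)]] <- sample(genes, sample(10:60, 1))
  }
  annotation_collection(terms, universe = genes)
}
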