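#' Module specification for the synthetic cohort generator
#'
#' Describes one planted co-expression module: a latent factor shared by
#' `size` genes, induced by one stimulus, optionally carrying an outcome
#' effect (mean shift of the factor in susceptible subjects) and/or a
#' connectivity effect (loadings scaled up in susceptible subjects, which
#' raises within-module correlation without moving marginal means).
#'
#' @param size number of genes in the module.
#' @param stimulus stimulus label that activates the module (e.g. "LPS").
#' @param eigen_effect standardized mean shift of the module factor in
#'   stimulated samples (the stimulation response).
#' @param loading_mean,loading_sd mean and sd of per-gene factor loadings.
#' @param connectivity_boost multiplicative factor applied to loadings of the
#'   *stochastic* factor component in susceptible subjects; values > 1 plant
#'   stronger wiring in the susceptible stratum with unchanged means.
#' @param predictive logical; marks the module as the planted risk module.
#' @param outcome_shift standardized mean shift of the factor in stimulated
#'   samples of susceptible subjects (the planted predictive signal).
#' @param name optional module name; defaults to `M<k>` at generation time.
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(size, stimulus = "LPS", eigen_effect = 2,
                        loading_mean = 1.5, loading_sd = 0.3,
                        connectivity_boost = 1, predictive = FALSE,
                        outcome_shift = 0, name = NULL) {
  if (size < 2) stop_cfg("module size must be >= 2 (got %d)", size)
  if (loading_sd <= 0) stop_cfg("loading_sd must be > 0")
  if (connectivity_boost <= 0) stop_cfg("connectivity_boost must be > 0")
  structure(list(size = as.integer(size), stimulus = stimulus,
                 eigen_effect = eigen_effect, loading_mean = loading_mean,
                 loading_sd = loading_sd,
                 connectivity_boost = connectivity_boost,
                 predictive = isTRUE(predictive),
                 outcome_shift = outcome_shift, name = name),
            class = "module_spec")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the profiled high-risk birth cohort: 50 subjects with 46%
#' outcome prevalence, paired stimulated/unstimulated samples for three
#' stimuli, 17,363 transcripts, 39 cytokines, 47 metabolites, 8 cell types,
#' and the six stimulus-specific interferon/proinflammatory modules at their
#' reported sizes, with the LPS interferon module planted as predictive and
#' more strongly wired in susceptible subjects. Tests and examples pass
#' scaled-down values explicitly.
#'
#' @param n_subjects number of subjects.
#' @param prevalence outcome prevalence in (0,1); assignment is deterministic
#'   (the first `ceiling(prevalence * n_subjects)` shuffled subjects), so the
#'   realized count is exact for every seed.
#' @param n_genes total number of genes (modules + TFs + background).
#' @param stimuli character vector of stimulus labels (CTRL is implicit).
#' @param modules list of [module_spec()] objects.
#' @param n_tfs number of simulated transcription-factor genes.
#' @param targets_per_tf regulon size for each TF.
#' @param tf_mode_fraction_negative fraction of repressed (mode -1) targets.
#' @param tf_effect standardized stimulus effect on each TF's expression.
#' @param noise_sd residual gene-level noise sd (log2 scale).
#' @param n_cytokines,n_metabolites,n_celltypes block sizes for the companion
#'   omics layers.
#' @param seed integer seed; all generator randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 50, prevalence = 0.46, n_genes = 17363,
                       stimuli = c("LPS", "IMQ", "PIC"),
                       modules = default_modules(),
                       n_tfs = 50, targets_per_tf = 20,
                       tf_mode_fraction_negative = 0.25, tf_effect = 2,
                       noise_sd = 1, n_cytokines = 39, n_metabolites = 47,
                       n_celltypes = 8, seed = 1L) {
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        prevalence = prevalence, n_genes = as.integer(n_genes),
                        stimuli = stimuli, modules = modules,
                        n_tfs = as.integer(n_tfs),
                        targets_per_tf = as.integer(targets_per_tf),
                        tf_mode_fraction_negative = tf_mode_fraction_negative,
                        tf_effect = tf_effect, noise_sd = noise_sd,
                        n_cytokines = as.integer(n_cytokines),
                        n_metabolites = as.integer(n_metabolites),
                        n_celltypes = as.integer(n_celltypes),
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_modules <- function() {
  list(
    module_spec(180, "LPS", predictive = TRUE, outcome_shift = 1,
                connectivity_boost = 1.5, name = "IFN_LPS"),
    module_spec(2297, "LPS", name = "INFLAM_LPS"),
    module_spec(1114, "IMQ", name = "IFN_IMQ"),
    module_spec(924, "IMQ", name = "INFLAM_IMQ"),
    module_spec(2201, "PIC", name = "IFN_PIC"),
    module_spec(646, "PIC", name = "INFLAM_PIC")
  )
}

validate_sim_config <- function(cfg) {
  msize <- sum(vapply(cfg$modules, function(m) m$size, integer(1)))
  if (msize + cfg$n_tfs > cfg$n_genes) {
    stop_cfg("invalid config: sum of module sizes (%d) + n_tfs (%d) exceeds n_genes (%d)",
             msize, cfg$n_tfs, cfg$n_genes)
  }
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    stop_cfg("invalid config: prevalence must lie in (0,1), got %g", cfg$prevalence)
  }
  n_pos <- ceiling(cfg$prevalence * cfg$n_subjects)
  if (n_pos < 2 || cfg$n_subjects - n_pos < 2) {
    stop_cfg("invalid config: need >= 2 subjects per outcome group (prevalence %g of %d gives %d/%d)",
             cfg$prevalence, cfg$n_subjects, n_pos, cfg$n_subjects - n_pos)
  }
  if (cfg$noise_sd <= 0) stop_cfg("invalid config: noise_sd must be > 0")
  if (length(cfg$stimuli) < 1) stop_cfg("invalid config: at least one stimulus required")
  for (m in cfg$modules) {
    if (!m$stimulus %in% cfg$stimuli) {
      stop_cfg("invalid config: module stimulus '%s' not among stimuli", m$stimulus)
    }
  }
  if (cfg$tf_mode_fraction_negative < 0 || cfg$tf_mode_fraction_negative > 1) {
    stop_cfg("invalid config: tf_mode_fraction_negative must lie in [0,1]")
  }
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))
tf_ids <- function(n) sprintf("TF%03d", seq_len(n))

#' Planted TF-target regulon table
#'
#' Draws, reproducibly from `config$seed`, the ground-truth regulons used by
#' [generate_cohort()]: each TF receives `targets_per_tf` target genes from
#' the non-module gene pool, a signed mode (negative with probability
#' `tf_mode_fraction_negative`) and a weight in (0.5, 1).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns tf, target, mode, weight, stimulus, module.
#' @export
generate_regulon_truth <- function(config) {
  validate_sim_config(config)
  if (config$n_tfs < 1) stop_cfg("n_tfs must be >= 1")
  layout <- cohort_layout(config)
  pool <- layout$background
  if (config$targets_per_tf > length(pool)) {
    stop_cfg("targets_per_tf (%d) exceeds available non-module, non-TF genes (%d)",
             config$targets_per_tf, length(pool))
  }
  with_seed(derive_seed(config$seed, 101), {
    out <- lapply(seq_len(config$n_tfs), function(k) {
      targets <- sample(pool, config$targets_per_tf)
      mode <- ifelse(stats::runif(config$targets_per_tf) <
                       config$tf_mode_fraction_negative, -1, 1)
      weight <- stats::runif(config$targets_per_tf, 0.5, 1)
      data.frame(tf = tf_ids(config$n_tfs)[k], target = targets,
                 mode = mode, weight = weight,
                 stimulus = config$stimuli[(k - 1L) %% length(config$stimuli) + 1L],
                 stringsAsFactors = FALSE)
    })
    reg <- do.call(rbind, out)
    n_mod <- length(config$modules)
    if (n_mod > 0) {
      mod_names <- module_names(config)
      reg$module <- mod_names[match(reg$stimulus,
                                    vapply(config$modules, `[[`, "", "stimulus"))]
    } else reg$module <- NA_character_
    rownames(reg) <- NULL
    reg
  })
}

module_names <- function(config) {
  vapply(seq_along(config$modules), function(k) {
    config$modules[[k]]$name %||% sprintf("M%d", k)
  }, "")
}

# Fixed deterministic gene layout: module blocks first, then TFs, then
# background genes (the regulon target pool).
cohort_layout <- function(config) {
  ids <- gene_ids(config$n_genes)
  sizes <- vapply(config$modules, function(m) m$size, integer(1))
  idx <- if (length(sizes)) split(seq_len(sum(sizes)),
                                  rep(seq_along(sizes), sizes)) else list()
  module_genes <- lapply(idx, function(i) ids[i])
  names(module_genes) <- module_names(config)
  tf_start <- sum(sizes)
  tfs <- tf_ids(config$n_tfs)
  all_ids <- ids
  if (config$n_tfs > 0) all_ids[tf_start + seq_len(config$n_tfs)] <- tfs
  background <- all_ids[setdiff(seq_len(config$n_genes),
                                seq_len(tf_start + config$n_tfs))]
  list(ids = all_ids, module_genes = module_genes, tfs = tfs,
       background = background)
}

#' Generate a paired stimulated/control synthetic cohort
#'
#' Emits a log2-scale expression matrix (genes x samples) with one CTRL and
#' one sample per stimulus for every subject, a sample table, matched
#' cytokine/metabolite matrices, per-subject cell proportions and the ground
#' truth (planted module membership, driver TFs, predictive genes, outcome,
#' factor scores). Module genes follow a one-factor model
#' `gene = mu + loading * factor + noise`; the factor carries the stimulus
#' effect, an optional outcome shift, and subject-level variation whose
#' loadings are scaled by `connectivity_boost` in susceptible subjects only.
#' TF genes respond to their assigned stimulus and drive their regulon
#' targets with signed weights. Fully reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `expr`, `samples`, `cytokines`, `metabolites`,
#'   `cellprops`, `truth`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  layout <- cohort_layout(config)
  regulons <- if (config$n_tfs > 0) generate_regulon_truth(config) else NULL
  n <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  conds <- c("CTRL", config$stimuli)
  samples <- data.frame(
    sample_id = as.vector(outer(subjects, conds, paste, sep = "_")),
    subject_id = rep(subjects, times = length(conds)),
    stimulus = rep(conds, each = n),
    age = "birth",
    stringsAsFactors = FALSE
  )

  with_seed(config$seed, {
    n_pos <- ceiling(config$prevalence * n)
    outcome <- integer(n)
    outcome[sample.int(n)[seq_len(n_pos)]] <- 1L
    names(outcome) <- subjects
    samples$outcome <- outcome[samples$subject_id]

    ns <- nrow(samples)
    mu <- stats::rnorm(config$n_genes, mean = 7, sd = 2)
    expr <- matrix(stats::rnorm(config$n_genes * ns, sd = config$noise_sd),
                   nrow = config$n_genes, ncol = ns,
                   dimnames = list(layout$ids, samples$sample_id))
    expr <- expr + mu

    stim_of_sample <- samples$stimulus
    subj_idx <- match(samples$subject_id, subjects)
    y <- outcome[subjects]

    factor_scores <- NULL
    if (length(config$modules)) {
      factor_scores <- matrix(0, nrow = length(config$modules), ncol = ns,
                              dimnames = list(module_names(config),
                                              samples$sample_id))
      for (k in seq_along(config$modules)) {
        m <- config$modules[[k]]
        genes <- layout$module_genes[[k]]
        u <- stats::rnorm(n)            # subject baseline latent
        r <- stats::rnorm(n)            # subject response amplitude latent
        is_stim <- as.numeric(stim_of_sample == m$stimulus)
        # deterministic (mean) part and stochastic part of the factor
        f_mean <- is_stim * (m$eigen_effect + m$outcome_shift * y[subj_idx])
        f_rand <- u[subj_idx] + is_stim * r[subj_idx]
        factor_scores[k, ] <- f_mean + f_rand
        loadings <- stats::rnorm(m$size, m$loading_mean, m$loading_sd)
        boost <- ifelse(y[subj_idx] == 1L, m$connectivity_boost, 1)
        # boost applies to the stochastic part only: stronger wiring in the
        # susceptible stratum, identical marginal means
        contrib <- loadings %o% f_mean + loadings %o% (boost * f_rand)
        expr[genes, ] <- expr[genes, ] + contrib
      }
    }

    if (config$n_tfs > 0) {
      a <- matrix(stats::rnorm(config$n_tfs * n), nrow = config$n_tfs)
      tf_stim <- config$stimuli[(seq_len(config$n_tfs) - 1L) %%
                                  length(config$stimuli) + 1L]
      z_tf <- matrix(0, nrow = config$n_tfs, ncol = ns)
      for (k in seq_len(config$n_tfs)) {
        is_stim <- as.numeric(stim_of_sample == tf_stim[k])
        z <- a[k, subj_idx] + is_stim * config$tf_effect
        expr[layout$tfs[k], ] <- expr[layout$tfs[k], ] +
          stats::rnorm(ns, sd = 0.25) + z
        z_tf[k, ] <- z
      }
      for (i in seq_len(nrow(regulons))) {
        k <- match(regulons$tf[i], layout$tfs)
        g <- regulons$target[i]
        expr[g, ] <- expr[g, ] +
          regulons$mode[i] * regulons$weight[i] * (z_tf[k, ] - mean(z_tf[k, ]))
      }
    }

    cyt <- companion_block(config$n_cytokines, "cyt", factor_scores,
                           ns, samples$sample_id, 0.8)
    met <- companion_block(config$n_metabolites, "met", factor_scores,
                           ns, samples$sample_id, 0.6)
    cp <- matrix(stats::rgamma(n * config$n_celltypes, shape = 4), nrow = n,
                 dimnames = list(subjects,
                                 sprintf("cell%02d", seq_len(config$n_celltypes))))
    cp <- cp / rowSums(cp)

    membership <- rep(names(layout$module_genes),
                      vapply(layout$module_genes, length, integer(1)))
    names(membership) <- unlist(layout$module_genes, use.names = FALSE)
    predictive <- unlist(layout$module_genes[vapply(config$modules,
                                                    `[[`, TRUE, "predictive")],
                         use.names = FALSE)
    driver_tfs <- if (!is.null(regulons)) {
      split(unique(regulons[, c("tf", "module")])$tf,
            unique(regulons[, c("tf", "module")])$module)
    } else list()

    truth <- list(module_membership = membership,
                  driver_tfs = driver_tfs,
                  predictive_genes = predictive %||% character(0),
                  outcome = outcome,
                  factor_scores = factor_scores,
                  regulons = regulons)

    expr <- set_expr_scale(expr, "log2")
    list(expr = expr, samples = samples, cytokines = cyt, metabolites = met,
         cellprops = cp, truth = truth)
  })
}

companion_block <- function(n_feat, prefix, factor_scores, ns, sample_ids, w) {
  if (n_feat == 0) return(NULL)
  b <- matrix(stats::rnorm(n_feat * ns), nrow = n_feat,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                              sample_ids))
  if (!is.null(factor_scores) && nrow(factor_scores) > 0) {
    link <- (seq_len(n_feat) - 1L) %% nrow(factor_scores) + 1L
    b <- b + w * factor_scores[link, , drop = FALSE]
  }
  b
}

#' Convert a log2-scale cohort matrix to integer counts
#'
#' Inverse-log transform followed by Poisson rounding; exercises the counts
#' entry point of the normalization stage.
#'
#' @param expr log2-scale expression matrix.
#' @param seed integer seed.
#' @return integer count matrix with `scale` attribute "counts".
#' @export
cohort_counts <- function(expr, seed = 1L) {
  assert_expr_matrix(expr)
  with_seed(seed, {
    lambda <- pmin(2^expr, 1e7)
    cnt <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(expr),
                  dimnames = dimnames(expr))
    set_expr_scale(cnt, "counts")
  })
}

#' Generate an external validation cohort sharing part of a gene namespace
#'
#' Draws an independent cohort from `config` (fresh subjects, fresh seed
#' stream) carrying the same planted predictive structure, then keeps exactly
#' `round(overlap_fraction * length(shared_genes))` of `shared_genes` under
#' their original ids and renames every other gene, emulating transfer
#' prediction to an external cohort filtered to identical input genes.
#'
#' @param config a [sim_config()]; gene layout must match the internal cohort.
#' @param shared_genes gene ids (from `config`'s namespace) available for
#'   sharing.
#' @param overlap_fraction fraction of `shared_genes` kept under identical
#'   ids, in (0, 1].
#' @param stimulus stimulus whose baseline-adjusted response is returned;
#'   defaults to the first predictive module's stimulus.
#' @return list with `expr` (baseline-adjusted genes x subjects), `labels`
#'   (named 0/1 vector) and `truth`.
#' @export
generate_external_cohort <- function(config, shared_genes, overlap_fraction = 1,
                                     stimulus = NULL) {
  if (length(shared_genes) == 0) stop_cfg("shared_genes must be nonempty")
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop_cfg("overlap_fraction must lie in (0,1]")
  }
  ext_cfg <- config
  ext_cfg$seed <- as.integer(derive_seed(config$seed, 7919) %% 2147483647)
  cohort <- generate_cohort(ext_cfg)
  if (is.null(stimulus)) {
    pred <- which(vapply(config$modules, `[[`, TRUE, "predictive"))
    stimulus <- if (length(pred)) config$modules[[pred[1]]]$stimulus else config$stimuli[1]
  }
  adj <- baseline_adjust(cohort$expr, cohort$samples, stimulus)
  shared_genes <- intersect(shared_genes, rownames(adj))
  if (length(shared_genes) == 0) stop_cfg("no shared_genes present in cohort namespace")
  n_keep <- round(overlap_fraction * length(shared_genes))
  keep <- sort(shared_genes)[seq_len(max(n_keep, 1L))]
  renames <- setdiff(rownames(adj), keep)
  new_ids <- rownames(adj)
  new_ids[match(renames, rownames(adj))] <- paste0("EXT_", renames)
  rownames(adj) <- new_ids
  labels <- cohort$truth$outcome
  list(expr = adj, labels = labels, truth = cohort$truth)
}
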