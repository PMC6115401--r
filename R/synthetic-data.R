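#' Configuration for the synthetic bulk-tumor cohort generator
#'
#' Collects every knob of [simulate_bulk_cohort()] with defaults that
#' emulate the structure of a purity-confounded bladder-cancer cohort:
#' each bulk sample is a purity-weighted three-component mixture
#' (cancer / stroma / immune), EMT and stromal-signature genes load on the
#' stromal component and T-cell markers on the immune component, so the
#' ITA and EMT scores are correlated solely through shared `(1 - purity)`
#' unless additional couplings are configured. Survival follows a Cox
#' model on the standardized scores, and objective response follows a
#' logistic model with a CD8 x stroma interaction.
#'
#' @param n_samples Cohort size (default 400).
#' @param n_genes Total genes (default 2000).
#' @param n_emt,n_t_marker,n_stromal,n_immune Sizes of the hallmark-EMT,
#'   T-cell marker, stromal-signature and immune-signature gene sets.
#' @param n_overlap_emt_stromal Genes shared by the EMT and stromal sets.
#' @param n_overlap_immune_tmarker Genes shared by the immune set and the
#'   T-cell markers.
#' @param n_core Size of the clinical-panel EMT/Stroma core subset.
#' @param n_screen_candidates Background genes earmarked as survival-screen
#'   candidates.
#' @param screen_planted Number of screen candidates given a real hazard
#'   effect (default 0).
#' @param beta_screen Per-SD log-hazard effect of each planted screen gene.
#' @param purity_shape1,purity_shape2 Beta parameters of the tumor-purity
#'   distribution (default Beta(8, 2), median about 0.82).
#' @param stroma_share_shape1,stroma_share_shape2 Beta parameters of the
#'   stromal share of the non-cancer fraction (default Beta(12, 12)).
#' @param base_log2_mean,base_log2_sd Per-gene baseline log2 intensity.
#' @param loading_log2 Log2 boost of a signature gene in its component
#'   (default 4, i.e. 16-fold per-component overexpression).
#' @param activity_sd Log2 SD of the per-sample stromal and immune
#'   activity multipliers (independent sample-level variation that
#'   decouples the two scores beyond shared purity).
#' @param noise_sd Log2 SD of per-gene, per-sample measurement noise.
#' @param baseline_hazard,censor_rate Exponential baseline hazard and
#'   censoring rate for overall survival (PFS uses twice the baseline
#'   hazard).
#' @param beta_ita,beta_emt Per-SD log-hazard effects of the ITA and EMT
#'   scores on survival.
#' @param surv_beta_cd8,surv_beta_stroma,surv_interaction Per-SD
#'   log-hazard effects of CD8, the core stroma score, and their product
#'   (default 0: survival depends only on ITA/EMT).
#' @param beta0,beta_cd8,beta_stroma,beta_interaction Logistic-model
#'   intercept and per-SD effects for objective response.
#' @param n_random_pathways,random_pathway_size Unstructured background
#'   gene sets included in the returned pathway collection.
#' @param seed Integer seed; the generator is a pure function of the
#'   config including this seed.
#' @return Object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_samples = 400L, n_genes = 2000L,
                          n_emt = 200L, n_t_marker = 144L,
                          n_stromal = 141L, n_immune = 141L,
                          n_overlap_emt_stromal = 30L,
                          n_overlap_immune_tmarker = 40L,
                          n_core = 8L,
                          n_screen_candidates = 200L,
                          screen_planted = 0L, beta_screen = 1.2,
                          purity_shape1 = 8, purity_shape2 = 2,
                          stroma_share_shape1 = 12, stroma_share_shape2 = 12,
                          base_log2_mean = 5, base_log2_sd = 1,
                          loading_log2 = 4, activity_sd = 0.5,
                          noise_sd = 0.3,
                          baseline_hazard = 0.08, censor_rate = 0.04,
                          beta_ita = -0.6, beta_emt = 0.75,
                          surv_beta_cd8 = 0, surv_beta_stroma = 0,
                          surv_interaction = 0,
                          beta0 = -1.2, beta_cd8 = 1, beta_stroma = 0,
                          beta_interaction = -0.8,
                          n_random_pathways = 20L,
                          random_pathway_size = 50L,
                          seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_samples >= 10, n_genes >= 10, n_emt >= n_core,
              n_overlap_emt_stromal <= min(n_emt, n_stromal),
              n_overlap_immune_tmarker <= min(n_t_marker, n_immune),
              screen_planted <= n_screen_candidates,
              purity_shape1 > 0, purity_shape2 > 0,
              stroma_share_shape1 > 0, stroma_share_shape2 > 0,
              noise_sd >= 0, activity_sd >= 0,
              baseline_hazard > 0, censor_rate > 0)
  })
  n_new <- cfg$n_emt + (cfg$n_stromal - cfg$n_overlap_emt_stromal) +
    cfg$n_t_marker + (cfg$n_immune - cfg$n_overlap_immune_tmarker) +
    cfg$n_screen_candidates
  if (n_new + cfg$n_random_pathways > cfg$n_genes)
    stop("n_genes too small for the configured gene sets")
  structure(cfg, class = "cohort_config")
}

#' CheckMate-like trial cohort configuration
#'
#' A [cohort_config()] preset emulating an immunotherapy trial cohort:
#' larger sample size, objective response driven by CD8 infiltration with
#' a negative CD8 x stroma interaction, and PFS/OS hazards carrying the
#' same CD8/stroma structure instead of the ITA/EMT prognostic effects.
#'
#' @param n_samples Cohort size (default 600).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [cohort_config()].
#' @return A `"cohort_config"`.
#' @export
checkmate_config <- function(n_samples = 600L, seed = 1L, ...) {
  cohort_config(n_samples = n_samples, seed = seed,
                beta_ita = 0, beta_emt = 0,
                surv_beta_cd8 = -0.45, surv_beta_stroma = 0.1,
                surv_interaction = 0.35,
                baseline_hazard = 0.06, censor_rate = 0.06, ...)
}

#' Simulate a purity-confounded bulk expression cohort
#'
#' Draws, per sample, a tumor purity `p ~ Beta`, splits `1 - p` into
#' stromal and immune fractions, and mixes three per-gene component
#' intensities (cancer / stroma / immune) weighted by those fractions;
#' observed expression is the log2 of the mixture times lognormal noise.
#' Signature genes are overexpressed 2^`loading_log2`-fold in their
#' component, and per-sample stromal/immune activity multipliers add
#' sample-level variation that is independent between the two components.
#' Overall survival times are exponential with log-hazard linear in the
#' standardized ITA and EMT scores (plus optional CD8/stroma terms and
#' planted screen genes); objective response is Bernoulli with the
#' configured CD8 x stroma logistic model. The generator is deterministic
#' given the config (seed included).
#'
#' @param config A [cohort_config()].
#' @return List with `expr` (genes x samples log2 matrix), `purity`
#'   (named vector), `clinical` (data.frame: `sample_id`, `os_time`,
#'   `os_event`, `pfs_time`, `pfs_event`, `response`, `cd8_ihc`,
#'   `emt_stroma`, `hbn`, `livermet`, `pdl1`), `gene_sets` (named list),
#'   `pathways` (collection for enrichment tests) and `truth` (generative
#'   quantities for recovery tests).
#' @export
simulate_bulk_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_samples
    G <- cfg$n_genes
    samples <- sprintf("S%04d", seq_len(n))
    genes <- sprintf("G%05d", seq_len(G))

    # gene-set layout: EMT block, stromal (partly overlapping EMT),
    # T-cell markers, immune (partly overlapping markers), screen pool
    emt_idx <- seq_len(cfg$n_emt)
    stromal_idx <- c(tail(emt_idx, cfg$n_overlap_emt_stromal),
                     seq(cfg$n_emt + 1L,
                         length.out = cfg$n_stromal - cfg$n_overlap_emt_stromal))
    nxt <- max(stromal_idx) + 1L
    tmark_idx <- seq(nxt, length.out = cfg$n_t_marker)
    immune_idx <- c(head(tmark_idx, cfg$n_overlap_immune_tmarker),
                    seq(max(tmark_idx) + 1L,
                        length.out = cfg$n_immune - cfg$n_overlap_immune_tmarker))
    nxt <- max(immune_idx) + 1L
    cand_idx <- seq(nxt, length.out = cfg$n_screen_candidates)
    bg_idx <- setdiff(seq_len(G), c(emt_idx, stromal_idx, tmark_idx,
                                    immune_idx, cand_idx))

    # mixture fractions
    p <- stats::rbeta(n, cfg$purity_shape1, cfg$purity_shape2)
    p <- pmin(p, 0.995)
    w <- stats::rbeta(n, cfg$stroma_share_shape1, cfg$stroma_share_shape2)
    f_s <- (1 - p) * w
    f_im <- (1 - p) * (1 - w)

    # component loadings and per-sample activities
    boost <- 2^cfg$loading_log2
    s_load <- rep(1, G); s_load[union(emt_idx, stromal_idx)] <- boost
    im_load <- rep(1, G); im_load[union(tmark_idx, immune_idx)] <- boost
    a_str <- 2^stats::rnorm(n, 0, cfg$activity_sd)
    a_im <- 2^stats::rnorm(n, 0, cfg$activity_sd)

    base <- 2^stats::rnorm(G, cfg$base_log2_mean, cfg$base_log2_sd)
    lin <- matrix(p, G, n, byrow = TRUE) +
      s_load %o% (f_s * a_str) + im_load %o% (f_im * a_im)
    # screen candidates carry no shared sample-level structure: pure
    # gene-specific noise, so per-gene screen error rates are interpretable
    lin[cand_idx, ] <- 1
    expr <- log2(base * lin) +
      matrix(stats::rnorm(G * n, 0, cfg$noise_sd), G, n)
    dimnames(expr) <- list(genes, samples)
    attr(expr, "log_transformed") <- TRUE

    gene_sets <- list(
      hallmark_emt = genes[emt_idx],
      t_cell_markers = genes[tmark_idx],
      stromal_estimate = genes[stromal_idx],
      immune_estimate = genes[immune_idx],
      emt_stroma_core = genes[head(emt_idx, cfg$n_core)],
      screen_candidates = genes[cand_idx]
    )

    # signature scores (mean log2 over set genes) and standardized versions
    ita <- colMeans(expr[gene_sets$t_cell_markers, , drop = FALSE])
    emt <- colMeans(expr[gene_sets$hallmark_emt, , drop = FALSE])
    core <- colMeans(expr[gene_sets$emt_stroma_core, , drop = FALSE])
    z_ita <- as.numeric(scale(ita))
    z_emt <- as.numeric(scale(emt))
    z_core <- as.numeric(scale(core))

    # CD8 IHC driven by the immune fraction, observed on a percent scale
    cd8_lat <- 0.9 * as.numeric(scale(log(f_im))) + stats::rnorm(n, 0, 0.6)
    cd8_ihc <- round(100 * stats::plogis(-2.2 + 1.1 * cd8_lat), 1)
    z_cd8 <- as.numeric(scale(cd8_ihc))

    # baseline covariates (no effect on outcomes by default; carried for
    # ladder analyses)
    hbn <- round(stats::rnorm(n, 12.8, 1.8), 1)
    livermet <- stats::rbinom(n, 1, 0.28)
    pdl1 <- round(100 * stats::rbeta(n, 0.4, 2.5))

    # planted survival-screen genes (taken from the candidate pool)
    planted <- head(gene_sets$screen_candidates, cfg$screen_planted)
    lp_screen <- if (length(planted)) {
      zg <- scale(t(expr[planted, , drop = FALSE]))
      as.numeric(zg %*% rep(cfg$beta_screen, length(planted)))
    } else rep(0, n)

    lp_os <- cfg$beta_ita * z_ita + cfg$beta_emt * z_emt + lp_screen +
      cfg$surv_beta_cd8 * z_cd8 + cfg$surv_beta_stroma * z_core +
      cfg$surv_interaction * z_cd8 * z_core
    os <- draw_survival(n, cfg$baseline_hazard, lp_os, cfg$censor_rate)
    pfs <- draw_survival(n, 2 * cfg$baseline_hazard, lp_os, cfg$censor_rate)

    lp_resp <- cfg$beta0 + cfg$beta_cd8 * z_cd8 + cfg$beta_stroma * z_core +
      cfg$beta_interaction * z_cd8 * z_core
    response <- stats::rbinom(n, 1, stats::plogis(lp_resp))

    clinical <- data.frame(
      sample_id = samples,
      os_time = os$time, os_event = os$event,
      pfs_time = pfs$time, pfs_event = pfs$event,
      response = response, cd8_ihc = cd8_ihc, emt_stroma = core,
      hbn = hbn, livermet = livermet, pdl1 = pdl1,
      stringsAsFactors = FALSE
    )

    random_sets <- lapply(seq_len(cfg$n_random_pathways), function(i) {
      sample(genes[bg_idx], min(cfg$random_pathway_size, length(bg_idx)))
    })
    names(random_sets) <- sprintf("RANDOM_%02d", seq_along(random_sets))
    pathways <- c(list(HALLMARK_EMT = gene_sets$hallmark_emt,
                       STROMAL_ESTIMATE = gene_sets$stromal_estimate,
                       IMMUNE_ESTIMATE = gene_sets$immune_estimate),
                  random_sets)

    list(expr = expr,
         purity = stats::setNames(p, samples),
         clinical = clinical,
         gene_sets = gene_sets,
         pathways = pathways,
         truth = list(purity = stats::setNames(p, samples),
                      stroma_fraction = f_s, immune_fraction = f_im,
                      ita = ita, emt = emt,
                      z_ita = z_ita, z_emt = z_emt,
                      z_cd8 = z_cd8, z_core = z_core,
                      planted_genes = planted,
                      lp_os = lp_os, p_response = stats::plogis(lp_resp),
                      config = cfg))
  })
}

draw_survival <- function(n, baseline_hazard, lp, censor_rate) {
  t_event <- stats::rexp(n, baseline_hazard * exp(lp))
  t_cens <- stats::rexp(n, censor_rate)
  list(time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

#' Simulate an immune reference profile with planted cell-type markers
#'
#' Builds a genes x cell-types matrix of standard-normal background noise
#' with, for each cell type, a block of planted marker genes elevated by
#' `effect_sd` standard deviations. Cell types carry LM22-style names so
#' the seven T-lineage columns are recognized by default.
#'
#' @param n_types Number of cell types (default 22).
#' @param n_genes Number of genes (default 513; must be at least
#'   `n_types * markers_per_type`).
#' @param markers_per_type Planted markers per cell type (default 23).
#' @param effect_sd Marker elevation in baseline SD units (default 5).
#' @param seed Integer seed.
#' @return List with `profile` (a [reference_profile()]) and `truth`
#'   (list: `markers_by_type`, `t_cell_markers`).
#' @export
simulate_reference_profiles <- function(n_types = 22L, n_genes = 513L,
                                        markers_per_type = 23L,
                                        effect_sd = 5, seed = 1L) {
  if (markers_per_type * n_types > n_genes)
    stop("infeasible sizes: markers_per_type * n_types exceeds n_genes")
  withr::with_seed(seed, {
    types <- lm22_like_types(n_types)
    genes <- sprintf("M%04d", seq_len(n_genes))
    v <- matrix(stats::rnorm(n_genes * n_types), n_genes, n_types,
                dimnames = list(genes, types))
    markers_by_type <- vector("list", n_types)
    names(markers_by_type) <- types
    for (k in seq_len(n_types)) {
      idx <- seq((k - 1L) * markers_per_type + 1L, k * markers_per_type)
      v[idx, k] <- v[idx, k] + effect_sd
      markers_by_type[[k]] <- genes[idx]
    }
    t_cols <- intersect(lm22_t_cell_columns(), types)
    profile <- reference_profile(v, t_cell_columns = t_cols)
    list(profile = profile,
         truth = list(markers_by_type = markers_by_type,
                      t_cell_markers = unlist(markers_by_type[t_cols],
                                              use.names = FALSE)))
  })
}

lm22_like_types <- function(n_types) {
  base <- c("T.cells.CD8", "T.cells.CD4.naive", "T.cells.CD4.memory.resting",
            "T.cells.CD4.memory.activated", "T.cells.follicular.helper",
            "T.cells.regulatory.Tregs", "T.cells.gamma.delta",
            "B.cells.naive", "B.cells.memory", "Plasma.cells",
            "NK.cells.resting", "NK.cells.activated", "Monocytes",
            "Macrophages.M0", "Macrophages.M1", "Macrophages.M2",
            "Dendritic.cells.resting", "Dendritic.cells.activated",
            "Mast.cells.resting", "Mast.cells.activated", "Eosinophils",
            "Neutrophils")
  if (n_types <= length(base)) head(base, n_types)
  else c(base, sprintf("Other.%02d", seq_len(n_types - length(base))))
}

#' Configuration for the synthetic PDX count generator
#'
#' @param n_models Number of PDX models (default 5).
#' @param n_genes Total genes in the transcriptome (default 20000).
#' @param n_emt,n_stromal Sizes of the EMT-like and stromal-like gene
#'   blocks (no overlap in the simulated sets).
#' @param emt_log2fc,stromal_log2fc Per-cell log2 overexpression of those
#'   blocks in mouse (stromal) cells relative to human (cancer) cells
#'   (defaults 2 and 4, i.e. 4x and 16x per cell).
#' @param purity Per-model target human read fraction; recycled to
#'   `n_models` (default `c(0.91, 0.93, 0.94, 0.95, 0.97)`, median 0.94).
#' @param library_size Total reads per model (default 1e6).
#' @param base_log2_sd Log2 SD of per-gene baseline expression.
#' @param seed Integer seed.
#' @return Object of class `"pdx_config"`.
#' @export
pdx_config <- function(n_models = 5L, n_genes = 20000L,
                       n_emt = 200L, n_stromal = 141L,
                       emt_log2fc = 2, stromal_log2fc = 4,
                       purity = c(0.91, 0.93, 0.94, 0.95, 0.97),
                       library_size = 1e6, base_log2_sd = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$purity <- rep_len(purity, n_models)
  if (any(cfg$purity <= 0 | cfg$purity > 1))
    stop("purity (human read fraction) must lie in (0, 1]")
  if (library_size <= 0) stop("library_size must be positive")
  if (n_emt + n_stromal > n_genes)
    stop("n_genes too small for the configured gene blocks")
  structure(cfg, class = "pdx_config")
}

#' Simulate species-partitioned PDX read counts
#'
#' Each PDX sample is a mixture of human cancer cells and mouse stromal
#' cells. Per-gene, per-cell expression is a shared lognormal baseline;
#' EMT-like and stromal-like gene blocks are overexpressed in mouse cells
#' by the configured per-cell fold changes. The mouse cell fraction of
#' each model is solved so the expected human read share equals the
#' configured purity, and reads are then allocated multinomially over
#' (gene, species) with probability proportional to cell fraction times
#' per-cell expression.
#'
#' @param config A [pdx_config()].
#' @return List with `counts` (a [species_counts()]), `gene_sets` (list:
#'   `emt_like`, `stromal_like`, `background`), and `truth` (per-gene
#'   per-cell log2 fold change, expected mouse fractions, configured
#'   purity, mouse cell fractions).
#' @export
simulate_pdx_counts <- function(config = pdx_config()) {
  stopifnot(inherits(config, "pdx_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    G <- cfg$n_genes
    genes <- sprintf("G%05d", seq_len(G))
    models <- sprintf("PDX%02d", seq_len(cfg$n_models))
    emt_idx <- seq_len(cfg$n_emt)
    stromal_idx <- seq(cfg$n_emt + 1L, length.out = cfg$n_stromal)

    base <- 2^stats::rnorm(G, 0, cfg$base_log2_sd)
    fc <- rep(1, G)
    fc[emt_idx] <- 2^cfg$emt_log2fc
    fc[stromal_idx] <- 2^cfg$stromal_log2fc
    e_h <- base
    e_m <- base * fc

    human <- matrix(0L, G, cfg$n_models, dimnames = list(genes, models))
    mouse <- human
    exp_mouse_frac <- matrix(NA_real_, G, cfg$n_models,
                             dimnames = list(genes, models))
    m_cells <- numeric(cfg$n_models)
    for (j in seq_len(cfg$n_models)) {
      s_m <- 1 - cfg$purity[j]           # target mouse read share
      r <- s_m * sum(e_h) / ((1 - s_m) * sum(e_m))  # mouse:human cell ratio
      m_cells[j] <- r / (1 + r)
      w_h <- e_h
      w_m <- r * e_m
      prob <- c(w_h, w_m) / sum(w_h + w_m)
      draw <- stats::rmultinom(1, cfg$library_size, prob)[, 1]
      human[, j] <- draw[seq_len(G)]
      mouse[, j] <- draw[G + seq_len(G)]
      exp_mouse_frac[, j] <- w_m / (w_m + w_h)
    }
    list(counts = species_counts(human, mouse),
         gene_sets = list(emt_like = genes[emt_idx],
                          stromal_like = genes[stromal_idx],
                          background = genes[-c(emt_idx, stromal_idx)]),
         truth = list(per_cell_log2fc = stats::setNames(log2(fc), genes),
                      expected_mouse_fraction = exp_mouse_frac,
                      purity = stats::setNames(cfg$purity, models),
                      mouse_cell_fraction = stats::setNames(m_cells, models),
                      config = cfg))
  })
}
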