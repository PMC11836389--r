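#' Simulate a noisy 4PL dose-response table
#'
#' Draws responses on a four-parameter logistic curve with additive Gaussian
#' noise — the shape of a donor dose versus demethylase activity experiment.
#' Pure function of its arguments and `seed`.
#'
#' @param doses Dose grid (> 0).
#' @param bottom,top,log_ic50,hill True curve parameters (negative `hill`
#'   for inhibition curves).
#' @param noise_sd Gaussian noise SD, response units.
#' @param n_replicates Replicates per dose.
#' @param seed Integer seed.
#' @return A tibble `dose`, `replicate`, `response`; attribute `truth` holds
#'   the generating parameters (with `ic50 = 10^log_ic50`).
#' @examples
#' synth_dose_response(10^seq(0, 3.5, 0.5), noise_sd = 0, seed = 1)
#' @export
synth_dose_response <- function(doses = 10^seq(0, 3.5, length.out = 8),
                                bottom = 0, top = 100,
                                log_ic50 = log10(165), hill = -1,
                                noise_sd = 5, n_replicates = 2, seed = 1) {
  if (any(doses <= 0)) abort("doses must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(n_replicates))
  mu <- fourpl(grid$dose, bottom, top, log_ic50, hill)
  resp <- withr::with_seed(seed, mu + rnorm(nrow(grid), 0, noise_sd))
  out <- dplyr::mutate(grid, response = resp)
  attr(out, "truth") <- list(bottom = bottom, top = top, log_ic50 = log_ic50,
                             hill = hill, ic50 = 10^log_ic50)
  out
}

#' Simulate an oxRRBS methylome with known ground truth
#'
#' Generates a synthetic single-chromosome methylome whose structure mirrors
#' an oxRRBS experiment: CpG sites with class-dependent baseline 5mC/5hmC
#' levels, paired BS/oxBS binomial read counts at Poisson coverage for each
#' condition and replicate, matching CpG-island and functional-element BED
#' tracks, and planted treatment effects (hyper and hypo, per mark) whose
#' locations are returned as truth labels.
#'
#' Layout: one island of width 1 kb every 20 kb, one site per island slot.
#' Each site's CpG class fixes its offset from its island (inside; <= 2 kb;
#' 2-4 kb; > 4 kb), so [annotate_sites()] recovers the generating class
#' exactly. Baselines follow the canonical methylation landscape — islands
#' hypomethylated, open sea highly methylated, 5hmC a minor mark — with
#' per-site jitter. Hyper effects add `effect_size` to the treated
#' condition's beta for the chosen mark; hypo effects subtract up to
#' `effect_size`, limited by the baseline. A modest hyper excess is the
#' default, mimicking a net gain of both marks under NO exposure.
#'
#' @param n_sites Number of CpG sites.
#' @param class_proportions Named fractions over
#'   `island`, `shore`, `shelf`, `open_sea`; open-sea-dominant by default.
#' @param baseline_beta_5mc,baseline_beta_5hmc Named per-class mean betas.
#' @param coverage_mean Expected per-assay read depth (Poisson).
#' @param effect_fraction_hyper,effect_fraction_hypo Fractions of sites with
#'   planted treated-vs-control effects, per mark.
#' @param effect_size Planted delta-beta magnitude.
#' @param effect_classes Optional CpG classes to restrict planted effects to
#'   (e.g. `"open_sea"`).
#' @param replicates Replicates per condition.
#' @param conditions Length-2 condition labels `(control, treated)`.
#' @param seed Integer seed.
#' @return A list: `counts` (long BS/oxBS count table), `islands` and
#'   `features` (BED-like tibbles), `sites` (per-site generating class,
#'   feature and betas), `truth` (per site and mark: `effect` in
#'   hyper/hypo/none and `applied_delta`), `spec` (the arguments).
#' @export
synth_oxrrbs <- function(n_sites = 1000,
                         class_proportions = c(island = 0.15, shore = 0.15,
                                               shelf = 0.10, open_sea = 0.60),
                         baseline_beta_5mc = c(island = 0.10, shore = 0.30,
                                               shelf = 0.50, open_sea = 0.70),
                         baseline_beta_5hmc = c(island = 0.03, shore = 0.06,
                                                shelf = 0.08, open_sea = 0.10),
                         coverage_mean = 50,
                         effect_fraction_hyper = 0.05,
                         effect_fraction_hypo = 0.025,
                         effect_size = 0.3,
                         effect_classes = NULL,
                         replicates = 2,
                         conditions = c("control", "treated"),
                         seed = 1) {
  classes <- c("island", "shore", "shelf", "open_sea")
  if (!setequal(names(class_proportions), classes)) {
    abort("`class_proportions` must name island, shore, shelf, open_sea")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("`class_proportions` must sum to 1")
  }
  if (any(baseline_beta_5mc < 0 | baseline_beta_5mc > 1) ||
      any(baseline_beta_5hmc < 0 | baseline_beta_5hmc > 1)) {
    abort("baseline betas must lie in [0, 1]")
  }
  if (any(baseline_beta_5mc[classes] + baseline_beta_5hmc[classes] > 1)) {
    abort("baseline beta_5mC + beta_5hmC exceeds 1 for some class")
  }
  if (coverage_mean <= 0) abort("`coverage_mean` must be positive")
  if (length(conditions) != 2L) abort("`conditions` must have length 2")
  if (effect_fraction_hyper + effect_fraction_hypo > 1) {
    abort("effect fractions sum above 1")
  }

  withr::with_seed(seed, {
    spacing <- 20000L; island_w <- 1000L
    island_start <- spacing * seq_len(n_sites)        # one slot per site
    islands <- tibble(chrom = "chrS", start = island_start,
                      end = island_start + island_w, label = "island")

    cls <- sample(classes, n_sites, replace = TRUE, prob = class_proportions[classes])
    offset <- dplyr::case_when(
      cls == "island" ~ sample(0:(island_w - 1L), n_sites, replace = TRUE) -
        island_w,                                      # inside the island
      cls == "shore" ~ sample(1:1999, n_sites, replace = TRUE),
      cls == "shelf" ~ sample(2001:3999, n_sites, replace = TRUE),
      .default = sample(5001:9000, n_sites, replace = TRUE)
    )
    pos <- island_start + island_w + offset

    feat_levels <- c(intron = 0.35, intergenic = 0.28, exon = 0.15,
                     promoter = 0.08, utr3 = 0.04, utr5 = 0.03,
                     enhancer = 0.04, super_enhancer = 0.03)
    feat <- sample(names(feat_levels), n_sites, replace = TRUE,
                   prob = feat_levels)
    features <- tibble(chrom = "chrS", start = pos, end = pos + 2L,
                       label = feat) |>
      dplyr::filter(.data$label != "intergenic")

    jitter_m <- rnorm(n_sites, 0, 0.05)
    beta_m <- unname(pmin(pmax(baseline_beta_5mc[cls] + jitter_m, 0.02), 0.85))
    jitter_h <- rnorm(n_sites, 0, 0.02)
    beta_h <- unname(pmin(pmax(baseline_beta_5hmc[cls] + jitter_h, 0.005), 0.25))

    eligible <- if (is.null(effect_classes)) seq_len(n_sites) else
      which(cls %in% effect_classes)
    plant <- function(beta) {
      n_hyper <- round(effect_fraction_hyper * n_sites)
      n_hypo <- round(effect_fraction_hypo * n_sites)
      if (n_hyper + n_hypo > length(eligible)) {
        abort("not enough eligible sites for the requested effect fractions")
      }
      chosen <- sample(eligible, n_hyper + n_hypo)
      hyper <- chosen[seq_len(n_hyper)]
      hypo <- setdiff(chosen, hyper)
      delta <- numeric(length(beta))
      delta[hyper] <- pmin(effect_size, 0.98 - beta[hyper])
      delta[hypo] <- -pmin(effect_size, beta[hypo] - 0.01)
      effect <- rep("none", length(beta))
      effect[hyper] <- "hyper"; effect[hypo] <- "hypo"
      list(delta = delta, effect = effect)
    }
    planted_m <- plant(beta_m)
    planted_h <- plant(beta_h)

    beta_m_trt <- beta_m + planted_m$delta
    beta_h_trt <- beta_h + planted_h$delta
    # keep the pair feasible under BS chemistry (reads 5mC + 5hmC)
    over <- beta_m_trt + beta_h_trt > 0.99
    beta_h_trt[over] <- 0.99 - beta_m_trt[over]

    site_tbl <- tibble(
      site = seq_len(n_sites), chrom = "chrS", pos = pos, strand = ".",
      cpg_class_true = cls, feature_true = feat,
      beta_5mc_control = beta_m, beta_5hmc_control = beta_h,
      beta_5mc_treated = beta_m_trt, beta_5hmc_treated = beta_h_trt
    )

    grid <- tidyr::expand_grid(site = seq_len(n_sites),
                               condition = conditions,
                               replicate = seq_len(replicates))
    grid <- grid |>
      dplyr::mutate(
        pos = pos[.data$site],
        bm = dplyr::if_else(.data$condition == conditions[2],
                            beta_m_trt[.data$site], beta_m[.data$site]),
        bh = dplyr::if_else(.data$condition == conditions[2],
                            beta_h_trt[.data$site], beta_h[.data$site]),
        bs_total = rpois(dplyr::n(), coverage_mean),
        oxbs_total = rpois(dplyr::n(), coverage_mean),
        bs_meth = rbinom(dplyr::n(), .data$bs_total,
                         pmin(.data$bm + .data$bh, 1)),
        oxbs_meth = rbinom(dplyr::n(), .data$oxbs_total, .data$bm)
      )
    counts <- dplyr::bind_rows(
      grid |> dplyr::transmute(
        chrom = "chrS", pos = .data$pos, strand = ".",
        condition = .data$condition, replicate = .data$replicate,
        assay = "BS", meth = .data$bs_meth, total = .data$bs_total),
      grid |> dplyr::transmute(
        chrom = "chrS", pos = .data$pos, strand = ".",
        condition = .data$condition, replicate = .data$replicate,
        assay = "oxBS", meth = .data$oxbs_meth, total = .data$oxbs_total)
    ) |>
      dplyr::arrange(.data$pos, .data$condition, .data$replicate, .data$assay)

    truth <- dplyr::bind_rows(
      tibble(site = seq_len(n_sites), chrom = "chrS", pos = pos,
             mark = "5mC", effect = planted_m$effect,
             applied_delta = planted_m$delta),
      tibble(site = seq_len(n_sites), chrom = "chrS", pos = pos,
             mark = "5hmC", effect = planted_h$effect,
             applied_delta = planted_h$delta)
    )

    list(counts = counts,
         islands = islands[, c("chrom", "start", "end", "label")],
         features = features,
         sites = site_tbl,
         truth = truth,
         spec = list(n_sites = n_sites, class_proportions = class_proportions,
                     coverage_mean = coverage_mean,
                     effect_fraction_hyper = effect_fraction_hyper,
                     effect_fraction_hypo = effect_fraction_hypo,
                     effect_size = effect_size, effect_classes = effect_classes,
                     replicates = replicates, conditions = conditions,
                     seed = seed))
  })
}

#' Simulate expression coupled to promoter methylation
#'
#' Log-expression is linear in promoter beta with negative slope plus
#' Gaussian noise — the classic promoter-silencing signature that
#' [methylation_expression_correlation()] should detect as a negative
#' Spearman correlation.
#'
#' @param promoter_betas A data frame with columns `gene`, `beta`; or a
#'   single integer, in which case that many genes are simulated with
#'   Beta(2, 2) promoter betas.
#' @param slope Coupling slope (<= 0) on the log-expression scale.
#' @param intercept Baseline log-expression.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A tibble `gene`, `beta`, `expression` (log scale).
#' @export
synth_expression <- function(promoter_betas, slope = -3, intercept = 5,
                             noise_sd = 0.5, seed = 1) {
  if (slope > 0) abort("`slope` must be <= 0 (methylation represses)")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  withr::with_seed(seed, {
    if (is.numeric(promoter_betas) && length(promoter_betas) == 1L) {
      n <- as.integer(promoter_betas)
      promoter_betas <- tibble(gene = sprintf("gene%04d", seq_len(n)),
                               beta = stats::rbeta(n, 2, 2))
    }
    stopifnot(is.data.frame(promoter_betas),
              all(c("gene", "beta") %in% names(promoter_betas)))
    tibble(
      gene = promoter_betas$gene,
      beta = promoter_betas$beta,
      expression = intercept + slope * promoter_betas$beta +
        rnorm(nrow(promoter_betas), 0, noise_sd)
    )
  })
}
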