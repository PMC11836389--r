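#' Beta-values from paired BS/oxBS counts
#'
#' Oxidative-bisulfite arithmetic: bisulfite (BS) libraries read
#' 5mC + 5hmC as methylated while oxidative-bisulfite (oxBS) libraries read
#' only 5mC, so per site and replicate
#' `beta_5mC = oxBS meth/total` and `beta_5hmC = max(0, beta_BS - beta_oxBS)`.
#' Negative subtraction results (sampling noise) are clipped to 0 and
#' flagged; sites with either assay below `min_coverage` are masked rather
#' than dropped, so coverage QC stays visible.
#'
#' @param counts A long count table with columns `chrom`, `pos`, `strand`,
#'   `condition`, `replicate`, `assay` (`"BS"` or `"oxBS"`), `meth`, `total`
#'   (`meth <= total`). One row per site/condition/replicate/assay.
#' @param min_coverage Minimum per-assay total read count (>= 1).
#' @return A tibble with one row per site/condition/replicate: the four
#'   counts plus `beta_bs`, `beta_5mc`, `beta_5hmc`, `clipped`, `masked`.
#' @examples
#' counts <- tibble::tibble(
#'   chrom = "chr1", pos = 100, strand = ".",
#'   condition = "ctrl", replicate = 1L,
#'   assay = c("BS", "oxBS"), meth = c(30L, 15L), total = c(60L, 50L))
#' compute_betas(counts)
#' @export
compute_betas <- function(counts, min_coverage = 10) {
  req <- c("chrom", "pos", "strand", "condition", "replicate", "assay",
           "meth", "total")
  missing_cols <- setdiff(req, names(counts))
  if (length(missing_cols)) {
    abort(paste0("count table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (min_coverage < 1) abort("`min_coverage` must be >= 1")
  if (any(counts$meth > counts$total)) abort("found rows with meth > total")
  if (!all(counts$assay %in% c("BS", "oxBS"))) {
    abort("`assay` must be 'BS' or 'oxBS'")
  }
  wide <- counts |>
    dplyr::select(dplyr::all_of(req)) |>
    tidyr::pivot_wider(names_from = "assay",
                       values_from = c("meth", "total"),
                       values_fill = 0L)
  for (col in c("meth_BS", "total_BS", "meth_oxBS", "total_oxBS")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  wide |>
    dplyr::rename(bs_meth = "meth_BS", bs_total = "total_BS",
                  oxbs_meth = "meth_oxBS", oxbs_total = "total_oxBS") |>
    dplyr::mutate(
      beta_bs = dplyr::if_else(.data$bs_total > 0,
                               .data$bs_meth / .data$bs_total, NA_real_),
      beta_oxbs = dplyr::if_else(.data$oxbs_total > 0,
                                 .data$oxbs_meth / .data$oxbs_total, NA_real_),
      beta_5mc = .data$beta_oxbs,
      beta_5hmc = pmax(0, .data$beta_bs - .data$beta_oxbs),
      clipped = !is.na(.data$beta_bs) & !is.na(.data$beta_oxbs) &
        (.data$beta_bs - .data$beta_oxbs) < 0,
      masked = .data$bs_total < min_coverage | .data$oxbs_total < min_coverage
    ) |>
    dplyr::select(-"beta_oxbs")
}

# vectorised Welch two-sample t-test on per-replicate betas; two-sided p
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate zero-variance sites: identical groups carry no evidence,
  # separated ones are as extreme as a t-test can report
  p[se2 == 0 & m1 == m2] <- 1
  p[se2 == 0 & m1 != m2] <- 0
  p
}

#' Call differentially (hydroxy)methylated positions
#'
#' Per-site comparison of treated versus control beta-values for one mark
#' (5mC from oxBS, or 5hmC from BS-minus-oxBS subtraction). A site is called
#' `hyper` when `p < alpha` and `delta_beta > delta`, `hypo` when `p < alpha`
#' and `delta_beta < -delta`, else `none`; defaults `alpha = 0.05`,
#' `delta = 0.1` — a raw-p plus effect-size rule. An FDR
#' (Benjamini-Hochberg) column is emitted for transparency but plays no part
#' in the calls.
#'
#' Tests: `"limma"` (default) fits a per-site linear model on per-replicate
#' beta-values and moderates the variance across sites with empirical-Bayes
#' shrinkage ([limma::eBayes()]) — the hierarchical approach used by
#' published methylation pipelines, and the only one of the three with
#' useful power at two replicates per condition. `"welch"` is an unmoderated
#' Welch two-sample t-test on per-replicate beta-values (needs >= 2 unmasked
#' replicates per condition). `"fisher_pooled"` pools counts across
#' replicates into a 2x2 table and applies Fisher's exact test (usable from
#' 1 replicate; for 5hmC the pooled hydroxymethylated count is reconstructed
#' as `round(pooled beta_5hmC x pooled BS total)`, an approximation since
#' oxBS chemistry only defines 5hmC as a beta difference).
#'
#' @param counts A long count table (see [compute_betas()]).
#' @param control,treated Condition labels present in `counts$condition`.
#' @param mark `"5mC"` or `"5hmC"`.
#' @param alpha P-value threshold.
#' @param delta Minimum absolute beta-value difference.
#' @param test `"limma"`, `"welch"` or `"fisher_pooled"`.
#' @param min_coverage Per-assay coverage mask passed to [compute_betas()].
#' @return A tibble of class `dmp_result`, one row per testable site:
#'   `chrom`, `pos`, `strand`, `mark`, `beta_control`, `beta_treated`,
#'   `delta_beta`, `p_value`, `fdr`, `call`.
#' @export
call_dmps <- function(counts, control, treated, mark = c("5mC", "5hmC"),
                      alpha = 0.05, delta = 0.1,
                      test = c("limma", "welch", "fisher_pooled"),
                      min_coverage = 10) {
  mark <- match.arg(mark)
  test <- match.arg(test)
  betas <- compute_betas(counts, min_coverage = min_coverage)
  if (!all(c(control, treated) %in% betas$condition)) {
    abort("`control` and `treated` must both appear in the count table")
  }
  betas <- betas |>
    dplyr::filter(!.data$masked,
                  .data$condition %in% c(control, treated)) |>
    dplyr::mutate(beta = if (mark == "5mC") .data$beta_5mc else .data$beta_5hmc)

  if (test == "limma") {
    mat_tbl <- betas |>
      dplyr::mutate(sample = paste(.data$condition, .data$replicate, sep = ".")) |>
      dplyr::select("chrom", "pos", "strand", "sample", "beta") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "beta")
    sample_cols <- setdiff(names(mat_tbl), c("chrom", "pos", "strand"))
    cond_of <- sub("\\.[^.]+$", "", sample_cols)
    B <- as.matrix(mat_tbl[, sample_cols])
    # need both conditions observed at a site for the contrast to exist
    ok <- rowSums(!is.na(B[, cond_of == control, drop = FALSE])) >= 1 &
      rowSums(!is.na(B[, cond_of == treated, drop = FALSE])) >= 1
    if (!any(ok)) {
      warn("no sites covered in both conditions")
      return(empty_dmp_result(mark))
    }
    mat_tbl <- mat_tbl[ok, ]
    B <- B[ok, , drop = FALSE]
    design <- cbind(intercept = 1, trt = as.numeric(cond_of == treated))
    # trend = TRUE: beta-value variance depends on the mean (binomial
    # sampling peaks at beta = 0.5), so the prior variance is fit as a
    # function of mean level rather than assumed exchangeable
    fit <- withCallingHandlers(
      limma::eBayes(limma::lmFit(B, design), trend = TRUE),
      warning = function(w) {
        # zero-variance sites (identical replicate betas) are expected at
        # high beta and finite coverage; limma offsets them internally
        if (grepl("Zero sample variances", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    res <- mat_tbl |>
      dplyr::transmute(
        .data$chrom, .data$pos, .data$strand, mark = mark,
        beta_control = fit$coefficients[, "intercept"],
        beta_treated = fit$coefficients[, "intercept"] +
          fit$coefficients[, "trt"],
        delta_beta = fit$coefficients[, "trt"],
        p_value = fit$p.value[, "trt"]
      )
  } else if (test == "welch") {
    stats_tbl <- betas |>
      dplyr::summarise(
        m = mean(.data$beta), v = stats::var(.data$beta), n = dplyr::n(),
        .by = c("chrom", "pos", "strand", "condition")
      ) |>
      tidyr::pivot_wider(names_from = "condition", values_from = c("m", "v", "n"))
    mc <- paste0("m_", control); vc <- paste0("v_", control); nc <- paste0("n_", control)
    mt <- paste0("m_", treated); vt <- paste0("v_", treated); nt <- paste0("n_", treated)
    stats_tbl <- stats_tbl |>
      dplyr::filter(!is.na(.data[[nc]]), !is.na(.data[[nt]]),
                    .data[[nc]] >= 2, .data[[nt]] >= 2)
    if (nrow(stats_tbl) == 0L) {
      warn("no sites with >= 2 covered replicates in both conditions")
      return(empty_dmp_result(mark))
    }
    res <- stats_tbl |>
      dplyr::mutate(
        mark = mark,
        beta_control = .data[[mc]],
        beta_treated = .data[[mt]],
        delta_beta = .data[[mt]] - .data[[mc]],
        p_value = welch_p(.data[[mc]], .data[[vc]], .data[[nc]],
                          .data[[mt]], .data[[vt]], .data[[nt]])
      )
  } else {
    pooled <- betas |>
      dplyr::summarise(
        bs_meth = sum(.data$bs_meth), bs_total = sum(.data$bs_total),
        oxbs_meth = sum(.data$oxbs_meth), oxbs_total = sum(.data$oxbs_total),
        .by = c("chrom", "pos", "strand", "condition")
      )
    if (mark == "5mC") {
      pooled <- pooled |>
        dplyr::mutate(k = .data$oxbs_meth, n = .data$oxbs_total)
    } else {
      pooled <- pooled |>
        dplyr::mutate(
          beta_h = pmax(0, .data$bs_meth / .data$bs_total -
                          .data$oxbs_meth / .data$oxbs_total),
          k = round(.data$beta_h * .data$bs_total), n = .data$bs_total
        )
    }
    wide <- pooled |>
      dplyr::select("chrom", "pos", "strand", "condition", "k", "n") |>
      tidyr::pivot_wider(names_from = "condition", values_from = c("k", "n"))
    kc <- paste0("k_", control); nc2 <- paste0("n_", control)
    kt <- paste0("k_", treated); nt2 <- paste0("n_", treated)
    wide <- wide |>
      dplyr::filter(!is.na(.data[[nc2]]), !is.na(.data[[nt2]]),
                    .data[[nc2]] > 0, .data[[nt2]] > 0)
    if (nrow(wide) == 0L) {
      warn("no sites covered in both conditions")
      return(empty_dmp_result(mark))
    }
    pv <- purrr::pmap_dbl(
      list(wide[[kc]], wide[[nc2]], wide[[kt]], wide[[nt2]]),
      function(kc_, nc_, kt_, nt_) {
        stats::fisher.test(matrix(c(kc_, nc_ - kc_, kt_, nt_ - kt_), 2))$p.value
      }
    )
    res <- wide |>
      dplyr::mutate(
        mark = mark,
        beta_control = .data[[kc]] / .data[[nc2]],
        beta_treated = .data[[kt]] / .data[[nt2]],
        delta_beta = .data$beta_treated - .data$beta_control,
        p_value = pv
      )
  }

  res <- res |>
    dplyr::mutate(
      fdr = p.adjust(.data$p_value, method = "BH"),
      call = dplyr::case_when(
        .data$p_value < alpha & .data$delta_beta > delta ~ "hyper",
        .data$p_value < alpha & .data$delta_beta < -delta ~ "hypo",
        .default = "none"
      )
    ) |>
    dplyr::select("chrom", "pos", "strand", "mark", "beta_control",
                  "beta_treated", "delta_beta", "p_value", "fdr", "call") |>
    dplyr::arrange(.data$chrom, .data$pos)
  structure(res, class = c("dmp_result", class(res)),
            alpha = alpha, delta = delta, test = test)
}

empty_dmp_result <- function(mark) {
  out <- tibble(chrom = character(), pos = integer(), strand = character(),
                mark = character(), beta_control = numeric(),
                beta_treated = numeric(), delta_beta = numeric(),
                p_value = numeric(), fdr = numeric(), call = character())
  structure(out, class = c("dmp_result", class(out)))
}

#' Summarise differential calls by annotation category
#'
#' Counts of hyper/hypo calls per CpG class and per functional element, with
#' each category's share of all calls of that mark. Fractions within each
#' category type sum to 1 when any calls exist.
#'
#' @param dmps An annotated [call_dmps()] result (after [annotate_sites()]).
#' @return A tibble: `category_type` (`"cpg_class"` or `"feature"`),
#'   `category`, `n_hyper`, `n_hypo`, `n_total`, `fraction`.
#' @export
summarize_by_annotation <- function(dmps) {
  if (!all(c("cpg_class", "feature", "call") %in% names(dmps))) {
    abort("`dmps` must carry `cpg_class`, `feature` and `call` columns; run annotate_sites() first")
  }
  one <- function(col, type) {
    called <- dmps |> dplyr::filter(.data$call != "none")
    lev <- if (type == "cpg_class") {
      c("island", "shore", "shelf", "open_sea")
    } else {
      c("promoter", "utr5", "utr3", "exon", "intron",
        "enhancer", "super_enhancer", "intergenic")
    }
    tab <- called |>
      dplyr::summarise(
        n_hyper = sum(.data$call == "hyper"),
        n_hypo = sum(.data$call == "hypo"),
        .by = dplyr::all_of(col)
      ) |>
      dplyr::rename(category = dplyr::all_of(col))
    full <- tibble(category = lev) |>
      dplyr::left_join(tab, by = "category") |>
      dplyr::mutate(
        dplyr::across(c("n_hyper", "n_hypo"), ~ tidyr::replace_na(.x, 0L)),
        n_total = .data$n_hyper + .data$n_hypo,
        fraction = if (sum(.data$n_hyper + .data$n_hypo) > 0) {
          .data$n_total / sum(.data$n_total)
        } else 0,
        category_type = type
      )
    full
  }
  dplyr::bind_rows(one("cpg_class", "cpg_class"), one("feature", "feature")) |>
    dplyr::select("category_type", "category", "n_hyper", "n_hypo",
                  "n_total", "fraction")
}

#' Promoter methylation versus expression correlation
#'
#' Spearman rank correlation between per-gene promoter beta-values and an
#' expression measure over the shared genes; a negative correlation is the
#' classic signature of promoter methylation silencing.
#'
#' @param promoter_betas A data frame with columns `gene`, `beta`.
#' @param expression A data frame with columns `gene`, `expression`.
#' @return A one-row tibble: `rho`, `p_value`, `n_genes`.
#' @export
methylation_expression_correlation <- function(promoter_betas, expression) {
  for (nm in list(c("promoter_betas", "gene", "beta"),
                  c("expression", "gene", "expression"))) {
    df <- get(nm[1])
    if (!all(nm[-1] %in% names(df))) {
      abort(sprintf("`%s` needs columns %s", nm[1],
                    paste0("`", nm[-1], "`", collapse = ", ")))
    }
  }
  shared <- dplyr::inner_join(promoter_betas, expression, by = "gene")
  if (nrow(shared) < 10L) {
    abort(sprintf("only %d shared genes; need at least 10", nrow(shared)))
  }
  ct <- suppressWarnings(
    stats::cor.test(shared$beta, shared$expression, method = "spearman")
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_genes = nrow(shared))
}
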