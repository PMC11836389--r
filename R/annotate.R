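#' Annotate CpG sites with CpG class and functional element
#'
#' CpG class by distance to the nearest CpG island on the same chromosome:
#' `island` inside one, `shore` within 2 kb of an island edge, `shelf`
#' 2-4 kb, `open_sea` beyond — the community distance convention. Functional
#' element by overlap with labelled intervals, resolved by precedence
#' `promoter > utr5 > utr3 > exon > intron > enhancer > super_enhancer`;
#' sites overlapping nothing are `intergenic`. Enhancer and super-enhancer
#' overlaps are additionally carried as flags (`in_enhancer`,
#' `in_super_enhancer`) since a promoter-labelled site can sit inside an
#' enhancer domain. Sites on chromosomes absent from every supplied track
#' are flagged `unannotated` with `NA` classes.
#'
#' All intervals use 0-based half-open (BED) coordinates; `pos` is the
#' 0-based position of the CpG cytosine. Strand is ignored — CpG sites are
#' treated as strand-symmetric units.
#'
#' @param sites A data frame with columns `chrom`, `pos` (0-based).
#'   Extra columns (e.g. a [call_dmps()] result) pass through.
#' @param cpg_islands A data frame of island intervals: `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param features Optional data frame `chrom`, `start`, `end`, `label` with
#'   labels among `promoter`, `utr5`, `utr3`, `exon`, `intron`, `enhancer`,
#'   `super_enhancer` (synonyms `5'UTR`/`3'UTR`, `SE`, `TE` are normalised).
#' @param shore_bp,shelf_bp Outer edges of the shore and shelf bands, bp.
#' @return `sites` with added columns `cpg_class`, `feature`,
#'   `in_enhancer`, `in_super_enhancer`, `unannotated`.
#' @export
annotate_sites <- function(sites, cpg_islands, features = NULL,
                           shore_bp = 2000, shelf_bp = 4000) {
  stopifnot(is.data.frame(sites))
  if (!all(c("chrom", "pos") %in% names(sites))) {
    abort("`sites` needs columns `chrom` and `pos`")
  }
  check_bed(cpg_islands, "cpg_islands")
  if (!is.null(features)) {
    check_bed(features, "features", labelled = TRUE)
    features$label <- normalise_feature_label(features$label)
  }

  known_chroms <- unique(c(cpg_islands$chrom,
                           if (!is.null(features)) features$chrom))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L))

  n <- nrow(sites)
  unannotated <- !(sites$chrom %in% known_chroms)

  cpg_class <- rep(NA_character_, n)
  if (nrow(cpg_islands) > 0L) {
    isl_gr <- GenomicRanges::GRanges(
      cpg_islands$chrom,
      IRanges::IRanges(start = cpg_islands$start + 1L, end = cpg_islands$end))
    dist <- rep(Inf, n)
    hits <- quiet_seqlevels(GenomicRanges::distanceToNearest(site_gr, isl_gr))
    dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    inside <- quiet_seqlevels(GenomicRanges::countOverlaps(site_gr, isl_gr)) > 0
    cpg_class <- dplyr::case_when(
      inside ~ "island",
      dist <= shore_bp ~ "shore",
      dist <= shelf_bp ~ "shelf",
      .default = "open_sea"
    )
  } else {
    cpg_class[!unannotated] <- "open_sea"
  }

  feature <- rep("intergenic", n)
  in_enh <- rep(FALSE, n)
  in_se <- rep(FALSE, n)
  if (!is.null(features) && nrow(features) > 0L) {
    feat_gr <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(start = features$start + 1L, end = features$end))
    ov <- quiet_seqlevels(GenomicRanges::findOverlaps(site_gr, feat_gr))
    if (length(ov) > 0L) {
      precedence <- c(promoter = 1, utr5 = 2, utr3 = 3, exon = 4, intron = 5,
                      enhancer = 6, super_enhancer = 7)
      hit_tbl <- tibble(
        i = S4Vectors::queryHits(ov),
        label = features$label[S4Vectors::subjectHits(ov)]
      ) |>
        dplyr::mutate(rank = precedence[.data$label])
      best <- hit_tbl |>
        dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE, by = "i")
      feature[best$i] <- best$label
      enh_hits <- hit_tbl |> dplyr::filter(.data$label == "enhancer")
      se_hits <- hit_tbl |> dplyr::filter(.data$label == "super_enhancer")
      in_enh[unique(enh_hits$i)] <- TRUE
      in_se[unique(se_hits$i)] <- TRUE
    }
  }

  cpg_class[unannotated] <- NA_character_
  feature[unannotated] <- NA_character_

  out <- sites
  out$cpg_class <- cpg_class
  out$feature <- feature
  out$in_enhancer <- in_enh
  out$in_super_enhancer <- in_se
  out$unannotated <- unannotated
  out
}

# chromosomes missing from a track are handled explicitly (unannotated flag);
# the seqlevel-mismatch warning would just repeat that
quiet_seqlevels <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

check_bed <- function(df, what, labelled = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", if (labelled) "label")
  if (!all(need %in% names(df))) {
    abort(sprintf("`%s` needs columns %s", what,
                  paste0("`", need, "`", collapse = ", ")))
  }
  if (any(df$start >= df$end)) {
    abort(sprintf("`%s` has intervals with start >= end", what))
  }
  if (any(df$start < 0)) {
    abort(sprintf("`%s` has negative starts", what))
  }
  invisible(df)
}

normalise_feature_label <- function(x) {
  key <- tolower(gsub("[^a-z0-9]+", "", tolower(x)))
  map <- c(promoter = "promoter",
           utr5 = "utr5", `5utr` = "utr5",
           utr3 = "utr3", `3utr` = "utr3",
           exon = "exon", intron = "intron",
           enhancer = "enhancer", te = "enhancer", typicalenhancer = "enhancer",
           superenhancer = "super_enhancer", se = "super_enhancer",
           intergenic = "intergenic")
  out <- unname(map[key])
  if (anyNA(out)) {
    abort(paste0("unknown feature label(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Promoter intervals from TSS positions
#'
#' Standard promoter window around transcription start sites: 1500 bp
#' upstream to 500 bp downstream, strand-aware, clipped at zero. Use when
#' only a TSS track is available; an explicit promoter BED overrides.
#'
#' @param tss A data frame with columns `chrom`, `pos` (0-based TSS) and
#'   optionally `strand` (`+` assumed when absent) and `gene`.
#' @param upstream,downstream Window extents in bp.
#' @return A BED-like tibble `chrom`, `start`, `end`, `label` (= "promoter"),
#'   plus `gene` when present.
#' @export
promoters_from_tss <- function(tss, upstream = 1500, downstream = 500) {
  stopifnot(is.data.frame(tss))
  if (!all(c("chrom", "pos") %in% names(tss))) {
    abort("`tss` needs columns `chrom` and `pos`")
  }
  strand <- if ("strand" %in% names(tss)) tss$strand else "+"
  minus <- strand == "-"
  start <- ifelse(minus, tss$pos - downstream, tss$pos - upstream)
  end <- ifelse(minus, tss$pos + upstream, tss$pos + downstream)
  out <- tibble(chrom = tss$chrom, start = pmax(0, start), end = end,
                label = "promoter")
  if ("gene" %in% names(tss)) out$gene <- tss$gene
  out
}
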