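islands <- tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L,
                          label = "island")

test_that("CpG class follows distance from the nearest island", {
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(10500L,        # inside the island
            11500L,        # 500 bp past the end: shore
            9000L,         # 1 kb before the start: shore
            14000L,        # 3 kb past the end: shelf
            20000L)        # far away: open sea
  )
  ann <- annotate_sites(sites, islands)
  expect_equal(ann$cpg_class,
               c("island", "shore", "shore", "shelf", "open_sea"))
  expect_false(any(ann$unannotated))
})

test_that("every site gets exactly one CpG class (partition property)", {
  sim <- synth_oxrrbs(n_sites = 200, seed = 3)
  ann <- annotate_sites(sim$sites, sim$islands, sim$features)
  expect_true(all(ann$cpg_class %in% c("island", "shore", "shelf", "open_sea")))
  expect_equal(ann$cpg_class, ann$cpg_class_true)
  expect_equal(ann$feature, ann$feature_true)
})

test_that("feature precedence and enhancer flags", {
  feats <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 500L, 500L),
    end   = c(200L, 200L, 600L, 600L),
    label = c("promoter", "intron", "exon", "SE")
  )
  sites <- tibble::tibble(chrom = "chr1", pos = c(150L, 550L, 900L))
  ann <- annotate_sites(sites, islands, feats)
  expect_equal(ann$feature, c("promoter", "exon", "intergenic"))
  expect_equal(ann$in_super_enhancer, c(FALSE, TRUE, FALSE))
  # unknown chromosome is flagged, not classified
  lost <- annotate_sites(tibble::tibble(chrom = "chrUn", pos = 5L), islands)
  expect_true(lost$unannotated)
  expect_true(is.na(lost$cpg_class))
  expect_error(
    annotate_sites(sites, islands,
                   tibble::tibble(chrom = "chr1", start = 1L, end = 2L,
                                  label = "mystery")),
    "unknown feature label")
})

test_that("promoter windows derive from TSS with strand awareness", {
  tss <- tibble::tibble(chrom = "chr1", pos = c(5000L, 5000L),
                        strand = c("+", "-"), gene = c("a", "b"))
  pr <- promoters_from_tss(tss)
  expect_equal(pr$start, c(3500, 4500))
  expect_equal(pr$end, c(5500, 6500))
  expect_equal(pr$label, rep("promoter", 2))
})

test_that("annotation summaries count and normalise calls per category", {
  dmps <- tibble::tibble(
    chrom = "chr1", pos = 1:9, mark = "5mC",
    call = c(rep("hyper", 6), rep("none", 3)),
    cpg_class = c("open_sea", "open_sea", "open_sea", "island", "shore",
                  "shelf", "open_sea", "island", "shore"),
    feature = c(rep("intron", 4), rep("exon", 2), rep("promoter", 3))
  )
  s <- summarize_by_annotation(dmps)
  open_sea <- dplyr::filter(s, category_type == "cpg_class",
                            category == "open_sea")
  expect_equal(open_sea$n_hyper, 3L)
  expect_equal(open_sea$fraction, 0.5)
  cpg <- dplyr::filter(s, category_type == "cpg_class")
  expect_equal(sum(cpg$fraction), 1)

  none <- summarize_by_annotation(dplyr::mutate(dmps, call = "none"))
  expect_true(all(none$n_total == 0))
  expect_true(all(none$fraction == 0))
})

test_that("effects planted only in open sea dominate the summary", {
  sim <- synth_oxrrbs(n_sites = 500, effect_fraction_hyper = 0.08,
                      effect_fraction_hypo = 0, effect_classes = "open_sea",
                      seed = 9)
  dm <- call_dmps(sim$counts, "control", "treated", mark = "5mC")
  ann <- annotate_sites(dm, sim$islands, sim$features)
  s <- summarize_by_annotation(ann)
  cpg <- dplyr::filter(s, category_type == "cpg_class")
  expect_identical(cpg$category[which.max(cpg$n_total)], "open_sea")
})
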