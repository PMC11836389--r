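# hand-built objects for unit tests

# a no_timecourse with a prescribed NO trajectory (other series zeroed)
make_no_timecourse <- function(times, no, dose = 0) {
  out <- tibble::tibble(
    time_s = times, donor_uM = 0, no_uM = no,
    o2_uM = 220, no_consumed_uM = 0
  )
  structure(out, class = c("no_timecourse", class(out)),
            dose = dose, donor = donor_spec("custom", 1, 1),
            params = kinetic_params())
}

make_activity <- function(times, product) {
  out <- tibble::tibble(time_s = times, no_uM = 0, product_fraction = product)
  structure(out, class = c("activity_timecourse", class(out)))
}

# long-format count rows for one site/condition/replicate
count_rows <- function(chrom, pos, condition, replicate,
                       bs_meth, bs_total, oxbs_meth, oxbs_total) {
  tibble::tibble(
    chrom = chrom, pos = pos, strand = ".",
    condition = condition, replicate = replicate,
    assay = c("BS", "oxBS"),
    meth = c(bs_meth, oxbs_meth),
    total = c(bs_total, oxbs_total)
  )
}

# a site with per-replicate oxBS methylation fractions set exactly (total 100)
site_counts <- function(pos, ctrl_beta5mc, trt_beta5mc, coverage = 100) {
  dplyr::bind_rows(
    purrr::imap(ctrl_beta5mc, function(b, i) {
      count_rows("chr1", pos, "control", i,
                 bs_meth = round(b * coverage), bs_total = coverage,
                 oxbs_meth = round(b * coverage), oxbs_total = coverage)
    }),
    purrr::imap(trt_beta5mc, function(b, i) {
      count_rows("chr1", pos, "treated", i,
                 bs_meth = round(b * coverage), bs_total = coverage,
                 oxbs_meth = round(b * coverage), oxbs_total = coverage)
    })
  )
}
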