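# design matrix of the generator's own linear predictor: five unhealthful
# indicators plus het/hom dummies per SNP, from the truth attribute
true_design <- function(cohort) {
  tr <- attr(cohort, "truth")
  stopifnot(!is.null(tr))
  des <- tr[, paste0("unhealthful_", c("diet", "bmi", "smoking", "activity",
                                       "drinking"))]
  des[] <- lapply(des, as.numeric)
  for (s in gl_snps()) {
    g <- cohort[[s]]
    des[[paste0(s, "_het")]] <- as.numeric(g == "het")
    des[[paste0(s, "_hom")]] <- as.numeric(g == "hom")
  }
  des
}

# the configured log-odds-ratios in the order of true_design's columns
configured_logors <- function(cfg) {
  c(log(cfg$lifestyle_or[c("diet", "bmi", "smoking", "activity", "drinking")]),
    as.vector(rbind(log(cfg$genotype_or$het_or), log(cfg$genotype_or$hom_or))))
}
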