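## truth-based novelty categories for recovered OTUs, used to evaluate the
## end-to-end pipeline: OTUs consisting solely of planted artifacts are
## excluded (they belong to no true OTU)
truth_novelty_fractions <- function(truth) {
  ok <- !truth$is_chimera & !truth$is_rogue
  by_otu <- split(truth$source[ok], truth$true_otu[ok])
  by_otu <- by_otu[vapply(by_otu, function(s)
    any(s %in% c("metagenome", "genome")), logical(1))]
  cat_of <- vapply(by_otu, function(s) {
    if (any(s == "genome")) "genome_backed"
    else if (any(s == "reference_db")) "mg_and_silva"
    else "mg_only"
  }, character(1))
  table(factor(cat_of, c("mg_only", "mg_and_silva", "genome_backed"))) /
    length(cat_of)
}

recovered_novelty_fractions <- function(census, truth) {
  artifacts <- truth$seq_id[truth$is_chimera | truth$is_rogue]
  by_otu <- split(census$tlc$membership$seq_id, census$tlc$membership$otu_id)
  keep <- names(by_otu)[vapply(by_otu, function(m) !all(m %in% artifacts),
                               logical(1))]
  nov <- census$otus$novelty[match(keep, census$otus$otu_id)]
  table(factor(nov, c("mg_only", "mg_and_silva", "genome_backed"))) /
    length(nov)
}

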