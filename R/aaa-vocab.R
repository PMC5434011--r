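# Controlled vocabularies shared across modules (defined in a file that
# collates first).

CONSEQUENCES <- c(
  "nonsynonymous", "stopgain", "stoploss",
  "frameshift_deletion", "frameshift_insertion",
  "nonframeshift_deletion", "nonframeshift_insertion",
  "splicing", "splice_acceptor_region",
  "synonymous", "noncoding"
)

# consequence classes that rescue an otherwise non-coding/synonymous call and
# that exempt a variant from missense predictor rules
SPLICE_CONSEQUENCES <- c("splicing", "splice_acceptor_region")

GENOTYPE_CONFIGS <- c("heterozygous", "homozygous", "compound_heterozygous", "hemizygote")

ZYGOSITIES <- c("hom_ref", "het", "hom_alt", "hemizygous", "missing")

INHERITANCE_MODELS <- c("dominant", "recessive", "sporadic", "xlinked")

UNIT_MODELS <- c("dominant", "recessive_hom", "recessive_comphet", "xlinked")

PROVEAN_LEVELS <- c("Deleterious", "Neutral", "missing")
SIFT_LEVELS <- c("Damaging", "Tolerated", "missing")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign", "missing")

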