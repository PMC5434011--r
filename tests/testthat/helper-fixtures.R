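# Shared fixtures and independent mini-oracles for the test suite.

known_mutations_tbl <- function() read_variant_table(rp_example("known_rp_mutations.tsv"))
rescue_tbl <- function() read_variant_table(rp_example("rescue_candidates.tsv"))
other_retinopathy_tbl <- function() read_variant_table(rp_example("other_retinopathy_mutations.tsv"))
known_panel <- function() load_panel(rp_example("panel_known_rp.tsv"), "known_rp")
other_panel <- function() load_panel(rp_example("panel_other_retinopathy.tsv"), "other_retinopathy")
reported_catalog <- function() load_catalog(rp_example("catalog_reported.tsv"))

# minimal variant-row builder
mk_variant <- function(gene = "GENE1", hgvs_c = "c.1A>G",
                       consequence = "nonsynonymous",
                       provean = "Deleterious", sift = "Damaging",
                       polyphen = "probably_damaging",
                       quality = NA_real_, depth = NA_integer_,
                       chrom = NA_character_, pos = NA_integer_,
                       frequencies = list(), family_id = NA_character_,
                       model = NA_character_, change = NA_character_) {
  df <- data.frame(gene = gene, hgvs_c = hgvs_c, consequence = consequence,
                   provean = provean, sift = sift, polyphen = polyphen,
                   quality = quality, depth = depth, chrom = chrom, pos = pos,
                   family_id = family_id, model = model, change = change,
                   stringsAsFactors = FALSE)
  df$frequencies <- list(frequencies)
  as_variant_table(df)
}

# random annotated variants for property tests (no genotypes)
random_variants <- function(n, seed = 1) {
  set.seed(seed)
  cons <- sample(c("nonsynonymous", "synonymous", "noncoding", "stopgain",
                   "splicing", "frameshift_deletion"), n, replace = TRUE)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    ac <- sample(0:60, 1)
    v <- mk_variant(gene = paste0("G", sample(1:8, 1)),
                    hgvs_c = paste0("c.", i, "A>G"),
                    consequence = cons[i],
                    provean = sample(c("Deleterious", "Neutral", "missing"), 1),
                    sift = sample(c("Damaging", "Tolerated", "missing"), 1),
                    polyphen = sample(c("probably_damaging", "possibly_damaging",
                                        "benign", "missing"), 1),
                    quality = sample(c(NA, 20, 31, 60), 1),
                    depth = sample(c(NA, 3L, 5L, 40L), 1),
                    frequencies = list(inhouse = c(ac = ac, an = 4040),
                                       exac = c(ac = sample(0:40, 1), an = 121412)))
    v
  }))
  as_variant_table(df)
}

# independent straight-line reimplementation of the cascade: every rule is
# evaluated directly from its definition, one variant at a time
oracle_retained_keys <- function(variants, model, policy) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    q <- variants$quality[i]; d <- variants$depth[i]
    ok <- (is.na(q) || q > policy$min_quality) && (is.na(d) || d >= policy$min_depth)
    if (ok && !is.null(policy$excluded_regions) && !is.na(variants$pos[i])) {
      r <- policy$excluded_regions
      inside <- any(r$chrom == variants$chrom[i] &
                    variants$pos[i] - 1 >= r$start & variants$pos[i] - 1 < r$end)
      ok <- !inside
    }
    if (ok) {
      maf <- 0
      for (s in policy$frequency_sources) {
        f <- variants$frequencies[[i]][[s]]
        if (!is.null(f) && f[["an"]] > 0) maf <- max(maf, f[["ac"]] / f[["an"]])
      }
      thr <- if (model == "dominant") policy$maf_dominant else policy$maf_recessive
      ok <- maf <= thr
    }
    if (ok) {
      cs <- variants$consequence[i]
      ok <- !(cs %in% c("noncoding", "synonymous"))
      if (cs %in% c("splicing", "splice_acceptor_region")) ok <- TRUE
    }
    keep[i] <- ok
  }
  variants$key[keep]
}

# a trio family with configurable genotype records
mk_trio <- function(fam = "FAM1", declared = "recessive", proband_sex = "male",
                    father_aff = "unaffected", mother_aff = "unaffected") {
  members <- data.frame(
    family_id = fam,
    sample_id = paste0(fam, c("_F", "_M", "_P")),
    father_id = c(NA, NA, paste0(fam, "_F")),
    mother_id = c(NA, NA, paste0(fam, "_M")),
    sex = c("male", "female", proband_sex),
    affected = c(father_aff, mother_aff, "affected"),
    sequenced = TRUE, stringsAsFactors = FALSE)
  new_family(fam, members, declared)
}

mk_geno <- function(fam, sample_suffixes, keys, zygosities) {
  data.frame(family_id = fam,
             sample_id = paste0(fam, "_", sample_suffixes),
             key = keys, zygosity = zygosities, stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 1, ...) {
  simulation_config(seed = seed,
                    n_families = c(dominant = 4L, recessive = 4L,
                                   sporadic = 6L, xlinked = 2L),
                    background_mean = 15, ...)
}
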