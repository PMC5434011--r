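# The inheritance-pattern engine: turns retained variants plus pedigree
# genotypes into candidate causal units (1 or 2 variants, a model, phase,
# de novo status and a segregation verdict).

TRUNCATING_CONSEQUENCES <- c("stopgain", "frameshift_deletion", "frameshift_insertion",
                             "splicing", "splice_acceptor_region")

new_unit <- function(family_id, gene, model, keys, hgvs,
                     phase = "not_applicable", de_novo = "untestable",
                     segregation = "untested", low_confidence = FALSE) {
  keys <- sort(keys)
  data.frame(family_id = family_id, gene = gene, model = model,
             variant_keys = paste(keys, collapse = ";"),
             hgvs_c = paste(hgvs[order(keys)], collapse = ";"),
             n_variants = length(keys),
             phase = phase, de_novo = de_novo, segregation = segregation,
             low_confidence = low_confidence,
             novelty = NA_character_, tier = NA_character_,
             stringsAsFactors = FALSE)
}

empty_units <- function() {
  data.frame(family_id = character(), gene = character(), model = character(),
             variant_keys = character(), hgvs_c = character(),
             n_variants = integer(), phase = character(), de_novo = character(),
             segregation = character(), low_confidence = logical(),
             novelty = character(), tier = character(), stringsAsFactors = FALSE)
}

#' Candidate unit models compatible with a genotype and a panel entry
#'
#' Intersects the panel's permitted modes for the gene with the
#' genotype-compatible patterns: heterozygous calls fit the dominant model,
#' two or more heterozygous calls additionally fit a compound-heterozygote
#' hypothesis, homozygous calls fit the recessive model, and hemizygous or
#' homozygous (or flagged heterozygous female) calls fit the X-linked
#' model. Families of the sporadic class are evaluated under all models.
#'
#' @param declared_model Family's declared class.
#' @param modes Panel modes for the gene (subset of `ad`, `ar`, `xl`);
#'   a gene absent from the panel has no modes and yields no models.
#' @param zygosities Proband zygosities for the gene's retained variants.
#' @return Character vector of candidate unit models (possibly empty).
#' @export
match_inheritance <- function(declared_model, modes, zygosities) {
  scan <- switch(declared_model,
    dominant = "ad", recessive = "ar", xlinked = "xl",
    sporadic = c("ad", "ar", "xl"))
  modes <- intersect(modes, scan)
  out <- character()
  n_het <- sum(zygosities == "het")
  if ("ad" %in% modes && n_het >= 1) out <- c(out, "dominant")
  if ("ar" %in% modes && any(zygosities == "hom_alt")) out <- c(out, "recessive_hom")
  if ("ar" %in% modes && n_het >= 2) out <- c(out, "recessive_comphet")
  if ("xl" %in% modes && any(zygosities %in% c("hemizygous", "hom_alt", "het"))) {
    out <- c(out, "xlinked")
  }
  out
}

# parental origin of one proband allele: "father", "mother", "both",
# "neither" (both parents sequenced hom_ref) or "unknown"
allele_origin <- function(family, genotypes, proband_id, key) {
  i <- match(proband_id, family$members$sample_id)
  f <- family$members$father_id[i]; m <- family$members$mother_id[i]
  zf <- if (is.na(f)) "missing" else zygosity_of(family, genotypes, f, key)
  zm <- if (is.na(m)) "missing" else zygosity_of(family, genotypes, m, key)
  if (zf == "missing" || zm == "missing") return("unknown")
  cf <- carries_alt(zf); cm <- carries_alt(zm)
  if (cf && cm) "both" else if (cf) "father" else if (cm) "mother" else "neither"
}

#' Scan heterozygous variants of one gene for compound-heterozygote pairs
#'
#' Enumerates all unordered pairs of distinct retained heterozygous
#' variants in the proband. A pair is rejected as cis when both alleles
#' are unambiguously inherited from the same parent. Phase is
#' `trans_confirmed` when father and mother each carry exactly one allele
#' of the pair, or when an unaffected sequenced direct relative carries
#' exactly one; otherwise `phase_unknown` (singleton probands are reported
#' with this explicit caveat). With more than two heterozygous variants,
#' all trans-compatible pairs are returned ranked by number of truncating
#' alleles, then by lower maximum reference MAF.
#'
#' @param family `rp_family`.
#' @param genotypes Family genotype slice.
#' @param gene Gene symbol.
#' @param het_keys Keys of retained heterozygous proband variants in `gene`.
#' @param variants Variant table (for consequence/frequency ranking).
#' @param policy [filter_policy()] (frequency sources for ranking).
#' @return Units data.frame (possibly zero-row).
#' @export
scan_compound_het <- function(family, genotypes, gene, het_keys, variants,
                              policy = filter_policy()) {
  het_keys <- unique(het_keys)
  if (length(het_keys) < 2) return(empty_units())
  proband <- proband_of(family)
  prob_i <- match(proband, family$members$sample_id)
  parents <- c(family$members$father_id[prob_i], family$members$mother_id[prob_i])
  origins <- vapply(het_keys, function(k) allele_origin(family, genotypes, proband, k),
                    character(1))
  relatives <- family$members[family$members$sequenced &
                              family$members$sample_id != proband &
                              !(family$members$sample_id %in% parents) &
                              family$members$affected == "unaffected", , drop = FALSE]
  pairs <- utils::combn(het_keys, 2, simplify = FALSE)
  units <- list()
  for (p in pairs) {
    o1 <- origins[[p[1]]]; o2 <- origins[[p[2]]]
    if (o1 %in% c("father", "mother") && o1 == o2) next  # cis: one parental haplotype
    phase <- "phase_unknown"
    if ((o1 == "father" && o2 == "mother") || (o1 == "mother" && o2 == "father")) {
      phase <- "trans_confirmed"
    } else if (nrow(relatives)) {
      for (r in relatives$sample_id) {
        carry <- vapply(p, function(k) carries_alt(zygosity_of(family, genotypes, r, k)),
                        logical(1))
        if (sum(carry) == 1) { phase <- "trans_confirmed"; break }
      }
    }
    hg <- variants$hgvs_c[match(p, variants$key)]
    units[[length(units) + 1L]] <- new_unit(family$family_id, gene,
                                            "recessive_comphet", p, hg, phase = phase)
  }
  if (!length(units)) return(empty_units())
  out <- do.call(rbind, units)
  if (nrow(out) > 1) {
    score <- vapply(strsplit(out$variant_keys, ";", fixed = TRUE), function(ks) {
      idx <- match(ks, variants$key)
      trunc_n <- sum(variants$consequence[idx] %in% TRUNCATING_CONSEQUENCES)
      maf <- max(vapply(idx, function(i)
        max_reference_maf(variants$frequencies[[i]], policy$frequency_sources)$maf,
        numeric(1)))
      trunc_n * 1e6 - maf  # more truncating alleles first, then rarer pairs
    }, numeric(1))
    out <- out[order(-score), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' De novo status of a proband variant
#'
#' A mutation is de novo when the affected proband carries the allele and
#' both biological parents are sequenced, called, and homozygous reference.
#' One parent carrying the allele refutes de novo even if the other is
#' unavailable; otherwise an unsequenced or uncalled parent makes the test
#' `"untestable"` (distinct from a refuted `"not_de_novo"`).
#'
#' @param family `rp_family`.
#' @param genotypes Family genotype slice.
#' @param key Variant key.
#' @param proband_id Proband sample (defaults to first affected member).
#' @return `"de_novo"`, `"not_de_novo"` or `"untestable"`.
#' @export
detect_de_novo <- function(family, genotypes, key, proband_id = proband_of(family)) {
  if (!carries_alt(zygosity_of(family, genotypes, proband_id, key))) return("not_de_novo")
  i <- match(proband_id, family$members$sample_id)
  f <- family$members$father_id[i]; m <- family$members$mother_id[i]
  zf <- if (is.na(f)) "missing" else zygosity_of(family, genotypes, f, key)
  zm <- if (is.na(m)) "missing" else zygosity_of(family, genotypes, m, key)
  if (carries_alt(zf) || carries_alt(zm)) return("not_de_novo")
  if (zf == "missing" || zm == "missing") return("untestable")
  "de_novo"
}

# does `sample` carry the full causal genotype of `unit`?
carries_full_genotype <- function(family, genotypes, sample_id, unit, sex) {
  keys <- strsplit(unit$variant_keys, ";", fixed = TRUE)[[1]]
  zyg <- vapply(keys, function(k) zygosity_of(family, genotypes, sample_id, k),
                character(1))
  switch(unit$model,
    dominant = carries_alt(zyg[1]),
    recessive_hom = zyg[1] == "hom_alt",
    recessive_comphet = all(carries_alt(zyg)),
    xlinked = zyg[1] == "hemizygous" || zyg[1] == "hom_alt",
    FALSE)
}

#' Segregation check for a candidate unit
#'
#' A unit is `violated` when an unaffected sequenced relative carries the
#' full causal genotype (the heterozygous allele for a dominant unit, the
#' homozygous genotype for a recessive one, both alleles of a
#' compound-heterozygote pair, the hemizygous or homozygous allele for an
#' X-linked one). Unaffected carriers of half a recessive unit are
#' `consistent` — carrier parents are what the compound-heterozygote
#' definition expects. Relatives of unknown affection status can neither
#' confirm nor violate. With no informative relative the unit is
#' `untested`.
#'
#' @param family `rp_family`.
#' @param genotypes Family genotype slice.
#' @param unit One-row units data.frame.
#' @return `"consistent"`, `"violated"` or `"untested"`.
#' @export
check_segregation <- function(family, genotypes, unit) {
  proband <- proband_of(family)
  rel <- family$members[family$members$sequenced &
                        family$members$sample_id != proband, , drop = FALSE]
  if (!nrow(rel)) return("untested")
  keys <- strsplit(unit$variant_keys, ";", fixed = TRUE)[[1]]
  informative <- FALSE
  for (i in seq_len(nrow(rel))) {
    zyg <- vapply(keys, function(k) zygosity_of(family, genotypes, rel$sample_id[i], k),
                  character(1))
    if (all(zyg == "missing")) next
    informative <- TRUE
    if (rel$affected[i] == "unaffected" &&
        carries_full_genotype(family, genotypes, rel$sample_id[i], unit, rel$sex[i])) {
      return("violated")
    }
  }
  if (informative) "consistent" else "untested"
}

#' Scan X-linked candidate genes in one family
#'
#' Affected hemizygous males yield a unit; affected homozygous females
#' yield a unit; affected heterozygous females are permitted by the
#' X-linked matching rule but emitted flagged low-confidence.
#'
#' @param family `rp_family`.
#' @param genotypes Family genotype slice.
#' @param gene Gene symbol (X panel gene).
#' @param keys Retained variant keys in `gene`.
#' @param variants Variant table.
#' @return Units data.frame (possibly zero-row).
#' @export
scan_xlinked <- function(family, genotypes, gene, keys, variants) {
  proband <- proband_of(family)
  sex <- family$members$sex[match(proband, family$members$sample_id)]
  units <- list()
  for (k in keys) {
    z <- zygosity_of(family, genotypes, proband, k)
    hg <- variants$hgvs_c[match(k, variants$key)]
    if (sex == "male" && z == "hemizygous") {
      units[[length(units) + 1L]] <- new_unit(family$family_id, gene, "xlinked", k, hg)
    } else if (sex == "female" && z == "hom_alt") {
      units[[length(units) + 1L]] <- new_unit(family$family_id, gene, "xlinked", k, hg)
    } else if (sex == "female" && z == "het") {
      units[[length(units) + 1L]] <- new_unit(family$family_id, gene, "xlinked", k, hg,
                                              low_confidence = TRUE)
    }
  }
  if (!length(units)) empty_units() else do.call(rbind, units)
}

#' Unit-level predictor exclusion
#'
#' A single-variant unit is excluded when its missense variant is
#' unanimously benign across the three predictors; a two-variant unit only
#' when both alleles are. This is the unit-level reading of the published
#' missense-consensus step: within a compound-heterozygote pair, one
#' damaging allele keeps the pair alive.
#'
#' @param units Units data.frame.
#' @param variants Variant table.
#' @return Logical vector, `TRUE` where the unit is excluded.
#' @export
unit_predictor_exclusion <- function(units, variants) {
  if (!nrow(units)) return(logical(0))
  vapply(seq_len(nrow(units)), function(i) {
    keys <- strsplit(units$variant_keys[i], ";", fixed = TRUE)[[1]]
    idx <- match(keys, variants$key)
    benign <- variants$consequence[idx] == "nonsynonymous" &
      triple_benign(variants$provean[idx], variants$sift[idx], variants$polyphen[idx])
    all(benign)
  }, logical(1))
}

#' Advisory digenic pairing
#'
#' When one family retains two or more monoallelic (dominant-model) units
#' in different genes, every cross-gene pair is flagged as a possible
#' digenic hypothesis. The flag is advisory: the individual units are
#' never suppressed, and units that already satisfy a biallelic model do
#' not participate.
#'
#' @param units Units data.frame (one family or a whole cohort).
#' @return data.frame `family_id`, `gene1`, `gene2`, `keys1`, `keys2`.
#' @export
flag_digenic <- function(units) {
  out <- data.frame(family_id = character(), gene1 = character(), gene2 = character(),
                    keys1 = character(), keys2 = character(), stringsAsFactors = FALSE)
  mono <- units[units$model == "dominant", , drop = FALSE]
  for (fam in unique(mono$family_id)) {
    u <- mono[mono$family_id == fam, , drop = FALSE]
    genes <- unique(u$gene)
    if (length(genes) < 2) next
    for (pair in utils::combn(sort(genes), 2, simplify = FALSE)) {
      out <- rbind(out, data.frame(
        family_id = fam, gene1 = pair[1], gene2 = pair[2],
        keys1 = u$variant_keys[match(pair[1], u$gene)],
        keys2 = u$variant_keys[match(pair[2], u$gene)],
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Scan one family for candidate causal units
#'
#' Runs the full engine for a single family over model-specific retained
#' variant sets: dominant heterozygotes (with de novo annotation),
#' recessive homozygotes, compound-heterozygote pairs, and X-linked
#' hypotheses, followed by unit-level predictor exclusion and segregation
#' checking. Units violating segregation are dropped (they never appear in
#' reports).
#'
#' @param family `rp_family`.
#' @param genotypes Family genotype slice (`sample_id`, `key`, `zygosity`).
#' @param retained Named list of retained `rp_variants` per scan model
#'   (`dominant`, `recessive`, `xlinked`), e.g. from [apply_cascade()] runs.
#' @param panel `rp_panel`.
#' @param policy [filter_policy()].
#' @return Units data.frame.
#' @export
scan_family <- function(family, genotypes, retained, panel,
                        policy = filter_policy()) {
  proband <- proband_of(family)
  units <- list()
  scan_models <- switch(family$declared_model,
    dominant = "dominant", recessive = "recessive", xlinked = "xlinked",
    sporadic = c("dominant", "recessive", "xlinked"))

  gene_variants <- function(variants, mode) {
    variants[vapply(variants$gene, function(g) mode %in% panel_modes(panel, g),
                    logical(1)), , drop = FALSE]
  }

  if ("dominant" %in% scan_models) {
    vs <- gene_variants(retained$dominant, "ad")
    for (i in seq_len(nrow(vs))) {
      k <- vs$key[i]
      if (zygosity_of(family, genotypes, proband, k) != "het") next
      dn <- detect_de_novo(family, genotypes, k, proband)
      if (family$declared_model == "sporadic" && dn == "not_de_novo") {
        # transmitted from an unaffected parent: incompatible with dominance
        next
      }
      units[[length(units) + 1L]] <- new_unit(family$family_id, vs$gene[i], "dominant",
                                              k, vs$hgvs_c[i], de_novo = dn)
    }
  }
  if ("recessive" %in% scan_models) {
    vs <- gene_variants(retained$recessive, "ar")
    for (i in seq_len(nrow(vs))) {
      k <- vs$key[i]
      if (zygosity_of(family, genotypes, proband, k) == "hom_alt") {
        units[[length(units) + 1L]] <- new_unit(family$family_id, vs$gene[i],
                                                "recessive_hom", k, vs$hgvs_c[i])
      }
    }
    for (g in unique(vs$gene)) {
      ks <- vs$key[vs$gene == g]
      het <- ks[vapply(ks, function(k)
        zygosity_of(family, genotypes, proband, k) == "het", logical(1))]
      ch <- scan_compound_het(family, genotypes, g, het, vs, policy)
      if (nrow(ch)) units[[length(units) + 1L]] <- ch
    }
  }
  if ("xlinked" %in% scan_models) {
    vs <- gene_variants(retained$xlinked, "xl")
    vs <- vs[is.na(vs$chrom) | is_x_chrom(vs$chrom), , drop = FALSE]
    for (g in unique(vs$gene)) {
      xs <- scan_xlinked(family, genotypes, g, vs$key[vs$gene == g], vs)
      if (nrow(xs)) units[[length(units) + 1L]] <- xs
    }
  }
  if (!length(units)) return(empty_units())
  units <- do.call(rbind, units)
  rownames(units) <- NULL

  all_vars <- unique(do.call(rbind, lapply(retained, function(v)
    v[, c("key", "gene", "hgvs_c", "consequence", "provean", "sift", "polyphen")])))
  excl <- unit_predictor_exclusion(units, all_vars)
  units <- units[!excl, , drop = FALSE]

  if (nrow(units)) {
    units$segregation <- vapply(seq_len(nrow(units)), function(i)
      check_segregation(family, genotypes, units[i, , drop = FALSE]), character(1))
    units <- units[units$segregation != "violated", , drop = FALSE]
  }
  rownames(units) <- NULL
  units
}
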