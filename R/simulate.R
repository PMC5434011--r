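# Synthetic family-cohort generator with ground truth.
#
# Emulates the study design: small families recruited under four declared
# inheritance classes, each carrying (with a per-class probability mirroring
# the published diagnostic yields) one implantable causal unit constructed
# to satisfy every filter and segregation rule, plus decoy variants each
# built to fail one named rule, plus a background variant load drawn from a
# frequency spectrum. Positions live on synthetic contigs; gene symbols and
# permitted modes come from the packaged known-RP panel. The manifest
# records every implanted unit and every decoy with its intended failing
# rule, so recovery is checkable exactly.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 22 dominant, 19 recessive, 52
#' sporadic and 5 X-linked families; per-class causal fractions equal to
#' the published per-class diagnostic yields (0.59/0.42/0.31/0.80); a mean
#' in-panel background load of 150 variants per family; sporadic probands
#' recruited without parents 80% of the time.
#'
#' @param seed Integer seed; fully determines the cohort.
#' @param n_families Named vector, families per declared model.
#' @param causal_fraction Named vector, probability a family of each class
#'   carries an implantable causal unit.
#' @param background_mean Mean background variants per family (Poisson).
#' @param predictor_false_benign Probability a causal missense is annotated
#'   unanimously benign (predictor noise; 0 = noise-free).
#' @param singleton_prob Probability a sporadic family is a parent-less
#'   singleton.
#' @param an_sources Named vector of fixed allele numbers per reference
#'   source (defaults: in-house 2020 controls = 4040 alleles, 1000 Genomes
#'   Phase III = 5008, ExAC = 121412).
#' @return An `rp_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_families = c(dominant = 22L, recessive = 19L,
                                             sporadic = 52L, xlinked = 5L),
                              causal_fraction = c(dominant = 0.59, recessive = 0.42,
                                                  sporadic = 0.31, xlinked = 0.80),
                              background_mean = 150,
                              predictor_false_benign = 0,
                              singleton_prob = 0.8,
                              an_sources = c(inhouse = 4040, `1kg` = 5008,
                                             exac = 121412)) {
  stopifnot(all(INHERITANCE_MODELS %in% names(n_families)),
            all(INHERITANCE_MODELS %in% names(causal_fraction)),
            all(causal_fraction >= 0 & causal_fraction <= 1),
            predictor_false_benign >= 0, predictor_false_benign <= 1,
            singleton_prob >= 0, singleton_prob <= 1,
            background_mean >= 0)
  if (sum(n_families) < 1) stop("empty cohort refused: n_families sums to 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_families = n_families,
                 causal_fraction = causal_fraction,
                 background_mean = background_mean,
                 predictor_false_benign = predictor_false_benign,
                 singleton_prob = singleton_prob, an_sources = an_sources),
            class = "rp_sim_config")
}

# ---- internal generator state helpers ----------------------------------

sim_panel <- function() {
  load_panel(system.file("extdata", "panel_known_rp.tsv", package = "rpcascade"),
             name = "known_rp")
}

# gene -> synthetic contig/base-position layout
gene_layout <- function(panel) {
  genes <- panel_genes(panel)
  modes <- panel$entries
  chrom <- vapply(seq_along(genes), function(i) {
    if ("xl" %in% modes[[i]]) "X" else as.character(1 + (i - 1) %% 22)
  }, character(1))
  data.frame(gene = genes, chrom = chrom, base = seq_along(genes) * 1e6,
             stringsAsFactors = FALSE)
}

DAMAGING <- c(provean = "Deleterious", sift = "Damaging", polyphen = "probably_damaging")
BENIGN <- c(provean = "Neutral", sift = "Tolerated", polyphen = "benign")
MISSING3 <- c(provean = "missing", sift = "missing", polyphen = "missing")

# one synthetic variant row; `counter` is an environment carrying a serial
sim_variant <- function(state, gene, consequence, preds, freqs) {
  state$serial <- state$serial + 1L
  gi <- match(gene, state$layout$gene)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  alt <- sample(setdiff(bases, ref), 1)
  hgvs_c <- paste0("c.", state$serial, ref, ">", alt)
  # plain list row (assembled into a data.frame once per cohort): a
  # data.frame per variant is prohibitively slow at 10^4 variants
  list(chrom = state$layout$chrom[gi], pos = state$layout$base[gi] + state$serial,
       ref = ref, alt = alt, gene = gene, transcript = "", hgvs_c = hgvs_c,
       hgvs_p = "", consequence = consequence,
       provean = preds[["provean"]], sift = preds[["sift"]],
       polyphen = preds[["polyphen"]],
       quality = round(runif(1, 50, 99), 1), depth = sample(10:120, 1),
       frequencies = freqs, key = variant_key(gene, hgvs_c))
}

# frequency maps
freq_absent <- function(an_sources) {
  fr <- lapply(an_sources, function(an) c(ac = 0, an = unname(an)))
  names(fr) <- names(an_sources)
  fr
}
freq_rare <- function(an_sources, maf_cap = 0.004) {
  fr <- lapply(an_sources, function(an) {
    c(ac = sample(0:max(1, floor(maf_cap * an * 0.8)), 1), an = unname(an))
  })
  names(fr) <- names(an_sources)
  fr
}
freq_common <- function(an_sources, maf_min = 0.01) {
  fr <- lapply(names(an_sources), function(s) {
    an <- an_sources[[s]]
    c(ac = sample(ceiling(maf_min * an):floor(0.5 * an), 1), an = unname(an))
  })
  names(fr) <- names(an_sources)
  fr
}

# pedigree builders; proband id is always <fam>_P
ped_member <- function(fam, id, father = NA, mother = NA, sex, affected) {
  data.frame(family_id = fam, sample_id = paste0(fam, "_", id),
             father_id = if (is.na(father)) NA_character_ else paste0(fam, "_", father),
             mother_id = if (is.na(mother)) NA_character_ else paste0(fam, "_", mother),
             sex = sex, affected = affected, sequenced = TRUE,
             stringsAsFactors = FALSE)
}

build_pedigree <- function(fam, template, proband_sex) {
  switch(template,
    singleton = ped_member(fam, "P", sex = proband_sex, affected = "affected"),
    trio = rbind(
      ped_member(fam, "F", sex = "male", affected = "unaffected"),
      ped_member(fam, "M", sex = "female", affected = "unaffected"),
      ped_member(fam, "P", "F", "M", sex = proband_sex, affected = "affected")),
    quartet = rbind(
      ped_member(fam, "F", sex = "male", affected = "affected"),
      ped_member(fam, "M", sex = "female", affected = "unaffected"),
      ped_member(fam, "P", "F", "M", sex = proband_sex, affected = "affected"),
      ped_member(fam, "S", "F", "M", sex = "female", affected = "unaffected")),
    quartet_unaffected_parents = rbind(
      ped_member(fam, "F", sex = "male", affected = "unaffected"),
      ped_member(fam, "M", sex = "female", affected = "unaffected"),
      ped_member(fam, "P", "F", "M", sex = proband_sex, affected = "affected"),
      ped_member(fam, "S", "F", "M", sex = "female", affected = "unaffected")),
    threegen = rbind(
      ped_member(fam, "GF", sex = "male", affected = "affected"),
      ped_member(fam, "GM", sex = "female", affected = "unaffected"),
      ped_member(fam, "F", "GF", "GM", sex = "male", affected = "affected"),
      ped_member(fam, "M", sex = "female", affected = "unaffected"),
      ped_member(fam, "P", "F", "M", sex = proband_sex, affected = "affected")),
    stop("unknown pedigree template: ", template))
}

geno <- function(fam, sample_suffix, key, zygosity) {
  list(family_id = fam, sample_id = paste0(fam, "_", sample_suffix),
       key = key, zygosity = zygosity)
}

#' Simulate a family WES cohort with ground truth
#'
#' Generates pedigrees, per-sample genotypes and variant annotations for a
#' cohort of small RP families, together with a truth manifest listing the
#' implanted causal unit of each family (if any) and every decoy variant
#' with the filter or segregation rule it is built to fail. Causal units
#' are Mendelian-consistent and satisfy every cascade and segregation rule
#' by construction (with zero predictor noise); decoys and background
#' variants each fail at least one named rule.
#'
#' @param config [simulation_config()].
#' @return List with `cohort` (an `rp_cohort`) and `manifest` (list with
#'   `families` and `decoys` data.frames, class `rp_manifest`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "rp_sim_config"))
  set.seed(config$seed)
  panel <- sim_panel()
  state <- new.env(parent = emptyenv())
  state$serial <- 0L
  state$layout <- gene_layout(panel)

  modes <- panel$entries
  ad_genes <- names(modes)[vapply(modes, function(m) "ad" %in% m, logical(1))]
  ar_genes <- names(modes)[vapply(modes, function(m) "ar" %in% m, logical(1))]
  xl_genes <- names(modes)[vapply(modes, function(m) "xl" %in% m, logical(1))]
  autosomal <- setdiff(panel_genes(panel), xl_genes)
  # recessive-only genes: biallelic hypotheses placed here are never also
  # dominant-compatible, keeping the implanted unit the unique solution
  ar_only <- setdiff(ar_genes, c(ad_genes, xl_genes))

  families <- list(); variants <- list(); genotypes <- list()
  truth <- list(); decoys <- list()
  an <- config$an_sources
  fam_no <- 0L

  add_variant <- function(v) variants[[length(variants) + 1L]] <<- v
  add_geno <- function(g) genotypes[[length(genotypes) + 1L]] <<- g
  add_decoy <- function(fam, key, rule) {
    decoys[[length(decoys) + 1L]] <<- data.frame(family_id = fam, key = key,
                                                 rule = rule, stringsAsFactors = FALSE)
  }

  # heterozygous carry of one variant through parent + proband (+optional others)
  carry_het <- function(fam, key, carriers) {
    for (s in carriers) add_geno(geno(fam, s, key, "het"))
  }

  for (model in INHERITANCE_MODELS) {
    for (i in seq_len(config$n_families[[model]])) {
      fam_no <- fam_no + 1L
      fam <- sprintf("SIM-%03d", fam_no)
      proband_sex <- if (model == "xlinked") "male" else sample(c("male", "female"), 1)
      template <- switch(model,
        dominant = sample(c("threegen", "quartet"), 1),
        recessive = sample(c("trio", "quartet_unaffected_parents"), 1),
        sporadic = if (runif(1) < config$singleton_prob) "singleton" else "trio",
        xlinked = "trio")
      members <- build_pedigree(fam, template, proband_sex)
      family <- new_family(fam, members, model)
      families[[fam]] <- family
      has_parents <- template != "singleton"
      has_unaffected_rel <- any(members$affected == "unaffected")

      causal <- runif(1) < config$causal_fraction[[model]]
      causal_gene <- NA_character_
      # genes already carrying a rare heterozygous hypothesis in this family;
      # kept disjoint so decoys cannot pair with each other or with the
      # causal unit inside one gene
      used_rare <- character()
      pick_gene <- function(pool) {
        pool <- setdiff(pool, used_rare)
        if (!length(pool)) return(NA_character_)
        g <- sample(pool, 1)
        used_rare <<- c(used_rare, g)
        g
      }
      if (causal) {
        noise_benign <- runif(1) < config$predictor_false_benign
        miss_preds <- if (noise_benign) BENIGN else DAMAGING
        unit_model <- switch(model,
          dominant = "dominant",
          recessive = sample(c("recessive_hom", "recessive_comphet"), 1),
          xlinked = "xlinked",
          sporadic = {
            choices <- c("recessive_comphet", "recessive_hom")
            if (has_parents) choices <- c(choices, "dominant")
            if (proband_sex == "male") choices <- c(choices, "xlinked")
            sample(choices, 1)
          })
        if (unit_model == "dominant") {
          causal_gene <- pick_gene(setdiff(ad_genes, xl_genes))
          truncating <- runif(1) < 0.4
          v <- sim_variant(state, causal_gene,
                           if (truncating) "stopgain" else "nonsynonymous",
                           if (truncating) MISSING3 else miss_preds,
                           freq_absent(an))
          add_variant(v)
          de_novo <- model == "sporadic"
          if (de_novo) {
            carry_het(fam, v$key, "P")  # parents hom_ref: de novo
          } else if (template == "threegen") {
            carry_het(fam, v$key, c("GF", "F", "P"))
          } else {
            carry_het(fam, v$key, c("F", "P"))  # affected father transmits
          }
          truth[[fam]] <- data.frame(family_id = fam, declared_model = model,
                                     model = "dominant", gene = causal_gene,
                                     variant_keys = v$key, de_novo = de_novo,
                                     stringsAsFactors = FALSE)
        } else if (unit_model == "recessive_hom") {
          causal_gene <- pick_gene(ar_only)
          v <- sim_variant(state, causal_gene, "nonsynonymous", miss_preds,
                           freq_absent(an))
          add_variant(v)
          add_geno(geno(fam, "P", v$key, "hom_alt"))
          if (has_parents) carry_het(fam, v$key, c("F", "M"))
          if ("S" %in% sub("^.*_", "", members$sample_id)) {
            carry_het(fam, v$key, "S")  # carrier sib: consistent, not violating
          }
          truth[[fam]] <- data.frame(family_id = fam, declared_model = model,
                                     model = "recessive_hom", gene = causal_gene,
                                     variant_keys = v$key, de_novo = FALSE,
                                     stringsAsFactors = FALSE)
        } else if (unit_model == "recessive_comphet") {
          causal_gene <- pick_gene(ar_only)
          trunc1 <- runif(1) < 0.3
          v1 <- sim_variant(state, causal_gene,
                            if (trunc1) "frameshift_deletion" else "nonsynonymous",
                            if (trunc1) MISSING3 else DAMAGING, freq_absent(an))
          v2 <- sim_variant(state, causal_gene, "nonsynonymous", miss_preds,
                            freq_absent(an))
          add_variant(v1); add_variant(v2)
          carry_het(fam, v1$key, "P"); carry_het(fam, v2$key, "P")
          if (has_parents) {
            carry_het(fam, v1$key, "F")  # paternal allele
            carry_het(fam, v2$key, "M")  # maternal allele
          }
          if ("S" %in% sub("^.*_", "", members$sample_id)) {
            carry_het(fam, v1$key, "S")  # sib carries exactly one allele
          }
          truth[[fam]] <- data.frame(family_id = fam, declared_model = model,
                                     model = "recessive_comphet", gene = causal_gene,
                                     variant_keys = paste(sort(c(v1$key, v2$key)), collapse = ";"),
                                     de_novo = FALSE, stringsAsFactors = FALSE)
        } else { # xlinked hemizygous male
          causal_gene <- pick_gene(xl_genes)
          truncating <- runif(1) < 0.5
          v <- sim_variant(state, causal_gene,
                           if (truncating) "frameshift_deletion" else "nonsynonymous",
                           if (truncating) MISSING3 else miss_preds,
                           freq_absent(an))
          add_variant(v)
          add_geno(geno(fam, "P", v$key, "hemizygous"))
          if (has_parents) carry_het(fam, v$key, "M")  # carrier mother
          truth[[fam]] <- data.frame(family_id = fam, declared_model = model,
                                     model = "xlinked", gene = causal_gene,
                                     variant_keys = v$key, de_novo = FALSE,
                                     stringsAsFactors = FALSE)
        }
      }

      # --- decoys: one per feasible rule class --------------------------
      # cascade-removed decoys (common/synonymous/noncoding) may share genes
      # freely; decoys that survive the cascade draw from disjoint genes via
      # pick_gene() so they can never pair up within a family
      # Mendelian closure: a carried allele is threaded down from a founder,
      # so every carrier with in-pedigree parents has a carrying parent
      carry_with_parent <- function(key) {
        if (!has_parents) {
          carry_het(fam, key, "P")
          return(invisible())
        }
        par <- sample(c("F", "M"), 1)
        carriers <- c(par, "P")
        if (template == "threegen" && par == "F") {
          carriers <- c(sample(c("GF", "GM"), 1), carriers)
        }
        carry_het(fam, key, carriers)
      }
      v <- sim_variant(state, sample(autosomal, 1), "nonsynonymous", DAMAGING,
                       freq_common(an))
      add_variant(v); carry_with_parent(v$key); add_decoy(fam, v$key, "frequency_common")
      v <- sim_variant(state, sample(autosomal, 1), "synonymous", MISSING3,
                       freq_rare(an))
      add_variant(v); carry_with_parent(v$key); add_decoy(fam, v$key, "synonymous")
      v <- sim_variant(state, sample(autosomal, 1), "noncoding", MISSING3,
                       freq_rare(an))
      add_variant(v); carry_with_parent(v$key); add_decoy(fam, v$key, "noncoding")
      g <- pick_gene(setdiff(ad_genes, xl_genes))
      if (!is.na(g)) {
        v <- sim_variant(state, g, "nonsynonymous", BENIGN, freq_absent(an))
        add_variant(v); carry_with_parent(v$key)
        add_decoy(fam, v$key, "triple_benign")
      }

      if (has_parents) {
        if (model == "xlinked") {
          # unaffected father hemizygous for the same allele the proband has
          g <- pick_gene(xl_genes)
          if (!is.na(g)) {
            vx <- sim_variant(state, g, "nonsynonymous", DAMAGING, freq_absent(an))
            add_variant(vx)
            add_geno(geno(fam, "P", vx$key, "hemizygous"))
            carry_het(fam, vx$key, "M")
            add_geno(geno(fam, "F", vx$key, "hemizygous"))
            add_decoy(fam, vx$key, "segregation")
          }
        } else if (model == "recessive") {
          # homozygous in the proband AND in the unaffected sibling
          sibs <- sub("^.*_", "", members$sample_id)
          if ("S" %in% sibs) {
            g <- pick_gene(ar_only)
            if (!is.na(g)) {
              vs <- sim_variant(state, g, "nonsynonymous", DAMAGING, freq_absent(an))
              add_variant(vs)
              add_geno(geno(fam, "P", vs$key, "hom_alt"))
              carry_het(fam, vs$key, c("F", "M"))
              add_geno(geno(fam, "S", vs$key, "hom_alt"))
              add_decoy(fam, vs$key, "segregation")
            }
          }
        } else {
          # dominant-acting allele transmitted by an unaffected parent
          g <- pick_gene(setdiff(ad_genes, xl_genes))
          if (!is.na(g)) {
            unaff_parent <- if (model == "sporadic") sample(c("F", "M"), 1) else "M"
            vs <- sim_variant(state, g, "nonsynonymous", DAMAGING, freq_absent(an))
            add_variant(vs)
            carry_het(fam, vs$key, c(unaff_parent, "P"))
            add_decoy(fam, vs$key, "segregation")
          }
        }
        cis_gene <- pick_gene(ar_only)
        if (!is.na(cis_gene)) {
          c1 <- sim_variant(state, cis_gene, "nonsynonymous", DAMAGING, freq_absent(an))
          c2 <- sim_variant(state, cis_gene, "nonsynonymous", DAMAGING, freq_absent(an))
          add_variant(c1); add_variant(c2)
          # both alleles on the paternal haplotype: cis pair (threaded through
          # a grandparent where the father is himself a pedigree child)
          chain <- if (template == "threegen") c(sample(c("GF", "GM"), 1), "F", "P")
                   else c("F", "P")
          carry_het(fam, c1$key, chain)
          carry_het(fam, c2$key, chain)
          add_decoy(fam, c1$key, "cis_pair"); add_decoy(fam, c2$key, "cis_pair")
        }
      }

      # --- background load ----------------------------------------------
      n_bg <- rpois(1, config$background_mean)
      if (n_bg > 0) {
        rules <- sample(c("frequency_common", "synonymous", "noncoding", "triple_benign"),
                        n_bg, replace = TRUE, prob = c(0.5, 0.32, 0.15, 0.03))
        for (r in rules) {
          if (r == "triple_benign") {
            g <- pick_gene(setdiff(ad_genes, xl_genes))
            if (is.na(g)) { r <- "synonymous"; g <- sample(autosomal, 1) }
          } else {
            g <- sample(autosomal, 1)
          }
          v <- switch(r,
            frequency_common = sim_variant(state, g, "nonsynonymous", DAMAGING,
                                           freq_common(an)),
            synonymous = sim_variant(state, g, "synonymous", MISSING3, freq_rare(an)),
            noncoding = sim_variant(state, g, "noncoding", MISSING3, freq_rare(an)),
            triple_benign = sim_variant(state, g, "nonsynonymous", BENIGN,
                                        freq_absent(an)))
          add_variant(v)
          carry_with_parent(v$key)
          add_decoy(fam, v$key, r)
        }
      }
      if (!causal) {
        truth[[fam]] <- data.frame(family_id = fam, declared_model = model,
                                   model = NA_character_, gene = NA_character_,
                                   variant_keys = NA_character_, de_novo = FALSE,
                                   stringsAsFactors = FALSE)
      }
    }
  }

  vcol <- function(nm) unlist(lapply(variants, `[[`, nm), use.names = FALSE)
  vdf <- data.frame(chrom = vcol("chrom"), pos = vcol("pos"), ref = vcol("ref"),
                    alt = vcol("alt"), gene = vcol("gene"),
                    transcript = vcol("transcript"), hgvs_c = vcol("hgvs_c"),
                    hgvs_p = vcol("hgvs_p"), consequence = vcol("consequence"),
                    provean = vcol("provean"), sift = vcol("sift"),
                    polyphen = vcol("polyphen"), quality = vcol("quality"),
                    depth = vcol("depth"), stringsAsFactors = FALSE)
  vdf$frequencies <- lapply(variants, `[[`, "frequencies")
  variants <- as_variant_table(vdf)
  gcol <- function(nm) unlist(lapply(genotypes, `[[`, nm), use.names = FALSE)
  genotypes <- data.frame(family_id = gcol("family_id"), sample_id = gcol("sample_id"),
                          key = gcol("key"), zygosity = gcol("zygosity"),
                          stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  cohort <- new_cohort(families, variants, genotypes)
  manifest <- structure(list(families = do.call(rbind, truth),
                             decoys = do.call(rbind, decoys)),
                        class = "rp_manifest")
  rownames(manifest$families) <- rownames(manifest$decoys) <- NULL
  list(cohort = cohort, manifest = manifest)
}

#' Evaluate pipeline recovery against a truth manifest
#'
#' Unit-level exact matching on (family, gene, model, variant key set).
#' Sensitivity is the fraction of implanted causal units recovered; decoy
#' leaks count emitted units containing any manifest decoy variant,
#' reported per failing-rule class; false discoveries are emitted units
#' matching no implanted unit.
#'
#' @param manifest `rp_manifest` from [simulate_cohort()].
#' @param units Units data.frame from [prioritize_cohort()].
#' @return List: `sensitivity` (`NA` for a cohort with no implanted unit),
#'   `n_implanted`, `n_recovered`, `false_discoveries`, `decoy_leaks`
#'   (total), `leaks_by_rule` (named vector), `missed` (data.frame).
#' @export
evaluate_recovery <- function(manifest, units) {
  stopifnot(inherits(manifest, "rp_manifest"))
  truth <- manifest$families
  if (nrow(units) && length(setdiff(units$family_id, truth$family_id))) {
    stop("units reference families absent from the manifest: cohort mismatch",
         call. = FALSE)
  }
  implanted <- truth[!is.na(truth$model), , drop = FALSE]
  unit_id <- function(df) paste(df$family_id, df$gene, df$model, df$variant_keys)
  got <- if (nrow(units)) unit_id(units) else character()
  want <- unit_id(implanted)
  recovered <- want %in% got
  decoy_keys <- manifest$decoys$key
  leak_rules <- character()
  if (nrow(units)) {
    for (i in seq_len(nrow(units))) {
      ks <- strsplit(units$variant_keys[i], ";", fixed = TRUE)[[1]]
      hit <- manifest$decoys$rule[manifest$decoys$key %in% ks &
                                  manifest$decoys$family_id == units$family_id[i]]
      leak_rules <- c(leak_rules, unique(hit))
    }
  }
  rules <- sort(unique(manifest$decoys$rule))
  leaks_by_rule <- vapply(rules, function(r) sum(leak_rules == r), integer(1))
  list(
    sensitivity = if (nrow(implanted)) mean(recovered) else NA_real_,
    n_implanted = nrow(implanted),
    n_recovered = sum(recovered),
    false_discoveries = sum(!(got %in% want)),
    decoy_leaks = length(leak_rules),
    leaks_by_rule = leaks_by_rule,
    missed = implanted[!recovered, , drop = FALSE]
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the same dialects the readers consume: one PED for the cohort, an
#' annotated VCF with per-sample genotypes, a families TSV carrying the
#' declared models, and the truth manifest as JSON.
#'
#' @param sim List from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- sim$cohort
  ped <- do.call(rbind, lapply(cohort$families, `[[`, "members"))
  rownames(ped) <- NULL
  write_ped(ped, file.path(dir, "cohort.ped"))
  write_annotated_vcf(cohort$variants, cohort$genotypes, ped,
                      file.path(dir, "cohort.vcf"))
  models <- data.frame(
    family_id = vapply(cohort$families, `[[`, character(1), "family_id"),
    declared_model = vapply(cohort$families, `[[`, character(1), "declared_model"),
    stringsAsFactors = FALSE)
  utils::write.table(models, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a truth manifest written by [write_cohort()]
#' @param path `manifest.json` path.
#' @return An `rp_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  fam <- as.data.frame(m$families, stringsAsFactors = FALSE)
  for (col in c("model", "gene", "variant_keys")) {
    if (is.logical(fam[[col]])) fam[[col]] <- as.character(fam[[col]])
    fam[[col]][fam[[col]] %in% c("NA", "")] <- NA_character_
  }
  structure(list(families = fam,
                 decoys = as.data.frame(m$decoys, stringsAsFactors = FALSE)),
            class = "rp_manifest")
}
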