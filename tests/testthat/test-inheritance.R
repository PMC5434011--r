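# Inheritance engine: model matching, compound-het phasing, de novo,
# segregation, X-linked scanning, unit-level predictor rule, digenic flags.

test_that("match_inheritance intersects panel modes with genotype patterns", {
  expect_equal(match_inheritance("dominant", "ad", "het"), "dominant")
  expect_equal(match_inheritance("recessive", "ar", c("het", "het")),
               "recessive_comphet")
  expect_equal(match_inheritance("recessive", c("ad", "ar"), "hom_alt"),
               "recessive_hom")
  # sporadic families are scanned under every model
  expect_setequal(match_inheritance("sporadic", c("ad", "ar"), c("het", "het")),
                  c("dominant", "recessive_comphet"))
  expect_equal(match_inheritance("dominant", character(), "het"), character())
  expect_equal(match_inheritance("xlinked", "xl", "hemizygous"), "xlinked")
})

# two-variant gene table used across the compound-het tests
comphet_vars <- function() {
  v <- rbind(mk_variant(gene = "USH2A", hgvs_c = "c.100A>G"),
             mk_variant(gene = "USH2A", hgvs_c = "c.200C>T"))
  class(v) <- c("rp_variants", "data.frame")
  v
}

test_that("compound-het phasing is correct over all parental carriage patterns", {
  v <- comphet_vars()
  k1 <- v$key[1]; k2 <- v$key[2]
  # independent statement of the rule: each allele's origin is the parent
  # that carries it (both parents called); trans is one-from-each, cis is
  # both-from-one-and-none-from-the-other
  expected_phase <- function(f_set, m_set) {
    o <- function(pf, pm) if (pf && pm) "both" else if (pf) "father"
         else if (pm) "mother" else "neither"
    o1 <- o(k1 %in% f_set, k1 %in% m_set)
    o2 <- o(k2 %in% f_set, k2 %in% m_set)
    if (o1 %in% c("father", "mother") && identical(o1, o2)) return("cis")
    if ((o1 == "father" && o2 == "mother") ||
        (o1 == "mother" && o2 == "father")) return("trans_confirmed")
    "phase_unknown"
  }
  subsets <- list(character(), k1, k2, c(k1, k2))
  fam <- mk_trio("CH")
  for (f_set in subsets) {
    for (m_set in subsets) {
      geno <- rbind(mk_geno("CH", "P", k1, "het"), mk_geno("CH", "P", k2, "het"),
                    if (length(f_set)) mk_geno("CH", rep("F", length(f_set)), f_set, "het"),
                    if (length(m_set)) mk_geno("CH", rep("M", length(m_set)), m_set, "het"))
      got <- scan_compound_het(fam, geno, "USH2A", c(k1, k2), v)
      want <- expected_phase(f_set, m_set)
      lbl <- paste("F:", paste(f_set, collapse = "+"), "M:", paste(m_set, collapse = "+"))
      if (want == "cis") {
        expect_equal(nrow(got), 0, info = lbl)
      } else {
        expect_equal(nrow(got), 1, info = lbl)
        expect_equal(got$phase, want, info = lbl)
        expect_equal(got$variant_keys, paste(sort(c(k1, k2)), collapse = ";"))
      }
    }
  }
})

test_that("a singleton proband with two heterozygotes gets phase_unknown", {
  v <- comphet_vars()
  members <- data.frame(family_id = "S1", sample_id = "S1_P",
                        father_id = NA_character_, mother_id = NA_character_,
                        sex = "female", affected = "affected", sequenced = TRUE,
                        stringsAsFactors = FALSE)
  fam <- new_family("S1", members, "sporadic")
  geno <- mk_geno("S1", c("P", "P"), v$key, c("het", "het"))
  got <- scan_compound_het(fam, geno, "USH2A", v$key, v)
  expect_equal(nrow(got), 1)
  expect_equal(got$phase, "phase_unknown")
})

test_that("an unaffected relative carrying exactly one allele confirms trans", {
  v <- comphet_vars()
  members <- rbind(
    data.frame(family_id = "R1", sample_id = "R1_P", father_id = NA_character_,
               mother_id = NA_character_, sex = "male", affected = "affected",
               sequenced = TRUE, stringsAsFactors = FALSE),
    data.frame(family_id = "R1", sample_id = "R1_B", father_id = NA_character_,
               mother_id = NA_character_, sex = "male", affected = "unaffected",
               sequenced = TRUE, stringsAsFactors = FALSE))
  fam <- new_family("R1", members, "recessive")
  geno <- rbind(mk_geno("R1", c("P", "P"), v$key, c("het", "het")),
                mk_geno("R1", "B", v$key[1], "het"))
  got <- scan_compound_het(fam, geno, "USH2A", v$key, v)
  expect_equal(got$phase, "trans_confirmed")
})

test_that("more than two heterozygotes: trans pairs ranked by truncation", {
  v <- rbind(mk_variant(gene = "USH2A", hgvs_c = "c.1A>G"),
             mk_variant(gene = "USH2A", hgvs_c = "c.2C>T", consequence = "stopgain",
                        provean = "missing", sift = "missing", polyphen = "missing"),
             mk_variant(gene = "USH2A", hgvs_c = "c.3G>A"))
  class(v) <- c("rp_variants", "data.frame")
  fam <- mk_trio("M1")
  geno <- rbind(mk_geno("M1", rep("P", 3), v$key, "het"),
                mk_geno("M1", "F", v$key[1], "het"),
                mk_geno("M1", "M", v$key[2], "het"),
                mk_geno("M1", "M", v$key[3], "het"))
  got <- scan_compound_het(fam, geno, "USH2A", v$key, v)
  # pair (1,2) and (1,3) are trans; (2,3) is cis (both maternal)
  expect_equal(nrow(got), 2)
  expect_false(any(got$variant_keys == paste(sort(v$key[2:3]), collapse = ";")))
  # the pair containing the stopgain ranks first
  expect_true(grepl("c.2C>T", got$variant_keys[1], fixed = TRUE))
  # a variant never pairs with itself and pairs are reported once
  expect_equal(anyDuplicated(got$variant_keys), 0)
})

test_that("de novo requires both parents hom_ref; one carrier refutes", {
  fam <- mk_trio("D1")
  k <- "RP1|c.5764A>G"
  # both parents sequenced, neither carries
  geno <- mk_geno("D1", "P", k, "het")
  expect_equal(detect_de_novo(fam, geno, k), "de_novo")
  # father carries the same allele
  geno2 <- rbind(geno, mk_geno("D1", "F", k, "het"))
  expect_equal(detect_de_novo(fam, geno2, k), "not_de_novo")
  # mother unsequenced: untestable, not false
  fam2 <- mk_trio("D2")
  fam2$members$sequenced[fam2$members$sample_id == "D2_M"] <- FALSE
  geno3 <- mk_geno("D2", "P", k, "het")
  expect_equal(detect_de_novo(fam2, geno3, k), "untestable")
  # ... but a carrying father still refutes even with mother unsequenced
  geno4 <- rbind(geno3, mk_geno("D2", "F", k, "het"))
  expect_equal(detect_de_novo(fam2, geno4, k), "not_de_novo")
})

test_that("de novo calls have no false positives on a noise-free cohort", {
  sim <- simulate_cohort(small_sim_config(seed = 21))
  co <- sim$cohort
  # oracle: direct genotype comparison against the generator's records — a
  # call is truly de novo iff the proband carries the allele and both
  # sequenced parents are explicitly reference
  carries <- function(geno, sample, k) {
    z <- geno$zygosity[geno$sample_id == sample & geno$key == k]
    length(z) && z[1] %in% c("het", "hom_alt", "hemizygous")
  }
  n_checked <- 0
  for (fam in co$families) {
    geno <- co$genotypes[co$genotypes$family_id == fam$family_id, ]
    p <- fam$members$sample_id[fam$members$affected == "affected"][1]
    i <- match(p, fam$members$sample_id)
    f <- fam$members$father_id[i]; m <- fam$members$mother_id[i]
    if (is.na(f) || is.na(m)) next
    carried <- unique(geno$key[geno$sample_id == p & geno$zygosity %in%
                                 c("het", "hom_alt", "hemizygous")])
    for (k in carried) {
      verdict <- detect_de_novo(fam, geno, k, proband_id = p)
      oracle <- !carries(geno, f, k) && !carries(geno, m, k)
      n_checked <- n_checked + 1
      if (verdict == "de_novo") {
        expect_true(oracle, info = paste(fam$family_id, k))
      }
      if (!oracle) expect_false(verdict == "de_novo", info = paste(fam$family_id, k))
    }
  }
  expect_gt(n_checked, 0)
})

test_that("segregation verdicts follow the full-causal-genotype rule", {
  v <- comphet_vars()
  # dominant unit violated by an unaffected carrier sibling
  members <- rbind(mk_trio("S2")$members,
                   data.frame(family_id = "S2", sample_id = "S2_B",
                              father_id = "S2_F", mother_id = "S2_M",
                              sex = "male", affected = "unaffected",
                              sequenced = TRUE, stringsAsFactors = FALSE))
  fam <- new_family("S2", members, "dominant")
  k <- "RHO|c.1040C>T"
  unit <- data.frame(family_id = "S2", gene = "RHO", model = "dominant",
                     variant_keys = k, n_variants = 1, stringsAsFactors = FALSE)
  geno <- rbind(mk_geno("S2", "P", k, "het"), mk_geno("S2", "F", k, "het"),
                mk_geno("S2", "B", k, "het"))
  expect_equal(check_segregation(fam, geno, unit), "violated")
  # same unit without the carrier sibling is consistent
  geno_ok <- rbind(mk_geno("S2", "P", k, "het"), mk_geno("S2", "F", k, "het"))
  fam_dom <- fam
  fam_dom$members$affected[fam_dom$members$sample_id == "S2_F"] <- "affected"
  expect_equal(check_segregation(fam_dom, geno_ok, unit), "consistent")
  # compound het: unaffected mother carrying ONE allele is consistent
  unit2 <- data.frame(family_id = "S2", gene = "USH2A", model = "recessive_comphet",
                      variant_keys = paste(sort(v$key), collapse = ";"),
                      n_variants = 2, stringsAsFactors = FALSE)
  geno2 <- rbind(mk_geno("S2", c("P", "P"), v$key, "het"),
                 mk_geno("S2", "M", v$key[1], "het"),
                 mk_geno("S2", "F", v$key[2], "het"))
  expect_equal(check_segregation(fam, geno2, unit2), "consistent")
  # ... but an unaffected sibling with BOTH alleles violates
  geno3 <- rbind(geno2, mk_geno("S2", c("B", "B"), v$key, "het"))
  expect_equal(check_segregation(fam, geno3, unit2), "violated")
  # recessive hom: unaffected sibling hom_alt violates, het carrier does not
  unit3 <- data.frame(family_id = "S2", gene = "USH2A", model = "recessive_hom",
                      variant_keys = v$key[1], n_variants = 1,
                      stringsAsFactors = FALSE)
  geno4 <- rbind(mk_geno("S2", "P", v$key[1], "hom_alt"),
                 mk_geno("S2", "B", v$key[1], "hom_alt"))
  expect_equal(check_segregation(fam, geno4, unit3), "violated")
  geno5 <- rbind(mk_geno("S2", "P", v$key[1], "hom_alt"),
                 mk_geno("S2", "B", v$key[1], "het"))
  expect_equal(check_segregation(fam, geno5, unit3), "consistent")
  # singleton: untested
  single <- new_family("S3", data.frame(
    family_id = "S3", sample_id = "S3_P", father_id = NA_character_,
    mother_id = NA_character_, sex = "male", affected = "affected",
    sequenced = TRUE, stringsAsFactors = FALSE), "sporadic")
  expect_equal(check_segregation(single, mk_geno("S3", "P", k, "het"),
                                 transform(unit, family_id = "S3")), "untested")
})

test_that("relatives of unknown affection status neither confirm nor violate", {
  fam <- mk_trio("U1", declared = "dominant", father_aff = "affected")
  fam$members$affected[fam$members$sample_id == "U1_M"] <- "unknown"
  k <- "RHO|c.1040C>T"
  unit <- data.frame(family_id = "U1", gene = "RHO", model = "dominant",
                     variant_keys = k, n_variants = 1, stringsAsFactors = FALSE)
  # unknown-status mother carries the allele: not a violation
  geno <- rbind(mk_geno("U1", "P", k, "het"), mk_geno("U1", "F", k, "het"),
                mk_geno("U1", "M", k, "het"))
  expect_equal(check_segregation(fam, geno, unit), "consistent")
})

test_that("X-linked scanning: hemizygous males, homozygous/flagged females", {
  v <- mk_variant(gene = "RPGR", hgvs_c = "c.100G>A", chrom = "X")
  fam_m <- mk_trio("X1", declared = "xlinked", proband_sex = "male")
  got <- scan_xlinked(fam_m, mk_geno("X1", "P", v$key, "hemizygous"),
                      "RPGR", v$key, v)
  expect_equal(nrow(got), 1)
  expect_equal(got$model, "xlinked")
  expect_false(got$low_confidence)
  # a hemizygous call in an unaffected carrier father yields no unit
  # (the proband does not carry it)
  got_none <- scan_xlinked(fam_m, mk_geno("X1", "F", v$key, "hemizygous"),
                           "RPGR", v$key, v)
  expect_equal(nrow(got_none), 0)
  fam_f <- mk_trio("X2", declared = "xlinked", proband_sex = "female")
  got_hom <- scan_xlinked(fam_f, mk_geno("X2", "P", v$key, "hom_alt"),
                          "RPGR", v$key, v)
  expect_false(got_hom$low_confidence)
  got_het <- scan_xlinked(fam_f, mk_geno("X2", "P", v$key, "het"),
                          "RPGR", v$key, v)
  expect_true(got_het$low_confidence)
})

test_that("unit-level predictor rule: one damaging allele rescues its partner", {
  v <- rbind(
    mk_variant(gene = "RBP3", hgvs_c = "c.3635C>T", provean = "Neutral",
               sift = "Tolerated", polyphen = "benign"),
    mk_variant(gene = "RBP3", hgvs_c = "c.2603T>C", provean = "Neutral",
               sift = "Damaging", polyphen = "possibly_damaging"),
    mk_variant(gene = "CRX", hgvs_c = "c.1X>Y", provean = "Neutral",
               sift = "Tolerated", polyphen = "benign"),
    mk_variant(gene = "RBP3", hgvs_c = "c.9X>Y", provean = "Neutral",
               sift = "Tolerated", polyphen = "benign"))
  class(v) <- c("rp_variants", "data.frame")
  units <- data.frame(
    family_id = "F", gene = c("RBP3", "CRX", "RBP3"),
    model = c("recessive_comphet", "dominant", "recessive_comphet"),
    variant_keys = c(paste(sort(v$key[1:2]), collapse = ";"),
                     v$key[3],
                     paste(sort(v$key[c(1, 4)]), collapse = ";")),
    n_variants = c(2, 1, 2), stringsAsFactors = FALSE)
  excl <- unit_predictor_exclusion(units, v)
  expect_equal(excl, c(FALSE, TRUE, TRUE))  # pair kept, benign single and
                                            # all-benign pair excluded
})

test_that("digenic pairs are advisory and cover monoallelic units only", {
  units <- data.frame(
    family_id = c("F1", "F1", "F2", "F3", "F3"),
    gene = c("RDH12", "SNRNP200", "RHO", "USH2A", "CRX"),
    model = c("dominant", "dominant", "dominant", "recessive_comphet", "dominant"),
    variant_keys = c("RDH12|c.121G>T", "SNRNP200|c.6025C>T", "RHO|c.1040C>T",
                     "USH2A|a;USH2A|b", "CRX|c.365G>A"),
    n_variants = c(1, 1, 1, 2, 1), stringsAsFactors = FALSE)
  pairs <- flag_digenic(units)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$family_id, "F1")
  expect_setequal(c(pairs$gene1, pairs$gene2), c("RDH12", "SNRNP200"))
})

test_that("scan_family output is invariant under member and genotype order", {
  sim <- simulate_cohort(small_sim_config(seed = 31))
  co <- sim$cohort
  known <- known_panel()
  pol <- filter_policy()
  retained <- lapply(c(dominant = "dominant", recessive = "recessive",
                       xlinked = "xlinked"),
                     function(m) apply_cascade(co$variants, m, pol)$retained)
  fam <- co$families[[which.max(vapply(co$families, function(f)
    nrow(f$members), integer(1)))]]
  geno <- co$genotypes[co$genotypes$family_id == fam$family_id, ]
  base <- scan_family(fam, geno, retained, known, pol)
  set.seed(99)
  for (r in 1:3) {
    fam2 <- fam
    fam2$members <- fam$members[sample(nrow(fam$members)), ]
    geno2 <- geno[sample(nrow(geno)), ]
    got <- scan_family(fam2, geno2, retained, known, pol)
    o1 <- base[order(base$variant_keys), ]; o2 <- got[order(got$variant_keys), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
  }
})

test_that("emitted units reference only cascade-retained variants", {
  sim <- simulate_cohort(small_sim_config(seed = 41))
  known <- known_panel()
  res <- prioritize_cohort(sim$cohort, known)
  pol <- filter_policy()
  retained_keys <- unique(unlist(lapply(c("dominant", "recessive", "xlinked"),
    function(m) apply_cascade(sim$cohort$variants, m, pol)$retained$key)))
  unit_keys <- unique(unlist(strsplit(res$units$variant_keys, ";", fixed = TRUE)))
  expect_true(all(unit_keys %in% retained_keys))
})
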