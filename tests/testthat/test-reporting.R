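# Novelty, tiering, rescue scan, gene burden, cohort summaries.

test_that("novelty is an exact catalog lookup on (gene, cDNA change)", {
  cat12 <- reported_catalog()
  units <- data.frame(
    family_id = c("A", "B"), gene = c("RHO", "PRPF31"),
    model = "dominant",
    variant_keys = c(variant_key("RHO", "c.1040C>T"),
                     variant_key("PRPF31", "c.1222C>T")),
    n_variants = 1, stringsAsFactors = FALSE)
  got <- classify_novelty(units, cat12)
  expect_equal(got$novelty, c("reported", "novel"))
  all_novel <- classify_novelty(units, empty_catalog())
  expect_equal(all_novel$novelty, c("novel", "novel"))
  # per-variant verdicts align with the key order of a pair
  pair <- data.frame(family_id = "C", gene = "USH2A", model = "recessive_comphet",
                     variant_keys = paste(sort(c(variant_key("USH2A", "c.4957C>T"),
                                                 variant_key("USH2A", "c.1X>Y"))),
                                          collapse = ";"),
                     n_variants = 2, stringsAsFactors = FALSE)
  got2 <- classify_novelty(pair, cat12)
  keys <- strsplit(pair$variant_keys, ";")[[1]]
  verdicts <- strsplit(got2$novelty, ";")[[1]]
  expect_equal(verdicts[keys == "USH2A|c.4957C>T"], "reported")
  expect_equal(verdicts[keys == "USH2A|c.1X>Y"], "novel")
})

test_that("tier assignment prefers the known panel and logs overlaps", {
  units <- data.frame(family_id = "F", gene = c("USH2A", "CYP4V2", "NOVELGENE"),
                      model = "dominant", variant_keys = "x", n_variants = 1,
                      stringsAsFactors = FALSE)
  got <- assign_tier(units, known_panel(), other_panel())
  expect_equal(got$tier, c("known_rp_gene", "other_retinopathy_gene", "unsolved"))
  # a gene on both panels resolves to the known panel, with a message
  both <- other_panel()
  both$entries$USH2A <- "ar"
  expect_message(got2 <- assign_tier(units, known_panel(), both), "USH2A")
  expect_equal(got2$tier[1], "known_rp_gene")
})

test_that("rescue scan keeps the three packaged candidates at the 0.001 ceiling", {
  r <- rescue_scan(rescue_tbl())
  expect_equal(nrow(r), 3)
  expect_true(all(r$tier == "uncertain_candidate"))
  expect_setequal(r$family_id, c("RP-145", "RP-050", "RP-060"))
  # every survivor satisfies the external-reference ceiling from raw counts
  v <- rescue_tbl()
  for (k in r$variant_keys) {
    fr <- v$frequencies[[match(k, v$key)]]
    ext <- fr[setdiff(names(fr), "inhouse")]
    mafs <- vapply(ext, function(f) allele_frequency(f[["ac"]], f[["an"]]), numeric(1))
    expect_lte(max(mafs), 0.001)
  }
})

test_that("tightening the rescue ceiling keeps only reference-absent variants", {
  pol <- filter_policy(maf_rescue = 1e-5, maf_dominant = 0)
  r <- rescue_scan(rescue_tbl(), pol)
  # RDH12 p.Val146Asp (every external AC = 0) survives; RDH12 p.Arg314Trp
  # (ExAC AC 2) does not
  expect_true("RDH12|c.437T>A" %in% r$variant_keys)
  expect_false("RDH12|c.940C>T" %in% r$variant_keys)
})

test_that("rescue scan rejects common in-house variants and non-consensus calls", {
  v <- rbind(
    mk_variant(gene = "PRPF4", hgvs_c = "c.1C>T", family_id = "RP-900",
               model = "sporadic", change = "heterozygous",
               frequencies = list(inhouse = c(ac = 30, an = 4040))),
    mk_variant(gene = "PRPF4", hgvs_c = "c.2C>T", family_id = "RP-901",
               model = "sporadic", change = "heterozygous", sift = "Tolerated"),
    mk_variant(gene = "PRPF4", hgvs_c = "c.3C>T", family_id = "RP-902",
               model = "dominant", change = "heterozygous"))
  class(v) <- c("rp_variants", "data.frame")
  r <- rescue_scan(v)
  expect_equal(nrow(r), 0)   # 30/4040 > 0.005; SIFT Tolerated; not sporadic
  # already-solved families are skipped
  v2 <- mk_variant(gene = "PRPF4", hgvs_c = "c.4C>T", family_id = "RP-903",
                   model = "sporadic", change = "heterozygous")
  expect_equal(nrow(rescue_scan(v2, solved_families = "RP-903")), 0)
  expect_equal(nrow(rescue_scan(v2)), 1)
})

test_that("gene burden scales distinct nonsynonymous counts per 100 samples", {
  panel <- known_panel()
  v <- rbind(mk_variant(gene = "USH2A", hgvs_c = "c.1A>G"),
             mk_variant(gene = "USH2A", hgvs_c = "c.2A>G"),
             mk_variant(gene = "USH2A", hgvs_c = "c.2A>G"),  # duplicate key
             mk_variant(gene = "RHO", hgvs_c = "c.5A>G", consequence = "stopgain",
                        provean = "missing", sift = "missing", polyphen = "missing"))
  class(v) <- c("rp_variants", "data.frame")
  b <- gene_burden(v, panel, n_samples = 50)
  expect_equal(b$per_100_samples[b$gene == "USH2A"], 4.0)
  # truncating variants do not count toward the nonsynonymous burden
  expect_equal(b$n_variants[b$gene == "RHO"], 0)
  expect_true(b$conserved[b$gene == "RHO"])
  expect_false(b$conserved[b$gene == "USH2A"])
  expect_error(gene_burden(v, panel, n_samples = 0))
})

test_that("gene burden recovers implanted counts on a simulated cohort", {
  sim <- simulate_cohort(small_sim_config(seed = 51))
  panel <- known_panel()
  n_samples <- sum(vapply(sim$cohort$families, function(f)
    sum(f$members$sequenced), integer(1)))
  b <- gene_burden(sim$cohort$variants, panel, n_samples)
  v <- sim$cohort$variants
  for (g in panel_genes(panel)) {
    direct <- length(unique(v$key[v$gene == g & v$consequence == "nonsynonymous"]))
    expect_equal(b$n_variants[b$gene == g], direct)
    expect_equal(b$per_100_samples[b$gene == g], 100 * direct / n_samples)
  }
})

test_that("cohort summary reproduces the fixture tallies", {
  res <- prioritize_variant_table(known_mutations_tbl(), known_panel(),
                                  catalog = reported_catalog())
  s <- res$summary
  expect_equal(s$distinct_mutations, 57)
  expect_equal(s$n_families_solved, 40)
  expect_equal(s$distinct_genes, 22)
  expect_equal(s$n_novel, 45)
  expect_equal(s$n_reported, 12)
  expect_equal(s$n_novel + s$n_reported, s$distinct_mutations)
  expect_equal(unname(s$solved_by_model[c("recessive", "sporadic", "xlinked")]),
               c(8, 16, 4))
  expect_equal(sum(s$solved_by_model), s$n_families_solved)
  expect_equal(s$percent_solved, 41)
  # USH2A: six compound-het families, the most frequently mutated gene
  expect_equal(s$per_gene$n_families[s$per_gene$gene == "USH2A"], 6)
  expect_equal(s$per_gene$percent[s$per_gene$gene == "USH2A"], 6)
  expect_equal(s$per_gene$gene[1], "USH2A")
})

test_that("summaries are idempotent and permutation-invariant", {
  res <- prioritize_variant_table(known_mutations_tbl(), known_panel(),
                                  catalog = reported_catalog())
  u <- res$units
  sizes <- c(dominant = 22L, recessive = 19L, sporadic = 52L, xlinked = 5L)
  s1 <- summarize_cohort(u, sizes)
  set.seed(8)
  s2 <- summarize_cohort(u[sample(nrow(u)), ], sizes)
  s1$per_gene <- s1$per_gene[order(s1$per_gene$gene), ]
  s2$per_gene <- s2$per_gene[order(s2$per_gene$gene), ]
  rownames(s1$per_gene) <- rownames(s2$per_gene) <- NULL
  expect_equal(s2, s1)
})

test_that("an empty unit list yields an all-zero summary with totals intact", {
  u <- prioritize_variant_table(known_mutations_tbl(), known_panel())$units[0, ]
  s <- summarize_cohort(u, c(dominant = 22L, recessive = 19L,
                             sporadic = 52L, xlinked = 5L))
  expect_equal(s$n_families_total, 98)
  expect_equal(s$n_families_solved, 0)
  expect_equal(s$distinct_mutations, 0)
  expect_equal(unname(s$solved_by_model), rep(0L, 4))
})

test_that("the other-retinopathy pass reports its own tier tallies", {
  res <- prioritize_variant_table(other_retinopathy_tbl(), other_panel = other_panel())
  tiers <- res$summary$tiers
  row <- tiers[tiers$tier == "other_retinopathy_gene", ]
  expect_equal(row$distinct_mutations, 14)
  expect_equal(row$n_families, 11)
  expect_equal(row$distinct_genes, 8)
  # other-tier units never count as solved known-RP families
  expect_equal(res$summary$n_families_solved, 0)
})
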