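# Novelty classification, gene-panel tiering, the sporadic-heterozygote
# rescue scan, per-gene burden, and cohort-level yield summaries.

TIERS <- c("known_rp_gene", "uncertain_candidate", "other_retinopathy_gene", "unsolved")

#' Classify unit variants as novel or previously reported
#'
#' A variant is `reported` exactly when its (gene, cDNA change) key is in
#' the known-mutation catalog; with an empty catalog everything is novel.
#'
#' @param units Units data.frame.
#' @param catalog `rp_catalog` from [load_catalog()].
#' @return `units` with the `novelty` column filled (per-variant verdicts
#'   joined by `";"` in key order, matching `variant_keys`).
#' @export
classify_novelty <- function(units, catalog = empty_catalog()) {
  if (!nrow(units)) return(units)
  units$novelty <- vapply(strsplit(units$variant_keys, ";", fixed = TRUE), function(ks) {
    paste(ifelse(ks %in% catalog$keys, "reported", "novel"), collapse = ";")
  }, character(1))
  units
}

#' Assign panel tiers to units
#'
#' Genes on the known-RP panel tier as `known_rp_gene`; otherwise genes on
#' the other-retinopathy panel tier as `other_retinopathy_gene`; genes on
#' neither panel contribute to the `unsolved` residue. A gene on both
#' panels tiers as `known_rp_gene` (logged via message). The
#' `uncertain_candidate` tier is reserved for [rescue_scan()] output.
#'
#' @param units Units data.frame.
#' @param known_panel,other_panel `rp_panel` objects (either may be `NULL`).
#' @return `units` with the `tier` column filled.
#' @export
assign_tier <- function(units, known_panel = NULL, other_panel = NULL) {
  if (!nrow(units)) return(units)
  known <- if (is.null(known_panel)) character() else panel_genes(known_panel)
  other <- if (is.null(other_panel)) character() else panel_genes(other_panel)
  both <- intersect(known, other)
  if (length(both) && any(units$gene %in% both)) {
    message("gene(s) on both panels tiered as known_rp_gene: ",
            paste(intersect(unique(units$gene), both), collapse = ", "))
  }
  units$tier <- ifelse(units$gene %in% known, "known_rp_gene",
                ifelse(units$gene %in% other, "other_retinopathy_gene", "unsolved"))
  units
}

#' Rescue scan over unsolved sporadic heterozygotes
#'
#' Second-pass scan rescuing dominant-acting candidates that the strict
#' absent-from-all-references rule would discard: heterozygous missense
#' variants in sporadic families without a solved unit are kept when the
#' in-house control MAF is below the recessive ceiling (0.005), the
#' required predictors (PROVEAN and SIFT by default) call the variant
#' deleterious/damaging, and the maximum MAF over all consulted reference
#' sources is at most `maf_rescue` (0.001). Surviving variants become
#' single-variant units in the `uncertain_candidate` tier.
#'
#' @param variants `rp_variants` with `family_id`, `model`, `change` filled
#'   (heterozygous sporadic rows are eligible).
#' @param policy [filter_policy()].
#' @param solved_families Family ids already carrying a surviving unit;
#'   their variants are not rescued.
#' @return Units data.frame, tier `uncertain_candidate`.
#' @export
rescue_scan <- function(variants, policy = filter_policy(),
                        solved_families = character()) {
  v <- variants[variants$model == "sporadic" &
                variants$change == "heterozygous" &
                variants$consequence == "nonsynonymous" &
                !(variants$family_id %in% solved_families), , drop = FALSE]
  if (!nrow(v)) return(empty_units())
  keep <- vapply(seq_len(nrow(v)), function(i) {
    fr <- v$frequencies[[i]]
    inh <- freq_entry(fr, "inhouse")
    if (allele_frequency(inh[["ac"]], inh[["an"]]) >= policy$maf_recessive) return(FALSE)
    deleterious <- c(
      provean = v$provean[i] == "Deleterious",
      sift = v$sift[i] == "Damaging",
      polyphen = v$polyphen[i] == "probably_damaging"
    )
    if (!all(deleterious[policy$rescue_requires])) return(FALSE)
    # the in-house gate is the scan's own first step; the maf_rescue ceiling
    # applies to the external reference sources looked up afterwards
    ext <- setdiff(policy$frequency_sources, "inhouse")
    max_reference_maf(fr, ext)$maf <= policy$maf_rescue
  }, logical(1))
  v <- v[keep, , drop = FALSE]
  if (!nrow(v)) return(empty_units())
  units <- do.call(rbind, lapply(seq_len(nrow(v)), function(i)
    new_unit(v$family_id[i], v$gene[i], "dominant", v$key[i], v$hgvs_c[i])))
  units$tier <- "uncertain_candidate"
  units
}

#' Per-gene nonsynonymous variant burden
#'
#' Counts distinct nonsynonymous variants per panel gene, scaled to
#' variants per 100 samples, and flags genes at or below a conservation
#' cutoff (genes in which almost no missense variation is tolerated).
#'
#' @param variants `rp_variants` (a cohort's observed variants).
#' @param panel `rp_panel` whose genes are tallied.
#' @param n_samples Number of samples the variants were observed in (> 0).
#' @param conserved_cutoff Per-100-sample level at or below which a gene is
#'   flagged conserved (default 0.15).
#' @return data.frame `gene`, `n_variants`, `per_100_samples`, `conserved`.
#' @export
gene_burden <- function(variants, panel, n_samples, conserved_cutoff = 0.15) {
  stopifnot(n_samples > 0)
  nonsyn <- variants[variants$consequence == "nonsynonymous", , drop = FALSE]
  genes <- panel_genes(panel)
  n <- vapply(genes, function(g) length(unique(nonsyn$key[nonsyn$gene == g])), integer(1))
  per100 <- 100 * n / n_samples
  data.frame(gene = genes, n_variants = unname(n),
             per_100_samples = unname(per100),
             conserved = unname(per100 <= conserved_cutoff),
             stringsAsFactors = FALSE)
}

#' Summarize a prioritized cohort
#'
#' Tallies the diagnostic yield: families are `solved` when they carry at
#' least one surviving known-RP-panel unit; distinct mutations are keyed by
#' (gene, cDNA change) so a mutation shared by two families counts once;
#' novelty totals partition the distinct mutations. Per-gene family counts
#' and cohort proportions are computed for known-panel genes; per-tier
#' tallies cover every tier present.
#'
#' @param units Units data.frame with `declared_model`, `novelty`, `tier`
#'   filled.
#' @param cohort_sizes Named integer vector of recruited families per
#'   declared model (e.g. `c(dominant = 22, recessive = 19, sporadic = 52,
#'   xlinked = 5)`); proportions are over the sum.
#' @return An `rp_summary` list: `n_families_total` (+ `families_by_model`),
#'   `n_families_solved` (+ `solved_by_model`), `distinct_mutations`,
#'   `distinct_genes`, `n_novel`, `n_reported` (known tier), `per_gene`
#'   data.frame, `tiers` data.frame, `digenic` data.frame.
#' @export
summarize_cohort <- function(units, cohort_sizes) {
  stopifnot(all(names(cohort_sizes) %in% INHERITANCE_MODELS))
  total <- sum(cohort_sizes)

  unit_key_df <- function(u) {
    if (!nrow(u)) return(data.frame(key = character(), novelty = character(),
                                    gene = character(), stringsAsFactors = FALSE))
    ks <- strsplit(u$variant_keys, ";", fixed = TRUE)
    nv <- strsplit(u$novelty, ";", fixed = TRUE)
    df <- data.frame(key = unlist(ks), novelty = unlist(nv),
                     gene = rep(u$gene, lengths(ks)), stringsAsFactors = FALSE)
    df[!duplicated(df$key), , drop = FALSE]
  }

  tier_stats <- function(u) {
    kd <- unit_key_df(u)
    list(n_units = nrow(u),
         n_families = length(unique(u$family_id)),
         distinct_mutations = nrow(kd),
         distinct_genes = length(unique(u$gene)),
         n_novel = sum(kd$novelty == "novel"),
         n_reported = sum(kd$novelty == "reported"))
  }

  tiers_present <- intersect(TIERS, unique(units$tier))
  tiers <- do.call(rbind, lapply(tiers_present, function(tr) {
    s <- tier_stats(units[units$tier == tr, , drop = FALSE])
    data.frame(tier = tr, s, stringsAsFactors = FALSE)
  }))
  if (is.null(tiers)) {
    tiers <- data.frame(tier = character(), n_units = integer(), n_families = integer(),
                        distinct_mutations = integer(), distinct_genes = integer(),
                        n_novel = integer(), n_reported = integer(),
                        stringsAsFactors = FALSE)
  }

  known <- units[units$tier == "known_rp_gene", , drop = FALSE]
  ks <- tier_stats(known)
  solved_by_model <- vapply(names(cohort_sizes), function(m)
    length(unique(known$family_id[known$declared_model == m])), integer(1))

  per_gene <- if (nrow(known)) {
    fam_gene <- unique(known[, c("family_id", "gene")])
    cnt <- table(fam_gene$gene)
    data.frame(gene = names(cnt), n_families = as.integer(cnt),
               proportion = as.integer(cnt) / total,
               percent = round(100 * as.integer(cnt) / total),
               stringsAsFactors = FALSE)[order(-as.integer(cnt), names(cnt)), ]
  } else {
    data.frame(gene = character(), n_families = integer(), proportion = numeric(),
               percent = numeric(), stringsAsFactors = FALSE)
  }
  rownames(per_gene) <- NULL

  structure(list(
    n_families_total = total,
    families_by_model = cohort_sizes,
    n_families_solved = ks$n_families,
    solved_by_model = solved_by_model,
    percent_solved = round(100 * ks$n_families / total),
    distinct_mutations = ks$distinct_mutations,
    distinct_genes = ks$distinct_genes,
    n_novel = ks$n_novel,
    n_reported = ks$n_reported,
    per_gene = per_gene,
    tiers = tiers
  ), class = "rp_summary")
}

#' @export
print.rp_summary <- function(x, ...) {
  cat("<rp_summary>\n",
      "  families: ", x$n_families_solved, "/", x$n_families_total,
      " solved (", x$percent_solved, "%)\n",
      "  distinct mutations (known RP genes): ", x$distinct_mutations,
      " in ", x$distinct_genes, " genes (",
      x$n_novel, " novel + ", x$n_reported, " reported)\n",
      "  solved by model: ",
      paste(names(x$solved_by_model), x$solved_by_model, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a cohort summary as JSON
#' @param summary `rp_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  out <- unclass(summary)
  out$families_by_model <- as.list(out$families_by_model)
  out$solved_by_model <- as.list(out$solved_by_model)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write units as a per-family TSV report
#' @param units Units data.frame (pair alleles joined by `";"`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_units_tsv <- function(units, path) {
  utils::write.table(units, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene mutation-proportion plot
#'
#' Bar chart of the proportion of cohort families carrying units in each
#' known-RP gene, with aggregate bars for the uncertain, other-retinopathy
#' and unsolved categories. Requires ggplot2.
#'
#' @param summary `rp_summary`.
#' @param path Optional output image path; when `NULL` the ggplot object is
#'   returned.
#' @return ggplot object (invisibly when written to `path`).
#' @export
plot_gene_proportions <- function(summary, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_gene_proportions requires ggplot2", call. = FALSE)
  }
  pg <- summary$per_gene
  total <- summary$n_families_total
  other <- summary$tiers
  extra <- data.frame(
    gene = c("uncertain", "other retinal", "unsolved"),
    n_families = c(
      if ("uncertain_candidate" %in% other$tier) other$n_families[other$tier == "uncertain_candidate"] else 0L,
      if ("other_retinopathy_gene" %in% other$tier) other$n_families[other$tier == "other_retinopathy_gene"] else 0L,
      max(0L, total - summary$n_families_solved)
    ), stringsAsFactors = FALSE)
  extra$proportion <- extra$n_families / total
  extra$percent <- round(100 * extra$proportion)
  df <- rbind(pg[, names(extra)], extra)
  df$gene <- factor(df$gene, levels = df$gene)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of families") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 4)
    return(invisible(p))
  }
  p
}
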