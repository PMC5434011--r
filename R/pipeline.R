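# End-to-end prioritization: filter cascade -> inheritance engine ->
# novelty/tiering -> cohort summary. Two entry modes share the downstream
# path: a flat annotated table whose genotype-configuration keywords stand
# in for per-sample calls (the dialect published mutation tables are
# packaged in), and a genotyped cohort (VCF/PED or simulator output).

# study cohort composition: recruited families per declared class
STUDY_COHORT_SIZES <- c(dominant = 22L, recessive = 19L, sporadic = 52L, xlinked = 5L)

# cascade model used for a genotype-configuration keyword
change_scan_model <- function(change) {
  c(heterozygous = "dominant", homozygous = "recessive",
    compound_heterozygous = "recessive", hemizygote = "xlinked")[change]
}

#' Build candidate units from a genotype-configuration table
#'
#' Fixture-mode inheritance matching: rows grouped by (family, gene,
#' configuration) become units when the panel's modes for the gene permit
#' the configuration — heterozygous rows need a dominant-capable gene,
#' homozygous rows a recessive-capable one (X-linked capable as fallback,
#' covering homozygous females), hemizygote rows an X-linked gene, and
#' compound-heterozygous rows a recessive-capable gene with exactly two
#' rows in the group (phase `phase_unknown`: the flat table carries no
#' parental calls). Rows in genes absent from the panel yield no unit.
#'
#' @param variants Retained `rp_variants` with `family_id`, `change` filled.
#' @param panel `rp_panel` giving permitted modes per gene.
#' @return Units data.frame with `declared_model` carried over.
#' @export
build_units_from_table <- function(variants, panel) {
  units <- list()
  grp <- unique(variants[, c("family_id", "gene", "change")])
  for (i in seq_len(nrow(grp))) {
    rows <- variants[variants$family_id == grp$family_id[i] &
                     variants$gene == grp$gene[i] &
                     variants$change == grp$change[i], , drop = FALSE]
    modes <- panel_modes(panel, grp$gene[i])
    if (!length(modes)) next
    cfg <- grp$change[i]
    u <- NULL
    if (cfg == "compound_heterozygous") {
      if (nrow(rows) != 2) {
        warning("family ", grp$family_id[i], ", gene ", grp$gene[i],
                ": compound-heterozygous group with ", nrow(rows),
                " row(s); expected 2 - skipped")
        next
      }
      if ("ar" %in% modes) {
        u <- new_unit(grp$family_id[i], grp$gene[i], "recessive_comphet",
                      rows$key, rows$hgvs_c, phase = "phase_unknown")
      }
    } else if (cfg == "homozygous") {
      if ("ar" %in% modes) {
        u <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j)
          new_unit(grp$family_id[i], grp$gene[i], "recessive_hom",
                   rows$key[j], rows$hgvs_c[j])))
      } else if ("xl" %in% modes) {
        u <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j)
          new_unit(grp$family_id[i], grp$gene[i], "xlinked",
                   rows$key[j], rows$hgvs_c[j])))
      }
    } else if (cfg == "heterozygous") {
      if ("ad" %in% modes) {
        u <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j)
          new_unit(grp$family_id[i], grp$gene[i], "dominant",
                   rows$key[j], rows$hgvs_c[j])))
      }
    } else if (cfg == "hemizygote") {
      if ("xl" %in% modes) {
        u <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j)
          new_unit(grp$family_id[i], grp$gene[i], "xlinked",
                   rows$key[j], rows$hgvs_c[j])))
      }
    }
    if (!is.null(u)) {
      u$declared_model <- rows$model[1]
      units[[length(units) + 1L]] <- u
    }
  }
  if (!length(units)) {
    u <- empty_units(); u$declared_model <- character(); return(u)
  }
  out <- do.call(rbind, units)
  rownames(out) <- NULL
  out
}

#' Prioritize an annotated variant table
#'
#' Full fixture-mode pipeline: per-row filter cascade (under the cascade
#' model implied by each row's genotype configuration), unit construction
#' against the panel(s), unit-level predictor exclusion, novelty
#' classification, tier assignment, digenic flagging, and the cohort
#' summary.
#'
#' @param variants `rp_variants` from [read_variant_table()].
#' @param known_panel,other_panel `rp_panel` objects (either may be
#'   `NULL`; unit construction uses the union of both).
#' @param catalog `rp_catalog` for novelty (default: empty, everything
#'   novel).
#' @param policy [filter_policy()].
#' @param cohort_sizes Families recruited per declared model; defaults to
#'   the 98-family study composition (22/19/52/5).
#' @return List: `units`, `summary` ([summarize_cohort()]), `trace`,
#'   `digenic`, `excluded` (units removed by the predictor rule).
#' @export
prioritize_variant_table <- function(variants, known_panel = NULL,
                                     other_panel = NULL,
                                     catalog = empty_catalog(),
                                     policy = filter_policy(),
                                     cohort_sizes = STUDY_COHORT_SIZES) {
  stopifnot(inherits(variants, "rp_variants"))
  if (is.null(known_panel) && is.null(other_panel)) {
    stop("at least one gene panel is required", call. = FALSE)
  }
  combined <- combine_panels(known_panel, other_panel)

  # cascade per scan model; rows are routed by genotype configuration
  traces <- list(); retained <- list()
  for (m in c("dominant", "recessive", "xlinked")) {
    rows <- variants[change_scan_model(variants$change) == m, , drop = FALSE]
    res <- apply_cascade(rows, m, policy, predictor_step = FALSE)
    traces[[m]] <- res$trace
    retained[[m]] <- res$retained
  }
  retained_all <- do.call(rbind, retained)
  trace <- do.call(rbind, traces)
  rownames(trace) <- NULL

  units <- build_units_from_table(retained_all, combined)
  excl <- unit_predictor_exclusion(units, retained_all)
  excluded <- units[excl, , drop = FALSE]
  units <- units[!excl, , drop = FALSE]

  units <- classify_novelty(units, catalog)
  units <- assign_tier(units, known_panel, other_panel)
  digenic <- flag_digenic(units)

  summary <- summarize_cohort(units, cohort_sizes)
  list(units = units, summary = summary, trace = trace,
       digenic = digenic, excluded = excluded)
}

combine_panels <- function(known, other) {
  entries <- list()
  for (p in list(known, other)) {
    if (is.null(p)) next
    for (g in names(p$entries)) {
      entries[[g]] <- unique(c(entries[[g]], p$entries[[g]]))
    }
  }
  if (!length(entries)) stop("no panel entries", call. = FALSE)
  structure(list(name = "combined", entries = entries), class = "rp_panel")
}

#' Prioritize a genotyped cohort
#'
#' Genotype-mode pipeline over an `rp_cohort`: runs the filter cascade per
#' scan model on the cohort variant table, then the inheritance engine per
#' family ([scan_family()]: dominant with de novo annotation, recessive
#' homozygote and compound-heterozygote, X-linked; unit-level predictor
#' exclusion; segregation filtering), then novelty, tiering and summary.
#'
#' @param cohort `rp_cohort` from [new_cohort()] or [simulate_cohort()].
#' @param known_panel,other_panel `rp_panel` objects.
#' @param catalog `rp_catalog` for novelty.
#' @param policy [filter_policy()].
#' @return List: `units`, `summary`, `trace`, `digenic`.
#' @export
prioritize_cohort <- function(cohort, known_panel, other_panel = NULL,
                              catalog = empty_catalog(),
                              policy = filter_policy()) {
  retained <- list(); traces <- list()
  for (m in c("dominant", "recessive", "xlinked")) {
    res <- apply_cascade(cohort$variants, m, policy, predictor_step = FALSE)
    retained[[m]] <- res$retained
    traces[[m]] <- res$trace
  }
  combined <- combine_panels(known_panel, other_panel)

  units <- list()
  for (family in cohort$families) {
    geno <- cohort$genotypes[cohort$genotypes$family_id == family$family_id, , drop = FALSE]
    # restrict each model's retained set to variants seen in this family
    fam_keys <- unique(geno$key[carries_alt(geno$zygosity)])
    fam_retained <- lapply(retained, function(v) v[v$key %in% fam_keys, , drop = FALSE])
    u <- scan_family(family, geno, fam_retained, combined, policy)
    if (nrow(u)) {
      u$declared_model <- family$declared_model
      units[[length(units) + 1L]] <- u
    }
  }
  units <- if (length(units)) do.call(rbind, units) else {
    u <- empty_units(); u$declared_model <- character(); u
  }
  rownames(units) <- NULL

  units <- classify_novelty(units, catalog)
  units <- assign_tier(units, known_panel, other_panel)
  digenic <- flag_digenic(units)

  models <- vapply(cohort$families, `[[`, character(1), "declared_model")
  cohort_sizes <- vapply(INHERITANCE_MODELS, function(m) sum(models == m), integer(1))
  summary <- summarize_cohort(units, cohort_sizes)

  trace <- do.call(rbind, lapply(names(traces), function(m) {
    t <- traces[[m]]; if (nrow(t)) t$model <- m else t$model <- character(); t
  }))
  list(units = units, summary = summary, trace = trace, digenic = digenic)
}
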