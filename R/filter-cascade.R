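# The staged variant-level filter: call QC, model-dependent reference
# allele-frequency thresholds, consequence class, and the missense
# predictor-consensus rule. Steps are evaluated in a fixed order with
# short-circuit at the first failure; the trace records the decision.

#' Filter policy
#'
#' Bundles every threshold of the cascade. Defaults follow the published
#' procedure: phred quality strictly greater than 30, read depth of at
#' least 5, reference MAF at most 0.005 under the recessive model and 0
#' (absent from every consulted source) under the dominant model, a 0.001
#' ceiling for the sporadic-heterozygote rescue scan, and an optional
#' excluded-region interval set (BED semantics, 0-based half-open) for
#' regions with homologous sequence such as the MHC.
#'
#' @param min_quality Phred call-quality threshold (strict `>`). Default 30.
#' @param min_depth Minimum read depth (`>=`). Default 5.
#' @param maf_recessive Reference-MAF ceiling for recessive/X-linked models.
#' @param maf_dominant Reference-MAF ceiling for the dominant model; the
#'   default 0 encodes "any observed frequency excludes".
#' @param maf_rescue Ceiling for the rescue scan over unsolved sporadic
#'   heterozygotes.
#' @param frequency_sources Ordered character vector of reference source
#'   names consulted by the run.
#' @param excluded_regions `NULL`, or a data.frame `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param rescue_requires Character vector of predictors that must call a
#'   rescue candidate deleterious (default PROVEAN and SIFT).
#' @return An `rp_filter_policy` list.
#' @export
filter_policy <- function(min_quality = 30, min_depth = 5,
                          maf_recessive = 0.005, maf_dominant = 0,
                          maf_rescue = 0.001,
                          frequency_sources = c("inhouse", "1kg", "exac", "dbsnp135_common"),
                          excluded_regions = NULL,
                          rescue_requires = c("provean", "sift")) {
  stopifnot(min_depth >= 1,
            maf_dominant >= 0, maf_dominant <= maf_rescue,
            maf_rescue <= maf_recessive, maf_recessive <= 1)
  structure(list(min_quality = min_quality, min_depth = min_depth,
                 maf_recessive = maf_recessive, maf_dominant = maf_dominant,
                 maf_rescue = maf_rescue, frequency_sources = frequency_sources,
                 excluded_regions = excluded_regions,
                 rescue_requires = rescue_requires),
            class = "rp_filter_policy")
}

#' Read a filter policy from a YAML config file
#'
#' Keys mirror the arguments of [filter_policy()]; absent keys keep their
#' defaults. `excluded_regions` may name a BED file (0-based half-open).
#'
#' @param path YAML file.
#' @return An `rp_filter_policy`.
#' @export
read_policy <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$excluded_regions) && is.character(cfg$excluded_regions)) {
    cfg$excluded_regions <- read_bed(cfg$excluded_regions)
  }
  do.call(filter_policy, cfg)
}

#' Read a BED interval file (0-based half-open)
#' @param path BED path (first three columns used).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
             stringsAsFactors = FALSE)
}

#' Allele frequency from an allele count / allele number pair
#'
#' Zero allele number (the source never observed the site) is defined as
#' frequency 0: no observations is not evidence of commonness.
#'
#' @param allele_count Non-negative count of alternate alleles.
#' @param allele_number Non-negative total allele count.
#' @return `allele_count / allele_number`, or 0 when `allele_number` is 0.
#' @examples
#' allele_frequency(4, 8640)
#' allele_frequency(0, 0)
#' @export
allele_frequency <- function(allele_count, allele_number) {
  stopifnot(allele_count >= 0, allele_number >= 0)
  if (any(allele_count > allele_number)) {
    stop("allele_count exceeds allele_number", call. = FALSE)
  }
  ifelse(allele_number == 0, 0, allele_count / allele_number)
}

#' Maximum reference allele frequency across consulted sources
#'
#' A variant absent from a source contributes frequency 0 from that source.
#'
#' @param frequencies Named list source -> `c(ac=, an=)` (one variant's
#'   frequency map).
#' @param sources Source names to consult.
#' @return List with `maf` (numeric) and `source` (attaining source name,
#'   or `NA` when the maximum is 0 because nothing was observed).
#' @export
max_reference_maf <- function(frequencies, sources) {
  best <- 0; best_src <- NA_character_
  for (s in sources) {
    f <- freq_entry(frequencies, s)
    maf <- allele_frequency(f[["ac"]], f[["an"]])
    if (maf > best) { best <- maf; best_src <- s }
  }
  list(maf = best, source = best_src)
}

in_excluded_region <- function(chrom, pos, regions) {
  if (is.null(regions) || is.na(pos)) return(FALSE)
  any(regions$chrom == chrom & pos - 1 >= regions$start & pos - 1 < regions$end)
}

#' Call-level quality control
#'
#' Passes calls with quality strictly above the threshold, depth at least
#' the minimum, and position outside the excluded regions. Records lacking
#' quality or depth (flat fixture tables carry neither) pass QC.
#'
#' @param variant One-row `rp_variants` slice (or list with `quality`,
#'   `depth`, `chrom`, `pos`).
#' @param policy [filter_policy()].
#' @return Logical.
#' @export
qc_pass <- function(variant, policy) {
  q_ok <- is.na(variant$quality) | variant$quality > policy$min_quality
  d_ok <- is.na(variant$depth) | variant$depth >= policy$min_depth
  r_ok <- !in_excluded_region(variant$chrom, variant$pos, policy$excluded_regions)
  isTRUE(q_ok && d_ok && r_ok)
}

#' Model-dependent reference-frequency filter
#'
#' Dominant-model candidates must be absent from every consulted reference
#' source (threshold `maf_dominant = 0`); recessive-model candidates may
#' reach `maf_recessive`. The X-linked model uses the recessive threshold
#' (carrier females appear in population references).
#'
#' @param variant One-row variant (needs `frequencies`).
#' @param model `"dominant"`, `"recessive"` or `"xlinked"`.
#' @param policy [filter_policy()].
#' @return Logical.
#' @export
frequency_pass <- function(variant, model, policy) {
  if (!model %in% c("dominant", "recessive", "xlinked")) {
    stop("unknown inheritance model: ", model, call. = FALSE)
  }
  threshold <- if (model == "dominant") policy$maf_dominant else policy$maf_recessive
  fr <- variant$frequencies
  if (is.data.frame(variant)) fr <- fr[[1]]
  max_reference_maf(fr, policy$frequency_sources)$maf <= threshold
}

#' Consequence-class filter
#'
#' Removes non-coding and synonymous variants unless the record alters a
#' splice site; every other consequence class passes.
#'
#' @param variant One-row variant (needs `consequence`).
#' @return Logical.
#' @export
consequence_pass <- function(variant) {
  !(variant$consequence %in% c("noncoding", "synonymous")) ||
    variant$consequence %in% SPLICE_CONSEQUENCES
}

#' Unanimous-benign predictor verdict
#'
#' `TRUE` only when PROVEAN says Neutral, SIFT says Tolerated and
#' PolyPhen-2 says benign simultaneously. Any missing verdict returns
#' `FALSE`: unanimity cannot be asserted, and truncating/splicing records
#' (annotated NA across all three tools) must never be predictor-excluded.
#'
#' @param provean,sift,polyphen Normalized verdict vectors.
#' @return Logical vector.
#' @export
triple_benign <- function(provean, sift, polyphen) {
  provean == "Neutral" & sift == "Tolerated" & polyphen == "benign"
}

CASCADE_STEPS <- c("qc", "frequency", "consequence", "predictor")

#' Apply the staged filter cascade
#'
#' Runs QC, the model-dependent frequency filter and the consequence filter
#' over a variant table, short-circuiting at the first failing step; the
#' trace records one row per variant with the step outcomes. The
#' unanimous-benign missense exclusion is applied here only when
#' `predictor_step = TRUE` (single-variant contexts); multi-variant
#' candidate units apply it at unit level ([unit_predictor_exclusion()]),
#' because one damaging allele rescues its partner.
#'
#' @param variants `rp_variants` table.
#' @param model `"dominant"`, `"recessive"` or `"xlinked"` (per family).
#' @param policy [filter_policy()].
#' @param predictor_step Apply the per-variant unanimous-benign exclusion
#'   (default `FALSE`; the inheritance engine owns the unit-level rule).
#' @return List with `retained` (filtered `rp_variants`) and `trace`
#'   (data.frame `key`, `family_id`, `step`, `pass`, `reason`, one row per
#'   variant giving the first failing step, or the final pass).
#' @export
apply_cascade <- function(variants, model, policy = filter_policy(),
                          predictor_step = FALSE) {
  n <- nrow(variants)
  if (!n) {
    trace <- data.frame(key = character(), family_id = character(),
                        step = character(), pass = logical(),
                        reason = character(), stringsAsFactors = FALSE)
    return(list(retained = variants, trace = trace))
  }
  if (!model %in% c("dominant", "recessive", "xlinked")) {
    stop("unknown inheritance model: ", model, call. = FALSE)
  }
  # vectorized evaluation of every step, then short-circuit bookkeeping
  q_ok <- (is.na(variants$quality) | variants$quality > policy$min_quality) &
          (is.na(variants$depth) | variants$depth >= policy$min_depth) &
          !vapply(seq_len(n), function(i)
            in_excluded_region(variants$chrom[i], variants$pos[i],
                               policy$excluded_regions), logical(1))
  threshold <- if (model == "dominant") policy$maf_dominant else policy$maf_recessive
  mafs <- vapply(variants$frequencies, function(fr)
    max_reference_maf(fr, policy$frequency_sources)$maf, numeric(1))
  f_ok <- mafs <= threshold
  c_ok <- !(variants$consequence %in% c("noncoding", "synonymous")) |
          variants$consequence %in% SPLICE_CONSEQUENCES
  p_ok <- !(predictor_step & variants$consequence == "nonsynonymous" &
            triple_benign(variants$provean, variants$sift, variants$polyphen))

  step <- rep("retained", n); reason <- rep("", n)
  pass <- q_ok & f_ok & c_ok & p_ok
  hit <- !p_ok
  step[hit] <- "predictor"
  reason[hit] <- "unanimously benign by PROVEAN, SIFT and PolyPhen-2"
  hit <- !c_ok
  step[hit] <- "consequence"
  reason[hit] <- paste0(variants$consequence[hit], " without splice-site effect")
  hit <- !f_ok
  step[hit] <- "frequency"
  reason[hit] <- sprintf("reference MAF %.3g exceeds %s-model threshold",
                         mafs[hit], model)
  hit <- !q_ok
  step[hit] <- "qc"
  reason[hit] <- "failed call QC (quality/depth/excluded region)"
  trace <- data.frame(key = variants$key,
                      family_id = variants$family_id,
                      step = step, pass = pass, reason = reason,
                      stringsAsFactors = FALSE)
  list(retained = variants[pass, , drop = FALSE], trace = trace)
}

#' Export a filter trace
#' @param trace Trace data.frame from [apply_cascade()].
#' @param path Output path ending in `.tsv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(trace, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
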