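# Annotated VCF ingestion (through vcfR) and the simple VCF writer the
# simulator uses. The VCF route and the flat-table route must yield the same
# (family, variant, zygosity) triples for the same cohort.

#' Default VCF annotation key map
#'
#' Maps the fields a variant record needs onto INFO keys. Frequency sources
#' are carried as paired `<SOURCE>_AC` / `<SOURCE>_AN` INFO keys.
#'
#' @return Named character vector INFO-key map.
#' @export
default_vcf_key_map <- function() {
  c(gene = "GENE", transcript = "TRANSCRIPT", hgvs_c = "HGVSC", hgvs_p = "HGVSP",
    consequence = "CSQCLASS", provean = "PROVEAN", sift = "SIFT",
    polyphen = "POLYPHEN", depth = "DP")
}

is_x_chrom <- function(chrom) toupper(sub("^chr", "", chrom)) == "X"

# parsimony trimming of a ref/alt pair (suffix first, then prefix);
# reference-free stand-in for full left-normalization
trim_allele_pair <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# scalar INFO extraction
info_value <- function(info, key) {
  vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    hit <- kv[startsWith(kv, paste0(key, "="))]
    if (!length(hit)) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
  }, character(1))
}

# j-th comma-separated element (per-ALT annotations), or the scalar value
nth_or_scalar <- function(x, j) {
  parts <- strsplit(x, ",", fixed = TRUE)
  vapply(seq_along(x), function(i) {
    p <- parts[[i]]
    if (is.na(x[i])) NA_character_ else if (length(p) >= j) p[j] else p[1]
  }, character(1))
}

#' Read an annotated VCF into variant and genotype tables
#'
#' Reads a VCF 4.x with per-sample GT fields and INFO annotations carrying
#' gene, consequence class, HGVS strings, predictor verdicts and per-source
#' allele counts under configurable keys. Multi-allelic records are split
#' into one record per ALT (with parsimony trimming of the allele pair);
#' zygosity is derived per sample from GT. Haploid calls are `hemizygous`;
#' a diploid heterozygous call on X in a male is coerced to `missing` with
#' a warning (pseudoautosomal regions are not modeled). Malformed GT fields
#' become `missing` with a warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @param ped Pedigree data.frame ([read_ped()]); supplies family and sex
#'   per sample. Samples absent from the pedigree are dropped with a warning.
#' @param key_map INFO key map, see [default_vcf_key_map()]. `gene`,
#'   `hgvs_c` and `consequence` are mandatory; a missing mandatory key is an
#'   error naming the key.
#' @param freq_sources Character vector of frequency source names; source
#'   `s` is read from INFO keys `toupper(s)_AC` and `toupper(s)_AN`.
#' @param sparse Omit explicit `hom_ref` rows from the genotype table
#'   (default `TRUE`; the pipeline treats an absent call of a sequenced
#'   sample as `hom_ref`). Set `FALSE` to materialize every call.
#' @return List with `variants` (cohort-level `rp_variants`, one row per
#'   distinct alt allele) and `genotypes` (data.frame `family_id`,
#'   `sample_id`, `key`, `zygosity`).
#' @export
read_annotated_vcf <- function(path, ped, key_map = default_vcf_key_map(),
                               freq_sources = character(), sparse = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (!n_rec) stop("VCF contains no records", call. = FALSE)
  info <- unname(fix[, "INFO", drop = TRUE])

  ann <- lapply(key_map, function(k) info_value(info, k))
  for (mand in c("gene", "hgvs_c", "consequence")) {
    if (all(is.na(ann[[mand]]))) {
      stop("mandatory annotation key absent from VCF INFO: ", key_map[[mand]],
           call. = FALSE)
    }
  }
  freq_ac <- lapply(freq_sources, function(s)
    info_value(info, paste0(toupper(s), "_AC")))
  freq_an <- lapply(freq_sources, function(s)
    suppressWarnings(as.numeric(info_value(info, paste0(toupper(s), "_AN")))))
  names(freq_ac) <- names(freq_an) <- freq_sources

  # expand multi-allelic records: one row per ALT allele
  alts_list <- strsplit(unname(fix[, "ALT"]), ",", fixed = TRUE)
  n_alts <- lengths(alts_list)
  ri <- rep.int(seq_len(n_rec), n_alts)   # source record per expanded row
  aj <- sequence(n_alts)                  # ALT index per expanded row
  n_exp <- length(ri)

  pick <- function(x) {
    out <- nth_or_scalar(x[ri], 1L)
    multi <- aj > 1L
    if (any(multi)) out[multi] <- vapply(which(multi), function(e)
      nth_or_scalar(x[ri[e]], aj[e]), character(1))
    out
  }
  trimmed <- lapply(seq_len(n_exp), function(e)
    trim_allele_pair(as.integer(fix[ri[e], "POS"]), fix[ri[e], "REF"],
                     alts_list[[ri[e]]][aj[e]]))
  cons_raw <- pick(ann$consequence)
  cons <- unname(CONSEQUENCE_TOKENS[tolower(cons_raw)])
  if (anyNA(cons)) {
    stop("unknown consequence token in VCF record ", ri[which(is.na(cons))[1]],
         call. = FALSE)
  }
  ts <- pick(ann$transcript); hp <- pick(ann$hgvs_p)
  vdf <- data.frame(
    chrom = fix[ri, "CHROM"],
    pos = vapply(trimmed, `[[`, numeric(1), "pos"),
    ref = vapply(trimmed, `[[`, character(1), "ref"),
    alt = vapply(trimmed, `[[`, character(1), "alt"),
    gene = pick(ann$gene),
    transcript = ifelse(is.na(ts), "", ts),
    hgvs_c = normalize_hgvs(pick(ann$hgvs_c)),
    hgvs_p = ifelse(is.na(hp), "", normalize_hgvs(hp)),
    consequence = cons,
    provean = normalize_prediction(pick(ann$provean), "provean"),
    sift = normalize_prediction(pick(ann$sift), "sift"),
    polyphen = normalize_prediction(pick(ann$polyphen), "polyphen"),
    quality = suppressWarnings(as.numeric(fix[ri, "QUAL"])),
    depth = suppressWarnings(as.integer(pick(ann$depth))),
    stringsAsFactors = FALSE)
  vdf$frequencies <- lapply(seq_len(n_exp), function(e) {
    fr <- list()
    for (s in freq_sources) {
      ac <- suppressWarnings(as.numeric(nth_or_scalar(freq_ac[[s]][ri[e]], aj[e])))
      an <- freq_an[[s]][ri[e]]
      if (!is.na(ac) && !is.na(an)) fr[[s]] <- c(ac = ac, an = an)
    }
    fr
  })
  keys <- variant_key(vdf$gene, vdf$hgvs_c)

  # --- genotypes ---------------------------------------------------------
  samples <- colnames(vcf@gt)[-1]
  known <- samples %in% ped$sample_id
  if (any(!known)) {
    warning("dropping sample(s) absent from pedigree: ",
            paste(samples[!known], collapse = ", "))
  }
  samples <- samples[known]
  geno_df <- data.frame(family_id = character(), sample_id = character(),
                        key = character(), zygosity = character(),
                        stringsAsFactors = FALSE)
  if (length(samples)) {
    gt_raw <- sub(":.*$", "", vcf@gt[, samples, drop = FALSE])
    # zygosity of a GT string w.r.t. ALT index j, memoised per unique string
    classify <- function(g, j) {
      if (is.na(g)) return("missing")
      alleles <- strsplit(g, "[/|]")[[1]]
      if (!length(alleles) || any(alleles == ".")) return("missing")
      if (any(!grepl("^[0-9]+$", alleles))) return("malformed")
      cnt <- sum(as.integer(alleles) == j)
      if (length(alleles) == 1L) {
        if (cnt >= 1L) "hemizygous" else "hom_ref"
      } else if (cnt == 0L) "hom_ref" else if (cnt == 2L) "hom_alt" else "het"
    }
    uniq <- unique(as.vector(gt_raw))
    zyg <- matrix("", n_exp, length(samples))
    for (j in sort(unique(aj))) {
      zmap <- vapply(uniq, classify, character(1), j = j)
      rows <- aj == j
      zyg[rows, ] <- zmap[gt_raw[ri[rows], , drop = FALSE]]
    }
    if (any(zyg == "malformed")) {
      warning("malformed GT field(s); call(s) set to missing")
      zyg[zyg == "malformed"] <- "missing"
    }
    sample_sex <- ped$sex[match(samples, ped$sample_id)]
    on_x <- is_x_chrom(vdf$chrom)
    male_x_het <- on_x & (zyg == "het") &
      matrix(sample_sex == "male", n_exp, length(samples), byrow = TRUE)
    if (any(male_x_het)) {
      warning("male X heterozygous call(s) coerced to missing")
      zyg[male_x_het] <- "missing"
    }
    keep <- if (sparse) zyg != "hom_ref" else zyg == zyg
    hit <- which(keep, arr.ind = TRUE)
    if (nrow(hit)) {
      geno_df <- data.frame(
        family_id = ped$family_id[match(samples[hit[, 2]], ped$sample_id)],
        sample_id = samples[hit[, 2]],
        key = keys[hit[, 1]],
        zygosity = zyg[hit],
        stringsAsFactors = FALSE)
      geno_df <- geno_df[order(hit[, 1], hit[, 2]), , drop = FALSE]
      rownames(geno_df) <- NULL
    }
  }
  variants <- as_variant_table(vdf)
  variants <- variants[!duplicated(variants$key), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, genotypes = geno_df)
}

#' Write a cohort as an annotated VCF
#'
#' Emits a minimal VCF 4.2 with the INFO annotation keys of
#' [default_vcf_key_map()] plus `<SOURCE>_AC`/`<SOURCE>_AN` frequency pairs,
#' and per-sample GT columns. X-chromosome calls in males are written as
#' haploid GTs. This is the dialect [read_annotated_vcf()] reads back.
#'
#' @param variants Cohort-level `rp_variants` (needs `chrom`, `pos`, `ref`,
#'   `alt` filled in).
#' @param genotypes Genotype data.frame (`sample_id`, `key`, `zygosity`).
#' @param ped Pedigree data.frame (sample order and sexes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, genotypes, ped, path) {
  samples <- ped$sample_id[ped$sequenced]
  sexes <- ped$sex[ped$sequenced]
  km <- default_vcf_key_map()
  sources <- unique(unlist(lapply(variants$frequencies, names)))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
            unname(km[names(km) != "depth"]), names(km)[names(km) != "depth"]),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    if (length(sources)) c(
      sprintf("##INFO=<ID=%s_AC,Number=A,Type=Integer,Description=\"allele count\">", toupper(sources)),
      sprintf("##INFO=<ID=%s_AN,Number=1,Type=Integer,Description=\"allele number\">", toupper(sources))
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  gmap <- split(genotypes, genotypes$key)
  zyg_to_gt <- function(zyg, haploid) {
    if (haploid) switch(zyg, hemizygous = "1", hom_ref = "0", missing = ".", "./.")
    else switch(zyg, hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                hemizygous = "1", missing = "./.", "./.")
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- c(
      paste0(km[["gene"]], "=", v$gene),
      if (nzchar(v$transcript) && !is.na(v$transcript)) paste0(km[["transcript"]], "=", v$transcript),
      paste0(km[["hgvs_c"]], "=", v$hgvs_c),
      if (nzchar(v$hgvs_p) && !is.na(v$hgvs_p)) paste0(km[["hgvs_p"]], "=", v$hgvs_p),
      paste0(km[["consequence"]], "=", v$consequence),
      paste0(km[["provean"]], "=", v$provean),
      paste0(km[["sift"]], "=", v$sift),
      paste0(km[["polyphen"]], "=", v$polyphen),
      if (!is.na(v$depth)) paste0("DP=", v$depth)
    )
    for (s in names(v$frequencies[[1]])) {
      f <- v$frequencies[[1]][[s]]
      info <- c(info, paste0(toupper(s), "_AC=", f[["ac"]]), paste0(toupper(s), "_AN=", f[["an"]]))
    }
    g <- gmap[[v$key]]
    on_x <- is_x_chrom(v$chrom)
    gts <- vapply(seq_along(samples), function(s) {
      z <- g$zygosity[match(samples[s], g$sample_id)]
      if (is.na(z)) z <- "hom_ref"
      zyg_to_gt(z, haploid = on_x && sexes[s] == "male")
    }, character(1))
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt,
            ifelse(is.na(v$quality), ".", format(v$quality)), "PASS",
            paste(info, collapse = ";"), "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
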