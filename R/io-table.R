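# Flat annotated-variant table dialect (the format the published mutation
# tables are packaged in): one row per (family, variant), tab-separated.

MODEL_TOKENS <- c(
  "dominant" = "dominant", "recessive" = "recessive",
  "sporadic" = "sporadic", "x-linked" = "xlinked", "xlinked" = "xlinked",
  "xl" = "xlinked"
)

CHANGE_TOKENS <- c(
  "heterozygous" = "heterozygous",
  "homozygous" = "homozygous",
  "compound heterozygous" = "compound_heterozygous",
  "compound_heterozygous" = "compound_heterozygous",
  "hemizygote" = "hemizygote",
  "hemizygous" = "hemizygote"
)

CONSEQUENCE_TOKENS <- c(
  setNames(CONSEQUENCES, CONSEQUENCES),
  "splice-acceptor" = "splice_acceptor_region",
  "splice_acceptor" = "splice_acceptor_region"
)

#' Read an annotated variant table
#'
#' Reads the tab-separated dialect used to package published per-family
#' mutation tables: columns `gene`, `inheritance_model`, `family`, `hgvs_c`,
#' `hgvs_p`, `change` (genotype-configuration keyword), `consequence`,
#' `provean`, `sift`, `polyphen`, and optionally `reported` plus paired
#' `ac_<source>`/`an_<source>` allele-count columns. Tokens are normalized
#' case-insensitively on ingest (HGVS spacing, predictor verdicts, the
#' genotype-configuration vocabulary).
#'
#' @param path TSV path.
#' @return An `rp_variants` data.frame (see [as_variant_table()]) with
#'   `family_id`, `model` and `change` filled in; zero-row for an empty file.
#' @export
read_variant_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) {
    return(as_variant_table(data.frame(
      gene = character(), hgvs_c = character(), consequence = character(),
      provean = character(), sift = character(), polyphen = character(),
      stringsAsFactors = FALSE
    )))
  }
  need <- c("gene", "inheritance_model", "family", "hgvs_c", "change",
            "consequence", "provean", "sift", "polyphen")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)

  lookup <- function(tokens, map, what) {
    hit <- map[tolower(trimws(tokens))]
    if (anyNA(hit)) {
      rows <- which(is.na(hit))
      stop("unknown ", what, " token '", tokens[rows[1]], "' at data row ",
           rows[1], call. = FALSE)
    }
    unname(hit)
  }

  df <- data.frame(
    family_id = trimws(raw$family),
    model = lookup(raw$inheritance_model, MODEL_TOKENS, "inheritance model"),
    gene = trimws(raw$gene),
    hgvs_c = normalize_hgvs(raw$hgvs_c),
    hgvs_p = normalize_hgvs(if (is.null(raw$hgvs_p)) "" else raw$hgvs_p),
    change = lookup(raw$change, CHANGE_TOKENS, "genotype-configuration"),
    consequence = lookup(raw$consequence, CONSEQUENCE_TOKENS, "consequence"),
    provean = normalize_prediction(raw$provean, "provean"),
    sift = normalize_prediction(raw$sift, "sift"),
    polyphen = normalize_prediction(raw$polyphen, "polyphen"),
    stringsAsFactors = FALSE
  )
  if (!is.null(raw$reported)) df$reported <- trimws(raw$reported)

  ac_cols <- grep("^ac_", names(raw), value = TRUE)
  if (length(ac_cols)) {
    sources <- sub("^ac_", "", ac_cols)
    an_cols <- paste0("an_", sources)
    miss_an <- setdiff(an_cols, names(raw))
    if (length(miss_an)) stop("allele-count column(s) without matching allele-number: ",
                              paste(miss_an, collapse = ", "), call. = FALSE)
    df$frequencies <- lapply(seq_len(nrow(raw)), function(i) {
      fr <- lapply(seq_along(sources), function(s) {
        c(ac = as.numeric(raw[[ac_cols[s]]][i]), an = as.numeric(raw[[an_cols[s]]][i]))
      })
      names(fr) <- sources
      fr
    })
  }
  as_variant_table(df)
}

#' Write an annotated variant table
#'
#' Inverse of [read_variant_table()]: emits the documented TSV dialect with
#' normalized tokens, so a read/write/read round trip is the identity.
#'
#' @param variants `rp_variants` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- data.frame(
    gene = variants$gene,
    inheritance_model = variants$model,
    family = variants$family_id,
    hgvs_c = variants$hgvs_c,
    hgvs_p = variants$hgvs_p,
    change = variants$change,
    consequence = variants$consequence,
    provean = variants$provean,
    sift = variants$sift,
    polyphen = variants$polyphen,
    stringsAsFactors = FALSE
  )
  if (!is.null(variants$reported) && any(!is.na(variants$reported))) {
    out$reported <- variants$reported
  }
  freqs <- variants$frequencies
  if (!is.null(freqs) && any(lengths(freqs) > 0)) {
    sources <- unique(unlist(lapply(freqs, names)))
    for (s in sources) {
      out[[paste0("ac_", s)]] <- vapply(freqs, function(f) freq_entry(f, s)[["ac"]], numeric(1))
      out[[paste0("an_", s)]] <- vapply(freqs, function(f) freq_entry(f, s)[["an"]], numeric(1))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
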