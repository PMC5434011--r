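# Variant records: construction, validation and normalization helpers.
#
# A variant table is a plain data.frame with one row per (family, alt allele)
# and a `frequencies` list-column mapping reference-population source names to
# c(ac = allele count, an = allele number). Multi-allelic sites are split
# before they reach this layer.

#' Normalize an HGVS change token
#'
#' HGVS strings are treated as opaque identifiers: whitespace is stripped,
#' spacing around `>` is canonicalized, trailing commas and unbalanced
#' closing parentheses (as printed in some published tables) are dropped.
#' No grammatical HGVS parsing is attempted; equality on the normalized
#' token is all downstream code needs.
#'
#' @param x Character vector of cDNA- or protein-level change strings.
#' @return Character vector of normalized tokens.
#' @examples
#' normalize_hgvs("c.1040C > T")    # "c.1040C>T"
#' normalize_hgvs("c.8559-2A > G)") # "c.8559-2A>G"
#' @export
normalize_hgvs <- function(x) {
  x <- gsub("[[:space:]]+", "", as.character(x))
  # drop trailing punctuation the source tables sometimes carry
  x <- sub(",+$", "", x)
  unbalanced <- !grepl("\\(", x) & grepl("\\)$", x)
  x[unbalanced] <- sub("\\)+$", "", x[unbalanced])
  x
}

#' Deduplication key of a variant
#'
#' Mutations are identified by (gene symbol, normalized cDNA change): the
#' source tables omit genomic coordinates, and the same change observed in
#' two families must count as one distinct mutation.
#'
#' @param gene Gene symbol vector.
#' @param hgvs_c cDNA change vector (normalized internally).
#' @return Character key vector, `gene|hgvs_c`.
#' @export
variant_key <- function(gene, hgvs_c) {
  paste(gene, normalize_hgvs(hgvs_c), sep = "|")
}

# --- predictor verdict normalization ------------------------------------

predictor_token_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "predictor_token_map.tsv", package = "rpcascade")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Normalize in-silico predictor verdict tokens
#'
#' Published tables carry the PROVEAN/SIFT/PolyPhen-2 verdicts with
#' inconsistent case and a few irregular tokens ("possibly neutral",
#' "possibly deleterious", "Possibly Damaging"). Tokens are mapped
#' case-insensitively to the closed per-predictor vocabulary via the
#' editable resource `inst/extdata/predictor_token_map.tsv`; `NA`, `"NA"`
#' and empty strings become `"missing"`.
#'
#' @param x Character vector of raw verdict tokens.
#' @param predictor One of `"provean"`, `"sift"`, `"polyphen"`.
#' @return Character vector over the predictor's closed vocabulary.
#' @export
normalize_prediction <- function(x, predictor = c("provean", "sift", "polyphen")) {
  predictor <- match.arg(predictor)
  map <- predictor_token_map()
  map <- map[map$predictor == predictor, ]
  tok <- tolower(trimws(as.character(x)))
  tok[is.na(x) | tok == "" | tok == "na"] <- "na"
  out <- map$normalized[match(tok, map$token)]
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop("unknown ", predictor, " verdict token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

# empty frequencies element
no_frequencies <- function() list()

#' Assemble a variant table
#'
#' Low-level constructor used by the readers and the simulator. All
#' vocabulary columns are validated; HGVS and predictor tokens must already
#' be normalized (the readers do this).
#'
#' @param df data.frame with at least `gene`, `hgvs_c`, `consequence`,
#'   `provean`, `sift`, `polyphen`; optional `family_id`, `model`, `change`,
#'   `chrom`, `pos`, `ref`, `alt`, `transcript`, `hgvs_p`, `quality`,
#'   `depth`, `reported`, `frequencies` (list-column).
#' @return The validated data.frame with a `key` column and class
#'   `rp_variants`.
#' @export
as_variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene", "hgvs_c", "consequence", "provean", "sift", "polyphen")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  opt_na <- c("family_id", "model", "change", "chrom", "transcript",
              "hgvs_p", "reported")
  for (col in opt_na) if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, n)
  if (is.null(df$pos)) df$pos <- rep(NA_integer_, n)
  if (is.null(df$ref)) df$ref <- rep(NA_character_, n)
  if (is.null(df$alt)) df$alt <- rep(NA_character_, n)
  if (is.null(df$quality)) df$quality <- rep(NA_real_, n)
  if (is.null(df$depth)) df$depth <- rep(NA_integer_, n)
  if (is.null(df$frequencies)) df$frequencies <- replicate(nrow(df), no_frequencies(), simplify = FALSE)

  bad_change <- setdiff(unique(df$change[!is.na(df$change)]), GENOTYPE_CONFIGS)
  if (length(bad_change)) {
    stop("unknown genotype-configuration token(s): ",
         paste(bad_change, collapse = ", "), call. = FALSE)
  }
  bad_cons <- setdiff(unique(df$consequence), CONSEQUENCES)
  if (length(bad_cons)) {
    stop("unknown consequence token(s): ", paste(bad_cons, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(df$provean %in% PROVEAN_LEVELS),
            all(df$sift %in% SIFT_LEVELS),
            all(df$polyphen %in% POLYPHEN_LEVELS))
  if (any(!is.na(df$pos) & df$pos < 1)) stop("positions are 1-based (pos >= 1)", call. = FALSE)
  for (fr in df$frequencies) {
    for (f in fr) {
      if (f[["ac"]] > f[["an"]]) stop("allele_count > allele_number in a frequency entry", call. = FALSE)
    }
  }
  df$key <- variant_key(df$gene, df$hgvs_c)
  if (any(df$gene == "" | df$hgvs_c == "")) {
    stop("gene and hgvs_c must be non-empty (they form the deduplication key)", call. = FALSE)
  }
  class(df) <- c("rp_variants", "data.frame")
  df
}

# look up one frequency pair, 0/0 when the source never saw the variant
freq_entry <- function(frequencies, source) {
  f <- frequencies[[source]]
  if (is.null(f)) c(ac = 0, an = 0) else f
}
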