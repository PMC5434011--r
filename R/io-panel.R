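# Gene panels (gene -> permitted inheritance modes) and the known-mutation
# catalog used for novelty classification.

PANEL_MODES <- c("ad", "ar", "xl")

#' Load a gene panel
#'
#' Two-column TSV: `gene`, `modes`, where `modes` is a comma-separated
#' subset of `ad`, `ar`, `xl`. Dual-mode genes (several genes cause both
#' dominant and recessive RP) list both modes.
#'
#' @param path Panel TSV path.
#' @param name Panel name (defaults to the file name).
#' @return An `rp_panel` object: list with `name` and `entries`
#'   (named list gene -> character vector of modes).
#' @export
load_panel <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty gene panel: ", path, call. = FALSE)
  if (!all(c("gene", "modes") %in% names(df))) {
    stop("panel file needs columns 'gene' and 'modes'", call. = FALSE)
  }
  entries <- lapply(strsplit(df$modes, ","), function(m) {
    m <- trimws(tolower(m))
    bad <- setdiff(m, PANEL_MODES)
    if (length(bad)) stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (!length(m)) stop("panel entry with no modes", call. = FALSE)
    unique(m)
  })
  names(entries) <- trimws(df$gene)
  structure(list(name = name, entries = entries), class = "rp_panel")
}

#' @export
print.rp_panel <- function(x, ...) {
  cat("<rp_panel> ", x$name, ": ", length(x$entries), " genes\n", sep = "")
  invisible(x)
}

panel_genes <- function(panel) names(panel$entries)

panel_modes <- function(panel, gene) {
  m <- panel$entries[[gene]]
  if (is.null(m)) character() else m
}

#' Load a known-mutation catalog
#'
#' Two-column TSV (`gene`, `hgvs_c`, optional `tag` holding a literature
#' reference). Lookup is exact on the normalized (gene, cDNA change) key; a
#' variant absent from the catalog is classified novel.
#'
#' @param path Catalog TSV path.
#' @return An `rp_catalog` object with a `keys` character vector and the
#'   raw `entries` data.frame.
#' @export
load_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "hgvs_c") %in% names(df))) {
    stop("catalog file needs columns 'gene' and 'hgvs_c'", call. = FALSE)
  }
  df$hgvs_c <- normalize_hgvs(df$hgvs_c)
  structure(list(keys = unique(variant_key(df$gene, df$hgvs_c)), entries = df),
            class = "rp_catalog")
}

#' @export
print.rp_catalog <- function(x, ...) {
  cat("<rp_catalog> ", length(x$keys), " reported mutations\n", sep = "")
  invisible(x)
}

#' An empty known-mutation catalog (everything classifies as novel)
#' @return An `rp_catalog` with no entries.
#' @export
empty_catalog <- function() {
  structure(list(keys = character(),
                 entries = data.frame(gene = character(), hgvs_c = character(),
                                      stringsAsFactors = FALSE)),
            class = "rp_catalog")
}
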