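# PED pedigree reading/writing (standard 6-column dialect).

SEX_CODES <- c("1" = "male", "2" = "female", "0" = "unknown")
AFFECTION_CODES <- c("2" = "affected", "1" = "unaffected", "0" = "unknown", "-9" = "unknown")

#' Read a PED pedigree file
#'
#' Standard whitespace-delimited 6-column PED: family, individual, father,
#' mother, sex (1 male / 2 female / 0 unknown), phenotype (2 affected /
#' 1 unaffected / 0 or -9 unknown). `0` (or an empty field) means no parent
#' recorded, so singleton probands are valid one-member families.
#'
#' @param path PED file path.
#' @return data.frame of individuals: `family_id`, `sample_id`, `father_id`,
#'   `mother_id` (`NA` when absent), `sex`, `affected`, `sequenced`
#'   (defaults `TRUE`; cohort assembly may override from available calls).
#' @export
read_ped <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(data.frame(family_id = character(), sample_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = character(), affected = character(),
                      sequenced = logical(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n <- lengths(fields)
  if (any(n < 6)) {
    stop("PED line(s) with fewer than 6 columns: ",
         paste(which(n < 6), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  ped <- data.frame(
    family_id = m[, 1],
    sample_id = m[, 2],
    father_id = ifelse(m[, 3] %in% c("0", ""), NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] %in% c("0", ""), NA_character_, m[, 4]),
    sex = unname(SEX_CODES[m[, 5]]),
    affected = unname(AFFECTION_CODES[m[, 6]]),
    sequenced = TRUE,
    stringsAsFactors = FALSE
  )
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$affected[is.na(ped$affected)] <- "unknown"
  validate_pedigree(ped)
  ped
}

# structural validation shared by the reader and the simulator
validate_pedigree <- function(ped) {
  key <- paste(ped$family_id, ped$sample_id)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(ped))) {
    fam <- ped[ped$family_id == ped$family_id[i], ]
    for (side in c("father_id", "mother_id")) {
      pid <- ped[[side]][i]
      if (!is.na(pid) && !(pid %in% fam$sample_id)) {
        stop("individual ", ped$sample_id[i], " references missing ",
             sub("_id$", "", side), " '", pid, "'", call. = FALSE)
      }
    }
    f <- ped$father_id[i]
    if (!is.na(f) && fam$sex[match(f, fam$sample_id)] == "female") {
      stop("father ", f, " of ", ped$sample_id[i], " is recorded as female", call. = FALSE)
    }
    m <- ped$mother_id[i]
    if (!is.na(m) && fam$sex[match(m, fam$sample_id)] == "male") {
      stop("mother ", m, " of ", ped$sample_id[i], " is recorded as male", call. = FALSE)
    }
  }
  # no individual is its own ancestor
  for (fam_id in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fam_id, ]
    parent_of <- function(id) {
      i <- match(id, fam$sample_id)
      c(fam$father_id[i], fam$mother_id[i])
    }
    for (id in fam$sample_id) {
      seen <- character()
      frontier <- setdiff(parent_of(id), NA)
      while (length(frontier)) {
        if (id %in% frontier) stop("pedigree cycle: ", id, " is its own ancestor", call. = FALSE)
        seen <- union(seen, frontier)
        frontier <- setdiff(unlist(lapply(frontier, parent_of)), c(NA, seen))
      }
    }
  }
  invisible(ped)
}

#' Write a PED pedigree file
#'
#' @param ped Individuals data.frame as returned by [read_ped()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex <- names(SEX_CODES)[match(ped$sex, SEX_CODES)]
  aff <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  lines <- paste(ped$family_id, ped$sample_id,
                 ifelse(is.na(ped$father_id), "0", ped$father_id),
                 ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                 sex, aff, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
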