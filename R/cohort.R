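# Family and cohort containers.
#
# A family couples a pedigree slice with a declared cohort inheritance
# class; a cohort adds the cohort-level variant table and the long genotype
# table (family_id, sample_id, key, zygosity). Genotype records are sparse:
# an absent record for a sequenced sample means hom_ref, and any call for an
# unsequenced sample is ignored.

#' Construct a family
#'
#' @param family_id Family identifier.
#' @param members data.frame with `sample_id`, `father_id`, `mother_id`,
#'   `sex`, `affected`, `sequenced` (the [read_ped()] columns).
#' @param declared_model One of `"dominant"`, `"recessive"`, `"sporadic"`,
#'   `"xlinked"` — the cohort class the family was recruited under.
#' @return An `rp_family` list.
#' @export
new_family <- function(family_id, members, declared_model) {
  declared_model <- match.arg(declared_model, INHERITANCE_MODELS)
  stopifnot(is.data.frame(members), nrow(members) >= 1)
  if (!any(members$affected == "affected" & members$sequenced)) {
    stop("family ", family_id, " has no affected, sequenced member", call. = FALSE)
  }
  members$family_id <- family_id
  validate_pedigree(members)
  structure(list(family_id = family_id, members = members,
                 declared_model = declared_model),
            class = "rp_family")
}

#' Construct a cohort
#'
#' @param families List of [new_family()] objects.
#' @param variants Cohort-level `rp_variants` table (one row per distinct
#'   variant; `key` column identifies it).
#' @param genotypes data.frame `family_id`, `sample_id`, `key`, `zygosity`.
#' @return An `rp_cohort` list.
#' @export
new_cohort <- function(families, variants, genotypes) {
  names(families) <- vapply(families, `[[`, character(1), "family_id")
  structure(list(families = families, variants = variants, genotypes = genotypes),
            class = "rp_cohort")
}

#' @export
print.rp_cohort <- function(x, ...) {
  models <- vapply(x$families, `[[`, character(1), "declared_model")
  cat("<rp_cohort> ", length(x$families), " families (",
      paste(names(table(models)), as.integer(table(models)), sep = ":", collapse = ", "),
      "), ", nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

# zygosity of one sample for one variant under the sparse convention
zygosity_of <- function(family, genotypes, sample_id, key) {
  i <- match(sample_id, family$members$sample_id)
  if (is.na(i) || !family$members$sequenced[i]) return("missing")
  hit <- genotypes$zygosity[genotypes$sample_id == sample_id & genotypes$key == key]
  if (!length(hit)) "hom_ref" else hit[1]
}

carries_alt <- function(zyg) zyg %in% c("het", "hom_alt", "hemizygous")

# deterministic proband: lexicographically first affected sequenced member
# (sorted, not pedigree-ordered, so results are invariant under member
# permutation)
proband_of <- function(family) {
  m <- family$members
  ids <- sort(m$sample_id[m$affected == "affected" & m$sequenced])
  ids[1]
}
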