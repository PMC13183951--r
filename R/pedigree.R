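#' Validate a pedigree table
#'
#' A pedigree is a plain `data.frame` with columns `family_id`,
#' `individual_id`, `father_id`, `mother_id` (`NA` for founders), `sex`
#' (`"female"`/`"male"`), `genotyped` (logical) and `role`
#' (`"offspring"`/`"mother"`/`"father"`). Checks referential integrity, that
#' nobody is their own ancestor, and that every offspring flagged for
#' analysis has at least one genotyped parent.
#'
#' @param ped data.frame as above.
#' @return `ped`, invisibly, after validation (errors otherwise).
#' @export
validatePedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id",
            "sex", "genotyped", "role")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual ids in pedigree")
  if (!all(ped$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (!all(ped$role %in% c("offspring", "mother", "father")))
    stop("role must be offspring/mother/father")
  par <- c(ped$father_id, ped$mother_id)
  par <- par[!is.na(par)]
  if (!all(par %in% ped$individual_id))
    stop("pedigree references parents absent from the table")
  if (any(!is.na(ped$father_id) & ped$father_id == ped$individual_id) ||
      any(!is.na(ped$mother_id) & ped$mother_id == ped$individual_id))
    stop("an individual cannot be its own parent")
  off <- ped[ped$role == "offspring", ]
  if (nrow(off)) {
    gset <- ped$individual_id[ped$genotyped]
    ok <- (off$father_id %in% gset) | (off$mother_id %in% gset)
    if (!all(ok))
      stop("every offspring must have at least one genotyped parent")
  }
  invisible(ped)
}

#' Classify offspring as trio or pair
#'
#' @param ped validated pedigree.
#' @return data.frame with `individual_id` and `structure`
#'   (`"trio"` if both parents genotyped, else `"pair"`).
#' @export
familyStructure <- function(ped) {
  off <- ped[ped$role == "offspring", ]
  gset <- ped$individual_id[ped$genotyped]
  both <- (off$father_id %in% gset) & (off$mother_id %in% gset)
  data.frame(individual_id = off$individual_id,
             structure = ifelse(both, "trio", "pair"),
             stringsAsFactors = FALSE)
}
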