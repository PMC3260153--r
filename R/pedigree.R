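# Sample manifests and pedigree builders -------------------------------------

.status_levels <- c("affected", "unaffected")
.role_levels <- c("case", "parent", "sibling", "population_control")

#' Validate a sample manifest
#'
#' A manifest is a data.frame with one row per sample and columns `id`,
#' `family_id`, `father`, `mother` (`NA` when unknown), `status`
#' (`affected`/`unaffected`), `role` (`case`, `parent`, `sibling`,
#' `population_control`) and `deme`. Parent references must resolve to rows
#' of the manifest (or be `NA`) and no sample may be its own ancestor.
#'
#' @param manifest data.frame as described.
#' @return The manifest, invisibly, with character columns normalised.
#' @export
validate_manifest <- function(manifest) {
  need <- c("id", "family_id", "father", "mother", "status", "role", "deme")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    abort_format("manifest missing columns: ", paste(miss, collapse = ", "))
  for (col in need) manifest[[col]] <- as.character(manifest[[col]])
  manifest$father[manifest$father %in% c("", "0", "NA")] <- NA
  manifest$mother[manifest$mother %in% c("", "0", "NA")] <- NA
  if (anyDuplicated(manifest$id))
    abort_format("duplicate sample ids in manifest")
  bad <- !manifest$status %in% .status_levels
  if (any(bad))
    abort_format("invalid status values: ",
                 paste(unique(manifest$status[bad]), collapse = ", "))
  bad <- !manifest$role %in% .role_levels
  if (any(bad))
    abort_format("invalid role values: ",
                 paste(unique(manifest$role[bad]), collapse = ", "))
  refs <- c(manifest$father, manifest$mother)
  unresolved <- setdiff(refs[!is.na(refs)], manifest$id)
  if (length(unresolved))
    abort_format("parent ids not in manifest: ",
                 paste(unresolved, collapse = ", "))
  # no sample may be its own ancestor
  for (id in manifest$id) {
    anc <- manifest_ancestors(manifest, id)
    if (id %in% anc) abort_format("pedigree cycle involving sample ", id)
  }
  invisible(manifest)
}

# all ancestors of `id` (breadth-first); guards against cycles by capping
manifest_ancestors <- function(manifest, id) {
  idx <- match(manifest$id, manifest$id)
  seen <- character()
  frontier <- id
  for (k in seq_len(nrow(manifest) + 1)) {
    rows <- manifest[manifest$id %in% frontier, , drop = FALSE]
    parents <- unique(c(rows$father, rows$mother))
    parents <- parents[!is.na(parents)]
    frontier <- setdiff(parents, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen
}

manifest_affected <- function(manifest) manifest$id[manifest$status == "affected"]

manifest_controls <- function(manifest) {
  manifest$id[manifest$role == "population_control"]
}

# do the parents of `id` share a common ancestor (consanguinity loop)?
manifest_has_loop <- function(manifest, id) {
  row <- manifest[manifest$id == id, ]
  if (is.na(row$father) || is.na(row$mother)) return(FALSE)
  a1 <- c(row$father, manifest_ancestors(manifest, row$father))
  a2 <- c(row$mother, manifest_ancestors(manifest, row$mother))
  length(intersect(a1, a2)) > 0
}

#' Build a consanguineous nuclear-family pedigree
#'
#' Constructs the canonical mapping family of an endogamous deme: a sibship
#' whose parents are related through a shared founder couple. The loop depth
#' sets the expected inbreeding coefficient of the children: first cousins
#' give F = 1/16, first cousins once removed F = 1/32, second cousins
#' F = 1/64 -- bracketing the 2.5--4% average coefficients typical of
#' Amish and Mennonite demes.
#'
#' @param consanguinity One of `"first_cousin"`, `"first_cousin_once_removed"`,
#'   `"second_cousin"`.
#' @param n_affected,n_unaffected Numbers of affected and unaffected children.
#' @param family_id,deme Labels carried into the manifest.
#' @param prefix Prefix for generated sample ids.
#' @return A manifest data.frame (see [validate_manifest()]).
#' @export
pedigree_cousin_family <- function(consanguinity = c("first_cousin_once_removed",
                                                     "first_cousin",
                                                     "second_cousin"),
                                   n_affected = 2, n_unaffected = 6,
                                   family_id = "F1", deme = "deme1",
                                   prefix = family_id) {
  consanguinity <- match.arg(consanguinity)
  if (n_affected + n_unaffected < 1) abort_config("need at least one child")
  id <- function(x) paste0(prefix, "_", x)
  row <- function(x, f = NA, m = NA, status = "unaffected", role = "parent") {
    data.frame(id = id(x), family_id = family_id,
               father = if (is.na(f)) NA_character_ else id(f),
               mother = if (is.na(m)) NA_character_ else id(m),
               status = status, role = role, deme = deme,
               stringsAsFactors = FALSE)
  }
  ped <- rbind(
    row("GF"), row("GM"),                      # shared founder couple
    row("S1", "GF", "GM"), row("S2", "GF", "GM"),
    row("U1"), row("U2"),
    row("P1", "S1", "U1"),                     # father lineage
    row("P2", "S2", "U2")                      # mother lineage
  )
  father <- "P1"; mother <- "P2"
  if (consanguinity %in% c("first_cousin_once_removed", "second_cousin")) {
    ped <- rbind(ped, row("U3"), row("P2b", "P2", "U3"))
    mother <- "P2b"
  }
  if (consanguinity == "second_cousin") {
    ped <- rbind(ped, row("U4"), row("P1b", "P1", "U4"))
    father <- "P1b"
  }
  kids <- c(
    if (n_affected > 0)
      lapply(seq_len(n_affected), function(i)
        row(sprintf("A%d", i), father, mother, "affected", "case")),
    if (n_unaffected > 0)
      lapply(seq_len(n_unaffected), function(i)
        row(sprintf("U%dS", i), father, mother, "unaffected", "sibling"))
  )
  out <- rbind(ped, do.call(rbind, kids))
  rownames(out) <- NULL
  validate_manifest(out)
  out
}

#' Build a cohort of unrelated population controls
#'
#' @param n Number of control individuals.
#' @param deme,prefix Labels for the manifest.
#' @return A manifest data.frame of founder individuals with role
#'   `population_control`.
#' @export
pedigree_controls <- function(n = 100, deme = "deme1", prefix = "CTRL") {
  out <- data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
                    family_id = paste0(prefix, "_pop"),
                    father = NA_character_, mother = NA_character_,
                    status = "unaffected", role = "population_control",
                    deme = deme, stringsAsFactors = FALSE)
  validate_manifest(out)
  out
}

# expected F for each supported loop depth
.consanguinity_F <- c(first_cousin = 1 / 16,
                      first_cousin_once_removed = 1 / 32,
                      second_cousin = 1 / 64)

# pick the loop depth whose expected F is closest to the target
consanguinity_for_F <- function(target_F) {
  names(.consanguinity_F)[which.min(abs(.consanguinity_F - target_F))]
}
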