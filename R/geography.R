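#' Nested census geography
#'
#' A geography hierarchy records which census block group (CBG) each census
#' block (CBK) belongs to, and which census tract (CT) each CBG belongs to.
#' Nesting is declared by explicit mapping tables: identifiers are opaque
#' strings and are never parsed for structure, so the hierarchy works equally
#' for FIPS-style codes and for synthetic identifiers.
#'
#' @param cbk_map data.frame with columns `cbk_id`, `cbg_id`; one row per
#'   census block.
#' @param cbg_map data.frame with columns `cbg_id`, `ct_id`; one row per
#'   census block group.
#'
#' @return An object of class `geo_hierarchy`: a list with elements `cbk`
#'   and `cbg` holding the validated mapping tables.
#' @export
geo_hierarchy <- function(cbk_map, cbg_map) {
  cbk_map <- as.data.frame(cbk_map)
  cbg_map <- as.data.frame(cbg_map)
  stopifnot(all(c("cbk_id", "cbg_id") %in% names(cbk_map)),
            all(c("cbg_id", "ct_id") %in% names(cbg_map)))
  cbk_map$cbk_id <- as.character(cbk_map$cbk_id)
  cbk_map$cbg_id <- as.character(cbk_map$cbg_id)
  cbg_map$cbg_id <- as.character(cbg_map$cbg_id)
  cbg_map$ct_id <- as.character(cbg_map$ct_id)
  if (anyDuplicated(cbk_map$cbk_id))
    stop("a census block maps to more than one block group")
  if (anyDuplicated(cbg_map$cbg_id))
    stop("a block group maps to more than one tract")
  orphan <- setdiff(cbk_map$cbg_id, cbg_map$cbg_id)
  if (length(orphan))
    stop("block groups referenced by blocks but absent from the CBG map: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  structure(list(cbk = cbk_map[, c("cbk_id", "cbg_id")],
                 cbg = cbg_map[, c("cbg_id", "ct_id")]),
            class = "geo_hierarchy")
}

#' @export
print.geo_hierarchy <- function(x, ...) {
  cat("Census geography hierarchy\n")
  cat("  census blocks:      ", nrow(x$cbk), "\n")
  cat("  block groups:       ", nrow(x$cbg), "\n")
  cat("  tracts:             ", length(unique(x$cbg$ct_id)), "\n")
  invisible(x)
}

#' Check that a cohort's geography identifiers are consistent
#'
#' Verifies that every cohort row's block, block-group and tract identifiers
#' agree with the declared hierarchy: the block must exist, its mapped block
#' group must equal the row's `cbg_id`, and that block group's mapped tract
#' must equal the row's `ct_id`. Violations are returned as data, not raised
#' as errors, so that a report can list them all.
#'
#' @param cohort A cohort data.frame with columns `cbk_id`, `cbg_id`, `ct_id`.
#' @param geo A [geo_hierarchy()].
#'
#' @return data.frame with columns `row`, `id`, `problem`; zero rows iff the
#'   cohort is consistent with the hierarchy.
#' @export
validate_hierarchy <- function(cohort, geo) {
  stopifnot(inherits(geo, "geo_hierarchy"), nrow(cohort) > 0L)
  cbk2cbg <- stats::setNames(geo$cbk$cbg_id, geo$cbk$cbk_id)
  cbg2ct <- stats::setNames(geo$cbg$ct_id, geo$cbg$cbg_id)

  out <- list()
  bad <- function(rows, id, problem) {
    if (length(rows))
      out[[length(out) + 1L]] <<- data.frame(row = rows, id = id,
                                             problem = problem)
  }
  cbk <- as.character(cohort$cbk_id)
  cbg <- as.character(cohort$cbg_id)
  ct <- as.character(cohort$ct_id)

  unknown_cbk <- which(!(cbk %in% names(cbk2cbg)))
  bad(unknown_cbk, cbk[unknown_cbk], "cbk_id not in hierarchy")
  unknown_cbg <- which(!(cbg %in% names(cbg2ct)))
  bad(unknown_cbg, cbg[unknown_cbg], "cbg_id not in hierarchy")

  known <- setdiff(seq_len(nrow(cohort)), union(unknown_cbk, unknown_cbg))
  mism_bg <- known[cbk2cbg[cbk[known]] != cbg[known]]
  bad(mism_bg, cbk[mism_bg], "cbk_id maps to a different cbg_id than recorded")
  mism_ct <- known[cbg2ct[cbg[known]] != ct[known]]
  bad(mism_ct, cbg[mism_ct], "cbg_id maps to a different ct_id than recorded")

  if (length(out)) do.call(rbind, out)
  else data.frame(row = integer(), id = character(), problem = character())
}
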