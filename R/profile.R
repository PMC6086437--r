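# Phase 1 of the evaluation: turn filtered homology hits into per-strain
# feature vectors over panel criteria and orthologous groups.

#' Build a strain profile from filtered hits
#'
#' Counts, for each panel criterion, the number of distinct subject proteins
#' it hit (hits are expected to have passed [filter_domain_complete()]), and
#' derives presence per criterion and satisfaction per orthologous group
#' (a group is satisfied when any member is present — e.g. a required step
#' covered by a backup enzyme).
#'
#' @param strain_id strain identifier.
#' @param hits data.frame of filtered homology hits; every `query_id` must be
#'   a panel criterion.
#' @param panel the [ffa_panel()] the hits were searched against.
#' @return An object of class `strain_profile`: list with `strain_id`,
#'   `hit_counts` (named integer over all criteria), `presence` (named
#'   logical) and `og_satisfied` (named logical over all groups).
#' @export
build_profile <- function(strain_id, hits, panel) {
    ids <- panel$criteria$criterion_id
    unknown <- setdiff(unique(hits$query_id), ids)
    if (length(unknown) > 0L)
        ffa_stop("ffa_value_error",
                 "hit(s) for unknown criterion id(s): %s",
                 paste(unknown, collapse = ", "))
    counts <- setNames(integer(length(ids)), ids)
    if (nrow(hits) > 0L) {
        per <- tapply(hits$subject_id, hits$query_id,
                      function(s) length(unique(s)))
        counts[names(per)] <- as.integer(per)
    }
    profile_from_counts(strain_id, counts, panel)
}

# Shared constructor: derives presence and OG satisfaction from counts.
profile_from_counts <- function(strain_id, counts, panel) {
    presence <- counts > 0L
    members <- og_members(panel)
    og_satisfied <- vapply(members, function(m) any(presence[m]), logical(1))
    og_satisfied <- og_satisfied[panel$groups$og_id]
    structure(list(strain_id = strain_id, hit_counts = counts,
                   presence = presence, og_satisfied = og_satisfied),
              class = "strain_profile")
}

#' Count satisfied required orthologous groups
#'
#' Model strains are expected to carry every required group; strains missing
#' one or more required steps (e.g. pyruvate, water dikinase and its backup
#' both absent) score lower here.
#'
#' @param profile a [build_profile()] result.
#' @param panel the matching [ffa_panel()].
#' @return Integer: number of required-impact groups satisfied.
#' @export
count_required_ogs <- function(profile, panel) {
    req <- panel$groups$og_id[panel$groups$impact == "required"]
    sum(profile$og_satisfied[req])
}

#' @export
print.strain_profile <- function(x, ...) {
    cat(sprintf("strain_profile '%s': %d/%d criteria present, %d/%d OGs satisfied\n",
                x$strain_id, sum(x$presence), length(x$presence),
                sum(x$og_satisfied), length(x$og_satisfied)))
    invisible(x)
}

#' Tabular exports of a strain profile
#'
#' `profile_table()` is the per-criterion view (strain_id, criterion_id,
#' hit_count, presence); `og_table()` is the per-group summary (strain_id,
#' og_id, impact, satisfied). Both are plain data.frames ready for
#' `write.csv()`.
#'
#' @param profile a `strain_profile`.
#' @param panel the matching [ffa_panel()].
#' @return data.frame.
#' @export
profile_table <- function(profile) {
    data.frame(strain_id = profile$strain_id,
               criterion_id = names(profile$hit_counts),
               hit_count = as.integer(profile$hit_counts),
               presence = as.logical(profile$presence))
}

#' @rdname profile_table
#' @export
og_table <- function(profile, panel) {
    data.frame(strain_id = profile$strain_id,
               og_id = panel$groups$og_id,
               impact = panel$groups$impact,
               satisfied = as.logical(profile$og_satisfied[panel$groups$og_id]))
}
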