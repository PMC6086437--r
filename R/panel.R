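# Criteria-panel data model and I/O.
#
# A panel is the curated list of criterion proteins whose presence in a
# strain's proteome affects free-fatty-acid production: positively (candidates
# for insertion/overexpression), negatively (candidates for deletion/
# underexpression) or as a synthesis requirement. Criteria are organized into
# orthologous groups (OGs); a required OG is satisfied when any member —
# including a backup enzyme catalyzing the same step — is present.

PANEL_COLUMNS <- c("criterion_id", "gene_symbol", "kegg_ko", "ec_number",
                   "impact", "og_id", "domains", "action_hint")
IMPACT_LEVELS <- c("positive", "negative", "required")
ACTION_LEVELS <- c("insertion", "deletion", "overexpression",
                   "underexpression", "present_required")

#' Construct a criteria panel
#'
#' Builds an `ffa_panel` from a criteria table and (optionally) the panel
#' protein sequences. Orthologous groups are reconstructed from the `og_id`
#' column. By default the panel is validated and construction fails on any
#' invariant violation; use [validate_panel()] to inspect violations instead.
#'
#' @param criteria data.frame with character columns `criterion_id`,
#'   `gene_symbol`, `kegg_ko`, `ec_number`, `impact` (one of `"positive"`,
#'   `"negative"`, `"required"`), `og_id`, `domains` (semicolon-separated
#'   domain-family accessions, possibly empty) and `action_hint`.
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   panel protein sequences; names must be criterion ids.
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return An object of class `ffa_panel`: a list with elements `criteria`
#'   (the table above), `groups` (data.frame `og_id`, `impact`, `n_members`)
#'   and `sequences` (named character vector).
#' @seealso [load_panel()], [write_panel()], [validate_panel()]
#' @export
ffa_panel <- function(criteria, sequences = NULL, validate = TRUE) {
    missing_cols <- setdiff(PANEL_COLUMNS, names(criteria))
    if (length(missing_cols) > 0L)
        ffa_stop("ffa_schema_error", "panel table is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
    criteria <- as.data.frame(criteria)[, PANEL_COLUMNS]
    for (cc in PANEL_COLUMNS) criteria[[cc]] <- as.character(criteria[[cc]])
    rownames(criteria) <- NULL

    if (is.null(sequences)) sequences <- character(0)
    if (methods::is(sequences, "XStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))

    groups <- unique(criteria[, c("og_id", "impact")])
    groups <- groups[!duplicated(groups$og_id), , drop = FALSE]
    groups$n_members <- as.integer(table(criteria$og_id)[groups$og_id])
    rownames(groups) <- NULL

    panel <- structure(list(criteria = criteria, groups = groups,
                            sequences = sequences), class = "ffa_panel")
    if (validate) {
        rep <- validate_panel(panel)
        if (nrow(rep) > 0L)
            ffa_stop("ffa_value_error", "invalid panel:\n%s",
                     paste(sprintf("  [%s %s] %s", rep$scope, rep$id,
                                   rep$problem), collapse = "\n"))
    }
    panel
}

#' Validate a panel against its invariants
#'
#' Checks every panel invariant and returns the violations as data, not
#' errors: unique criterion ids, legal impact and action values, consistent
#' impact within each orthologous group, sequences restricted to the 20
#' amino-acid letters plus X, and sequence ids cross-referencing criterion
#' rows. An empty report means the panel is valid.
#'
#' @param panel an `ffa_panel` (possibly built with `validate = FALSE`).
#' @return data.frame with columns `scope` (`"criterion"`, `"group"` or
#'   `"sequence"`), `id` and `problem`; zero rows if the panel is valid.
#' @export
validate_panel <- function(panel) {
    cr <- panel$criteria
    out <- list()
    add <- function(scope, id, problem)
        out[[length(out) + 1L]] <<- data.frame(scope = scope, id = id,
                                               problem = problem)

    dup <- unique(cr$criterion_id[duplicated(cr$criterion_id)])
    for (d in dup) add("criterion", d, "duplicated criterion_id")

    bad_imp <- !(cr$impact %in% IMPACT_LEVELS)
    for (i in which(bad_imp))
        add("criterion", cr$criterion_id[i],
            sprintf("unknown impact '%s'", cr$impact[i]))

    bad_act <- !(cr$action_hint %in% ACTION_LEVELS)
    for (i in which(bad_act))
        add("criterion", cr$criterion_id[i],
            sprintf("unknown action_hint '%s'", cr$action_hint[i]))

    for (i in which(!nzchar(cr$og_id)))
        add("criterion", cr$criterion_id[i], "empty og_id")

    mixed <- tapply(cr$impact, cr$og_id, function(x) length(unique(x)) > 1L)
    for (g in names(mixed)[which(mixed)])
        add("group", g, "members mix impact classes")

    if (length(panel$sequences) > 0L) {
        orphan <- setdiff(names(panel$sequences), cr$criterion_id)
        for (s in orphan)
            add("sequence", s, "sequence id has no criterion row")
        for (s in names(panel$sequences)) {
            seq <- panel$sequences[[s]]
            if (!nzchar(seq))
                add("sequence", s, "empty sequence")
            else if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq))
                add("sequence", s,
                    "sequence contains letters outside the amino-acid alphabet (plus X)")
        }
    }
    if (length(out) == 0L)
        return(data.frame(scope = character(0), id = character(0),
                          problem = character(0)))
    do.call(rbind, out)
}

#' Load a panel from a TSV table and FASTA sequences
#'
#' Reads the panel table (UTF-8 TSV with a header row and the eight
#' documented columns) and, if given, the panel-protein FASTA whose record
#' ids (first whitespace-delimited header token) are criterion ids.
#'
#' @param path path to the panel TSV.
#' @param seq_path optional path to the panel-protein FASTA.
#' @return A validated [ffa_panel()].
#' @export
load_panel <- function(path, seq_path = NULL) {
    if (!file.exists(path))
        ffa_stop("ffa_io_error", "panel table not found: %s", path)
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", quote = "",
                      na.strings = NULL, check.names = TRUE)
    missing_cols <- setdiff(PANEL_COLUMNS, names(tab))
    if (length(missing_cols) > 0L)
        ffa_stop("ffa_schema_error", "panel table %s is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
    bad <- setdiff(unique(tab$impact), IMPACT_LEVELS)
    if (length(bad) > 0L)
        ffa_stop("ffa_value_error",
                 "panel table %s: unknown impact value(s): %s", path,
                 paste(bad, collapse = ", "))
    sequences <- NULL
    if (!is.null(seq_path)) {
        if (!file.exists(seq_path))
            ffa_stop("ffa_io_error", "panel FASTA not found: %s", seq_path)
        ss <- Biostrings::readAAStringSet(seq_path)
        names(ss) <- sub("\\s.*$", "", names(ss))
        orphan <- setdiff(names(ss), tab$criterion_id)
        if (length(orphan) > 0L)
            ffa_stop("ffa_xref_error",
                     "FASTA id(s) with no criterion row: %s",
                     paste(orphan, collapse = ", "))
        sequences <- ss
    }
    ffa_panel(tab, sequences)
}

#' Write a panel to a TSV table and FASTA sequences
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p))` reproduces `p`.
#'
#' @param panel an `ffa_panel`.
#' @param path output path for the panel TSV.
#' @param seq_path optional output path for the panel-protein FASTA.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, seq_path = NULL) {
    utils::write.table(panel$criteria, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    if (!is.null(seq_path) && length(panel$sequences) > 0L) {
        ss <- Biostrings::AAStringSet(unlist(panel$sequences))
        Biostrings::writeXStringSet(ss, seq_path)
    }
    invisible(path)
}

#' @export
print.ffa_panel <- function(x, ...) {
    imp <- table(factor(x$criteria$impact, levels = IMPACT_LEVELS))
    req_ogs <- sum(x$groups$impact == "required")
    cat(sprintf(paste0("ffa_panel: %d criteria (%d positive, %d negative, ",
                       "%d required), %d OGs (%d required), %d sequences\n"),
                nrow(x$criteria), imp[["positive"]], imp[["negative"]],
                imp[["required"]], nrow(x$groups), req_ogs,
                length(x$sequences)))
    invisible(x)
}

#' Per-criterion domain-accession sets of a panel
#'
#' The query-side input of [filter_domain_complete()]: the domain families
#' each criterion protein is expected to carry, as a named list. Criteria
#' with an empty `domains` field map to empty sets (their hits pass the
#' domain-completeness test vacuously).
#'
#' @param panel an [ffa_panel()].
#' @return Named list: criterion id -> character vector of accessions.
#' @export
criterion_domains <- function(panel) {
    doms <- strsplit(panel$criteria$domains, ";", fixed = TRUE)
    doms <- lapply(doms, function(d) d[nzchar(d)])
    names(doms) <- panel$criteria$criterion_id
    doms
}

# Named list og_id -> member criterion ids, in panel order.
og_members <- function(panel) {
    split(panel$criteria$criterion_id, panel$criteria$og_id)
}
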