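# Engineering-suggestion report: which criterion proteins to insert/
# overexpress and which to delete/underexpress for a given strain.

#' Suggest engineering modifications for a strain
#'
#' For each absent positive-impact criterion, suggests insertion or
#' overexpression; for each unsatisfied required orthologous group, suggests
#' inserting one representative member (the first in panel order — one
#' enzyme suffices to satisfy a group, so backup co-members are not listed
#' separately); for each present negative-impact criterion, suggests
#' deletion or underexpression. Output order follows the panel.
#'
#' @param profile a [build_profile()] result.
#' @param panel the matching [ffa_panel()].
#' @return data.frame with columns `criterion_id`, `gene_symbol`, `action`
#'   (`"insert_or_overexpress"` or `"delete_or_underexpress"`) and `reason`
#'   (`"missing_positive"`, `"missing_required"` or `"present_negative"`).
#' @export
suggest_modifications <- function(profile, panel) {
    cr <- panel$criteria
    rep_of <- !duplicated(cr$og_id)  # first member of each OG in panel order
    rows <- list()
    for (i in seq_len(nrow(cr))) {
        id <- cr$criterion_id[i]
        present <- profile$presence[[id]]
        if (cr$impact[i] == "positive" && !present) {
            rows[[length(rows) + 1L]] <- data.frame(
                criterion_id = id, gene_symbol = cr$gene_symbol[i],
                action = "insert_or_overexpress", reason = "missing_positive")
        } else if (cr$impact[i] == "required" && rep_of[i] &&
                   !profile$og_satisfied[[cr$og_id[i]]]) {
            rows[[length(rows) + 1L]] <- data.frame(
                criterion_id = id, gene_symbol = cr$gene_symbol[i],
                action = "insert_or_overexpress", reason = "missing_required")
        } else if (cr$impact[i] == "negative" && present) {
            rows[[length(rows) + 1L]] <- data.frame(
                criterion_id = id, gene_symbol = cr$gene_symbol[i],
                action = "delete_or_underexpress", reason = "present_negative")
        }
    }
    if (length(rows) == 0L)
        return(data.frame(criterion_id = character(0),
                          gene_symbol = character(0),
                          action = character(0), reason = character(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
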