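# Homology and domain evidence: parsers for BLAST tabular (outfmt 6) and
# HMMER domtblout, the domain-completeness filter, and a dependency-free
# Smith-Waterman fallback aligner so the whole pipeline can run without
# external search binaries.

BLAST_COLUMNS <- c("query_id", "subject_id", "pct_identity", "align_length",
                   "mismatches", "gap_opens", "q_start", "q_end",
                   "s_start", "s_end", "e_value", "bit_score")
BLAST_NUMERIC <- BLAST_COLUMNS[3:12]

read_lines_arg <- function(x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x)
    else x
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Parses standard 12-column tab-separated alignment records
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore). Blank lines and lines starting with `#` are
#' ignored. Malformed lines raise a format error naming the line number.
#'
#' @param x a file path or a character vector of lines.
#' @return data.frame of homology hits with columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
parse_blast_tabular <- function(x) {
    lines <- read_lines_arg(x)
    trimmed <- trimws(lines)
    keep <- which(nzchar(trimmed) & !startsWith(trimmed, "#"))
    if (length(keep) == 0L) {
        out <- as.data.frame(setNames(
            c(list(character(0), character(0)),
              rep(list(numeric(0)), 10L)), BLAST_COLUMNS))
        return(out)
    }
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L)) {
        i <- which(nf != 12L)[1L]
        ffa_stop("ffa_format_error",
                 "BLAST tabular line %d: expected 12 tab-separated columns, got %d",
                 keep[i], nf[i])
    }
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
    num <- matrix(num, ncol = 10L)
    if (anyNA(num)) {
        i <- which(rowSums(is.na(num)) > 0L)[1L]
        ffa_stop("ffa_format_error",
                 "BLAST tabular line %d: unparsable numeric field", keep[i])
    }
    hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                       num, stringsAsFactors = FALSE)
    names(hits) <- BLAST_COLUMNS
    bad <- hits$q_start > hits$q_end | hits$s_start > hits$s_end |
        hits$e_value < 0
    if (any(bad))
        ffa_stop("ffa_format_error",
                 "BLAST tabular line %d: invalid coordinates or e-value",
                 keep[which(bad)[1L]])
    hits
}

#' Serialize homology hits back to 12-column BLAST tabular lines
#'
#' Inverse of [parse_blast_tabular()]: re-parsing the output reproduces the
#' input values exactly.
#'
#' @param hits data.frame as returned by [parse_blast_tabular()].
#' @param path optional file to write; if `NULL`, lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_blast_tabular <- function(hits, path = NULL) {
    cols <- lapply(hits[BLAST_COLUMNS], function(col)
        if (is.numeric(col)) vapply(col, format, "", digits = 17) else col)
    lines <- do.call(paste, c(cols, sep = "\t"))
    if (!is.null(path)) {
        writeLines(lines, path)
        return(invisible(lines))
    }
    lines
}

#' Parse HMMER per-domain tabular output (domtblout)
#'
#' Parses `hmmscan --domtblout` style output, in which the target is a
#' domain-family model and the query is a protein. `#` comment lines are
#' ignored. The domain accession's version suffix (e.g. `PF00109.27` ->
#' `PF00109`) is stripped; if the accession field is `-`, the target name is
#' used instead.
#'
#' @param x a file path or a character vector of lines.
#' @return data.frame with columns `protein_id`, `domain_accession`,
#'   `i_evalue`, `env_from`, `env_to` (1-based inclusive envelope
#'   coordinates).
#' @export
parse_domtblout <- function(x) {
    lines <- read_lines_arg(x)
    trimmed <- trimws(lines)
    keep <- which(nzchar(trimmed) & !startsWith(trimmed, "#"))
    empty <- data.frame(protein_id = character(0),
                        domain_accession = character(0),
                        i_evalue = numeric(0), env_from = integer(0),
                        env_to = integer(0))
    if (length(keep) == 0L) return(empty)
    rows <- vector("list", length(keep))
    for (k in seq_along(keep)) {
        f <- strsplit(trimmed[keep[k]], "[ \t]+")[[1L]]
        if (length(f) < 22L)
            ffa_stop("ffa_format_error",
                     "domtblout line %d: expected >= 22 whitespace-separated fields, got %d",
                     keep[k], length(f))
        acc <- if (f[2L] == "-") f[1L] else f[2L]
        acc <- sub("\\.\\d+$", "", acc)
        i_evalue <- suppressWarnings(as.numeric(f[13L]))
        env_from <- suppressWarnings(as.integer(f[20L]))
        env_to <- suppressWarnings(as.integer(f[21L]))
        if (is.na(i_evalue) || is.na(env_from) || is.na(env_to))
            ffa_stop("ffa_format_error",
                     "domtblout line %d: unparsable numeric field", keep[k])
        if (i_evalue < 0 || env_from > env_to)
            ffa_stop("ffa_format_error",
                     "domtblout line %d: invalid i-Evalue or envelope coordinates",
                     keep[k])
        rows[[k]] <- data.frame(protein_id = f[4L], domain_accession = acc,
                                i_evalue = i_evalue, env_from = env_from,
                                env_to = env_to)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-protein domain-accession sets from domain annotations
#'
#' Collapses parsed domtblout rows into the set of domain families observed
#' on each protein, keeping only annotations at or below the i-Evalue
#' threshold.
#'
#' @param annotations data.frame from [parse_domtblout()].
#' @param max_ievalue independent-domain e-value threshold (default `1e-5`).
#' @return Named list: protein id -> character vector of domain accessions.
#' @export
domain_sets <- function(annotations, max_ievalue = 1e-5) {
    ann <- annotations[annotations$i_evalue <= max_ievalue, , drop = FALSE]
    lapply(split(ann$domain_accession, ann$protein_id), unique)
}

#' Domain-completeness filter for homology hits
#'
#' Applies the stringent evidence rule at the core of the screen: a homology
#' hit is kept only if its e-value passes the threshold *and* the subject
#' protein carries every domain family of the query criterion protein.
#' Criteria with no known domains pass the domain test vacuously; domain
#' comparison is set inclusion on accessions (multiplicity and order are
#' ignored).
#'
#' @param hits data.frame of homology hits ([parse_blast_tabular()]).
#' @param query_domains named list criterion_id -> domain accessions, e.g.
#'   from `criterion_domains()` applied to a panel (see [ffa_panel()]).
#' @param subject_domains named list protein_id -> domain accessions (from
#'   [domain_sets()]), a raw annotation data.frame (then filtered at
#'   `max_ievalue`), or `NULL` meaning no domain evidence is available, in
#'   which case the domain test is skipped with a warning.
#' @param max_evalue homology e-value threshold (default `1e-5`).
#' @param max_ievalue per-domain i-Evalue threshold used when
#'   `subject_domains` is an annotation data.frame (default `1e-5`).
#' @return The retained subset of `hits` (row order preserved).
#' @export
filter_domain_complete <- function(hits, query_domains, subject_domains,
                                   max_evalue = 1e-5, max_ievalue = 1e-5) {
    if (nrow(hits) == 0L) return(hits)
    unknown <- setdiff(unique(hits$query_id), names(query_domains))
    if (length(unknown) > 0L)
        ffa_stop("ffa_config_error",
                 "hit query id(s) absent from the query domain map: %s",
                 paste(unknown, collapse = ", "))
    keep_e <- hits$e_value <= max_evalue
    if (is.null(subject_domains)) {
        warning("no subject domain evidence supplied; ",
                "domain-completeness test skipped", call. = FALSE)
        return(hits[keep_e, , drop = FALSE])
    }
    if (is.data.frame(subject_domains))
        subject_domains <- domain_sets(subject_domains, max_ievalue)
    keep_d <- vapply(seq_len(nrow(hits)), function(i) {
        qd <- query_domains[[hits$query_id[i]]]
        if (length(qd) == 0L) return(TRUE)
        sd <- subject_domains[[hits$subject_id[i]]]
        all(qd %in% sd)
    }, logical(1))
    hits[keep_e & keep_d, , drop = FALSE]
}

#' Local (Smith-Waterman) alignment with simple scoring
#'
#' Dependency-free local aligner used to generate homology evidence when no
#' external search output is available: match/mismatch scoring with a linear
#' gap penalty. Returns the maximal local score and one optimal span pair;
#' ties are broken deterministically toward the smallest `(q_end, s_end)`.
#'
#' @param query,subject amino-acid sequences (character scalars or
#'   `AAString`).
#' @param match match score (default `1`).
#' @param mismatch mismatch penalty (default `-1`).
#' @param gap linear gap penalty per gapped residue (default `-2`).
#' @return List with `score`, `q_span` and `s_span` (integer `c(start, end)`,
#'   1-based inclusive, empty when no positive-scoring alignment exists),
#'   `align_length`, `matches` and `gaps`.
#' @export
align_local <- function(query, subject, match = 1, mismatch = -1, gap = -2) {
    query <- as.character(query)
    subject <- as.character(subject)
    r <- sw_align_cpp(query, subject, match, mismatch, gap)
    if (r$score <= 0)
        return(list(score = 0, q_span = integer(0), s_span = integer(0),
                    align_length = 0L, matches = 0L, gaps = 0L))
    list(score = r$score,
         q_span = c(r$q_start, r$q_end), s_span = c(r$s_start, r$s_end),
         align_length = r$align_length, matches = r$matches, gaps = r$gaps)
}

#' Search a proteome with the fallback aligner
#'
#' Aligns every panel criterion sequence against every proteome protein with
#' [align_local()] and emits BLAST-tabular-shaped hits for alignments scoring
#' at least `min_score_frac` of the query's self-alignment score. The nominal
#' e-value is `len_q * len_s * 2^-score`, so retained hits fall far below the
#' conventional 1e-5 homology threshold while spurious decoy alignments do
#' not.
#'
#' @param panel an [ffa_panel()] carrying criterion sequences.
#' @param proteome named character vector or `AAStringSet` of strain
#'   proteins.
#' @param match,mismatch,gap scoring parameters passed to [align_local()].
#' @param min_score_frac minimum fraction of the query self-score for a hit
#'   (default `0.3`).
#' @return data.frame of hits in the [parse_blast_tabular()] layout.
#' @export
internal_search <- function(panel, proteome, match = 1, mismatch = -1,
                            gap = -2, min_score_frac = 0.3) {
    if (methods::is(proteome, "XStringSet"))
        proteome <- setNames(as.character(proteome), names(proteome))
    qids <- names(panel$sequences)
    if (length(qids) == 0L)
        ffa_stop("ffa_config_error",
                 "panel carries no sequences; internal search needs them")
    rows <- list()
    for (q in qids) {
        qseq <- panel$sequences[[q]]
        self_score <- match * nchar(qseq)
        for (s in names(proteome)) {
            a <- align_local(qseq, proteome[[s]], match, mismatch, gap)
            if (a$score < min_score_frac * self_score) next
            e_val <- nchar(qseq) * nchar(proteome[[s]]) * 2^(-a$score)
            rows[[length(rows) + 1L]] <- data.frame(
                query_id = q, subject_id = s,
                pct_identity = round(100 * a$matches / a$align_length, 2),
                align_length = a$align_length,
                mismatches = a$align_length - a$matches - a$gaps,
                gap_opens = a$gaps,
                q_start = a$q_span[1L], q_end = a$q_span[2L],
                s_start = a$s_span[1L], s_end = a$s_span[2L],
                e_value = e_val, bit_score = a$score)
        }
    }
    if (length(rows) == 0L)
        return(parse_blast_tabular(character(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
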