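# Phase 2 of the evaluation: sign-constrained weighted scoring, cohort
# min-max normalization, ranking, the exact 1-D 2-means category boundary,
# categorization, and reference-anchored weight calibration.

CATEGORY_LEVELS <- c("Top-ranked", "Positive", "Negative")

#' Reference-strain configuration
#'
#' Names the experimentally characterized strains that anchor the score
#' scale: positive references (strains engineered successfully for FFA
#' production) must outrank negative references (poor producers); the upper
#' boundary strain separates "Top-ranked" from "Positive" and the lower
#' boundary strain (by default found with [find_boundary()]) separates
#' "Positive" from "Negative". Defaults name the classical cyanobacterial
#' reference strains.
#'
#' @param positive_refs character vector of positive reference strain ids.
#' @param negative_refs character vector of negative reference strain ids.
#' @param upper_boundary strain id of the upper category boundary, or `NULL`
#'   to use the highest-scoring positive reference.
#' @param lower_boundary strain id of the lower category boundary, or `NULL`
#'   to determine it with [find_boundary()].
#' @return An object of class `reference_config`.
#' @export
reference_config <- function(positive_refs = c("Synechococcus sp. PCC 7002",
                                               "Synechocystis sp. PCC 6803",
                                               "Synechococcus elongatus PCC 7942"),
                             negative_refs = c("Arthrospira platensis NIES-39",
                                               "Lyngbya sp. PCC 8106"),
                             upper_boundary = "Synechococcus sp. PCC 7002",
                             lower_boundary = "Pseudanabaena sp. PCC 7367") {
    if (length(intersect(positive_refs, negative_refs)) > 0L)
        ffa_stop("ffa_config_error",
                 "positive and negative reference sets overlap")
    structure(list(positive_refs = positive_refs,
                   negative_refs = negative_refs,
                   upper_boundary = upper_boundary,
                   lower_boundary = lower_boundary),
              class = "reference_config")
}

#' Unit weights for a panel
#'
#' The default weight vector: +1 for criteria with positive or required
#' impact, -1 for negative impact.
#'
#' @param panel an [ffa_panel()].
#' @return Named numeric vector over all panel criteria.
#' @export
unit_weights <- function(panel) {
    setNames(ifelse(panel$criteria$impact == "negative", -1, 1),
             panel$criteria$criterion_id)
}

#' Validate sign constraints of a weight vector
#'
#' Weights must be positive for positive/required criteria and negative for
#' negative criteria.
#'
#' @param weights named numeric vector.
#' @param panel an [ffa_panel()].
#' @return `TRUE` invisibly; raises a configuration error otherwise.
#' @export
validate_weights <- function(weights, panel) {
    ids <- panel$criteria$criterion_id
    missing <- setdiff(ids, names(weights))
    if (length(missing) > 0L)
        ffa_stop("ffa_config_error", "missing weight(s) for criterion: %s",
                 paste(missing, collapse = ", "))
    sign_ok <- ifelse(panel$criteria$impact == "negative",
                      weights[ids] < 0, weights[ids] > 0)
    if (!all(sign_ok))
        ffa_stop("ffa_config_error",
                 "weight sign violates impact class for: %s",
                 paste(ids[!sign_ok], collapse = ", "))
    invisible(TRUE)
}

#' Raw strain score
#'
#' The weighted sum over panel criteria of the strain's feature vector:
#' presence indicators (default) or hit counts.
#'
#' @param profile a [build_profile()] result.
#' @param weights named numeric weights covering every panel criterion.
#' @param feature_mode `"presence"` (default) or `"count"`.
#' @return Numeric scalar.
#' @export
score_raw <- function(profile, weights, feature_mode = c("presence", "count")) {
    feature_mode <- match.arg(feature_mode)
    ids <- names(profile$hit_counts)
    missing <- setdiff(ids, names(weights))
    if (length(missing) > 0L)
        ffa_stop("ffa_config_error", "missing weight(s) for criterion: %s",
                 paste(missing, collapse = ", "))
    x <- if (feature_mode == "presence") as.numeric(profile$presence)
         else as.numeric(profile$hit_counts)
    sum(weights[ids] * x)
}

#' Min-max normalize cohort scores
#'
#' Rescales raw scores to `[0, 1]` over the cohort: `(x - min) / (max -
#' min)`. When all raw scores are equal every strain maps to 0.5.
#'
#' @param raw named numeric vector of raw scores (names = strain ids).
#' @return Named numeric vector in `[0, 1]`.
#' @export
normalize_scores <- function(raw) {
    if (length(raw) == 0L)
        ffa_stop("ffa_value_error", "cannot normalize an empty cohort")
    rng <- range(raw)
    if (rng[1L] == rng[2L])
        return(setNames(rep(0.5, length(raw)), names(raw)))
    (raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Rank a cohort by normalized score
#'
#' Descending by score; ties broken by ascending lexicographic strain id;
#' ranks are `1..N` without gaps.
#'
#' @param normalized named numeric vector of normalized scores.
#' @return data.frame with columns `strain_id`, `normalized_score`, `rank`,
#'   ordered by rank.
#' @export
rank_cohort <- function(normalized) {
    ord <- order(-normalized, names(normalized), method = "radix")
    data.frame(strain_id = names(normalized)[ord],
               normalized_score = as.numeric(normalized[ord]),
               rank = seq_along(normalized))
}

# Exact 1-D 2-means: the optimal 2-partition minimizing within-cluster SSE is
# a contiguous split of the sorted values; scan all n-1 splits with prefix
# sums. Returns the index k of the last element of the lower cluster.
split_1d_2means <- function(x_sorted) {
    n <- length(x_sorted)
    cs <- cumsum(x_sorted)
    cs2 <- cumsum(x_sorted^2)
    k <- seq_len(n - 1L)
    sse_lo <- cs2[k] - cs[k]^2 / k
    sse_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    which.min(sse_lo + sse_hi)
}

#' Find the lower category boundary strain
#'
#' Splits the cohort's 1-D scores into two clusters by K-means (k = 2,
#' solved exactly: the optimal 1-D 2-partition is a contiguous split of the
#' sorted scores, found by scanning all splits for minimum within-cluster
#' sum of squares) and returns the lowest-scoring strain of the cluster
#' containing all positive references. That strain marks the boundary
#' between the "Positive" and "Negative" categories.
#'
#' @param normalized named numeric vector of cohort scores.
#' @param positive_refs strain ids of the positive references; all must fall
#'   in the same cluster.
#' @param seed unused (the solver is deterministic); retained for API
#'   stability.
#' @return The boundary strain id.
#' @export
find_boundary <- function(normalized, positive_refs, seed = 1L) {
    if (length(normalized) < 2L)
        ffa_stop("ffa_value_error",
                 "boundary detection needs at least 2 strains")
    missing <- setdiff(positive_refs, names(normalized))
    if (length(missing) > 0L)
        ffa_stop("ffa_config_error",
                 "positive reference(s) missing from cohort: %s",
                 paste(missing, collapse = ", "))
    ord <- order(normalized, names(normalized), method = "radix")
    x <- normalized[ord]
    k <- split_1d_2means(as.numeric(x))
    lower <- names(x)[seq_len(k)]
    upper <- names(x)[(k + 1L):length(x)]
    in_lower <- positive_refs %in% lower
    if (any(in_lower) && !all(in_lower))
        ffa_stop("ffa_boundary_error",
                 "positive references split across the two score clusters; boundary undefined")
    cluster <- if (all(in_lower)) lower else upper
    cluster[1L]
}

#' Assign a category from boundary scores
#'
#' Strains scoring strictly above the upper boundary are "Top-ranked";
#' strains above the lower boundary (but not above the upper) are
#' "Positive"; the rest are "Negative". "Higher than" is strict: a score
#' equal to a boundary falls below it.
#'
#' @param score numeric vector of scores to categorize.
#' @param upper_score,lower_score boundary scores (`lower_score <=
#'   upper_score`).
#' @return Factor with levels `Top-ranked`, `Positive`, `Negative`.
#' @export
categorize <- function(score, upper_score, lower_score) {
    if (lower_score > upper_score)
        ffa_stop("ffa_config_error",
                 "lower boundary score exceeds upper boundary score")
    out <- ifelse(score > upper_score, "Top-ranked",
                  ifelse(score > lower_score, "Positive", "Negative"))
    factor(out, levels = CATEGORY_LEVELS)
}

# strains x criteria feature matrix from a list of profiles
feature_matrix <- function(profiles, feature_mode = "presence") {
    ids <- vapply(profiles, `[[`, "", "strain_id")
    X <- t(vapply(profiles, function(p) {
        if (feature_mode == "presence") as.numeric(p$presence)
        else as.numeric(p$hit_counts)
    }, numeric(length(profiles[[1L]]$hit_counts))))
    rownames(X) <- ids
    colnames(X) <- names(profiles[[1L]]$hit_counts)
    X
}

#' Calibrate weights against reference strains
#'
#' Searches for sign-constrained weights under which every positive
#' reference out-scores every negative reference with the largest possible
#' margin. The objective is the SVM-style normalized margin — the minimum
#' pairwise raw-score difference (positive minus negative reference) divided
#' by the Euclidean norm of the weight vector — maximized by deterministic
#' coordinate ascent over log-magnitudes (multiplicative steps 2, 1.5, 1/1.5
#' and 1/2; magnitudes clamped to `[0.01, 100]`), starting from unit
#' magnitudes. Signs are fixed by impact class, so the sign constraints hold
#' by construction. If no improvement leaves the margin positive the result
#' carries `separable = FALSE`.
#'
#' @param profiles list of [build_profile()] results (the cohort, including
#'   all reference strains).
#' @param panel the [ffa_panel()] defining impact classes.
#' @param refs a [reference_config()] with non-empty, disjoint reference
#'   sets.
#' @param seed unused (the ascent is deterministic); retained for API
#'   stability.
#' @param max_iter maximum number of coordinate-ascent passes (default 50).
#' @param feature_mode `"presence"` (default) or `"count"`.
#' @return Named numeric weight vector with attributes `margin` (raw-score
#'   margin of the worst reference pair) and `separable` (logical).
#' @export
calibrate_weights <- function(profiles, panel, refs, seed = 1L,
                              max_iter = 50L,
                              feature_mode = c("presence", "count")) {
    feature_mode <- match.arg(feature_mode)
    X <- feature_matrix(profiles, feature_mode)
    need <- c(refs$positive_refs, refs$negative_refs)
    missing <- setdiff(need, rownames(X))
    if (length(missing) > 0L)
        ffa_stop("ffa_config_error",
                 "reference strain(s) missing from cohort: %s",
                 paste(missing, collapse = ", "))
    ids <- panel$criteria$criterion_id
    X <- X[, ids, drop = FALSE]
    signs <- ifelse(panel$criteria$impact == "negative", -1, 1)
    mag <- rep(1, length(ids))
    Xp <- X[refs$positive_refs, , drop = FALSE]
    Xn <- X[refs$negative_refs, , drop = FALSE]

    raw_margin <- function(w) min(Xp %*% w) - max(Xn %*% w)
    objective <- function(m) {
        w <- signs * m
        raw_margin(w) / sqrt(sum(w^2))
    }
    cur <- objective(mag)
    factors <- c(2, 1.5, 1 / 1.5, 1 / 2)
    for (pass in seq_len(max_iter)) {
        improved <- FALSE
        for (j in seq_along(mag)) {
            best_obj <- cur
            best_m <- mag[j]
            for (f in factors) {
                mj <- min(100, max(0.01, mag[j] * f))
                if (mj == mag[j]) next
                m2 <- mag
                m2[j] <- mj
                o <- objective(m2)
                if (o > best_obj + 1e-12) {
                    best_obj <- o
                    best_m <- mj
                }
            }
            if (best_m != mag[j]) {
                mag[j] <- best_m
                cur <- best_obj
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    w <- setNames(signs * mag, ids)
    attr(w, "margin") <- raw_margin(w)
    attr(w, "separable") <- raw_margin(w) > 0
    w
}

#' Score, rank and categorize a cohort of strain profiles
#'
#' Runs the full second phase on a cohort: raw scores, min-max
#' normalization, ranking, boundary detection and categorization. The upper
#' boundary is the configured strain (or, when unset, the highest-scoring
#' positive reference); the lower boundary is the configured strain or the
#' [find_boundary()] result. With `refs = NULL` the cohort is ranked without
#' categories.
#'
#' @param profiles list of [build_profile()] results.
#' @param panel the matching [ffa_panel()].
#' @param weights named weight vector (default [unit_weights()]).
#' @param refs a [reference_config()] whose strains are cohort members, or
#'   `NULL`.
#' @param feature_mode `"presence"` (default) or `"count"`.
#' @return data.frame (class `ffa_ranking`) with columns `strain_id`,
#'   `raw_score`, `normalized_score`, `rank` and (with references)
#'   `category`; attributes `upper_boundary`/`lower_boundary` name the
#'   boundary strains and `raw_scores` carries the named raw-score vector.
#' @export
score_cohort <- function(profiles, panel, weights = unit_weights(panel),
                         refs = NULL,
                         feature_mode = c("presence", "count")) {
    feature_mode <- match.arg(feature_mode)
    raw <- vapply(profiles, score_raw, numeric(1), weights = weights,
                  feature_mode = feature_mode)
    names(raw) <- vapply(profiles, `[[`, "", "strain_id")
    if (anyDuplicated(names(raw)))
        ffa_stop("ffa_value_error", "duplicated strain id(s) in cohort")
    normalized <- normalize_scores(raw)
    tab <- rank_cohort(normalized)
    tab$raw_score <- as.numeric(raw[tab$strain_id])
    tab <- tab[, c("strain_id", "raw_score", "normalized_score", "rank")]
    upper_id <- lower_id <- NULL
    if (!is.null(refs)) {
        missing <- setdiff(refs$positive_refs, names(normalized))
        if (length(missing) > 0L)
            ffa_stop("ffa_config_error",
                     "positive reference(s) missing from cohort: %s",
                     paste(missing, collapse = ", "))
        upper_id <- refs$upper_boundary
        if (is.null(upper_id) || !(upper_id %in% names(normalized))) {
            pos <- normalized[refs$positive_refs]
            upper_id <- names(pos)[order(-pos, names(pos))][1L]
        }
        lower_id <- refs$lower_boundary
        if (is.null(lower_id) || !(lower_id %in% names(normalized)))
            lower_id <- find_boundary(normalized, refs$positive_refs)
        tab$category <- categorize(tab$normalized_score,
                                   normalized[[upper_id]],
                                   normalized[[lower_id]])
    }
    structure(tab, class = c("ffa_ranking", "data.frame"),
              upper_boundary = upper_id, lower_boundary = lower_id,
              raw_scores = raw)
}

#' Evaluate a new strain against a pre-evaluated cohort
#'
#' The new strain's raw score joins the cohort's stored raw scores;
#' normalization is recomputed over the union (so normalized values may
#' shift), ranks reassigned, and the category taken against the renormalized
#' boundary strains. Returns the four headline outputs — score, category,
#' recommendation and rank — plus the updated ranking view; the stored
#' cohort scores are not modified.
#'
#' @param new_profile the new strain's [build_profile()] result.
#' @param cohort_raws named numeric vector of the cohort's raw scores under
#'   the same weights.
#' @param weights named weight vector covering the panel.
#' @param refs a [reference_config()]; boundary strains are resolved within
#'   the extended cohort.
#' @param panel the [ffa_panel()]; when supplied, engineering
#'   recommendations ([suggest_modifications()]) are included.
#' @param feature_mode `"presence"` (default) or `"count"`.
#' @return An object of class `ffa_evaluation`: list with `strain_id`,
#'   `score` (normalized), `raw_score`, `category`, `recommendation`
#'   (data.frame, empty without a panel), `rank`, and `ranking` (the updated
#'   cohort table).
#' @export
evaluate_new_strain <- function(new_profile, cohort_raws, weights, refs,
                                panel = NULL,
                                feature_mode = c("presence", "count")) {
    feature_mode <- match.arg(feature_mode)
    sid <- new_profile$strain_id
    if (sid %in% names(cohort_raws))
        ffa_stop("ffa_value_error",
                 "strain id '%s' already present in the cohort", sid)
    raw_new <- score_raw(new_profile, weights, feature_mode)
    raw <- c(cohort_raws, setNames(raw_new, sid))
    normalized <- normalize_scores(raw)
    tab <- rank_cohort(normalized)
    tab$raw_score <- as.numeric(raw[tab$strain_id])
    upper_id <- refs$upper_boundary
    if (is.null(upper_id) || !(upper_id %in% names(normalized))) {
        pos <- normalized[intersect(refs$positive_refs, names(normalized))]
        if (length(pos) == 0L)
            ffa_stop("ffa_config_error",
                     "no positive reference present in cohort")
        upper_id <- names(pos)[order(-pos, names(pos))][1L]
    }
    lower_id <- refs$lower_boundary
    if (is.null(lower_id) || !(lower_id %in% names(normalized)))
        lower_id <- find_boundary(normalized, refs$positive_refs)
    tab$category <- categorize(tab$normalized_score,
                               normalized[[upper_id]],
                               normalized[[lower_id]])
    rec <- if (!is.null(panel)) suggest_modifications(new_profile, panel)
           else data.frame(criterion_id = character(0),
                           gene_symbol = character(0),
                           action = character(0), reason = character(0))
    structure(list(strain_id = sid,
                   score = as.numeric(normalized[[sid]]),
                   raw_score = raw_new,
                   category = as.character(tab$category[tab$strain_id == sid]),
                   recommendation = rec,
                   rank = tab$rank[tab$strain_id == sid],
                   ranking = tab),
              class = "ffa_evaluation")
}

#' @export
print.ffa_evaluation <- function(x, ...) {
    cat(sprintf("ffa_evaluation '%s': score %.4f, category %s, rank %d/%d, %d recommendation(s)\n",
                x$strain_id, x$score, x$category, x$rank, nrow(x$ranking),
                nrow(x$recommendation)))
    invisible(x)
}

#' Read and write weight vectors as TSV
#'
#' Two-column TSV (`criterion_id`, `weight`) used to persist calibrated
#' weights.
#'
#' @param path file path.
#' @param weights named numeric vector.
#' @return `read_weights()`: named numeric vector; `write_weights()`:
#'   `path`, invisibly.
#' @export
read_weights <- function(path) {
    if (!file.exists(path))
        ffa_stop("ffa_io_error", "weights file not found: %s", path)
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "numeric"))
    if (!all(c("criterion_id", "weight") %in% names(tab)))
        ffa_stop("ffa_schema_error",
                 "weights file must have columns criterion_id, weight")
    setNames(tab$weight, tab$criterion_id)
}

#' @rdname read_weights
#' @export
write_weights <- function(weights, path) {
    utils::write.table(data.frame(criterion_id = names(weights),
                                  weight = as.numeric(weights)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
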