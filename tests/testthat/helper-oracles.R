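# Independent oracles used against the implementation. These deliberately
# use naive enumeration/looping, not the production code paths.

# Brute-force local alignment: enumerate every monotone matching of residue
# positions (the substitution columns of a candidate local alignment);
# unpaired residues between consecutive matched pairs are gap columns at the
# linear gap cost. The local-alignment optimum is the best matching score,
# floored at 0.
brute_local_score <- function(q, s, match = 1, mismatch = -1, gap = -2) {
    qc <- strsplit(q, "")[[1L]]
    sc <- strsplit(s, "")[[1L]]
    n <- length(qc)
    m <- length(sc)
    best <- 0
    for (k in seq_len(min(n, m))) {
        qi <- utils::combn(n, k, simplify = FALSE)
        si <- utils::combn(m, k, simplify = FALSE)
        for (a in qi) {
            for (b in si) {
                sc_pairs <- sum(ifelse(qc[a] == sc[b], match, mismatch))
                gaps <- sum(diff(a) - 1L) + sum(diff(b) - 1L)
                best <- max(best, sc_pairs + gap * gaps)
            }
        }
    }
    best
}

# Exhaustive minimum-SSE 2-partition of 1-D scores: all n-1 contiguous
# splits of the sorted values, SSE computed naively per split.
oracle_split <- function(scores) {
    ord <- order(scores, names(scores), method = "radix")
    x <- scores[ord]
    n <- length(x)
    best <- Inf
    bestk <- NA_integer_
    for (k in seq_len(n - 1L)) {
        lo <- x[seq_len(k)]
        hi <- x[(k + 1L):n]
        sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
        if (sse < best) {
            best <- sse
            bestk <- k
        }
    }
    list(lower = names(x)[seq_len(bestk)],
         upper = names(x)[(bestk + 1L):n])
}

# Lowest member of the cluster holding all positive references (assumes the
# references share a cluster).
oracle_boundary <- function(scores, refs) {
    sp <- oracle_split(scores)
    cl <- if (all(refs %in% sp$lower)) sp$lower else sp$upper
    cl[1L]
}

# Brute-force dot product over the feature vector.
oracle_score <- function(profile, weights, feature_mode = "presence") {
    total <- 0
    for (id in names(profile$hit_counts)) {
        x <- if (feature_mode == "presence") {
            if (profile$presence[[id]]) 1 else 0
        } else {
            profile$hit_counts[[id]]
        }
        total <- total + weights[[id]] * x
    }
    total
}

# Set-inclusion oracle for the domain-completeness rule.
oracle_domain_keep <- function(qd, sd, e_value, max_evalue) {
    e_value <= max_evalue && all(qd %in% sd)
}

# Small hand-built panel shared across tests: 2 positive, 1 negative,
# 1 required OG with a backup co-member (5 criteria, 4 OGs).
tiny_panel <- function(with_seqs = FALSE) {
    criteria <- data.frame(
        criterion_id = c("c1", "c2", "c3", "c4", "c5"),
        gene_symbol = c("aas", "fadD", "aap", "pps", "ppdK"),
        kegg_ko = c("K05939", "K01897", "", "K01007", "K01006"),
        ec_number = c("", "", "", "2.7.9.2", "2.7.9.1"),
        impact = c("positive", "positive", "negative", "required", "required"),
        og_id = c("OG1", "OG2", "OG3", "OG4", "OG4"),
        domains = c("D1;D2", "D3", "", "D4", "D5"),
        action_hint = c("insertion", "overexpression", "deletion",
                        "present_required", "present_required"))
    seqs <- NULL
    if (with_seqs) {
        seqs <- setNames(with_seed(99, vapply(rep(60, 5),
                                              ffascreen:::random_aa, "")),
                         criteria$criterion_id)
    }
    ffa_panel(criteria, seqs)
}

with_seed <- ffascreen:::with_seed

# Hits data.frame in the parsed BLAST layout with strong defaults.
make_hits <- function(query_id, subject_id, e_value = 1e-30) {
    n <- length(query_id)
    data.frame(query_id = query_id, subject_id = subject_id,
               pct_identity = rep(95, n), align_length = rep(100, n),
               mismatches = rep(5, n), gap_opens = rep(0, n),
               q_start = rep(1, n), q_end = rep(100, n),
               s_start = rep(1, n), s_end = rep(100, n),
               e_value = rep_len(e_value, n), bit_score = rep(200, n))
}

# Profile with a stated presence set, bypassing the search path.
presence_profile <- function(panel, present, strain_id = "S") {
    ffascreen:::truth_profile(panel, present, strain_id)
}
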