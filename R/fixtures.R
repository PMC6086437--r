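# Synthetic-data generator: panels, proteomes, evidence files and whole
# cohorts with known ground truth, so every pipeline stage is testable
# without external downloads or search binaries. All outputs are
# deterministic given the seed. Synthetic domain accessions live in a
# reserved SYND namespace that cannot collide with real Pfam ids; all
# emitted objects are synthetic stand-ins, not curated biology.

#' Cohort-simulation settings
#'
#' Defaults emulate the screening study conditions: a 140-strain cohort;
#' required criteria present in most strains (over 70% of real strains carry
#' the complete synthesis route, so `required = 0.9`), positive and negative
#' criteria at 0.5; 5 decoy proteins per strain; homolog copies mutated at
#' 5% per residue (within-clade ortholog divergence).
#'
#' @param n_strains number of strains to simulate (default 140).
#' @param presence_probability named probabilities per impact class.
#' @param decoys_per_strain decoy proteins per proteome (default 5).
#' @param mutation_rate per-residue substitution probability for homolog
#'   copies (default 0.05).
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_strains = 140L,
                        presence_probability = c(positive = 0.5,
                                                 negative = 0.5,
                                                 required = 0.9),
                        decoys_per_strain = 5L,
                        mutation_rate = 0.05,
                        seed = 1L) {
    if (n_strains < 1L)
        ffa_stop("ffa_value_error", "n_strains must be >= 1")
    p <- presence_probability[IMPACT_LEVELS]
    if (anyNA(p) || any(p < 0) || any(p > 1))
        ffa_stop("ffa_value_error",
                 "presence_probability needs values in [0,1] for %s",
                 paste(IMPACT_LEVELS, collapse = ", "))
    if (mutation_rate < 0 || mutation_rate > 1)
        ffa_stop("ffa_value_error", "mutation_rate must be in [0,1]")
    structure(list(n_strains = as.integer(n_strains),
                   presence_probability = p,
                   decoys_per_strain = as.integer(decoys_per_strain),
                   mutation_rate = mutation_rate,
                   seed = as.integer(seed)),
              class = "cohort_spec")
}

#' Generate a synthetic criteria panel
#'
#' Builds a panel with random amino-acid sequences (length 120-400), 0 to
#' `n_domains_max` synthetic domain accessions per criterion, and required
#' criteria distributed over `n_required_ogs` orthologous groups; when
#' `n_required > n_required_ogs` the surplus criteria become backup
#' co-members of existing required groups. The first required groups carry
#' the classical gene labels of the fatty-acid synthesis steps (pps/ppdK,
#' odhB, pyk); everything else is synthetic. Defaults emulate the curated
#' 64-protein panel with 12 required groups.
#'
#' @param n_positive,n_negative,n_required criteria counts per impact class.
#' @param n_required_ogs number of required orthologous groups
#'   (`n_required >= n_required_ogs >= 1`).
#' @param n_domains_max maximum synthetic domains per criterion (default 3).
#' @param seed RNG seed.
#' @return A validated [ffa_panel()] with sequences.
#' @export
make_panel <- function(n_positive = 40L, n_negative = 12L, n_required = 12L,
                       n_required_ogs = 12L, n_domains_max = 3L, seed = 1L) {
    if (n_required_ogs < 1L || n_required < n_required_ogs)
        ffa_stop("ffa_value_error",
                 "need n_required >= n_required_ogs >= 1 (got %d, %d)",
                 n_required, n_required_ogs)
    with_seed(seed, {
        n <- n_positive + n_negative + n_required
        ids <- c(sprintf("POS%03d", seq_len(n_positive)),
                 sprintf("NEG%03d", seq_len(n_negative)),
                 sprintf("REQ%03d", seq_len(n_required)))
        impact <- rep(IMPACT_LEVELS[c(1L, 2L, 3L)],
                      c(n_positive, n_negative, n_required))
        og <- c(sprintf("OGP%03d", seq_len(n_positive)),
                sprintf("OGN%03d", seq_len(n_negative)),
                sprintf("OGR%03d",
                        c(seq_len(n_required_ogs),
                          rep_len(seq_len(n_required_ogs),
                                  n_required - n_required_ogs))))
        gene <- sprintf("syng%03d", seq_len(n))
        kegg <- sprintf("K9%04d", seq_len(n))
        ec <- rep("", n)
        # classical labels for the first required steps
        named <- list(c("pps", "K01007", "2.7.9.2"),
                      c("odhB", "K00627", "2.3.1.12"),
                      c("pyk", "K00873", "2.7.1.40"))
        for (i in seq_len(min(n_required_ogs, 3L))) {
            j <- n_positive + n_negative + i
            gene[j] <- named[[i]][1L]
            kegg[j] <- named[[i]][2L]
            ec[j] <- named[[i]][3L]
        }
        # the first backup co-member of OGR001 is the backup dikinase
        if (n_required > n_required_ogs) {
            j <- n_positive + n_negative + n_required_ogs + 1L
            gene[j] <- "ppdK"
            kegg[j] <- "K01006"
            ec[j] <- "2.7.9.1"
        }
        action <- ifelse(impact == "positive",
                         sample(c("insertion", "overexpression"), n,
                                replace = TRUE),
                         ifelse(impact == "negative",
                                sample(c("deletion", "underexpression"), n,
                                       replace = TRUE),
                                "present_required"))
        pool <- sprintf("SYND%05d", seq_len(max(2L * n, 40L)))
        domains <- vapply(seq_len(n), function(i) {
            k <- sample(0:n_domains_max, 1L)
            paste(sample(pool, k), collapse = ";")
        }, "")
        sequences <- setNames(
            vapply(sample(120:400, n, replace = TRUE), random_aa, ""), ids)
        criteria <- data.frame(criterion_id = ids, gene_symbol = gene,
                               kegg_ko = kegg, ec_number = ec,
                               impact = impact, og_id = og,
                               domains = domains, action_hint = action)
        ffa_panel(criteria, sequences)
    })
}

# Ground-truth profile for a known presence set (one hit per present
# criterion).
truth_profile <- function(panel, present, strain_id) {
    ids <- panel$criteria$criterion_id
    counts <- setNames(as.integer(ids %in% present), ids)
    profile_from_counts(strain_id, counts, panel)
}

mutate_sequence <- function(seq, rate) {
    if (rate <= 0) return(seq)
    chars <- strsplit(seq, "")[[1L]]
    hit <- runif(length(chars)) < rate
    if (any(hit))
        chars[hit] <- vapply(chars[hit], function(a)
            sample(setdiff(AA_ALPHABET20, a), 1L), "")
    paste(chars, collapse = "")
}

# Decoy amino-acid sequence rejected until its local-alignment score against
# every panel sequence stays below 30% of the shorter sequence's length
# (match = 1), keeping decoys unambiguously non-homologous.
make_decoy <- function(panel, len) {
    repeat {
        d <- random_aa(len)
        ok <- all(vapply(panel$sequences, function(q) {
            a <- align_local(q, d, 1, -1, -2)
            a$score < 0.3 * min(nchar(q), len)
        }, logical(1)))
        if (ok) return(d)
    }
}

format_domtbl_row <- function(protein_id, qlen, acc, i_evalue, idx, of,
                              env_from, env_to) {
    base <- sub("\\.\\d+$", "", acc)
    paste(base, acc, "100", protein_id, "-", qlen,
          "1e-12", "150.0", "0.1", idx, of, format(i_evalue), format(i_evalue),
          "140.0", "0.1", "1", "100", env_from, env_to, env_from, env_to,
          "0.95", "-", sep = " ")
}

#' Generate a synthetic proteome with consistent evidence files
#'
#' Emits one strain's proteome FASTA together with homology (BLAST tabular)
#' and domain (domtblout) evidence consistent with it: each criterion in
#' `present` contributes a mutated copy of its panel sequence with a
#' below-threshold homology hit and a complete domain annotation; decoy
#' proteins contribute only above-threshold noise hits. The ground-truth
#' profile marks exactly `present`.
#'
#' @param panel an [ffa_panel()] with sequences.
#' @param present character vector of present criterion ids.
#' @param spec a [cohort_spec()] (mutation rate, decoys).
#' @param strain_id strain identifier (default `"S1"`).
#' @param omit_domains criterion ids whose subject protein is emitted with
#'   one domain annotation deliberately left out — such hits must be
#'   rejected by the domain-completeness filter.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return List with `strain_id`, `proteome` (named character), `fasta`,
#'   `blast`, `domtbl` (character vectors of file lines), `truth` (the
#'   ground-truth `strain_profile`) and `mapping` (criterion -> protein id).
#' @export
make_proteome <- function(panel, present, spec = cohort_spec(),
                          strain_id = "S1", omit_domains = character(0),
                          seed = spec$seed) {
    bad <- setdiff(present, panel$criteria$criterion_id)
    if (length(bad) > 0L)
        ffa_stop("ffa_value_error", "unknown criterion id(s) in present: %s",
                 paste(bad, collapse = ", "))
    with_seed(seed, {
        qdom <- criterion_domains(panel)
        proteome <- character(0)
        blast <- character(0)
        domtbl <- character(0)
        mapping <- data.frame(criterion_id = character(0),
                              protein_id = character(0))
        pnum <- 0L
        for (cid in present) {
            pnum <- pnum + 1L
            pid <- sprintf("%s_p%04d", strain_id, pnum)
            qseq <- panel$sequences[[cid]]
            sseq <- mutate_sequence(qseq, spec$mutation_rate)
            proteome[pid] <- sseq
            len <- nchar(qseq)
            matches <- sum(strsplit(qseq, "")[[1L]] ==
                           strsplit(sseq, "")[[1L]])
            blast <- c(blast, paste(
                cid, pid, format(round(100 * matches / len, 2)), len,
                len - matches, 0, 1, len, 1, len, "1e-50", 2L * matches,
                sep = "\t"))
            doms <- qdom[[cid]]
            if (cid %in% omit_domains && length(doms) > 0L)
                doms <- doms[-length(doms)]
            if (length(doms) > 0L) {
                span <- floor(len / length(doms))
                for (k in seq_along(doms)) {
                    domtbl <- c(domtbl, format_domtbl_row(
                        pid, len, paste0(doms[k], ".1"), 1e-12, k,
                        length(doms), (k - 1L) * span + 1L,
                        min(len, k * span)))
                }
            }
            mapping <- rbind(mapping,
                             data.frame(criterion_id = cid, protein_id = pid))
        }
        for (d in seq_len(spec$decoys_per_strain)) {
            pnum <- pnum + 1L
            pid <- sprintf("%s_p%04d", strain_id, pnum)
            len <- sample(120:400, 1L)
            proteome[pid] <- make_decoy(panel, len)
            # weak self-noise hit, always above the homology threshold
            if (runif(1) < 0.5) {
                cid <- sample(panel$criteria$criterion_id, 1L)
                blast <- c(blast, paste(
                    cid, pid, "24.5", 45, 34, 2, 10, 54, 20, 64,
                    format(signif(10^runif(1, -3, 1), 3)), 18, sep = "\t"))
            }
            # occasional stray domain annotation on a decoy
            if (runif(1) < 0.3) {
                acc <- sample(sub(";.*", "",
                                  panel$criteria$domains[
                                      nzchar(panel$criteria$domains)]), 1L)
                domtbl <- c(domtbl, format_domtbl_row(
                    pid, len, paste0(acc, ".1"), 1e-8, 1L, 1L, 5L,
                    min(len, 90L)))
            }
        }
        fasta <- as.character(rbind(paste0(">", names(proteome)),
                                    unname(proteome)))
        list(strain_id = strain_id, proteome = proteome, fasta = fasta,
             blast = blast,
             domtbl = c("# synthetic per-domain annotation table", domtbl),
             truth = truth_profile(panel, present, strain_id),
             mapping = mapping)
    })
}

# Presence sampling for one strain given per-class probabilities.
sample_presence <- function(panel, prob) {
    p <- prob[panel$criteria$impact]
    panel$criteria$criterion_id[runif(nrow(panel$criteria)) < p]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples per-strain criterion presence by impact-class probabilities and
#' injects reference-like strains: two high-presence positive references
#' (`REFPOS1`, `REFPOS2`: positive/required criteria at 0.97, negative at
#' 0.03), one intermediate boundary-like strain (`BOUND1`) and one very low
#' negative reference (`REFNEG1`: positive at 0.05, negative at 0.95,
#' required at 0.4). When `true_weights` is given, the ground-truth ranking
#' under those weights is included. With `materialize = TRUE`, per-strain
#' proteomes and evidence files are generated with [make_proteome()].
#'
#' @param panel an [ffa_panel()].
#' @param spec a [cohort_spec()].
#' @param true_weights optional named weight vector defining the true
#'   ranking.
#' @param materialize generate proteome/evidence files per strain
#'   (default `FALSE`; the truth profiles alone support scoring studies).
#' @return List with `panel`, `spec`, `strains` (data.frame `strain_id`,
#'   `role`), `presence` (named list of present criterion ids), `profiles`
#'   (named list of ground-truth profiles), `ref_config` (a
#'   [reference_config()] naming the injected references), and optionally
#'   `proteomes` (list of [make_proteome()] bundles) and `truth_ranking`.
#' @export
make_cohort <- function(panel, spec = cohort_spec(), true_weights = NULL,
                        materialize = FALSE) {
    with_seed(spec$seed, {
        ids <- sprintf("SYN%03d", seq_len(spec$n_strains))
        roles <- rep("sampled", spec$n_strains)
        presence <- lapply(ids, function(i)
            sample_presence(panel, spec$presence_probability))
        names(presence) <- ids
        inject <- list(
            REFPOS1 = c(positive = 0.97, negative = 0.03, required = 0.97),
            REFPOS2 = c(positive = 0.97, negative = 0.03, required = 0.97),
            BOUND1  = c(positive = 0.30, negative = 0.50, required = 0.80),
            REFNEG1 = c(positive = 0.05, negative = 0.95, required = 0.40))
        for (nm in names(inject))
            presence[[nm]] <- sample_presence(panel, inject[[nm]])
        ids <- c(ids, names(inject))
        roles <- c(roles, "positive_ref", "positive_ref", "boundary",
                   "negative_ref")
        profiles <- lapply(ids, function(i)
            truth_profile(panel, presence[[i]], i))
        names(profiles) <- ids
        refs <- reference_config(positive_refs = c("REFPOS1", "REFPOS2"),
                                 negative_refs = "REFNEG1",
                                 upper_boundary = NULL,
                                 lower_boundary = NULL)
        out <- list(panel = panel, spec = spec,
                    strains = data.frame(strain_id = ids, role = roles),
                    presence = presence, profiles = profiles,
                    ref_config = refs)
        if (!is.null(true_weights)) {
            raw <- vapply(profiles, score_raw, numeric(1),
                          weights = true_weights)
            names(raw) <- ids
            out$truth_raw <- raw
            out$truth_ranking <- rank_cohort(normalize_scores(raw))
        }
        if (materialize) {
            seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
            out$proteomes <- lapply(seq_along(ids), function(k)
                make_proteome(panel, presence[[ids[k]]], spec,
                              strain_id = ids[k], seed = seeds[k]))
            names(out$proteomes) <- ids
        }
        out
    })
}

#' Sign-constrained ground-truth weights for simulation studies
#'
#' Magnitudes are drawn from Uniform(0.5, 2) — criterion impacts of the same
#' order of magnitude — with signs fixed by impact class.
#'
#' @param panel an [ffa_panel()].
#' @param seed RNG seed.
#' @param magnitude_range range of weight magnitudes (default `c(0.5, 2)`).
#' @return Named numeric weight vector satisfying the sign constraints.
#' @export
random_weights <- function(panel, seed = 1L, magnitude_range = c(0.5, 2)) {
    with_seed(seed, {
        mag <- runif(nrow(panel$criteria), magnitude_range[1L],
                     magnitude_range[2L])
        signs <- ifelse(panel$criteria$impact == "negative", -1, 1)
        setNames(signs * mag, panel$criteria$criterion_id)
    })
}
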