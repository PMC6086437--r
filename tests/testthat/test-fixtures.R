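test_that("panel generation enforces the required-OG partition precondition", {
    expect_error(make_panel(40, 15, 9, 12), class = "ffa_value_error")
    p <- make_panel(40, 12, 12, 12, 3, seed = 5)
    expect_equal(nrow(p$criteria), 64L)
    expect_equal(sum(p$groups$impact == "required"), 12L)
})

test_that("generators are byte-deterministic given the seed", {
    p1 <- make_panel(6, 3, 4, 3, seed = 50)
    p2 <- make_panel(6, 3, 4, 3, seed = 50)
    expect_identical(p1$criteria, p2$criteria)
    expect_identical(p1$sequences, p2$sequences)
    expect_false(identical(p1$sequences,
                           make_panel(6, 3, 4, 3, seed = 51)$sequences))

    spec <- cohort_spec(n_strains = 3, decoys_per_strain = 2, seed = 52)
    b1 <- make_proteome(p1, c("POS001", "REQ001"), spec, "S1")
    b2 <- make_proteome(p1, c("POS001", "REQ001"), spec, "S1")
    expect_identical(b1$fasta, b2$fasta)
    expect_identical(b1$blast, b2$blast)
    expect_identical(b1$domtbl, b2$domtbl)

    c1 <- make_cohort(p1, spec)
    c2 <- make_cohort(p1, spec)
    expect_identical(c1$presence, c2$presence)
})

test_that("backup co-members land in shared required OGs with matching impact", {
    p <- make_panel(4, 2, 6, 3, seed = 53)
    req <- p$criteria[p$criteria$impact == "required", ]
    expect_equal(length(unique(req$og_id)), 3L)
    expect_true(all(table(req$og_id) == 2L))  # each OG got one backup
    expect_equal(p$criteria$gene_symbol[p$criteria$kegg_ko == "K01006"],
                 "ppdK")
    # pps and its backup share a group
    pps_og <- p$criteria$og_id[p$criteria$gene_symbol == "pps"]
    ppdk_og <- p$criteria$og_id[p$criteria$gene_symbol == "ppdK"]
    expect_equal(pps_og, ppdk_og)
})

test_that("noise-free proteomes reproduce ground truth through the evidence path", {
    p <- make_panel(6, 3, 4, 3, seed = 54)
    spec <- cohort_spec(n_strains = 1, decoys_per_strain = 3,
                        mutation_rate = 0, seed = 55)
    present <- p$criteria$criterion_id  # everything present
    b <- make_proteome(p, present, spec, "S1")
    hits <- parse_blast_tabular(b$blast)
    ann <- parse_domtblout(b$domtbl)
    filtered <- filter_domain_complete(hits,
                                       ffascreen:::criterion_domains(p), ann)
    pr <- build_profile("S1", filtered, p)
    expect_identical(pr$presence, b$truth$presence)
    expect_identical(pr$og_satisfied, b$truth$og_satisfied)

    # empty presence: only decoy noise in the evidence, all-absent profile
    b0 <- make_proteome(p, character(0), spec, "S0")
    hits0 <- parse_blast_tabular(b0$blast)
    filtered0 <- filter_domain_complete(
        hits0, ffascreen:::criterion_domains(p), parse_domtblout(b0$domtbl))
    pr0 <- build_profile("S0", filtered0, p)
    expect_false(any(pr0$presence))
})

test_that("an omitted subject domain removes the criterion from the pipeline profile", {
    p <- make_panel(5, 2, 3, 2, seed = 56)
    # pick a criterion that carries at least one domain
    has_dom <- p$criteria$criterion_id[nzchar(p$criteria$domains)]
    victim <- has_dom[1]
    spec <- cohort_spec(n_strains = 1, decoys_per_strain = 2,
                        mutation_rate = 0, seed = 57)
    b <- make_proteome(p, p$criteria$criterion_id, spec, "S1",
                       omit_domains = victim)
    filtered <- filter_domain_complete(
        parse_blast_tabular(b$blast), ffascreen:::criterion_domains(p),
        parse_domtblout(b$domtbl))
    pr <- build_profile("S1", filtered, p)
    expect_false(pr$presence[[victim]])
    others <- setdiff(p$criteria$criterion_id, victim)
    expect_true(all(pr$presence[others]))
    # ground truth still marks it present: the filter did the rejection
    expect_true(b$truth$presence[[victim]])
})

test_that("cohorts carry injected references with the documented roles", {
    p <- make_panel(6, 3, 4, 3, seed = 58)
    co <- make_cohort(p, cohort_spec(n_strains = 7, seed = 59),
                      true_weights = unit_weights(p))
    expect_equal(nrow(co$strains), 11L)  # 7 sampled + 4 injected
    expect_setequal(
        co$strains$strain_id[co$strains$role == "positive_ref"],
        c("REFPOS1", "REFPOS2"))
    expect_equal(co$strains$strain_id[co$strains$role == "negative_ref"],
                 "REFNEG1")
    expect_equal(co$ref_config$positive_refs, c("REFPOS1", "REFPOS2"))
    # truth ranking present and complete when weights are given
    expect_equal(sort(co$truth_ranking$rank), 1:11)

    # all-certain presence probabilities make every sampled strain identical
    spec1 <- cohort_spec(n_strains = 4,
                         presence_probability = c(positive = 1,
                                                  negative = 1,
                                                  required = 1),
                         seed = 60)
    co1 <- make_cohort(p, spec1)
    sampled <- co1$presence[co1$strains$strain_id[co1$strains$role ==
                                                  "sampled"]]
    expect_true(all(vapply(sampled, identical, logical(1), sampled[[1]])))
})

test_that("random ground-truth weights respect the sign constraints", {
    p <- make_panel(6, 3, 4, 3, seed = 61)
    w <- random_weights(p, seed = 62)
    expect_silent(validate_weights(w, p))
    expect_true(all(abs(w) >= 0.5 & abs(w) <= 2))
})
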