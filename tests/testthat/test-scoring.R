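test_that("raw scores are signed weighted sums of presence features", {
    p <- make_panel(6, 3, 3, 3, seed = 5)
    w <- unit_weights(p)
    ids <- p$criteria$criterion_id
    pos <- ids[p$criteria$impact == "positive"]
    neg <- ids[p$criteria$impact == "negative"]

    expect_equal(score_raw(presence_profile(p, character(0)), w), 0)
    expect_equal(score_raw(presence_profile(p, pos[1]), w), 1)
    expect_equal(score_raw(presence_profile(p, neg[1]), w), -1)
    expect_equal(score_raw(presence_profile(p, c(pos[1:3], neg[1:2])), w), 1)

    expect_error(score_raw(presence_profile(p, pos[1]), w[-1]),
                 class = "ffa_config_error")
})

test_that("count mode weights hit counts instead of presence", {
    p <- tiny_panel()
    pr <- build_profile("S", make_hits(c("c1", "c1", "c3"),
                                       c("p1", "p2", "p3")), p)
    w <- unit_weights(p)
    expect_equal(score_raw(pr, w, "presence"), 0)   # +1 (c1) - 1 (c3)
    expect_equal(score_raw(pr, w, "count"), 1)      # +2 (c1) - 1 (c3)
})

test_that("score_raw agrees with a brute-force dot product on random profiles", {
    p <- make_panel(8, 4, 4, 3, seed = 17)
    w <- random_weights(p, seed = 18)
    with_seed(19, {
        for (i in 1:25) {
            present <- sample(p$criteria$criterion_id,
                              sample(0:16, 1))
            pr <- presence_profile(p, present)
            expect_equal(score_raw(pr, w), oracle_score(pr, w))
        }
    })
})

test_that("min-max normalization pins the cohort to [0, 1]", {
    expect_equal(normalize_scores(c(A = 5, B = 3, C = 1)),
                 c(A = 1, B = 0.5, C = 0))
    expect_equal(normalize_scores(c(A = 2, B = 2)), c(A = 0.5, B = 0.5))
    expect_error(normalize_scores(numeric(0)), class = "ffa_value_error")
})

test_that("ranking is descending with lexicographic tie-break and gapless ranks", {
    r <- rank_cohort(c(A = 0.9, B = 0.5, C = 0.1))
    expect_equal(r$strain_id, c("A", "B", "C"))
    expect_equal(r$rank, 1:3)
    r <- rank_cohort(c(B = 0.5, A = 0.5))
    expect_equal(r$strain_id, c("A", "B"))
    expect_equal(r$rank, 1:2)
})

test_that("find_boundary returns the lowest strain of the positive-reference cluster", {
    x <- c(A = 0.95, B = 0.93, C = 0.90, D = 0.10, E = 0.05)
    expect_equal(find_boundary(x, c("A", "B")), "C")
    # frozen against the exhaustive minimum-SSE oracle
    expect_equal(oracle_boundary(x, c("A", "B")), "C")

    # singleton cluster: the reference itself
    expect_equal(find_boundary(c(R = 0.9, S = 0.1), "R"), "R")

    # references split across clusters
    expect_error(find_boundary(x, c("A", "E")), class = "ffa_boundary_error")
    expect_error(find_boundary(c(A = 1), "A"), class = "ffa_value_error")
})

test_that("the exact 1-D 2-means split agrees with stats::kmeans on separated data", {
    with_seed(23, {
        x <- c(runif(8, 0.8, 1), runif(7, 0, 0.2))
        names(x) <- paste0("s", 1:15)
        km <- kmeans(matrix(x), centers = matrix(c(min(x), max(x))))
        hi <- names(x)[km$cluster == which.max(km$centers)]
        expect_equal(find_boundary(x, names(which.max(x))),
                     hi[which.min(x[hi])])
    })
})

test_that("categorization is strict at both boundaries", {
    expect_equal(as.character(categorize(0.99, 0.9433, 0.45)), "Top-ranked")
    expect_equal(as.character(categorize(0.9433, 0.9433, 0.45)), "Positive")
    expect_equal(as.character(categorize(0.45, 0.9433, 0.45)), "Negative")
    expect_error(categorize(0.5, 0.4, 0.6), class = "ffa_config_error")

    # partition: every strain gets exactly one category
    with_seed(29, {
        s <- runif(40)
        cats <- categorize(s, 0.8, 0.3)
        expect_false(anyNA(cats))
        expect_equal(sum(table(cats)), 40L)
    })
})

test_that("calibration separates separable references and flags equal ones", {
    p <- make_panel(6, 3, 3, 3, seed = 31)
    ids <- p$criteria$criterion_id
    pos <- ids[p$criteria$impact == "positive"]
    neg <- ids[p$criteria$impact == "negative"]
    req <- ids[p$criteria$impact == "required"]
    profiles <- list(
        presence_profile(p, c(pos, req), "P1"),
        presence_profile(p, c(pos[1:4], req), "P2"),
        presence_profile(p, c(pos[1:2], neg[1:2], req[1:2]), "M1"),
        presence_profile(p, c(pos[1], neg), "N1"))
    refs <- reference_config(positive_refs = c("P1", "P2"),
                             negative_refs = "N1",
                             upper_boundary = NULL, lower_boundary = NULL)
    w <- calibrate_weights(profiles, p, refs)
    expect_true(attr(w, "separable"))
    validate_weights(w, p)
    raws <- vapply(profiles, score_raw, numeric(1), weights = w)
    names(raws) <- vapply(profiles, `[[`, "", "strain_id")
    expect_gt(min(raws[c("P1", "P2")]), raws[["N1"]])

    # identical positive and negative reference profiles: non-separable
    same <- list(presence_profile(p, pos[1:2], "X"),
                 presence_profile(p, pos[1:2], "Y"))
    refs2 <- reference_config(positive_refs = "X", negative_refs = "Y",
                              upper_boundary = NULL, lower_boundary = NULL)
    w2 <- calibrate_weights(same, p, refs2)
    expect_false(attr(w2, "separable"))

    refs3 <- reference_config(positive_refs = "missing", negative_refs = "Y",
                              upper_boundary = NULL, lower_boundary = NULL)
    expect_error(calibrate_weights(same, p, refs3),
                 class = "ffa_config_error")
})

test_that("sign-constrained scores are monotone in single-criterion flips", {
    p <- make_panel(5, 3, 2, 2, seed = 37)
    w <- random_weights(p, seed = 38)
    with_seed(39, {
        for (i in 1:10) {
            present <- sample(p$criteria$criterion_id, sample(0:9, 1))
            base <- score_raw(presence_profile(p, present), w)
            absent <- setdiff(p$criteria$criterion_id, present)
            if (length(absent) == 0) next
            flip <- sample(absent, 1)
            s2 <- score_raw(presence_profile(p, c(present, flip)), w)
            imp <- p$criteria$impact[p$criteria$criterion_id == flip]
            if (imp == "negative") expect_lte(s2, base)
            else expect_gte(s2, base)
        }
    })
})

test_that("a new strain joins the cohort with recomputed normalization and rank", {
    p <- make_panel(6, 3, 3, 3, seed = 41)
    co <- make_cohort(p, cohort_spec(n_strains = 10, seed = 42))
    w <- unit_weights(p)
    rk <- score_cohort(co$profiles, p, w, refs = co$ref_config)
    raws <- attr(rk, "raw_scores")

    # duplicate of an existing strain: identical raw score, adjacent rank
    twin <- presence_profile(p, co$presence[["SYN001"]], "SYN001twin")
    ev <- evaluate_new_strain(twin, raws, w, co$ref_config, panel = p)
    expect_equal(ev$raw_score, raws[["SYN001"]])
    r_old <- ev$ranking$rank[ev$ranking$strain_id == "SYN001"]
    expect_equal(ev$rank, r_old + 1L)  # lexicographic tie-break

    # id collision is refused
    expect_error(evaluate_new_strain(
        presence_profile(p, character(0), "SYN001"), raws, w, co$ref_config),
        class = "ffa_value_error")

    # dominant strain takes rank 1 and Top-ranked: cohort raw scores are an
    # input of this workflow, so use a pre-evaluated table whose references
    # sit below the maximum attainable score
    ids <- p$criteria$criterion_id
    best <- presence_profile(p, ids[p$criteria$impact != "negative"], "NEW")
    top <- score_raw(best, w)
    raws2 <- c(REFPOS1 = top - 1, REFPOS2 = top - 2, MID1 = top / 2,
               MID2 = 1, REFNEG1 = -2)
    refs2 <- reference_config(positive_refs = c("REFPOS1", "REFPOS2"),
                              negative_refs = "REFNEG1",
                              upper_boundary = NULL, lower_boundary = NULL)
    ev2 <- evaluate_new_strain(best, raws2, w, refs2, panel = p)
    expect_equal(ev2$rank, 1L)
    expect_equal(ev2$category, "Top-ranked")
    expect_equal(ev2$score, 1)

    # the four headline outputs are exposed
    expect_true(all(c("score", "category", "recommendation", "rank")
                    %in% names(ev2)))
})

test_that("weight vectors round-trip through the TSV format", {
    p <- tiny_panel()
    w <- unit_weights(p)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_weights(w, f)
    expect_equal(read_weights(f), w)
})
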