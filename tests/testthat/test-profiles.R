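test_that("naive profiles: self-match rows and degenerate collections", {
    # single document: every entry is the suffix length
    ss <- buildSuffixStructures(DocumentCollection("GATTACA"))
    P <- profilesNaive(ss)
    n <- textLength(ss)
    expect_equal(P[, 1L], n - ss@sa + 1L)

    # two identical documents: columns differ only on self-match rows
    ss2 <- buildSuffixStructures(DocumentCollection(c("TAGA", "TAGA")))
    P2 <- profilesNaive(ss2)
    off <- which(P2[, 1L] != P2[, 2L])
    lens <- textLength(ss2) - ss2@sa + 1L
    expect_true(all(pmax(P2[off, 1L], P2[off, 2L]) == lens[off]))
    # own-document entry always equals the suffix length
    set.seed(31)
    ss3 <- buildSuffixStructures(randomCollection(d = 3))
    P3 <- profilesNaive(ss3)
    expect_equal(P3[cbind(seq_len(nrow(P3)), ss3@da)],
                 textLength(ss3) - ss3@sa + 1L)
})

test_that("naive profiles equal an independent loop-based re-implementation", {
    set.seed(41)
    for (it in 1:8) {
        ss <- buildSuffixStructures(randomCollection(d = sample(2:4, 1),
                                                     maxLen = 20))
        expect_equal(unname(profilesNaive(ss)), bruteProfiles(ss))
    }
})

test_that("two-pass equals naive, including the boundary rows", {
    set.seed(51)
    for (it in 1:40) {
        ss <- buildSuffixStructures(randomCollection())
        expect_identical(unname(profilesTwoPass(ss)),
                         unname(profilesNaive(ss)))
    }
})

test_that("streaming samples equal naive samples at every run boundary", {
    # single run, d = 1: "AAA" gives a BWT with one long run whose
    # boundary profiles are plain suffix lengths at LF
    ss0 <- buildSuffixStructures(DocumentCollection("AAA"))
    runs0 <- bwtRuns(ss0)
    st0 <- profilesStreaming(ss0, runs0)
    ref0 <- sampleProfiles(profilesNaive(ss0), runs0, ss0@lf)
    expect_identical(unname(st0$profStart), unname(ref0$profStart))
    expect_identical(unname(st0$profEnd), unname(ref0$profEnd))

    set.seed(61)
    for (it in 1:60) {
        ss <- buildSuffixStructures(randomCollection())
        runs <- bwtRuns(ss)
        st <- profilesStreaming(ss, runs, check = TRUE)
        ref <- sampleProfiles(profilesNaive(ss), runs, ss@lf)
        expect_identical(unname(st$profStart), unname(ref$profStart))
        expect_identical(unname(st$profEnd), unname(ref$profEnd))
        # instrumented run: the queue-counter invariant held at every step
        expect_true(st$lqcOk)
    }
})

test_that("streaming rejects inconsistent inputs", {
    ss <- buildSuffixStructures(DocumentCollection(c("ACGT", "ACCT")))
    runs <- bwtRuns(ss)
    expect_error(
        profiles_streaming_cpp(ss@sa[-1L], ss@lcp, rep(1L, textLength(ss)),
                               ss@da, rep(1L, textLength(ss)),
                               rep(TRUE, textLength(ss)),
                               rep(TRUE, textLength(ss)),
                               2L, 5L, runCount(runs), FALSE),
        "inconsistent")
})

test_that("reference sampler stores exactly 2r profiles; length-1 runs sample twice", {
    set.seed(71)
    ss <- buildSuffixStructures(randomCollection(d = 3))
    runs <- bwtRuns(ss)
    sp <- sampleProfiles(profilesNaive(ss), runs, ss@lf)
    expect_equal(ncol(sp$profStart) + ncol(sp$profEnd), 2L * runCount(runs))
    one <- which(runs@start == runs@end)
    for (k in one)
        expect_equal(sp$profStart[, k], sp$profEnd[, k])
})

test_that("LF-step bound and exact increment hold across full matrices and on the printed pair", {
    # printed pair: [1,2,4] -> [1,3,5] under an LF step with ell = 2
    expect_true(checkLfStepBounds(c(1, 2, 4), c(1, 3, 5), ell = 2))
    expect_equal(incrementConfined(c(1, 2, 4), 2), c(1, 3, 5))
    expect_false(checkLfStepBounds(c(1, 2, 4), c(1, 4, 5)))       # bound broken
    expect_false(checkLfStepBounds(c(1, 2, 4), c(1, 3, 4), ell = 2))  # no +1

    set.seed(81)
    for (it in 1:25) {
        ss <- buildSuffixStructures(randomCollection())
        P <- unname(profilesNaive(ss))
        runs <- bwtRuns(ss)
        runId <- rep.int(seq_len(runCount(runs)),
                         runs@end - runs@start + 1L)
        sep <- strsplit(ss@bwt, "")[[1L]] == "#"
        # every document change under LF happens on a separator position
        changed <- ss@da != ss@da[ss@lf]
        expect_true(all(sep[changed]))
        for (i in seq_len(textLength(ss))) {
            # the bounds cover LF steps on ordinary characters
            if (sep[i] || ss@da[i] != ss@da[ss@lf[i]]) next
            ell <- minRunSubstringLength(ss@lcp, runs@start[runId[i]],
                                         runs@end[runId[i]])
            expect_true(checkLfStepBounds(P[i, ], P[ss@lf[i], ], ell = ell))
        }
    }
})

test_that("minimal confined substring length: formula vs occurrence oracle", {
    # printed boundary values: LCP[s] = 0, LCP[e+1] = 1 for run [4, 5]
    expect_equal(minRunSubstringLength(c(0, 0, 1, 0, 2, 1), 4, 5), 2L)
    # run ending at n uses LCP[n + 1] = 0
    expect_equal(minRunSubstringLength(c(0, 1, 2), 3, 3), 3L)

    set.seed(91)
    for (it in 1:15) {
        ss <- buildSuffixStructures(randomCollection(d = sample(2:4, 1)))
        runs <- bwtRuns(ss)
        text <- ss@concat@text
        n <- textLength(ss)
        for (k in seq_len(runCount(runs))) {
            s <- runs@start[k]; e <- runs@end[k]
            ell <- minRunSubstringLength(ss@lcp, s, e)
            lcpNext <- if (e < n) ss@lcp[e + 1L] else 0L
            b <- if (ss@lcp[s] >= lcpNext) s else e
            pat <- substr(text, ss@sa[b], ss@sa[b] + ell - 1L)
            if (grepl("#", pat, fixed = TRUE)) next  # separator suffixes
            occ <- ss@isa[bruteOccurrences(text, pat)]
            expect_true(all(occ >= s & occ <= e))
            if (ell > 1L) {
                occ2 <- ss@isa[bruteOccurrences(
                    text, substr(text, ss@sa[b], ss@sa[b] + ell - 2L))]
                expect_true(any(occ2 < s | occ2 > e))
            }
        }
    }
})

test_that("truncation caps stored values and preserves bounded listings", {
    set.seed(99)
    coll <- randomCollection(d = 4, maxLen = 30)
    idx <- buildDocProfileIndex(coll)
    idxT <- truncateIndex(idx, 255L)
    expect_equal(widthCap(idxT), 255L)
    expect_true(max(idxT@profStart) <= 255L)
    # all values here are far below the cap: content unchanged
    expect_identical(idxT@profStart, idx@profStart)

    # a biting cap still answers bounded-length queries exactly
    idx5 <- truncateIndex(idx, 5L)
    expect_true(max(idx5@profStart) <= 5L)
    for (pat in allSubstrings(coll@docs, 5L)) {
        q1 <- queryWithProfiles(idx, pat)
        q2 <- queryWithProfiles(idx5, pat)
        expect_equal(q2$found, q1$found)
        if (q1$found)
            expect_identical(listDocuments(q2$profile, q2$matchedLength),
                             listDocuments(q1$profile, q1$matchedLength))
    }
    expect_error(truncateIndex(idx, 0L), "positive")
    # identity case: values below the cap are untouched, only the cap is set
    idxSame <- truncateIndex(idxT, 255L)
    expect_identical(idxSame@profStart, idxT@profStart)
})
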