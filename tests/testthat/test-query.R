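test_that("profile query + listing equals brute membership and locate baseline", {
    set.seed(111)
    for (it in 1:12) {
        coll <- randomCollection(d = sample(2:5, 1), maxLen = 30)
        idx <- buildDocProfileIndex(coll)
        d <- nDocs(idx)
        for (pat in allSubstrings(coll@docs, 8L)) {
            truth <- as.integer(docsContaining(coll@docs, pat))
            q <- queryWithProfiles(idx, pat)
            got <- if (q$found)
                as.integer(listDocuments(q$profile, q$matchedLength))
            else integer(0)
            loc <- listDocumentsViaLocate(idx, pat)
            expect_identical(got, truth)
            expect_identical(as.integer(loc), truth)
            # ndoc <= min(d, occ)
            expect_lte(length(got), min(d, attr(loc, "occ")))
        }
        # a pattern never in the text, and out-of-alphabet characters
        absent <- strrep("ACGT", 20)
        expect_false(queryWithProfiles(idx, absent)$found)
        expect_false(queryWithProfiles(idx, "AZQ")$found)
        expect_error(queryWithProfiles(idx, ""), "empty")
    }
})

test_that("a whole unique document is listed in exactly its own class", {
    set.seed(121)
    coll <- randomCollection(d = 4, minLen = 15, maxLen = 30)
    idx <- buildDocProfileIndex(coll)
    for (j in seq_len(4)) {
        pat <- coll@docs[j]
        if (length(docsContaining(coll@docs, pat)) != 1L) next
        q <- queryWithProfiles(idx, pat)
        expect_true(q$found)
        expect_identical(as.integer(listDocuments(q$profile,
                                                  q$matchedLength)), j)
    }
})

test_that("listing from printed profile [1,2,4] at lengths 1..3", {
    expect_identical(as.integer(listDocuments(c(1, 2, 4), 1)), 1:3)
    expect_identical(as.integer(listDocuments(c(1, 2, 4), 2)), 2:3)
    expect_identical(as.integer(listDocuments(c(1, 2, 4), 3)), 3L)
})

test_that("work accounting: profile listing is O(d), locate is O(occ)", {
    # a pattern occurring many times in few documents
    coll <- DocumentCollection(c(a = strrep("TA", 40), b = "GGCC"))
    idx <- buildDocProfileIndex(coll)
    q <- queryWithProfiles(idx, "TA")
    docs <- listDocuments(q$profile, 2L)
    loc <- listDocumentsViaLocate(idx, "TA")
    expect_identical(as.integer(docs), as.integer(loc))
    expect_equal(attr(docs, "ops"), nDocs(idx))         # d comparisons
    expect_equal(attr(loc, "ops"), attr(loc, "occ"))    # per-occurrence work
    expect_gt(attr(loc, "ops"), attr(docs, "ops"))
})

test_that("sampled-DA lookup returns a containing document deterministically", {
    set.seed(131)
    for (it in 1:10) {
        coll <- randomCollection(d = sample(2:5, 1), maxLen = 30)
        idx <- buildDocProfileIndex(coll)
        for (pat in allSubstrings(coll@docs, 4L)) {
            q <- queryWithProfiles(idx, pat)
            if (!q$found) next
            one <- sampledDaLookup(idx, q$interval)
            expect_true(one %in% listDocuments(q$profile, q$matchedLength))
        }
    }
    # a unique match resolves to its only containing document
    coll <- DocumentCollection(c(x = "AACCGGTT", y = "TTTT"))
    idx <- buildDocProfileIndex(coll)
    q <- queryWithProfiles(idx, "AACCGGTT")
    expect_equal(sampledDaLookup(idx, q$interval), 1L)
    # deterministic on repeated calls
    expect_equal(sampledDaLookup(idx, q$interval),
                 sampledDaLookup(idx, q$interval))
})

test_that("matching statistics equal the quadratic oracle", {
    set.seed(141)
    for (it in 1:10) {
        coll <- randomCollection(d = sample(1:4, 1), sigma = 2, maxLen = 50)
        idx <- buildDocProfileIndex(coll)
        read <- paste0(sample(c("A", "C", "G"), 40, replace = TRUE),
                       collapse = "")
        expect_equal(matchingStatistics(idx, read),
                     bruteMatchingStats(coll@docs, read))
    }
    # a read that is a prefix of a document matches full length at position 1
    coll <- DocumentCollection(c("GATTACAT", "CCCC"))
    idx <- buildDocProfileIndex(coll)
    expect_equal(matchingStatistics(idx, "GATTAC")[1L], 6L)
    # characters absent from the text yield all zeros
    expect_equal(matchingStatistics(idx, "NNNN"), rep(0L, 4L))
})

test_that("MEM extraction equals the brute-force maximal-match enumeration", {
    set.seed(151)
    for (it in 1:10) {
        coll <- randomCollection(d = sample(1:4, 1), sigma = 2, maxLen = 50)
        idx <- buildDocProfileIndex(coll)
        read <- paste0(sample(c("A", "C"), 50, replace = TRUE), collapse = "")
        ms <- bruteMatchingStats(coll@docs, read)
        starts <- which(ms >= 3L & c(TRUE, ms[-length(ms)] <= ms[-1L]))
        fm <- findMems(idx, read, minLen = 3L)
        expect_equal(fm$mems$start, starts)
        expect_equal(fm$mems$len, ms[starts])
        # each MEM's profile listing equals brute membership of its string
        for (k in seq_len(nrow(fm$mems))) {
            pat <- substr(read, fm$mems$start[k],
                          fm$mems$start[k] + fm$mems$len[k] - 1L)
            expect_identical(
                as.integer(which(fm$profiles[, k] >= fm$mems$len[k])),
                as.integer(docsContaining(coll@docs, pat)))
        }
    }
})

test_that("MEM boundary behaviour on clean and mutated reads", {
    # read identical to a document: a single MEM covering the read
    coll <- DocumentCollection(c(a = "GATTACATTGCA", b = "CGCGCGCG"))
    idx <- buildDocProfileIndex(coll)
    fm <- findMems(idx, "GATTACATTGCA", minLen = 4L)
    expect_equal(nrow(fm$mems), 1L)
    expect_equal(fm$mems$start, 1L)
    expect_equal(fm$mems$len, 12L)

    # one mismatch mid-way against a single-document text: two MEMs
    # flanking the mismatch
    doc <- strrep("GATC", 10)
    idx1 <- buildDocProfileIndex(DocumentCollection(doc))
    read <- paste0(substr(doc, 1, 20), "A", substr(doc, 22, 40))
    stopifnot(substr(doc, 21, 21) != "A")
    fm1 <- findMems(idx1, read, minLen = 4L)
    expect_equal(nrow(fm1$mems), 2L)
    expect_true(fm1$mems$start[1L] == 1L && fm1$mems$len[1L] == 20L)
    expect_true(fm1$mems$start[2L] == 22L)
})
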