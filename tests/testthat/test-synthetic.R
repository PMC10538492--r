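test_that("configuration validation and tier presets", {
    expect_error(datasetConfig(accuracy = 0))
    expect_error(datasetConfig(betweenClassDivergence = 1.5))
    expect_error(datasetConfig(readsPerClass = 0))
    expect_warning(datasetConfig(betweenClassDivergence = 0.9), "aturation")
    g <- tierPreset("genus")
    s <- tierPreset("strain")
    expect_gt(g$betweenClassDivergence, s$betweenClassDivergence)
    expect_equal(s$docsPerClass, 1L)
})

test_that("generation is reproducible under the same seed", {
    cfg <- datasetConfig(ancestorLength = 1500L, readLength = 120L,
                         readsPerClass = 5L, seed = 42L)
    d1 <- generateCollection(cfg)
    d2 <- generateCollection(cfg)
    expect_identical(d1$records, d2$records)
    r1 <- simulateReads(d1, cfg)
    r2 <- simulateReads(d2, cfg)
    expect_identical(r1$seq, r2$seq)
})

test_that("zero divergence copies the ancestor; substitution rate is nominal", {
    cfg0 <- datasetConfig(nClasses = 3L, betweenClassDivergence = 0,
                          ancestorLength = 800L, seed = 3L)
    ds0 <- generateCollection(cfg0)
    expect_equal(length(unique(ds0$records)), 1L)

    # substitution-only process: aligned mismatch fraction ~ p within 3 SE
    set.seed(9)
    p <- 0.03
    n <- 100000L
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    mut <- docarray:::.mutateChars(anc, pSub = p, pIns = 0, pDel = 0)
    expect_length(mut, n)
    rate <- mean(mut != anc)
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("read error rate matches 1 - accuracy within sampling error", {
    cfg <- datasetConfig(nClasses = 2L, ancestorLength = 3000L,
                         betweenClassDivergence = 0.1, readLength = 500L,
                         readsPerClass = 100L, accuracy = 0.95, seed = 13L)
    ds <- generateCollection(cfg)
    rds <- simulateReads(ds, cfg)
    ev <- attr(rds, "events")
    rate <- (ev[["sub"]] + ev[["ins"]] + ev[["del"]]) / ev[["sites"]]
    e <- 1 - cfg$accuracy
    # indel-length dispersion roughly triples the per-site variance
    se <- sqrt(3 * e / ev[["sites"]])
    expect_lt(abs(rate - e), 3 * se)

    # perfect accuracy: every read is an exact substring of its document
    cfg1 <- datasetConfig(nClasses = 2L, ancestorLength = 1000L,
                          betweenClassDivergence = 0.1, readLength = 200L,
                          readsPerClass = 5L, accuracy = 1.0, seed = 13L)
    ds1 <- generateCollection(cfg1)
    rds1 <- simulateReads(ds1, cfg1)
    for (i in seq_len(nrow(rds1))) {
        doc <- ds1$collection@docs[
            ds1$collection@labels == rds1$true_label[i]]
        expect_true(grepl(rds1$seq[i], doc, fixed = TRUE))
    }
})

test_that("mean MEM length shrinks as read accuracy drops", {
    cfg <- function(acc) datasetConfig(nClasses = 1L, ancestorLength = 5000L,
                                       betweenClassDivergence = 0,
                                       readLength = 500L, readsPerClass = 20L,
                                       accuracy = acc, seed = 23L)
    ds <- generateCollection(cfg(0.95))
    idx <- buildDocProfileIndex(ds$collection)
    meanMem <- function(acc) {
        rds <- simulateReads(ds, cfg(acc))
        mean(unlist(lapply(rds$seq, function(r)
            findMems(idx, r, minLen = 5L)$mems$len)))
    }
    m95 <- meanMem(0.95)
    m90 <- meanMem(0.90)
    expect_true(is.finite(m95) && is.finite(m90))
    expect_gt(m95, m90)
})

test_that("strain-tier MEMs are shared across more classes than genus-tier", {
    meanNdoc <- function(tier) {
        cfg <- tierPreset(tier, seed = 31L, ancestorLength = 3000L,
                          docsPerClass = 1L, readLength = 300L,
                          readsPerClass = 10L)
        ds <- generateCollection(cfg)
        rds <- simulateReads(ds, cfg)
        idx <- buildDocProfileIndex(ds$collection)
        nd <- unlist(lapply(rds$seq, function(r) {
            fm <- findMems(idx, r, minLen = 15L)
            vapply(seq_len(nrow(fm$mems)), function(k)
                sum(fm$profiles[, k] >= fm$mems$len[k]), integer(1))
        }))
        mean(nd)
    }
    expect_gt(meanNdoc("strain"), meanNdoc("genus"))
})

test_that("dataset writer emits FASTA records, grouping and reads round trip", {
    dir <- withr::local_tempdir()
    cfg <- datasetConfig(nClasses = 4L, docsPerClass = 2L,
                         ancestorLength = 400L, betweenClassDivergence = 0.1,
                         withinClassDivergence = 0.01, readLength = 80L,
                         readsPerClass = 3L, seed = 17L)
    ds <- generateCollection(cfg)
    rds <- simulateReads(ds, cfg)
    paths <- writeDataset(ds, dir, reads = rds, config = cfg)
    # 4 classes x 2 genomes -> 8 FASTA records
    fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
    expect_length(fa, 8L)
    coll <- readDocumentCollection(paths[["fasta"]],
                                   grouping = paths[["grouping"]])
    expect_equal(nDocs(coll), 4L)
    expect_identical(unname(coll@docs), unname(ds$collection@docs))
    back <- readReadsFastq(paths[["reads"]])
    expect_identical(back$seq, rds$seq)
    expect_identical(back$true_label, rds$true_label)
    mf <- jsonlite::read_json(paths[["manifest"]])
    expect_equal(mf$seed, 17L)
})
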