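#' Configuration for a synthetic pangenome dataset
#'
#' Describes a dataset of \code{nClasses} classes derived from a single
#' random ancestor: each class ancestor diverges from it at
#' \code{betweenClassDivergence} events per site, each genome within a
#' class diverges from the class ancestor at \code{withinClassDivergence},
#' and error-bearing long reads are drawn uniformly from each class at the
#' given per-base \code{accuracy}.  Divergence events are split
#' \code{1 - indelFrac} substitutions / \code{indelFrac} indel
#' initiations; read errors are split 50:25:25 between substitutions,
#' insertions and deletions; indel lengths are geometric with mean 1.5.
#'
#' @param nClasses number of classes (documents), default 4.
#' @param docsPerClass genomes per class (concatenated into one document).
#' @param ancestorLength ancestor length in bases.
#' @param betweenClassDivergence,withinClassDivergence events per site.
#' @param readLength,readsPerClass read simulation dimensions.
#' @param accuracy per-base read accuracy in (0, 1], default 0.95.
#' @param indelFrac fraction of divergence events that are indels.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a validated list of class \code{"docarrayConfig"}.
#' @seealso [tierPreset()], [generateCollection()], [simulateReads()]
#' @export
datasetConfig <- function(nClasses = 4L, docsPerClass = 1L,
                          ancestorLength = 20000L,
                          betweenClassDivergence = 0.005,
                          withinClassDivergence = 0,
                          readLength = 1000L, readsPerClass = 500L,
                          accuracy = 0.95, indelFrac = 0.1, seed = 1L) {
    cfg <- list(nClasses = as.integer(nClasses),
                docsPerClass = as.integer(docsPerClass),
                ancestorLength = as.integer(ancestorLength),
                betweenClassDivergence = betweenClassDivergence,
                withinClassDivergence = withinClassDivergence,
                readLength = as.integer(readLength),
                readsPerClass = as.integer(readsPerClass),
                accuracy = accuracy, indelFrac = indelFrac,
                seed = as.integer(seed))
    with(cfg, {
        stopifnot(nClasses >= 1L, docsPerClass >= 1L, ancestorLength >= 1L,
                  readLength >= 1L, readsPerClass >= 1L,
                  betweenClassDivergence >= 0, betweenClassDivergence <= 1,
                  withinClassDivergence >= 0, withinClassDivergence <= 1,
                  accuracy > 0, accuracy <= 1,
                  indelFrac >= 0, indelFrac <= 1)
    })
    if (cfg$betweenClassDivergence > 0.75)
        warning("divergence so high that expected identity < 0.25 ",
                "(saturation)")
    class(cfg) <- "docarrayConfig"
    cfg
}

#' Preset configurations for the classification difficulty tiers
#'
#' \code{"genus"}: classes as dissimilar as different genera (20%
#' divergence, 3 genomes per class at 1% within-class divergence).
#' \code{"species"}: congeneric species (5% between, 3 genomes per class).
#' \code{"strain"}: same-species strains (0.5% between-class divergence,
#' one genome per class) -- the hard regime where full listings matter.
#'
#' @param tier one of \code{"genus"}, \code{"species"}, \code{"strain"}.
#' @param ... overrides passed to [datasetConfig()].
#' @return a \code{"docarrayConfig"}.
#' @export
tierPreset <- function(tier = c("genus", "species", "strain"), ...) {
    tier <- match.arg(tier)
    base <- switch(tier,
        genus = list(betweenClassDivergence = 0.20,
                     withinClassDivergence = 0.01, docsPerClass = 3L),
        species = list(betweenClassDivergence = 0.05,
                       withinClassDivergence = 0.01, docsPerClass = 3L),
        strain = list(betweenClassDivergence = 0.005,
                      withinClassDivergence = 0, docsPerClass = 1L))
    do.call(datasetConfig, utils::modifyList(base, list(...)))
}

# i.i.d. per-site mutation.  pSub / pIns / pDel are the AFFECTED-BASE
# rates; indel initiation probabilities are scaled by the mean geometric
# indel length (1.5) so that the expected fraction of bases touched by
# each event type matches its nominal rate.  Returns the mutated character
# vector with event-base counts in attr "events".
.mutateChars <- function(chars, pSub, pIns, pDel,
                         alphabet4 = c("A", "C", "G", "T")) {
    n <- length(chars)
    meanIndel <- 1.5
    pi0 <- pIns / meanIndel
    pd0 <- pDel / meanIndel
    u <- runif(n)
    sub <- which(u < pSub)
    ins <- which(u >= pSub & u < pSub + pi0)
    del <- which(u >= pSub + pi0 & u < pSub + pi0 + pd0)
    if (length(sub)) {
        shift <- sample.int(3L, length(sub), replace = TRUE)
        cur <- match(chars[sub], alphabet4)
        cur[is.na(cur)] <- 1L          # N and friends substitute from A
        chars[sub] <- alphabet4[(cur - 1L + shift) %% 4L + 1L]
    }
    nIns <- 0L
    keep <- rep(TRUE, n)
    insTxt <- character(0); insAt <- integer(0)
    if (length(del)) {
        lens <- rgeom(length(del), 2 / 3) + 1L
        for (k in seq_along(del)) {
            to <- min(n, del[k] + lens[k] - 1L)
            keep[del[k]:to] <- FALSE
        }
    }
    if (length(ins)) {
        lens <- rgeom(length(ins), 2 / 3) + 1L
        insTxt <- vapply(lens, function(l)
            paste0(sample(alphabet4, l, replace = TRUE), collapse = ""),
            character(1))
        insAt <- ins
        nIns <- sum(lens)
    }
    pieces <- ifelse(keep, chars, "")
    if (length(insAt))
        pieces[insAt] <- paste0(insTxt, pieces[insAt])
    out <- .chars(paste0(pieces, collapse = ""))
    attr(out, "events") <- c(sub = length(sub), ins = nIns,
                             del = sum(!keep), sites = n)
    out
}

#' Generate a synthetic document collection
#'
#' Draws one uniform random ancestor, derives a class ancestor per class
#' at the between-class divergence, and \code{docsPerClass} genomes per
#' class at the within-class divergence.  Genomes of a class are
#' concatenated into one document (one document = one class), mirroring
#' pangenome usage where a class is a group of related genomes.
#'
#' @param config a \code{"docarrayConfig"} from [datasetConfig()].
#' @return list with \code{collection} (a [DocumentCollection-class] with
#'   one document per class), \code{records} (named character vector of
#'   the individual genomes) and \code{recordClass} (class label of each
#'   record).  Deterministic given \code{config$seed}.
#' @export
generateCollection <- function(config) {
    stopifnot(inherits(config, "docarrayConfig"))
    set.seed(config$seed)
    a4 <- c("A", "C", "G", "T")
    anc <- sample(a4, config$ancestorLength, replace = TRUE)
    bt <- config$betweenClassDivergence
    wi <- config$withinClassDivergence
    f <- config$indelFrac
    recs <- character(0); recClass <- character(0)
    for (k in seq_len(config$nClasses)) {
        lab <- paste0("class", k)
        ck <- .mutateChars(anc, pSub = bt * (1 - f), pIns = bt * f / 2,
                           pDel = bt * f / 2)
        for (g in seq_len(config$docsPerClass)) {
            gk <- if (wi > 0)
                .mutateChars(ck, pSub = wi * (1 - f), pIns = wi * f / 2,
                             pDel = wi * f / 2)
            else ck
            recs <- c(recs,
                      stats::setNames(paste0(gk, collapse = ""),
                                      sprintf("%s_g%d", lab, g)))
            recClass <- c(recClass, lab)
        }
    }
    docs <- vapply(unique(recClass), function(l)
        paste0(recs[recClass == l], collapse = ""), character(1))
    list(collection = DocumentCollection(docs, labels = unique(recClass)),
         records = recs, recordClass = recClass)
}

#' Simulate error-bearing long reads from a collection
#'
#' Draws \code{readsPerClass} reads per class with uniform start positions
#' in the class document, then applies a per-base error process at rate
#' \code{1 - accuracy}, split 50:25:25 between substitutions, insertions
#' and deletions (geometric indel lengths, mean 1.5).  The true class of
#' every read is recorded.
#'
#' @param dataset result of [generateCollection()], or a
#'   [DocumentCollection-class].
#' @param config a \code{"docarrayConfig"}.
#' @return data.frame with \code{read_id}, \code{true_label}, \code{seq};
#'   attribute \code{"events"} holds total substitution / insertion /
#'   deletion counts and sites, for generator self-checks.  Deterministic
#'   given \code{config$seed}.
#' @export
simulateReads <- function(dataset, config) {
    stopifnot(inherits(config, "docarrayConfig"))
    coll <- if (is(dataset, "DocumentCollection")) dataset
            else dataset$collection
    set.seed(config$seed + 500000L)
    err <- 1 - config$accuracy
    L <- config$readLength
    ids <- character(0); labs <- character(0); seqs <- character(0)
    ev <- c(sub = 0L, ins = 0L, del = 0L, sites = 0L)
    for (k in seq_len(nDocs(coll))) {
        doc <- .chars(coll@docs[k])
        if (length(doc) < L)
            stop("readLength exceeds the length of document ",
                 coll@labels[k])
        starts <- sample.int(length(doc) - L + 1L, config$readsPerClass,
                             replace = TRUE)
        for (i in seq_len(config$readsPerClass)) {
            frag <- doc[starts[i]:(starts[i] + L - 1L)]
            rd <- .mutateChars(frag, pSub = err / 2, pIns = err / 4,
                               pDel = err / 4)
            ev <- ev + attr(rd, "events")
            ids <- c(ids, sprintf("%s_read%d", coll@labels[k], i))
            labs <- c(labs, coll@labels[k])
            seqs <- c(seqs, paste0(rd, collapse = ""))
        }
    }
    out <- data.frame(read_id = ids, true_label = labs, seq = seqs,
                      stringsAsFactors = FALSE)
    attr(out, "events") <- ev
    out
}

#' Write a synthetic dataset to disk
#'
#' Writes the genome records as FASTA (class recorded in the header), the
#' record-to-class grouping TSV consumed by [readDocumentCollection()],
#' the reads as FASTQ (true class in the comment) and a JSON manifest
#' recording the configuration, including the seed.
#'
#' @param dataset result of [generateCollection()].
#' @param reads optional result of [simulateReads()].
#' @param dir output directory (created if needed).
#' @param config the \code{"docarrayConfig"} used (stored in the manifest).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir, reads = NULL, config = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "documents.fasta")
    seqs <- Biostrings::DNAStringSet(dataset$records)
    names(seqs) <- sprintf("%s class=%s", names(dataset$records),
                           dataset$recordClass)
    Biostrings::writeXStringSet(seqs, fa)
    tsv <- file.path(dir, "grouping.tsv")
    utils::write.table(data.frame(prefix = names(dataset$records),
                                  label = dataset$recordClass),
                       tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(fasta = fa, grouping = tsv)
    if (!is.null(reads)) {
        fq <- file.path(dir, "reads.fastq")
        rs <- Biostrings::DNAStringSet(reads$seq)
        names(rs) <- sprintf("%s class=%s", reads$read_id, reads$true_label)
        qs <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(l)
            strrep("I", l), character(1)))
        Biostrings::writeXStringSet(rs, fq, format = "fastq", qualities = qs)
        paths <- c(paths, reads = fq)
    }
    if (!is.null(config)) {
        mf <- file.path(dir, "manifest.json")
        jsonlite::write_json(unclass(config), mf, auto_unbox = TRUE,
                             digits = NA)
        paths <- c(paths, manifest = mf)
    }
    invisible(paths)
}

#' Read simulated reads back from FASTQ
#'
#' @param path FASTQ file written by [writeDataset()] (true class parsed
#'   from a \code{class=} tag in the header comment when present).
#' @return data.frame with \code{read_id}, \code{true_label} (NA when no
#'   tag), \code{seq}.
#' @export
readReadsFastq <- function(path) {
    rs <- Biostrings::readDNAStringSet(path, format = "fastq")
    hdr <- names(rs)
    id <- sub("\\s.*$", "", hdr)
    lab <- ifelse(grepl("class=", hdr),
                  sub(".*class=(\\S+).*", "\\1", hdr), NA_character_)
    data.frame(read_id = id, true_label = lab,
               seq = as.character(rs), stringsAsFactors = FALSE,
               row.names = NULL)
}
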