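#' MEM-length weights over documents
#'
#' Each reported (MEM, document) pair adds the MEM's length to that
#' document's weight.  The full-listing mode reports every document in the
#' MEM's listing; the one-document baseline reports a single document per
#' MEM, so its weights are a per-document lower bound of the full-listing
#' weights for the same MEMs.
#'
#' @param lens integer MEM lengths.
#' @param listings list (parallel to \code{lens}) of integer document
#'   indices reported for each MEM.
#' @param d number of documents.
#' @return numeric weight vector of length d.
#' @export
memWeights <- function(lens, listings, d) {
    stopifnot(d >= 1L, length(lens) == length(listings))
    w <- numeric(d)
    for (k in seq_along(lens))
        w[listings[[k]]] <- w[listings[[k]]] + lens[k]
    w
}

#' Classify one read by MEM-weighted document voting
#'
#' Extracts MEMs of length at least \code{minLen}, obtains each MEM's
#' documents (all containing documents in \code{"full"} mode; the single
#' [sampledDaLookup()] document in \code{"one_doc"} mode), weights
#' documents by MEM length and assigns the read to the document with the
#' largest total weight.  Ties, and reads with no surviving MEM, are
#' reported as \code{"unclassified"}.
#'
#' @param index a [DocProfileIndex-class].
#' @param read single read string.
#' @param mode \code{"full"} (full document listing per MEM) or
#'   \code{"one_doc"} (one document per MEM baseline).
#' @param minLen minimum MEM length (default 15).
#' @return list with \code{assigned} (label or \code{"unclassified"}),
#'   \code{weights} (named d-vector) and \code{nMems}.
#' @export
classifyRead <- function(index, read, mode = c("full", "one_doc"),
                         minLen = 15L) {
    mode <- match.arg(mode)
    d <- nDocs(index)
    if (d == 0L) stop("index has no documents")
    w <- numeric(d)
    nm <- 0L
    if (nchar(read) >= minLen) {
        fm <- findMems(index, read, minLen)
        lens <- fm$mems$len
        nm <- length(lens)
        if (nm > 0L) {
            listings <- if (mode == "full") {
                lapply(seq_len(nm), function(k)
                    which(fm$profiles[, k] >= lens[k]))
            } else {
                lapply(seq_len(nm), function(k)
                    sampledDaLookup(index,
                                    c(fm$mems$s[k], fm$mems$e[k])))
            }
            w <- memWeights(lens, listings, d)
        }
    }
    names(w) <- index@labels
    assigned <- "unclassified"
    if (nm > 0L && max(w) > 0) {
        top <- which(w == max(w))
        if (length(top) == 1L) assigned <- index@labels[top]
    }
    list(assigned = assigned, weights = w, nMems = nm)
}

#' Classify a batch of reads and summarise accuracy
#'
#' Applies [classifyRead()] to each read and, when true class labels are
#' supplied, tabulates the confusion matrix (true class by assigned class,
#' including \code{"unclassified"}), per-class recall and overall accuracy.
#' Unclassified reads count as errors.  The result is deterministic and
#' invariant to read order.
#'
#' @param index a [DocProfileIndex-class].
#' @param reads character vector of read sequences (names used as read ids).
#' @param trueLabels optional character vector of true class labels, which
#'   must all be labels of the index.
#' @param mode,minLen passed to [classifyRead()].
#' @return list with \code{assignments} (data.frame: read_id, true_label,
#'   assigned, weight of the top 3 documents), and, when true labels are
#'   given, \code{confusion}, \code{recall} and \code{accuracy}.
#' @export
classifyBatch <- function(index, reads, trueLabels = NULL,
                          mode = c("full", "one_doc"), minLen = 15L) {
    mode <- match.arg(mode)
    stopifnot(length(reads) >= 1L)
    if (!is.null(trueLabels)) {
        stopifnot(length(trueLabels) == length(reads))
        bad <- setdiff(unique(trueLabels), index@labels)
        if (length(bad))
            stop("true labels not in the index: ",
                 paste(bad, collapse = ", "))
    }
    ids <- if (!is.null(names(reads))) names(reads)
           else paste0("read", seq_along(reads))
    res <- lapply(reads, classifyRead, index = index, mode = mode,
                  minLen = minLen)
    assigned <- vapply(res, `[[`, character(1), "assigned")
    top3 <- t(vapply(res, function(x) {
        ws <- sort(x$weights, decreasing = TRUE)
        length(ws) <- 3L
        ifelse(is.na(ws), 0, ws)
    }, numeric(3)))
    out <- data.frame(read_id = ids,
                      true_label = if (is.null(trueLabels)) NA_character_
                                   else trueLabels,
                      assigned = assigned,
                      w1 = top3[, 1L], w2 = top3[, 2L], w3 = top3[, 3L],
                      stringsAsFactors = FALSE)
    ans <- list(assignments = out, mode = mode)
    if (!is.null(trueLabels)) {
        lv <- c(index@labels, "unclassified")
        conf <- table(factor(trueLabels, levels = index@labels),
                      factor(assigned, levels = lv))
        names(dimnames(conf)) <- c("true", "assigned")
        correct <- assigned == trueLabels
        ans$confusion <- conf
        ans$recall <- diag(conf[, index@labels, drop = FALSE]) /
            rowSums(conf)
        ans$accuracy <- mean(correct)
        ans$errorRate <- 1 - ans$accuracy
    }
    ans
}
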