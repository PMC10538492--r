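#' Create a document collection
#'
#' @param docs character vector of document strings (one per class).
#' @param labels class labels; defaults to \code{names(docs)} or
#'   \code{doc1..docd}.
#' @param alphabet allowed symbols; defaults to A, C, G, T, N.  Documents
#'   containing the separator \code{"#"} or symbols outside the alphabet
#'   are rejected.
#' @return a [DocumentCollection-class].
#' @examples
#' dc <- DocumentCollection(c(s1 = "GATTA", s2 = "GATA", s3 = "TAGA"))
#' nDocs(dc)
#' @export
DocumentCollection <- function(docs, labels = NULL, alphabet = DNA_ALPHABET) {
    nms <- names(docs)
    docs <- as.character(docs)
    if (is.null(labels))
        labels <- if (!is.null(nms)) nms else paste0("doc", seq_along(docs))
    new("DocumentCollection", docs = unname(docs),
        labels = as.character(labels), alphabet = alphabet)
}

#' Read a document collection from FASTA
#'
#' Each file becomes one document (its records concatenated), labelled by
#' the file name, unless a two-column grouping table maps record names to
#' class labels, in which case records sharing a label are concatenated
#' into one document.  This mirrors pangenome usage where a class is a
#' collection of related genomes.
#'
#' @param paths FASTA file path(s).
#' @param grouping optional path to a two-column TSV (no header):
#'   record-name prefix, class label.  A record belongs to the first row
#'   whose prefix matches the start of its name.
#' @param alphabet allowed symbols (default A, C, G, T, N); sequences are
#'   uppercased first.
#' @return a [DocumentCollection-class].
#' @export
readDocumentCollection <- function(paths, grouping = NULL,
                                   alphabet = DNA_ALPHABET) {
    recs <- character(0)
    src <- character(0)
    for (p in paths) {
        ss <- Biostrings::readDNAStringSet(p)
        if (length(ss) == 0L) stop("no records in ", p)
        v <- toupper(as.character(ss))
        nm <- sub("\\s.*$", "", names(ss))
        recs <- c(recs, stats::setNames(v, nm))
        src <- c(src, rep(p, length(ss)))
    }
    if (is.null(grouping)) {
        lab <- sub("\\.(fa|fasta|fna)$", "", basename(src))
        docs <- vapply(unique(lab), function(l)
            paste0(recs[lab == l], collapse = ""), character(1))
        return(DocumentCollection(docs, labels = unique(lab),
                                  alphabet = alphabet))
    }
    g <- utils::read.delim(grouping, header = FALSE,
                           col.names = c("prefix", "label"),
                           stringsAsFactors = FALSE)
    labOf <- function(nm) {
        hit <- which(startsWith(nm, g$prefix))
        if (!length(hit)) stop("record '", nm, "' matches no grouping prefix")
        g$label[hit[1L]]
    }
    lab <- vapply(names(recs), labOf, character(1))
    ulab <- unique(g$label[g$label %in% lab])
    docs <- vapply(ulab, function(l) paste0(recs[lab == l], collapse = ""),
                   character(1))
    DocumentCollection(docs, labels = ulab, alphabet = alphabet)
}

#' Concatenate a collection with per-document separators
#'
#' Joins the documents in order, appending one separator \code{"#"} to
#' each, and records the document boundary map.  Separators compare
#' smaller than every alphabet symbol and, between themselves, by text
#' position (earlier smaller), so all suffixes of the result are distinct.
#'
#' @param collection a [DocumentCollection-class].
#' @return a [ConcatenatedText-class].
#' @examples
#' ct <- concatenateDocs(DocumentCollection(c("AC", "A")))
#' textLength(ct)  # 2 + 1 + 2 = 5
#' @export
concatenateDocs <- function(collection) {
    stopifnot(is(collection, "DocumentCollection"))
    validObject(collection)
    lens <- nchar(collection@docs)
    docStart <- as.integer(cumsum(c(1L, lens[-length(lens)] + 1L)))
    text <- paste0(paste0(collection@docs, DOC_SEP), collapse = "")
    new("ConcatenatedText", text = text, docStart = docStart,
        n = nchar(text), labels = collection@labels,
        alphabet = collection@alphabet)
}

#' Document containing a text position
#'
#' @param x a [ConcatenatedText-class].
#' @param pos 1-based position(s) in the concatenation; a document's
#'   trailing separator belongs to that document.
#' @return integer document indices in 1..d.
#' @export
docOf <- function(x, pos) {
    stopifnot(is(x, "ConcatenatedText"), all(pos >= 1L), all(pos <= x@n))
    findInterval(pos, x@docStart)
}
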