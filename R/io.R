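#' Read a scored interaction table
#'
#' Parses STITCH/STRING-style tab-separated tables (source id, target
#' id, combined score; header optional) into interaction records.
#' Combined scores printed on the 0-1000 integer scale are auto-detected
#' (any score greater than 1) and divided by 1000, so a table and its
#' rescaling filter identically at equal thresholds. Records are kept
#' only when the normalized score is strictly greater than
#' \code{scoreThreshold}; self-loops are dropped and duplicate
#' (source, target) pairs are collapsed keeping the maximum score.
#'
#' @param path path to a TSV file with at least 3 columns.
#' @param kind \code{"chemical-protein"} or \code{"protein-protein"};
#'   for protein-protein tables the pair is treated as unordered when
#'   collapsing duplicates.
#' @param scoreThreshold strict lower cutoff on the normalized score,
#'   in [0,1]. The conventional values are 0.4 for chemical-protein and
#'   0.7 for protein-protein confidence.
#' @param scoreScale \code{"auto"} (default), \code{"unit"} (scores
#'   already in [0,1]) or \code{"per-mille"} (force division by 1000).
#' @return data.frame with columns \code{source_id}, \code{target_id},
#'   \code{score}, \code{kind}, sorted by (source, target).
#' @export
readInteractionTable <- function(path, kind = c("chemical-protein", "protein-protein"),
                                 scoreThreshold,
                                 scoreScale = c("auto", "unit", "per-mille")) {
  kind <- match.arg(kind)
  scoreScale <- match.arg(scoreScale)
  if (!is.numeric(scoreThreshold) || length(scoreThreshold) != 1 ||
      is.na(scoreThreshold) || scoreThreshold < 0 || scoreThreshold > 1)
    stop("scoreThreshold must be a single number in [0,1]")
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(source_id = character(), target_id = character(),
                      score = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("line %d: expected at least 3 tab-separated columns, got %d",
                 which(nf < 3)[1], nf[which(nf < 3)[1]]))
  first_line <- 1L
  if (suppressWarnings(is.na(as.numeric(fields[[1]][3])))) first_line <- 2L  # header
  if (first_line > length(fields)) return(empty)
  rows <- fields[first_line:length(fields)]
  src <- vapply(rows, `[`, character(1), 1L)
  tgt <- vapply(rows, `[`, character(1), 2L)
  sc_raw <- vapply(rows, `[`, character(1), 3L)
  sc <- suppressWarnings(as.numeric(sc_raw))
  if (anyNA(sc)) {
    bad <- which(is.na(sc))[1]
    stop(sprintf("line %d: non-numeric score '%s'",
                 bad + first_line - 1L, sc_raw[bad]))
  }
  if (scoreScale == "per-mille" || (scoreScale == "auto" && any(sc > 1)))
    sc <- sc / 1000
  if (any(sc < 0 | sc > 1))
    stop("scores outside [0,1] after normalization")
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]; sc <- sc[keep]
  if (kind == "protein-protein") {  # unordered pair
    a <- pmin(src, tgt); b <- pmax(src, tgt)
    src <- a; tgt <- b
  }
  keep <- sc > scoreThreshold
  src <- src[keep]; tgt <- tgt[keep]; sc <- sc[keep]
  if (!length(src)) return(empty)
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    mx <- tapply(sc, key, max)
    first <- !duplicated(key)
    src <- src[first]; tgt <- tgt[first]; key <- key[first]
    sc <- as.numeric(mx[key])
  }
  o <- order(src, tgt)
  data.frame(source_id = src[o], target_id = tgt[o], score = sc[o],
             kind = kind, stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, term name, then one member symbol per
#' field, tab-separated. Members are uppercased and deduplicated. The
#' background size defaults to the size of the union of all member
#' sets.
#'
#' @param path path to a GMT file.
#' @param backgroundSize optional integer overriding the default
#'   background universe size (e.g. a genome-wide gene count).
#' @return an [AnnotationSet-class].
#' @export
readGeneSets <- function(path, backgroundSize = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("no terms in GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("line %d: GMT line needs term id, term name and at least one member",
                 which(nf < 3)[1]))
  termId <- vapply(fields, `[`, character(1), 1L)
  termName <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  if (anyDuplicated(termId))
    stop(sprintf("duplicate term id in GMT: %s", termId[duplicated(termId)][1]))
  bg <- if (is.null(backgroundSize))
    length(unique(unlist(members))) else as.integer(backgroundSize)
  methods::new("AnnotationSet", termId = termId, termName = termName,
               members = members, backgroundSize = as.integer(bg))
}

#' Accessors for AnnotationSet objects
#'
#' @param x an [AnnotationSet-class].
#' @return \code{termIds}/\code{termNames}: character vectors;
#'   \code{termMembers}: named list of member symbol vectors;
#'   \code{backgroundSize}: integer N; \code{backgroundSymbols}: the
#'   union of all member sets (sorted).
#' @name AnnotationSet-accessors
NULL

#' @rdname AnnotationSet-accessors
#' @export
setMethod("termIds", "AnnotationSet", function(x) x@termId)

#' @rdname AnnotationSet-accessors
#' @export
setMethod("termNames", "AnnotationSet", function(x) x@termName)

#' @rdname AnnotationSet-accessors
#' @export
setMethod("termMembers", "AnnotationSet", function(x)
  stats::setNames(x@members, x@termId))

#' @rdname AnnotationSet-accessors
#' @export
setMethod("backgroundSize", "AnnotationSet", function(x) x@backgroundSize)

#' @rdname AnnotationSet-accessors
#' @export
setMethod("backgroundSymbols", "AnnotationSet", function(x)
  sort(unique(unlist(x@members))))

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d terms, background N = %d\n",
              length(object@termId), object@backgroundSize))
  invisible(NULL)
})

#' Read a one-symbol-per-line target list
#'
#' @param path path to a text file, one gene symbol per line.
#' @return sorted character vector of unique uppercase symbols.
#' @export
readTargetList <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  x <- trimws(readLines(path))
  sort(unique(toupper(x[nzchar(x)])))
}

#' Read a herb-compound membership table
#'
#' Three tab-separated columns: herb label, compound id, compound name
#' (header optional, detected by the literal column names).
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{herb_label},
#'   \code{compound_id}, \code{compound_name}; (herb, compound) pairs
#'   unique.
#' @export
readHerbCompoundTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3) stop("herb-compound table needs 3 columns")
  if (tolower(df[1, 1]) %in% c("herb", "herb_label")) df <- df[-1, , drop = FALSE]
  df <- df[, 1:3]
  names(df) <- c("herb_label", "compound_id", "compound_name")
  if (any(!nzchar(df$herb_label))) stop("empty herb label")
  if (anyDuplicated(df[, c("herb_label", "compound_id")]))
    stop("duplicate (herb, compound) pair in table")
  rownames(df) <- NULL
  df
}

#' Read an identifier-mapping table
#'
#' Two tab-separated columns: raw identifier, official gene symbol.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{raw_id}, \code{symbol}.
#' @export
readIdMapping <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("mapping table needs 2 columns")
  if (tolower(df[1, 1]) %in% c("raw_id", "id")) df <- df[-1, , drop = FALSE]
  df <- df[, 1:2]
  names(df) <- c("raw_id", "symbol")
  .checkMapping(df)
  rownames(df) <- NULL
  df
}

.checkMapping <- function(mapping) {
  stopifnot(is.data.frame(mapping), all(c("raw_id", "symbol") %in% names(mapping)))
  if (any(!nzchar(mapping$symbol))) stop("mapping contains empty symbols")
  conflict <- unique(mapping$raw_id[duplicated(mapping$raw_id)])
  if (length(conflict)) {
    for (id in conflict) {
      syms <- unique(mapping$symbol[mapping$raw_id == id])
      if (length(syms) > 1)
        stop(sprintf("conflicting mapping for raw id '%s': %s",
                     id, paste(syms, collapse = ", ")))
    }
  }
  invisible(mapping)
}

#' Map raw target identifiers to official gene symbols
#'
#' Replaces every mappable \code{target_id} in a set of interaction
#' records by its official symbol (uppercased). Unmapped identifiers
#' are dropped (default) or passed through verbatim; the number of
#' unmapped ids is reported via \code{message()}.
#'
#' @param records interaction record data.frame as returned by
#'   [readInteractionTable()].
#' @param mapping data.frame with columns \code{raw_id}, \code{symbol}.
#' @param policy \code{"drop"} (default) or \code{"keep_raw"}.
#' @return the records with \code{target_id} replaced by symbols.
#' @export
mapIdentifiers <- function(records, mapping, policy = c("drop", "keep_raw")) {
  policy <- match.arg(policy)
  .checkMapping(mapping)
  mapping <- mapping[!duplicated(mapping$raw_id), , drop = FALSE]
  lut <- stats::setNames(toupper(mapping$symbol), mapping$raw_id)
  hit <- records$target_id %in% names(lut)
  n_unmapped <- length(unique(records$target_id[!hit]))
  if (n_unmapped > 0)
    message(sprintf("mapIdentifiers: %d unmapped identifier(s) %s",
                    n_unmapped,
                    if (policy == "drop") "dropped" else "kept verbatim"))
  out <- records
  out$target_id[hit] <- unname(lut[out$target_id[hit]])
  if (policy == "drop") out <- out[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
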