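#' Seed alignment for the p20-like profile
#'
#' A small multiple alignment of p20-like sub-domain sequences from which the
#' position-specific scoring profile is built. Rows are equal-length aligned
#' amino-acid strings with `-` as the gap character; `hCol` and `cCol` give
#' the 1-based alignment columns of the catalytic histidine and cysteine.
#'
#' @slot rows character vector of aligned rows (equal length, gaps as `-`).
#' @slot hCol integer, alignment column of the catalytic histidine.
#' @slot cCol integer, alignment column of the catalytic cysteine.
#' @exportClass SeedAlignment
setClass("SeedAlignment",
  representation(rows = "character", hCol = "integer", cCol = "integer"))

setValidity("SeedAlignment", function(object) {
  msg <- character()
  if (length(object@rows) < 2) msg <- c(msg, "need at least 2 aligned rows")
  w <- unique(nchar(object@rows))
  if (length(w) != 1) msg <- c(msg, "rows must all have equal length")
  else {
    if (object@hCol < 1L || object@cCol > w)
      msg <- c(msg, "dyad columns outside the alignment")
    if (object@hCol >= object@cCol) msg <- c(msg, "hCol must be < cCol")
    colres <- function(j) {
      r <- substring(object@rows, j, j)
      r[r != "-"]
    }
    maj <- function(j) {
      r <- colres(j)
      if (!length(r)) "-" else names(which.max(table(r)))
    }
    if (length(msg) == 0) {
      if (maj(object@hCol) != "H")
        msg <- c(msg, "majority residue at hCol is not H")
      if (maj(object@cCol) != "C")
        msg <- c(msg, "majority residue at cCol is not C")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Position-specific scoring profile for the p20-like sub-domain
#'
#' Log-odds scores per match column for the 20 standard residues (plus a
#' zero-scoring row for the ambiguity letters X/B/Z), with affine gap
#' penalties, the match-column indices of the catalytic dyad, the consensus
#' sequence, its self-score, and the minimum reported hit score.
#'
#' @slot scores numeric matrix, 21 rows (20 residues + ambiguity) by
#'   `length` match columns, log2 odds.
#' @slot gapOpen,gapExtend negative reals, affine gap penalties.
#' @slot hCol,cCol integer match-column indices of the catalytic dyad.
#' @slot consensus character, per-column argmax residue string.
#' @slot selfScore numeric, local-alignment score of the consensus against
#'   the profile (the maximum attainable hit score).
#' @slot threshold numeric, minimum reported hit score.
#' @slot background numeric length-20 background composition.
#' @exportClass P20Profile
setClass("P20Profile",
  representation(scores = "matrix", gapOpen = "numeric", gapExtend = "numeric",
                 hCol = "integer", cCol = "integer", consensus = "character",
                 selfScore = "numeric", threshold = "numeric",
                 background = "numeric"))

setValidity("P20Profile", function(object) {
  msg <- character()
  L <- ncol(object@scores)
  if (nrow(object@scores) != 21L) msg <- c(msg, "scores must have 21 rows")
  if (L < 2L) msg <- c(msg, "profile needs at least 2 match columns")
  if (!(object@hCol >= 1L && object@hCol < object@cCol && object@cCol <= L))
    msg <- c(msg, "dyad columns must satisfy 1 <= hCol < cCol <= length")
  if (object@gapOpen >= 0 || object@gapExtend >= 0)
    msg <- c(msg, "gap penalties must be negative")
  if (length(object@threshold) == 1 && length(object@selfScore) == 1 &&
      object@threshold >= object@selfScore)
    msg <- c(msg, "threshold must be below the profile self-score")
  if (length(msg)) msg else TRUE
})

#' Whole-protein domain architecture
#'
#' The ordered domain content of one p20-containing protein: its p20 hit(s),
#' accessory domains and predicted transmembrane segments, the N-to-C
#' architecture string, and the set of accessory domain names after
#' collapsing successive repeats.
#'
#' @slot proteinId character protein identifier.
#' @slot elements data.frame with columns `name`, `start`, `end`, sorted by
#'   `start` (1-based inclusive residue coordinates).
#' @slot architectureString character, element names joined N-to-C.
#' @slot uniqueDomains character vector of accessory names (excludes
#'   `p20` and `TM`).
#' @slot multiP20 logical, TRUE when the protein carries more than one p20
#'   hit.
#' @exportClass DomainArchitecture
setClass("DomainArchitecture",
  representation(proteinId = "character", elements = "data.frame",
                 architectureString = "character", uniqueDomains = "character",
                 multiP20 = "logical"))

setValidity("DomainArchitecture", function(object) {
  el <- object@elements
  msg <- character()
  if (!all(c("name", "start", "end") %in% names(el)))
    msg <- c(msg, "elements needs columns name, start, end")
  else {
    if (nrow(el) && any(el$start > el$end)) msg <- c(msg, "start > end element")
    if (is.unsorted(el$start)) msg <- c(msg, "elements must be sorted by start")
    if (any(object@uniqueDomains %in% c("p20", "TM")))
      msg <- c(msg, "uniqueDomains must exclude p20 and TM")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "SeedAlignment", function(object) {
  cat("SeedAlignment with", length(object@rows), "rows x",
      nchar(object@rows[1]), "columns\n")
  cat("  catalytic columns: H =", object@hCol, ", C =", object@cCol, "\n")
})

setMethod("show", "P20Profile", function(object) {
  cat("P20Profile with", ncol(object@scores), "match columns\n")
  cat("  dyad columns: H =", object@hCol, ", C =", object@cCol, "\n")
  cat("  consensus:", substr(object@consensus, 1, 60),
      if (nchar(object@consensus) > 60) "..." else "", "\n")
  cat(sprintf("  self-score %.2f, threshold %.2f, gaps (%g, %g)\n",
              object@selfScore, object@threshold, object@gapOpen,
              object@gapExtend))
})

setMethod("show", "DomainArchitecture", function(object) {
  cat("DomainArchitecture for", object@proteinId, "\n")
  cat("  ", object@architectureString, "\n")
})

## ---- accessors ------------------------------------------------------------

#' Profile accessors
#'
#' @param x a [P20Profile-class] object.
#' @return `profileLength` the number of match columns; `dyadColumns` a named
#'   integer vector with the H and C match columns; `selfScore` the consensus
#'   self-alignment score; `scoreThreshold` the minimum reported hit score;
#'   `consensusSequence` the per-column argmax residue string.
#' @name profile-accessors
#' @examples
#' prof <- buildProfile(exampleSeedAlignment())
#' profileLength(prof)
#' dyadColumns(prof)
NULL

#' @rdname profile-accessors
#' @export
profileLength <- function(x) ncol(x@scores)

#' @rdname profile-accessors
#' @export
dyadColumns <- function(x) c(h = x@hCol, c = x@cCol)

#' @rdname profile-accessors
#' @export
selfScore <- function(x) x@selfScore

#' @rdname profile-accessors
#' @export
scoreThreshold <- function(x) x@threshold

#' Set the minimum reported hit score of a profile
#'
#' @param x a [P20Profile-class].
#' @param value new threshold, must be below `selfScore(x)`.
#' @return the updated profile.
#' @export
`scoreThreshold<-` <- function(x, value) {
  x@threshold <- as.numeric(value)
  validObject(x)
  x
}

#' @rdname profile-accessors
#' @export
consensusSequence <- function(x) x@consensus

#' Architecture accessors
#'
#' @param x a [DomainArchitecture-class] object.
#' @return `architectureString` the N-to-C element string;
#'   `uniqueDomains` the accessory domain names after repeat collapsing;
#'   `archElements` the ordered element table.
#' @name architecture-accessors
NULL

#' @rdname architecture-accessors
#' @export
architectureString <- function(x) x@architectureString

#' @rdname architecture-accessors
#' @export
uniqueDomains <- function(x) x@uniqueDomains

#' @rdname architecture-accessors
#' @export
archElements <- function(x) x@elements
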