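## Position-specific scoring profile for the p20-like sub-domain: built from
## a seed alignment, calibrated on shuffled background, scanned against
## proteomes with an affine-gap local aligner (see src/scan.cpp).

#' Construct a seed alignment
#'
#' @param rows character vector of equal-length aligned amino-acid strings
#'   (gap `-`).
#' @param hCol,cCol 1-based alignment columns of the catalytic histidine and
#'   cysteine.
#' @return a [SeedAlignment-class] object.
#' @export
SeedAlignment <- function(rows, hCol, cCol) {
  methods::new("SeedAlignment", rows = toupper(rows),
               hCol = as.integer(hCol), cCol = as.integer(cCol))
}

#' Read a seed alignment from aligned FASTA plus a column sidecar
#'
#' The sidecar TSV has two lines, `h_col<TAB>n` and `c_col<TAB>m`, naming the
#' catalytic alignment columns.
#'
#' @param fastaPath aligned FASTA (equal-length rows, `-` gaps).
#' @param colsPath the 2-line sidecar TSV.
#' @return a [SeedAlignment-class].
#' @export
readSeedAlignment <- function(fastaPath, colsPath) {
  aln <- Biostrings::readAAMultipleAlignment(fastaPath, format = "fasta")
  rows <- as.character(Biostrings::AAStringSet(aln))
  side <- utils::read.delim(colsPath, header = FALSE,
                            stringsAsFactors = FALSE)
  vals <- stats::setNames(as.integer(side[[2]]), side[[1]])
  if (!all(c("h_col", "c_col") %in% names(vals)))
    stop("sidecar must name h_col and c_col")
  SeedAlignment(unname(rows), vals[["h_col"]], vals[["c_col"]])
}

#' The seed alignment bundled with the package
#'
#' A 10-row synthetic alignment built from the package's designed p20
#' template (see [defaultSimulationConfig()]); user-replaceable via
#' [readSeedAlignment()].
#'
#' @return a [SeedAlignment-class].
#' @export
exampleSeedAlignment <- function() {
  readSeedAlignment(
    system.file("extdata", "p20_seed_synthetic.afa", package = "ocascan"),
    system.file("extdata", "p20_seed_synthetic_cols.tsv", package = "ocascan"))
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' Per match column the log-odds score of residue `a` is
#' `log2((count_a + pseudocount * bg_a) / (total + pseudocount) / bg_a)`
#' against a fixed background composition. Alignment columns with more than
#' 50\% gaps are dropped from the match states and the dyad columns are
#' re-indexed to the surviving columns; a dyad column removed by the gap rule
#' makes the seed unusable. Ambiguity letters (X/B/Z) are excluded from the
#' counts and score zero during scanning. The consensus sequence (per-column
#' argmax) is aligned back against the profile to fix `selfScore`; the
#' initial reporting threshold is half the self-score and is normally
#' replaced via [calibrateThreshold()].
#'
#' @param seed a [SeedAlignment-class].
#' @param pseudocount positive real added as `pseudocount * bg_a` per
#'   residue; default 1.
#' @param background length-20 residue composition (default uniform 1/20).
#' @param gapOpen,gapExtend affine gap penalties (negative; defaults -11, -1).
#' @return a [P20Profile-class].
#' @examples
#' prof <- buildProfile(exampleSeedAlignment())
#' prof
#' @export
buildProfile <- function(seed, pseudocount = 1,
                         background = rep(1 / 20, 20),
                         gapOpen = -11, gapExtend = -1) {
  stopifnot(methods::is(seed, "SeedAlignment"), pseudocount > 0,
            length(background) == 20, all(background > 0))
  background <- background / sum(background)
  names(background) <- AMINO_ACIDS
  chars <- do.call(rbind, strsplit(seed@rows, ""))
  W <- ncol(chars)
  gapFrac <- colMeans(chars == "-")
  keep <- gapFrac <= 0.5
  if (!keep[seed@hCol] || !keep[seed@cCol])
    stop("seed unusable: a catalytic column is dropped by the >50% gap rule")
  scores <- matrix(0, nrow = 21L, ncol = sum(keep),
                   dimnames = list(c(AMINO_ACIDS, "X"), NULL))
  cols <- which(keep)
  for (k in seq_along(cols)) {
    col <- chars[, cols[k]]
    col <- col[col %in% AMINO_ACIDS]
    cnt <- table(factor(col, levels = AMINO_ACIDS))
    tot <- sum(cnt)
    freq <- (as.numeric(cnt) + pseudocount * background) /
      (tot + pseudocount)
    scores[1:20, k] <- log2(freq / background)
  }
  newIndex <- cumsum(keep)
  cons <- apply(scores[1:20, , drop = FALSE], 2,
                function(s) AMINO_ACIDS[which.max(s)])
  prof <- methods::new("P20Profile", scores = scores,
                       gapOpen = as.numeric(gapOpen),
                       gapExtend = as.numeric(gapExtend),
                       hCol = as.integer(newIndex[seed@hCol]),
                       cCol = as.integer(newIndex[seed@cCol]),
                       consensus = paste(cons, collapse = ""),
                       selfScore = 1, threshold = 0,
                       background = unname(background))
  self <- bestLocalScore(prof, prof@consensus)
  prof@selfScore <- self
  prof@threshold <- self / 2
  validObject(prof)
  prof
}

encodeQuery <- function(sequence) {
  codes <- match(strsplit(sequence, "")[[1]], AMINO_ACIDS)
  codes[is.na(codes)] <- 21L  # ambiguity letters score 0
  as.integer(codes)
}

bestLocalScore <- function(profile, sequence) {
  .sw_best_hit(encodeQuery(sequence), profile@scores, profile@gapOpen,
               profile@gapExtend, logical(nchar(sequence)))$score
}

#' Calibrate the hit-score threshold on background proteins
#'
#' Scans each background protein (shuffled or simulated, carrying no planted
#' domain), collects the best local-alignment score per protein, and returns
#' the requested empirical quantile. By contract the fraction of background
#' best-hit scores at or above the returned value is approximately
#' `1 - quantile`.
#'
#' @param profile a [P20Profile-class].
#' @param backgroundProteins protein table (`sequence` column) with at least
#'   100 rows.
#' @param quantile probability in (0, 1); default 0.999.
#' @return the score threshold (numeric scalar).
#' @seealso [makeShuffledBackground()] to build the background set.
#' @export
calibrateThreshold <- function(profile, backgroundProteins,
                               quantile = 0.999) {
  stopifnot(methods::is(profile, "P20Profile"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  seqs <- backgroundProteins$sequence
  if (length(seqs) < 100)
    stop("need at least 100 background proteins, got ", length(seqs))
  best <- vapply(seqs, function(s) bestLocalScore(profile, s), 0.0,
                 USE.NAMES = FALSE)
  unname(stats::quantile(best, probs = quantile, type = 7))
}

#' Residue-shuffled background proteins
#'
#' Draws `n` proteins (with replacement) from a study's protein table and
#' permutes the residues of each, preserving composition and length while
#' destroying any planted domain.
#'
#' @param proteins protein table with a `sequence` column.
#' @param n number of background proteins; default 1000.
#' @param seed integer seed; all randomness flows from it.
#' @return data.frame with `protein_id` and `sequence`.
#' @export
makeShuffledBackground <- function(proteins, n = 1000, seed) {
  stopifnot(nrow(proteins) >= 1)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(proteins), n, replace = TRUE)
  seqs <- vapply(proteins$sequence[idx], function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
  data.frame(protein_id = sprintf("shuf%04d", seq_len(n)), sequence = seqs,
             stringsAsFactors = FALSE)
}

emptyHits <- function() {
  data.frame(strain_id = character(), protein_id = character(),
             start = integer(), end = integer(), score = numeric(),
             col_map = I(list()), stringsAsFactors = FALSE)
}

#' Scan one protein for p20-like sub-domain hits
#'
#' Local (Smith-Waterman-style) alignment of the profile match columns
#' against the query with affine gaps; query insertions carry gap costs but
#' no emission score. All non-overlapping hits scoring at least the
#' profile threshold are returned by greedy best-score-first extraction with
#' full masking of claimed residues; score ties resolve to the earlier hit.
#' Each hit records the mapping from profile match column to 1-based query
#' residue index (`NA` where the column is deleted in the query).
#'
#' @param profile a [P20Profile-class].
#' @param protein one-row protein table (or list) with `strain_id`,
#'   `protein_id`, `sequence`.
#' @param threshold minimum reported score; defaults to
#'   `scoreThreshold(profile)`.
#' @return hit table: `strain_id`, `protein_id`, `start`, `end`, `score`,
#'   plus a `col_map` list column; zero rows when nothing reaches the
#'   threshold.
#' @export
scanProtein <- function(profile, protein,
                        threshold = scoreThreshold(profile)) {
  seqc <- protein$sequence
  stopifnot(length(seqc) == 1, nzchar(seqc))
  q <- encodeQuery(seqc)
  mask <- logical(length(q))
  hits <- list()
  repeat {
    h <- .sw_best_hit(q, profile@scores, profile@gapOpen, profile@gapExtend,
                      mask)
    if (is.na(h$start) || h$score < threshold) break
    hits[[length(hits) + 1L]] <- h
    mask[h$start:h$end] <- TRUE
  }
  if (!length(hits)) return(emptyHits())
  out <- data.frame(
    strain_id = protein$strain_id, protein_id = protein$protein_id,
    start = vapply(hits, `[[`, 0L, "start"),
    end = vapply(hits, `[[`, 0L, "end"),
    score = vapply(hits, `[[`, 0.0, "score"),
    stringsAsFactors = FALSE)
  out$col_map <- I(lapply(hits, `[[`, "col_map"))
  out[order(out$start), , drop = FALSE]
}

#' Scan a whole protein table
#'
#' @inheritParams scanProtein
#' @param proteins protein table (`strain_id`, `protein_id`, `sequence`).
#' @return row-bound hit table as in [scanProtein()].
#' @export
scanProteins <- function(profile, proteins,
                         threshold = scoreThreshold(profile)) {
  res <- lapply(seq_len(nrow(proteins)), function(i)
    scanProtein(profile, proteins[i, ], threshold))
  res <- res[vapply(res, nrow, 0L) > 0]
  if (!length(res)) return(emptyHits())
  do.call(rbind, res)
}

#' Map the catalytic dyad columns of a hit onto query coordinates
#'
#' @param profile the [P20Profile-class] used for scanning.
#' @param colMap a hit's `col_map` (integer vector over match columns).
#' @return named integer vector `c(h = , c = )` of 1-based query positions;
#'   `NA` where the catalytic column is deleted in the query (unresolved).
#' @export
mapCatalyticPositions <- function(profile, colMap) {
  c(h = colMap[[profile@hCol]], c = colMap[[profile@cCol]])
}
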