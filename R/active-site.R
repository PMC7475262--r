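## Catalytic-dyad classification, specificity pockets, substitution tallies
## and degenerate pocket consensus patterns.

#' Extract the specificity pockets around the catalytic dyad
#'
#' The H-pocket is the 5-mer at offsets -3..+1 around the catalytic
#' histidine position (catalytic residue at unit 4); the C-pocket spans
#' offsets -2..+2 around the catalytic cysteine (catalytic residue at unit
#' 3). These are the unique 5-mer frames in which a conserved wild-type site
#' reads FSGHG and DTCHS. Offsets falling outside the sequence are padded
#' with `-`; an unresolved position yields `-----`.
#'
#' @param sequence the protein sequence.
#' @param hPos,cPos 1-based catalytic positions (`NA` when unresolved).
#' @return named character vector `c(h_pocket = , c_pocket = )`.
#' @examples
#' extractPockets("AAFSGHGKKDTCHSAA", hPos = 6, cPos = 12)
#' @export
extractPockets <- function(sequence, hPos, cPos) {
  window <- function(pos, lo, hi) {
    if (is.na(pos)) return("-----")
    idx <- (pos + lo):(pos + hi)
    ch <- strsplit(sequence, "")[[1]]
    out <- ifelse(idx >= 1 & idx <= length(ch), ch[pmax(idx, 1)], "-")
    paste(out, collapse = "")
  }
  c(h_pocket = window(hPos, -3L, 1L), c_pocket = window(cPos, -2L, 2L))
}

#' Classify a catalytic dyad
#'
#' A protein whose p20-like sub-domain carries histidine and cysteine at the
#' catalytic sites is a wild-type orthocaspase; any substitution makes it a
#' mutated pseudo-variant; a dyad position deleted in the hit alignment is
#' unresolved.
#'
#' @param hRes,cRes single residue letters, or `NA` when the position is
#'   unresolved.
#' @return list with `oca_class` (`wild_type`/`mutated`/`unresolved`) and
#'   `dyad_label` (two characters, `-` for an unresolved side).
#' @examples
#' classifyDyad("H", "C")  # wild type
#' classifyDyad("Y", "S")  # the modal mutated dyad
#' @export
classifyDyad <- function(hRes, cRes) {
  chk <- function(r) {
    if (is.na(r)) return(NA_character_)
    r <- toupper(r)
    if (!r %in% c(AMINO_ACIDS, AMBIGUOUS_AA))
      stop("not a residue letter: ", r)
    r
  }
  h <- chk(hRes); c <- chk(cRes)
  if (is.na(h) || is.na(c)) {
    label <- paste0(ifelse(is.na(h), "-", h), ifelse(is.na(c), "-", c))
    return(list(oca_class = "unresolved", dyad_label = label))
  }
  list(oca_class = if (h == "H" && c == "C") "wild_type" else "mutated",
       dyad_label = paste0(h, c))
}

#' Call active sites for a table of p20 hits
#'
#' Maps each hit's catalytic columns onto the query, reads the dyad
#' residues, extracts both specificity pockets and classifies the dyad.
#'
#' @param profile the [P20Profile-class] used for scanning.
#' @param hits hit table from [scanProteins()].
#' @param proteins protein table supplying the sequences.
#' @return calls table: `strain_id`, `protein_id`, `start`, `end`, `score`,
#'   `h_pos`, `c_pos`, `h_res`, `c_res`, `dyad_label`, `oca_class`,
#'   `h_pocket`, `c_pocket`.
#' @export
callActiveSites <- function(profile, hits, proteins) {
  key <- paste(proteins$strain_id, proteins$protein_id)
  out <- hits[setdiff(names(hits), "col_map")]
  n <- nrow(hits)
  cols <- c("h_pos", "c_pos")
  out$h_pos <- out$c_pos <- rep(NA_integer_, n)
  out$h_res <- out$c_res <- rep(NA_character_, n)
  out$dyad_label <- out$oca_class <- rep(NA_character_, n)
  out$h_pocket <- out$c_pocket <- rep("-----", n)
  for (i in seq_len(n)) {
    seqc <- proteins$sequence[match(paste(hits$strain_id[i],
                                          hits$protein_id[i]), key)]
    if (is.na(seqc)) stop("hit references unknown protein ",
                          hits$protein_id[i])
    pos <- mapCatalyticPositions(profile, hits$col_map[[i]])
    res <- function(p) if (is.na(p)) NA_character_ else substr(seqc, p, p)
    cl <- classifyDyad(res(pos[["h"]]), res(pos[["c"]]))
    pk <- extractPockets(seqc, pos[["h"]], pos[["c"]])
    out$h_pos[i] <- pos[["h"]]; out$c_pos[i] <- pos[["c"]]
    out$h_res[i] <- res(pos[["h"]]); out$c_res[i] <- res(pos[["c"]])
    out$dyad_label[i] <- cl$dyad_label; out$oca_class[i] <- cl$oca_class
    out$h_pocket[i] <- pk[["h_pocket"]]; out$c_pocket[i] <- pk[["c_pocket"]]
  }
  out
}

#' Tally dyad substitutions
#'
#' Counts residues observed at the H and C catalytic sites, full dyad
#' labels, and (when metadata is supplied) the same counts partitioned by
#' morphotype. Unresolved calls are excluded from all counts and reported
#' separately; percentages use the resolved-call denominator.
#'
#' @param calls calls table from [callActiveSites()].
#' @param metadata optional strain metadata for the morphotype partition.
#' @return list with `n_resolved`, `n_unresolved`, `h_site`, `c_site`,
#'   `dyads` (named count vectors), `dyad_pct` (percent of resolved calls),
#'   and `by_morphotype` (list of per-dyad count vectors) when metadata is
#'   given.
#' @export
tallySubstitutions <- function(calls, metadata = NULL) {
  resolved <- calls[calls$oca_class != "unresolved", , drop = FALSE]
  cnt <- function(x) {
    t <- table(x)
    v <- stats::setNames(as.integer(t), names(t))
    if (length(v)) v[order(-v, names(v))] else v
  }
  out <- list(
    n_resolved = nrow(resolved),
    n_unresolved = sum(calls$oca_class == "unresolved"),
    h_site = cnt(resolved$h_res),
    c_site = cnt(resolved$c_res),
    dyads = cnt(resolved$dyad_label))
  out$dyad_pct <- if (nrow(resolved))
    round(100 * out$dyads / nrow(resolved), 2) else numeric()
  if (!is.null(metadata)) {
    m <- match(resolved$strain_id, metadata$strain_id)
    if (anyNA(m))
      stop("call references unknown strain ",
           resolved$strain_id[is.na(m)][1])
    out$by_morphotype <- lapply(split(resolved$dyad_label,
                                      metadata$morphotype[m]), cnt)
  }
  out
}

#' Derive a degenerate pocket consensus
#'
#' Per pocket column, residues observed at frequency at least `minFreq`
#' among non-gap, non-ambiguous characters survive; a single survivor prints
#' as a plain letter, several as a parenthesised group ordered by descending
#' frequency (ties alphabetical). A column where nothing survives keeps its
#' single most frequent residue.
#'
#' @param pockets character vector of 5-character pocket strings.
#' @param minFreq frequency threshold in (0, 1]; default 0.05.
#' @return list with `pattern` (e.g. `"FSG(H/Y)G"`) and `min_freq`.
#' @examples
#' deriveConsensus(c(rep("FSGHG", 6), rep("FSGYG", 4)))
#' @export
deriveConsensus <- function(pockets, minFreq = 0.05) {
  if (!length(pockets)) stop("no pockets supplied")
  stopifnot(all(nchar(pockets) == 5), minFreq > 0, minFreq <= 1)
  chars <- do.call(rbind, strsplit(pockets, ""))
  units <- vapply(1:5, function(j) {
    col <- chars[, j]
    col <- col[col %in% AMINO_ACIDS]
    if (!length(col)) return("-")
    t <- table(col) / length(col)
    keep <- names(t)[t >= minFreq]
    if (!length(keep)) keep <- names(t)[which.max(t)]
    keep <- keep[order(-t[keep], keep)]
    if (length(keep) == 1) keep else
      paste0("(", paste(keep, collapse = "/"), ")")
  }, "")
  list(pattern = paste(units, collapse = ""), min_freq = minFreq)
}

parseConsensus <- function(pattern) {
  units <- list()
  i <- 1L; n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "(") {
      close <- regexpr(")", substr(pattern, i, n), fixed = TRUE)
      if (close < 0) stop("malformed consensus pattern: unbalanced '('")
      grp <- substr(pattern, i + 1, i + close - 2)
      alt <- strsplit(grp, "/", fixed = TRUE)[[1]]
      if (!length(alt) || any(nchar(alt) != 1))
        stop("malformed consensus group: (", grp, ")")
      units[[length(units) + 1L]] <- alt
      i <- i + close
    } else {
      units[[length(units) + 1L]] <- ch
      i <- i + 1L
    }
  }
  if (length(units) != 5) stop("consensus must have exactly 5 units")
  units
}

#' Match a pocket against a degenerate consensus pattern
#'
#' @param pattern a consensus pattern string (or the list returned by
#'   [deriveConsensus()]).
#' @param pocket 5-character pocket string.
#' @return TRUE iff every pocket character equals the plain letter or lies
#'   within the alternative group at its unit; `-` matches nothing.
#' @export
matchConsensus <- function(pattern, pocket) {
  if (is.list(pattern)) pattern <- pattern$pattern
  units <- parseConsensus(pattern)
  stopifnot(nchar(pocket) == 5)
  ch <- strsplit(pocket, "")[[1]]
  all(vapply(1:5, function(j) ch[j] %in% units[[j]], TRUE))
}
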